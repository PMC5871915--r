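test_that("planted-partition edges respect p_in and p_out", {
  # p_out = 0: no between-module edges; p_in = 1: complete modules
  cfg <- scenario_config(n_modules = 3L, module_size = 5L, p_in = 1,
                         p_out = 0, n_pathways = 3L, pathway_size = 5L,
                         n_patients = 10L, n_subgroups = 1L,
                         hazard_per_subgroup = 1, seed = 5L)
  net <- generate_network(cfg)
  mods <- net$modules
  cross <- mods[net$network$edges$from] != mods[net$network$edges$to]
  expect_identical(sum(cross), 0L)
  expect_equal(nrow(net$network$edges), 3 * choose(5, 2))
  # p_in = 0.3, 2 modules of 50: within-module count in the 99.9% binomial
  # band around 0.3 * C(50,2) per module
  cfg <- scenario_config(n_modules = 2L, module_size = 50L, p_in = 0.3,
                         p_out = 0, n_pathways = 2L, pathway_size = 10L,
                         n_patients = 10L, n_subgroups = 1L,
                         hazard_per_subgroup = 1, seed = 6L)
  net <- generate_network(cfg)
  n_within <- nrow(net$network$edges)
  trials <- 2 * choose(50, 2)
  band <- stats::qbinom(c(0.0005, 0.9995), trials, 0.3)
  expect_gte(n_within, band[1])
  expect_lte(n_within, band[2])
})

test_that("pathways have the configured size and module alignment", {
  cfg <- scenario_config(seed = 8L)
  net <- generate_network(cfg)
  pw <- generate_pathways(cfg, net$modules)
  expect_true(all(lengths(pw$pathways) == cfg$pathway_size))
  anchor <- attr(pw, "anchor")
  # anchored pathways draw the overlap fraction from their module
  for (i in which(!is.na(anchor))) {
    genes <- pw$pathways[[i]]
    frac <- mean(net$modules[genes] == anchor[i])
    expect_equal(frac, cfg$pathway_module_overlap, tolerance = 0.051)
  }
  # overlap = 1 with pathway_size = module_size: pathway equals a module
  cfg1 <- scenario_config(pathway_module_overlap = 1, pathway_size = 20L,
                          seed = 8L)
  pw1 <- generate_pathways(cfg1, net$modules)
  expect_identical(sort(pw1$pathways[["PW01"]]),
                   sort(names(net$modules)[net$modules == 1]))
  # overlap = 0: uniform draw, no forced module genes
  cfg0 <- scenario_config(pathway_module_overlap = 0, seed = 8L)
  pw0 <- generate_pathways(cfg0, net$modules)
  expect_true(all(lengths(pw0$pathways) == cfg0$pathway_size))
})

test_that("driver mutations are mutually exclusive by construction", {
  cfg <- scenario_config(n_subgroups = 1L, n_patients = 200L,
                         driver_patient_rate = 1, passenger_rate = 0,
                         hazard_per_subgroup = 1, seed = 9L)
  sc <- generate_scenario(cfg)
  # every patient has exactly one mutation, and it lies in the driver pathway
  expect_true(all(rowSums(sc$cohort$M) == 1L))
  driver_genes <- sc$pathways$pathways[["PW01"]]
  hit_genes <- colnames(sc$cohort$M)[colSums(sc$cohort$M) > 0]
  expect_true(all(hit_genes %in% driver_genes))
})

test_that("driver gene choice is uniform within the pathway", {
  cfg <- scenario_config(n_subgroups = 1L, n_patients = 500L,
                         driver_patient_rate = 1, passenger_rate = 0,
                         hazard_per_subgroup = 1, seed = 10L)
  sc <- generate_scenario(cfg)
  counts <- colSums(sc$cohort$M)
  counts <- counts[sc$pathways$pathways[["PW01"]]]
  gof <- stats::chisq.test(counts, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("per-gene driver frequency tracks rate / pathway_size below 5%", {
  cfg <- scenario_config(n_subgroups = 1L, n_patients = 1000L,
                         driver_patient_rate = 0.6, passenger_rate = 0,
                         hazard_per_subgroup = 1, seed = 12L)
  sc <- generate_scenario(cfg)
  freq <- colMeans(sc$cohort$M)[sc$pathways$pathways[["PW01"]]]
  expected <- 0.6 / 20
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_true(all(abs(freq - expected) <= 3 * se + 1e-12))
  expect_true(all(freq < 0.05))
})

test_that("survival times follow the subgroup hazards with tuned censoring", {
  cfg <- scenario_config(n_patients = 3000L, n_subgroups = 2L,
                         hazard_per_subgroup = c(1, 3), censor_rate = 0,
                         seed = 13L)
  net <- generate_network(scenario_config(n_modules = 2L, module_size = 5L,
                                          n_pathways = 2L, pathway_size = 4L,
                                          n_subgroups = 2L,
                                          hazard_per_subgroup = c(1, 3),
                                          seed = 13L))
  truth <- list(subgroup = stats::setNames(
    rep(1:2, length.out = 3000L), sprintf("S%04d", 1:3000)))
  surv <- generate_survival(truth, cfg)
  expect_true(all(surv$event == 1L))
  # exponential medians are ln(2)/h, so the ratio is 1/3
  m1 <- stats::median(surv$time[surv$group == 1])
  m3 <- stats::median(surv$time[surv$group == 2])
  expect_equal(m3 / m1, 1 / 3, tolerance = 0.15)
  # censoring fraction matches the configured rate
  cfg2 <- scenario_config(n_patients = 3000L, n_subgroups = 2L,
                          hazard_per_subgroup = c(1, 3), censor_rate = 0.3,
                          seed = 14L)
  surv2 <- generate_survival(truth, cfg2)
  expect_equal(mean(surv2$event == 0L), 0.3, tolerance = 0.05)
})

test_that("scenario bundles are byte-identical given the same seed and round-trip", {
  cfg <- mini_cfg(seed = 21L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_scenario(cfg, d1)
  p2 <- write_scenario(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = sprintf("file %s", nm))
  }
  # loaders read back exactly what the generators produced
  sc <- generate_scenario(cfg)
  net <- load_network(p1[["network"]])
  expect_identical(net$nodes, sc$network$nodes)
  expect_equal(net$edges, sc$network$edges)
  expect_identical(read_gmt(p1[["pathways"]])$pathways,
                   sc$pathways$pathways)
  expect_identical(load_mutations(p1[["mutations"]])$M, sc$cohort$M)
  clin <- load_clinical(p1[["clinical"]])
  expect_equal(clin$time, sc$survival$time)
  expect_identical(clin$event, sc$survival$event)
  cfg_back <- yaml::read_yaml(p1[["config"]])
  expect_equal(cfg_back$driver_patient_rate, cfg$driver_patient_rate)
})

test_that("configuration invariants are validated", {
  expect_error(scenario_config(p_in = 1.2), "probabilities")
  expect_error(scenario_config(module_size = 1L), ">= 2")
  expect_error(scenario_config(hazard_per_subgroup = c(1, -1, 1)), "> 0")
  expect_error(scenario_config(hazard_per_subgroup = c(1, 2)), "per subgroup")
  expect_error(scenario_config(pathway_size = 1000L), "exceeds")
  expect_error(generate_cohort(scenario_config(
    driver_pathways = c("NOPE", "PW02", "PW03")),
    generate_pathways(scenario_config(),
                      generate_network(scenario_config())$modules)),
    "NOPE")
})
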