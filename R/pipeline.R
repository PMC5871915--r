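#' Pipeline stage runners
#'
#' Each `run_*` function is a thin orchestration layer over the package's
#' analysis functions: it reads standard-format inputs, writes TSV outputs
#' into `outdir`, and records a JSON run manifest (`manifest.json`) listing
#' inputs, parameters, seeds, package version and wall time. The
#' command-line dispatcher `inst/cli/netprop.R` exposes the same stages as
#' shell subcommands (`netprop simulate|score|enrich|stratify|run-all`).
#'
#' @name pipeline
NULL

write_manifest <- function(outdir, stage, inputs, params, outputs, t0) {
  manifest <- list(stage = stage,
                   inputs = as.list(inputs),
                   params = params,
                   outputs = as.list(outputs),
                   package = "netprop",
                   version = as.character(utils::packageVersion("netprop")),
                   wall_time_sec = round(as.numeric(Sys.time()) - t0, 3))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

default_lambda <- function(mode) switch(mode, cohort = 0.5, patient = 0.1)

#' Simulate a synthetic scenario bundle
#'
#' @param outdir output directory.
#' @param preset `"default"` or `"mini"` (2 modules of 8 genes, 20
#'   patients; a seconds-scale smoke fixture).
#' @param seed master seed.
#' @param ... overrides passed to [scenario_config()].
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(outdir, preset = c("default", "mini"), seed = 1L,
                         ...) {
  preset <- match.arg(preset)
  t0 <- as.numeric(Sys.time())
  args <- list(...)
  if (preset == "mini") {
    mini <- list(n_modules = 2L, module_size = 8L, p_in = 0.6, p_out = 0.05,
                 n_pathways = 4L, pathway_size = 6L, n_patients = 20L,
                 n_subgroups = 2L, hazard_per_subgroup = c(1, 3),
                 passenger_rate = 0.05)
    args <- utils::modifyList(mini, args)
  }
  cfg <- do.call(scenario_config, c(args, list(seed = seed)))
  paths <- write_scenario(cfg, outdir)
  write_manifest(outdir, "simulate", character(),
                 c(unclass(cfg), list(preset = preset)), paths, t0)
}

#' Score pathways by network propagation
#'
#' Cohort mode propagates gene mutation frequencies (`lambda` defaults to
#' 0.5); patient mode propagates each patient's normalized mutation
#' indicator (`lambda` defaults to 0.1) and additionally writes the
#' combined patients x pathways `-log10(p)` feature matrix.
#'
#' @param network_path edge-list TSV (or SIF via `fmt`).
#' @param mutations_path mutation matrix TSV.
#' @param gmt_path pathway GMT file.
#' @param outdir output directory.
#' @param mode `"cohort"` or `"patient"`.
#' @param lambda propagation weight; mode-dependent default when `NULL`.
#' @param n_null random gene sets per empirical null.
#' @param min_size minimum network-mapped pathway size.
#' @param rng_seed integer seed for the null draws.
#' @param fmt network file format.
#' @return The manifest, invisibly.
#' @export
run_score <- function(network_path, mutations_path, gmt_path, outdir,
                      mode = c("cohort", "patient"), lambda = NULL,
                      n_null = 10000L, min_size = 5L, rng_seed = 1L,
                      fmt = "edge_list_tsv") {
  mode <- match.arg(mode)
  t0 <- as.numeric(Sys.time())
  lambda <- lambda %||% default_lambda(mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  net <- load_network(network_path, fmt = fmt)
  cohort <- load_mutations(mutations_path)
  pathways <- read_gmt(gmt_path)
  op <- normalize_adjacency(net)
  inputs <- c(network = network_path, mutations = mutations_path,
              pathways = gmt_path)
  params <- list(mode = mode, lambda = lambda, n_null = n_null,
                 min_size = min_size, rng_seed = rng_seed)
  if (mode == "cohort") {
    tab <- score_cohort(cohort, op, pathways, lambda = lambda,
                        n_null = n_null, rng_seed = rng_seed,
                        min_size = min_size)
    out <- c(scores = file.path(outdir, "pathway_scores.tsv"))
    write_score_table(tab, out["scores"])
  } else {
    res <- score_patients(cohort, op, pathways, lambda = lambda,
                          n_null = n_null, rng_seed = rng_seed,
                          min_size = min_size)
    pdir <- file.path(outdir, "patients")
    dir.create(pdir, showWarnings = FALSE)
    for (s in names(res$tables)) {
      write_score_table(res$tables[[s]], file.path(pdir, paste0(s, ".tsv")))
    }
    F <- build_feature_matrix(res$tables)
    out <- c(feature_matrix = file.path(outdir, "feature_matrix.tsv"),
             patients_dir = pdir)
    fm <- data.frame(sample = rownames(F), F, check.names = FALSE)
    for (cn in colnames(F)) fm[[cn]] <- format_full(fm[[cn]])
    write_tsv(fm, out["feature_matrix"])
    params$skipped <- res$skipped
  }
  write_manifest(outdir, "score", inputs, params, out, t0)
}

#' Baseline hypergeometric enrichment (no network)
#'
#' @inheritParams run_score
#' @param min_freq frequency threshold for highly mutated genes (cohort
#'   mode); in patient mode each patient's mutated gene set is used
#'   directly.
#' @param universe `"cohort"` (default; the mutation matrix's genes) or
#'   `"network"` (requires `network_path`).
#' @param network_path only needed when `universe = "network"`.
#' @return The manifest, invisibly.
#' @export
run_enrich <- function(mutations_path, gmt_path, outdir,
                       mode = c("cohort", "patient"), min_freq = 0.05,
                       universe = c("cohort", "network"),
                       network_path = NULL) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  t0 <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_mutations(mutations_path)
  pathways <- read_gmt(gmt_path)
  univ <- if (universe == "cohort") cohort$genes else
    load_network(network_path)$nodes
  inputs <- c(mutations = mutations_path, pathways = gmt_path)
  params <- list(mode = mode, min_freq = min_freq, universe = universe)
  if (mode == "cohort") {
    sel <- select_highly_mutated(cohort, min_freq = min_freq)
    tab <- enrich(intersect(sel, univ), pathways, univ)
    out <- c(enrichment = file.path(outdir, "enrichment.tsv"))
    write_enrichment_table(tab, out["enrichment"])
  } else {
    pdir <- file.path(outdir, "patients")
    dir.create(pdir, showWarnings = FALSE)
    for (s in cohort$samples) {
      sel <- intersect(cohort$genes[cohort$M[s, ] == 1L], univ)
      tab <- enrich(sel, pathways, univ)
      write_enrichment_table(tab, file.path(pdir, paste0(s, ".tsv")))
    }
    out <- c(patients_dir = pdir)
  }
  write_manifest(outdir, "enrich", inputs, params, out, t0)
}

#' Stratify patients from a feature matrix and compare survival
#'
#' @param feature_matrix_path the `feature_matrix.tsv` written by
#'   [run_score()] in patient mode.
#' @param clinical_path clinical TSV (`sample`, `time`, `event`).
#' @param outdir output directory.
#' @param k number of groups.
#' @param linkage,metric passed to [hierarchical_cluster()].
#' @return The manifest, invisibly.
#' @export
run_stratify <- function(feature_matrix_path, clinical_path, outdir,
                         k = 3L, linkage = "ward", metric = "euclidean") {
  t0 <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fm <- utils::read.delim(feature_matrix_path, check.names = FALSE)
  F <- as.matrix(fm[, -1, drop = FALSE])
  rownames(F) <- fm[[1]]
  clinical <- load_clinical(clinical_path)
  labels <- hierarchical_cluster(F, k = k, linkage = linkage,
                                 metric = metric)
  cl <- clinical[match(names(labels), clinical$sample), , drop = FALSE]
  ok <- !is.na(cl$sample)
  time <- cl$time[ok]; event <- cl$event[ok]; grp <- labels[ok]
  pooled <- lapply(seq_len(k), function(g) {
    logrank_test(time, event, grp, setdiff(seq_len(k), g), g)
  })
  out <- c(labels = file.path(outdir, "labels.tsv"),
           logrank = file.path(outdir, "logrank.tsv"),
           km = file.path(outdir, "km_curves.tsv"))
  write_tsv(data.frame(sample = names(labels),
                       group = as.integer(labels)), out["labels"])
  lr <- data.frame(
    comparison = vapply(seq_len(k), function(g) {
      sprintf("%s_vs_%d", paste(setdiff(seq_len(k), g), collapse = "+"), g)
    }, ""),
    chi_square = format_full(vapply(pooled, `[[`, 0, "chi_square")),
    df = 1L,
    p_value = format_full(vapply(pooled, `[[`, 0, "p_value")))
  write_tsv(lr, out["logrank"])
  km <- km_curves(time, event, grp)
  km$time <- format_full(km$time)
  km$survival <- format_full(km$survival)
  write_tsv(km, out["km"])
  write_manifest(outdir, "stratify",
                 c(feature_matrix = feature_matrix_path,
                   clinical = clinical_path),
                 list(k = k, linkage = linkage, metric = metric), out, t0)
}

#' Run the full pipeline on a scenario bundle
#'
#' Patient-mode propagation scoring, baseline enrichment, and survival
#' stratification, reading the file bundle written by [run_simulate()] (or
#' any directory with the same layout).
#'
#' @param indir directory holding `network.tsv`, `pathways.gmt`,
#'   `mutations.tsv`, `clinical.tsv`.
#' @param outdir output directory.
#' @param k number of patient groups.
#' @param lambda patient-mode propagation weight.
#' @param n_null random gene sets per empirical null.
#' @param min_size minimum network-mapped pathway size.
#' @param min_freq baseline selection threshold.
#' @param rng_seed integer seed.
#' @return The manifest, invisibly.
#' @export
run_all <- function(indir, outdir, k = 3L, lambda = 0.1, n_null = 1000L,
                    min_size = 5L, min_freq = 0.05, rng_seed = 1L) {
  t0 <- as.numeric(Sys.time())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(indir, "network.tsv"),
             pathways = file.path(indir, "pathways.gmt"),
             mutations = file.path(indir, "mutations.tsv"),
             clinical = file.path(indir, "clinical.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  run_score(paths["network"], paths["mutations"], paths["pathways"],
            file.path(outdir, "score"), mode = "patient", lambda = lambda,
            n_null = n_null, min_size = min_size, rng_seed = rng_seed)
  run_enrich(paths["mutations"], paths["pathways"],
             file.path(outdir, "enrich"), mode = "patient",
             min_freq = min_freq)
  run_stratify(file.path(outdir, "score", "feature_matrix.tsv"),
               paths["clinical"], file.path(outdir, "stratify"), k = k)
  write_manifest(outdir, "run-all", paths,
                 list(k = k, lambda = lambda, n_null = n_null,
                      min_size = min_size, min_freq = min_freq,
                      rng_seed = rng_seed),
                 c(score = file.path(outdir, "score"),
                   enrich = file.path(outdir, "enrich"),
                   stratify = file.path(outdir, "stratify")), t0)
}
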