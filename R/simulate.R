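#' Synthetic scenario configuration
#'
#' Defines the study conditions for the synthetic-data generators: a
#' planted-partition gene network, pathway collections aligned with (and
#' offset from) the network modules, mutation cohorts in which each
#' subgroup's driver pathway is hit mutually exclusively at a per-gene
#' frequency below 5%, and exponential survival with subgroup-dependent
#' hazards.
#'
#' With the defaults (pathway_size 20, driver_patient_rate 0.6) each driver
#' gene's expected within-subgroup frequency is 0.6 / 20 = 0.03, below the
#' 5% regime in which threshold-based gene selection misses dispersed
#' drivers while pathway-level propagation does not.
#'
#' @param n_modules number of network modules.
#' @param module_size genes per module.
#' @param p_in,p_out within-/between-module edge probabilities.
#' @param n_pathways total pathways; the first `min(n_pathways, n_modules)`
#'   are anchored to modules 1, 2, ..., the remainder are fully random
#'   decoys.
#' @param pathway_size genes per pathway.
#' @param pathway_module_overlap fraction of each anchored pathway drawn
#'   from its module (the rest drawn uniformly elsewhere).
#' @param n_patients cohort size.
#' @param n_subgroups number of planted patient subgroups.
#' @param driver_pathways character vector naming one driver pathway per
#'   subgroup; defaults to the first `n_subgroups` anchored pathways.
#' @param driver_patient_rate probability that a subgroup patient receives a
#'   (single, mutually exclusive) driver mutation.
#' @param passenger_rate per-gene per-patient background mutation
#'   probability.
#' @param hazard_per_subgroup positive exponential event rates, one per
#'   subgroup.
#' @param censor_rate expected censored fraction of the cohort.
#' @param seed integer master seed (< 2^31 - 10; stage seeds are derived by
#'   fixed offsets).
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_modules = 10L, module_size = 20L,
                            p_in = 0.3, p_out = 0.01,
                            n_pathways = 15L, pathway_size = 20L,
                            pathway_module_overlap = 0.8,
                            n_patients = 120L, n_subgroups = 3L,
                            driver_pathways = NULL,
                            driver_patient_rate = 0.6,
                            passenger_rate = 0.01,
                            hazard_per_subgroup = c(1, 1, 3),
                            censor_rate = 0.2, seed = 1L) {
  cfg <- list(n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              p_in = p_in, p_out = p_out,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              pathway_module_overlap = pathway_module_overlap,
              n_patients = as.integer(n_patients),
              n_subgroups = as.integer(n_subgroups),
              driver_pathways = driver_pathways,
              driver_patient_rate = driver_patient_rate,
              passenger_rate = passenger_rate,
              hazard_per_subgroup = as.numeric(hazard_per_subgroup),
              censor_rate = censor_rate, seed = as.integer(seed))
  probs <- c(cfg$p_in, cfg$p_out, cfg$pathway_module_overlap,
             cfg$driver_patient_rate, cfg$passenger_rate, cfg$censor_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$module_size < 2 || cfg$pathway_size < 2) {
    stop("module and pathway sizes must be >= 2")
  }
  if (cfg$pathway_size > cfg$n_modules * cfg$module_size) {
    stop("pathway_size exceeds total gene count")
  }
  if (length(cfg$hazard_per_subgroup) == 1) {
    cfg$hazard_per_subgroup <- rep(cfg$hazard_per_subgroup, cfg$n_subgroups)
  }
  if (length(cfg$hazard_per_subgroup) != cfg$n_subgroups) {
    stop("need one hazard per subgroup")
  }
  if (any(cfg$hazard_per_subgroup <= 0)) stop("hazards must be > 0")
  if (cfg$seed < 0 || cfg$seed > 2^31 - 10) stop("seed out of range")
  if (is.null(cfg$driver_pathways)) {
    cfg$driver_pathways <- sprintf("PW%02d", seq_len(cfg$n_subgroups))
  }
  if (length(cfg$driver_pathways) != cfg$n_subgroups) {
    stop("need one driver pathway per subgroup")
  }
  structure(cfg, class = "scenario_config")
}

#' Generate a planted-partition gene network
#'
#' Genes `G0001...` are split into `n_modules` modules of `module_size`;
#' each within-module pair is connected independently with probability
#' `p_in`, each between-module pair with `p_out` (all weights 1).
#'
#' @param cfg a [scenario_config].
#' @return List with `network` (a [gene_network]) and `modules` (named
#'   integer vector, gene -> module).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_modules * cfg$module_size
  genes <- sprintf("G%04d", seq_len(n))
  module <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
  ut <- which(upper.tri(matrix(FALSE, n, n)))
  ij <- arrayInd(ut, c(n, n))
  p <- ifelse(module[ij[, 1]] == module[ij[, 2]], cfg$p_in, cfg$p_out)
  keep <- withr::with_seed(cfg$seed + 1L,
                           stats::rbinom(length(p), 1L, p) == 1L)
  net <- gene_network(genes[ij[keep, 1]], genes[ij[keep, 2]], 1,
                      nodes = genes)
  list(network = net, modules = stats::setNames(module, genes))
}

#' Generate module-aligned pathway collections
#'
#' Anchored pathways (`PW01..`) draw a fraction `pathway_module_overlap` of
#' their genes from one module and the rest uniformly from the other genes,
#' so they are network-coherent without coinciding with modules. Remaining
#' pathways are fully random decoys. All pathways have exactly
#' `pathway_size` genes.
#'
#' @param cfg a [scenario_config].
#' @param modules named gene -> module vector from [generate_network()].
#' @return A [pathway_collection] with attribute `anchor` (named integer
#'   vector, pathway -> module; `NA` for decoys).
#' @export
generate_pathways <- function(cfg, modules) {
  stopifnot(inherits(cfg, "scenario_config"))
  genes <- names(modules)
  n_anchored <- min(cfg$n_pathways, cfg$n_modules)
  withr::with_seed(cfg$seed + 2L, {
    sets <- vector("list", cfg$n_pathways)
    anchor <- rep(NA_integer_, cfg$n_pathways)
    for (i in seq_len(cfg$n_pathways)) {
      if (i <= n_anchored) {
        anchor[i] <- i
        pool <- genes[modules == i]
        n_in <- min(round(cfg$pathway_module_overlap * cfg$pathway_size),
                    length(pool), cfg$pathway_size)
        inside <- sample(pool, n_in)
        outside <- sample(setdiff(genes, pool), cfg$pathway_size - n_in)
        sets[[i]] <- sort(c(inside, outside))
      } else {
        sets[[i]] <- sort(sample(genes, cfg$pathway_size))
      }
    }
    names(sets) <- sprintf("PW%02d", seq_len(cfg$n_pathways))
    names(anchor) <- names(sets)
    out <- pathway_collection(sets, source = "synthetic planted-module")
    attr(out, "anchor") <- anchor
    out
  })
}

#' Generate a mutation cohort with mutually exclusive planted drivers
#'
#' Patients are split evenly into `n_subgroups`. With probability
#' `driver_patient_rate` a patient receives exactly one driver mutation in a
#' uniformly chosen gene of its subgroup's driver pathway (mutual
#' exclusivity by construction); independent passenger mutations occur
#' everywhere at `passenger_rate`.
#'
#' @param cfg a [scenario_config].
#' @param pathways the [pathway_collection] from [generate_pathways()].
#' @return List with `cohort` (a [mutation_cohort]) and `truth` (list with
#'   `subgroup` per sample, `driver_pathways` per subgroup, and
#'   `driver_hit` logical per sample).
#' @export
generate_cohort <- function(cfg, pathways) {
  stopifnot(inherits(cfg, "scenario_config"),
            inherits(pathways, "pathway_collection"))
  missing <- setdiff(cfg$driver_pathways, names(pathways$pathways))
  if (length(missing) > 0) {
    stop("driver pathway(s) not in collection: ",
         paste(missing, collapse = ", "))
  }
  genes <- sort(unique(unlist(pathways$pathways, use.names = FALSE)))
  # the cohort gene universe is the full network gene list when available
  if (!is.null(attr(pathways, "gene_universe"))) {
    genes <- attr(pathways, "gene_universe")
  }
  samples <- sprintf("S%04d", seq_len(cfg$n_patients))
  subgroup <- rep(seq_len(cfg$n_subgroups), length.out = cfg$n_patients)
  subgroup <- sort(subgroup)
  withr::with_seed(cfg$seed + 3L, {
    M <- matrix(stats::rbinom(cfg$n_patients * length(genes), 1L,
                              cfg$passenger_rate),
                nrow = cfg$n_patients,
                dimnames = list(samples, genes))
    hit <- stats::rbinom(cfg$n_patients, 1L, cfg$driver_patient_rate) == 1L
    for (i in which(hit)) {
      pw <- pathways$pathways[[cfg$driver_pathways[subgroup[i]]]]
      pw <- intersect(pw, genes)
      g <- if (length(pw) == 1) pw else sample(pw, 1)
      M[i, g] <- 1L
    }
  })
  list(cohort = mutation_cohort(M),
       truth = list(subgroup = stats::setNames(subgroup, samples),
                    driver_pathways = cfg$driver_pathways,
                    driver_hit = stats::setNames(hit, samples)))
}

#' Generate exponential survival with subgroup-dependent hazards
#'
#' Event times are exponential with each subgroup's hazard. Censoring is
#' exponential, independent of group and of the event time
#' (non-informative), with a single rate solved so that the expected
#' censored fraction over the cohort equals `censor_rate`.
#'
#' @param truth the `truth` element from [generate_cohort()].
#' @param cfg a [scenario_config].
#' @return `data.frame` with columns `sample`, `time`, `event`, `group`.
#' @export
generate_survival <- function(truth, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  subgroup <- truth$subgroup
  h <- cfg$hazard_per_subgroup[subgroup]
  crate <- 0
  if (cfg$censor_rate > 0) {
    # P(censored | hazard h, censor rate c) = c / (h + c)
    target <- function(c) mean(c / (h + c)) - cfg$censor_rate
    hi <- max(h) * 1e6
    crate <- stats::uniroot(target, lower = 1e-12, upper = hi,
                            tol = 1e-12)$root
  }
  withr::with_seed(cfg$seed + 4L, {
    t_ev <- stats::rexp(length(h), rate = h)
    t_c <- if (crate > 0) stats::rexp(length(h), rate = crate) else
      rep(Inf, length(h))
  })
  data.frame(sample = names(subgroup),
             time = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c),
             group = as.integer(subgroup),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic scenario in memory
#'
#' Convenience wrapper chaining [generate_network()],
#' [generate_pathways()], [generate_cohort()] and [generate_survival()].
#'
#' @param cfg a [scenario_config].
#' @return List with `network`, `modules`, `pathways`, `cohort`, `truth`,
#'   `survival` and the resolved `config`.
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  net <- generate_network(cfg)
  pw <- generate_pathways(cfg, net$modules)
  attr(pw, "gene_universe") <- names(net$modules)
  coh <- generate_cohort(cfg, pw)
  surv <- generate_survival(coh$truth, cfg)
  list(network = net$network, modules = net$modules, pathways = pw,
       cohort = coh$cohort, truth = coh$truth, survival = surv,
       config = cfg)
}

#' Write a scenario to disk as a self-contained fixture
#'
#' Emits exactly the formats the loaders read: `network.tsv` (edge list),
#' `pathways.gmt`, `mutations.tsv` (binary matrix), `clinical.tsv`
#' (`sample`, `time`, `event`), ground truth (`truth_subgroups.tsv`:
#' `sample<TAB>subgroup`; `truth_modules.tsv`: `gene<TAB>module`) and the
#' resolved `config.yaml`. Byte-identical given the same config.
#'
#' @param cfg a [scenario_config].
#' @param outdir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(cfg, outdir) {
  sc <- generate_scenario(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(outdir, "network.tsv"),
             pathways = file.path(outdir, "pathways.gmt"),
             mutations = file.path(outdir, "mutations.tsv"),
             clinical = file.path(outdir, "clinical.tsv"),
             truth_subgroups = file.path(outdir, "truth_subgroups.tsv"),
             truth_modules = file.path(outdir, "truth_modules.tsv"),
             config = file.path(outdir, "config.yaml"))
  write_network(sc$network, paths["network"])
  write_gmt(sc$pathways, paths["pathways"])
  write_mutations(sc$cohort, paths["mutations"])
  cl <- sc$survival
  cl$time <- format_full(cl$time)
  write_tsv(cl[, c("sample", "time", "event")], paths["clinical"])
  write_tsv(data.frame(sample = names(sc$truth$subgroup),
                       subgroup = as.integer(sc$truth$subgroup)),
            paths["truth_subgroups"])
  write_tsv(data.frame(gene = names(sc$modules),
                       module = as.integer(sc$modules)),
            paths["truth_modules"])
  yaml::write_yaml(unclass(sc$config), paths["config"])
  invisible(paths)
}
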