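# End-to-end orchestration: simulate (or load) a dataset, run every
# diagnostic with per-stage substream seeds, and write a results bundle
# (TSV per figure/table, a machine-readable JSON manifest, optional plots).

#' Assemble a pipeline run configuration
#'
#' Thresholds default to the conventional gates of this analysis family:
#' 0.05 for the ancestry-informative marker screen, 0.001 for the sequence
#' genotype display, 0.01 for calling an LD pair associated.
#'
#' @param scenario A [scenario_params()] (simulation mode), or `NULL` when
#'   `loci`/`aflp` inputs are supplied directly.
#' @param loci,aflp Optional pre-loaded data (named list of
#'   [aligned_locus()]; marker tibble) used instead of simulation.
#' @param seed Mandatory master seed; expanded into per-stage substreams.
#' @param out_dir Output directory (created if needed).
#' @param alpha_markers,alpha_sequence,alpha_ld Stage significance gates.
#' @param K_values Cluster numbers for the admixture stage.
#' @param n_markers Markers to simulate (simulation mode).
#' @param n_perm Permutations per AMOVA test.
#' @param bootstrap_reps NJ bootstrap pseudo-replicates.
#' @param mcmc_burnin,mcmc_iterations Admixture sweeps.
#' @param make_plots Write PDF figures.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL, loci = NULL, aflp = NULL,
                       seed, out_dir = "hybridhallmarks_run",
                       alpha_markers = 0.05, alpha_sequence = 0.001,
                       alpha_ld = 0.01, K_values = c(2, 3, 4),
                       n_markers = 250, n_perm = 1000,
                       bootstrap_reps = 200,
                       mcmc_burnin = 1000, mcmc_iterations = 4000,
                       make_plots = TRUE) {
  if (missing(seed)) abort("seed is mandatory.")
  for (a in c(alpha_markers, alpha_sequence, alpha_ld)) check_alpha(a)
  if (is.null(scenario) && (is.null(loci) || is.null(aflp))) {
    abort("provide either a scenario or both loci and aflp inputs.")
  }
  structure(list(scenario = scenario, loci = loci, aflp = aflp,
                 seed = as.integer(seed), out_dir = out_dir,
                 alpha_markers = alpha_markers, alpha_sequence = alpha_sequence,
                 alpha_ld = alpha_ld, K_values = K_values,
                 n_markers = n_markers, n_perm = n_perm,
                 bootstrap_reps = bootstrap_reps,
                 mcmc_burnin = mcmc_burnin, mcmc_iterations = mcmc_iterations,
                 make_plots = make_plots),
            class = "run_config")
}

stage_log <- function(log, stage, status, note = "") {
  bind_rows(log, tibble(stage = stage, status = status, note = note))
}

#' Run the full diagnostic pipeline
#'
#' Stages: simulate (skipped when inputs are supplied) -> locus-by-locus
#' AMOVA and pairwise Phi_ST -> marker screen/classification and sequence
#' genotype classes -> admixture at each K -> LD comparison (parents,
#' hybrid, F2 cross) -> diversity statistics -> NJ tree with bootstrap.
#' Every stage draws from a named substream of the master seed, so the same
#' config and seed give a byte-identical manifest. A failed stage is logged
#' and its dependents skipped.
#'
#' @param config A [run_config()].
#' @return A results bundle (named list of tibbles/objects, plus `log`),
#'   invisibly; files are written under `config$out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- tibble(stage = character(), status = character(), note = character())
  bundle <- list()
  seed <- config$seed

  # --- data -------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sim <- tryCatch(simulate_dataset(config$scenario,
                                     n_markers = config$n_markers, seed = seed),
                    error = function(e) e)
    if (inherits(sim, "error")) {
      log <- stage_log(log, "simulate", "failed", conditionMessage(sim))
      return(invisible(list(log = log)))
    }
    loci <- sim$loci; aflp <- sim$aflp
    log <- stage_log(log, "simulate", "ok",
                     sprintf("%d loci, %d markers", length(loci),
                             length(aflp_marker_ids(aflp))))
  } else {
    loci <- config$loci; aflp <- config$aflp
    log <- stage_log(log, "simulate", "skipped", "inputs supplied")
  }
  pops <- unique(aflp$population)
  parentA <- if ("parentA" %in% pops) "parentA" else pops[1L]
  parentB <- if ("parentB" %in% pops) "parentB" else pops[2L]
  hybrid <- if ("hybrid" %in% pops) "hybrid" else pops[min(3L, length(pops))]
  tables <- map(loci, extract_polymorphisms)

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      log <<- stage_log(log, name, "failed", conditionMessage(res))
      NULL
    } else {
      log <<- stage_log(log, name, "ok")
      res
    }
  }

  bundle$fst_sequence <- run_stage("fst_sequence",
    locus_by_locus(tables, n_perm = config$n_perm,
                   seed = substream_seed(seed, "fst_seq")))
  bundle$fst_markers <- run_stage("fst_markers",
    locus_by_locus(aflp, n_perm = config$n_perm,
                   seed = substream_seed(seed, "fst_aflp")))
  bundle$pairwise_fst <- run_stage("pairwise_fst", {
    res <- map(tables, pairwise_fst)
    list_rbind(imap(res, function(m, nm) {
      as_tibble(m, rownames = "population_1") |>
        tidyr::pivot_longer(-"population_1", names_to = "population_2",
                            values_to = "phi_st") |>
        mutate(locus = nm)
    }))
  })
  bundle$marker_classes <- run_stage("marker_classes",
    classify_markers(aflp, hybrid = hybrid, parentA = parentA,
                     parentB = parentB, alpha = config$alpha_markers,
                     n_perm = config$n_perm,
                     seed = substream_seed(seed, "markers")))
  bundle$genotype_classes <- run_stage("genotype_classes",
    classify_sequence_genotypes(tables, parentA = parentA, parentB = parentB,
                                hybrid = hybrid,
                                alpha = config$alpha_sequence,
                                n_perm = max(config$n_perm,
                                             ceiling(2 / config$alpha_sequence)),
                                seed = substream_seed(seed, "genotypes")))
  bundle$admixture <- run_stage("admixture", {
    fits <- map(config$K_values, function(K) {
      estimate_admixture(aflp, K = K, burnin = config$mcmc_burnin,
                         iterations = config$mcmc_iterations,
                         seed = substream_seed(seed, paste0("admix", K)))
    })
    setNames(fits, paste0("K", config$K_values))
  })
  bundle$ld <- run_stage("ld", {
    sets <- map(setNames(pops, pops),
                function(p) filter_polymorphic(filter(aflp, .data$population == p)))
    if (!is.null(config$scenario)) {
      f2 <- simulate_cross(
        filter(aflp, .data$population == parentA) |>
          structure(genotypes = attr(aflp, "genotypes")[aflp$population == parentA, , drop = FALSE]),
        filter(aflp, .data$population == parentB) |>
          structure(genotypes = attr(aflp, "genotypes")[aflp$population == parentB, , drop = FALSE]),
        type = "F2", n = sum(aflp$population == hybrid),
        seed = substream_seed(seed, "f2"))
      sets$F2_cross <- filter_polymorphic(f2)
    }
    compare_ld(sets, alpha = config$alpha_ld)
  })
  bundle$diversity <- run_stage("diversity", {
    counts <- species_specific_counts(tables)
    list(counts = counts,
         polymorphisms = proportion_summary(counts, "polymorphisms"),
         haplotypes = proportion_summary(counts, "haplotypes"))
  })
  bundle$tree <- run_stage("tree",
    bootstrap_support(aflp, n_reps = config$bootstrap_reps,
                      seed = substream_seed(seed, "boot")))

  # --- outputs ----------------------------------------------------------
  out <- function(name) file.path(config$out_dir, name)
  if (!is.null(bundle$fst_sequence)) readr::write_tsv(bundle$fst_sequence, out("fst_sequence.tsv"), progress = FALSE)
  if (!is.null(bundle$fst_markers)) readr::write_tsv(bundle$fst_markers, out("fst_markers.tsv"), progress = FALSE)
  if (!is.null(bundle$pairwise_fst)) readr::write_tsv(bundle$pairwise_fst, out("pairwise_fst.tsv"), progress = FALSE)
  if (!is.null(bundle$marker_classes)) {
    readr::write_tsv(bundle$marker_classes, out("marker_classes.tsv"), progress = FALSE)
    readr::write_tsv(classification_counts(bundle$marker_classes), out("marker_class_counts.tsv"), progress = FALSE)
  }
  if (!is.null(bundle$genotype_classes)) readr::write_tsv(bundle$genotype_classes, out("genotype_classes.tsv"), progress = FALSE)
  if (!is.null(bundle$admixture)) {
    for (nm in names(bundle$admixture)) {
      readr::write_tsv(tidy.admixture_fit(bundle$admixture[[nm]]),
                       out(sprintf("admixture_q_%s.tsv", nm)), progress = FALSE)
    }
  }
  if (!is.null(bundle$ld)) {
    readr::write_tsv(as_tibble(bundle$ld), out("ld_summary.tsv"), progress = FALSE)
    readr::write_tsv(attr(bundle$ld, "tests"), out("ld_tests.tsv"), progress = FALSE)
  }
  if (!is.null(bundle$diversity)) {
    readr::write_tsv(bundle$diversity$counts, out("diversity_counts.tsv"), progress = FALSE)
    readr::write_tsv(bundle$diversity$polymorphisms, out("diversity_polymorphism_summary.tsv"), progress = FALSE)
    readr::write_tsv(bundle$diversity$haplotypes, out("diversity_haplotype_summary.tsv"), progress = FALSE)
  }
  if (!is.null(bundle$tree)) write_newick(bundle$tree, out("nj_tree.nwk"))

  if (isTRUE(config$make_plots)) {
    if (!is.null(bundle$genotype_classes) && nrow(bundle$genotype_classes)) {
      ggplot2::ggsave(out("genotype_mosaic.pdf"),
                      ggplot2::autoplot(bundle$genotype_classes),
                      width = 8, height = 5)
    }
    if (!is.null(bundle$admixture)) {
      for (nm in names(bundle$admixture)) {
        ggplot2::ggsave(out(sprintf("admixture_%s.pdf", nm)),
                        ggplot2::autoplot(bundle$admixture[[nm]]),
                        width = 8, height = 3)
      }
    }
    if (!is.null(bundle$tree)) {
      grDevices::pdf(out("nj_tree.pdf"), width = 7, height = 9)
      plot_nj_tree(bundle$tree)
      grDevices::dev.off()
    }
  }

  manifest <- list(
    seed = seed,
    populations = pops,
    n_loci = length(loci),
    n_markers = length(aflp_marker_ids(aflp)),
    fst_sequence = if (!is.null(bundle$fst_sequence)) {
      select(bundle$fst_sequence, "locus_id", "phi_st", "p_value")
    },
    marker_class_counts = if (!is.null(bundle$marker_classes)) {
      classification_counts(bundle$marker_classes)
    },
    admixture_population_means = if (!is.null(bundle$admixture)) {
      map(bundle$admixture, ~ admixture_summary(.x))
    },
    ld = if (!is.null(bundle$ld)) as_tibble(bundle$ld),
    diversity_polymorphisms = bundle$diversity$polymorphisms,
    diversity_haplotypes = bundle$diversity$haplotypes,
    stages = log
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)

  bundle$log <- log
  bundle$manifest_path <- out("manifest.json")
  failed <- sum(log$status == "failed")
  if (failed > 0) {
    warn(sprintf("%d stage(s) failed; see the log.", failed))
  }
  invisible(bundle)
}
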