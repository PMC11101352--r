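# End-to-end orchestration: simulate -> harmonize -> select instruments
# -> univariable MR -> mediation, with deterministic seeding, per-stage
# attrition accounting and tidy result tables.

#' Pipeline run configuration
#'
#' Collects every threshold of the analysis as a named default:
#' genome-wide significance 5e-8; clumping p1 = 1e-4, p2 = 0.01,
#' kb = 250, r2 = 0.01; allele-frequency concordance 0.05; Steiger
#' boundary -1.96; strict significance 0.05/141 (effective number of
#' tests) and mediation significance 0.05/323 (mediation pairs).
#'
#' @param sim `sim_config` for the synthetic inputs.
#' @param gw_threshold,p1,p2,kb,r2 instrument-selection thresholds.
#' @param af_max_diff,steiger_threshold filter boundaries.
#' @param n_effective_tests,n_mediation_pairs test counts from which
#'   the strict and mediation significance thresholds derive.
#' @param n_sim_ci mediation CI draws.
#' @param stages character vector of stages to run, a subset of
#'   `c("mr", "mediation")` (simulation, harmonization and IV selection
#'   always run).
#' @param seed master seed (propagated to every stochastic stage).
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), gw_threshold = 5e-8, p1 = 1e-4,
                       p2 = 0.01, kb = 250, r2 = 0.01, af_max_diff = 0.05,
                       steiger_threshold = -1.96, n_effective_tests = 141,
                       n_mediation_pairs = 323, n_sim_ci = 10000,
                       stages = c("mr", "mediation"), seed = 1) {
  stopifnot(gw_threshold > 0, p1 > 0, p2 > 0, kb > 0, r2 > 0,
            af_max_diff > 0, n_effective_tests >= 1, n_mediation_pairs >= 1)
  structure(list(sim = sim, gw_threshold = gw_threshold, p1 = p1, p2 = p2,
                 kb = kb, r2 = r2, af_max_diff = af_max_diff,
                 steiger_threshold = steiger_threshold,
                 n_effective_tests = n_effective_tests,
                 n_mediation_pairs = n_mediation_pairs,
                 n_sim_ci = n_sim_ci, stages = stages, seed = seed),
            class = "run_config")
}

#' Significance gate
#'
#' Labels p-values `strict` below 0.05/n_effective_tests, `nominal`
#' below 0.05, and `ns` otherwise.
#'
#' @param pvalues numeric vector.
#' @param n_effective_tests effective number of independent tests.
#' @return character vector of labels.
#' @export
significance_gate <- function(pvalues, n_effective_tests = 141) {
  if (n_effective_tests < 1) stop("n_effective_tests must be >= 1")
  ifelse(pvalues < 0.05 / n_effective_tests, "strict",
         ifelse(pvalues < 0.05, "nominal", "ns"))
}

#' Number of exposure-outcome mediation pairs
#'
#' Enumerates the mediation design: each of `n_exposures` traits tested
#' against each of `n_outcomes` outcomes, minus pairs excluded because a
#' trait appears on both sides.
#'
#' @param n_exposures mediator-affecting exposures (default 18).
#' @param n_outcomes outcomes per exposure (default 18: 17 traits plus
#'   lifespan).
#' @param n_excluded overlapping trait pairs removed (default 1).
#' @return integer pair count.
#' @export
count_mediation_pairs <- function(n_exposures = 18, n_outcomes = 18,
                                  n_excluded = 1) {
  as.integer(n_exposures * n_outcomes - n_excluded)
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a GWAS triplet, harmonizes each study against the emitted
#' panel, selects instruments, and runs bidirectional univariable MR
#' between exposure and outcome plus the mediation analysis through the
#' mediator. All randomness derives from `config$seed`; rerunning with
#' the same config reproduces identical tables.
#'
#' @param config `run_config`.
#' @return list of class `run_report`: `mr` (method table per
#'   direction with significance labels), `mediation`
#'   (`mediation_result`), `attrition` (per-stage counts), `truth`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  cfg$sim$seed <- cfg$seed
  study <- simulate_gwas_triplet(cfg$sim)
  n_panel <- nrow(study$panel)

  hz <- lapply(list(exposure = study$exposure, mediator = study$mediator,
                    outcome = study$outcome),
               harmonize, panel = study$panel)
  attrition <- data.table(stage = "harmonize",
                          item = names(hz),
                          n_in = n_panel,
                          n_out = vapply(hz, nrow, 0L))

  mr_tab <- NULL
  if ("mr" %in% cfg$stages) {
    bi <- bidirectional_mr(hz$exposure, hz$outcome, study$ld,
                           masks_ltl = default_masks(),
                           masks_trait = default_masks(),
                           p1 = cfg$p1, p2 = cfg$p2, kb = cfg$kb,
                           r2 = cfg$r2, gw_threshold = cfg$gw_threshold,
                           af_max_diff = cfg$af_max_diff,
                           steiger_threshold = cfg$steiger_threshold,
                           seed = cfg$seed)
    rows <- list()
    if (!is.null(bi$forward))
      rows[[1]] <- cbind(exposure = "exposure", outcome = "outcome",
                         bi$forward)
    if (!is.null(bi$reverse))
      rows[[length(rows) + 1L]] <- cbind(exposure = "outcome",
                                         outcome = "exposure", bi$reverse)
    if (length(rows)) {
      mr_tab <- do.call(rbind, rows)
      mr_tab$label <- significance_gate(mr_tab$p, cfg$n_effective_tests)
    }
    att_f <- bi$attrition_forward; att_r <- bi$attrition_reverse
    attrition <- rbind(attrition,
                       data.table(stage = "iv_forward", item = att_f$step,
                                  n_in = shift_n(att_f$n), n_out = att_f$n),
                       data.table(stage = "iv_reverse", item = att_r$step,
                                  n_in = shift_n(att_r$n), n_out = att_r$n))
  }

  med <- NULL
  if ("mediation" %in% cfg$stages) {
    med <- mediate(hz$exposure, hz$mediator, hz$outcome, study$ld,
                   p1 = cfg$p1, p2 = cfg$p2, kb = cfg$kb, r2 = cfg$r2,
                   gw_threshold = cfg$gw_threshold,
                   steiger_threshold = cfg$steiger_threshold,
                   n_sim = cfg$n_sim_ci, seed = cfg$seed)
  }

  structure(list(mr = mr_tab, mediation = med, attrition = attrition,
                 truth = study$truth, config = cfg),
            class = "run_report")
}

shift_n <- function(n) c(NA_integer_, n[-length(n)])

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run (seed", x$config$seed, ")\n")
  if (!is.null(x$mr)) {
    cat("\nunivariable MR:\n")
    print(x$mr[, c("exposure", "outcome", "method", "n_iv", "alpha", "se",
                   "p", "label")])
  }
  if (!is.null(x$mediation)) {
    cat("\n")
    print(x$mediation)
  }
  invisible(x)
}

#' Write pipeline result tables as TSV
#'
#' @param report `run_report`.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(report$mr)) {
    p <- file.path(dir, "mr_results.tsv")
    fwrite(as.data.table(report$mr), p, sep = "\t")
    paths <- c(paths, p)
  }
  if (!is.null(report$mediation) && isTRUE(report$mediation$ok)) {
    m <- report$mediation
    p <- file.path(dir, "mediation_results.tsv")
    fwrite(data.table(
      exposure = m$exposure, mediator = m$mediator, outcome = m$outcome,
      total = m$alpha_total, total_se = m$se_total, direct = m$alpha_direct,
      direct_se = m$se_direct, indirect_product = m$alpha_indirect_product,
      indirect_difference = m$alpha_indirect_difference, P_M = m$P_M,
      ci_low = m$ci_lower, ci_high = m$ci_upper,
      n_iv_exposure = m$n_iv_exposure, n_iv_mediator = m$n_iv_mediator,
      cond_F_exposure = m$cond_F_exposure,
      cond_F_mediator = m$cond_F_mediator, seed = m$seed), p, sep = "\t")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "attrition.tsv")
  fwrite(report$attrition, p, sep = "\t")
  paths <- c(paths, p)
  invisible(paths)
}
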