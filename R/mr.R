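# Univariable two-sample MR estimators and diagnostics. All operate on
# an aligned, filtered IV table with columns beta_exp, se_exp, beta_out,
# se_out (see align_pair). Effects are in SD outcome per SD exposure for
# continuous traits and log(OR) per SD for binary outcomes.

mr_estimate <- function(method, alpha, se, n_iv, Q = NA_real_, Q_df = NA_real_,
                        egger_intercept = NA_real_, intercept_se = NA_real_) {
  p <- 2 * pnorm(-abs(alpha / se))
  intercept_p <- if (is.na(egger_intercept)) NA_real_ else
    2 * pnorm(-abs(egger_intercept / intercept_se))
  structure(list(method = method, alpha = alpha, se = se, pvalue = p,
                 n_iv = n_iv, Q = Q, Q_df = Q_df,
                 Q_p = if (is.na(Q)) NA_real_ else
                   stats::pchisq(Q, Q_df, lower.tail = FALSE),
                 egger_intercept = egger_intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR %s: alpha = %.4g (SE %.3g, p = %.3g), %d IV(s)",
              x$method, x$alpha, x$se, x$pvalue, x$n_iv))
  if (!is.na(x$Q)) cat(sprintf("; Q = %.3g (df %d, p = %.3g)", x$Q,
                               x$Q_df, x$Q_p))
  cat("\n")
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' alpha = beta_out / beta_exp with first-order SE |se_out / beta_exp|.
#'
#' @param beta_exp,se_exp,beta_out,se_out per-variant associations.
#' @return `mr_estimate`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("beta_exp = 0: Wald ratio undefined")
  mr_estimate("wald", beta_out / beta_exp, abs(se_out / beta_exp), 1L)
}

check_mr_input <- function(input, min_iv, method) {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(input))
  if (length(miss)) stop("MR input missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(input) < min_iv)
    stop(method, " requires >= ", min_iv, " instruments",
         if (min_iv == 2) " (use wald_ratio for a single IV)" else "")
  if (any(input$se_out <= 0) || any(input$se_exp <= 0))
    stop("standard errors must be positive")
  invisible(input)
}

#' Inverse-variance weighted estimator
#'
#' Weighted zero-intercept regression of outcome on exposure
#' associations with weights 1/se_out^2:
#' alpha = sum(w bx by) / sum(w bx^2). Cochran's Q (df = k - 1)
#' measures heterogeneity; under the multiplicative random-effects model
#' (default) the SE is inflated by sqrt(max(1, Q/df)).
#'
#' @param input data.frame with `beta_exp, se_exp, beta_out, se_out`,
#'   one row per IV (k >= 2).
#' @param random_effects multiplicative over-dispersion scaling of the
#'   SE (default `TRUE`); `FALSE` gives the fixed-effect SE.
#' @return list with `estimate` (`mr_estimate`) and `heterogeneity`
#'   (`Q`, `df`, `pvalue`).
#' @export
ivw <- function(input, random_effects = TRUE) {
  check_mr_input(input, 2L, "ivw")
  w <- 1 / input$se_out^2
  bx <- input$beta_exp; by <- input$beta_out
  sxx <- sum(w * bx^2)
  alpha <- sum(w * bx * by) / sxx
  Q <- sum(w * (by - alpha * bx)^2)
  df <- nrow(input) - 1L
  se <- sqrt(1 / sxx)
  if (random_effects) se <- se * sqrt(max(1, Q / df))
  list(estimate = mr_estimate("ivw", alpha, se, nrow(input), Q, df),
       heterogeneity = list(Q = Q, df = df,
                            pvalue = stats::pchisq(Q, df, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations *with* an
#' intercept, after orienting all exposure effects non-negative (the
#' intercept is only identifiable under a fixed orientation). The slope
#' is the pleiotropy-adjusted causal effect; the intercept estimates
#' average directional pleiotropy. SEs carry the same multiplicative
#' over-dispersion as [ivw()], with df = k - 2.
#'
#' @inheritParams ivw
#' @return list with `estimate` and `heterogeneity`.
#' @export
egger <- function(input, random_effects = TRUE) {
  check_mr_input(input, 3L, "egger")
  flip <- sign(input$beta_exp)
  flip[flip == 0] <- 1
  bx <- input$beta_exp * flip
  by <- input$beta_out * flip
  w <- 1 / input$se_out^2
  sw <- sum(w)
  mx <- sum(w * bx) / sw; my <- sum(w * by) / sw
  sxx <- sum(w * (bx - mx)^2)
  if (sxx == 0) stop("no spread in exposure effects: Egger slope undefined")
  slope <- sum(w * (bx - mx) * (by - my)) / sxx
  intercept <- my - slope * mx
  k <- nrow(input)
  df <- k - 2L
  Q <- sum(w * (by - intercept - slope * bx)^2)
  scale <- if (random_effects) max(1, Q / df) else 1
  se_slope <- sqrt(scale / sxx)
  se_int <- sqrt(scale * (1 / sw + mx^2 / sxx))
  list(estimate = mr_estimate("egger", slope, se_slope, k, Q, df,
                              egger_intercept = intercept,
                              intercept_se = se_int),
       heterogeneity = list(Q = Q, df = df,
                            pvalue = stats::pchisq(Q, df, lower.tail = FALSE)))
}

# per-IV Wald ratios and first-order delta-method SEs
ratio_table <- function(input, second_order = FALSE) {
  ratio <- input$beta_out / input$beta_exp
  se2 <- input$se_out^2 / input$beta_exp^2
  if (second_order)
    se2 <- se2 + input$beta_out^2 * input$se_exp^2 / input$beta_exp^4
  data.frame(ratio = ratio, se = sqrt(se2))
}

weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(x[1])
  if (cs[length(x)] <= 0.5) return(x[length(x)])
  stats::approx(cs, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Weighted median of per-IV Wald ratios with inverse-variance weights;
#' consistent when at least half the weight lies on valid instruments.
#' SE by seeded parametric bootstrap of the ratios.
#'
#' @inheritParams ivw
#' @param n_boot bootstrap replicates for the SE.
#' @param seed integer seed for the bootstrap.
#' @param second_order include the second-order term in the ratio SE.
#' @return `mr_estimate`.
#' @export
weighted_median <- function(input, n_boot = 1000, seed = 1,
                            second_order = FALSE) {
  check_mr_input(input, 3L, "weighted_median")
  rt <- ratio_table(input, second_order)
  w <- 1 / rt$se^2
  est <- weighted_median_point(rt$ratio, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      r <- rnorm(nrow(rt), rt$ratio, rt$se)
      weighted_median_point(r, w)
    }, 0)
  })
  mr_estimate("weighted_median", est, sd(boot), nrow(input))
}

# evaluate expr with a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

mode_point <- function(ratio, w, bandwidth_factor) {
  s <- mad(ratio)
  if (s == 0) return(ratio[1])
  h <- bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
  d <- density(ratio, weights = w / sum(w), bw = h, n = 512)
  d$x[which.max(d$y)]
}

#' Mode-based estimator
#'
#' Mode of the kernel-smoothed density of per-IV Wald ratios: simple
#' (equal weights) or weighted (inverse-variance weights). The bandwidth
#' is a median-absolute-deviation rule, 0.9 * MAD(ratios) * k^(-1/5),
#' scaled by `bandwidth_factor`. SE by seeded parametric bootstrap.
#'
#' @inheritParams weighted_median
#' @param weighted use inverse-variance weights (`TRUE`) or equal
#'   weights (`FALSE`, the simple mode).
#' @param bandwidth_factor multiplier on the bandwidth rule.
#' @return `mr_estimate`.
#' @export
mode_estimator <- function(input, weighted = FALSE, bandwidth_factor = 1,
                           n_boot = 1000, seed = 1, second_order = FALSE) {
  check_mr_input(input, 3L, "mode_estimator")
  rt <- ratio_table(input, second_order)
  w <- if (weighted) 1 / rt$se^2 else rep(1, nrow(rt))
  est <- mode_point(rt$ratio, w, bandwidth_factor)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      r <- rnorm(nrow(rt), rt$ratio, rt$se)
      mode_point(r, w, bandwidth_factor)
    }, 0)
  })
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              est, sd(boot), nrow(input))
}

#' Run every univariable estimator on one IV table
#'
#' @inheritParams ivw
#' @param seed seed for the bootstrap-based estimators.
#' @param n_boot bootstrap replicates.
#' @return data.frame with one row per method (`method, n_iv, alpha,
#'   se, p, Q, Q_df, Q_p, egger_intercept, intercept_p`).
#' @export
mr_all_methods <- function(input, seed = 1, n_boot = 1000) {
  rows <- list()
  add <- function(e) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = e$method, n_iv = e$n_iv, alpha = e$alpha, se = e$se,
      p = e$pvalue, Q = e$Q, Q_df = e$Q_df, Q_p = e$Q_p,
      egger_intercept = e$egger_intercept, intercept_p = e$intercept_p)
  }
  if (nrow(input) == 1L) {
    add(wald_ratio(input$beta_exp, input$se_exp, input$beta_out, input$se_out))
    return(do.call(rbind, rows))
  }
  add(ivw(input)$estimate)
  if (nrow(input) >= 3L) {
    add(egger(input)$estimate)
    add(weighted_median(input, n_boot = n_boot, seed = seed))
    add(mode_estimator(input, weighted = FALSE, n_boot = n_boot, seed = seed + 1L))
    add(mode_estimator(input, weighted = TRUE, n_boot = n_boot, seed = seed + 2L))
  }
  do.call(rbind, rows)
}

#' Select instruments and align one exposure/outcome pair
#'
#' The full IV-selection chain for one direction: clump the exposure's
#' genome-wide significant variants, apply genomic masks, align with the
#' outcome, then the allele-frequency concordance and Steiger filters.
#'
#' @param exposure,outcome harmonized `summary_stats`.
#' @param ld `ld_matrix`.
#' @param masks region masks (default [default_masks()]).
#' @param af_max_diff allele-frequency concordance threshold.
#' @param steiger_threshold Steiger removal boundary (`NULL` disables).
#' @param trait_panel optional list of `summary_stats` for the
#'   multi-trait Steiger pleiotropy filter (`NULL` disables).
#' @inheritParams clump
#' @return aligned, filtered IV table (possibly with < 2 rows) with an
#'   `attrition` attribute counting rows surviving each stage.
#' @export
select_instruments <- function(exposure, outcome, ld, masks = default_masks(),
                               p1 = 1e-4, p2 = 0.01, kb = 250, r2 = 0.01,
                               gw_threshold = 5e-8, af_max_diff = 0.05,
                               steiger_threshold = -1.96, trait_panel = NULL) {
  ivs <- clump(exposure, ld, p1 = p1, p2 = p2, kb = kb, r2 = r2,
               gw_threshold = gw_threshold)
  n_clump <- nrow(ivs)
  ivs <- apply_region_masks(ivs, masks)
  n_mask <- nrow(ivs)
  if (!is.null(trait_panel)) ivs <- multi_trait_steiger_filter(
    exposure, trait_panel, ivs, threshold = steiger_threshold)
  n_multi <- nrow(ivs)
  n_af <- 0L
  if (nrow(ivs) == 0L) {
    out <- data.table(SNP = character(0))
  } else {
    iv_ss <- ss_rewrap(ivs[, SS_COLS, with = FALSE], exposure)
    out <- align_pair(iv_ss, outcome)
    out <- af_concordance_filter(out, max_diff = af_max_diff)
    n_af <- nrow(out)
    if (!is.null(steiger_threshold))
      out <- steiger_filter(out, threshold = steiger_threshold)
  }
  att <- data.table(step = c("clump", "masks", "multi_trait_steiger",
                             "align_af", "steiger"),
                    n = c(n_clump, n_mask, n_multi, n_af, nrow(out)))
  setattr(out, "attrition", att)
  out
}

#' Bidirectional univariable MR for one trait pair
#'
#' Runs the complete IV-selection chain and all estimators in both
#' directions (LTL as exposure and as outcome). A direction with fewer
#' than 2 surviving instruments is reported as not computable.
#'
#' @param ltl_ss,trait_ss harmonized `summary_stats`.
#' @param ld `ld_matrix`.
#' @param masks_ltl masks applied when LTL is the exposure (HBB + HLA by
#'   default); `masks_trait` when the trait is (HLA only by default).
#' @inheritParams select_instruments
#' @param seed bootstrap seed.
#' @return list with `forward` (LTL -> trait) and `reverse`
#'   (trait -> LTL), each either a method table from [mr_all_methods()]
#'   or `NULL` with attrition recorded in `attrition_forward/reverse`.
#' @export
bidirectional_mr <- function(ltl_ss, trait_ss, ld,
                             masks_ltl = default_masks(),
                             masks_trait = default_masks()[
                               default_masks()$name == "HLA", ],
                             p1 = 1e-4, p2 = 0.01, kb = 250, r2 = 0.01,
                             gw_threshold = 5e-8, af_max_diff = 0.05,
                             steiger_threshold = -1.96, seed = 1) {
  fwd_iv <- select_instruments(ltl_ss, trait_ss, ld, masks = masks_ltl,
                               p1 = p1, p2 = p2, kb = kb, r2 = r2,
                               gw_threshold = gw_threshold,
                               af_max_diff = af_max_diff,
                               steiger_threshold = steiger_threshold)
  rev_iv <- select_instruments(trait_ss, ltl_ss, ld, masks = masks_trait,
                               p1 = p1, p2 = p2, kb = kb, r2 = r2,
                               gw_threshold = gw_threshold,
                               af_max_diff = af_max_diff,
                               steiger_threshold = steiger_threshold)
  run <- function(iv) if (nrow(iv) >= 2) mr_all_methods(iv, seed = seed) else NULL
  list(forward = run(fwd_iv), reverse = run(rev_iv),
       n_iv_forward = nrow(fwd_iv), n_iv_reverse = nrow(rev_iv),
       attrition_forward = attr(fwd_iv, "attrition"),
       attrition_reverse = attr(rev_iv, "attrition"))
}
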