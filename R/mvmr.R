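# Multivariable MR, conditional instrument-strength diagnostics, and
# mediation analysis: total/direct/indirect effects, mediation
# proportion with a simulated confidence interval, and the iterative
# causal-network construction.

#' Multivariable MR fit
#'
#' Weighted zero-intercept multiple regression of outcome associations
#' on the matrix of exposure associations with weights 1/se_out^2. Each
#' coefficient is the direct effect of that exposure conditional on the
#' others. SEs carry multiplicative over-dispersion scaling
#' sqrt(max(1, Q/df)) with df = k - p, as in [ivw()].
#'
#' @param beta_exp numeric matrix (k IVs x p exposures) of exposure
#'   associations; column names identify exposures.
#' @param se_exp matrix of matching standard errors (used by
#'   [conditional_f()], not by the point fit).
#' @param beta_out,se_out outcome associations (length k).
#' @param random_effects multiplicative over-dispersion (default TRUE).
#' @return list of class `mvmr_result`: per-exposure `effects` table
#'   (`exposure, theta, se, p`), heterogeneity `Q`, `Q_df`, `Q_p`, and
#'   `conditional_F` per exposure.
#' @export
mvmr_fit <- function(beta_exp, se_exp, beta_out, se_out,
                     random_effects = TRUE) {
  X <- as.matrix(beta_exp)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  k <- nrow(X); p <- ncol(X)
  if (k < p + 1) stop("need more instruments than exposures (k >= p + 1)")
  if (any(se_out <= 0)) stop("standard errors must be positive")
  w <- 1 / se_out^2
  XtW <- t(X * w)
  A <- XtW %*% X
  qrA <- qr(A)
  if (qrA$rank < p) {
    stop("rank-deficient exposure matrix; collinear exposures: ",
         paste(colnames(X), collapse = ", "))
  }
  theta <- solve(A, XtW %*% cbind(beta_out))[, 1]
  resid <- beta_out - as.numeric(X %*% theta)
  Q <- sum(w * resid^2)
  df <- k - p
  scale <- if (random_effects) max(1, Q / df) else 1
  V <- solve(A) * scale
  se <- sqrt(diag(V))
  condF <- vapply(seq_len(p), function(j)
    conditional_f(X, as.matrix(se_exp), j), 0)
  structure(list(
    effects = data.frame(exposure = colnames(X), theta = theta, se = se,
                         p = 2 * pnorm(-abs(theta / se)), row.names = NULL),
    Q = Q, Q_df = df, Q_p = stats::pchisq(Q, df, lower.tail = FALSE),
    conditional_F = setNames(condF, colnames(X)),
    vcov = V, n_iv = k), class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("MVMR: %d IVs, %d exposures; Q = %.3g (df %d, p = %.3g)\n",
              x$n_iv, nrow(x$effects), x$Q, x$Q_df, x$Q_p))
  print(cbind(x$effects, cond_F = x$conditional_F))
  invisible(x)
}

#' Conditional F-statistic for one exposure
#'
#' Instrument strength for exposure `j` conditional on the remaining
#' exposures: the exposure-association vector is regressed (weights
#' 1/se_exp_j^2) on the other exposures' associations; the residual
#' chi-square Q_j with df = k - (p - 1) gives F = max(0, (Q_j - df)/df).
#' With a single exposure this reduces to the unconditional mean
#' F = mean((beta/se)^2).
#'
#' @param beta_exp k x p matrix of exposure associations.
#' @param se_exp matching SE matrix.
#' @param j exposure column index.
#' @return scalar F value (>= 0).
#' @export
conditional_f <- function(beta_exp, se_exp, j) {
  X <- as.matrix(beta_exp); S <- as.matrix(se_exp)
  k <- nrow(X); p <- ncol(X)
  w <- 1 / S[, j]^2
  if (p == 1L) return(mean((X[, 1] / S[, 1])^2))
  y <- X[, j]
  Z <- X[, -j, drop = FALSE]
  ZtW <- t(Z * w)
  A <- ZtW %*% Z
  fit <- tryCatch(solve(A, ZtW %*% cbind(y))[, 1], error = function(e) NULL)
  resid <- if (is.null(fit)) rep(0, k) else y - as.numeric(Z %*% fit)
  Qj <- sum(w * resid^2)
  df <- k - (p - 1L)
  max(0, (Qj - df) / df)
}

#' Correct an MR estimate for regression dilution bias
#'
#' Noise in the exposure-association estimates attenuates any slope
#' regressed on them by the reliability ratio
#' lambda = var_signal / (var_signal + mean(se_exp^2)), where
#' var_signal = max(var(beta_exp) - mean(se_exp^2), eps). The corrected
#' estimate divides by lambda. When the signal variance hits the floor
#' the correction is capped and flagged.
#'
#' @param alpha estimate to correct.
#' @param beta_exp,se_exp instrument exposure associations and SEs.
#' @param eps floor on the signal variance.
#' @return list with `alpha` (corrected), `lambda`, `capped`.
#' @export
dilution_correct <- function(alpha, beta_exp, se_exp, eps = 1e-12) {
  noise <- mean(se_exp^2)
  vs <- var(beta_exp) - noise
  capped <- vs <= eps
  vs <- max(vs, eps)
  lambda <- vs / (vs + noise)
  list(alpha = alpha / lambda, lambda = lambda, capped = capped)
}

#' Simulated confidence interval for a mediation proportion
#'
#' Draws `n_sim` (indirect, total) pairs from
#' N(alpha_indirect, se_indirect) and N(alpha_total, se_total), forms
#' the ratio per draw, and reports the 2.5th/97.5th percentiles (in %)
#' with the upper limit capped at 100%. The point estimate is
#' 100 * alpha_indirect / alpha_total, likewise capped at 100%; negative
#' ratios are reported uncapped with a sign flag. A total effect within
#' 2 SE of zero flags the ratio distribution as unstable.
#'
#' @param alpha_indirect,se_indirect indirect effect and SE.
#' @param alpha_total,se_total total effect and SE.
#' @param n_sim simulated ratios (default 10000).
#' @param seed integer seed.
#' @return list `P_M`, `ci_lower`, `ci_upper` (percent), `negative`,
#'   `unstable`.
#' @export
mediation_ci <- function(alpha_indirect, se_indirect, alpha_total, se_total,
                         n_sim = 10000, seed = 1) {
  if (se_indirect < 0 || se_total < 0) stop("SEs must be non-negative")
  draws <- withr_seed(seed, {
    ind <- rnorm(n_sim, alpha_indirect, se_indirect)
    tot <- rnorm(n_sim, alpha_total, se_total)
    100 * ind / tot
  })
  qs <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  pm <- 100 * alpha_indirect / alpha_total
  list(P_M = min(pm, 100),
       ci_lower = qs[1],
       ci_upper = min(qs[2], 100),
       negative = pm < 0,
       unstable = abs(alpha_total) < 2 * se_total)
}

#' Mediation analysis through a mediator trait
#'
#' Quantifies how much of an exposure's causal effect on an outcome is
#' transmitted through a mediator (here LTL). Instruments come from the
#' two-phase clumping scheme; Steiger filtering is applied to exposure
#' IVs with respect to both mediator and outcome, and to mediator IVs
#' with respect to the outcome. Then:
#' total = IVW(exposure -> outcome) on exposure IVs;
#' (direct, theta_M) from the two-exposure MVMR of the outcome on
#' exposure + mediator over the pooled IVs;
#' indirect (difference) = total - direct (exact identity);
#' indirect (product) = IVW(exposure -> mediator) * theta_M, each factor
#' corrected for regression dilution bias; and the mediation proportion
#' with its simulated CI from [mediation_ci()] using the product-method
#' indirect effect and a first-order delta SE.
#'
#' @param exposure_ss,mediator_ss,outcome_ss harmonized `summary_stats`.
#' @param ld `ld_matrix`.
#' @param masks region masks applied to both IV sets.
#' @param n_sim,seed CI simulation controls.
#' @param steiger_threshold Steiger boundary (`NULL` disables).
#' @param dilution apply the regression-dilution correction to the
#'   product-method factors (default TRUE).
#' @inheritParams clump
#' @return list of class `mediation_result` with the effects, the
#'   mediation proportion and CI, instrument counts and conditional
#'   F-statistics; `ok = FALSE` when any stage has < 2 instruments.
#' @export
mediate <- function(exposure_ss, mediator_ss, outcome_ss, ld,
                    masks = default_masks(), p1 = 1e-4, p2 = 0.01, kb = 250,
                    r2 = 0.01, gw_threshold = 5e-8,
                    steiger_threshold = -1.96, dilution = TRUE,
                    n_sim = 10000, seed = 1) {
  not_computable <- function(why) structure(list(ok = FALSE, reason = why),
                                            class = "mediation_result")
  tp <- two_phase_mediation_clump(exposure_ss, mediator_ss, ld, p1 = p1,
                                  p2 = p2, kb = kb, r2 = r2,
                                  gw_threshold = gw_threshold)
  exp_iv <- apply_region_masks(tp$exposure_ivs, masks)
  med_iv <- apply_region_masks(tp$mediator_ivs, masks)
  if (nrow(exp_iv) < 2 || nrow(med_iv) < 1)
    return(not_computable("too few instruments after two-phase clumping"))

  sub_ss <- function(ss, snps) ss_rewrap(
    as.data.table(ss)[SNP %in% snps, SS_COLS, with = FALSE], ss)
  if (!is.null(steiger_threshold)) {
    # exposure IVs: Steiger vs outcome and vs mediator
    ex_keep <- steiger_filter(align_pair(sub_ss(exposure_ss, exp_iv$SNP),
                                         outcome_ss), steiger_threshold)$SNP
    ex_keep2 <- steiger_filter(align_pair(sub_ss(exposure_ss, exp_iv$SNP),
                                          mediator_ss), steiger_threshold)$SNP
    exp_iv <- exp_iv[SNP %in% intersect(ex_keep, ex_keep2)]
    # mediator IVs: Steiger vs outcome
    md_keep <- steiger_filter(align_pair(sub_ss(mediator_ss, med_iv$SNP),
                                         outcome_ss), steiger_threshold)$SNP
    med_iv <- med_iv[SNP %in% md_keep]
  }
  if (nrow(exp_iv) < 2 || nrow(med_iv) < 1)
    return(not_computable("too few instruments after Steiger filtering"))

  # total effect: IVW exposure -> outcome on exposure IVs
  pair_eo <- align_pair(sub_ss(exposure_ss, exp_iv$SNP), outcome_ss)
  if (nrow(pair_eo) < 2) return(not_computable("exposure IVs absent from outcome"))
  total <- ivw(pair_eo)$estimate

  # exposure -> mediator (for the product method)
  pair_em <- align_pair(sub_ss(exposure_ss, exp_iv$SNP), mediator_ss)
  if (nrow(pair_em) < 2) return(not_computable("exposure IVs absent from mediator"))
  a_em <- ivw(pair_em)$estimate

  # two-exposure MVMR over pooled IVs
  pool <- unique(c(exp_iv$SNP, med_iv$SNP))
  edt <- as.data.table(exposure_ss)[match(pool, SNP)]
  mdt <- as.data.table(mediator_ss)[match(pool, SNP)]
  odt <- as.data.table(outcome_ss)[match(pool, SNP)]
  ok <- !(is.na(edt$SNP) | is.na(mdt$SNP) | is.na(odt$SNP))
  if (sum(ok) < 3) return(not_computable("too few pooled IVs present in all traits"))
  X <- cbind(exposure = edt$BETA[ok], mediator = mdt$BETA[ok])
  S <- cbind(exposure = edt$SE[ok], mediator = mdt$SE[ok])
  fit <- mvmr_fit(X, S, odt$BETA[ok], odt$SE[ok])
  direct <- fit$effects[fit$effects$exposure == "exposure", ]
  theta_m <- fit$effects[fit$effects$exposure == "mediator", ]

  ind_diff <- total$alpha - direct$theta
  a_em_c <- a_em$alpha; se_em_c <- a_em$se
  th_m_c <- theta_m$theta; se_thm_c <- theta_m$se
  dil <- list(exposure = NULL, mediator = NULL)
  if (dilution) {
    d1 <- dilution_correct(a_em_c, pair_em$beta_exp, pair_em$se_exp)
    a_em_c <- d1$alpha; se_em_c <- a_em$se / d1$lambda
    d2 <- dilution_correct(th_m_c, mdt$BETA[ok], mdt$SE[ok])
    th_m_c <- d2$alpha; se_thm_c <- theta_m$se / d2$lambda
    dil <- list(exposure = d1, mediator = d2)
  }
  ind_prod <- a_em_c * th_m_c
  se_prod <- sqrt(a_em_c^2 * se_thm_c^2 + th_m_c^2 * se_em_c^2)
  se_diff <- sqrt(total$se^2 + direct$se^2) # conservative: ignores covariance

  ci <- mediation_ci(ind_prod, se_prod, total$alpha, total$se,
                     n_sim = n_sim, seed = seed)
  structure(list(
    ok = TRUE,
    exposure = trait_id(exposure_ss), mediator = trait_id(mediator_ss),
    outcome = trait_id(outcome_ss),
    alpha_total = total$alpha, se_total = total$se, p_total = total$pvalue,
    alpha_direct = direct$theta, se_direct = direct$se, p_direct = direct$p,
    alpha_EM = a_em$alpha, se_EM = a_em$se,
    theta_M = theta_m$theta, se_theta_M = theta_m$se,
    alpha_indirect_difference = ind_diff, se_indirect_difference = se_diff,
    alpha_indirect_product = ind_prod, se_indirect_product = se_prod,
    p_indirect = 2 * pnorm(-abs(ind_prod / se_prod)),
    P_M = ci$P_M, ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
    unstable = ci$unstable,
    n_iv_exposure = nrow(exp_iv), n_iv_mediator = nrow(med_iv),
    cond_F_exposure = fit$conditional_F[["exposure"]],
    cond_F_mediator = fit$conditional_F[["mediator"]],
    dilution = dil, n_sim = n_sim, seed = seed),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat("mediation not computable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("mediation %s -> %s -> %s\n", x$exposure, x$mediator, x$outcome))
  cat(sprintf("  total %.4g (SE %.3g) | direct %.4g | indirect prod %.4g, diff %.4g\n",
              x$alpha_total, x$se_total, x$alpha_direct,
              x$alpha_indirect_product, x$alpha_indirect_difference))
  cat(sprintf("  P_M = %.1f%% [%.1f%%, %.1f%%]\n", x$P_M, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Build a causal network by iterative MVMR
#'
#' For every ordered trait pair (A -> B), fits an MVMR of B on A with
#' all remaining traits as co-exposures, instruments chosen by
#' minimum-rank clumping over the exposures. Edges are kept at nominal
#' p < 0.05 and tiered at the strict threshold.
#'
#' @param ss_map named list of harmonized `summary_stats` (>= 3 traits).
#' @param ld `ld_matrix`.
#' @param strict_threshold strict significance boundary (default
#'   0.05/141).
#' @param masks region masks.
#' @inheritParams clump
#' @return data.frame of edges: `from, to, theta, se, p, tier`.
#' @export
build_network <- function(ss_map, ld, strict_threshold = 0.05 / 141,
                          masks = default_masks(), p1 = 1e-4, p2 = 0.01,
                          kb = 250, r2 = 0.01, gw_threshold = 5e-8) {
  traits <- names(ss_map)
  if (length(traits) < 3) stop("network construction needs >= 3 traits")
  edges <- list()
  for (to in traits) {
    expos <- setdiff(traits, to)
    ivs <- tryCatch(minrank_clump(ss_map[expos], ld, p1 = p1, p2 = p2,
                                  kb = kb, r2 = r2,
                                  gw_threshold = gw_threshold),
                    error = function(e) NULL)
    if (is.null(ivs)) next
    ivs <- apply_region_masks(ivs, masks)
    if (nrow(ivs) < length(expos) + 1) next
    snps <- ivs$SNP
    X <- sapply(expos, function(tr) {
      dt <- as.data.table(ss_map[[tr]]); dt$BETA[match(snps, dt$SNP)]
    })
    S <- sapply(expos, function(tr) {
      dt <- as.data.table(ss_map[[tr]]); dt$SE[match(snps, dt$SNP)]
    })
    odt <- as.data.table(ss_map[[to]])
    oidx <- match(snps, odt$SNP)
    ok <- stats::complete.cases(cbind(X, S)) & !is.na(oidx)
    if (sum(ok) < length(expos) + 1) next
    fit <- tryCatch(
      mvmr_fit(matrix(X[ok, ], ncol = length(expos),
                      dimnames = list(NULL, expos)),
               matrix(S[ok, ], ncol = length(expos)),
               odt$BETA[oidx[ok]], odt$SE[oidx[ok]]),
      error = function(e) NULL)
    if (is.null(fit)) next
    eff <- fit$effects
    sig <- eff[eff$p < 0.05, , drop = FALSE]
    if (nrow(sig))
      edges[[length(edges) + 1L]] <- data.frame(
        from = sig$exposure, to = to, theta = sig$theta, se = sig$se,
        p = sig$p,
        tier = ifelse(sig$p < strict_threshold, "strict", "nominal"))
  }
  if (!length(edges))
    return(data.frame(from = character(0), to = character(0),
                      theta = numeric(0), se = numeric(0), p = numeric(0),
                      tier = character(0)))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
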