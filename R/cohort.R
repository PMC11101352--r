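# Observational arm: LTL covariate adjustment, per-trait regressions,
# Lasso stability selection, effective number of tests, female
# reproductive-phase model, and effect-comparison statistics.

#' Set extreme values missing
#'
#' Entries outside mean +/- 5 SD (computed on the non-missing input) are
#' set to `NA`; a constant vector (SD = 0) is returned unchanged.
#'
#' @param values numeric vector.
#' @param n_sd width of the retention band in standard deviations.
#' @return vector with outliers replaced by `NA`.
#' @export
trim_outliers <- function(values, n_sd = 5) {
  ok <- !is.na(values)
  if (sum(ok) < 2) {
    warning("fewer than 2 non-missing values; returned unchanged")
    return(values)
  }
  m <- mean(values[ok]); s <- sd(values[ok])
  if (s == 0) return(values)
  out <- values
  out[ok & abs(values - m) > n_sd * s] <- NA
  out
}

#' Adjust LTL for core covariates
#'
#' Residualizes raw standardized LTL on age, age squared, genotyping
#' array, sex, and the sex interactions with each of those (sex x age,
#' sex x age^2, sex x array), plus any extra covariate columns.
#' Residuals are re-standardized to unit variance. Aliased (rank
#' deficient) design columns are dropped with a warning.
#'
#' @param cohort data.frame with columns `ltl`, `age`, `sex` (0/1),
#'   `array` (0/1 or factor), and any extra covariates.
#' @param extra_covariates character vector of additional column names
#'   to regress out (e.g. blood-count traits for the hematological
#'   sensitivity model).
#' @return numeric vector of adjusted LTL aligned to the cohort rows
#'   (`NA` where any model variable is missing).
#' @export
adjust_ltl <- function(cohort, extra_covariates = NULL) {
  need <- c("ltl", "age", "sex", "array", extra_covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort missing column(s): ", paste(miss, collapse = ", "))
  d <- cohort[, need, drop = FALSE]
  d$age2 <- d$age^2
  form <- ltl ~ age + age2 + array + sex + sex:age + sex:age2 + sex:array
  if (length(extra_covariates))
    form <- stats::update(form, stats::as.formula(
      paste("~ . +", paste(extra_covariates, collapse = " + "))))
  cc <- complete.cases(d)
  fit <- lm(form, data = d[cc, , drop = FALSE])
  if (anyNA(coef(fit)))
    warning("rank-deficient adjustment design; aliased columns dropped: ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  res <- rep(NA_real_, nrow(cohort))
  res[cc] <- residuals(fit)
  res / sd(res, na.rm = TRUE)
}

#' Regress adjusted LTL on a single trait
#'
#' The trait (and any covariates) is scaled to zero mean and unit
#' variance on the complete cases, so the slope is in SD_LTL per
#' SD_trait. Fewer than 10 complete cases flags the result unusable.
#'
#' @param adjusted_ltl numeric vector (output of [adjust_ltl()]).
#' @param trait numeric vector, same length.
#' @param covariates optional numeric matrix/data.frame of additional
#'   regressors.
#' @param trait_id label carried into the result.
#' @param scale_trait set `FALSE` to keep the trait on its native scale
#'   (used for age, reported per year).
#' @return one-row data.frame `trait, beta, se, pvalue, n_used, usable`.
#' @export
regress_single_trait <- function(adjusted_ltl, trait, covariates = NULL,
                                 trait_id = "trait", scale_trait = TRUE) {
  d <- data.frame(y = adjusted_ltl, x = trait)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < 10 || sd(d$x) == 0)
    return(data.frame(trait = trait_id, beta = NA_real_, se = NA_real_,
                      pvalue = NA_real_, n_used = n, usable = FALSE))
  if (scale_trait) d$x <- as.numeric(scale(d$x))
  if (ncol(d) > 2)
    for (j in seq(3, ncol(d))) d[[j]] <- as.numeric(scale(d[[j]]))
  fit <- lm(y ~ ., data = d)
  sm <- summary(fit)$coefficients
  beta <- sm["x", 1]; se <- sm["x", 2]
  # normal approximation at biobank scale, exact t otherwise
  p <- if (n > 200) 2 * pnorm(-abs(beta / se)) else sm["x", 4]
  data.frame(trait = trait_id, beta = beta, se = se, pvalue = p,
             n_used = n, usable = TRUE)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate input with zero variance in both
#' groups and equal means returns `t = 0, p = 1`.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  va <- var(a) / length(a); vb <- var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Lasso stability selection of LTL predictors
#'
#' Fits `n_fits` cross-validated Lasso regressions of (unadjusted) LTL
#' on the standardized candidate traits, re-randomizing the CV fold
#' assignment each time, taking lambda by the one-standard-error rule,
#' and recording which candidates receive a nonzero coefficient. Traits
#' selected in at least `freq_cut` of the fits are returned; the
#' variance explained is the R-squared of a joint OLS refit on the
#' selected traits. Restricted to complete cases.
#'
#' @param cohort data.frame containing `ltl` and the candidate columns.
#' @param candidates character vector of candidate trait columns.
#' @param n_fits number of repeated CV fits (default 50).
#' @param freq_cut selection-frequency threshold (default 0.95).
#' @param nfolds CV folds per fit.
#' @param seed integer seed; fold seeds are derived from it.
#' @param max_missing candidates with a higher missingness fraction are
#'   excluded before complete-case restriction (default 0.07).
#' @return list with `selected_traits`, `selection_frequency`,
#'   `variance_explained`, `n_complete`, `candidates_used`.
#' @export
lasso_stability <- function(cohort, candidates, n_fits = 50, freq_cut = 0.95,
                            nfolds = 10, seed = 1, max_missing = 0.07) {
  stopifnot("ltl" %in% names(cohort))
  miss_frac <- vapply(candidates, function(v) mean(is.na(cohort[[v]])), 0)
  candidates <- candidates[miss_frac < max_missing]
  if (length(candidates) == 0L) stop("no candidate passes the missingness gate")
  d <- cohort[, c("ltl", candidates)]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("complete-case submatrix is empty")
  x <- scale(as.matrix(d[, candidates, drop = FALSE]))
  keep <- !is.na(colSums(x)) # drop zero-variance candidates
  x <- x[, keep, drop = FALSE]
  candidates <- candidates[keep]
  y <- d$ltl
  # glmnet needs >= 2 columns; pad with an inert zero column if needed
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, .pad = 0)
  counts <- setNames(numeric(length(candidates)), candidates)
  for (i in seq_len(n_fits)) {
    set.seed(seed + i - 1L)
    folds <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, foldid = folds, standardize = FALSE)
    b <- as.numeric(coef(cv, s = "lambda.1se"))[-1]
    if (pad) b <- b[-length(b)]
    counts[b != 0] <- counts[b != 0] + 1
  }
  freq <- counts / n_fits
  selected <- names(freq)[freq >= freq_cut]
  r2 <- if (length(selected)) {
    summary(lm(y ~ x[, selected, drop = FALSE]))$r.squared
  } else 0
  list(selected_traits = selected, selection_frequency = freq,
       variance_explained = r2, n_complete = nrow(d),
       candidates_used = candidates)
}

#' Effective number of independent tests
#'
#' Smallest k such that the k largest eigenvalues of the trait
#' correlation matrix sum to at least `variance_fraction` of the total
#' variance. Negative eigenvalues (possible with pairwise-complete
#' correlation estimates) are clipped to zero with a warning.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param variance_fraction fraction of variance to capture (default
#'   0.995).
#' @return integer number of effective tests.
#' @export
effective_tests <- function(corr, variance_fraction = 0.995) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("corr must be square")
  corr <- (corr + t(corr)) / 2
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    warning("non-PSD correlation matrix; negative eigenvalues clipped to 0")
  }
  ev <- pmax(ev, 0)
  cum <- cumsum(ev)
  as.integer(which(cum >= variance_fraction * sum(ev))[1])
}

#' Female reproductive-phase regression
#'
#' Splits each woman's age into years spent (1) before first live
#' birth, (2) premenopausal after first live birth, and (3)
#' postmenopausal, and jointly regresses LTL on the three durations plus
#' indicator variables for parity and menopause. Phase 2 and 3 are 0 for
#' nulliparous and premenopausal women respectively. Women whose first
#' child came after menopause, who lack a menopausal status (or age at
#' menopause when postmenopausal), or who lack childbirth information
#' are excluded, as is any record yielding a negative duration.
#'
#' @param cohort data.frame with columns `ltl`, `age`, `sex`, and the
#'   female reproductive fields `age_first_birth`, `age_menopause`,
#'   `n_live_births`, `menopause_status` (0/1).
#' @return list with the fitted coefficients table (`beta_phase1..3`,
#'   parity and menopause indicators, SEs, p-values), `n_used`, and
#'   `n_excluded`.
#' @export
reproductive_phases <- function(cohort) {
  f <- cohort[cohort$sex == 1 | cohort$sex == "female", , drop = FALSE]
  if (!nrow(f)) stop("no female participants")
  n0 <- nrow(f)
  known_parity <- !is.na(f$n_live_births)
  parous <- known_parity & f$n_live_births > 0
  has_meno_status <- !is.na(f$menopause_status)
  post <- has_meno_status & f$menopause_status == 1
  keep <- known_parity & has_meno_status &
    (!parous | !is.na(f$age_first_birth)) &
    (!post | !is.na(f$age_menopause)) &
    !(parous & post & !is.na(f$age_first_birth) & !is.na(f$age_menopause) &
        f$age_first_birth > f$age_menopause) &
    !is.na(f$ltl) & !is.na(f$age)
  f <- f[keep, , drop = FALSE]
  parous <- parous[keep]; post <- post[keep]

  afb <- ifelse(parous, f$age_first_birth, NA_real_)
  amp <- ifelse(post, f$age_menopause, NA_real_)
  # phase 1 runs from birth to first live birth (or current age if
  # nulliparous); the intercept absorbs pre-adult effects
  t1 <- ifelse(parous, pmin(f$age, afb), f$age)
  t2 <- ifelse(parous, ifelse(post, amp, f$age) - afb, 0)
  t3 <- ifelse(post, f$age - amp, 0)
  ok <- t1 >= 0 & t2 >= 0 & t3 >= 0
  n_neg <- sum(!ok)
  f <- f[ok, , drop = FALSE]
  dat <- data.frame(ltl = f$ltl, t1 = t1[ok], t2 = t2[ok], t3 = t3[ok],
                    parity = as.numeric(parous[ok]),
                    menopause = as.numeric(post[ok]))
  fit <- lm(ltl ~ t1 + t2 + t3 + parity + menopause, data = dat)
  sm <- summary(fit)$coefficients
  co <- function(nm, col) if (nm %in% rownames(sm)) sm[nm, col] else NA_real_
  list(
    coefficients = data.frame(
      term = c("phase1", "phase2", "phase3", "parity", "menopause"),
      beta = vapply(c("t1", "t2", "t3", "parity", "menopause"), co, 0, col = 1),
      se = vapply(c("t1", "t2", "t3", "parity", "menopause"), co, 0, col = 2),
      pvalue = vapply(c("t1", "t2", "t3", "parity", "menopause"), co, 0, col = 4),
      row.names = NULL),
    n_used = nrow(dat),
    n_excluded = n0 - nrow(dat),
    n_negative_duration = n_neg)
}

SIMVASTATIN_EFFECT <- c(TC = 1.6, LDL = 1.4, TG = 0.4, HDL = -0.1)

#' Correct lipid levels for statin use
#'
#' Adds the average simvastatin effect back onto measured serum lipid
#' levels of medication users: +1.6 (total cholesterol), +1.4 (LDL),
#' +0.4 (triglycerides), -0.1 (HDL) mmol/L.
#'
#' @param values numeric lipid measurements in mmol/L.
#' @param user logical/0-1 vector flagging cholesterol-lowering drug
#'   users.
#' @param kind one of `"TC"`, `"LDL"`, `"TG"`, `"HDL"`.
#' @return corrected values.
#' @export
statin_adjust <- function(values, user, kind) {
  if (!kind %in% names(SIMVASTATIN_EFFECT))
    stop("unknown lipid kind '", kind, "'; expected TC, LDL, TG or HDL")
  values + SIMVASTATIN_EFFECT[[kind]] * as.numeric(user)
}

#' Compare two effect estimates
#'
#' Tests the difference of two (assumed uncorrelated) estimates:
#' t = (beta_x - beta_y) / sqrt(se_x^2 + se_y^2), two-sided p from a
#' standard normal.
#'
#' @param beta_x,se_x,beta_y,se_y estimates and standard errors.
#' @return list with `t` and `p`.
#' @export
compare_effects <- function(beta_x, se_x, beta_y, se_y) {
  if (any(c(se_x, se_y) <= 0)) stop("standard errors must be positive")
  t <- (beta_x - beta_y) / sqrt(se_x^2 + se_y^2)
  list(t = t, p = 2 * pnorm(-abs(t)))
}
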