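# cohort_observational: outlier trimming, LTL adjustment, per-trait
# regression, Welch test, Lasso stability, effective tests, the
# reproductive-phase model, statin correction, effect comparison.

test_that("trim_outliers applies the 5-SD band", {
  set.seed(1)
  x <- c(rnorm(1000), 8)
  tr <- trim_outliers(x)
  # recompute the bound by hand on the input
  bound <- mean(x) + 5 * sd(x)
  expect_true(8 > bound)
  expect_true(is.na(tr[1001]))
  expect_equal(sum(is.na(tr)), sum(abs(x - mean(x)) > 5 * sd(x)))
  # degenerate inputs unchanged
  expect_equal(trim_outliers(rep(2, 5)), rep(2, 5))
  expect_equal(trim_outliers(c(-1, 1)), c(-1, 1))
  expect_warning(trim_outliers(c(NA_real_, NA_real_)), "non-missing")
})

test_that("adjust_ltl residuals are orthogonal to the design", {
  co <- simulate_cohort(cohort_config(n = 4000, use_phases = FALSE, seed = 5))
  adj <- adjust_ltl(co)
  design <- cbind(co$age, co$age^2, co$array, co$sex, co$sex * co$age,
                  co$sex * co$age^2, co$sex * co$array)
  for (j in seq_len(ncol(design)))
    expect_lt(abs(cor(adj, design[, j])), 1e-10)
  expect_equal(sd(adj), 1, tolerance = 1e-12)
  # planted age decline leaves no age trend in residuals
  expect_lt(abs(coef(lm(adj ~ co$age))[2]), 1e-10)
})

test_that("regress_single_trait recovers planted effects and flags tiny n", {
  co <- simulate_cohort(cohort_config(
    n = 100000, use_phases = FALSE,
    trait_effects = c(planted = 0.05, noise = 0), seed = 11))
  adj <- adjust_ltl(co)
  r <- regress_single_trait(adj, co$planted, trait_id = "planted")
  # generated ltl has noise sd 1, so effects scale by 1/sd(adj basis);
  # recovery within 3 SE of the planted value on the adjusted scale
  expect_lt(abs(r$beta - 0.05), 3 * r$se + 0.002)
  r0 <- regress_single_trait(adj, co$noise)
  expect_gt(r0$pvalue, 0.001)
  # self-regression gives slope 1 (perfect fit warns)
  rs <- suppressWarnings(regress_single_trait(adj, adj * 2 + 1))
  expect_equal(rs$beta, sd(adj), tolerance = 1e-8)
  # fewer than 10 complete cases -> unusable
  ru <- regress_single_trait(adj[1:5], co$planted[1:5])
  expect_false(ru$usable)
})

test_that("welch_t matches t.test and handles degenerate input", {
  a <- c(0, 1); b <- c(10, 11)
  w <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  expect_lt(w$p, 0.05)
  # antisymmetry
  w2 <- welch_t(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  # identical constant groups
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)
  set.seed(2)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(welch_t(x, y)$p, t.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("lasso_stability selects planted signal, not noise", {
  set.seed(9)
  n <- 20000 # biobank-scale power for a 0.15-SD predictor
  noise <- matrix(rnorm(n * 10), n)
  colnames(noise) <- paste0("noise", 1:10)
  planted <- rnorm(n)
  co <- data.frame(ltl = 0.15 * planted + rnorm(n), noise,
                   planted = planted)
  res <- lasso_stability(co, c("planted", paste0("noise", 1:10)),
                         n_fits = 20, seed = 3)
  expect_equal(res$selection_frequency[["planted"]], 1)
  expect_true("planted" %in% res$selected_traits)
  expect_true(all(res$selection_frequency[paste0("noise", 1:10)] < 0.95))
  expect_gt(res$variance_explained, 0.005)
  # deterministic given seed
  res2 <- lasso_stability(co, c("planted", paste0("noise", 1:10)),
                          n_fits = 20, seed = 3)
  expect_identical(res$selection_frequency, res2$selection_frequency)
  # freq_cut = 0 returns the union of per-fit selections
  res0 <- lasso_stability(co, c("planted", paste0("noise", 1:10)),
                          n_fits = 5, freq_cut = 0, seed = 3)
  expect_setequal(res0$selected_traits,
                  names(res0$selection_frequency))
})

test_that("lasso_stability honors the missingness gate", {
  set.seed(10)
  co <- data.frame(ltl = rnorm(500), a = rnorm(500), b = rnorm(500))
  co$b[1:50] <- NA  # 10% missing > 7% gate
  res <- lasso_stability(co, c("a", "b"), n_fits = 2, seed = 1)
  expect_false("b" %in% res$candidates_used)
  expect_error(lasso_stability(co, "b", n_fits = 2), "missingness gate")
})

test_that("effective_tests follows the cumulative-eigenvalue rule", {
  expect_equal(effective_tests(diag(10)), 10L)
  expect_equal(effective_tests(matrix(1, 3, 3)), 1L)
  # two perfectly correlated pairs + 1 free trait: eigenvalues 2,2,1,0,0
  blk <- diag(5)
  blk[1, 2] <- blk[2, 1] <- 1
  blk[3, 4] <- blk[4, 3] <- 1
  expect_equal(effective_tests(blk), 3L)
  # clipping warning on a non-PSD matrix
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_warning(effective_tests(bad), "clipped")
  # never exceeds the trait count
  set.seed(4)
  X <- matrix(rnorm(200 * 8), 200)
  expect_lte(effective_tests(cor(X)), 8L)
})

test_that("reproductive phase durations and coefficients are exact on a
           noiseless fixture", {
  # women with known durations; ltl built from known coefficients
  b <- c(-0.014, -0.017, -0.022); par_c <- -0.03; men_c <- -0.02
  w <- data.frame(
    sex = 1,
    age = c(60, 45, 55, 70, 52, 48, 41, 66),
    age_first_birth = c(26, NA, 30, 22, 24, NA, 28, 35),
    age_menopause = c(50, NA, 48, 51, NA, 46, NA, 54),
    n_live_births = c(2, 0, 1, 3, 2, 0, 1, 2),
    menopause_status = c(1, 0, 1, 1, 0, 1, 0, 1))
  t1 <- c(26, 45, 30, 22, 24, 48, 28, 35)
  t2 <- c(24, 0, 18, 29, 28, 0, 13, 19)
  t3 <- c(10, 0, 7, 19, 0, 2, 0, 12)
  parity <- as.numeric(w$n_live_births > 0)
  meno <- w$menopause_status
  w$ltl <- b[1] * t1 + b[2] * t2 + b[3] * t3 + par_c * parity + men_c * meno
  fit <- suppressWarnings(reproductive_phases(w)) # perfect fit warns
  expect_equal(fit$n_used, 8)
  expect_equal(fit$coefficients$beta[1:3], b, tolerance = 1e-10)
  expect_equal(fit$coefficients$beta[4:5], c(par_c, men_c), tolerance = 1e-10)
  # spec-sheet spot checks: age 60, first birth 26, menopause 50
  expect_equal(c(t1[1], t2[1], t3[1]), c(26, 24, 10))
  # nulliparous premenopausal age 45 -> phases (45, 0, 0)
  expect_equal(c(t1[2], t2[2], t3[2]), c(45, 0, 0))
  # t1 + t2 + t3 = age for parous postmenopausal women
  pp <- parity == 1 & meno == 1
  expect_equal((t1 + t2 + t3)[pp], w$age[pp])
})

test_that("reproductive_phases applies exclusions", {
  w <- data.frame(
    sex = 1, age = c(60, 60, 60, 60),
    age_first_birth = c(26, 55, NA, 26),
    age_menopause = c(50, 50, 50, 50),
    n_live_births = c(2, 2, 2, NA),
    menopause_status = c(1, 1, NA, 1),
    ltl = rnorm(4))
  # only the first woman is eligible: #2 first child post-menopause,
  # #3 lacks menopausal status, #4 lacks childbirth info
  fit <- suppressWarnings(reproductive_phases(
    rbind(w, within(w[rep(1, 8), ], {
      age <- 50 + 1:8 * 2; age_first_birth <- 20 + 1:8
      age_menopause <- 45 + 1:8 / 2; ltl <- rnorm(8)
    }))))
  expect_equal(fit$n_excluded, 3)
})

test_that("statin_adjust adds the published simvastatin constants", {
  expect_equal(statin_adjust(3.0, TRUE, "LDL"), 4.4)
  expect_equal(statin_adjust(1.5, TRUE, "HDL"), 1.4)
  expect_equal(statin_adjust(5.0, TRUE, "TC"), 6.6)
  expect_equal(statin_adjust(1.0, TRUE, "TG"), 1.4)
  expect_equal(statin_adjust(3.0, FALSE, "LDL"), 3.0)
  expect_equal(statin_adjust(c(2, 3), c(TRUE, FALSE), "LDL"), c(3.4, 3))
  expect_error(statin_adjust(1, TRUE, "VLDL"), "unknown lipid kind")
})

test_that("compare_effects computes the uncorrelated-difference test", {
  r <- compare_effects(0.10, 0.02, 0.16, 0.025)
  expect_equal(r$t, -0.06 / sqrt(0.02^2 + 0.025^2), tolerance = 1e-12)
  expect_equal(r$t, -1.874, tolerance = 1e-3)
  expect_equal(compare_effects(0.3, 0.1, 0.3, 0.2)$p, 1)
  r2 <- compare_effects(0.16, 0.025, 0.10, 0.02)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(compare_effects(1, 0, 1, 1), "positive")
})
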