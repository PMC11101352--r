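# instrument_selection: clumping vs the naive oracle, masks, AF
# concordance, Steiger filtering, multi-trait Steiger, two-phase and
# minimum-rank clumping.

test_that("clump reproduces the worked three-SNP example", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)
  r[1, 3] <- r[3, 1] <- r[2, 3] <- r[3, 2] <- sqrt(0.001)
  ld <- make_ld(paste0("s", 1:3), r, pos = c(1e5L, 2e5L, 3e5L))
  ss <- make_ss(paste0("s", 1:3), beta = c(0.08, 0.07, 0.06), se = 0.01,
                pos = c(1e5L, 2e5L, 3e5L),
                p = c(1e-10, 1e-9, 1e-8))
  out <- clump(ss, ld)
  expect_equal(out$SNP, c("s1", "s3"))
  # single significant SNP is its own index
  one <- clump(make_ss("s9", 0.08, 0.01, p = 1e-9), NULL)
  expect_equal(one$SNP, "s9")
  # two linked SNPs 300 kb apart: outside the window, both kept
  r2 <- matrix(c(1, 0.95, 0.95, 1), 2)
  ld2 <- make_ld(c("a", "b"), r2, pos = c(1e6L, 1.3e6L))
  ss2 <- make_ss(c("a", "b"), beta = c(0.08, 0.07), se = 0.01,
                 pos = c(1e6L, 1.3e6L), p = c(1e-10, 1e-9))
  expect_equal(nrow(clump(ss2, ld2)), 2)
  # no genome-wide significant candidate -> empty set
  expect_equal(nrow(clump(make_ss("s1", 0.01, 0.01, p = 1e-4), NULL)), 0)
})

test_that("clump matches the exhaustive greedy oracle on random instances", {
  for (seed in 1:100) {
    inst <- random_clump_instance(seed)
    ld <- make_ld(inst$snp, inst$r, pos = inst$pos)
    ss <- make_ss(inst$snp, beta = rep(0.05, length(inst$snp)), se = 0.01,
                  pos = inst$pos, p = inst$p)
    got <- clump(ss, ld)$SNP
    want <- oracle_clump(inst$snp, inst$chr, inst$pos, inst$p,
                         inst$r^2 * sign(inst$r)^2)
    expect_identical(got, want, label = paste("seed", seed))
  }
})

test_that("retained index variants are mutually unlinked within the window", {
  for (seed in 101:120) {
    inst <- random_clump_instance(seed)
    ld <- make_ld(inst$snp, inst$r, pos = inst$pos)
    ss <- make_ss(inst$snp, beta = rep(0.05, length(inst$snp)), se = 0.01,
                  pos = inst$pos, p = inst$p)
    kept <- clump(ss, ld)
    if (nrow(kept) < 2) next
    for (i in seq_len(nrow(kept) - 1)) for (j in seq(i + 1, nrow(kept))) {
      if (abs(kept$POS[i] - kept$POS[j]) <= 250e3) {
        expect_lt(inst$r[kept$SNP[i], kept$SNP[j]]^2, 0.01)
      }
    }
  }
})

test_that("region masks use 1-based inclusive bounds", {
  ivs <- data.table::data.table(
    SNP = c("a", "b", "c", "d", "e"),
    CHR = c(6L, 6L, 6L, 11L, 1L),
    POS = c(30000000L, 24999999L, 37000000L, 5246696L, 100L))
  out <- apply_region_masks(ivs, default_masks())
  expect_equal(out$SNP, c("b", "e"))           # HLA interior + edges gone
  expect_true("b" %in% out$SNP)                # one bp left of HLA kept
  # HBB mask start is inclusive
  expect_false("d" %in% out$SNP)
  # empty mask list is the identity
  expect_equal(apply_region_masks(ivs, NULL)$SNP, ivs$SNP)
})

test_that("allele-frequency filter removes at the printed >= 0.05 boundary", {
  pair <- data.table::data.table(
    SNP = c("a", "b", "c", "d", "e"),
    eaf_exp = c(0.30, 0.30, 0.30, 0.10, NA),
    eaf_out = c(0.36, 0.349, 0.30, 0.05, 0.3))  # |0.10-0.05| == 0.05 exactly
  out <- af_concordance_filter(pair)
  expect_false("a" %in% out$SNP)  # 0.06 >= 0.05 removed
  expect_true("b" %in% out$SNP)   # 0.049 kept
  expect_true("c" %in% out$SNP)   # equal kept
  expect_false("d" %in% out$SNP)  # exactly 0.05 removed (>= semantics)
  expect_true("e" %in% out$SNP)   # missing retained, flagged
  expect_true(out[out$SNP == "e"]$af_flagged)
})

test_that("steiger_z follows the Fisher-transform closed form", {
  expect_equal(steiger_z(0.05, 1000, 0.05, 1000), 0)
  z <- steiger_z(0.05, 100000, 0.01, 100000)
  want <- (atanh(0.05) - atanh(0.01)) / sqrt(2 / (100000 - 3))
  expect_equal(z, want, tolerance = 1e-12)
  expect_gt(z, 1.96)
  # antisymmetric counterpart
  expect_equal(steiger_z(0.01, 100000, 0.05, 100000), -want)
  # magnitude comparison: sign of r irrelevant
  expect_equal(steiger_z(-0.05, 1e5, 0.01, 1e5),
               steiger_z(0.05, 1e5, 0.01, 1e5))
  expect_error(steiger_z(0.5, 3, 0.1, 100), "exceed 3")
  expect_error(steiger_z(1, 100, 0.1, 100), "< 1")
})

test_that("steiger_filter removes at Z <= -1.96 including the boundary", {
  n <- 100000
  # construct r values giving Z exactly at, just above, just below -1.96
  r_out <- 0.05
  target_z <- function(Z) tanh(atanh(r_out) + Z * sqrt(2 / (n - 3)))
  r_exp <- c(target_z(-1.96), target_z(-1.9599), target_z(-3), 0.05)
  # convert r to beta/se with se = 1/sqrt(n): beta = r (approximately);
  # use exact inversion: r = z/sqrt(z^2+n-2) -> z = r*sqrt((n-2)/(1-r^2))
  to_beta <- function(r) r * sqrt((n - 2) / (1 - r^2)) / sqrt(n)
  pair <- data.table::data.table(
    SNP = c("at", "above", "below", "equal"),
    beta_exp = to_beta(r_exp), se_exp = 1 / sqrt(n), n_exp = n,
    beta_out = to_beta(rep(r_out, 4)), se_out = 1 / sqrt(n), n_out = n)
  out <- steiger_filter(pair)
  expect_false("at" %in% out$SNP)      # Z = -1.96 exactly -> removed
  expect_true("above" %in% out$SNP)    # Z just above -1.96 -> kept
  expect_false("below" %in% out$SNP)
  expect_true("equal" %in% out$SNP)    # Z = 0
  # threshold -Inf is the identity
  expect_equal(nrow(steiger_filter(pair, threshold = -Inf)), 4)
})

test_that("multi-trait Steiger filter enforces exposure primacy and presence", {
  n <- 50000
  exposure <- make_ss(paste0("s", 1:4), beta = 0.04, se = 1 / sqrt(n), n = n)
  # panel trait B: s2 has a much stronger association; s4 absent
  bB <- c(0.01, 0.10, 0.01, NA)
  panelB <- make_ss(paste0("s", 1:3), beta = bB[1:3], se = 1 / sqrt(n), n = n)
  ivs <- data.table::as.data.table(exposure)
  out <- multi_trait_steiger_filter(exposure, list(panelB), ivs)
  expect_false("s2" %in% out$SNP)  # stronger on the panel trait -> removed
  expect_false("s4" %in% out$SNP)  # absent from panel trait -> removed
  expect_true(all(c("s1", "s3") %in% out$SNP))
  # a panel containing the exposure itself: Z = 0 everywhere, retained
  self <- multi_trait_steiger_filter(exposure, list(exposure), ivs)
  expect_equal(self$SNP, ivs$SNP)
  # empty panel is the identity
  expect_equal(multi_trait_steiger_filter(exposure, list(), ivs)$SNP,
               ivs$SNP)
})

test_that("multi-trait output is a subset of the pairwise Steiger output", {
  set.seed(31)
  n <- 50000
  m <- 12
  exposure <- make_ss(paste0("s", 1:m), beta = rnorm(m, 0.04, 0.01),
                      se = 1 / sqrt(n), n = n, pos = 1:m * 1e6L)
  outcome <- make_ss(paste0("s", 1:m), beta = rnorm(m, 0.04, 0.02),
                     se = 1 / sqrt(n), n = n, pos = 1:m * 1e6L)
  ivs <- data.table::as.data.table(exposure)
  multi <- multi_trait_steiger_filter(exposure, list(outcome), ivs)
  pair <- align_pair(exposure, outcome)
  single <- steiger_filter(pair)
  expect_true(all(multi$SNP %in% single$SNP))
})

test_that("filters are order-stable pure row predicates", {
  set.seed(17)
  m <- 30
  pair <- data.table::data.table(
    SNP = paste0("s", 1:m), CHR = sample(c(1L, 6L, 11L), m, TRUE),
    POS = sample(c(3e7L, 2e7L, 5246700L, 1e6L), m, TRUE),
    beta_exp = rnorm(m, 0.03, 0.02), se_exp = 0.004, n_exp = 60000,
    beta_out = rnorm(m, 0.02, 0.02), se_out = 0.004, n_out = 60000,
    eaf_exp = runif(m), eaf_out = runif(m))
  ord1 <- steiger_filter(af_concordance_filter(
    apply_region_masks(pair, default_masks())))
  ord2 <- apply_region_masks(steiger_filter(
    af_concordance_filter(pair)), default_masks())
  expect_setequal(ord1$SNP, ord2$SNP)
})

test_that("two-phase clumping prioritizes exposure IVs over mediator IVs", {
  # exposure IV and a *more significant* mediator SNP in strong LD
  r <- diag(2); r[1, 2] <- r[2, 1] <- sqrt(0.9)
  ld <- make_ld(c("e1", "m1"), r, pos = c(1e5L, 2e5L))
  expo <- make_ss(c("e1", "m1"), beta = c(0.08, 0.01), se = 0.01,
                  pos = c(1e5L, 2e5L), p = c(1e-9, 0.5))
  medi <- make_ss(c("e1", "m1"), beta = c(0.01, 0.09), se = 0.01,
                  pos = c(1e5L, 2e5L), p = c(0.5, 1e-12))
  res <- two_phase_mediation_clump(expo, medi, ld)
  expect_equal(res$exposure_ivs$SNP, "e1")  # kept despite larger p
  expect_equal(nrow(res$mediator_ivs), 0)   # absorbed by the exposure IV
  expect_false(res$ok)

  # no LD between the sets: both fully retained
  ld0 <- make_ld(c("e1", "m1"), diag(2), pos = c(1e6L, 5e6L))
  res0 <- two_phase_mediation_clump(expo, medi, ld0)
  expect_equal(res0$exposure_ivs$SNP, "e1")
  expect_equal(res0$mediator_ivs$SNP, "m1")
  expect_true(res0$ok)
})

test_that("minimum-rank clumping prioritizes per-exposure top hits", {
  # SNP a: rank 1 for exposure A; SNP b: rank 2 for both; in LD
  r <- diag(2); r[1, 2] <- r[2, 1] <- sqrt(0.5)
  ld <- make_ld(c("a", "b"), r, pos = c(1e5L, 2e5L))
  expA <- make_ss(c("a", "b"), beta = c(0.09, 0.08), se = 0.01,
                  pos = c(1e5L, 2e5L), p = c(1e-12, 1e-9))
  expB <- make_ss(c("a", "b"), beta = c(0.07, 0.08), se = 0.01,
                  pos = c(1e5L, 2e5L), p = c(1e-8, 1e-9))
  out <- minrank_clump(list(expA, expB), ld)
  expect_equal(out$SNP, "a")
  # single exposure reduces to ordinary clumping
  single <- minrank_clump(list(expA), ld)
  expect_equal(single$SNP, clump(expA, ld)$SNP)
  # duplicated exposure changes nothing
  dup <- minrank_clump(list(expA, expA), ld)
  expect_equal(dup$SNP, single$SNP)
})

test_that("minrank keeps an exposure top hit over a globally smaller p", {
  # b has the smallest p overall (for exposure B, rank 2 there is a's),
  # while a is rank 1 for A; min ranks: a -> 1, b -> 1; tie broken by
  # smaller min p -> b first
  r <- diag(2); r[1, 2] <- r[2, 1] <- sqrt(0.9)
  ld <- make_ld(c("a", "b"), r, pos = c(1e5L, 2e5L))
  expA <- make_ss(c("a", "b"), beta = c(0.09, 0.05), se = 0.01,
                  pos = c(1e5L, 2e5L), p = c(1e-10, 1e-9))
  expB <- make_ss(c("a", "b"), beta = c(0.05, 0.09), se = 0.01,
                  pos = c(1e5L, 2e5L), p = c(1e-9, 1e-14))
  out <- minrank_clump(list(expA, expB), ld)
  expect_equal(out$SNP, "b")
})
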