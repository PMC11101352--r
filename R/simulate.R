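# Synthetic-data generators: block-LD reference panels, GWAS
# summary-statistic triplets under a linear structural model
# exposure -> mediator -> outcome, and individual-level cohorts with
# age/sex structure and planted trait-LTL effects. Every generator
# returns its ground truth so downstream estimates can be checked by
# parameter recovery.

# non-palindromic allele pairs only, so harmonization keeps everything
SAFE_ALLELES <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                         "T", "G", "G", "T", "T", "C", "C", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulation configuration for GWAS triplets
#'
#' The default configuration is the package's stated synthetic world: a
#' mediation structure exposure -> mediator -> outcome with
#' alpha_EM = 0.5, theta_M = 0.3 and a direct effect theta_direct =
#' 0.35, i.e. a true total effect of 0.5 and mediation proportion of
#' 30%; 50 LD blocks of 4 variants (AR(1) correlation 0.5 within
#' blocks); 20,000 samples per study with no overlap; exposure
#' heritability 0.15 concentrated on its causal block leads so
#' instruments are genome-wide significant; no pleiotropy and no
#' reverse-causal variants unless requested.
#'
#' @param n_blocks,block_size,within_block_rho LD structure: AR(1)
#'   blocks, zero correlation between blocks.
#' @param maf_range effect-allele frequency range.
#' @param n_exp,n_med,n_out per-study GWAS sample sizes.
#' @param sample_overlap_fraction correlation of estimation noise
#'   across studies (0 = two-sample design).
#' @param alpha_EM exposure -> mediator causal effect (SD/SD).
#' @param theta_M mediator -> outcome direct effect.
#' @param theta_direct exposure -> outcome direct effect.
#' @param h2_exp,h2_med,h2_out variance explained by each trait's own
#'   causal variants (exposure; mediator beyond the exposure path;
#'   outcome beyond exposure/mediator paths).
#' @param prop_blocks_exp,prop_blocks_med fraction of blocks whose lead
#'   variant is causal for the exposure / for the mediator's own
#'   genetics (disjoint sets; remaining blocks host outcome-only
#'   variants).
#' @param pleiotropy_frac fraction of exposure-causal variants given a
#'   direct path to the outcome.
#' @param pleiotropy_mean,pleiotropy_sd distribution of those direct
#'   effects (mean > 0 gives directional pleiotropy, mean = 0 balanced).
#' @param reverse_fraction fraction of blocks turned into reverse-causal
#'   hosts: their lead variant acts on the outcome, and the exposure
#'   association is the echo `reverse_ratio` times weaker.
#' @param reverse_ratio exposure/outcome effect ratio of reverse
#'   variants (< 1 so Steiger filtering can catch them).
#' @param effect_dist `"normal"` (spike-and-slab: causal effects drawn
#'   normal then rescaled to the target heritability) or `"fixed"`
#'   (equal magnitude, random sign), the latter guaranteeing every
#'   causal variant clears genome-wide significance at the default
#'   sample sizes.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_blocks = 50, block_size = 4, within_block_rho = 0.5,
                       maf_range = c(0.05, 0.5),
                       n_exp = 20000, n_med = 20000, n_out = 20000,
                       sample_overlap_fraction = 0,
                       alpha_EM = 0.5, theta_M = 0.3, theta_direct = 0.35,
                       h2_exp = 0.15, h2_med = 0.10, h2_out = 0.05,
                       prop_blocks_exp = 0.5, prop_blocks_med = 0.25,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       reverse_fraction = 0, reverse_ratio = 0.5,
                       effect_dist = c("normal", "fixed"), seed = 1) {
  effect_dist <- match.arg(effect_dist)
  cfg <- list(n_blocks = n_blocks, block_size = block_size,
              within_block_rho = within_block_rho, maf_range = maf_range,
              n_exp = n_exp, n_med = n_med, n_out = n_out,
              sample_overlap_fraction = sample_overlap_fraction,
              alpha_EM = alpha_EM, theta_M = theta_M,
              theta_direct = theta_direct,
              h2_exp = h2_exp, h2_med = h2_med, h2_out = h2_out,
              prop_blocks_exp = prop_blocks_exp,
              prop_blocks_med = prop_blocks_med,
              pleiotropy_frac = pleiotropy_frac,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              reverse_fraction = reverse_fraction,
              reverse_ratio = reverse_ratio, effect_dist = effect_dist,
              seed = seed)
  stopifnot(abs(within_block_rho) < 1,
            all(c(n_exp, n_med, n_out) >= 100),
            sample_overlap_fraction >= 0, sample_overlap_fraction <= 1,
            prop_blocks_exp + prop_blocks_med + reverse_fraction <= 1,
            all(c(h2_exp, h2_med, h2_out) > 0),
            all(c(h2_exp, h2_med, h2_out) < 1))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a block-diagonal LD matrix
#'
#' AR(1) correlation rho^|i-j| within each block, zero between blocks.
#' Blocks are placed 1 Mb apart (so distinct blocks always fall outside
#' the default 250 kb clumping window) on chromosomes cycling 1..22,
#' starting at 40 Mb (clear of the default HBB/HLA masks); variants
#' within a block are 1 kb apart.
#'
#' @param n_blocks,block_size,rho LD structure.
#' @param seed unused (the matrix is deterministic) but accepted for
#'   interface symmetry.
#' @return `ld_matrix` whose ids are `rs1..rsM` in genome order.
#' @export
simulate_ld <- function(n_blocks, block_size, rho, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  m <- n_blocks * block_size
  ids <- paste0("rs", seq_len(m))
  block <- rho^abs(outer(seq_len(block_size), seq_len(block_size), "-"))
  r <- matrix(0, m, m, dimnames = list(ids, ids))
  chr <- integer(m); pos <- integer(m)
  for (b in seq_len(n_blocks)) {
    idx <- (b - 1L) * block_size + seq_len(block_size)
    r[idx, idx] <- block
    chr[idx] <- ((b - 1L) %% 22L) + 1L
    pos[idx] <- 40e6 + ((b - 1L) %/% 22L) * 1e6 + seq_len(block_size) * 1000L
  }
  ld_matrix(r, chr, pos)
}

# allele table + panel for a simulated variant set
sim_panel <- function(ld, maf) {
  m <- length(ld$ids)
  al <- SAFE_ALLELES[((seq_len(m) - 1L) %% nrow(SAFE_ALLELES)) + 1L, ,
                     drop = FALSE]
  ref_panel(data.frame(SNP = ld$ids, CHR = ld$chr, POS = ld$pos,
                       EA = al[, 1], OA = al[, 2], EAF = maf))
}

# draw effects for `idx` scaled so their variance contribution is h2
scaled_effects <- function(m, idx, h2, dist = "normal") {
  b <- numeric(m)
  if (!length(idx)) return(b)
  raw <- if (dist == "fixed") sample(c(-1, 1), length(idx), replace = TRUE)
    else rnorm(length(idx))
  b[idx] <- raw * sqrt(h2 / sum(raw^2))
  b
}

#' Simulate a GWAS summary-statistics triplet with known causal truth
#'
#' Generates exposure, mediator and outcome GWAS summary statistics
#' under the linear structural model
#' M = alpha_EM * E + G_M + e, O = theta_direct * E + theta_M * M +
#' G_O + pleiotropy + e, where each trait also has its own genetic
#' component. Two backends: `"analytic"` samples marginal effect
#' estimates directly from their asymptotic distribution
#' (beta_hat ~ N(R b, R/n) per LD block, with cross-study noise
#' correlation equal to the sample-overlap fraction); `"cohort"`
#' simulates standardized individual-level genotypes and phenotypes and
#' runs per-variant regressions. Both return the same `truth`.
#'
#' @param config `sim_config`.
#' @param mode `"analytic"` (fast, default) or `"cohort"`.
#' @return list of class `sim_study` with `exposure`, `mediator`,
#'   `outcome` (`summary_stats`, harmonized by construction), `panel`,
#'   `ld`, and `truth` (per-variant joint/marginal effects and labels
#'   plus the causal parameters `alpha_total`, `alpha_direct`,
#'   `alpha_indirect`, `P_M`).
#' @export
simulate_gwas_triplet <- function(config = sim_config(),
                                  mode = c("analytic", "cohort")) {
  mode <- match.arg(mode)
  cfg <- config
  withr_seed(cfg$seed, {
    nb <- cfg$n_blocks; bs <- cfg$block_size
    m <- nb * bs
    ld <- simulate_ld(nb, bs, cfg$within_block_rho)
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    panel <- sim_panel(ld, maf)

    # block roles: exposure-causal, mediator-causal, reverse, inert
    n_exp_b <- round(cfg$prop_blocks_exp * nb)
    n_med_b <- round(cfg$prop_blocks_med * nb)
    n_rev_b <- round(cfg$reverse_fraction * nb)
    lead <- (seq_len(nb) - 1L) * bs + 1L
    exp_idx <- lead[seq_len(n_exp_b)]
    med_idx <- lead[n_exp_b + seq_len(n_med_b)]
    rev_idx <- if (n_rev_b > 0) lead[n_exp_b + n_med_b + seq_len(n_rev_b)]
      else integer(0)
    out_idx <- setdiff(lead, c(exp_idx, med_idx, rev_idx))

    b_exp <- scaled_effects(m, exp_idx, cfg$h2_exp, cfg$effect_dist)
    g_med <- scaled_effects(m, med_idx, cfg$h2_med, cfg$effect_dist)
    g_out <- scaled_effects(m, out_idx, cfg$h2_out, cfg$effect_dist)

    # reverse-causal variants: primary effect on the outcome, echoed
    # into the exposure at reverse_ratio strength
    d_rev <- scaled_effects(m, rev_idx, cfg$h2_out, cfg$effect_dist)
    b_exp_total <- b_exp + cfg$reverse_ratio * d_rev

    # pleiotropic exposure variants: direct path to the outcome,
    # planted relative to the exposure-increasing allele so a nonzero
    # mean is directional after the Egger orientation convention
    n_pl <- round(cfg$pleiotropy_frac * length(exp_idx))
    pl_idx <- exp_idx[seq_len(n_pl)]
    d_pl <- numeric(m)
    if (n_pl > 0)
      d_pl[pl_idx] <- sign(b_exp[pl_idx]) *
        rnorm(n_pl, cfg$pleiotropy_mean, cfg$pleiotropy_sd)

    joint_E <- b_exp_total
    joint_M <- cfg$alpha_EM * joint_E + g_med
    joint_O <- cfg$theta_direct * joint_E + cfg$theta_M * joint_M +
      g_out + d_rev + d_pl

    label <- rep("null", m)
    label[exp_idx] <- "valid"
    label[pl_idx] <- "pleiotropic"
    label[med_idx] <- "mediator"
    label[rev_idx] <- "reverse"
    label[out_idx] <- "outcome"

    # residual phenotype SDs so each trait has unit variance
    v_E <- sum(joint_E * as.numeric(ld_mult(ld, joint_E)))
    sd_eE <- sqrt(max(1 - v_E, 0.05))
    # mediator/outcome residuals: keep unit-variance approximation
    if (mode == "analytic") {
      studies <- analytic_sumstats(ld, list(joint_E, joint_M, joint_O),
                                   c(cfg$n_exp, cfg$n_med, cfg$n_out),
                                   cfg$sample_overlap_fraction)
    } else {
      studies <- cohort_sumstats(ld, joint_E, g_med, g_out + d_rev + d_pl,
                                 cfg, sd_eE)
    }
    mk <- function(tbl, n, id) {
      dt <- data.table(SNP = ld$ids, CHR = ld$chr, POS = ld$pos,
                       EA = panel$EA, OA = panel$OA, EAF = maf,
                       BETA = tbl$beta, SE = tbl$se,
                       # floor: extreme z underflows pnorm to exactly 0
                       P = pmax(2 * pnorm(-abs(tbl$beta / tbl$se)), 1e-320),
                       N = n)
      ss <- summary_stats(dt, trait_id = id, validate = TRUE)
      setattr(ss, "harmonized", TRUE)
      ss
    }
    alpha_total <- cfg$theta_direct + cfg$alpha_EM * cfg$theta_M
    truth <- list(
      per_variant = data.table(SNP = ld$ids, label = label,
                               joint_E = joint_E, joint_M = joint_M,
                               joint_O = joint_O,
                               marginal_E = as.numeric(ld_mult(ld, joint_E)),
                               marginal_M = as.numeric(ld_mult(ld, joint_M)),
                               marginal_O = as.numeric(ld_mult(ld, joint_O))),
      alpha_EM = cfg$alpha_EM, theta_M = cfg$theta_M,
      theta_direct = cfg$theta_direct,
      alpha_total = alpha_total,
      alpha_direct = cfg$theta_direct,
      alpha_indirect = cfg$alpha_EM * cfg$theta_M,
      P_M = 100 * cfg$alpha_EM * cfg$theta_M / alpha_total)
    structure(list(exposure = mk(studies[[1]], cfg$n_exp, "exposure"),
                   mediator = mk(studies[[2]], cfg$n_med, "mediator"),
                   outcome = mk(studies[[3]], cfg$n_out, "outcome"),
                   panel = panel, ld = ld, truth = truth, config = cfg),
              class = "sim_study")
  })
}

# multiply block-diagonal LD matrix by a vector
ld_mult <- function(ld, v) ld$r %*% v

# sample marginal estimates from their asymptotic distribution,
# blockwise, with cross-study noise correlation = overlap
analytic_sumstats <- function(ld, joints, ns, overlap) {
  m <- length(ld$ids)
  n_study <- length(joints)
  beta <- lapply(joints, function(j) as.numeric(ld_mult(ld, j)))
  blocks <- ld_blocks(ld)
  noise <- matrix(0, m, n_study)
  for (idx in blocks) {
    L <- chol(ld$r[idx, idx, drop = FALSE])
    u0 <- rnorm(length(idx))
    for (s in seq_len(n_study)) {
      us <- sqrt(1 - overlap) * rnorm(length(idx)) + sqrt(overlap) * u0
      noise[idx, s] <- as.numeric(t(L) %*% us) / sqrt(ns[s])
    }
  }
  lapply(seq_len(n_study), function(s)
    list(beta = beta[[s]] + noise[, s], se = rep(1 / sqrt(ns[s]), m)))
}

# contiguous blocks of the block-diagonal LD matrix: for each row, the
# furthest nonzero column; a block ends where no earlier row reaches past it
ld_blocks <- function(ld) {
  m <- length(ld$ids)
  reach <- vapply(seq_len(m), function(i) max(which(ld$r[i, ] != 0)), 0L)
  ends <- which(cummax(reach) == seq_len(m))
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

# individual-level backend: standardized genotype dosages per block,
# phenotypes from the structural model, per-variant OLS
cohort_sumstats <- function(ld, joint_E, g_med, g_out_extra, cfg, sd_eE) {
  m <- length(ld$ids)
  blocks <- ld_blocks(ld)
  n_max <- max(cfg$n_exp, cfg$n_med, cfg$n_out)
  X <- matrix(0, n_max, m)
  for (idx in blocks) {
    L <- chol(ld$r[idx, idx, drop = FALSE])
    X[, idx] <- matrix(rnorm(n_max * length(idx)), n_max) %*% L
  }
  E <- as.numeric(X %*% joint_E) + rnorm(n_max, 0, sd_eE)
  M <- cfg$alpha_EM * E + as.numeric(X %*% g_med) + rnorm(n_max)
  O <- cfg$theta_direct * E + cfg$theta_M * M +
    as.numeric(X %*% g_out_extra) + rnorm(n_max)
  gwas <- function(y, n) {
    yi <- y[seq_len(n)]; Xi <- X[seq_len(n), , drop = FALSE]
    ys <- as.numeric(scale(yi))
    xs <- scale(Xi)
    beta <- as.numeric(crossprod(xs, ys)) / (n - 1)
    se <- sqrt(pmax(1 - beta^2, 1e-8) / (n - 2))
    list(beta = beta, se = se)
  }
  list(gwas(E, cfg$n_exp), gwas(M, cfg$n_med), gwas(O, cfg$n_out))
}

#' Cohort simulation configuration
#'
#' Defaults emulate the observational cohort: ages uniform on [40, 70),
#' 54% women, a binary genotyping-array indicator, LTL declining with
#' age at the published sex-specific rates (-0.025 SD/year in men,
#' -0.021 in women, population slope about -0.023) and higher in women,
#' and (for women) reproductive phases with slopes (-0.014, -0.017,
#' -0.022) SD/year before first birth, premenopausal after first birth,
#' and postmenopausal. Mean age at first birth is 26 and at menopause
#' 50. Trait effects are planted per `trait_effects` (SD_LTL/SD_trait)
#' with missingness per `trait_missingness`. Residual noise has SD 1 and
#' the generated LTL is left unstandardized so planted slopes are exact.
#'
#' @param n participants.
#' @param use_phases build female LTL from the reproductive-phase model
#'   (`TRUE`) or from the linear female age slope (`FALSE`).
#' @param phase_slopes SD_LTL/year for the three phases.
#' @param beta_age_male,beta_age_female linear age slopes (SD/year).
#' @param beta_sex additive female effect (SD).
#' @param beta_array additive array effect (SD).
#' @param parity_effect,menopause_effect indicator effects in the phase
#'   model.
#' @param prop_nulliparous,prop_female cohort composition.
#' @param trait_effects named numeric vector of planted trait effects.
#' @param trait_missingness named numeric vector of missingness
#'   fractions for those traits.
#' @param noise_sd residual LTL noise.
#' @param seed integer seed.
#' @export
cohort_config <- function(n = 10000, use_phases = TRUE,
                          phase_slopes = c(-0.014, -0.017, -0.022),
                          beta_age_male = -0.025, beta_age_female = -0.021,
                          beta_sex = 0.091, beta_array = 0.01,
                          parity_effect = -0.03, menopause_effect = -0.02,
                          prop_nulliparous = 0.2, prop_female = 0.54,
                          trait_effects = numeric(0),
                          trait_missingness = numeric(0),
                          noise_sd = 1, seed = 1) {
  if (any(trait_missingness < 0 | trait_missingness > 1))
    stop("missingness fractions must lie in [0, 1]")
  if (length(trait_missingness) &&
      !all(names(trait_missingness) %in% names(trait_effects)))
    stop("missingness specified for unknown trait")
  structure(list(n = n, use_phases = use_phases, phase_slopes = phase_slopes,
                 beta_age_male = beta_age_male,
                 beta_age_female = beta_age_female, beta_sex = beta_sex,
                 beta_array = beta_array, parity_effect = parity_effect,
                 menopause_effect = menopause_effect,
                 prop_nulliparous = prop_nulliparous,
                 prop_female = prop_female, trait_effects = trait_effects,
                 trait_missingness = trait_missingness, noise_sd = noise_sd,
                 seed = seed), class = "cohort_config")
}

#' Simulate an individual-level cohort
#'
#' @param config `cohort_config`.
#' @return data.frame with columns `id, age, sex` (1 = female),
#'   `array, ltl`, one column per planted trait, and the female
#'   reproductive fields `age_first_birth, age_menopause,
#'   n_live_births, menopause_status` (`NA` for men and where
#'   undefined). The true generator parameters are attached as
#'   attribute `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  withr_seed(cfg$seed, {
    n <- cfg$n
    age <- runif(n, 40, 70)
    sex <- rbinom(n, 1, cfg$prop_female) # 1 = female
    array <- rbinom(n, 1, 0.5)
    female <- sex == 1

    afb <- rep(NA_real_, n); amp <- rep(NA_real_, n)
    nlb <- rep(NA_real_, n); meno <- rep(NA_real_, n)
    nf <- sum(female)
    parous <- rbinom(nf, 1, 1 - cfg$prop_nulliparous) == 1
    afb_f <- ifelse(parous, pmin(pmax(rnorm(nf, 26, 4), 16), 45), NA)
    amp_f <- pmin(pmax(rnorm(nf, 50, 3), 40), 60)
    post_f <- age[female] > amp_f
    amp_obs <- ifelse(post_f, amp_f, NA) # premenopausal: age unknown yet
    nlb[female] <- ifelse(parous, rpois(nf, 1) + 1, 0)
    afb[female] <- afb_f
    amp[female] <- amp_obs
    meno[female] <- as.numeric(post_f)

    ltl <- cfg$beta_sex * sex + cfg$beta_array * array +
      rnorm(n, 0, cfg$noise_sd)
    ltl[!female] <- ltl[!female] + cfg$beta_age_male * age[!female]
    if (cfg$use_phases) {
      a <- age[female]
      t1 <- ifelse(parous, pmin(a, afb_f), a)
      t2 <- ifelse(parous, ifelse(post_f, amp_f, a) - afb_f, 0)
      t2 <- pmax(t2, 0)
      t3 <- ifelse(post_f, a - amp_f, 0)
      ltl[female] <- ltl[female] + cfg$phase_slopes[1] * t1 +
        cfg$phase_slopes[2] * t2 + cfg$phase_slopes[3] * t3 +
        cfg$parity_effect * parous + cfg$menopause_effect * post_f
    } else {
      ltl[female] <- ltl[female] + cfg$beta_age_female * age[female]
    }

    out <- data.frame(id = seq_len(n), age = age, sex = sex, array = array,
                      ltl = ltl, age_first_birth = afb, age_menopause = amp,
                      n_live_births = nlb, menopause_status = meno)
    for (tr in names(cfg$trait_effects)) {
      x <- rnorm(n)
      out$ltl <- out$ltl + cfg$trait_effects[[tr]] * x
      miss <- cfg$trait_missingness[tr]
      if (!is.na(miss) && length(miss) && miss > 0)
        x[runif(n) < miss] <- NA
      out[[tr]] <- x
    }
    attr(out, "truth") <- cfg
    out
  })
}
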