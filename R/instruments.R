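# Instrument selection: LD clumping, genomic region masks,
# allele-frequency concordance, Steiger directionality filtering (single
# and multi-trait), and the bespoke clumping schemes used for mediation
# (two-phase) and multivariable MR (minimum rank).

#' Construct an LD matrix object
#'
#' Carries signed pairwise correlations r between variants together with
#' their genomic coordinates for window checks. Pairs absent from the
#' matrix are treated as unlinked (r = 0) by consumers, with a warning.
#'
#' @param r square symmetric matrix of signed correlations with unit
#'   diagonal; dimnames give the variant ids.
#' @param chr,pos integer vectors of chromosome and position per variant
#'   (same order as `r`).
#' @return an `ld_matrix` object.
#' @export
ld_matrix <- function(r, chr, pos) {
  r <- as.matrix(r)
  ids <- rownames(r)
  if (is.null(ids) || is.null(colnames(r))) stop("r needs dimnames (variant ids)")
  stopifnot(identical(ids, colnames(r)), length(chr) == nrow(r),
            length(pos) == nrow(r))
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-8) stop("|r| must be <= 1")
  structure(list(ids = ids, r = r, chr = as.integer(chr),
                 pos = as.integer(pos)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d variants, %d chromosome(s)\n",
              length(x$ids), length(unique(x$chr))))
  invisible(x)
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix with a header row and first column of
#' variant ids, or a triplet list with columns `id_a, id_b, r`.
#' Positions are supplied separately (from the reference panel).
#'
#' @param path TSV path.
#' @param panel `ref_panel` used to look up chromosome/position.
#' @export
read_ld_matrix <- function(path, panel) {
  dt <- fread(path, header = TRUE)
  if (all(c("id_a", "id_b", "r") %in% names(dt))) {
    ids <- sort(unique(c(dt$id_a, dt$id_b)))
    r <- diag(length(ids)); dimnames(r) <- list(ids, ids)
    r[cbind(match(dt$id_a, ids), match(dt$id_b, ids))] <- dt$r
    r[cbind(match(dt$id_b, ids), match(dt$id_a, ids))] <- dt$r
  } else {
    ids <- as.character(dt[[1]])
    r <- as.matrix(dt[, -1, with = FALSE])
    dimnames(r) <- list(ids, ids)
  }
  idx <- match(ids, panel$SNP)
  if (anyNA(idx)) stop("LD matrix variants missing from panel")
  ld_matrix(r, chr = panel$CHR[idx], pos = panel$POS[idx])
}

# squared LD between one id and a set; unknown pairs -> 0 with warning
ld_r2 <- function(ld, id, ids) {
  out <- numeric(length(ids))
  if (is.null(ld)) return(out)
  i <- match(id, ld$ids)
  j <- match(ids, ld$ids)
  known <- !is.na(j)
  if (!is.na(i)) {
    out[known] <- ld$r[i, j[known]]^2
  } else known[] <- FALSE
  if (any(!known) || is.na(i))
    warning("LD matrix does not cover all candidate pairs; missing pairs treated as r = 0",
            call. = FALSE)
  out
}

#' Greedy LD clumping of genome-wide significant variants
#'
#' Candidates are variants with p below `gw_threshold` (and `p1`).
#' Greedily, the most significant remaining candidate becomes an index
#' variant and removes every variant with p < `p2` lying within `kb`
#' kilobases on the same chromosome and correlated at r^2 >= `r2`. Only
#' index variants are returned. Ties on p are broken by position, then
#' variant id, so output is deterministic.
#'
#' @param ss harmonized `summary_stats`.
#' @param ld `ld_matrix` covering the candidates (missing pairs are
#'   treated as unlinked, with a warning).
#' @param p1 index-variant significance threshold.
#' @param p2 secondary threshold governing which neighbors are absorbed.
#' @param kb window half-width in kilobases.
#' @param r2 LD threshold.
#' @param gw_threshold genome-wide significance cutoff for candidacy.
#' @return `data.table` of index variants (summary-statistics columns
#'   plus `clump_index`), ordered by selection; zero rows if no
#'   candidate is genome-wide significant.
#' @export
clump <- function(ss, ld, p1 = 1e-4, p2 = 0.01, kb = 250, r2 = 0.01,
                  gw_threshold = 5e-8) {
  dt <- as.data.table(ss)
  cand <- dt[P < gw_threshold & P < p1]
  setorder(cand, P, POS, SNP)
  clump_candidates(cand, ld, kb = kb, r2 = r2, p2 = p2)
}

# core greedy pass over `cand`, which must already be ordered by index
# priority (most eligible first). Each index removes later rows on the
# same chromosome within the kb window at r^2 >= r2 whose absorb_p is
# below p2. Only index rows are returned.
clump_candidates <- function(cand, ld, kb, r2, p2, absorb_p = cand$P) {
  if (nrow(cand) == 0L) {
    out <- copy(cand)
    out[, clump_index := integer(0)]
    return(out[])
  }
  alive <- rep(TRUE, nrow(cand))
  picked <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    picked <- c(picked, i)
    alive[i] <- FALSE
    in_win <- alive & cand$CHR == cand$CHR[i] &
      abs(cand$POS - cand$POS[i]) <= kb * 1000 & absorb_p < p2
    if (any(in_win)) {
      r2v <- ld_r2(ld, cand$SNP[i], cand$SNP[in_win])
      alive[which(in_win)[r2v >= r2]] <- FALSE
    }
  }
  out <- cand[picked]
  out[, clump_index := seq_len(.N)]
  out[]
}

#' Default genomic exclusion masks
#'
#' HBB (chr11:5,246,696-5,248,301, GRCh37) — the gene used as a
#' technical control in qPCR telomere-length measurement, so LTL
#' associations there are suspect — and the extended HLA region
#' (chr6:25,000,000-37,000,000, GRCh37) with its complex long-range LD.
#'
#' @return data.frame with columns `name, chr, start, end` (1-based
#'   inclusive).
#' @export
default_masks <- function() {
  data.frame(name = c("HBB", "HLA"),
             chr = c(11L, 6L),
             start = c(5246696L, 25000000L),
             end = c(5248301L, 37000000L))
}

#' Remove variants inside masked genomic regions
#'
#' @param ivs data.frame/data.table with columns `CHR` and `POS`.
#' @param masks data.frame like [default_masks()]; coordinates 1-based
#'   inclusive.
#' @return the table without masked variants.
#' @export
apply_region_masks <- function(ivs, masks = default_masks()) {
  dt <- as.data.table(ivs)
  if (is.null(masks) || nrow(masks) == 0L) return(dt[])
  stopifnot(all(masks$start <= masks$end))
  hit <- rep(FALSE, nrow(dt))
  for (k in seq_len(nrow(masks)))
    hit <- hit | (dt$CHR == masks$chr[k] & dt$POS >= masks$start[k] &
                    dt$POS <= masks$end[k])
  dt[!hit]
}

#' Allele-frequency concordance filter
#'
#' Removes aligned rows where the exposure and outcome effect-allele
#' frequencies differ by at least `max_diff` (default 0.05, removal at
#' the printed `>= 0.05` boundary). Rows with a missing frequency on
#' either side are retained and flagged.
#'
#' @param pair aligned table from [align_pair()].
#' @param max_diff removal threshold.
#' @return filtered table with logical column `af_flagged` marking rows
#'   kept despite a missing frequency.
#' @export
af_concordance_filter <- function(pair, max_diff = 0.05) {
  dt <- as.data.table(pair)
  d <- abs(dt$eaf_exp - dt$eaf_out)
  flagged <- is.na(d)
  keep <- flagged | d < max_diff
  out <- dt[keep]
  out[, af_flagged := flagged[keep]]
  out[]
}

#' Steiger directionality statistic
#'
#' Compares the magnitude of a variant's association with the exposure
#' and with the outcome on the correlation scale:
#' Z = (atanh(|r_exp|) - atanh(|r_out|)) /
#' sqrt(1/(n_exp - 3) + 1/(n_out - 3)). Z well below zero indicates a
#' stronger outcome association, i.e. likely reverse causation.
#'
#' @param r_exp,r_out standardized-scale correlations (|r| < 1).
#' @param n_exp,n_out sample sizes (> 3).
#' @return numeric vector of Z statistics.
#' @export
steiger_z <- function(r_exp, n_exp, r_out, n_out) {
  if (any(n_exp <= 3) || any(n_out <= 3)) stop("sample sizes must exceed 3")
  if (any(abs(c(r_exp, r_out)) >= 1)) stop("|r| must be < 1")
  (atanh(abs(r_exp)) - atanh(abs(r_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
}

# correlation-scale effect from a z-statistic: r = z / sqrt(z^2 + n - 2)
z_to_r <- function(beta, se, n) {
  z <- beta / se
  z / sqrt(z^2 + n - 2)
}

#' Steiger filter on an aligned pair
#'
#' Removes rows whose Steiger Z falls at or below `threshold` (default
#' -1.96): instruments more strongly associated with the outcome than
#' with the exposure. Correlations are computed on the
#' explained-variance scale from each side's z-statistic and sample
#' size, so the filter works on raw or standardized input.
#'
#' @param pair aligned table from [align_pair()].
#' @param threshold removal boundary (rows with `Z <= threshold` drop).
#' @return filtered table with column `steiger_Z`.
#' @export
steiger_filter <- function(pair, threshold = -1.96) {
  dt <- as.data.table(pair)
  r_exp <- z_to_r(dt$beta_exp, dt$se_exp, dt$n_exp)
  r_out <- z_to_r(dt$beta_out, dt$se_out, dt$n_out)
  Z <- steiger_z(r_exp, dt$n_exp, r_out, dt$n_out)
  out <- dt[!(Z <= threshold)]
  out[, steiger_Z := Z[!(Z <= threshold)]]
  out[]
}

#' Multi-trait Steiger pleiotropy filter
#'
#' Retains an instrument only if its association with the exposure is
#' not significantly weaker than its association with *any* trait in a
#' panel of other traits: the Steiger comparison against every panel
#' trait must stay above the threshold. Instruments absent from any
#' panel trait's summary statistics are excluded (the presence
#' requirement), which is why candidates should be harmonized across the
#' whole panel before clumping.
#'
#' @param exposure `summary_stats` for the exposure.
#' @param trait_panel list of `summary_stats` for the other traits.
#' @param ivs data.table of candidate instruments (rows of the exposure
#'   table, e.g. [clump()] output).
#' @param threshold Steiger removal boundary.
#' @return filtered instrument table.
#' @export
multi_trait_steiger_filter <- function(exposure, trait_panel, ivs,
                                       threshold = -1.96) {
  dt <- as.data.table(ivs)
  if (length(trait_panel) == 0L) return(dt[])
  keep <- rep(TRUE, nrow(dt))
  r_exp <- z_to_r(dt$BETA, dt$SE, dt$N)
  for (tr in trait_panel) {
    tt <- as.data.table(tr)
    idx <- match(dt$SNP, tt$SNP)
    present <- !is.na(idx)
    keep <- keep & present
    if (!any(present)) next
    r_t <- z_to_r(tt$BETA[idx[present]], tt$SE[idx[present]], tt$N[idx[present]])
    Z <- steiger_z(r_exp[present], dt$N[present], r_t, tt$N[idx[present]])
    ok <- !(Z <= threshold)
    keep[present] <- keep[present] & ok
  }
  dt[keep]
}

#' Two-phase clumping for mediation analyses
#'
#' Phase 1 clumps the exposure's genome-wide significant variants alone.
#' Phase 2 pools the phase-1 exposure instruments with the mediator's
#' genome-wide significant candidates and clumps the pool with every
#' exposure variant ranked strictly above every mediator variant
#' (ascending p within each group), so an exposure instrument is always
#' retained over a correlated mediator candidate regardless of p.
#'
#' @param exposure,mediator harmonized `summary_stats`.
#' @param ld `ld_matrix`.
#' @inheritParams clump
#' @return list with `exposure_ivs` and `mediator_ivs` (disjoint
#'   data.tables) and logical `ok` (both non-empty).
#' @export
two_phase_mediation_clump <- function(exposure, mediator, ld, p1 = 1e-4,
                                      p2 = 0.01, kb = 250, r2 = 0.01,
                                      gw_threshold = 5e-8) {
  phase1 <- clump(exposure, ld, p1 = p1, p2 = p2, kb = kb, r2 = r2,
                  gw_threshold = gw_threshold)
  med <- as.data.table(mediator)[P < gw_threshold & P < p1]
  med <- med[!SNP %in% phase1$SNP]
  setorder(med, P, POS, SNP)
  # exposure instruments ranked strictly above all mediator candidates
  pool <- rbind(phase1[, SS_COLS, with = FALSE], med[, SS_COLS, with = FALSE])
  res <- clump_candidates(pool, ld, kb = kb, r2 = r2, p2 = p2)
  exposure_ivs <- res[SNP %in% phase1$SNP]
  mediator_ivs <- res[!SNP %in% phase1$SNP]
  list(exposure_ivs = exposure_ivs, mediator_ivs = mediator_ivs,
       ok = nrow(exposure_ivs) > 0 && nrow(mediator_ivs) > 0)
}

#' Minimum-rank clumping across several exposures
#'
#' For multivariable MR without a predefined mediator: variants are
#' ranked by p within each exposure (rank 1 = most significant), each
#' variant gets its minimum rank across exposures, and greedy clumping
#' proceeds in order of that minimum rank (ties broken by the smaller
#' minimum p, then id). Candidacy requires genome-wide significance for
#' at least one exposure and presence in all.
#'
#' @param exposures list of harmonized `summary_stats` on a common
#'   variant set.
#' @param ld `ld_matrix`.
#' @inheritParams clump
#' @return data.table of index variants with columns from the first
#'   exposure plus `min_rank` and `clump_index`.
#' @export
minrank_clump <- function(exposures, ld, p1 = 1e-4, p2 = 0.01, kb = 250,
                          r2 = 0.01, gw_threshold = 5e-8) {
  stopifnot(length(exposures) >= 1)
  common <- Reduce(intersect, lapply(exposures, function(s) s$SNP))
  if (!length(common)) stop("no variant shared by all exposures")
  pmat <- sapply(exposures, function(s) {
    dt <- as.data.table(s)
    dt$P[match(common, dt$SNP)]
  })
  pmat <- matrix(pmat, nrow = length(common))
  rmat <- apply(pmat, 2, rank, ties.method = "first")
  rmat <- matrix(rmat, nrow = length(common))
  min_rank <- apply(rmat, 1, min)
  min_p <- apply(pmat, 1, min)
  base <- as.data.table(exposures[[1]])[match(common, SNP)]
  base[, `:=`(min_rank = min_rank, min_p = min_p)]
  cand <- base[min_p < gw_threshold & min_p < p1]
  setorder(cand, min_rank, min_p, SNP)
  res <- clump_candidates(cand, ld, kb = kb, r2 = r2, p2 = p2,
                          absorb_p = cand$min_p)
  res[]
}
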