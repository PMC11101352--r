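# Shared fixtures: constructed summary statistics, panels and LD
# matrices, plus a naive greedy-clumping oracle used to validate the
# packaged implementation.

# summary statistics from vectors, with permissive defaults
make_ss <- function(snp, beta, se, n = 10000, chr = 1L,
                    pos = seq_along(snp) * 1e6L, ea = "A", oa = "G",
                    eaf = 0.3, p = NULL, trait_id = "trait",
                    validate = TRUE) {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  summary_stats(data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea,
                           OA = oa, EAF = eaf, BETA = beta, SE = se,
                           P = p, N = n),
                trait_id = trait_id, validate = validate)
}

make_panel <- function(snp, chr = 1L, pos = seq_along(snp) * 1e6L,
                       ea = "A", oa = "G", eaf = 0.3) {
  ref_panel(data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa,
                       EAF = eaf))
}

# LD matrix from an explicit correlation matrix
make_ld <- function(snp, r, chr = 1L, pos = seq_along(snp) * 1e6L) {
  dimnames(r) <- list(snp, snp)
  ld_matrix(r, chr = rep(chr, length.out = length(snp)), pos = pos)
}

# Independent clumping oracle: a literal transcription of the greedy
# rule, written over explicit pairwise loops with no shared code with
# clump(). Returns retained SNP ids in selection order.
oracle_clump <- function(snp, chr, pos, p, r2mat, p1 = 1e-4, p2 = 0.01,
                         kb = 250, r2 = 0.01, gw = 5e-8) {
  cand <- which(p < gw & p < p1)
  # deterministic ordering: ascending p, then position, then id
  cand <- cand[order(p[cand], pos[cand], snp[cand])]
  kept <- integer(0)
  removed <- rep(FALSE, length(snp))
  for (i in cand) {
    if (removed[i]) next
    kept <- c(kept, i)
    for (j in cand) {
      if (j == i || removed[j]) next
      if (chr[j] == chr[i] && abs(pos[j] - pos[i]) <= kb * 1000 &&
          p[j] < p2 && r2mat[i, j] >= r2) {
        removed[j] <- TRUE
      }
    }
    removed[i] <- TRUE
  }
  snp[kept]
}

# random clumping instance with <= n_max variants on one chromosome
random_clump_instance <- function(seed, n_max = 15) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  snp <- paste0("s", seq_len(n))
  pos <- sort(sample(1:2e6, n))
  p <- 10^runif(n, -12, -2)
  A <- matrix(rnorm(n * n), n)
  r <- cov2cor(crossprod(A) + diag(n) * 0.1)
  dimnames(r) <- list(snp, snp)
  list(snp = snp, chr = rep(1L, n), pos = pos, p = p, r = r)
}
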