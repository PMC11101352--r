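#' @import data.table
#' @importFrom stats pnorm pt qnorm rnorm rbinom runif var sd mad median
#'   quantile coef lm residuals complete.cases cor density setNames
#'   optimize aggregate cov rpois
#' @importFrom utils head
NULL

# Canonical summary-statistics columns. EA = effect allele, OA = other
# allele, EAF = effect-allele frequency, BETA on SD (continuous) or
# log(OR) (binary) scale.
SS_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
PANEL_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF")

ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a summary-statistics object
#'
#' Wraps a per-variant association table for one trait. Validation drops
#' rows violating invariants (non-positive SE, p outside (0,1], n < 2,
#' non-autosomal chromosome, malformed alleles) and errors on duplicated
#' variant identifiers.
#'
#' @param x data.frame with columns `SNP, CHR, POS, EA, OA, EAF, BETA,
#'   SE, P, N` (`EAF` may be `NA`).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`; binary effects are
#'   log odds ratios.
#' @param scale `"raw"` or `"standardized"` (explained-variance scale,
#'   see [standardize_effects()]).
#' @param validate drop invalid rows and check invariants.
#' @return A `summary_stats` object (a `data.table` with attributes
#'   `trait_id`, `trait_type`, `scale`).
#' @export
summary_stats <- function(x, trait_id, trait_type = "continuous",
                          scale = "raw", validate = TRUE) {
  trait_type <- match.arg(trait_type, c("continuous", "binary"))
  scale <- match.arg(scale, c("raw", "standardized"))
  dt <- as.data.table(x)
  missing_cols <- setdiff(SS_COLS, names(dt))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  dt <- dt[, SS_COLS, with = FALSE]
  dt[, `:=`(SNP = as.character(SNP), CHR = as.integer(CHR),
            POS = as.integer(POS), EA = toupper(as.character(EA)),
            OA = toupper(as.character(OA)), EAF = as.numeric(EAF),
            BETA = as.numeric(BETA), SE = as.numeric(SE),
            P = as.numeric(P), N = as.numeric(N))]
  if (validate) {
    n0 <- nrow(dt)
    keep <- !is.na(dt$SNP) & !is.na(dt$BETA) & !is.na(dt$SE) & dt$SE > 0 &
      !is.na(dt$P) & dt$P > 0 & dt$P <= 1 &
      !is.na(dt$N) & dt$N >= 2 &
      !is.na(dt$CHR) & dt$CHR >= 1 & dt$CHR <= 22 &
      !is.na(dt$POS) & dt$POS >= 1 &
      dt$EA %in% ALLELES & dt$OA %in% ALLELES & dt$EA != dt$OA &
      (is.na(dt$EAF) | (dt$EAF >= 0 & dt$EAF <= 1))
    dt <- dt[keep]
    n_dropped <- n0 - nrow(dt)
    if (n_dropped > 0)
      warning(sprintf("[%s] dropped %d invalid row(s)", trait_id, n_dropped))
    if (nrow(dt) == 0L) stop("no valid rows for trait ", trait_id)
    dup <- dt$SNP[duplicated(dt$SNP)]
    if (length(dup))
      stop("duplicated variant_id in ", trait_id, ": ",
           paste(unique(dup)[seq_len(min(5, length(unique(dup))))],
                 collapse = ", "))
  }
  setattr(dt, "trait_id", trait_id)
  setattr(dt, "trait_type", trait_type)
  setattr(dt, "scale", scale)
  setattr(dt, "class", c("summary_stats", class(dt)))
  dt[]
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: trait '%s' (%s, %s scale), %d variants\n",
              trait_id(x), attr(x, "trait_type"), attr(x, "scale"), nrow(x)))
  print(as.data.table(head(x, 5)))
  invisible(x)
}

#' @rdname summary_stats
#' @param ss a `summary_stats` object.
#' @export
trait_id <- function(ss) attr(ss, "trait_id")

ss_scale <- function(ss) attr(ss, "scale")

# rebuild attributes after data.table ops strip them
ss_rewrap <- function(dt, template, scale = NULL) {
  summary_stats(dt, trait_id = trait_id(template),
                trait_type = attr(template, "trait_type"),
                scale = if (is.null(scale)) ss_scale(template) else scale,
                validate = FALSE)
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping canonical
#'   names (`SNP`, `CHR`, ...) to the file's column names, e.g.
#'   `c(SNP = "rsid", BETA = "effect")`. Unmapped canonical names are
#'   looked up verbatim.
#' @param trait_id trait label; defaults to the file name.
#' @param trait_type,scale see [summary_stats()].
#' @return validated `summary_stats`.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_id = basename(path),
                               trait_type = "continuous", scale = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = TRUE)
  if (nrow(dt) == 0L) stop("empty summary-statistics file: ", path)
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (!src %in% names(dt))
      stop("mapped column '", src, "' (for ", canon, ") not in file")
    setnames(dt, src, canon)
  }
  missing_cols <- setdiff(SS_COLS, names(dt))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  summary_stats(dt, trait_id = trait_id, trait_type = trait_type,
                scale = scale, validate = TRUE)
}

#' Construct a variant reference panel
#'
#' @param x data.frame with columns `SNP, CHR, POS, EA, OA, EAF`.
#' @return a `ref_panel` data.table with unique variant ids.
#' @export
ref_panel <- function(x) {
  dt <- as.data.table(x)
  missing_cols <- setdiff(PANEL_COLS, names(dt))
  if (length(missing_cols))
    stop("panel missing column(s): ", paste(missing_cols, collapse = ", "))
  dt <- dt[, PANEL_COLS, with = FALSE]
  dt[, `:=`(SNP = as.character(SNP), EA = toupper(as.character(EA)),
            OA = toupper(as.character(OA)))]
  if (anyDuplicated(dt$SNP)) stop("duplicated variant_id in reference panel")
  setattr(dt, "class", c("ref_panel", class(dt)))
  dt[]
}

#' @rdname ref_panel
#' @param path delimited file with the panel columns.
#' @export
read_ref_panel <- function(path) {
  ref_panel(fread(path, header = TRUE))
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "G" & oa == "C") | (ea == "C" & oa == "G")
}

#' Harmonize summary statistics against a reference panel
#'
#' Variants absent from the panel are removed; palindromic (A/T, G/C)
#' variants are removed (strand ambiguous across studies); variants whose
#' alleles match the panel only after complementing both alleles are
#' strand-corrected; variants whose effect/other alleles are swapped
#' relative to the panel have their effect sign and allele frequency
#' flipped (beta -> -beta, eaf -> 1 - eaf). Output alleles always match
#' panel orientation, so harmonization is idempotent.
#'
#' @param ss `summary_stats`.
#' @param panel `ref_panel`.
#' @param verbose log removal counts.
#' @return harmonized `summary_stats` with attribute `harmonized = TRUE`
#'   and an attrition table in attribute `harmonize_log`.
#' @export
harmonize <- function(ss, panel, verbose = FALSE) {
  stopifnot(inherits(ss, "summary_stats"), inherits(panel, "ref_panel"))
  dt <- copy(as.data.table(ss))
  n_in <- nrow(dt)
  idx <- match(dt$SNP, panel$SNP)
  in_panel <- !is.na(idx)
  n_absent <- sum(!in_panel)
  dt <- dt[in_panel]
  pEA <- panel$EA[idx[in_panel]]
  pOA <- panel$OA[idx[in_panel]]

  pal <- is_palindromic(dt$EA, dt$OA) | is_palindromic(pEA, pOA)
  n_pal <- sum(pal)
  dt <- dt[!pal]; pEA <- pEA[!pal]; pOA <- pOA[!pal]

  cEA <- unname(COMPLEMENT[dt$EA])
  cOA <- unname(COMPLEMENT[dt$OA])
  same <- dt$EA == pEA & dt$OA == pOA
  swap <- dt$EA == pOA & dt$OA == pEA
  flip <- cEA == pEA & cOA == pOA          # strand flip only
  flip_swap <- cEA == pOA & cOA == pEA     # strand flip + allele swap
  # for non-palindromic alleles these four cases are mutually exclusive
  match_any <- same | swap | flip | flip_swap
  n_mismatch <- sum(!match_any)
  keep <- match_any
  dt <- dt[keep]
  do_swap <- (swap | flip_swap)[keep]
  dt[do_swap, `:=`(BETA = -BETA, EAF = 1 - EAF)]
  dt[, `:=`(EA = pEA[keep], OA = pOA[keep])]

  out <- ss_rewrap(dt, ss)
  log <- data.table(step = c("absent_from_panel", "palindromic",
                             "allele_mismatch", "retained"),
                    n = c(n_absent, n_pal, n_mismatch, nrow(dt)))
  setattr(out, "harmonize_log", log)
  setattr(out, "harmonized", TRUE)
  if (verbose)
    message(sprintf("[harmonize %s] in=%d absent=%d palindromic=%d mismatch=%d kept=%d",
                    trait_id(ss), n_in, n_absent, n_pal, n_mismatch, nrow(dt)))
  out
}

#' Standardize effects to the explained-variance scale
#'
#' Converts raw effects to the signed square root of the per-variant
#' explained variance: with z = beta/se, the standardized effect is
#' r = z / sqrt(z^2 + n - 2) and its standard error 1 / sqrt(z^2 + n - 2),
#' so that r^2 = z^2 / (z^2 + n - 2) is the variance in a standardized
#' trait explained by the variant and z is preserved. Calling it on
#' already-standardized input is a no-op.
#'
#' @param ss `summary_stats` with `scale = "raw"`.
#' @return `summary_stats` with `scale = "standardized"`.
#' @export
standardize_effects <- function(ss) {
  stopifnot(inherits(ss, "summary_stats"))
  if (ss_scale(ss) == "standardized") return(ss)
  dt <- copy(as.data.table(ss))
  z <- dt$BETA / dt$SE
  denom <- sqrt(z^2 + dt$N - 2)
  dt[, `:=`(BETA = z / denom, SE = 1 / denom)]
  out <- ss_rewrap(dt, ss, scale = "standardized")
  setattr(out, "harmonized", isTRUE(attr(ss, "harmonized")))
  out
}

#' Align an exposure/outcome pair on shared variants
#'
#' Inner join on variant id. Both inputs must be harmonized to the same
#' panel so that alleles agree row-wise.
#'
#' @param exposure,outcome harmonized `summary_stats`.
#' @return data.table with columns `SNP, CHR, POS, EA, OA, beta_exp,
#'   se_exp, p_exp, eaf_exp, n_exp, beta_out, se_out, p_out, eaf_out,
#'   n_out`.
#' @export
align_pair <- function(exposure, outcome) {
  ex <- as.data.table(exposure)
  ou <- as.data.table(outcome)
  m <- merge(
    ex[, .(SNP, CHR, POS, EA, OA, beta_exp = BETA, se_exp = SE,
           p_exp = P, eaf_exp = EAF, n_exp = N)],
    ou[, .(SNP, beta_out = BETA, se_out = SE, p_out = P,
           eaf_out = EAF, n_out = N)],
    by = "SNP")
  if (nrow(m) == 0L)
    stop("no shared variants between ", trait_id(exposure), " and ",
         trait_id(outcome))
  setorder(m, CHR, POS, SNP)
  m[]
}

#' Derive difference-trait summary statistics
#'
#' Builds summary statistics for the difference of two traits (e.g.
#' reproductive lifespan = age at menopause minus age at menarche) by
#' back-transforming per-variant effects to the original unit scale and
#' differencing: beta = sd_a * beta_a - sd_b * beta_b with
#' SE = sqrt(sd_a^2 SE_a^2 + sd_b^2 SE_b^2). The sample size is the
#' smaller of the two and p-values come from a two-sided normal test on
#' beta / SE.
#'
#' @param ss_a,ss_b `summary_stats` for the minuend and subtrahend.
#' @param sd_a,sd_b phenotype standard deviations on the unit scale
#'   (e.g. years); must be positive.
#' @param trait_id label for the derived trait.
#' @return `summary_stats` for the difference trait (variants present in
#'   both inputs; alleles from `ss_a`).
#' @export
derive_difference_trait <- function(ss_a, ss_b, sd_a, sd_b, trait_id = NULL) {
  if (!is.numeric(sd_a) || !is.numeric(sd_b) || sd_a <= 0 || sd_b <= 0)
    stop("phenotype SDs must be positive")
  if (is.null(trait_id))
    trait_id <- paste0(attr(ss_a, "trait_id"), "_minus_", attr(ss_b, "trait_id"))
  pair <- align_pair(ss_a, ss_b)
  beta <- sd_a * pair$beta_exp - sd_b * pair$beta_out
  se <- sqrt(sd_a^2 * pair$se_exp^2 + sd_b^2 * pair$se_out^2)
  p <- 2 * pnorm(-abs(beta / se))
  out <- data.table(SNP = pair$SNP, CHR = pair$CHR, POS = pair$POS,
                    EA = pair$EA, OA = pair$OA, EAF = pair$eaf_exp,
                    BETA = beta, SE = se, P = p,
                    N = pmin(pair$n_exp, pair$n_out))
  res <- summary_stats(out, trait_id = trait_id, trait_type = "continuous",
                       scale = "raw", validate = FALSE)
  setattr(res, "harmonized",
          isTRUE(attr(ss_a, "harmonized")) && isTRUE(attr(ss_b, "harmonized")))
  res
}

#' Write summary statistics as tab-separated text
#'
#' @param ss `summary_stats`.
#' @param path output path.
#' @export
write_summary_stats <- function(ss, path) {
  fwrite(as.data.table(ss), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
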