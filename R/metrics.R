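#' Mask genotypes for imputation experiments
#'
#' Generates held-out missingness from a complete genotype matrix.
#' `"systematic"` masks `round(rate * p)` uniformly chosen marker columns
#' in every sample (markers absent from a whole population, the
#' reconstructive scenario); `"sporadic"` masks `round(rate * p)`
#' uniformly chosen entries per sample independently (assay dropouts, the
#' general scenario). Rounding is to the nearest integer, ties to even.
#'
#' @param g missing-free [genotype_matrix()].
#' @param rate masking rate in (0, 1).
#' @param pattern `"systematic"` or `"sporadic"`.
#' @param seed RNG seed.
#' @return list with `masked` (a `genomat` with masked entries set to 0)
#'   and `mask` (logical samples x markers truth mask).
#' @export
mask_genotypes <- function(g, rate, pattern = c("systematic", "sporadic"),
                           seed = 1L) {
  pattern <- match.arg(pattern)
  if (rate <= 0 || rate >= 1) stop("rate must lie strictly in (0, 1)")
  if (any(g$codes == 0L)) stop("input must be missing-free")
  set.seed(seed)
  n <- n_samples(g); p <- n_markers(g)
  mask <- matrix(FALSE, n, p)
  n_mask <- round(rate * p)
  if (pattern == "systematic") {
    mask[, sample.int(p, n_mask)] <- TRUE
  } else {
    for (i in seq_len(n)) mask[i, sample.int(p, n_mask)] <- TRUE
  }
  codes <- g$codes
  codes[mask] <- 0L
  list(masked = genotype_matrix(codes, g$markers, g$sample_ids), mask = mask)
}

as_codes <- function(x) if (inherits(x, "genomat")) x$codes else as.matrix(x)

check_metric_args <- function(imputed, truth, mask) {
  if (!identical(dim(imputed), dim(truth)) ||
      !identical(dim(imputed), dim(mask)))
    stop("imputed, truth and mask must have identical dimensions")
  if (!any(mask)) stop("empty mask: no entries to evaluate")
}

#' Genotype concordance rate
#'
#' Proportion of originally missing genotypes imputed to the true
#' genotype. A genotype counts as concordant only when both alleles match,
#' so an imputed heterozygote against a homozygous truth is discordant.
#'
#' @param imputed,truth code matrices (or `genomat`s) of equal shape.
#' @param mask logical matrix marking the originally missing entries.
#' @return fraction in `[0, 1]`.
#' @export
genotype_cr <- function(imputed, truth, mask) {
  imputed <- as_codes(imputed); truth <- as_codes(truth)
  check_metric_args(imputed, truth, mask)
  mean(imputed[mask] == truth[mask])
}

#' Allelic concordance rate
#'
#' Each masked diploid genotype contributes two allele comparisons: codes
#' map to allele pairs A1A1 / A1A2 / A2A2 and the numerator counts the
#' multiset overlap between imputed and true pairs (a heterozygote imputed
#' as a homozygote still gets one allele right). With `scope = "minor"`
#' the denominator is restricted to true minor-allele copies, where the
#' minor allele is determined per locus from the truth matrix; monomorphic
#' loci carry no minor copies and drop out.
#'
#' @inheritParams genotype_cr
#' @param scope `"all"` or `"minor"`.
#' @return fraction in `[0, 1]`.
#' @export
allelic_cr <- function(imputed, truth, mask, scope = c("all", "minor")) {
  scope <- match.arg(scope)
  imputed <- as_codes(imputed); truth <- as_codes(truth)
  check_metric_args(imputed, truth, mask)
  alt_i <- imputed - 1L # alt-allele copies 0/1/2
  alt_t <- truth - 1L
  if (scope == "all") {
    # multiset overlap of allele pairs = 2 - |alt_i - alt_t|
    return(mean(2L - abs(alt_i[mask] - alt_t[mask])) / 2)
  }
  # per-locus minor allele from the truth genotypes
  p_alt <- colMeans(alt_t) / 2
  minor_is_alt <- p_alt <= 0.5
  mono <- p_alt == 0 | p_alt == 1
  minor_t <- sweep_minor(alt_t, minor_is_alt)
  minor_i <- sweep_minor(alt_i, minor_is_alt)
  keep <- mask & !matrix(mono, nrow(mask), ncol(mask), byrow = TRUE)
  denom <- sum(minor_t[keep])
  if (denom == 0) stop("no true minor-allele copies among masked entries")
  sum(pmin(minor_t[keep], minor_i[keep])) / denom
}

sweep_minor <- function(alt, minor_is_alt) {
  # copies of the locus minor allele per entry
  out <- alt
  flip <- !minor_is_alt
  out[, flip] <- 2L - out[, flip, drop = FALSE]
  out
}

#' Genotype r-squared
#'
#' Squared Pearson correlation between imputed and true integer genotype
#' codes over the masked entries. Undefined (returns `NA`) when either
#' vector is constant, e.g. when the truth is all-heterozygous.
#'
#' @inheritParams genotype_cr
#' @return squared correlation, or `NA` when undefined.
#' @export
genotype_r2 <- function(imputed, truth, mask) {
  imputed <- as_codes(imputed); truth <- as_codes(truth)
  check_metric_args(imputed, truth, mask)
  x <- imputed[mask]; y <- truth[mask]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Heterozygous-locus concordance rate
#'
#' Genotype concordance restricted to masked entries whose true genotype
#' is heterozygous (code 2); `NA` when the mask holds none.
#'
#' @inheritParams genotype_cr
#' @return fraction, or `NA` when no true heterozygotes are masked.
#' @export
het_cr <- function(imputed, truth, mask) {
  imputed <- as_codes(imputed); truth <- as_codes(truth)
  check_metric_args(imputed, truth, mask)
  sel <- mask & truth == 2L
  if (!any(sel)) return(NA_real_)
  mean(imputed[sel] == truth[sel])
}

#' Accuracy metrics stratified by minor-allele frequency
#'
#' Computes, per MAF interval, the minor-allele CR, the all-allele CR and
#' the genotype r-squared over the masked entries of loci falling in that
#' interval. MAF is computed per locus from the truth genotypes; bins are
#' half-open `(lo, hi]` over the default edges
#' 0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5. Empty bins are reported with `NA`
#' values.
#'
#' @inheritParams genotype_cr
#' @param bins increasing numeric vector of bin edges covering (0, 0.5].
#' @return data.frame with one row per bin: `maf_lo`, `maf_hi`,
#'   `n_loci`, `n_masked`, `minor_cr`, `all_cr`, `r2`.
#' @export
maf_binned_metrics <- function(imputed, truth, mask,
                               bins = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  imputed <- as_codes(imputed); truth <- as_codes(truth)
  check_metric_args(imputed, truth, mask)
  p_alt <- colMeans(truth - 1L) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  bin_of <- cut(maf, breaks = bins, include.lowest = FALSE)
  out <- data.frame(maf_lo = head(bins, -1), maf_hi = tail(bins, -1),
                    n_loci = 0L, n_masked = 0L, minor_cr = NA_real_,
                    all_cr = NA_real_, r2 = NA_real_)
  for (b in seq_len(nrow(out))) {
    loci <- which(!is.na(bin_of) & as.integer(bin_of) == b)
    out$n_loci[b] <- length(loci)
    if (!length(loci)) next
    sub_mask <- mask[, loci, drop = FALSE]
    out$n_masked[b] <- sum(sub_mask)
    if (!any(sub_mask)) next
    imp <- imputed[, loci, drop = FALSE]
    tru <- truth[, loci, drop = FALSE]
    out$all_cr[b] <- allelic_cr(imp, tru, sub_mask, "all")
    out$minor_cr[b] <- tryCatch(allelic_cr(imp, tru, sub_mask, "minor"),
                                error = function(e) NA_real_)
    out$r2[b] <- genotype_r2(imp, tru, sub_mask)
  }
  out
}

#' Full accuracy report for an imputation run
#'
#' Bundles genotype CR, allelic CR (all and minor alleles), genotype
#' r-squared, heterozygous-locus CR and the MAF-binned breakdown.
#'
#' @inheritParams genotype_cr
#' @param bins MAF bin edges for [maf_binned_metrics()].
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(imputed, truth, mask,
                           bins = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  structure(list(
    genotype_cr = genotype_cr(imputed, truth, mask),
    allelic_cr = allelic_cr(imputed, truth, mask, "all"),
    minor_allelic_cr = tryCatch(allelic_cr(imputed, truth, mask, "minor"),
                                error = function(e) NA_real_),
    genotype_r2 = genotype_r2(imputed, truth, mask),
    het_cr = het_cr(imputed, truth, mask),
    n_masked = sum(mask),
    per_maf_bin = maf_binned_metrics(imputed, truth, mask, bins)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("imputation accuracy over %d masked genotypes\n", x$n_masked))
  cat(sprintf("  genotype CR : %.4f\n", x$genotype_cr))
  cat(sprintf("  allelic CR  : %.4f (minor alleles: %s)\n", x$allelic_cr,
              ifelse(is.na(x$minor_allelic_cr), "NA",
                     sprintf("%.4f", x$minor_allelic_cr))))
  cat(sprintf("  genotype r2 : %s\n",
              ifelse(is.na(x$genotype_r2), "NA (constant vector)",
                     sprintf("%.4f", x$genotype_r2))))
  cat(sprintf("  het-locus CR: %s\n",
              ifelse(is.na(x$het_cr), "NA (no true heterozygotes)",
                     sprintf("%.4f", x$het_cr))))
  invisible(x)
}
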