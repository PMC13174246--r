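#' Plan training windows over a chromosome
#'
#' Markers are trained and imputed in contiguous windows. Full forward
#' windows `[0,w), [w,2w), ...` cover the chromosome; when a remainder of
#' `r` markers is left at the end, one reverse terminal window trains on
#' the last `w` markers `[p-w, p)` but imputes only the remaining
#' `[p-r, p)`, so terminal regions are processed with a full-width window
#' like everything else. Chromosomes shorter than `w` get a single window.
#' Spans are 0-based half-open; the impute spans partition `[0, p)`.
#'
#' @param p marker count (`>= 1`).
#' @param window window size in markers (`>= 1`).
#' @return data.frame with columns `train_start`, `train_end`,
#'   `impute_start`, `impute_end`, `reverse`.
#' @export
plan_windows <- function(p, window) {
  stopifnot(p >= 1L, window >= 1L)
  p <- as.integer(p); w <- as.integer(window)
  if (p <= w) {
    return(data.frame(train_start = 0L, train_end = p,
                      impute_start = 0L, impute_end = p, reverse = FALSE))
  }
  k <- p %/% w
  r <- p - k * w
  fw <- data.frame(train_start = (0:(k - 1L)) * w,
                   train_end = (1:k) * w, reverse = FALSE)
  fw$impute_start <- fw$train_start
  fw$impute_end <- fw$train_end
  out <- fw[, c("train_start", "train_end", "impute_start", "impute_end",
                "reverse")]
  if (r > 0L) {
    out <- rbind(out, data.frame(train_start = p - w, train_end = p,
                                 impute_start = p - r, impute_end = p,
                                 reverse = TRUE))
  }
  out
}

# Corrupt training rows with random masks at a fixed per-row rate
# (the no-matching ablation).
random_mask_codes <- function(tr_codes, rate) {
  w <- ncol(tr_codes)
  n_mask <- round(rate * w)
  out <- tr_codes
  if (n_mask > 0L)
    for (i in seq_len(nrow(out)))
      out[i, sample.int(w, n_mask)] <- 0L
  out
}

# Train on one aligned window and impute the testing rows.
# Returns the full predicted code matrix for te_w (observed passed through).
impute_window <- function(te_w, tr_w, cfg, mode, seed) {
  n <- nrow(tr_w); m <- nrow(te_w)
  known <- NULL
  corrupt_fn <- NULL
  if (!cfg$matching) {
    rate <- mean(te_w == 0L)
    set.seed(seed)
    clean <- tr_w
    corrupted <- random_mask_codes(tr_w, rate)
    if (cfg$remask_per_epoch)
      corrupt_fn <- function(epoch) random_mask_codes(tr_w, rate)
  } else if (mode == "general" && cfg$augmentation && m >= 2L) {
    k_eff <- max(1L, min(cfg$knn_k, m - 1L))
    aug <- general_mask_augment(as_genomat_codes(tr_w),
                                as_genomat_codes(te_w), k_eff)
    clean <- aug$clean$codes
    corrupted <- aug$corrupted$codes
    known <- aug$known
  } else {
    rec <- reconstructive_mask(as_genomat_codes(tr_w), as_genomat_codes(te_w))
    clean <- tr_w
    corrupted <- rec$corrupted
  }
  model <- train_window(clean, corrupted, cfg, known = known, seed = seed,
                        corrupt_fn = corrupt_fn)
  predict_window(model, te_w)
}

# wrap a bare code matrix in a genomat with dummy positions
as_genomat_codes <- function(codes) {
  genotype_matrix(codes, data.frame(chrom = "w", pos = seq_len(ncol(codes))))
}

# Windowed imputation over all chromosomes of aligned te/tr genomats.
impute_engine <- function(te, tr, cfg, mode) {
  stopifnot(identical(marker_keys(te), marker_keys(tr)))
  out <- te$codes
  n_windows <- 0L
  w_counter <- 0L
  for (ch in unique(te$markers$chrom)) {
    idx <- which(te$markers$chrom == ch)
    wins <- plan_windows(length(idx), cfg$window)
    for (wi in seq_len(nrow(wins))) {
      w_counter <- w_counter + 1L
      cols <- idx[(wins$train_start[wi] + 1L):wins$train_end[wi]]
      rel <- (wins$impute_start[wi] - wins$train_start[wi] + 1L):
        (wins$impute_end[wi] - wins$train_start[wi])
      icols <- cols[rel]
      if (!any(te$codes[, icols] == 0L)) next # nothing to impute here
      n_windows <- n_windows + 1L
      if (cfg$verbose)
        message(sprintf("chromosome %s window %d/%d (%d markers)",
                        ch, wi, nrow(wins), length(cols)))
      seed_w <- (cfg$seed + 7919L * w_counter) %% .Machine$integer.max
      pred <- impute_window(te$codes[, cols, drop = FALSE],
                            tr$codes[, cols, drop = FALSE],
                            cfg, mode, seed_w)
      blk <- te$codes[, icols, drop = FALSE]
      fill <- blk == 0L
      blk[fill] <- pred[, rel, drop = FALSE][fill]
      out[, icols] <- blk
    }
  }
  list(codes = out, n_windows = n_windows)
}

new_impute_result <- function(genotypes, provenance, report) {
  structure(list(genotypes = genotypes, provenance = provenance,
                 report = report), class = "impute_result")
}

#' @export
print.impute_result <- function(x, ...) {
  r <- x$report
  cat("imputation result:", nrow(x$genotypes$codes), "samples x",
      ncol(x$genotypes$codes), "markers;",
      r$n_imputed, "entries imputed in", r$n_windows, "window(s)\n")
  if (r$n_dropped_target_loci > 0)
    cat("  target loci dropped (absent from panel):",
        r$n_dropped_target_loci, "\n")
  invisible(x)
}

#' General imputation against a reference panel
#'
#' Imputes the sporadically (and systematically) missing genotypes of a
#' target set using a missing-free reference panel, window by window: the
#' panel rows are corrupted with the target's own missingness patterns by
#' automatic matching, augmented with KNN-imputed target rows, and a
#' denoising autoencoder is trained per window. Only markers shared by
#' target and panel are imputed; target loci absent from the panel are
#' dropped (counted in the report). Only originally missing entries are
#' replaced.
#'
#' @param target [genotype_matrix()] to impute.
#' @param panel missing-free reference panel `genomat`.
#' @param cfg a [network_config()].
#' @return an `impute_result`: complete genotypes, per-entry provenance
#'   (`TRUE` = imputed) and a count report.
#' @export
general_impute <- function(target, panel, cfg = network_config()) {
  panel_s <- subset_panel(panel, target)
  keep <- marker_keys(target) %in% marker_keys(panel_s)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " target loci absent from the panel were dropped")
  target_s <- subset_markers(target, which(keep))
  miss0 <- target_s$codes == 0L
  eng <- impute_engine(target_s, panel_s, cfg, mode = "general")
  gen <- genotype_matrix(eng$codes, target_s$markers, target_s$sample_ids)
  new_impute_result(gen, miss0, list(
    n_markers = n_markers(gen), n_imputed = sum(miss0),
    n_windows = eng$n_windows, n_dropped_target_loci = n_drop,
    n_allele_dropped = attr(panel_s, "n_allele_dropped")))
}

#' One-way reconstructive imputation for across-population selection
#'
#' Imputes population I onto the union of its own marker set A and a
#' second population's marker set B, restricted to the panel set P: the
#' output contains all samples of population I on exactly the marker set
#' `(A | B) & P`. Loci in `B \ A` enter as systematic missing columns
#' (absent in every sample) before window planning; the matched-mask
#' algorithm then trains each window on precisely those patterns. Marker
#' metadata for appended columns comes from the panel.
#'
#' @param pop1 [genotype_matrix()] of population I.
#' @param positions2 marker positions of population II: a
#'   [position_set()], a marker data.frame, or a genotype matrix (whose
#'   alleles, when present, join the panel consistency check).
#' @param panel missing-free reference panel `genomat`.
#' @param cfg a [network_config()].
#' @return an `impute_result` on the marker set `(A | B) & P`.
#' @export
reconstructive_impute <- function(pop1, positions2, panel,
                                  cfg = network_config()) {
  a_mark <- pop1$markers
  b_mark <- if (inherits(positions2, "genomat")) positions2$markers
            else if (is.data.frame(positions2) && "ref" %in% names(positions2))
              positions2
            else as.data.frame(position_set(positions2))
  if (is.null(b_mark$ref)) { b_mark$ref <- NA_character_; b_mark$alt <- NA_character_ }
  b_only <- !(paste(b_mark$chrom, b_mark$pos, sep = ":") %in%
                paste(a_mark$chrom, a_mark$pos, sep = ":"))
  targets <- rbind(a_mark[, c("chrom", "pos", "ref", "alt")],
                   b_mark[b_only, c("chrom", "pos", "ref", "alt")])
  panel_s <- subset_panel(panel, targets) # (A | B) & P, allele-checked
  out_keys <- marker_keys(panel_s)
  # assemble the target matrix: pop1 codes where locus is in A, else 0
  n1 <- n_samples(pop1)
  codes <- matrix(0L, n1, length(out_keys))
  ma <- match(out_keys, marker_keys(pop1))
  in_a <- !is.na(ma)
  codes[, in_a] <- pop1$codes[, ma[in_a], drop = FALSE]
  target <- genotype_matrix(codes, panel_s$markers, pop1$sample_ids)
  miss0 <- target$codes == 0L
  eng <- impute_engine(target, panel_s, cfg, mode = "reconstructive")
  gen <- genotype_matrix(eng$codes, target$markers, target$sample_ids)
  new_impute_result(gen, miss0, list(
    n_markers = n_markers(gen), n_imputed = sum(miss0),
    n_windows = eng$n_windows, n_dropped_target_loci = 0L,
    n_allele_dropped = attr(panel_s, "n_allele_dropped")))
}

#' Two-way reconstructive imputation
#'
#' Two independent one-way imputations: population I guided by the
#' positions of population II, and population II guided by the positions
#' of population I. Both outputs land on the identical marker set
#' `(A | B) & P`, giving the two populations a shared, expanded marker
#' set for across-population genomic selection.
#'
#' @param pop1,pop2 [genotype_matrix()] objects for the two populations.
#' @param panel missing-free reference panel `genomat`.
#' @param cfg a [network_config()].
#' @return list with `pop1` and `pop2` `impute_result`s.
#' @export
two_way_impute <- function(pop1, pop2, panel, cfg = network_config()) {
  stopifnot(n_samples(pop1) >= 1L, n_samples(pop2) >= 1L)
  r1 <- reconstructive_impute(pop1, pop2, panel, cfg)
  r2 <- reconstructive_impute(pop2, pop1, panel, cfg)
  list(pop1 = r1, pop2 = r2)
}
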