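#' Integer-coded genotype matrix
#'
#' The universal currency of the package: an `n` samples by `p` markers
#' integer matrix with entries in `{0, 1, 2, 3}` plus per-marker metadata.
#' Code 0 means missing; 1, 2 and 3 are the genotypes A1A1, A1A2 and A2A2,
#' where A1 is the allele identical to the reference genome.
#'
#' Markers must be sorted by chromosome with strictly increasing position
#' within each chromosome; `(chrom, pos)` is the identity key used by all
#' marker-set operations.
#'
#' @param codes integer matrix, samples in rows, markers in columns, entries
#'   in `{0,1,2,3}`.
#' @param markers data.frame with columns `chrom`, `pos` and optionally `id`,
#'   `ref`, `alt` (one row per marker, aligned with `codes` columns).
#' @param sample_ids character vector of sample labels (defaults to the row
#'   names of `codes`, or `S1..Sn`).
#' @return An object of class `genomat`.
#' @examples
#' g <- genotype_matrix(matrix(c(1L, 2L, 3L, 0L), 2, 2),
#'                      data.frame(chrom = "1", pos = c(100L, 200L)))
#' g
#' @export
genotype_matrix <- function(codes, markers, sample_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (any(is.na(codes)) || any(codes < 0L | codes > 3L))
    stop("genotype codes must be integers in {0,1,2,3} (0 = missing)")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(markers)))
    stop("markers must have 'chrom' and 'pos' columns")
  if (nrow(markers) != ncol(codes))
    stop("markers rows (", nrow(markers), ") != code columns (", ncol(codes), ")")
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (any(markers$pos < 1L)) stop("marker positions must be >= 1")
  if (is.null(markers$id)) markers$id <- paste0(markers$chrom, "_", markers$pos)
  if (is.null(markers$ref)) markers$ref <- NA_character_
  if (is.null(markers$alt)) markers$alt <- NA_character_
  markers <- markers[, c("chrom", "pos", "id", "ref", "alt")]
  ok <- !is.na(markers$ref) & !is.na(markers$alt)
  if (any(markers$ref[ok] == markers$alt[ok]))
    stop("ref and alt alleles must differ (biallelic markers)")
  check_sorted_markers(markers)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(codes)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(codes)))
  }
  if (length(sample_ids) != nrow(codes))
    stop("sample_ids length != number of code rows")
  dimnames(codes) <- list(sample_ids, markers$id)
  structure(list(sample_ids = as.character(sample_ids),
                 markers = markers, codes = codes),
            class = "genomat")
}

check_sorted_markers <- function(markers) {
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("marker positions on chromosome ", ch,
           " are not strictly increasing")
  }
  invisible(TRUE)
}

#' @export
print.genomat <- function(x, ...) {
  cat("genotype matrix:", nrow(x$codes), "samples x", ncol(x$codes),
      "markers on", length(unique(x$markers$chrom)), "chromosome(s)\n")
  mr <- mean(x$codes == 0L)
  cat(sprintf("  missing: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' @export
dim.genomat <- function(x) dim(x$codes)

#' Number of samples / markers in a genotype matrix
#' @param g a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$codes)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$codes)

#' Marker identity keys
#'
#' `"chrom:pos"` key strings for the markers of a genotype matrix (or a
#' marker data.frame) — the identity used by all marker-set operations.
#' @param x a [genotype_matrix()] or marker data.frame.
#' @return character vector of keys.
#' @export
marker_keys <- function(x) {
  m <- if (inherits(x, "genomat")) x$markers else x
  paste(m$chrom, m$pos, sep = ":")
}

#' Restrict a genotype matrix to a subset of markers or samples
#' @param g a [genotype_matrix()].
#' @param idx integer or logical index over markers (resp. samples).
#' @return a `genomat`.
#' @export
subset_markers <- function(g, idx) {
  genotype_matrix(g$codes[, idx, drop = FALSE], g$markers[idx, , drop = FALSE],
                  g$sample_ids)
}

#' @rdname subset_markers
#' @export
subset_samples <- function(g, idx) {
  genotype_matrix(g$codes[idx, , drop = FALSE], g$markers, g$sample_ids[idx])
}

#' One-hot encode genotype codes
#'
#' Maps codes to binary channel triples: 0 (missing) -> `[0,0,0]`,
#' 1 -> `[1,0,0]`, 2 -> `[0,1,0]`, 3 -> `[0,0,1]`.
#'
#' @param g a [genotype_matrix()] or an integer code matrix.
#' @return numeric array of dim `c(samples, markers, 3)`.
#' @export
encode_onehot <- function(g) {
  codes <- if (inherits(g, "genomat")) g$codes else g
  if (any(codes < 0L | codes > 3L)) stop("codes out of range {0,1,2,3}")
  out <- array(0, dim = c(nrow(codes), ncol(codes), 3L))
  for (k in 1:3) out[, , k] <- (codes == k) * 1
  out
}

#' Decode a one-hot block back to integer codes
#'
#' All-zero channel triples decode to 0 (missing); otherwise the argmax
#' channel maps to codes 1..3, so `decode_onehot(encode_onehot(g))`
#' reproduces `g` exactly.
#'
#' @param x numeric array of dim `c(samples, markers, 3)`.
#' @return integer matrix of codes.
#' @export
decode_onehot <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  n <- dim(x)[1]; p <- dim(x)[2]
  flat <- matrix(x, n * p, 3L)
  code <- max.col(flat, ties.method = "first")
  code[rowSums(flat) == 0] <- 0L
  matrix(as.integer(code), n, p)
}

#' Split a genotype matrix into contiguous marker segments
#'
#' Large chromosomes can be processed in independent segments; the slices
#' are contiguous, non-overlapping and concatenate back to the input.
#'
#' @param g a [genotype_matrix()].
#' @param max_markers maximum number of markers per segment (>= 1).
#' @return list of `genomat` slices.
#' @export
segment_chromosome <- function(g, max_markers) {
  stopifnot(max_markers >= 1)
  p <- n_markers(g)
  starts <- seq(1L, p, by = as.integer(max_markers))
  lapply(starts, function(s) {
    subset_markers(g, s:min(s + max_markers - 1L, p))
  })
}
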