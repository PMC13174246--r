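#' Marker position sets
#'
#' A `position_set` is a deduplicated, sorted set of `(chrom, pos)` keys —
#' the currency of the marker-set algebra used for across-population
#' imputation (population marker sets A and B and the panel set P).
#'
#' @param chrom character vector of chromosome labels, or a data.frame with
#'   `chrom`/`pos` columns, or a [genotype_matrix()].
#' @param pos integer positions (ignored when `chrom` is not atomic).
#' @return object of class `position_set`: a data.frame with `chrom`, `pos`.
#' @examples
#' a <- position_set(c("1", "1"), c(5L, 9L))
#' b <- position_set(c("1", "2"), c(9L, 3L))
#' marker_set_op(a, b, "union")
#' @export
position_set <- function(chrom, pos = NULL) {
  if (inherits(chrom, "genomat")) {
    df <- chrom$markers[, c("chrom", "pos")]
  } else if (is.data.frame(chrom)) {
    df <- chrom[, c("chrom", "pos")]
  } else {
    df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                     stringsAsFactors = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df <- unique(df)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("position_set", "data.frame")
  df
}

#' @export
print.position_set <- function(x, ...) {
  cat("position set:", nrow(x), "loci on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

pos_keys <- function(x) paste(x$chrom, x$pos, sep = ":")

#' Union / intersection of marker position sets
#'
#' Standard set semantics on `(chrom, pos)` keys. Across-population genomic
#' selection without imputation is limited to the intersection of the two
#' population sets; reconstructive imputation targets `(A | B) & P`.
#'
#' @param a,b [position_set()] objects (or coercibles).
#' @param op `"union"` or `"intersection"`.
#' @return a `position_set`.
#' @export
marker_set_op <- function(a, b, op = c("union", "intersection")) {
  op <- match.arg(op)
  a <- position_set(a); b <- position_set(b)
  if (op == "union") {
    position_set(rbind(as.data.frame(a), as.data.frame(b)))
  } else {
    keep <- pos_keys(a) %in% pos_keys(b)
    position_set(a[keep, , drop = FALSE])
  }
}

#' Restrict a reference panel to target loci
#'
#' Keeps the panel markers whose `(chrom, pos)` key is in `targets`,
#' preserving panel order. When `targets` carries allele metadata (it is a
#' genotype matrix or marker data.frame with `ref`/`alt`), loci whose
#' alleles disagree with the panel (including swapped ref/alt) are dropped
#' with a warning; no allele flipping is attempted. The number of dropped
#' loci is recorded in the `"n_allele_dropped"` attribute.
#'
#' @param panel a missing-free [genotype_matrix()] (the reference panel).
#' @param targets a [position_set()], marker data.frame or `genomat`.
#' @return a `genomat` restricted to the intersection loci.
#' @export
subset_panel <- function(panel, targets) {
  stopifnot(inherits(panel, "genomat"))
  if (any(panel$codes == 0L))
    stop("missing genotypes are not permitted in the reference panel")
  tgt_markers <- NULL
  if (inherits(targets, "genomat")) tgt_markers <- targets$markers
  else if (is.data.frame(targets) && all(c("ref", "alt") %in% names(targets)))
    tgt_markers <- targets
  ts <- position_set(targets)
  keep <- marker_keys(panel) %in% pos_keys(ts)
  n_dropped <- 0L
  if (!is.null(tgt_markers)) {
    tk <- paste(tgt_markers$chrom, tgt_markers$pos, sep = ":")
    m <- match(marker_keys(panel), tk)
    has_t <- !is.na(m)
    cand <- which(keep & has_t)
    if (length(cand)) {
      tr <- tgt_markers$ref[m[cand]]; ta <- tgt_markers$alt[m[cand]]
      pr <- panel$markers$ref[cand]; pa <- panel$markers$alt[cand]
      mismatch <- !is.na(tr) & !is.na(ta) & !is.na(pr) & !is.na(pa) &
        !(tr == pr & ta == pa)
      if (any(mismatch)) {
        n_dropped <- sum(mismatch)
        warning(n_dropped, " loci dropped for ref/alt allele mismatch ",
                "between target and panel")
        keep[cand[mismatch]] <- FALSE
      }
    }
  }
  if (!any(keep)) stop("no panel loci intersect the target position set")
  out <- subset_markers(panel, which(keep))
  attr(out, "n_allele_dropped") <- n_dropped
  out
}
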