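# LD-structured diploid genotype simulator: founder haplotypes copied by a
# first-order mosaic (haplotype-copying) process, so nearby markers are
# correlated and imputation is learnable.

draw_haplotypes <- function(founders, n_hap, switch_rate, mutation_rate) {
  K <- nrow(founders); p <- ncol(founders)
  H <- matrix(0L, n_hap, p)
  for (h in seq_len(n_hap)) {
    seg <- cumsum(c(1L, runif(p - 1) < switch_rate))
    path <- sample.int(K, max(seg), replace = TRUE)[seg]
    al <- founders[cbind(path, seq_len(p))]
    if (mutation_rate > 0) {
      flip <- runif(p) < mutation_rate
      al[flip] <- 1L - al[flip]
    }
    H[h, ] <- al
  }
  H
}

make_founders <- function(n_founders, p, maf_floor) {
  f <- runif(p, maf_floor, 1 - maf_floor)
  k <- pmin(pmax(round(f * n_founders), 1L), n_founders - 1L)
  founders <- matrix(0L, n_founders, p)
  for (j in seq_len(p))
    founders[sample.int(n_founders, k[j]), j] <- 1L
  founders
}

random_markers <- function(p, chrom) {
  pos <- cumsum(sample.int(200L, p, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, p, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(chrom = chrom, pos = pos, id = paste0(chrom, "_", pos),
             ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate an LD-structured reference panel
#'
#' Founder haplotypes with per-locus minor-allele frequencies bounded
#' below by `maf_floor` are copied into sample haplotypes by a first-order
#' mosaic: each haplotype follows one founder and switches to a random
#' founder between adjacent markers with probability `switch_rate`, plus
#' rare allele flips at `mutation_rate`. Two haplotypes pair into a
#' diploid genotype (codes 1/2/3; no missing values). Smaller switch
#' rates give longer shared haplotype blocks, i.e. stronger linkage
#' disequilibrium.
#'
#' @param n_samples panel size.
#' @param n_markers marker count.
#' @param n_founders founder haplotype count.
#' @param switch_rate per-interval haplotype switch probability.
#' @param mutation_rate per-allele flip probability.
#' @param maf_floor minimum simulated minor-allele frequency (< 0.5).
#' @param chrom chromosome label for the simulated markers.
#' @param seed RNG seed (the same seed reproduces the matrix exactly).
#' @return a missing-free `genomat`; the founder haplotypes are attached
#'   as attribute `"founders"` so related populations can be derived.
#' @export
simulate_panel <- function(n_samples = 100L, n_markers = 500L,
                           n_founders = 6L, switch_rate = 0.02,
                           mutation_rate = 0.001, maf_floor = 0.05,
                           chrom = "1", seed = 1L) {
  stopifnot(n_samples >= 1L, n_markers >= 1L, n_founders >= 2L,
            switch_rate >= 0, switch_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, maf_floor < 0.5)
  set.seed(seed)
  founders <- make_founders(n_founders, n_markers, maf_floor)
  markers <- random_markers(n_markers, chrom)
  H <- draw_haplotypes(founders, 2L * n_samples, switch_rate, mutation_rate)
  codes <- 1L + H[seq(1, 2 * n_samples, 2), , drop = FALSE] +
    H[seq(2, 2 * n_samples, 2), , drop = FALSE]
  g <- genotype_matrix(codes, markers,
                       sample_ids = sprintf("P%03d", seq_len(n_samples)))
  attr(g, "founders") <- founders
  attr(g, "sim") <- list(switch_rate = switch_rate,
                         mutation_rate = mutation_rate,
                         maf_floor = maf_floor, seed = seed)
  g
}

#' Derive two chip-genotyped populations from a simulated panel
#'
#' Draws two fresh sample sets from the panel's founders by the same
#' mosaic process (so the panel is informative for them) and assigns each
#' population a marker subset — emulating two populations genotyped on
#' different chips A and B whose overlap is configurable down to zero.
#'
#' @param panel a [simulate_panel()] result (its `"founders"` attribute
#'   is reused; set `unrelated = TRUE` to draw new founders instead, a
#'   negative control where the panel carries no information).
#' @param n_pop1,n_pop2 sample counts.
#' @param size_a,size_b marker subset sizes for the two chips.
#' @param n_overlap exact number of shared markers between the chips.
#' @param unrelated draw independent founders for the populations.
#' @param seed RNG seed.
#' @return list with `pop1`, `pop2` (genomats restricted to their chips),
#'   `pop1_full`, `pop2_full` (complete truth at all panel markers) and
#'   the chip index vectors `idx_a`, `idx_b`.
#' @export
derive_populations <- function(panel, n_pop1, n_pop2, size_a, size_b,
                               n_overlap, unrelated = FALSE, seed = 2L) {
  p <- n_markers(panel)
  stopifnot(size_a <= p, size_b <= p, n_overlap <= min(size_a, size_b))
  if (size_a + size_b - n_overlap > p)
    stop("requested chip sizes and overlap exceed the marker count")
  sim <- attr(panel, "sim")
  founders <- attr(panel, "founders")
  if (is.null(founders) || is.null(sim))
    stop("panel lacks simulation attributes; use simulate_panel()")
  set.seed(seed)
  if (unrelated)
    founders <- make_founders(nrow(founders), p, sim$maf_floor)
  draw_pop <- function(n, prefix) {
    H <- draw_haplotypes(founders, 2L * n, sim$switch_rate, sim$mutation_rate)
    codes <- 1L + H[seq(1, 2 * n, 2), , drop = FALSE] +
      H[seq(2, 2 * n, 2), , drop = FALSE]
    genotype_matrix(codes, panel$markers,
                    sample_ids = sprintf("%s%03d", prefix, seq_len(n)))
  }
  pop1_full <- draw_pop(n_pop1, "A")
  pop2_full <- draw_pop(n_pop2, "B")
  shared <- sample.int(p, n_overlap)
  rest <- setdiff(seq_len(p), shared)
  a_extra <- sample(rest, size_a - n_overlap)
  b_extra <- sample(setdiff(rest, a_extra), size_b - n_overlap)
  idx_a <- sort(c(shared, a_extra))
  idx_b <- sort(c(shared, b_extra))
  list(pop1 = subset_markers(pop1_full, idx_a),
       pop2 = subset_markers(pop2_full, idx_b),
       pop1_full = pop1_full, pop2_full = pop2_full,
       idx_a = idx_a, idx_b = idx_b)
}

#' Simulate additive phenotypes
#'
#' Additive model `y = Z[, qtl] beta + e` on marker codes recoded to
#' genetic values -1/0/1, with standard-normal effects at `n_qtl` random
#' loci and residual variance chosen so the realized narrow-sense
#' heritability matches `h2`.
#'
#' @param g missing-free [genotype_matrix()].
#' @param n_qtl number of causal loci (`<= n_markers(g)`).
#' @param h2 target narrow-sense heritability in (0, 1].
#' @param seed RNG seed.
#' @return list with `y` (phenotypes), `genetic_values`, `qtl` (loci) and
#'   `beta` (effects).
#' @export
simulate_phenotypes <- function(g, n_qtl = 50L, h2 = 0.5, seed = 1L) {
  stopifnot(n_qtl <= n_markers(g), h2 > 0, h2 <= 1)
  if (any(g$codes == 0L)) stop("genotypes must be missing-free")
  set.seed(seed)
  z <- g$codes - 2L
  qtl <- sort(sample.int(ncol(z), n_qtl))
  beta <- rnorm(n_qtl)
  gval <- as.numeric(z[, qtl, drop = FALSE] %*% beta)
  vg <- var(gval)
  ve <- if (h2 >= 1) 0 else vg * (1 - h2) / h2
  y <- gval + rnorm(length(gval), 0, sqrt(ve))
  list(y = y, genetic_values = gval, qtl = qtl, beta = beta)
}
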