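#' Mean-fill missing genotypes of a testing set
#'
#' Replaces each missing (code 0) entry of the testing samples with the
#' mean code of the corresponding marker across the training samples,
#' producing the real-valued matrix used for distance computation.
#'
#' @param te testing [genotype_matrix()] (may contain code 0).
#' @param tr training [genotype_matrix()] (reference panel; missing-free),
#'   sharing `te`'s marker set and order.
#' @return numeric matrix, samples x markers.
#' @export
mean_fill <- function(te, tr) {
  if (!identical(marker_keys(te), marker_keys(tr)))
    stop("testing and training marker sets are not aligned")
  if (any(tr$codes == 0L)) stop("training set must be missing-free")
  filled <- te$codes * 1.0
  mu <- colMeans(tr$codes)
  miss <- te$codes == 0L
  filled[miss] <- rep(mu, each = nrow(filled))[miss]
  filled
}

#' Manhattan distance matrix between two sets of samples
#'
#' Entry `(i, j)` is the sum of absolute differences of the numerically
#' encoded genotypes of sample `i` of `a` and sample `j` of `b`.
#'
#' @param a,b numeric matrices (samples x markers) with equal marker count.
#' @return `nrow(a)` x `nrow(b)` distance matrix.
#' @export
manhattan_distances <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("marker dimension mismatch")
  D <- manhattan_dist_cpp(a, b)
  dimnames(D) <- list(rownames(a), rownames(b))
  D
}

new_mask_plan <- function(train_id, test_id, masks, round) {
  structure(list(train_id = train_id, test_id = test_id, masks = masks,
                 round = round),
            class = "mask_plan")
}

#' @export
print.mask_plan <- function(x, ...) {
  cat("mask plan:", length(x$masks), "corrupted training rows,",
      sum(lengths(x$masks)), "masked entries in", max(x$round), "round(s)\n")
  invisible(x)
}

#' Tabulate a mask plan
#'
#' @param x a `mask_plan`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per corrupted training sample: its id,
#'   the matched testing sample, the matching round and the mask size.
#' @export
as.data.frame.mask_plan <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(train_id = x$train_id, test_id = x$test_id, round = x$round,
             n_masked = lengths(x$masks), stringsAsFactors = FALSE)
}

#' Masked-marker generation by automatic sample matching (reconstructive)
#'
#' Builds the corrupted training set for the denoising autoencoder so that
#' training rows carry exactly the missingness patterns present in the
#' testing set. Procedure: mean-fill the testing set; compute the
#' Manhattan distance matrix between training and (filled) testing
#' samples; order testing samples by descending average distance; each
#' testing sample in turn claims its nearest still-unselected training
#' sample (without replacement) and stamps its missing positions onto it;
#' passes over the ordered testing list repeat until every training
#' sample has been selected. Ties (equal average or nearest distances)
#' break towards the smallest sample index.
#'
#' @param tr training [genotype_matrix()] (missing-free reference panel).
#' @param te testing [genotype_matrix()] on the same marker set.
#' @return list with `plan` (a `mask_plan`) and `corrupted` (the training
#'   codes with masked entries set to 0).
#' @export
reconstructive_mask <- function(tr, te) {
  if (n_samples(te) == 0L) stop("testing set has zero samples")
  n <- n_samples(tr); m <- n_samples(te)
  te_missing <- lapply(seq_len(m), function(j) unname(which(te$codes[j, ] == 0L)))
  te_filled <- mean_fill(te, tr)
  # mean-filled entries are multiples of 1/n, so n*D is integer-valued;
  # rounding removes float noise and makes ties (and the smallest-index
  # tie-break) exact
  D <- round(manhattan_distances(tr$codes, te_filled) * n)
  avg <- colMeans(D)
  ord <- order(-avg) # stable: ties fall back to ascending sample index
  remaining <- rep(TRUE, n)
  test_of <- integer(n); round_of <- integer(n)
  rnd <- 0L
  while (any(remaining)) {
    rnd <- rnd + 1L
    for (j in ord) {
      if (!any(remaining)) break
      cand <- which(remaining)
      i <- cand[which.min(D[cand, j])]
      test_of[i] <- j
      round_of[i] <- rnd
      remaining[i] <- FALSE
    }
  }
  masks <- te_missing[test_of]
  corrupted <- tr$codes
  for (i in seq_len(n)) if (length(masks[[i]])) corrupted[i, masks[[i]]] <- 0L
  plan <- new_mask_plan(tr$sample_ids, te$sample_ids[test_of], masks, round_of)
  list(plan = plan, corrupted = corrupted)
}

#' KNN imputation of a testing set
#'
#' Classical k-nearest-neighbour fill used to build the augmented training
#' rows for general imputation: distances are Manhattan distances on the
#' column-mean-filled codes; each missing entry takes the majority code
#' among the k nearest samples (votes from samples observed at that
#' marker; ties towards the smallest code). A marker missing in every
#' sample cannot be voted on and raises an error.
#'
#' @param te testing [genotype_matrix()].
#' @param k neighbour count (`>= 1`; needs at least `k + 1` samples).
#' @return a missing-free `genomat`.
#' @export
knn_impute <- function(te, k = 5L) {
  m <- n_samples(te)
  if (k < 1L) stop("k must be >= 1")
  if (m < k + 1L) stop("need at least k + 1 testing samples")
  codes <- te$codes
  if (any(colSums(codes > 0L) == 0L))
    stop("marker(s) missing in every testing sample cannot be KNN-imputed")
  filled <- codes * 1.0
  obs <- codes > 0L
  mu <- colSums(codes * obs) / colSums(obs)
  filled[!obs] <- rep(mu, each = m)[!obs]
  D <- manhattan_distances(filled, filled)
  diag(D) <- Inf
  out <- codes
  for (j in seq_len(m)) {
    gaps <- which(codes[j, ] == 0L)
    if (!length(gaps)) next
    ordn <- order(D[, j]) # stable ties -> smallest sample index
    nb <- ordn[seq_len(k)]
    for (t in gaps) {
      votes <- codes[nb, t]
      votes <- votes[votes > 0L]
      if (length(votes)) {
        out[j, t] <- which.max(tabulate(votes, 3L)) # tie -> smallest code
      } else {
        donor <- ordn[which(codes[ordn, t] > 0L)[1]]
        out[j, t] <- codes[donor, t]
      }
    }
  }
  genotype_matrix(out, te$markers, te$sample_ids)
}

#' Masked-marker generation with data augmentation (general imputation)
#'
#' Extends [reconstructive_mask()] for sporadic missingness: the testing
#' set is KNN-imputed and stacked onto the training set as augmented rows,
#' each corrupted with a missingness pattern borrowed from another testing
#' sample. Pairwise Manhattan distances between KNN-imputed testing
#' samples are computed with the diagonal set to twice the matrix maximum
#' (self-matching is forbidden); testing samples are arranged both in
#' descending and ascending order of average distance, and in each pass
#' every arranged sample claims its nearest remaining sample (fresh
#' without-replacement pool per pass) and stamps its missing pattern onto
#' that sample's KNN row. The matched row's own originally-missing
#' positions are excluded from the stamp (their clean values are KNN
#' guesses, not observations); masks from the two passes are unioned.
#'
#' @param tr training [genotype_matrix()] (missing-free reference panel).
#' @param te testing [genotype_matrix()] with at least 2 samples.
#' @param k KNN neighbour count.
#' @return an `aug_set`: list with `clean` and `corrupted` genomats of
#'   `n + m` rows, `origin` (`"panel"`/`"augmented"` per row), `known`
#'   (logical matrix of rows x markers marking genuinely observed clean
#'   entries), and the reconstructive `plan`.
#' @export
general_mask_augment <- function(tr, te, k = 5L) {
  m <- n_samples(te)
  if (m < 2L) stop("general matching needs at least 2 testing samples")
  rec <- reconstructive_mask(tr, te)
  te_missing <- lapply(seq_len(m), function(j) unname(which(te$codes[j, ] == 0L)))
  # markers missing in every testing sample carry no votes; seed them with
  # the panel's per-marker majority code so KNN can run. They stay flagged
  # as originally missing, so they are excluded from both the loss support
  # and the mask stamps of the augmented rows.
  all_miss <- which(colSums(te$codes > 0L) == 0L)
  if (length(all_miss)) {
    te2 <- te$codes
    for (j in all_miss)
      te2[, j] <- which.max(tabulate(tr$codes[, j], 3L))
    te <- genotype_matrix(te2, te$markers, te$sample_ids)
  }
  te_knn <- knn_impute(te, k)
  D <- manhattan_distances(te_knn$codes, te_knn$codes)
  D[cbind(seq_len(m), seq_len(m))] <- 2 * max(D)
  avg <- colMeans(D)
  masks <- vector("list", m)
  for (ord in list(order(-avg), order(avg))) {
    pool <- rep(TRUE, m)
    for (j in ord) {
      if (!any(pool)) break
      cand <- which(pool)
      i <- cand[which.min(D[cand, j])]
      masks[[i]] <- union(masks[[i]], setdiff(te_missing[[j]], te_missing[[i]]))
      pool[i] <- FALSE
    }
  }
  te_corr <- te_knn$codes
  for (i in seq_len(m)) if (length(masks[[i]])) te_corr[i, masks[[i]]] <- 0L
  clean_codes <- rbind(tr$codes, te_knn$codes)
  corr_codes <- rbind(rec$corrupted, te_corr)
  ids <- make.unique(c(tr$sample_ids, te$sample_ids))
  known <- matrix(TRUE, nrow(clean_codes), ncol(clean_codes))
  for (j in seq_len(m)) known[n_samples(tr) + j, te_missing[[j]]] <- FALSE
  structure(list(
    clean = genotype_matrix(clean_codes, tr$markers, ids),
    corrupted = genotype_matrix(corr_codes, tr$markers, ids),
    origin = rep(c("panel", "augmented"), c(n_samples(tr), m)),
    known = known,
    plan = rec$plan,
    aug_masks = masks), class = "aug_set")
}

#' Literal reference implementation of the reconstructive matching steps
#'
#' An unvectorised, loop-by-loop transcription of the matching procedure
#' (mean fill, distance matrix, descending average-distance ordering,
#' without-replacement nearest-neighbour selection, repeated passes),
#' kept deliberately independent of [reconstructive_mask()] so the two
#' routes can be cross-validated on random instances.
#'
#' @inheritParams reconstructive_mask
#' @return same structure as [reconstructive_mask()].
#' @export
matching_reference <- function(tr, te) {
  n <- nrow(tr$codes); m <- nrow(te$codes); p <- ncol(tr$codes)
  # step 2: mean fill. Worked in units of 1/n (numerators of the exact
  # rationals) so distance comparisons and ties are exact.
  te_f <- matrix(0L, m, p) # n * filled value
  for (t in seq_len(p)) {
    s <- 0L
    for (i in seq_len(n)) s <- s + tr$codes[i, t]
    for (j in seq_len(m))
      te_f[j, t] <- if (te$codes[j, t] == 0L) s else n * te$codes[j, t]
  }
  # step 3: Manhattan distances (scaled by n)
  D <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d <- 0
    for (t in seq_len(p)) d <- d + abs(n * tr$codes[i, t] - te_f[j, t])
    D[i, j] <- d
  }
  # steps 4-5: average distance, descending order (ties: sample index)
  avg <- numeric(m)
  for (j in seq_len(m)) avg[j] <- sum(D[, j]) / n
  ord <- integer(0)
  left <- seq_len(m)
  while (length(left)) {
    best <- left[1]
    for (j in left) if (avg[j] > avg[best]) best <- j
    ord <- c(ord, best)
    left <- setdiff(left, best)
  }
  # steps 6-7: without-replacement nearest selection, repeated passes
  selected <- logical(n)
  test_of <- integer(n); round_of <- integer(n)
  rnd <- 0L
  while (!all(selected)) {
    rnd <- rnd + 1L
    for (j in ord) {
      if (all(selected)) break
      best <- 0L
      for (i in seq_len(n))
        if (!selected[i] && (best == 0L || D[i, j] < D[best, j])) best <- i
      selected[best] <- TRUE
      test_of[best] <- j
      round_of[best] <- rnd
    }
  }
  corrupted <- tr$codes
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    masks[[i]] <- unname(which(te$codes[test_of[i], ] == 0L))
    for (t in masks[[i]]) corrupted[i, t] <- 0L
  }
  plan <- new_mask_plan(tr$sample_ids, te$sample_ids[test_of], masks, round_of)
  list(plan = plan, corrupted = corrupted)
}
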