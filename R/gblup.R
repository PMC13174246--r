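#' Additive genomic relationship matrix (VanRaden)
#'
#' Markers are recoded to genetic values -1/0/1 (codes 1/2/3 for A1A1,
#' A1A2, A2A2), centred by twice the allele-frequency deviation and
#' cross-multiplied, normalised by `2 * sum(p_j (1 - p_j))`.
#'
#' @param Z matrix of genetic values in \{-1, 0, 1\} (samples x markers),
#'   or a [genotype_matrix()] (codes are recoded internally).
#' @return symmetric positive semidefinite relationship matrix.
#' @export
grm <- function(Z) {
  if (inherits(Z, "genomat")) {
    if (any(Z$codes == 0L)) stop("genotypes must be missing-free")
    Z <- Z$codes - 2L
  }
  Z <- as.matrix(Z)
  p_alt <- colMeans(Z + 1L) / 2
  denom <- 2 * sum(p_alt * (1 - p_alt))
  if (denom == 0) stop("all markers are monomorphic; relationship undefined")
  W <- sweep(Z, 2, 2 * p_alt - 1)
  tcrossprod(W) / denom
}

# REML profile over h2 on the eigenbasis of the training-block G.
reml_h2 <- function(y, G_tt) {
  n <- length(y)
  eg <- eigen(G_tt, symmetric = TRUE)
  U <- eg$vectors; delta <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  nll <- function(h2) {
    d <- h2 * delta + (1 - h2)
    w <- 1 / d
    xwx <- sum(xt * xt * w)
    beta <- sum(xt * yt * w) / xwx
    r <- yt - xt * beta
    rss <- sum(r * r * w)
    0.5 * (sum(log(d)) + log(xwx) + (n - 1) * log(rss))
  }
  opt <- optimize(nll, c(1e-4, 1 - 1e-4))
  h2 <- opt$minimum
  if (!is.finite(opt$objective)) h2 <- 0.5 # degenerate likelihood fallback
  h2
}

#' Fit GBLUP and predict test individuals
#'
#' The mixed model `y = X beta + a + e` with breeding values
#' `a ~ N(0, G_a sigma_a^2)` and residuals `e ~ N(0, I sigma_e^2)`, where
#' `G_a` is the VanRaden relationship matrix over the stacked training and
#' test genotypes (which must share an identical marker set — the
#' across-population contract). The variance ratio is estimated by
#' restricted maximum likelihood profiled over the heritability
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)` on the eigenbasis of the
#' training-block relationship matrix; fixed effects default to an
#' intercept. Test breeding values come from the mixed-model equations,
#' and predictability is the Pearson correlation between predicted and
#' observed test phenotypes (when supplied).
#'
#' @param train_geno [genotype_matrix()] (or -1/0/1 matrix) of the
#'   training population.
#' @param train_pheno numeric phenotype vector for the training samples.
#' @param test_geno genotypes of the individuals to predict, on the same
#'   markers.
#' @param test_pheno optional observed test phenotypes (enables
#'   predictability).
#' @param h2 optional fixed heritability; bypasses REML (used e.g. for
#'   variance-ratio-fixed comparisons).
#' @return object of class `gblup`: estimates `h2`, `sigma2_a`,
#'   `sigma2_e`, `beta` (intercept), predicted values `pred_train` and
#'   `pred_test`, test breeding values `a_test`, and `predictability`
#'   (`NA` without test phenotypes).
#' @export
gblup_fit_predict <- function(train_geno, train_pheno, test_geno,
                              test_pheno = NULL, h2 = NULL) {
  zc <- function(g) if (inherits(g, "genomat")) g$codes - 2L else as.matrix(g)
  if (inherits(train_geno, "genomat") && inherits(test_geno, "genomat") &&
      !identical(marker_keys(train_geno), marker_keys(test_geno)))
    stop("training and test sets must share an identical marker set")
  Z1 <- zc(train_geno); Z2 <- zc(test_geno)
  if (ncol(Z1) != ncol(Z2)) stop("marker count mismatch")
  n1 <- nrow(Z1); n2 <- nrow(Z2)
  y <- as.numeric(train_pheno)
  stopifnot(length(y) == n1)
  G <- grm(rbind(Z1, Z2))
  it <- seq_len(n1); ip <- n1 + seq_len(n2)
  if (is.null(h2)) h2 <- reml_h2(y, G[it, it])
  eg <- eigen(G[it, it], symmetric = TRUE)
  d <- h2 * pmax(eg$values, 0) + (1 - h2)
  Ut_y <- drop(crossprod(eg$vectors, y))
  Ut_1 <- drop(crossprod(eg$vectors, rep(1, n1)))
  beta <- sum(Ut_1 * Ut_y / d) / sum(Ut_1 * Ut_1 / d)
  vinv_r <- eg$vectors %*% ((Ut_y - Ut_1 * beta) / d)
  a_train <- h2 * drop(G[it, it] %*% vinv_r)
  a_test <- h2 * drop(G[ip, it] %*% vinv_r)
  r <- y - beta
  s2 <- sum((Ut_y - Ut_1 * beta)^2 / d) / (n1 - 1)
  pred_test <- beta + a_test
  predictability <- if (is.null(test_pheno)) NA_real_ else
    cor(pred_test, as.numeric(test_pheno))
  structure(list(h2 = h2, sigma2_a = h2 * s2, sigma2_e = (1 - h2) * s2,
                 beta = beta, pred_train = beta + a_train,
                 pred_test = pred_test, a_test = a_test,
                 predictability = predictability,
                 n_train = n1, n_test = n2, n_markers = ncol(Z1)),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("GBLUP fit: %d training / %d test samples, %d markers\n",
              x$n_train, x$n_test, x$n_markers))
  cat(sprintf("  h2 = %.3f (sigma2_a %.3f, sigma2_e %.3f)\n",
              x$h2, x$sigma2_a, x$sigma2_e))
  if (!is.na(x$predictability))
    cat(sprintf("  predictability (Pearson r) = %.3f\n", x$predictability))
  invisible(x)
}
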