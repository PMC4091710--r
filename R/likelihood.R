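#' Probability that a read carries the variant allele
#'
#' Under the heterozygous, copy-number-one assumption, a clone carrying a
#' mutation contributes half of its cell fraction to the variant-read
#' probability, so for a genotype vector `z` and a column `p` of the clone
#' frequency matrix the probability is `sum(z * p) / 2`, which always lies in
#' \[0, 1/2\].
#'
#' @param z binary genotype vector of length C; the first entry (normal
#'   clone) must be 0.
#' @param p clone-frequency column of length C summing to 1.
#' @return a single probability in \[0, 0.5\].
#' @examples
#' variant_read_prob(c(0, 1), c(0.4, 0.6))      # 0.30
#' variant_read_prob(c(0, 1, 1), c(0.2, 0.5, 0.3)) # 0.40
#' @export
variant_read_prob <- function(z, p) {
  if (length(z) != length(p)) stop("z and p must have equal length")
  if (!all(z %in% c(0, 1))) stop("z must be a binary (0/1) vector")
  if (z[1L] != 0) stop("the first (normal-clone) entry of z must be 0")
  if (abs(sum(p) - 1) > 1e-6) stop("p must sum to 1")
  sum(z * p) / 2
}

# M x S matrix of variant-read probabilities for a genotype matrix W (M x C)
# and clone frequency matrix P (C x S). Entries are in [0, 1/2].
variant_prob_matrix <- function(W, P) {
  (W %*% P) / 2
}

# All 2^(C-1) admissible genotype vectors as a K x C binary matrix whose
# first column (normal clone) is zero. Row 1 is the all-zero vector; clone 2
# is the fastest-varying bit, so the ordering is reproducible.
enumerate_genotypes <- function(C, cap = 12L) {
  if (C < 1L) stop("C must be >= 1")
  if (C > cap)
    stop("C = ", C, " exceeds the genotype enumeration cap (", cap,
         "); refit with fewer clones")
  if (C == 1L) return(matrix(0, 1L, 1L))
  bits <- as.matrix(expand.grid(rep(list(c(0, 1)), C - 1L)))
  Z <- cbind(0, bits)
  dimnames(Z) <- NULL
  Z
}

check_theta <- function(theta, C) {
  if (length(theta) != C) stop("theta must have length C = ", C)
  if (any(theta < 0 | theta > 1)) stop("theta entries must lie in [0, 1]")
  if (theta[1L] != 0) stop("theta[1] (normal clone) must be 0")
  invisible(theta)
}

check_P <- function(P, S = NULL, tol = 1e-8) {
  P <- as.matrix(P)
  if (!is.null(S) && ncol(P) != S) stop("P must have ", S, " columns")
  if (any(P < -tol | P > 1 + tol)) stop("P entries must lie in [0, 1]")
  cs <- colSums(P)
  if (any(abs(cs - 1) > tol))
    stop("each column of P must sum to 1 (column ",
         which.max(abs(cs - 1)), " sums to ", cs[which.max(abs(cs - 1))], ")")
  P
}

check_W <- function(W, M = NULL) {
  W <- as.matrix(W)
  if (!is.null(M) && nrow(W) != M) stop("W must have ", M, " rows")
  if (!all(W %in% c(0, 1))) stop("W entries must be 0 or 1")
  if (any(W[, 1L] != 0)) stop("the first column of W (normal clone) must be all zero")
  W
}

#' Complete-data log-likelihood of the clonal model
#'
#' The joint log-probability of the observed variant counts and a fixed
#' genotype matrix: Bernoulli terms for the tumor-clone entries of `W` under
#' the mutation prior `theta`, plus binomial terms for every count `X[i,j]`
#' given `N[i,j]` and the variant-read probability implied by `(W, P)`.
#' An observation that is impossible under the model (e.g. variant reads at
#' a locus where no clone carries the mutation and the variant-read
#' probability is exactly zero) yields `-Inf` rather than an error.
#'
#' @param panel a [counts_panel()].
#' @param W M x C binary genotype matrix (column 1 all zero).
#' @param P C x S clone frequency matrix (columns sum to 1).
#' @param theta length-C mutation prior; `theta[1] == 0`.
#' @param include_coef include the binomial coefficient terms (constant in
#'   the parameters)? Default `TRUE`, so reported values are comparable
#'   across software.
#' @return a scalar log-likelihood (possibly `-Inf`).
#' @export
complete_loglik <- function(panel, W, P, theta, include_coef = TRUE) {
  stopifnot(inherits(panel, "counts_panel"))
  M <- nrow(panel$N); S <- ncol(panel$N)
  W <- check_W(W, M)
  C <- ncol(W)
  P <- check_P(P, S)
  if (nrow(P) != C) stop("W and P disagree on the number of clones")
  check_theta(theta, C)

  B <- variant_prob_matrix(W, P)
  ll_binom <- sum(stats::dbinom(panel$X, panel$N, B, log = TRUE))
  ll_bern <- 0
  if (C >= 2L)
    ll_bern <- sum(stats::dbinom(W[, -1L, drop = FALSE], 1,
                                 rep(theta[-1L], each = M), log = TRUE))
  ll <- ll_binom + ll_bern
  if (!include_coef) ll <- ll - sum(lchoose(panel$N, panel$X))
  ll
}

#' Observed-data log-likelihood of the clonal model
#'
#' Marginalizes the latent genotypes out of the model: for each locus the
#' likelihood is a sum over all 2^(C-1) admissible genotype vectors of the
#' Bernoulli prior mass times the product over subsections of binomial count
#' probabilities. Computed with log-sum-exp stabilization; the enumeration is
#' capped (default 12 clones, 2048 vectors per locus).
#'
#' @inheritParams complete_loglik
#' @param enum_cap maximum number of clones for which enumeration is
#'   attempted.
#' @return a scalar log-likelihood (binomial coefficients included).
#' @export
observed_loglik <- function(panel, P, theta, include_coef = TRUE,
                            enum_cap = 12L) {
  stopifnot(inherits(panel, "counts_panel"))
  S <- ncol(panel$N)
  P <- check_P(P, S)
  C <- nrow(P)
  check_theta(theta, C)
  Z <- enumerate_genotypes(C, cap = enum_cap)
  lw <- locus_pattern_logliks(panel, Z, P, theta)  # M x K
  ll <- sum(apply(lw, 1L, log_sum_exp))
  if (!include_coef) ll <- ll - sum(lchoose(panel$N, panel$X))
  ll
}

# M x K matrix: log prior(z_k) + sum_j log Binom(X_ij; N_ij, B_kj).
# dbinom handles B = 0 exactly (mass 1 at X = 0, 0 elsewhere), so no
# probability clipping is needed here.
locus_pattern_logliks <- function(panel, Z, P, theta) {
  K <- nrow(Z)
  M <- nrow(panel$N)
  C <- ncol(Z)
  Bk <- (Z %*% P) / 2                      # K x S
  lprior <- if (C >= 2L)
    rowSums(matrix(stats::dbinom(Z[, -1L, drop = FALSE], 1,
                                 rep(theta[-1L], each = K), log = TRUE),
                   K, C - 1L))
  else rep(0, K)
  lw <- matrix(0, M, K)
  for (k in seq_len(K)) {
    lw[, k] <- lprior[k] +
      rowSums(stats::dbinom(panel$X, panel$N,
                            rep(Bk[k, ], each = M), log = TRUE))
  }
  lw
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# x * log(y) with the 0 * log(0) = 0 convention.
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

zap_tiny <- function(x, tol = 1e-12) {
  x[x < tol] <- 0
  x
}
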