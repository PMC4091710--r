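#' Simulate multi-section deep-sequencing counts from the clonal model
#'
#' Generates a synthetic study with known ground truth, mirroring the
#' model's generative process:
#' \enumerate{
#'   \item Coverage: each subsection's column of `N` is drawn from
#'     `Multinomial(M * coverage, uniform over the M loci)`, so the column
#'     total is exactly `M * coverage` reads.
#'   \item Genotypes: tumor-clone entries of `W` are independent
#'     `Bernoulli(genotype_p)`; the normal clone's column is all zero. By
#'     default each locus is conditioned on carrying the mutation in at
#'     least one tumor clone (rows are redrawn otherwise), emulating the
#'     variant-calling step that admits a locus to the panel only when it is
#'     somatically mutated somewhere in the tumor; set
#'     `only_mutated = FALSE` for unconditioned draws.
#'   \item Frequencies: each column of `P` is uniform draws normalized to
#'     sum to 1; the normal subsection's column is then set to the pure
#'     normal vector `(1, 0, ..., 0)` (the fitted model still estimates it
#'     freely).
#'   \item Counts: `X[i,j] ~ Binomial(N[i,j], B[i,j])` with
#'     `B = (W P) / 2`.
#' }
#'
#' @param M number of loci.
#' @param S number of subsections (first is the matched normal).
#' @param C number of clones including the normal clone.
#' @param coverage mean reads per locus (default 1000).
#' @param genotype_p Bernoulli success probability for tumor-clone genotype
#'   entries (default 0.3).
#' @param noise optional per-read flip probability applied to the drawn
#'   counts via [inject_noise()] (default 0, no noise).
#' @param only_mutated condition every locus on being mutated in at least
#'   one tumor clone (default `TRUE`; ignored when `genotype_p` is 0 or
#'   there is no tumor clone).
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return a list of class `clone_sim` with elements `panel`
#'   (a [counts_panel()]), `W` (true M x C genotype matrix), `P` (true C x S
#'   frequency matrix), `B` (true M x S variant-read probabilities), and
#'   `params`.
#' @examples
#' sim <- simulate_panel(M = 30, S = 4, C = 3, coverage = 500, seed = 1)
#' sim$panel
#' @export
simulate_panel <- function(M, S, C, coverage = 1000, genotype_p = 0.3,
                           noise = 0, only_mutated = TRUE, seed = 1L) {
  stopifnot(M >= 1, S >= 2, C >= 1, coverage > 0,
            genotype_p >= 0, genotype_p <= 1)
  set.seed(seed)
  loci <- paste0("locus", seq_len(M))
  subsections <- c("normal", paste0("tumor", seq_len(S - 1L)))
  clones <- paste0("C", seq_len(C) - 1L)

  N <- vapply(seq_len(S), function(j)
    as.integer(stats::rmultinom(1L, size = round(M * coverage),
                                prob = rep(1 / M, M))),
    integer(M))
  dim(N) <- c(M, S)

  W <- matrix(0L, M, C, dimnames = list(loci, clones))
  if (C >= 2L) {
    W[, -1L] <- stats::rbinom(M * (C - 1L), 1L, genotype_p)
    if (only_mutated && genotype_p > 0) {
      # loci enter a real panel only if somatically mutated somewhere in the
      # tumor; redraw all-zero rows (truncated Bernoulli via rejection)
      empty <- which(rowSums(W) == 0L)
      while (length(empty) > 0L) {
        W[empty, -1L] <- stats::rbinom(length(empty) * (C - 1L), 1L,
                                       genotype_p)
        empty <- empty[rowSums(W[empty, , drop = FALSE]) == 0L]
      }
    }
  }

  P <- matrix(stats::runif(C * S), C, S,
              dimnames = list(clones, subsections))
  P <- sweep(P, 2L, colSums(P), `/`)
  P[, 1L] <- c(1, rep(0, C - 1L))

  B <- variant_prob_matrix(W, P)
  X <- matrix(stats::rbinom(M * S, N, B), M, S)
  dimnames(N) <- dimnames(X) <- list(loci, subsections)
  panel <- counts_panel(X, N, normal = 1L)
  if (noise > 0)
    panel <- inject_noise(panel, noise, seed = seed + 1L)

  structure(list(panel = panel, W = W, P = P, B = B,
                 params = list(M = M, S = S, C = C, coverage = coverage,
                               genotype_p = genotype_p, noise = noise,
                               seed = seed)),
            class = "clone_sim")
}

#' @export
print.clone_sim <- function(x, ...) {
  p <- x$params
  cat("Simulated multi-section study: M =", p$M, "loci, S =", p$S,
      "subsections, C =", p$C, "clones\n")
  cat("  mean coverage", p$coverage, "| genotype Bernoulli p =",
      p$genotype_p, "| read-flip noise =", p$noise, "| seed =", p$seed, "\n")
  invisible(x)
}

#' Inject per-read flip noise into a counts panel
#'
#' Models sequencing error as independent Bernoulli flips: each variant read
#' is mis-read as normal with probability `error_rate` and each normal read
#' is mis-read as variant with the same probability, so
#' `X' = X - Binomial(X, e) + Binomial(N - X, e)` with `N` unchanged.
#'
#' @param panel a [counts_panel()].
#' @param error_rate flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return a new [counts_panel()] with perturbed variant counts.
#' @export
inject_noise <- function(panel, error_rate, seed = 1L) {
  stopifnot(inherits(panel, "counts_panel"))
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (error_rate == 0) return(panel)
  set.seed(seed)
  X <- panel$X
  N <- panel$N
  lost <- matrix(stats::rbinom(length(X), X, error_rate), nrow(X), ncol(X))
  gained <- matrix(stats::rbinom(length(X), N - X, error_rate),
                   nrow(X), ncol(X))
  X2 <- X - lost + gained
  dimnames(X2) <- dimnames(X)
  counts_panel(X2, N, normal = 1L)
}
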