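#' @export
print.clone_fit <- function(x, ...) {
  cat("Clonal decomposition fit (", x$C, " clones, ",
      ncol(x$panel$N), " subsections, ", nrow(x$panel$N), " loci)\n", sep = "")
  cat("  converged: ", x$converged, " after ", x$n_iter, " iterations\n",
      sep = "")
  cat("  Q* = ", format(x$Q_star, digits = 8),
      ";  observed log-likelihood = ",
      format(x$observed_loglik, digits = 8), "\n", sep = "")
  if (!is.null(x$restart_logliks))
    cat("  restarts: ", length(x$restart_logliks), " (best seed ",
        x$seed, ")\n", sep = "")
  cat("  clone frequencies (columns sum to 1):\n")
  print(round(x$P, 3))
  invisible(x)
}

#' @export
summary.clone_fit <- function(object, ...) {
  mut_per_clone <- colSums(object$W)
  out <- list(
    C = object$C,
    M = nrow(object$panel$N),
    S = ncol(object$panel$N),
    converged = object$converged,
    n_iter = object$n_iter,
    Q_star = object$Q_star,
    observed_loglik = object$observed_loglik,
    bic = BIC(object),
    P = object$P,
    theta = object$theta,
    mutations_per_clone = mut_per_clone,
    marginal_sharpness = max(abs(object$marginals -
                                   round(object$marginals))),
    restart_logliks = object$restart_logliks)
  class(out) <- "summary.clone_fit"
  out
}

#' @export
print.summary.clone_fit <- function(x, ...) {
  cat("Clonal decomposition of", x$S, "subsections at", x$M, "loci into",
      x$C, "clones\n\n")
  cat("Converged:", x$converged, "in", x$n_iter, "EM iterations\n")
  cat("Q* =", format(x$Q_star, digits = 8),
      "  observed log-likelihood =", format(x$observed_loglik, digits = 8),
      "  BIC =", format(x$bic, digits = 8), "\n")
  cat("Max distance of posterior mutation probabilities from {0,1}:",
      format(x$marginal_sharpness, digits = 3), "\n\n")
  cat("Mutations per clone:\n")
  print(x$mutations_per_clone)
  cat("\nMutation prior theta:\n")
  print(round(x$theta, 4))
  cat("\nClone frequencies:\n")
  print(round(x$P, 4))
  if (!is.null(x$restart_logliks)) {
    cat("\nFinal Q* across", length(x$restart_logliks), "restarts:\n")
    print(summary(x$restart_logliks))
  }
  invisible(x)
}

#' Extract fitted parameters from a clonal decomposition
#'
#' @param object a `clone_fit`.
#' @param what `"frequencies"` (clone frequency matrix P, the default),
#'   `"genotypes"` (called binary genotype matrix W), or `"theta"` (mutation
#'   prior).
#' @param ... unused.
#' @return the requested matrix or vector.
#' @export
coef.clone_fit <- function(object,
                           what = c("frequencies", "genotypes", "theta"),
                           ...) {
  what <- match.arg(what)
  switch(what,
         frequencies = object$P,
         genotypes = object$W,
         theta = object$theta)
}

#' @export
fitted.clone_fit <- function(object, ...) {
  B <- variant_prob_matrix(object$W, object$P)
  dimnames(B) <- dimnames(object$panel$N)
  B
}

#' Residual variant-allele fractions
#'
#' @param object a `clone_fit`.
#' @param type `"raw"` gives `X/N - B`; `"pearson"` standardizes by the
#'   binomial standard deviation `sqrt(B (1 - B) / N)`.
#' @param ... unused.
#' @return an M x S matrix.
#' @export
residuals.clone_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  B <- fitted(object)
  N <- object$panel$N
  vaf <- object$panel$X / pmax(N, 1L)
  r <- vaf - B
  if (type == "pearson") {
    sd <- sqrt(B * (1 - B) / pmax(N, 1L))
    r <- ifelse(sd > 0, r / sd, 0)
  }
  r
}

#' Expected variant read counts under the fitted model
#'
#' @param object a `clone_fit`.
#' @param newdata optional M x S matrix of total read counts; defaults to
#'   the fitted panel's coverage.
#' @param ... unused.
#' @return an M x S matrix of expected variant-supporting read counts
#'   `N * B`.
#' @export
predict.clone_fit <- function(object, newdata = NULL, ...) {
  N <- if (is.null(newdata)) object$panel$N else as.matrix(newdata)
  B <- variant_prob_matrix(object$W, object$P)
  if (!all(dim(N) == dim(B)))
    stop("newdata must be an M x S matrix of total read counts")
  N * B
}

#' @export
logLik.clone_fit <- function(object, ...) {
  val <- object$observed_loglik
  attr(val, "df") <- (object$C - 1L) *
    (nrow(object$panel$N) + ncol(object$panel$N))
  attr(val, "nobs") <- sum(as.numeric(object$panel$N))
  class(val) <- "logLik"
  val
}

#' @export
plot.clone_fit <- function(x, which = c("trace", "frequencies"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                   xlab = "EM iteration", ylab = "Q*",
                   main = "Expected complete-data log-likelihood", ...)
  } else {
    graphics::barplot(x$P, legend.text = rownames(x$P),
                      xlab = "subsection", ylab = "clone fraction",
                      main = "Inferred clone frequencies", ...)
  }
  invisible(x)
}

#' Simulate variant counts from a fitted clonal decomposition
#'
#' Parametric bootstrap: draws `X[i,j] ~ Binomial(N[i,j], B[i,j])` with the
#' fitted variant-read probabilities, keeping the observed coverage.
#'
#' @param object a `clone_fit`.
#' @param nsim number of replicate panels.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` [counts_panel()] objects.
#' @export
simulate.clone_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  B <- fitted(object)
  N <- object$panel$N
  lapply(seq_len(nsim), function(r) {
    X <- matrix(stats::rbinom(length(N), N, B), nrow(N), ncol(N),
                dimnames = dimnames(N))
    counts_panel(X, N, normal = 1L)
  })
}

#' Write a fitted clonal decomposition to a directory
#'
#' Writes the clone frequency matrix, mutation prior, posterior marginals
#' and called genotype matrix as labeled TSV files, plus a JSON manifest
#' recording the seed, convergence settings and log-likelihoods so a run can
#' be reproduced exactly.
#'
#' @param fit a `clone_fit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_clone_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "clone_fit"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  paths <- file.path(dir, c("frequencies.tsv", "theta.tsv", "marginals.tsv",
                            "genotypes.tsv", "manifest.json"))
  write_labeled_tsv(fit$P, paths[1L], row_label = "clone")
  utils::write.table(
    data.frame(clone = names(fit$theta), theta = unname(fit$theta)),
    paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write_labeled_tsv(fit$marginals, paths[3L])
  write_labeled_tsv(fit$W, paths[4L])
  manifest <- list(
    clones = fit$C,
    loci = nrow(fit$panel$N),
    subsections = ncol(fit$panel$N),
    normal_subsection = fit$panel$subsections[1L],
    seed = fit$seed,
    epsilon = fit$control$epsilon,
    max_iter = fit$control$max_iter,
    delta_normal = fit$control$delta_normal,
    n_iter = fit$n_iter,
    converged = fit$converged,
    Q_star = fit$Q_star,
    observed_loglik = fit$observed_loglik,
    loglik_trace = fit$loglik_trace,
    restart_seeds = fit$restart_seeds,
    restart_logliks = fit$restart_logliks)
  jsonlite::write_json(manifest, paths[5L], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
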