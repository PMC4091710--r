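#' BIC of a fitted clonal decomposition
#'
#' Computed as `-2 Q* + K log(n)`, where `Q*` is the expected complete-data
#' log-likelihood maximized in the last M step, `K = (C - 1)(M + S)` is the
#' number of free parameters (one genotype bit per locus and one frequency
#' per subsection for each tumor clone; the normal clone and the simplex
#' redundancy carry no free parameters), and `n` is the total read count.
#' The parameter counting is isolated in [free_param_count()] so that
#' alternative conventions can be swapped in.
#'
#' @param object a `clone_fit`.
#' @param ... unused.
#' @return a scalar BIC value (smaller indicates a better fit).
#' @export
BIC.clone_fit <- function(object, ...) {
  n <- sum(as.numeric(object$panel$N))
  -2 * object$Q_star + free_param_count(object$C, nrow(object$panel$N),
                                        ncol(object$panel$N)) * log(n)
}

#' Free-parameter count of the clonal model
#'
#' @param C number of clones (including the normal clone).
#' @param M number of loci.
#' @param S number of subsections.
#' @return `(C - 1) * (M + S)`.
#' @export
free_param_count <- function(C, M, S) {
  (C - 1) * (M + S)
}

#' Select the number of clones by BIC
#'
#' Fits the model for each candidate clone number with [clonal_fit()] and
#' tabulates the BIC together with the percentage BIC improvement between
#' consecutive clone numbers. The table is reported rather than thresholded:
#' the smallest BIC indicates the best fit, but a small relative improvement
#' suggests the added clones may be over-fitting, so the elbow column is
#' left to the analyst.
#'
#' @param panel a [counts_panel()].
#' @param C_range integer vector of candidate clone numbers (default
#'   `2:min(S, 8)`).
#' @param restarts restarts per candidate (default `control$restarts`).
#' @param seed master seed; candidate `C` reuses `seed` so runs are
#'   independent of the range requested.
#' @param control an [em_control()] list.
#' @return a `data.frame` of class `bic_table` with columns `C`, `Q_star`,
#'   `K`, `n`, `BIC` and `pct_improvement` (percent BIC decrease relative to
#'   the previous row; `NA` for the first).
#' @examples
#' sim <- simulate_panel(M = 20, S = 4, C = 2, coverage = 300, seed = 11)
#' tab <- select_clones(sim$panel, C_range = 2:3, restarts = 2, seed = 11)
#' tab
#' @export
select_clones <- function(panel, C_range = NULL, restarts = NULL, seed = 1L,
                          control = em_control()) {
  stopifnot(inherits(panel, "counts_panel"))
  S <- ncol(panel$N)
  if (is.null(C_range)) C_range <- 2:min(S, 8L)
  C_range <- sort(unique(as.integer(C_range)))
  fits <- lapply(C_range, function(C)
    clonal_fit(panel, C, restarts = restarts, seed = seed, control = control))
  n <- sum(as.numeric(panel$N))
  tab <- data.frame(
    C = C_range,
    Q_star = vapply(fits, function(f) f$Q_star, numeric(1)),
    K = free_param_count(C_range, nrow(panel$N), S),
    n = n,
    BIC = vapply(fits, BIC, numeric(1)))
  tab$pct_improvement <- c(NA_real_,
                           if (nrow(tab) > 1L)
                             100 * -diff(tab$BIC) / abs(tab$BIC[-nrow(tab)]))
  attr(tab, "fits") <- fits
  class(tab) <- c("bic_table", "data.frame")
  tab
}

#' @export
print.bic_table <- function(x, ...) {
  cat("BIC across candidate clone numbers (best: C =",
      x$C[which.min(x$BIC)], ")\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
plot.bic_table <- function(x, ...) {
  graphics::plot(x$C, x$BIC, type = "b", xlab = "number of clones C",
                 ylab = "BIC", main = "Clone-number selection", ...)
  graphics::points(x$C[which.min(x$BIC)], min(x$BIC), pch = 19)
  invisible(x)
}
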