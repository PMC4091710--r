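#' Permutation-matched genotype and clone-frequency errors
#'
#' Because clone labels are arbitrary, the estimated tumor-clone columns are
#' compared against every permutation of the true tumor-clone columns and
#' the permutation minimizing the genotype error is selected; the same
#' permutation is then used for the clone frequency error. The normal clone
#' (column 1) is fixed and excluded from the permutation.
#'
#' The genotype error is the mean absolute difference over all tumor-clone
#' genotype entries; the frequency error is the mean absolute difference
#' over all entries of the frequency matrix (normal row included).
#'
#' @param W_true,W_est M x C binary genotype matrices (column 1 all zero).
#' @param P_true,P_est C x S clone frequency matrices; pass `NULL` to skip
#'   the frequency error (e.g. when comparing genotype calls across fits on
#'   different subsection sets).
#' @return a list of class `clone_error` with elements `genotype_error`,
#'   `frequency_error`, and `permutation` (an integer vector `p` such that
#'   estimated tumor clone `k` is matched to true tumor clone `p[k]`).
#' @examples
#' W <- cbind(0, matrix(c(1, 0, 1, 0, 1, 1), 3, 2))
#' match_and_score(W, NULL, W[, c(1, 3, 2)], NULL)$genotype_error  # 0
#' @export
match_and_score <- function(W_true, P_true, W_est, P_est) {
  W_true <- check_W(W_true)
  W_est <- check_W(W_est, nrow(W_true))
  C <- ncol(W_true)
  if (ncol(W_est) != C)
    stop("genotype matrices disagree on the number of clones")
  if (C < 2L) stop("at least one tumor clone is required")
  have_P <- !is.null(P_true) && !is.null(P_est)
  if (have_P) {
    P_true <- check_P(P_true)
    P_est <- check_P(P_est)
    if (nrow(P_true) != C || nrow(P_est) != C ||
        !all(dim(P_true) == dim(P_est)))
      stop("frequency matrices must be C x S with C matching the genotypes")
  }

  k <- C - 1L                       # tumor clones
  Wt <- W_true[, -1L, drop = FALSE]
  We <- W_est[, -1L, drop = FALSE]
  # cost[a, b] = number of mismatched genotype bits if estimated tumor clone
  # a is matched to true tumor clone b; the total error is additive, so the
  # best permutation is an assignment problem.
  cost <- matrix(0, k, k)
  for (a in seq_len(k))
    for (b in seq_len(k))
      cost[a, b] <- sum(abs(We[, a] - Wt[, b]))
  perm <- solve_assignment(cost)

  eps_w <- sum(cost[cbind(seq_len(k), perm)]) / (nrow(W_true) * k)
  eps_p <- NA_real_
  if (have_P) {
    P_true_perm <- P_true[c(1L, perm + 1L), , drop = FALSE]
    eps_p <- mean(abs(P_est - P_true_perm))
  }
  structure(list(genotype_error = eps_w, frequency_error = eps_p,
                 permutation = perm),
            class = "clone_error")
}

#' @export
print.clone_error <- function(x, ...) {
  cat("Permutation-matched errors\n")
  cat("  genotype error:  ", format(x$genotype_error, digits = 6), "\n")
  cat("  frequency error: ", format(x$frequency_error, digits = 6), "\n")
  cat("  tumor-clone matching (estimated -> true): ",
      paste(seq_along(x$permutation), "->", x$permutation, collapse = ", "),
      "\n")
  invisible(x)
}

# Minimal-cost assignment. Exhaustive over permutations up to n = 9; above
# that, an O(n^3) Hungarian algorithm on the same additive cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 1L) return(1L)
  if (n <= 9L) {
    perms <- permutations(n)
    totals <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(n), p)]))
    return(unname(perms[which.min(totals), ]))
  }
  hungarian(cost)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
  dimnames(out) <- NULL
  out
}

# Hungarian algorithm, shortest-augmenting-path formulation with potentials.
# Columns are indexed 1..(n+1) where column 1 is the virtual start column;
# p[j] is the row matched to column j (0 = unmatched). Returns p with
# p[row] = assigned column minimizing sum cost[row, p[row]].
hungarian <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials (incl. virtual col 1)
  p <- integer(n + 1L)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}
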