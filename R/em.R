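#' Control parameters for the EM fit
#'
#' @param epsilon relative convergence threshold on the expected
#'   complete-data log-likelihood Q*: iteration stops when
#'   `|Q*_t - Q*_{t-1}| < epsilon * |Q*_{t-1}|`.
#' @param max_iter maximum number of EM iterations.
#' @param restarts default number of random restarts used by [clonal_fit()].
#' @param delta_normal lower bound on the normal-clone fraction in every
#'   subsection (the non-zero normal-contamination assumption).
#' @param enum_cap maximum number of clones for genotype enumeration.
#' @param optim_maxit iteration cap for the L-BFGS-B solver in each M step.
#' @param pen_weight weight of the quadratic penalty that keeps the tumor
#'   clone fractions of each subsection summing to at most
#'   `1 - delta_normal`; `NULL` scales it to the total read count.
#' @return a list of class `em_control`.
#' @export
em_control <- function(epsilon = 1e-6, max_iter = 1000L, restarts = 10L,
                       delta_normal = 1e-3, enum_cap = 12L,
                       optim_maxit = 100L, pen_weight = NULL) {
  stopifnot(epsilon > 0, max_iter >= 1L, restarts >= 1L,
            delta_normal > 0, delta_normal < 0.5)
  structure(list(epsilon = epsilon, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts),
                 delta_normal = delta_normal,
                 enum_cap = as.integer(enum_cap),
                 optim_maxit = as.integer(optim_maxit),
                 pen_weight = pen_weight),
            class = "em_control")
}

#' E step: posterior over genotype vectors at each locus
#'
#' For every locus, applies Bayes' theorem over all 2^(C-1) admissible
#' genotype vectors: the unnormalized posterior is the Bernoulli prior mass
#' of the vector times the product over subsections of binomial count
#' probabilities, evaluated in log-space and normalized per locus. Per-clone
#' marginal mutation probabilities are obtained by summing the posterior over
#' all vectors that carry the mutation.
#'
#' @param panel a [counts_panel()].
#' @param P C x S clone frequency matrix.
#' @param theta length-C mutation prior (`theta[1] == 0`).
#' @param enum_cap clone enumeration cap.
#' @return a list of class `posterior_table` with elements `q` (M x K
#'   posterior matrix), `patterns` (K x C genotype vectors), `marginals`
#'   (M x C matrix of `P(Z[i,c] = 1 | data)`), and `locus_loglik` (length-M
#'   observed log-likelihood contributions).
#' @export
e_step <- function(panel, P, theta, enum_cap = 12L) {
  stopifnot(inherits(panel, "counts_panel"))
  P <- check_P(P, ncol(panel$N))
  C <- nrow(P)
  check_theta(theta, C)
  Z <- enumerate_genotypes(C, cap = enum_cap)
  lw <- locus_pattern_logliks(panel, Z, P, theta)   # M x K
  ll <- apply(lw, 1L, log_sum_exp)
  if (any(!is.finite(ll))) {
    bad <- panel$loci[!is.finite(ll)]
    stop("no genotype vector has positive likelihood at ",
         length(bad), " locus/loci: ", paste(bad, collapse = ", "),
         " (variant reads observed where every admissible variant-read",
         " probability is zero)")
  }
  q <- exp(lw - ll)
  q <- q / rowSums(q)          # guard against residual rounding
  marginals <- q %*% Z
  dimnames(marginals) <- list(panel$loci, paste0("C", seq_len(C) - 1L))
  structure(list(q = q, patterns = Z, marginals = marginals,
                 locus_loglik = ll),
            class = "posterior_table")
}

#' M step for the mutation prior
#'
#' The Bernoulli parameter of each tumor clone is updated to the mean of its
#' posterior marginal mutation probabilities across loci; the normal clone's
#' parameter is fixed at zero.
#'
#' @param post a `posterior_table` from [e_step()].
#' @return a length-C numeric vector.
#' @export
m_step_theta <- function(post) {
  stopifnot(inherits(post, "posterior_table"))
  theta <- colMeans(post$marginals)
  theta[1L] <- 0
  unname(theta)
}

#' M step for the clone frequency matrix
#'
#' Maximizes the expected binomial log-likelihood over the clone frequency
#' matrix subject to each column being a probability simplex with normal
#' fraction at least `delta_normal`. Only the tumor-clone entries enter the
#' likelihood; they are optimized by L-BFGS-B with an analytic chain-rule
#' gradient inside the box `[0, 1 - delta_normal]`, a smooth quadratic
#' penalty on column sums exceeding `1 - delta_normal`, and a final
#' projection. If the solver fails to improve the objective, the current
#' matrix is returned unchanged (with attribute `improved = FALSE`) so the
#' EM ascent property is preserved.
#'
#' @param panel a [counts_panel()].
#' @param post a `posterior_table` from [e_step()].
#' @param P_current the current C x S clone frequency matrix (warm start).
#' @param control an [em_control()] list.
#' @return an updated C x S clone frequency matrix.
#' @export
m_step_P <- function(panel, post, P_current, control = em_control()) {
  stopifnot(inherits(panel, "counts_panel"), inherits(post, "posterior_table"))
  P_current <- check_P(P_current, ncol(panel$N))
  C <- nrow(P_current)
  S <- ncol(P_current)
  delta <- control$delta_normal
  if (C == 1L) return(P_current)

  parts <- q1_parts(panel, post)
  smax <- 1 - delta
  w <- control$pen_weight
  if (is.null(w)) w <- 100 * sum(as.numeric(panel$N))

  q1 <- function(u) {          # penalised objective, u is (C-1) x S
    over <- pmax(colSums(u) - smax, 0)
    q1_value(u, parts) - w * sum(over^2)
  }
  q1_grad <- function(u) {
    g <- q1_gradient(u, parts)
    over <- pmax(colSums(u) - smax, 0)
    sweep(g, 2L, 2 * w * over, `-`)
  }
  q1_raw <- function(u) q1_value(u, parts)
  project <- function(u) {
    u <- pmin(pmax(u, 0), smax)   # guard solver round-off past the box
    s <- colSums(u)
    scale <- ifelse(s > smax, smax / s, 1)
    sweep(u, 2L, scale, `*`)
  }

  u0 <- project(P_current[-1L, , drop = FALSE])
  opt <- tryCatch(
    stats::optim(as.vector(u0),
                 fn = function(v) -q1(matrix(v, C - 1L, S)),
                 gr = function(v) -as.vector(q1_grad(matrix(v, C - 1L, S))),
                 method = "L-BFGS-B", lower = 0, upper = smax,
                 control = list(maxit = control$optim_maxit)),
    error = function(e) NULL)

  improved <- FALSE
  u_new <- u0
  if (!is.null(opt)) {
    cand <- project(matrix(opt$par, C - 1L, S))
    if (q1_raw(cand) >= q1_raw(u0) - 1e-8 * abs(q1_raw(u0))) {
      u_new <- cand
      improved <- TRUE
    }
  }
  if (!improved)
    warning("M-step optimizer did not improve the objective; ",
            "keeping the current clone frequencies")
  P_new <- rbind(1 - colSums(u_new), u_new)
  dimnames(P_new) <- dimnames(P_current)
  attr(P_new, "improved") <- improved
  P_new
}

# Sufficient statistics of the expected binomial log-likelihood Q1 as a
# function of the tumor-clone frequency block u = P[2..C, ]: Zt holds the
# tumor bits of the non-null genotype patterns, A1/D1 the posterior-expected
# variant/reference counts per pattern and subsection. Row 1 of the pattern
# table (the all-zero genotype) is dropped: its variant-read probability is
# 0 for any P, so its contribution is constant (and its expected variant
# count is exactly zero).
q1_parts <- function(panel, post) {
  Z <- post$patterns
  A <- crossprod(post$q, panel$X)
  D <- crossprod(post$q, panel$N - panel$X)
  list(Zt = Z[-1L, -1L, drop = FALSE],
       A1 = A[-1L, , drop = FALSE],
       D1 = D[-1L, , drop = FALSE])
}

# Expected binomial log-likelihood (no penalty) at tumor-frequency block u,
# with probabilities clipped to [eps, 1 - eps] for numerical safety.
q1_value <- function(u, parts, eps = 1e-12) {
  B <- (parts$Zt %*% u) / 2
  Bc <- pmin(pmax(B, eps), 1 - eps)
  sum(parts$A1 * log(Bc) + parts$D1 * log(1 - Bc))
}

# Chain-rule gradient of q1_value with respect to u. The slope is evaluated
# at the clipped probability so that, at the boundary, it still points
# steeply back into the interior and the box edge never looks like a
# spurious stationary point to the solver.
q1_gradient <- function(u, parts, eps = 1e-12) {
  B <- (parts$Zt %*% u) / 2
  Bc <- pmin(pmax(B, eps), 1 - eps)
  G <- parts$A1 / Bc - parts$D1 / (1 - Bc)
  crossprod(parts$Zt, G) / 2
}

# Expected complete-data log-likelihood Q* at (q, P, theta), the EM surrogate
# objective: expected binomial terms over genotype vectors plus expected
# Bernoulli prior terms from the marginals, plus the (constant) binomial
# coefficients when include_coef.
q_star <- function(panel, post, P, theta, include_coef = TRUE) {
  Z <- post$patterns
  C <- ncol(Z)
  A <- crossprod(post$q, panel$X)
  D <- crossprod(post$q, panel$N - panel$X)
  Bk <- (Z %*% P) / 2
  # Posterior mass below 1e-12 on a genotype pattern is treated as zero so
  # that a pattern made impossible by the current M step (e.g. a redundant
  # clone whose fraction was driven to the boundary) does not send the
  # surrogate to -Inf on account of numerically negligible mass.
  Q1 <- sum(xlogy(zap_tiny(A), Bk) + xlogy(zap_tiny(D), 1 - Bk))
  Q2 <- 0
  if (C >= 2L) {
    marg <- post$marginals[, -1L, drop = FALSE]
    th <- rep(theta[-1L], each = nrow(marg))
    Q2 <- sum(xlogy(marg, th) + xlogy(1 - marg, 1 - th))
  }
  if (include_coef) Q1 <- Q1 + sum(lchoose(panel$N, panel$X))
  Q1 + Q2
}

random_init <- function(panel, C, delta) {
  S <- ncol(panel$N)
  P <- matrix(stats::runif(C * S), C, S)
  P <- sweep(P, 2L, colSums(P), `/`)
  P <- enforce_floor(P, delta)
  theta <- c(0, stats::runif(C - 1L))
  list(P = P, theta = theta)
}

enforce_floor <- function(P, delta) {
  low <- P[1L, ] < delta
  if (any(low)) {
    for (j in which(low)) {
      P[-1L, j] <- P[-1L, j] * (1 - delta) / sum(P[-1L, j])
      P[1L, j] <- delta
    }
  }
  P
}

#' Fit the clonal model by EM from one initialization
#'
#' Alternates the posterior E step with closed-form updates of the mutation
#' prior and a box-constrained quasi-Newton update of the clone frequencies,
#' starting from a seeded random initialization (clone frequencies uniform
#' then column-normalized; tumor-clone mutation priors uniform), until the
#' relative change in the expected complete-data log-likelihood Q* falls
#' below `control$epsilon` or `control$max_iter` is reached.
#'
#' @param panel a [counts_panel()].
#' @param C number of clones including the normal clone; must not exceed the
#'   number of subsections unless `allow_extra_clones = TRUE` (with more
#'   clones than samples the decomposition is under-constrained).
#' @param seed integer seed for the random initialization.
#' @param control an [em_control()] list.
#' @param init optional explicit initialization, a list with elements `P`
#'   (C x S) and `theta` (length C); overrides the seeded random draw.
#' @param allow_extra_clones permit `C` greater than the number of
#'   subsections.
#' @return an object of class `clone_fit`; see [clonal_fit()] for the
#'   fields and available methods.
#' @seealso [clonal_fit()] for the multi-restart driver.
#' @export
run_em <- function(panel, C, seed = 1L, control = em_control(), init = NULL,
                   allow_extra_clones = FALSE) {
  stopifnot(inherits(panel, "counts_panel"))
  C <- as.integer(C)
  S <- ncol(panel$N)
  if (C < 2L) stop("C must be at least 2 (normal clone plus one tumor clone)")
  if (C > control$enum_cap)
    stop("C = ", C, " exceeds the enumeration cap (", control$enum_cap, ")")
  if (C > S && !allow_extra_clones)
    stop("C = ", C, " clones with only ", S, " subsections: the number of ",
         "inferred clones may not exceed the number of samples ",
         "(set allow_extra_clones = TRUE to override)")

  if (is.null(init)) {
    set.seed(seed)
    init <- random_init(panel, C, control$delta_normal)
  } else {
    set.seed(seed)  # the M-step itself is deterministic; seed kept for parity
    init$P <- enforce_floor(check_P(init$P, S), control$delta_normal)
    check_theta(init$theta, C)
  }
  P <- init$P
  theta <- init$theta

  trace <- numeric(0)
  obs_trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (iter in seq_len(control$max_iter)) {
    post <- e_step(panel, P, theta, enum_cap = control$enum_cap)
    obs_trace <- c(obs_trace, sum(post$locus_loglik))
    theta <- m_step_theta(post)
    P <- m_step_P(panel, post, P, control)
    qs <- q_star(panel, post, P, theta)
    trace <- c(trace, qs)
    if (iter >= 2L) {
      delta <- abs(qs - trace[iter - 1L])
      if (is.finite(delta) &&
          delta < control$epsilon * abs(trace[iter - 1L])) {
        converged <- TRUE
        break
      }
    }
  }
  # Reporting pass at the final parameters.
  post <- e_step(panel, P, theta, enum_cap = control$enum_cap)
  marginals <- post$marginals
  W <- matrix(as.integer(marginals >= 0.5), nrow(marginals), C,
              dimnames = dimnames(marginals))
  W[, 1L] <- 0L
  attr(P, "improved") <- NULL
  dimnames(P) <- list(paste0("C", seq_len(C) - 1L), panel$subsections)
  theta <- stats::setNames(theta, rownames(P))

  structure(list(
    panel = panel, C = C,
    P = P, theta = theta,
    marginals = marginals, W = W,
    posterior = post,
    loglik_trace = trace,
    observed_trace = c(obs_trace, sum(post$locus_loglik)),
    Q_star = trace[length(trace)],
    observed_loglik = sum(post$locus_loglik),
    converged = converged, n_iter = length(trace),
    seed = seed, control = control,
    restart_logliks = NULL, restart_seeds = NULL),
    class = "clone_fit")
}

#' Fit the clonal decomposition model with multiple random restarts
#'
#' The main model-fitting entry point. Runs [run_em()] to convergence from
#' `restarts` seeded random initializations (restart `r` uses seed
#' `seed + r`) and returns the run with the highest expected complete-data
#' log-likelihood Q*. The final Q* of every restart is retained for
#' restart-sufficiency diagnostics.
#'
#' @inheritParams run_em
#' @param restarts number of random restarts; defaults to
#'   `control$restarts` (10).
#' @param seed master seed; restart `r` uses `seed + r`.
#' @return an object of class `clone_fit` with components
#'   \describe{
#'     \item{P}{C x S clone frequency matrix (rows `C0`, `C1`, ...; `C0` is
#'       the normal clone; columns are subsections, normal first).}
#'     \item{theta}{length-C mutation prior (Bernoulli probability that a
#'       tumor clone carries a mutation at a random locus).}
#'     \item{marginals}{M x C posterior mutation probabilities.}
#'     \item{W}{M x C called genotype matrix (marginals thresholded at 0.5,
#'       ties rounded to 1).}
#'     \item{loglik_trace}{per-iteration Q* values of the winning restart
#'       (the surrogate maximized in each M step, also used for
#'       convergence). Because Q* omits the posterior entropy it can dip by
#'       entropy-sized amounts on ambiguous data; `observed_trace` holds the
#'       marginal log-likelihood at each iteration, which the EM ascent
#'       property guarantees to be non-decreasing.}
#'     \item{Q_star, observed_loglik}{final surrogate and marginal
#'       log-likelihoods (binomial coefficients included).}
#'     \item{restart_logliks}{final Q* of every restart.}
#'   }
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
#'   `logLik`, `BIC`, `plot`, `simulate`.
#' @examples
#' sim <- simulate_panel(M = 20, S = 4, C = 2, coverage = 300, seed = 7)
#' fit <- clonal_fit(sim$panel, C = 2, restarts = 3, seed = 7)
#' fit
#' coef(fit)
#' @export
clonal_fit <- function(panel, C, restarts = NULL, seed = 1L,
                       control = em_control(), allow_extra_clones = FALSE) {
  if (is.null(restarts)) restarts <- control$restarts
  restarts <- as.integer(restarts)
  stopifnot(restarts >= 1L)
  seeds <- seed + seq_len(restarts)
  fits <- lapply(seeds, function(s)
    run_em(panel, C, seed = s, control = control,
           allow_extra_clones = allow_extra_clones))
  lls <- vapply(fits, function(f) f$Q_star, numeric(1))
  best <- fits[[which.max(lls)]]
  best$restart_logliks <- lls
  best$restart_seeds <- seeds
  best
}
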