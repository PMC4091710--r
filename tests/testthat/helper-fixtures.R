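# Shared fixtures and independent oracles used across the suite.

# A tiny hand-built panel: M loci x S subsections with prescribed counts.
tiny_panel <- function(X, N, loci = NULL, subs = NULL) {
  M <- nrow(N)
  S <- ncol(N)
  if (is.null(loci)) loci <- paste0("L", seq_len(M))
  if (is.null(subs)) subs <- c("normal", paste0("T", seq_len(S - 1L)))
  dimnames(X) <- dimnames(N) <- list(loci, subs)
  counts_panel(X, N, normal = 1L)
}

# A random small panel drawn from the generative model.
random_panel <- function(M = 5, S = 3, C = 3, coverage = 50, seed = 1) {
  simulate_panel(M = M, S = S, C = C, coverage = coverage, seed = seed)
}

# Random feasible clone-frequency matrix with normal floor delta.
random_P <- function(C, S, delta = 1e-3) {
  P <- matrix(runif(C * S), C, S)
  P <- sweep(P, 2, colSums(P), `/`)
  low <- P[1, ] < delta
  for (j in which(low)) {
    P[-1, j] <- P[-1, j] * (1 - delta) / sum(P[-1, j])
    P[1, j] <- delta
  }
  P
}

# Linear-space Bayes posterior over all genotype vectors at each locus:
# the independent oracle for the E step (no log-sum-exp tricks).
brute_posterior <- function(panel, P, theta) {
  C <- nrow(P)
  Z <- clonesect:::enumerate_genotypes(C)
  K <- nrow(Z)
  M <- nrow(panel$N)
  q <- matrix(0, M, K)
  for (i in seq_len(M)) {
    for (k in seq_len(K)) {
      pri <- prod(dbinom(Z[k, -1], 1, theta[-1]))
      lik <- 1
      for (j in seq_len(ncol(panel$N))) {
        b <- sum(Z[k, ] * P[, j]) / 2
        lik <- lik * dbinom(panel$X[i, j], panel$N[i, j], b)
      }
      q[i, k] <- pri * lik
    }
    q[i, ] <- q[i, ] / sum(q[i, ])
  }
  q
}

# Genotype matrix read off a random mutation-unique clonal tree: guaranteed
# to admit a perfect phylogeny by construction.
random_tree_genotypes <- function(C = 4, M = 10, seed = 1) {
  set.seed(seed)
  parent <- c(NA, vapply(2:C, function(c) sample.int(c - 1L, 1L), integer(1)))
  W <- matrix(0L, M, C,
              dimnames = list(paste0("m", seq_len(M)),
                              paste0("C", seq_len(C) - 1L)))
  # descendants (inclusive) of each clone in the clone tree
  desc <- lapply(seq_len(C), function(c) {
    out <- c
    repeat {
      grow <- which(parent %in% out & !(seq_len(C) %in% out))
      if (length(grow) == 0L) break
      out <- c(out, grow)
    }
    out
  })
  for (i in seq_len(M)) {
    edge <- sample(2:C, 1L)        # mutation arises on the edge above clone
    W[i, desc[[edge]]] <- 1L
  }
  W
}

# Brute-force perfect-phylogeny test straight from the definition: every
# pair of loci must have nested or disjoint carrier sets.
brute_valid_phylogeny <- function(W) {
  M <- nrow(W)
  if (M < 2) return(TRUE)
  for (a in seq_len(M - 1)) {
    for (b in (a + 1):M) {
      sa <- which(W[a, ] == 1)
      sb <- which(W[b, ] == 1)
      inter <- length(intersect(sa, sb))
      if (inter > 0 && inter < length(sa) && inter < length(sb))
        return(FALSE)
    }
  }
  TRUE
}

# Exact p-value of independence in a 2 x k table by full enumeration over
# all tables with the observed margins (Freeman-Halton), for tiny totals.
brute_fisher_2xk <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  k <- length(cs)
  prob_table <- function(x1) {
    # multivariate hypergeometric mass of first row x1 given margins
    exp(sum(lchoose(cs, x1)) - lchoose(sum(cs), rs[1]))
  }
  cells <- lapply(seq_len(k), function(j) 0:min(rs[1], cs[j]))
  grid <- do.call(expand.grid, cells)
  grid <- grid[rowSums(grid) == rs[1], , drop = FALSE]
  probs <- apply(grid, 1, prob_table)
  p_obs <- prob_table(tab[1, ])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
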