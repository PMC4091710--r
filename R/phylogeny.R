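# Distinct nonzero mutation carrier sets of a genotype matrix, as a binary
# pattern matrix over tumor clones, plus the loci carrying each pattern.
carrier_patterns <- function(W) {
  W <- check_W(W)
  tum <- W[, -1L, drop = FALSE]
  keys <- apply(tum, 1L, paste, collapse = "")
  loci <- rownames(W)
  if (is.null(loci)) loci <- paste0("locus", seq_len(nrow(W)))
  nz <- rowSums(tum) > 0
  ukeys <- unique(keys[nz])
  pat <- do.call(rbind, lapply(ukeys, function(k)
    as.integer(strsplit(k, "")[[1L]])))
  list(patterns = pat,                      # R x (C-1)
       loci = lapply(ukeys, function(k) loci[keys == k & nz]),
       keys = ukeys, all_keys = keys, all_loci = loci)
}

#' Test whether a genotype matrix admits a mutation-unique clonal tree
#'
#' A rooted clonal tree in which every mutation arises on exactly one edge
#' (and is never lost) exists if and only if, for every pair of mutations,
#' the sets of clones carrying them are nested or disjoint. When the test
#' fails, one witness pair of incompatible mutations is returned.
#'
#' @param W M x C binary genotype matrix (column 1 = normal clone, all
#'   zero).
#' @return a list with `valid` (logical) and `witness` (`NULL`, or a
#'   character vector of two locus labels whose carrier sets overlap without
#'   nesting).
#' @examples
#' # two founder mutations shared by both tumor clones, the rest private:
#' W <- cbind(C0 = 0, C1 = c(1, 1, 1, 0), C2 = c(1, 1, 0, 1))
#' rownames(W) <- c("chr4a", "chr9b", "chr5", "chr11")
#' is_valid_phylogeny(W)$valid
#' @export
is_valid_phylogeny <- function(W) {
  cp <- carrier_patterns(W)
  pat <- cp$patterns
  R <- if (is.null(pat)) 0L else nrow(pat)
  if (R >= 2L) {
    for (a in seq_len(R - 1L)) {
      for (b in (a + 1L):R) {
        inter <- sum(pat[a, ] & pat[b, ])
        if (inter > 0L &&
            inter < sum(pat[a, ]) && inter < sum(pat[b, ])) {
          return(list(valid = FALSE,
                      witness = c(cp$loci[[a]][1L], cp$loci[[b]][1L])))
        }
      }
    }
  }
  list(valid = TRUE, witness = NULL)
}

#' Build the clonal phylogeny implied by a genotype matrix
#'
#' Constructs the unique mutation-unique rooted tree over the clones: each
#' distinct mutation carrier set defines one edge (all mutations sharing
#' that carrier set sit on it), carrier sets are nested into a tree by
#' containment (implied trunk nodes are created where sibling clones share
#' mutations), and every clone attaches at the deepest node whose carrier
#' set contains it — the root for the normal clone and for any all-zero
#' tumor clone. Clones with identical genotypes share a node.
#'
#' @param W M x C binary genotype matrix; must pass [is_valid_phylogeny()].
#' @return an object of class `clone_tree`: a list with `parent` (integer
#'   vector over nodes, node 1 is the root with parent `NA`), `mutations`
#'   (list of locus labels per node, attached to the edge above the node),
#'   `clones` (list of clone labels per node), plus the original `loci` and
#'   `clone_labels`. Methods: `print`, [tree_genotypes()],
#'   `as.phylo` (ape).
#' @export
build_tree <- function(W) {
  W <- check_W(W)
  C <- ncol(W)
  clone_labels <- colnames(W)
  if (is.null(clone_labels)) clone_labels <- paste0("C", seq_len(C) - 1L)
  chk <- is_valid_phylogeny(W)
  if (!chk$valid)
    stop("genotype matrix admits no mutation-unique tree; mutations '",
         chk$witness[1L], "' and '", chk$witness[2L],
         "' have overlapping, non-nested carrier sets")
  cp <- carrier_patterns(W)
  pat <- cp$patterns
  R <- if (is.null(pat)) 0L else nrow(pat)

  # Node 1 is the root; carrier-set r becomes node r + 1. The parent of a
  # carrier set is its smallest strict superset (unique under laminarity).
  parent <- rep(NA_integer_, R + 1L)
  if (R > 0L) {
    sizes <- rowSums(pat)
    for (r in seq_len(R)) {
      sup <- which(vapply(seq_len(R), function(s)
        s != r && all(pat[r, ] <= pat[s, ]) && sizes[s] > sizes[r],
        logical(1)))
      parent[r + 1L] <- if (length(sup) == 0L) 1L
                        else sup[which.min(sizes[sup])] + 1L
    }
  }
  mutations <- c(list(character(0)), cp$loci)

  clones <- vector("list", R + 1L)
  clones[[1L]] <- clone_labels[1L]          # normal clone at the root
  if (C >= 2L) {
    for (c in 2L:C) {
      containing <- if (R > 0L) which(pat[, c - 1L] == 1L) else integer(0)
      node <- if (length(containing) == 0L) 1L
              else containing[which.min(rowSums(pat[containing, ,
                                                    drop = FALSE]))] + 1L
      clones[[node]] <- c(clones[[node]], clone_labels[c])
    }
  }
  structure(list(parent = parent, mutations = mutations, clones = clones,
                 clone_labels = clone_labels,
                 loci = cp$all_loci,
                 W = W),
            class = "clone_tree")
}

#' Read clone genotypes off a clonal tree
#'
#' Each clone's genotype is the union of the mutations on the edges along
#' its path to the root; loci absent from every edge are zero everywhere.
#' `tree_genotypes(build_tree(W))` reproduces `W` exactly.
#'
#' @param tree a `clone_tree` from [build_tree()].
#' @return an M x C binary genotype matrix with the original locus order.
#' @export
tree_genotypes <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  loci <- tree$loci
  labels <- tree$clone_labels
  W <- matrix(0L, length(loci), length(labels),
              dimnames = list(loci, labels))
  for (node in seq_along(tree$parent)) {
    for (cl in tree$clones[[node]]) {
      at <- node
      while (!is.na(at)) {
        W[tree$mutations[[at]], cl] <- 1L
        at <- tree$parent[at]
      }
    }
  }
  W
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clonal phylogeny with", length(x$parent), "nodes\n")
  show_node <- function(node, indent) {
    muts <- x$mutations[[node]]
    cls <- x$clones[[node]]
    cat(strrep("  ", indent),
        if (node == 1L) "root" else
          paste0("+ [", paste(muts, collapse = ","), "]"),
        if (length(cls) > 0L) paste0("  {", paste(cls, collapse = ","), "}")
        else "",
        "\n", sep = "")
    for (ch in which(!is.na(x$parent) & x$parent == node))
      show_node(ch, indent + 1L)
  }
  show_node(1L, 0L)
  invisible(x)
}

# Canonical string signature of a clone_tree; equal signatures <=> equal
# trees (same edges, mutation sets, and clone placements).
tree_signature <- function(tree) {
  sig <- function(node) {
    kids <- sort(vapply(which(!is.na(tree$parent) & tree$parent == node),
                        sig, character(1)))
    paste0("(", paste(kids, collapse = ","), ")[",
           paste(sort(tree$mutations[[node]]), collapse = "|"), "]{",
           paste(sort(tree$clones[[node]]), collapse = "|"), "}")
  }
  sig(1L)
}

#' Convert a clonal tree to an ape phylogeny
#'
#' Clones become tips; the mutations of each edge are recorded in the node
#' label of the child node, pipe-separated, so they survive Newick export
#' via [ape::write.tree()].
#'
#' @param x a `clone_tree`.
#' @param ... unused.
#' @return an object of class `phylo`.
#' @importFrom ape as.phylo
#' @export
as.phylo.clone_tree <- function(x, ...) {
  n_nodes <- length(x$parent)
  tips <- x$clone_labels
  n_tip <- length(tips)
  # phylo numbering: tips 1..n_tip, internal nodes n_tip+1 .. n_tip+n_nodes
  node_id <- function(node) n_tip + node
  edges <- matrix(0L, 0L, 2L)
  for (node in 2L:max(2L, n_nodes)) {
    if (node <= n_nodes)
      edges <- rbind(edges, c(node_id(x$parent[node]), node_id(node)))
  }
  for (node in seq_len(n_nodes)) {
    for (cl in x$clones[[node]])
      edges <- rbind(edges, c(node_id(node), match(cl, tips)))
  }
  node_labels <- vapply(seq_len(n_nodes), function(node)
    paste(x$mutations[[node]], collapse = "|"), character(1))
  tr <- structure(list(edge = edges, tip.label = tips,
                       Nnode = n_nodes, node.label = node_labels),
                  class = "phylo", order = "cladewise")
  tr
}

#' Enumerate valid one-bit-flip neighbors of a genotype matrix
#'
#' A "nearby" genotype matrix differs from the input in exactly one bit
#' among its distinct row patterns: flipping a bit changes that clone's
#' entry for *all* loci sharing the pattern. Every pattern-by-tumor-clone
#' flip is enumerated and, by default, only the candidates that admit a
#' mutation-unique tree are returned.
#'
#' @param W M x C binary genotype matrix.
#' @param only_valid return only candidates passing
#'   [is_valid_phylogeny()] (default `TRUE`).
#' @return a list of candidates, each a list with `W` (the flipped matrix),
#'   `pattern` (the original distinct row pattern over tumor clones),
#'   `loci` (loci sharing that pattern), `clone` (flipped clone index),
#'   `flipped_to` (0 or 1), and `valid`.
#' @export
nearby_variants <- function(W, only_valid = TRUE) {
  W <- check_W(W)
  C <- ncol(W)
  if (C < 2L) return(list())
  loci <- rownames(W)
  if (is.null(loci)) {
    loci <- paste0("locus", seq_len(nrow(W)))
    rownames(W) <- loci
  }
  keys <- apply(W[, -1L, drop = FALSE], 1L, paste, collapse = "")
  ukeys <- unique(keys)             # all distinct patterns, zero included
  out <- list()
  for (k in ukeys) {
    rows <- which(keys == k)
    for (clone in 2L:C) {
      W2 <- W
      W2[rows, clone] <- 1L - W2[rows, clone]
      chk <- is_valid_phylogeny(W2)
      if (chk$valid || !only_valid) {
        out[[length(out) + 1L]] <- list(
          W = W2,
          pattern = unname(W[rows[1L], -1L]),
          loci = loci[rows],
          clone = clone,
          flipped_to = W2[rows[1L], clone],
          valid = chk$valid)
      }
    }
  }
  out
}

#' Maximize the model likelihood for a fixed genotype matrix
#'
#' Holds the genotype matrix fixed (a degenerate posterior with all mass on
#' each locus's row) and maximizes the binomial likelihood over the clone
#' frequency matrix by multi-restart box-constrained quasi-Newton
#' optimization; the mutation prior's maximizer given a fixed genotype
#' matrix is the column mean of the tumor-clone entries. Because the
#' convention for reporting a fixed-genotype likelihood varies, all
#' variants are returned: the complete-data log-likelihood with and without
#' binomial coefficients and Bernoulli prior terms, and the observed-data
#' (marginal) log-likelihood at the fitted parameters.
#'
#' @param panel a [counts_panel()].
#' @param W M x C binary genotype matrix to hold fixed.
#' @param restarts number of random frequency initializations (default
#'   200; this one-shot optimization is far easier than a full EM fit).
#' @param seed integer seed.
#' @param control an [em_control()] list.
#' @return a list of class `genotype_score` with elements `W`, `P`,
#'   `theta`, `loglik` (complete-data, coefficients and prior included; used
#'   for ranking), `complete_loglik`, `complete_loglik_nocoef`,
#'   `binom_loglik`, `binom_loglik_nocoef`, `observed_loglik`.
#' @export
score_genotype <- function(panel, W, restarts = 200L, seed = 1L,
                           control = em_control()) {
  stopifnot(inherits(panel, "counts_panel"))
  M <- nrow(panel$N)
  S <- ncol(panel$N)
  W <- check_W(W, M)
  C <- ncol(W)
  # degenerate posterior: each locus puts mass 1 on its own genotype row;
  # the all-zero genotype is kept in row 1 of the pattern table (whether or
  # not any locus uses it) to match the E-step's pattern layout
  keys <- apply(W, 1L, paste, collapse = "")
  zkey <- paste(rep(0L, C), collapse = "")
  ukeys <- c(zkey, setdiff(unique(keys), zkey))
  patterns <- do.call(rbind, lapply(strsplit(ukeys, ""), as.integer))
  q <- matrix(0, M, length(ukeys))
  q[cbind(seq_len(M), match(keys, ukeys))] <- 1
  post <- structure(list(q = q, patterns = patterns, marginals = W,
                         locus_loglik = NULL),
                    class = "posterior_table")
  theta <- c(0, colMeans(W[, -1L, drop = FALSE]))

  best_P <- NULL
  best_val <- -Inf
  set.seed(seed)
  for (r in seq_len(restarts)) {
    P0 <- matrix(stats::runif(C * S), C, S)
    P0 <- sweep(P0, 2L, colSums(P0), `/`)
    P0 <- enforce_floor(P0, control$delta_normal)
    P1 <- suppressWarnings(m_step_P(panel, post, P0, control))
    val <- sum(stats::dbinom(panel$X, panel$N,
                             variant_prob_matrix(W, P1), log = TRUE))
    # val may be -Inf for a genotype matrix that cannot explain the counts
    # (e.g. variant reads at a locus no clone carries); keep the first such
    # fit so the impossibility is reported as a -Inf score, not an error
    if (is.null(best_P) || val > best_val) {
      best_val <- val
      best_P <- P1
    }
  }
  attr(best_P, "improved") <- NULL
  dimnames(best_P) <- list(colnames(W), panel$subsections)
  cll <- complete_loglik(panel, W, best_P, theta)
  cll_nc <- complete_loglik(panel, W, best_P, theta, include_coef = FALSE)
  coefsum <- sum(lchoose(panel$N, panel$X))
  structure(list(W = W, P = best_P,
                 theta = stats::setNames(theta, colnames(W)),
                 loglik = cll,
                 complete_loglik = cll,
                 complete_loglik_nocoef = cll_nc,
                 binom_loglik = best_val + coefsum,
                 binom_loglik_nocoef = best_val,
                 observed_loglik = observed_loglik(panel, best_P, theta,
                                                   enum_cap = control$enum_cap)),
            class = "genotype_score")
}

#' @export
print.genotype_score <- function(x, ...) {
  cat("Fixed-genotype likelihood fit\n")
  cat("  complete log-likelihood:          ",
      format(x$complete_loglik, digits = 8), "\n")
  cat("  ... without binomial coefficients:",
      format(x$complete_loglik_nocoef, digits = 8), "\n")
  cat("  binomial part only:               ",
      format(x$binom_loglik, digits = 8), "\n")
  cat("  observed log-likelihood:          ",
      format(x$observed_loglik, digits = 8), "\n")
  invisible(x)
}

#' Repair a genotype matrix into a valid clonal tree
#'
#' If the genotype matrix already admits a mutation-unique tree it is
#' returned as is. Otherwise all valid one-bit "nearby" candidates
#' ([nearby_variants()]) are rescored by [score_genotype()] and the
#' highest-likelihood candidate is selected.
#'
#' @inheritParams score_genotype
#' @param restarts restarts per candidate rescoring.
#' @return a list with `W` (the selected genotype matrix), `repaired`
#'   (logical), `tree` (its `clone_tree`), and when repaired, `scores`
#'   (a data.frame of candidate log-likelihoods, best last) and
#'   `candidates`.
#' @export
repair_genotype <- function(panel, W, restarts = 200L, seed = 1L,
                            control = em_control()) {
  W <- check_W(W)
  if (is_valid_phylogeny(W)$valid)
    return(list(W = W, repaired = FALSE, tree = build_tree(W)))
  cands <- nearby_variants(W, only_valid = TRUE)
  if (length(cands) == 0L)
    stop("no valid one-bit neighbor exists for this genotype matrix")
  scores <- lapply(seq_along(cands), function(i)
    score_genotype(panel, cands[[i]]$W, restarts = restarts,
                   seed = seed + i, control = control))
  lls <- vapply(scores, function(s) s$loglik, numeric(1))
  ord <- order(lls)
  tab <- data.frame(
    candidate = ord,
    clone = vapply(cands, function(x) x$clone, integer(1))[ord],
    n_loci_flipped = vapply(cands, function(x) length(x$loci),
                            integer(1))[ord],
    loglik = lls[ord])
  best <- which.max(lls)
  list(W = cands[[best]]$W, repaired = TRUE,
       tree = build_tree(cands[[best]]$W),
       scores = tab, candidates = cands)
}

#' Leave-one-out stability of the inferred genotypes and tree
#'
#' Refits the model with each tumor subsection held out in turn (the normal
#' subsection is never held out) and reports, per held-out fit, the number
#' of genotype bits that differ from the full-data solution after
#' permutation matching of tumor clones, and whether the repaired clonal
#' trees are identical.
#'
#' @param panel a [counts_panel()] with at least 3 subsections.
#' @param C number of clones.
#' @param restarts EM restarts per fit.
#' @param seed master seed.
#' @param control an [em_control()] list.
#' @param score_restarts restarts used when rescoring repair candidates.
#' @return a data.frame of class `loo_stability` with columns `held_out`,
#'   `bits_different`, `same_tree`, and `converged`; the full-data fit is
#'   attached as attribute `full_fit`.
#' @export
leave_one_out <- function(panel, C, restarts = 10L, seed = 1L,
                          control = em_control(), score_restarts = 20L) {
  stopifnot(inherits(panel, "counts_panel"))
  S <- ncol(panel$N)
  if (S < 3L) stop("leave-one-out needs at least 3 subsections")
  full <- clonal_fit(panel, C, restarts = restarts, seed = seed,
                     control = control)
  full_repair <- repair_genotype(panel, full$W, restarts = score_restarts,
                                 seed = seed, control = control)
  full_sig <- tree_signature(full_repair$tree)

  rows <- lapply(2L:S, function(j) {
    sub <- drop_subsection(panel, j)
    fit <- clonal_fit(sub, C, restarts = restarts, seed = seed + 1000L * j,
                      control = control)
    err <- match_and_score(full$W, NULL, fit$W, NULL)
    bits <- round(err$genotype_error * nrow(panel$N) * (C - 1L))
    # align the held-out fit's clone labels to the full-data fit before
    # comparing trees
    Wj <- fit$W
    Wj[, 1L + seq_len(C - 1L)] <- Wj[, 1L + order(err$permutation),
                                     drop = FALSE]
    colnames(Wj) <- colnames(full$W)
    rep_j <- repair_genotype(sub, Wj, restarts = score_restarts,
                             seed = seed + j, control = control)
    data.frame(held_out = panel$subsections[j],
               bits_different = bits,
               same_tree = identical(tree_signature(rep_j$tree), full_sig),
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_fit") <- full
  class(out) <- c("loo_stability", "data.frame")
  out
}

#' @export
print.loo_stability <- function(x, ...) {
  cat("Leave-one-out stability over", nrow(x), "held-out tumor subsections\n")
  print.data.frame(x, row.names = FALSE)
  cat("Identical repaired tree in", sum(x$same_tree), "/", nrow(x),
      "fits\n")
  invisible(x)
}
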