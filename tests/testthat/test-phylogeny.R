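test_that("a trunk-and-branches genotype structure is a valid phylogeny", {
  # two founder mutations carried by both tumor clones, nine private to the
  # first and six private to the second
  W <- cbind(C0 = 0L,
             C1 = c(rep(1L, 2), rep(1L, 9), rep(0L, 6)),
             C2 = c(rep(1L, 2), rep(0L, 9), rep(1L, 6)))
  rownames(W) <- paste0("m", 1:17)
  expect_true(is_valid_phylogeny(W)$valid)
  tree <- build_tree(W)
  # trunk node carrying the founders, with both clones below it
  expect_identical(tree_genotypes(tree), W)
  sizes <- vapply(tree$mutations, length, integer(1))
  expect_setequal(sizes, c(0, 2, 9, 6))
})

test_that("overlapping non-nested carrier sets are rejected with a witness", {
  W <- cbind(0,
             c(1, 0), c(1, 1), c(0, 1))   # m1 in {C1,C2}, m2 in {C2,C3}
  rownames(W) <- c("mA", "mB")
  chk <- is_valid_phylogeny(W)
  expect_false(chk$valid)
  expect_setequal(chk$witness, c("mA", "mB"))
  expect_error(build_tree(W), "mA|mB")
})

test_that("genotypes read off random clonal trees are always valid", {
  for (seed in 1:50) {
    W <- random_tree_genotypes(C = sample(3:6, 1), M = sample(5:15, 1),
                               seed = seed)
    expect_true(is_valid_phylogeny(W)$valid)
    expect_true(brute_valid_phylogeny(W))
  }
})

test_that("the validity test agrees with the pairwise-loci brute force", {
  set.seed(99)
  agree <- 0L
  for (r in 1:200) {
    W <- cbind(0, matrix(rbinom(4 * 8, 1, 0.5), 8))
    rownames(W) <- paste0("m", 1:8)
    expect_equal(is_valid_phylogeny(W)$valid, brute_valid_phylogeny(W))
    agree <- agree + 1L
  }
  expect_equal(agree, 200L)
})

test_that("tree to genotype to tree is the identity on valid inputs", {
  for (seed in 1:100) {
    W <- random_tree_genotypes(C = sample(3:6, 1), M = sample(4:12, 1),
                               seed = 1000 + seed)
    t1 <- build_tree(W)
    W2 <- tree_genotypes(t1)
    expect_identical(W2, W)
    t2 <- build_tree(W2)
    expect_identical(clonesect:::tree_signature(t1),
                     clonesect:::tree_signature(t2))
  }
})

test_that("an all-zero genotype matrix gives a star of clones at the root", {
  W <- matrix(0L, 3, 4,
              dimnames = list(paste0("m", 1:3), paste0("C", 0:3)))
  tree <- build_tree(W)
  expect_equal(length(tree$parent), 1L)
  expect_setequal(tree$clones[[1]], paste0("C", 0:3))
  expect_identical(tree_genotypes(tree), W)
})

test_that("clones with identical genotypes share a tree node", {
  W <- cbind(C0 = c(0, 0), C1 = c(1, 0), C2 = c(1, 0))
  rownames(W) <- c("mA", "mB")
  tree <- build_tree(W)
  node <- which(vapply(tree$clones, function(x) "C1" %in% x, logical(1)))
  expect_true("C2" %in% tree$clones[[node]])
})

test_that("nearby enumeration matches an exhaustive flip search", {
  for (seed in 1:10) {
    set.seed(seed)
    W <- cbind(0, matrix(rbinom(15 * 3, 1, 0.5), 15))
    rownames(W) <- paste0("m", 1:15)
    colnames(W) <- paste0("C", 0:3)
    cands <- nearby_variants(W)
    # brute force: flip each distinct pattern x tumor clone, keep valid ones
    keys <- apply(W[, -1], 1, paste, collapse = "")
    expected <- 0L
    seen <- character(0)
    for (k in unique(keys)) {
      for (cl in 2:4) {
        W2 <- W
        W2[keys == k, cl] <- 1L - W2[keys == k, cl]
        if (brute_valid_phylogeny(W2)) {
          expected <- expected + 1L
          seen <- c(seen, paste(W2[, -1], collapse = ""))
        }
      }
    }
    expect_equal(length(cands), expected)
    got <- vapply(cands, function(x) paste(x$W[, -1], collapse = ""),
                  character(1))
    expect_setequal(got, seen)
    # every candidate flips exactly one bit among the distinct patterns
    for (x in cands) {
      diffs <- which(x$W != W, arr.ind = TRUE)
      expect_true(all(diffs[, "col"] == diffs[1, "col"]))
      expect_setequal(rownames(W)[diffs[, "row"]], x$loci)
      expect_true(x$valid)
    }
  }
})

test_that("the true genotype outscores its one-bit corruptions on clean data", {
  sim <- simulate_panel(M = 12, S = 5, C = 3, coverage = 1000, seed = 8)
  ref <- score_genotype(sim$panel, sim$W, restarts = 10, seed = 8)
  set.seed(8)
  for (r in 1:4) {
    W2 <- sim$W
    i <- sample(12, 1)
    c <- sample(2:3, 1)
    W2[i, c] <- 1L - W2[i, c]
    corrupted <- score_genotype(sim$panel, W2, restarts = 10, seed = 8 + r)
    expect_gt(ref$loglik, corrupted$loglik)
    expect_gt(ref$binom_loglik_nocoef, corrupted$binom_loglik_nocoef)
  }
})

test_that("fixed-genotype scoring is invariant to clone relabeling", {
  sim <- simulate_panel(M = 10, S = 4, C = 3, coverage = 500, seed = 12)
  s1 <- score_genotype(sim$panel, sim$W, restarts = 20, seed = 3)
  s2 <- score_genotype(sim$panel, sim$W[, c(1, 3, 2)], restarts = 20,
                       seed = 3)
  expect_equal(s1$loglik, s2$loglik, tolerance = 1e-4)
  expect_equal(s1$observed_loglik, s2$observed_loglik, tolerance = 1e-4)
})

test_that("random dense genotype matrices are almost never valid phylogenies", {
  set.seed(123)
  n_valid <- 0L
  n_eligible <- 0L
  for (r in 1:2000) {
    W <- cbind(0, matrix(rbinom(12 * 3, 1, 0.5), 12))
    if (nrow(unique(W[, -1])) >= 6) {
      n_eligible <- n_eligible + 1L
      if (is_valid_phylogeny(W)$valid) n_valid <- n_valid + 1L
    }
  }
  expect_gt(n_eligible, 1000)
  # at only 3 tumor clones the laminar constraint is already rarely met by
  # chance; the fraction shrinks rapidly with more clones and patterns
  expect_lt(n_valid / n_eligible, 0.1)
})

test_that("repair selects the best-scoring valid neighbor", {
  # counts drawn from a tree-consistent genotype matrix, then one pattern
  # bit corrupted so the carrier sets conflict
  W <- random_tree_genotypes(C = 4, M = 10, seed = 14)
  set.seed(14)
  P <- random_P(4, 5)
  P[, 1] <- c(1, 0, 0, 0)
  B <- (W %*% P) / 2
  N <- matrix(800L, 10, 5,
              dimnames = list(rownames(W),
                              c("normal", paste0("T", 1:4))))
  X <- matrix(rbinom(50, N, B), 10, 5, dimnames = dimnames(N))
  panel <- counts_panel(X, N)

  keys <- apply(W[, -1], 1, paste, collapse = "")
  W_bad <- NULL
  for (pat in unique(keys)) {
    for (cl in 2:4) {
      cand <- W
      cand[keys == pat, cl] <- 1L - cand[keys == pat, cl]
      if (!is_valid_phylogeny(cand)$valid) {
        W_bad <- cand
        break
      }
    }
    if (!is.null(W_bad)) break
  }
  expect_false(is.null(W_bad))

  rep <- repair_genotype(panel, W_bad, restarts = 5, seed = 14)
  expect_true(rep$repaired)
  expect_true(is_valid_phylogeny(rep$W)$valid)
  expect_equal(rep$scores$loglik[nrow(rep$scores)], max(rep$scores$loglik))
  # the repair should rediscover the uncorrupted truth
  expect_identical(unname(rep$W), unname(W))
})

test_that("leave-one-out refits every tumor subsection and compares trees", {
  sim <- simulate_panel(M = 8, S = 3, C = 2, coverage = 800, seed = 15)
  loo <- leave_one_out(sim$panel, 2, restarts = 3, seed = 15,
                       score_restarts = 5)
  expect_equal(nrow(loo), 2L)
  expect_setequal(loo$held_out, c("tumor1", "tumor2"))

  # strongly separated clones: each tumor clone dominates somewhere in
  # every leave-one-out subset, so all held-out fits recover the same tree
  W <- random_tree_genotypes(C = 3, M = 15, seed = 16)
  P <- rbind(c(1, 0.3, 0.3, 0.3, 0.3),
             c(0, 0.6, 0.1, 0.5, 0.1),
             c(0, 0.1, 0.6, 0.2, 0.6))
  set.seed(16)
  N <- matrix(1000L, 15, 5,
              dimnames = list(rownames(W),
                              c("normal", paste0("T", 1:4))))
  X <- matrix(rbinom(75, N, (W %*% P) / 2), 15, 5, dimnames = dimnames(N))
  panel <- counts_panel(X, N)
  loo2 <- leave_one_out(panel, 3, restarts = 5, seed = 16,
                        score_restarts = 5)
  expect_equal(nrow(loo2), 4L)
  expect_true(all(loo2$same_tree))
  expect_true(all(loo2$bits_different == 0))
})

test_that("clone trees export to parsable Newick via ape", {
  W <- random_tree_genotypes(C = 4, M = 8, seed = 77)
  tree <- build_tree(W)
  ph <- ape::as.phylo(tree)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, paste0("C", 0:3))
  txt <- ape::write.tree(ph)
  back <- ape::read.tree(text = txt)
  expect_setequal(back$tip.label, ph$tip.label)
})

test_that("validity is invariant to permuting clones and loci", {
  for (seed in 1:10) {
    W <- random_tree_genotypes(C = 4, M = 10, seed = 200 + seed)
    set.seed(seed)
    pc <- sample(3)
    pl <- sample(10)
    expect_true(is_valid_phylogeny(W[pl, c(1, pc + 1)])$valid)
    # and an invalid matrix stays invalid
    Wb <- cbind(0, c(1, 0), c(1, 1), c(0, 1))
    rownames(Wb) <- c("x", "y")
    expect_false(is_valid_phylogeny(Wb[, c(1, sample(3) + 1)])$valid)
  }
})
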