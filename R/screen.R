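ALLELE_OUTCOMES <- c("A", "C", "G", "T", "del", "unknown")

#' Per-locus allele-count tables across subsections
#'
#' Container for the multi-sample somatic variant screen: for each locus, a
#' 6 x S matrix of read counts over the mutually exclusive outcomes A, C, G,
#' T, deletion, and unknown, across S subsections of which the first is the
#' matched normal.
#'
#' @param counts a named list of 6 x S non-negative integer matrices (rows
#'   `A, C, G, T, del, unknown`), one per locus, all with identical
#'   subsection columns.
#' @param normal label or index of the normal subsection (moved to column
#'   1).
#' @return an object of class `allele_counts`.
#' @seealso [read_allele_counts()], [screen_variants()]
#' @export
allele_counts <- function(counts, normal = 1L) {
  if (length(counts) == 0L) stop("at least one locus is required")
  if (is.null(names(counts))) stop("the list of count tables must be named by locus")
  subs <- colnames(counts[[1L]])
  if (is.null(subs)) stop("count tables must have subsection column names")
  S <- length(subs)
  if (S < 2L) stop("at least one tumor subsection besides the normal is required")
  loci <- names(counts)
  counts <- lapply(loci, function(l) {
    m <- as.matrix(counts[[l]])
    if (!identical(colnames(m), subs))
      stop("locus '", l, "' has mismatching subsection labels")
    if (nrow(m) != 6L)
      stop("locus '", l, "' must have 6 outcome rows (A, C, G, T, del, unknown)")
    if (anyNA(m) || any(m < 0) || any(m != round(m)))
      stop("locus '", l, "' has a negative, missing or non-integer count")
    storage.mode(m) <- "integer"
    rownames(m) <- ALLELE_OUTCOMES
    m
  })
  names(counts) <- loci
  if (is.character(normal)) normal <- match(normal, subs)
  normal <- as.integer(normal)
  if (is.na(normal) || normal < 1L || normal > S)
    stop("unknown normal subsection")
  ord <- c(normal, setdiff(seq_len(S), normal))
  counts <- lapply(counts, function(m) m[, ord, drop = FALSE])
  structure(list(counts = counts, loci = loci, subsections = subs[ord]),
            class = "allele_counts")
}

#' Read allele-count tables from a long-format TSV
#'
#' Expected columns: `locus`, `subsection`, `A`, `C`, `G`, `T`, `del`,
#' `unknown` (one row per locus-subsection pair).
#'
#' @param path TSV path.
#' @param normal label of the normal subsection (default: first subsection
#'   encountered).
#' @return an [allele_counts()] object.
#' @export
read_allele_counts <- function(path, normal = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("locus", "subsection", ALLELE_OUTCOMES)
  if (!all(need %in% colnames(df)))
    stop("allele-count TSV must have columns: ", paste(need, collapse = ", "))
  subs <- unique(df$subsection)
  counts <- lapply(split(df, df$locus), function(d) {
    m <- t(as.matrix(d[match(subs, d$subsection), ALLELE_OUTCOMES]))
    colnames(m) <- subs
    m
  })
  counts <- counts[unique(df$locus)]
  if (is.null(normal)) normal <- subs[1L]
  allele_counts(counts, normal = normal)
}

# Exact (or seeded Monte-Carlo, for large totals) p-value of independence
# in a 2 x k contingency table; all-zero outcome columns are dropped first
# (they do not affect the exact p-value). Returns NA if either margin is
# empty; p = 1 if fewer than two outcome columns remain.
fisher_2xk <- function(tab, mc_total = 1000L, mc_B = 1e5L, mc_seed = 1L) {
  keep <- colSums(tab) > 0L
  tab <- tab[, keep, drop = FALSE]
  if (any(rowSums(tab) == 0L)) return(NA_real_)
  if (ncol(tab) < 2L) return(1)
  if (sum(tab) <= mc_total) {
    stats::fisher.test(tab)$p.value
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(mc_seed)
    stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_B)$p.value
  }
}

#' Stage 1 of the variant screen: per-locus exact tests
#'
#' For every locus and every tumor subsection, the six outcome counts of
#' normal versus tumor are compared with a 2 x 6 Fisher's exact test; the
#' resulting p-values are converted to q-values jointly over all tests
#' (Storey's procedure, see [storey_qvalue()]). A locus is accepted when
#' any of its normal-versus-tumor comparisons has a q-value below the
#' threshold.
#'
#' @param ac an [allele_counts()] object.
#' @param q_threshold acceptance q-value cutoff (default 0.05).
#' @param mc_total table total above which a seeded Monte-Carlo p-value
#'   (`B = 1e5` draws) replaces full exact enumeration.
#' @param mc_seed seed for the Monte-Carlo p-values.
#' @return a list with `tests` (data.frame of locus, subsection, p, q),
#'   `accepted` (character vector of accepted loci) and `q_threshold`.
#' @export
stage1_locus_test <- function(ac, q_threshold = 0.05, mc_total = 1000L,
                              mc_seed = 1L) {
  stopifnot(inherits(ac, "allele_counts"))
  S <- length(ac$subsections)
  grid <- expand.grid(locus = ac$loci,
                      subsection = ac$subsections[-1L],
                      stringsAsFactors = FALSE)
  p <- mapply(function(l, s) {
    m <- ac$counts[[l]]
    tab <- rbind(normal = m[, 1L], tumor = m[, s])
    fisher_2xk(tab, mc_total = mc_total, mc_seed = mc_seed)
  }, grid$locus, grid$subsection)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- storey_qvalue(p[ok])
  tests <- data.frame(locus = grid$locus, subsection = grid$subsection,
                      p = unname(p), q = q, stringsAsFactors = FALSE)
  hit <- tapply(tests$q < q_threshold, tests$locus,
                function(z) any(z, na.rm = TRUE))
  accepted <- ac$loci[ac$loci %in% names(hit)[hit]]
  list(tests = tests, accepted = accepted, q_threshold = q_threshold)
}

#' Stage 2 of the variant screen: per-allele calls
#'
#' For each accepted locus, tumor subsection, and each of the six outcomes,
#' a 2 x 2 Fisher's exact test compares that outcome's counts against the
#' sum of the other five, normal versus tumor. With p below the threshold
#' the allele is declared `increased` or `decreased` according to the
#' direction of the proportion change, otherwise `unchanged`. Calls that
#' are `increased` with a normal count of exactly zero are flagged
#' tumor-specific.
#'
#' @param ac an [allele_counts()] object.
#' @param accepted character vector of loci that passed stage 1.
#' @param p_threshold per-test p-value cutoff (default 0.01).
#' @return a data.frame with columns `locus`, `subsection`, `allele`,
#'   `normal_count`, `tumor_count`, `p`, `status`, `tumor_specific`.
#' @export
stage2_allele_calls <- function(ac, accepted, p_threshold = 0.01) {
  stopifnot(inherits(ac, "allele_counts"))
  if (length(accepted) == 0L)
    return(data.frame(locus = character(0), subsection = character(0),
                      allele = character(0), normal_count = integer(0),
                      tumor_count = integer(0), p = numeric(0),
                      status = character(0), tumor_specific = logical(0)))
  missing <- setdiff(accepted, ac$loci)
  if (length(missing) > 0L)
    stop("unknown loci: ", paste(missing, collapse = ", "))
  rows <- list()
  for (l in accepted) {
    m <- ac$counts[[l]]
    for (s in ac$subsections[-1L]) {
      nrm <- m[, 1L]
      tum <- m[, s]
      for (a in ALLELE_OUTCOMES) {
        tab <- matrix(c(nrm[a], sum(nrm) - nrm[a],
                        tum[a], sum(tum) - tum[a]), 2L, 2L, byrow = TRUE)
        if (nrm[a] == 0L && tum[a] == 0L) {
          p <- 1
        } else {
          p <- stats::fisher.test(tab)$p.value
        }
        prop_n <- if (sum(nrm) > 0L) nrm[a] / sum(nrm) else 0
        prop_t <- if (sum(tum) > 0L) tum[a] / sum(tum) else 0
        status <- if (p < p_threshold && prop_t > prop_n) "increased"
                  else if (p < p_threshold && prop_t < prop_n) "decreased"
                  else "unchanged"
        rows[[length(rows) + 1L]] <- data.frame(
          locus = l, subsection = s, allele = a,
          normal_count = unname(nrm[a]), tumor_count = unname(tum[a]),
          p = p, status = status,
          tumor_specific = status == "increased" && nrm[a] == 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Multi-sample somatic variant screen
#'
#' Runs the two-stage screen: a per-locus 2 x 6 exact test with q-value
#' correction selects candidate loci, then per-allele 2 x 2 exact tests
#' classify each allele in each tumor subsection as increased, decreased or
#' unchanged, flagging tumor-specific mutations (increased with zero
#' supporting reads in the normal).
#'
#' @inheritParams stage1_locus_test
#' @inheritParams stage2_allele_calls
#' @return a list of class `screen_report` with elements `stage1`, `calls`,
#'   `tumor_specific` (subset of calls), `q_threshold`, `p_threshold`.
#' @export
screen_variants <- function(ac, q_threshold = 0.05, p_threshold = 0.01,
                            mc_total = 1000L, mc_seed = 1L) {
  s1 <- stage1_locus_test(ac, q_threshold = q_threshold,
                          mc_total = mc_total, mc_seed = mc_seed)
  calls <- stage2_allele_calls(ac, s1$accepted, p_threshold = p_threshold)
  structure(list(stage1 = s1, calls = calls,
                 tumor_specific = calls[calls$tumor_specific, , drop = FALSE],
                 q_threshold = q_threshold, p_threshold = p_threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Two-stage somatic variant screen",
      sprintf("(q < %g, per-allele p < %g)\n", x$q_threshold, x$p_threshold))
  cat("  loci tested:   ", length(unique(x$stage1$tests$locus)), "\n")
  cat("  loci accepted: ", length(x$stage1$accepted), "\n")
  cat("  tumor-specific calls:", nrow(x$tumor_specific), "\n")
  invisible(x)
}

#' Deep-sequencing locus filters
#'
#' Keeps loci whose matched-normal coverage is at least `min_normal_total`
#' reads and whose variant support in the normal is at most
#' `max_normal_variant` reads (allowing a few stray variant reads that may
#' reflect sequencing error). A third common criterion — absence of
#' nearby clustered mutations, assessed visually — is not automated; loci
#' passing these two filters are flagged for manual review.
#'
#' @param panel a [counts_panel()].
#' @param min_normal_total minimum normal-subsection coverage (default 3).
#' @param max_normal_variant maximum variant reads tolerated in the normal
#'   (default 2).
#' @return a character vector of retained locus labels.
#' @export
deep_locus_filter <- function(panel, min_normal_total = 3L,
                              max_normal_variant = 2L) {
  stopifnot(inherits(panel, "counts_panel"))
  keep <- panel$N[, 1L] >= min_normal_total &
    panel$X[, 1L] <= max_normal_variant
  panel$loci[keep]
}

#' Storey q-values
#'
#' Converts p-values to q-values: the proportion of true nulls `pi0` is
#' estimated on a grid of tuning values by a cubic smoothing spline
#' evaluated at the largest tuning value, and q-values are `pi0` times the
#' step-up (Benjamini-Hochberg) adjusted p-values. With fewer than 30
#' p-values, or if the spline estimate is unusable, `pi0` is set to 1,
#' which reduces to plain Benjamini-Hochberg.
#'
#' @param p vector of p-values.
#' @param lambda grid of tuning values for the `pi0` estimate.
#' @return a vector of q-values, same length and order as `p`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (m >= 30L) {
    pi0_l <- vapply(lambda, function(l) mean(p > l, na.rm = TRUE) / (1 - l),
                    numeric(1))
    fit <- tryCatch(stats::smooth.spline(lambda, pi0_l, df = 3),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      est <- stats::predict(fit, x = max(lambda))$y
      if (is.finite(est) && est > 0) pi0 <- min(est, 1)
    }
  }
  pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
}
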