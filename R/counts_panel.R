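#' Paired read-count matrices over loci and tumor subsections
#'
#' A `counts_panel` holds the two M x S integer matrices that the clonal
#' decomposition model consumes: `N`, the total read count (coverage) at each
#' locus in each subsection, and `X`, the number of reads supporting the
#' variant allele. One subsection is the matched normal; internally it is
#' always stored as the first column so that downstream formulas can assume
#' subsection 1 is normal.
#'
#' @param X M x S matrix of non-negative integer variant-supporting read
#'   counts.
#' @param N M x S matrix of non-negative integer total read counts; must
#'   satisfy `X <= N` elementwise.
#' @param loci character vector of locus identifiers (length M). Defaults to
#'   the row names of `N`.
#' @param subsections character vector of subsection identifiers (length S).
#'   Defaults to the column names of `N`.
#' @param normal label or index of the matched-normal subsection; it is moved
#'   to column 1. Default: the first column.
#'
#' @return An object of class `counts_panel`: a list with integer matrices
#'   `X` and `N` (row names = loci, column names = subsections, normal
#'   first), plus `loci` and `subsections`.
#' @examples
#' N <- matrix(c(100L, 100L, 120L, 90L), 2, 2,
#'             dimnames = list(c("chr1a", "chr2a"), c("normal", "tumor1")))
#' X <- matrix(c(0L, 0L, 55L, 12L), 2, 2, dimnames = dimnames(N))
#' counts_panel(X, N)
#' @export
counts_panel <- function(X, N, loci = rownames(N), subsections = colnames(N),
                         normal = 1L) {
  X <- as.matrix(X)
  N <- as.matrix(N)
  if (!all(dim(X) == dim(N)))
    stop("X and N must have identical dimensions (got ",
         paste(dim(X), collapse = "x"), " vs ",
         paste(dim(N), collapse = "x"), ")")
  M <- nrow(N)
  S <- ncol(N)
  if (M < 1L) stop("at least one locus is required")
  if (S < 2L) stop("at least two subsections (one normal, one tumor) are required")
  if (is.null(loci)) loci <- paste0("locus", seq_len(M))
  if (is.null(subsections)) subsections <- paste0("S", seq_len(S))
  loci <- as.character(loci)
  subsections <- as.character(subsections)
  if (length(loci) != M) stop("length(loci) must equal nrow(N)")
  if (length(subsections) != S) stop("length(subsections) must equal ncol(N)")
  if (anyDuplicated(loci))
    stop("duplicate locus labels are not allowed: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (anyDuplicated(subsections))
    stop("duplicate subsection labels are not allowed: ",
         paste(unique(subsections[duplicated(subsections)]), collapse = ", "))

  check_count_matrix(X, "X", loci, subsections)
  check_count_matrix(N, "N", loci, subsections)
  bad <- which(X > N, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("X exceeds N at locus '", loci[bad[1L, 1L]], "', subsection '",
         subsections[bad[1L, 2L]], "' (", X[bad[1L, , drop = FALSE]], " > ",
         N[bad[1L, , drop = FALSE]], ")")

  if (is.character(normal)) {
    normal_idx <- match(normal, subsections)
    if (is.na(normal_idx))
      stop("normal subsection '", normal, "' not found among: ",
           paste(subsections, collapse = ", "))
  } else {
    normal_idx <- as.integer(normal)
    if (normal_idx < 1L || normal_idx > S)
      stop("normal subsection index out of range")
  }
  ord <- c(normal_idx, setdiff(seq_len(S), normal_idx))
  X <- X[, ord, drop = FALSE]
  N <- N[, ord, drop = FALSE]
  subsections <- subsections[ord]

  storage.mode(X) <- "integer"
  storage.mode(N) <- "integer"
  dimnames(X) <- dimnames(N) <- list(loci, subsections)

  structure(list(X = X, N = N, loci = loci, subsections = subsections),
            class = "counts_panel")
}

check_count_matrix <- function(mat, name, loci, subsections) {
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop(name, " contains a missing value at locus '", loci[bad[1L, 1L]],
         "', subsection '", subsections[bad[1L, 2L]], "'")
  }
  if (!is.numeric(mat))
    stop(name, " must be numeric")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)
    stop(name, " has a negative count at locus '", loci[bad[1L, 1L]],
         "', subsection '", subsections[bad[1L, 2L]], "'")
  }
  if (any(mat != round(mat))) {
    bad <- which(mat != round(mat), arr.ind = TRUE)
    stop(name, " has a non-integer count at locus '", loci[bad[1L, 1L]],
         "', subsection '", subsections[bad[1L, 2L]], "'")
  }
  invisible(TRUE)
}

#' @export
print.counts_panel <- function(x, ...) {
  cat("Multi-section read counts panel\n")
  cat("  loci:        ", length(x$loci), "\n")
  cat("  subsections: ", length(x$subsections),
      " (normal: ", x$subsections[1L], ")\n", sep = "")
  cat("  total reads: ", format(sum(as.numeric(x$N)), big.mark = ","), "\n")
  vaf <- x$X / pmax(x$N, 1L)
  cat("  variant-allele fraction range: ",
      sprintf("%.4f .. %.4f", min(vaf), max(vaf)), "\n")
  invisible(x)
}

#' @export
dim.counts_panel <- function(x) dim(x$N)

#' Drop one subsection from a panel
#'
#' Used by the leave-one-out stability analysis; the normal subsection
#' (column 1) cannot be dropped.
#'
#' @param panel a [counts_panel()].
#' @param j index or label of a tumor subsection.
#' @return a `counts_panel` with the subsection removed.
#' @export
drop_subsection <- function(panel, j) {
  stopifnot(inherits(panel, "counts_panel"))
  if (is.character(j)) j <- match(j, panel$subsections)
  j <- as.integer(j)
  if (is.na(j) || j < 1L || j > ncol(panel$N)) stop("unknown subsection")
  if (j == 1L) stop("the normal subsection cannot be dropped")
  counts_panel(panel$X[, -j, drop = FALSE], panel$N[, -j, drop = FALSE],
               normal = 1L)
}

#' Read a counts panel from two TSV files
#'
#' Each file is tab-separated with a header row of subsection labels and a
#' leading column of locus labels. The two files must carry identical locus
#' and subsection labels. The matched-normal subsection is moved to column 1.
#'
#' @param path_x path to the variant-count (X) TSV.
#' @param path_n path to the total-count (N) TSV.
#' @param normal label of the normal subsection (default: first column of the
#'   files).
#' @return a [counts_panel()].
#' @seealso [write_counts_panel()]
#' @export
read_counts_panel <- function(path_x, path_n, normal = NULL) {
  X <- read_labeled_tsv(path_x)
  N <- read_labeled_tsv(path_n)
  if (!identical(dim(X), dim(N)) ||
      !identical(rownames(X), rownames(N)) ||
      !identical(colnames(X), colnames(N)))
    stop("count files disagree in dimensions or labels: '", path_x,
         "' is ", nrow(X), "x", ncol(X), " [", colnames(X)[1L], "...], '",
         path_n, "' is ", nrow(N), "x", ncol(N), " [", colnames(N)[1L], "...]")
  if (is.null(normal)) normal <- 1L
  counts_panel(X, N, normal = normal)
}

read_labeled_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          row.names = 1L, comment.char = "")
  as.matrix(df)
}

#' Write a counts panel to two TSV files
#'
#' @param panel a [counts_panel()].
#' @param path_x,path_n output paths for the variant-count and total-count
#'   matrices.
#' @return invisibly, the two paths.
#' @export
write_counts_panel <- function(panel, path_x, path_n) {
  stopifnot(inherits(panel, "counts_panel"))
  write_labeled_tsv(panel$X, path_x)
  write_labeled_tsv(panel$N, path_n)
  invisible(c(path_x, path_n))
}

write_labeled_tsv <- function(mat, path, row_label = "locus") {
  df <- data.frame(mat, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(mat)), row_label), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
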