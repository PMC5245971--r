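#' Two-level full factorial design matrix
#'
#' Builds the 2^n x 2^n design matrix of a two-level full factorial:
#' one column for the intercept, one per main effect, and one per interaction
#' of every factor subset, evaluated over all 2^n factor settings. Rows follow
#' standard Yates order (first factor varies fastest, low level first);
#' columns are ordered by interaction order, then lexicographically — for
#' n = 3 the columns are I, A, B, C, AB, AC, BC, ABC. The matrix is
#' Hadamard-like: all distinct rows and all distinct columns are orthogonal
#' (integer dot product 0), and dividing by sqrt(2^n) makes it orthogonal,
#' `Q %*% t(Q) == t(Q) %*% Q == I`.
#'
#' @param n_factors number of two-level factors, 1..12 (the matrix has
#'   4^n entries, so larger designs stop being desk-scale).
#' @return an object of class `factorial_design`: list with `n_factors`,
#'   `matrix` (integer matrix of +/-1 with dimnames), `settings`
#'   (2^n x n matrix of the factor levels per row).
#' @export
build_factorial_design <- function(n_factors) {
  if (!is.numeric(n_factors) || n_factors < 1 || n_factors > 12 ||
      n_factors != round(n_factors)) {
    stop_fmricode("n_factors must be an integer in 1..12",
                  "fmricode_invalid_parameter")
  }
  n <- as.integer(n_factors)
  n_runs <- 2L^n
  factor_names <- LETTERS[seq_len(n)]
  # Yates order: factor 1 alternates fastest, starting at its low level
  settings <- sapply(seq_len(n), function(j) {
    rep(rep(c(-1L, 1L), each = 2L^(j - 1L)), length.out = n_runs)
  })
  settings <- matrix(settings, nrow = n_runs)
  colnames(settings) <- factor_names
  subsets <- .factor_subsets(n)
  design <- sapply(subsets, function(s) {
    if (length(s) == 0L) rep(1L, n_runs)
    else as.integer(apply(settings[, s, drop = FALSE], 1, prod))
  })
  design <- matrix(as.integer(design), nrow = n_runs)
  colnames(design) <- vapply(subsets, function(s) {
    if (length(s) == 0L) "I" else paste(factor_names[s], collapse = "")
  }, character(1))
  rownames(design) <- sprintf("run_%d", seq_len(n_runs))
  structure(list(n_factors = n, matrix = design, settings = settings),
            class = "factorial_design")
}

# all subsets of 1..n ordered by size then lexicographically
.factor_subsets <- function(n) {
  out <- list(integer(0))
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size, simplify = FALSE)
    out <- c(out, combs)
  }
  out
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("<factorial_design> %d factors, %d x %d matrix\n",
              x$n_factors, nrow(x$matrix), ncol(x$matrix)))
  print(x$matrix)
  invisible(x)
}

#' Factorial-design coding of a binary factor setting
#'
#' Represents an item described by `n` two-level factors as the corresponding
#' row of the full factorial design matrix: intercept, main effects, and all
#' interaction products. Every pair of distinct settings yields orthogonal
#' representations (dot product exactly 0), so this code carries no graded
#' similarity structure — two items differing in a single factor are as
#' dissimilar as items differing in all of them.
#'
#' @param factors vector of +1/-1 factor levels, length n.
#' @param design optionally a pre-built [build_factorial_design()] object
#'   (must match `length(factors)`).
#' @return integer vector of length 2^n (+/-1 entries).
#' @export
encode_factorial <- function(factors, design = NULL) {
  if (!is.numeric(factors) || length(factors) < 1 || !all(factors %in% c(-1, 1))) {
    stop_fmricode("factors must be a vector with entries exactly +1 or -1",
                  "fmricode_invalid_input")
  }
  n <- length(factors)
  if (is.null(design)) design <- build_factorial_design(n)
  stopifnot(inherits(design, "factorial_design"), design$n_factors == n)
  row <- which(apply(design$settings, 1, function(s) all(s == factors)))
  design$matrix[row, ]
}
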