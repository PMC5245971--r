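#' Pearson similarity between two activity patterns
#'
#' Standard product-moment correlation, the similarity measure of the
#' simulated scanner. Constant inputs are an error rather than silently 0:
#' degenerate patterns must be handled by the caller's pair selection.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_fmricode("pearson_similarity() needs two vectors of equal length >= 2",
                  "fmricode_invalid_dimension")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_fmricode("similarity is undefined for a constant pattern",
                  "fmricode_degenerate_similarity")
  }
  stats::cor(a, b)
}

#' Representational similarity matrix
#'
#' All pairwise Pearson similarities over a set of representations — the RSA
#' object. Constant representations yield `NA` entries (flagged, not imputed
#' as 0) and are reported in the `degenerate` attribute.
#'
#' @param reps a list of numeric vectors of common length, or a matrix with
#'   one representation per row.
#' @param labels optional stimulus identifiers (defaults to names/rownames).
#' @return an object of class `similarity_matrix`: a symmetric numeric matrix
#'   with unit diagonal (where defined) and dimnames, with attribute
#'   `degenerate` listing labels of constant representations.
#' @export
representational_similarity_matrix <- function(reps, labels = NULL) {
  m <- if (is.matrix(reps)) reps else do.call(rbind, reps)
  if (nrow(m) < 2) {
    stop_fmricode("need at least 2 representations", "fmricode_invalid_dimension")
  }
  if (is.null(labels)) {
    labels <- rownames(m) %||% (if (!is.matrix(reps)) names(reps) else NULL) %||%
      sprintf("item_%02d", seq_len(nrow(m)))
  }
  sds <- apply(m, 1, stats::sd)
  degenerate <- labels[sds == 0]
  S <- suppressWarnings(stats::cor(t(m)))
  S[sds == 0, ] <- NA_real_
  S[, sds == 0] <- NA_real_
  diag(S)[sds > 0] <- 1
  dimnames(S) <- list(labels, labels)
  structure(S, class = c("similarity_matrix", "matrix"),
            degenerate = degenerate)
}

#' Write / read a similarity matrix as labelled delimited text
#'
#' @param sim a `similarity_matrix` (or plain labelled matrix).
#' @param file path of the tab-separated file.
#' @return `write_similarity_matrix()` returns `file` invisibly;
#'   `read_similarity_matrix()` returns the matrix with labels.
#' @export
write_similarity_matrix <- function(sim, file) {
  df <- data.frame(label = rownames(sim), unclass(sim), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  structure(m, class = c("similarity_matrix", "matrix"),
            degenerate = character(0))
}

#' RSA over an externally produced activation matrix
#'
#' Reads a delimited stimulus-by-unit activation table (e.g. exported from a
#' deep network layer) and returns its representational similarity matrix, so
#' layer-wise RSA can be run on activations produced outside this package.
#'
#' @param file path to a delimited text table, one row per stimulus; the
#'   first column is taken as the stimulus label if non-numeric.
#' @param sep field separator (default tab).
#' @return a `similarity_matrix`.
#' @export
rsa_from_activations <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE)
  labels <- NULL
  if (!is.numeric(df[[1]])) {
    labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  representational_similarity_matrix(as.matrix(df), labels = labels)
}

#' Functional-smoothness statistic
#'
#' Quantifies the degree to which an encoder satisfies
#' `sim(x1, x2) %prop% sim(y1, y2)`: for each stimulus pair the Pearson
#' similarity of the inputs and of their encoded representations is computed,
#' and the statistic is the Pearson correlation between the two similarity
#' lists. 1 means similarity structure is perfectly preserved; 0 means the
#' code carries no recoverable similarity structure.
#'
#' Pairs whose encoded representation is constant (so output similarity is
#' undefined) are excluded with a count rather than imputed. Self-pairs are
#' the caller's responsibility to exclude (a stimulus set's default pairs
#' never include them).
#'
#' @param pairs either a `stimulus_set` — in which case the pairs are
#'   (prototype, distortion level i) for every level, with
#'   `all_pairs = TRUE` switching to all distinct item pairs — or a list of
#'   two-element lists `list(x1, x2)` of stimulus vectors.
#' @param encoder a function mapping a stimulus vector to its representation
#'   (see [make_encoder()]), or an `encoder_spec` (encoded with
#'   [encode_multilayer()]).
#' @param all_pairs when `pairs` is a `stimulus_set`: use all distinct item
#'   pairs instead of only prototype-distortion pairs.
#' @return an object of class `smoothness_result`: list with `statistic`,
#'   `input_sims`, `output_sims`, `n_pairs` (pairs used), `n_excluded`,
#'   `aggregation` (`"single"` for one evaluation).
#' @export
functional_smoothness <- function(pairs, encoder, all_pairs = FALSE) {
  if (inherits(encoder, "encoder_spec")) {
    spec <- encoder
    encoder <- function(x) encode_multilayer(x, spec)
  }
  if (inherits(pairs, "stimulus_set")) {
    m <- stimulus_matrix(pairs)
    idx <- if (all_pairs) {
      t(utils::combn(nrow(m), 2))
    } else {
      cbind(1L, 1L + seq_len(nrow(pairs$distortions)))
    }
    pairs <- lapply(seq_len(nrow(idx)), function(r) {
      list(m[idx[r, 1], ], m[idx[r, 2], ])
    })
  }
  if (!is.list(pairs) || length(pairs) < 3) {
    stop_fmricode("need at least 3 stimulus pairs", "fmricode_degenerate_statistic")
  }
  input_sims <- output_sims <- rep(NA_real_, length(pairs))
  for (i in seq_along(pairs)) {
    x1 <- pairs[[i]][[1]]; x2 <- pairs[[i]][[2]]
    y1 <- encoder(x1); y2 <- encoder(x2)
    ok <- stats::sd(y1) > 0 && stats::sd(y2) > 0
    if (ok) {
      input_sims[i] <- pearson_similarity(x1, x2)
      output_sims[i] <- pearson_similarity(y1, y2)
    }
  }
  keep <- !is.na(output_sims)
  n_excluded <- sum(!keep)
  input_sims <- input_sims[keep]
  output_sims <- output_sims[keep]
  if (length(input_sims) < 3) {
    stop_fmricode("fewer than 3 non-degenerate pairs remain",
                  "fmricode_degenerate_statistic")
  }
  if (stats::sd(input_sims) == 0 || stats::sd(output_sims) == 0) {
    stop_fmricode("zero variance in a similarity list; statistic undefined",
                  "fmricode_degenerate_statistic")
  }
  structure(list(statistic = stats::cor(input_sims, output_sims),
                 input_sims = input_sims,
                 output_sims = output_sims,
                 n_pairs = length(input_sims),
                 n_excluded = n_excluded,
                 aggregation = "single"),
            class = "smoothness_result")
}

#' @export
print.smoothness_result <- function(x, ...) {
  cat(sprintf("<smoothness_result> statistic=%.4f over %d pairs (%d excluded)\n",
              x$statistic, x$n_pairs, x$n_excluded))
  invisible(x)
}

#' Serialize a smoothness result to JSON
#'
#' Writes the statistic together with the raw pair-similarity lists so the
#' statistic is recomputable from the stored report.
#'
#' @param result a `smoothness_result`.
#' @param file path of the JSON file.
#' @return `file`, invisibly.
#' @export
write_smoothness_result <- function(result, file) {
  stopifnot(inherits(result, "smoothness_result"))
  jsonlite::write_json(unclass(result), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Gini coefficient of activation sparseness
#'
#' Inequality of the absolute activation magnitudes: with the magnitudes
#' sorted ascending as a_1..a_n,
#' `G = sum((2i - n - 1) * a_i) / (n * sum(a_i))`.
#' 0 for perfectly uniform activity; `(n-1)/n` (approaching 1) for one-hot
#' activity. Scale-invariant.
#'
#' @param activations numeric vector with at least one non-zero element.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_sparseness <- function(activations) {
  if (!is.numeric(activations) || length(activations) < 1) {
    stop_fmricode("activations must be a non-empty numeric vector",
                  "fmricode_invalid_input")
  }
  a <- sort(abs(activations))
  n <- length(a)
  total <- sum(a)
  if (total == 0) {
    stop_fmricode("sparseness is undefined for an all-zero vector",
                  "fmricode_undefined_sparseness")
  }
  sum((2 * seq_len(n) - n - 1) * a) / (n * total)
}
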