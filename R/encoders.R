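#' Initialize a random fully-connected network encoder
#'
#' Builds `depth` square weight matrices of independent standard-normal
#' entries (no bias terms), the random multi-layer tanh network used as a
#' candidate neural coding scheme. With the default `dim = 100`,
#' `depth = 8` this is the 8 x 100^2-weight stack from which the shallower
#' models take their leading layers.
#'
#' @param dim input/output dimensionality of every layer (>= 2).
#' @param depth number of layers. Depths outside 1..8 are allowed but warned
#'   about, since the simulation protocol covers 1..8.
#' @param seed integer RNG seed; weights are deterministic given it.
#' @return an object of class `encoder_spec`: list with `scheme`
#'   (`"multilayer"`), `dim`, `depth`, `weights` (list of `dim` x `dim`
#'   matrices), `seed`.
#' @export
init_network <- function(dim = 100L, depth = 8L, seed) {
  if (dim < 2) {
    stop_fmricode("dim must be >= 2", "fmricode_invalid_dimension")
  }
  if (depth < 1) {
    stop_fmricode("depth must be >= 1", "fmricode_invalid_parameter")
  }
  if (depth > 8) {
    warning("depth > 8 is outside the standard protocol range 1..8")
  }
  set.seed(seed)
  weights <- lapply(seq_len(depth), function(k) {
    matrix(stats::rnorm(dim * dim), nrow = dim, ncol = dim)
  })
  structure(list(scheme = "multilayer", dim = as.integer(dim),
                 depth = as.integer(depth), weights = weights,
                 seed = as.integer(seed)),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf("<encoder_spec> scheme=%s dim=%d depth=%d seed=%s\n",
              x$scheme, x$dim, x$depth %||% 0L,
              if (is.null(x$seed)) "NA" else x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accept a stimulus vector or a dim x n matrix of column stimuli
.as_cols <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}
.like_input <- function(y, x) {
  if (is.matrix(x)) y else as.numeric(y)
}
.check_dim <- function(x, dim) {
  if (nrow(.as_cols(x)) != dim) {
    stop_fmricode(sprintf("stimulus has %d dimensions but weights expect %d",
                          nrow(.as_cols(x)), dim),
                  "fmricode_shape_error")
  }
}

#' Vector-space coding (identity)
#'
#' Represents a stimulus as itself: the representation equals the input, so
#' similarity structure is preserved trivially (functional smoothness 1).
#'
#' @param x stimulus vector (or dim-by-n matrix of column stimuli).
#' @return the representation, same shape as `x`.
#' @export
encode_vector_space <- function(x) x

#' Gain-control coding (elementwise tanh)
#'
#' Squashes each element through the hyperbolic tangent, bounding activity in
#' (-1, 1) as a model of neural gain control. Monotone, hence functionally
#' smooth.
#'
#' @inheritParams encode_vector_space
#' @return tanh of `x`, same shape.
#' @export
encode_gain_control <- function(x) tanh(x)

#' Matrix-multiplication coding (one linear layer)
#'
#' Computes the weighted sums `W %*% x` of a one-layer linear network.
#' Linear in the stimulus and similarity-preserving in expectation, but the
#' representation is not spatially smooth.
#'
#' @inheritParams encode_vector_space
#' @param w an `encoder_spec` (its first weight layer is used) or a square
#'   numeric weight matrix.
#' @return the linear representation, same shape convention as `x`.
#' @export
encode_matrix_multiplication <- function(x, w) {
  W <- if (inherits(w, "encoder_spec")) w$weights[[1]] else w
  .check_dim(x, ncol(W))
  .like_input(W %*% .as_cols(x), x)
}

#' Perceptron coding (one tanh layer)
#'
#' A single-layer network with the tanh non-linearity applied post-synaptically:
#' `tanh(W %*% x)`. Identical to [encode_gain_control()] applied to
#' [encode_matrix_multiplication()].
#'
#' @inheritParams encode_matrix_multiplication
#' @return the bounded representation, entries in (-1, 1).
#' @export
encode_perceptron <- function(x, w) {
  encode_gain_control(encode_matrix_multiplication(x, w))
}

#' Multi-layer random network coding
#'
#' Stacks perceptron layers so the output of each layer feeds the next:
#' `y_k = tanh(W_k %*% y_(k-1))`. Only the final layer is returned by default
#' (the simulated scanner measures the final layer); all intermediate layers
#' can be retrieved for diagnostics.
#'
#' @inheritParams encode_vector_space
#' @param spec an `encoder_spec` from [init_network()].
#' @param depth number of layers to apply (default: all of `spec`).
#' @param all_layers if `TRUE`, return a list of every layer's output.
#' @return final-layer representation, or a list of layer outputs.
#' @export
encode_multilayer <- function(x, spec, depth = spec$depth, all_layers = FALSE) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (depth < 1 || depth > spec$depth) {
    stop_fmricode("depth must be between 1 and the spec's depth",
                  "fmricode_invalid_parameter")
  }
  .check_dim(x, spec$dim)
  y <- .as_cols(x)
  layers <- vector("list", depth)
  for (k in seq_len(depth)) {
    y <- tanh(spec$weights[[k]] %*% y)
    if (all_layers) layers[[k]] <- .like_input(y, x)
  }
  if (all_layers) layers else .like_input(y, x)
}

#' Build an encoder closure by scheme name
#'
#' Uniform interface over every coding scheme: given a scheme name and a seed,
#' returns a function mapping a stimulus vector (or column matrix) to its
#' representation.
#'
#' @param scheme one of `"vector_space"`, `"gain_control"`,
#'   `"matrix_multiplication"`, `"perceptron"`, `"multilayer"`, `"hash"`.
#' @param dim stimulus dimensionality (needed for weight-bearing schemes).
#' @param depth number of layers for `"multilayer"`.
#' @param seed RNG seed for weight initialization.
#' @param spec optionally, a pre-built `encoder_spec` whose leading layers are
#'   used instead of drawing fresh weights.
#' @return a function `x -> representation`.
#' @export
make_encoder <- function(scheme = c("vector_space", "gain_control",
                                    "matrix_multiplication", "perceptron",
                                    "multilayer", "hash"),
                         dim = 100L, depth = 2L, seed = NULL, spec = NULL) {
  scheme <- match.arg(scheme)
  needs_weights <- scheme %in% c("matrix_multiplication", "perceptron", "multilayer")
  if (needs_weights && is.null(spec)) {
    if (is.null(seed)) {
      stop_fmricode("a seed (or a pre-built spec) is required for weight-bearing schemes",
                    "fmricode_invalid_parameter")
    }
    spec <- init_network(dim, if (scheme == "multilayer") depth else 1L, seed)
  }
  switch(scheme,
    vector_space          = encode_vector_space,
    gain_control          = encode_gain_control,
    matrix_multiplication = function(x) encode_matrix_multiplication(x, spec),
    perceptron            = function(x) encode_perceptron(x, spec),
    multilayer            = function(x) encode_multilayer(x, spec, depth = depth),
    hash                  = encode_hash)
}

#' The eleven-model roster of the distortion experiment
#'
#' Model ids follow the standard numbering: (1) vector space, (2) gain
#' control, (3) matrix multiplication, (4) perceptron, (5)-(11) 2- to 8-layer
#' random networks.
#'
#' @return data.frame with `model_id`, `model_name`, `depth` (`NA` for the
#'   weight-free schemes; 1 for the single-layer schemes; 2..8 for stacks).
#' @export
model_roster <- function() {
  data.frame(
    model_id = 1:11,
    model_name = c("vector_space", "gain_control", "matrix_multiplication",
                   "perceptron", sprintf("%d-layer", 2:8)),
    depth = c(NA, NA, 1L, 1L, 2:8),
    stringsAsFactors = FALSE
  )
}

#' Write / read a weight stack as delimited text
#'
#' Weights are stored as one long tab-separated table (`layer`, `row`, `col`,
#' `weight`) with a JSON sidecar (`<file>.json`) recording `dim`, `depth` and
#' `seed`, so a stack round-trips exactly.
#'
#' @param spec an `encoder_spec`.
#' @param file path of the weight table to write (sidecar written alongside).
#' @return `write_network()` returns `file` invisibly; `read_network()`
#'   returns an `encoder_spec`.
#' @export
write_network <- function(spec, file) {
  stopifnot(inherits(spec, "encoder_spec"))
  long <- do.call(rbind, lapply(seq_along(spec$weights), function(k) {
    W <- spec$weights[[k]]
    data.frame(layer = k,
               row = rep(seq_len(nrow(W)), times = ncol(W)),
               col = rep(seq_len(ncol(W)), each = nrow(W)),
               weight = as.vector(W))
  }))
  utils::write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(dim = spec$dim, depth = spec$depth, seed = spec$seed),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  long <- utils::read.table(file, header = TRUE, sep = "\t")
  weights <- lapply(seq_len(meta$depth), function(k) {
    sub <- long[long$layer == k, ]
    W <- matrix(NA_real_, meta$dim, meta$dim)
    W[cbind(sub$row, sub$col)] <- sub$weight
    W
  })
  structure(list(scheme = "multilayer", dim = as.integer(meta$dim),
                 depth = as.integer(meta$depth), weights = weights,
                 seed = as.integer(meta$seed)),
            class = "encoder_spec")
}
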