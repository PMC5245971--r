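#' Z-normalize a vector to mean 0, standard deviation 1
#'
#' Centers and rescales so that the result has mean exactly 0 and standard
#' deviation exactly 1. The population convention (divide by `n`) is the
#' default so that "sd = 1" holds literally for each item; the sample
#' convention (`n - 1`) is available for interoperability. The map is
#' invariant to positive affine transforms: `znormalize(a * v + b)` equals
#' `znormalize(v)` for `a > 0`.
#'
#' @param v numeric vector, length >= 2, non-constant.
#' @param type `"population"` (divide by `n`, default) or `"sample"`
#'   (divide by `n - 1`).
#' @return numeric vector of the same length with mean 0 and sd 1.
#' @export
#' @examples
#' znormalize(c(1, 2, 3)) # -sqrt(3/2), 0, +sqrt(3/2)
znormalize <- function(v, type = c("population", "sample")) {
  type <- match.arg(type)
  if (!is.numeric(v) || length(v) < 2) {
    stop_fmricode("znormalize() needs a numeric vector of length >= 2",
                  "fmricode_invalid_dimension")
  }
  centered <- v - mean(v)
  denom <- if (type == "population") length(v) else length(v) - 1L
  s <- sqrt(sum(centered^2) / denom)
  if (s == 0) {
    stop_fmricode("cannot z-normalize a constant vector (zero variance)",
                  "fmricode_degenerate_input")
  }
  centered / s
}

#' Generate a Gaussian prototype stimulus
#'
#' Draws `dim` independent standard-normal values and z-normalizes them, giving
#' the category prototype of a prototype/distortion stimulus design.
#' Deterministic given `seed`.
#'
#' @param dim stimulus dimensionality (default 100; must be >= 2, since
#'   Pearson similarity is undefined below 2).
#' @param seed integer RNG seed.
#' @param sd_type normalization convention passed to [znormalize()].
#' @return an object of class `prototype`: list with `values` (numeric
#'   vector), `dim`, `seed`.
#' @export
generate_prototype <- function(dim = 100L, seed, sd_type = "population") {
  if (dim < 2) {
    stop_fmricode("dim must be >= 2 (Pearson similarity undefined below 2)",
                  "fmricode_invalid_dimension")
  }
  set.seed(seed)
  values <- znormalize(stats::rnorm(dim), type = sd_type)
  structure(list(values = values, dim = as.integer(dim), seed = as.integer(seed)),
            class = "prototype")
}

#' @export
print.prototype <- function(x, ...) {
  cat(sprintf("<prototype> dim=%d seed=%d mean=%.2e sd=%.6f\n",
              x$dim, x$seed, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Generate graded distortions of a prototype
#'
#' Level `i` (1-based) adds fresh independent Gaussian noise of standard
#' deviation `i * sd_step` to the prototype and re-normalizes the result to
#' mean 0, sd 1, so every item has identical first and second moments
#' regardless of distortion level. With `cumulative = TRUE` the level-`i` noise
#' (sd `i * sd_step`) is instead added to the previous *distortion*, giving a
#' random-walk variant of the schedule.
#'
#' @param prototype a [generate_prototype()] object (or numeric vector already
#'   normalized to mean 0, sd 1).
#' @param n_levels number of distortion levels (default 19).
#' @param sd_step noise sd increment per level (default 0.05).
#' @param seed integer RNG seed for the noise draws.
#' @param cumulative logical; add each level's noise to the previous
#'   distortion rather than to the prototype (default `FALSE`).
#' @param sd_type normalization convention passed to [znormalize()].
#' @return an object of class `stimulus_set`: list with `prototype` (numeric
#'   vector), `distortions` (`n_levels` x `dim` matrix, one row per level),
#'   `noise_sds` (`sd_step * 1:n_levels`), `seed`, `cumulative`.
#' @export
generate_distortions <- function(prototype, n_levels = 19L, sd_step = 0.05,
                                 seed, cumulative = FALSE,
                                 sd_type = "population") {
  proto <- if (inherits(prototype, "prototype")) prototype$values else prototype
  if (!is.numeric(proto) || length(proto) < 2) {
    stop_fmricode("prototype must be a numeric vector of length >= 2",
                  "fmricode_invalid_dimension")
  }
  if (n_levels < 1) {
    stop_fmricode("n_levels must be >= 1", "fmricode_invalid_parameter")
  }
  if (!is.numeric(sd_step) || sd_step <= 0) {
    stop_fmricode("sd_step must be a positive real", "fmricode_invalid_parameter")
  }
  dim <- length(proto)
  noise_sds <- sd_step * seq_len(n_levels)
  set.seed(seed)
  distortions <- matrix(NA_real_, nrow = n_levels, ncol = dim)
  prev <- proto
  for (i in seq_len(n_levels)) {
    base <- if (cumulative) prev else proto
    d <- znormalize(base + stats::rnorm(dim, sd = noise_sds[i]), type = sd_type)
    distortions[i, ] <- d
    prev <- d
  }
  rownames(distortions) <- sprintf("distortion_%02d", seq_len(n_levels))
  structure(list(prototype = proto,
                 distortions = distortions,
                 noise_sds = noise_sds,
                 seed = as.integer(seed),
                 cumulative = cumulative),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> dim=%d, %d distortions, noise sd %.2f..%.2f%s\n",
              length(x$prototype), nrow(x$distortions),
              min(x$noise_sds), max(x$noise_sds),
              if (x$cumulative) " (cumulative)" else ""))
  invisible(x)
}

#' Stack a stimulus set into a stimulus-by-dimension matrix
#'
#' Row 1 is the prototype, rows 2..(n+1) the distortions in level order.
#'
#' @param set a `stimulus_set`.
#' @return numeric matrix with labelled rows.
#' @export
stimulus_matrix <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  m <- rbind(prototype = set$prototype, set$distortions)
  m
}

#' Write / read a stimulus set as a delimited text table
#'
#' One row per stimulus (prototype first), with `level` (0 for the prototype)
#' and `noise_sd` columns followed by one column per dimension.
#'
#' @param set a `stimulus_set`.
#' @param file path of the tab-separated file to write.
#' @return `write_stimulus_set()` returns `file` invisibly;
#'   `read_stimulus_set()` returns a `stimulus_set`.
#' @export
write_stimulus_set <- function(set, file) {
  stopifnot(inherits(set, "stimulus_set"))
  m <- stimulus_matrix(set)
  df <- data.frame(level = c(0L, seq_len(nrow(set$distortions))),
                   noise_sd = c(0, set$noise_sds),
                   m, check.names = FALSE, row.names = NULL)
  colnames(df) <- c("level", "noise_sd", sprintf("dim%03d", seq_len(ncol(m))))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  proto <- as.numeric(vals[df$level == 0, ])
  dists <- vals[df$level > 0, , drop = FALSE]
  rownames(dists) <- sprintf("distortion_%02d", df$level[df$level > 0])
  structure(list(prototype = proto, distortions = dists,
                 noise_sds = df$noise_sd[df$level > 0],
                 seed = NA_integer_, cumulative = NA),
            class = "stimulus_set")
}
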