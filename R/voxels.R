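#' Construct a 2-D neural activity field
#'
#' A grid of non-negative activity values standing in for neurons, over which
#' a voxel grid is laid. Convenience generators cover the canonical
#' demonstrations: a smooth left-to-right gradient (recoverable after voxel
#' summation), a fine-scale alternating pattern (summed away), and a
#' checkerboard of configurable period.
#'
#' @param grid numeric matrix of finite, non-negative values.
#' @return an object of class `activity_field` (the validated matrix).
#' @export
activity_field <- function(grid) {
  if (!is.matrix(grid) || !is.numeric(grid) || any(!is.finite(grid)) ||
      any(grid < 0) || nrow(grid) < 1 || ncol(grid) < 1) {
    stop_fmricode("an activity field is a matrix of finite non-negative values",
                  "fmricode_invalid_input")
  }
  structure(grid, class = c("activity_field", "matrix"))
}

#' @rdname activity_field
#' @param rows,cols field dimensions in pixels.
#' @param low,high activity at the left and right edges of the gradient.
#' @export
field_gradient <- function(rows, cols, low = 0, high = 1) {
  activity_field(matrix(rep(seq(low, high, length.out = cols), each = rows),
                        nrow = rows))
}

#' @rdname activity_field
#' @param period half-period of the pattern in pixels: values alternate in
#'   blocks of `period` columns (`field_alternating`) or in a 2-D
#'   checkerboard of `period` x `period` blocks (`field_checkerboard`).
#' @param a,b the two activity values of the pattern.
#' @export
field_alternating <- function(rows, cols, period = 1L, a = 0, b = 1) {
  block <- ((seq_len(cols) - 1L) %/% period) %% 2L
  activity_field(matrix(rep(ifelse(block == 0L, a, b), each = rows),
                        nrow = rows))
}

#' @rdname activity_field
#' @export
field_checkerboard <- function(rows, cols, period = 1L, a = 0, b = 1) {
  ri <- ((seq_len(rows) - 1L) %/% period) %% 2L
  ci <- ((seq_len(cols) - 1L) %/% period) %% 2L
  par <- outer(ri, ci, function(r, c) (r + c) %% 2L)
  activity_field(matrix(ifelse(par == 0L, a, b), nrow = rows))
}

#' Spatial summation of an activity field into voxels
#'
#' Partitions the field into non-overlapping `voxel_size` blocks (0-based,
#' row-major, half-open ranges) and sums the activity within each block —
#' the spatial part of the BOLD sampling model. Total activity is conserved
#' exactly: `sum(voxels) == sum(field)`.
#'
#' @param field an [activity_field()] (or plain numeric matrix).
#' @param voxel_size integer vector `c(height, width)` in pixels.
#' @param edge what to do when the field dimensions are not divisible by the
#'   voxel size: `"error"` (default, keeps conservation guarantees) or
#'   `"truncate"` (drop trailing rows/columns).
#' @return an object of class `voxel_grid`: the matrix of block sums, with
#'   attribute `voxel_size`.
#' @export
spatial_summate <- function(field, voxel_size, edge = c("error", "truncate")) {
  edge <- match.arg(edge)
  f <- unclass(activity_field(as.matrix(field)))
  vs <- as.integer(voxel_size)
  if (length(vs) != 2 || any(vs < 1)) {
    stop_fmricode("voxel_size must be two positive integers (height, width)",
                  "fmricode_invalid_parameter")
  }
  if (vs[1] > nrow(f) || vs[2] > ncol(f)) {
    stop_fmricode("voxel larger than the field", "fmricode_invalid_parameter")
  }
  if (nrow(f) %% vs[1] != 0 || ncol(f) %% vs[2] != 0) {
    if (edge == "error") {
      stop_fmricode("field dimensions not divisible by voxel_size (use edge = \"truncate\")",
                    "fmricode_invalid_parameter")
    }
    f <- f[seq_len(nrow(f) %/% vs[1] * vs[1]),
           seq_len(ncol(f) %/% vs[2] * vs[2]), drop = FALSE]
  }
  nr <- nrow(f) %/% vs[1]
  nc <- ncol(f) %/% vs[2]
  ri <- (seq_len(nrow(f)) - 1L) %/% vs[1]
  ci <- (seq_len(ncol(f)) - 1L) %/% vs[2]
  sums <- rowsum(t(rowsum(f, ri)), ci)
  voxels <- t(sums)
  dimnames(voxels) <- NULL
  structure(matrix(voxels, nrow = nr, ncol = nc),
            class = c("voxel_grid", "matrix"), voxel_size = vs)
}

#' Between-voxel inhomogeneity
#'
#' Population standard deviation of the voxel values. Zero iff all voxels
#' summate to the same value — the regime in which the scanner is blind to the
#' underlying pattern; positive inhomogeneity is necessary for any pattern
#' information to survive voxel summation.
#'
#' @param voxels a [spatial_summate()] result (or numeric matrix/vector of
#'   at least 2 voxel values).
#' @return non-negative real.
#' @export
voxel_inhomogeneity <- function(voxels) {
  v <- as.numeric(voxels)
  if (length(v) < 2) {
    stop_fmricode("inhomogeneity needs at least 2 voxels",
                  "fmricode_degenerate_input")
  }
  sqrt(mean((v - mean(v))^2))
}

#' Temporal summation of a spike train
#'
#' Sums event counts over non-overlapping windows, the temporal analogue of
#' voxel summation: the BOLD signal roughly integrates activity through time,
#' so two trains with equal totals but different burst structure become
#' indistinguishable once the window covers them — burstiness is invisible to
#' temporal summation.
#'
#' @param spike_train numeric vector of event counts per time bin.
#' @param window window length in bins (must not exceed the train length).
#' @param edge `"error"` (default) or `"truncate"` for trailing partial
#'   windows.
#' @return numeric vector of window sums.
#' @export
temporal_summate <- function(spike_train, window, edge = c("error", "truncate")) {
  edge <- match.arg(edge)
  if (!is.numeric(spike_train) || length(spike_train) < 1) {
    stop_fmricode("spike_train must be a non-empty numeric vector",
                  "fmricode_invalid_input")
  }
  w <- as.integer(window)
  if (length(w) != 1 || w < 1 || w > length(spike_train)) {
    stop_fmricode("window must be a positive integer <= train length",
                  "fmricode_invalid_parameter")
  }
  n <- length(spike_train)
  if (n %% w != 0) {
    if (edge == "error") {
      stop_fmricode("train length not divisible by window (use edge = \"truncate\")",
                    "fmricode_invalid_parameter")
    }
    spike_train <- spike_train[seq_len(n %/% w * w)]
  }
  as.numeric(rowsum(spike_train, (seq_along(spike_train) - 1L) %/% w))
}
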