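#' Experiment configuration
#'
#' Bundles the parameters of the simulated-fMRI protocol. The defaults are
#' the reference protocol: 100-dimensional stimuli, 19 distortion levels with
#' noise sd steps of 0.05, 100 independently initialized random networks of
#' up to 8 layers.
#'
#' @param dim stimulus dimensionality.
#' @param n_distortions distortion levels per prototype.
#' @param sd_step noise sd increment per level.
#' @param n_networks number of independently seeded random networks
#'   (replications for the weight-free schemes).
#' @param max_depth deepest network layer, 1..8.
#' @param seed master seed; every stochastic component derives its own
#'   sub-seed from it via [derive_seed()].
#' @param aggregation how the smoothness statistic aggregates across
#'   networks: `"per_network_mean"` (statistic per network over its pairs,
#'   then averaged; default) or `"pooled"` (all networks' pairs in one
#'   correlation).
#' @param all_pairs use all distinct item pairs instead of only
#'   (prototype, distortion) pairs.
#' @param cumulative_noise distortion schedule variant; see
#'   [generate_distortions()].
#' @param output_dir optional directory for [write_report()].
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(dim = 100L, n_distortions = 19L, sd_step = 0.05,
                              n_networks = 100L, max_depth = 8L, seed = 1L,
                              aggregation = c("per_network_mean", "pooled"),
                              all_pairs = FALSE, cumulative_noise = FALSE,
                              output_dir = NULL) {
  aggregation <- match.arg(aggregation)
  if (dim < 2 || n_distortions < 1 || sd_step <= 0 || n_networks < 1 ||
      max_depth < 1 || max_depth > 8) {
    stop_fmricode("invalid experiment configuration", "fmricode_invalid_parameter")
  }
  structure(list(dim = as.integer(dim), n_distortions = as.integer(n_distortions),
                 sd_step = sd_step, n_networks = as.integer(n_networks),
                 max_depth = as.integer(max_depth), seed = as.integer(seed),
                 aggregation = aggregation, all_pairs = all_pairs,
                 cumulative_noise = cumulative_noise, output_dir = output_dir),
            class = "experiment_config")
}

# one network replication: stimulus set and the shared 8-layer weight stack.
# Sub-seeds: index n*10 + {1 prototype, 2 distortions, 3 weights}.
.network_inputs <- function(config, n, with_weights = TRUE) {
  proto <- generate_prototype(config$dim, derive_seed(config$seed, n * 10 + 1))
  set <- generate_distortions(proto, n_levels = config$n_distortions,
                              sd_step = config$sd_step,
                              seed = derive_seed(config$seed, n * 10 + 2),
                              cumulative = config$cumulative_noise)
  spec <- if (with_weights) {
    init_network(config$dim, config$max_depth, derive_seed(config$seed, n * 10 + 3))
  }
  list(set = set, spec = spec)
}

# pairwise similarities prototype-vs-items (or all pairs) over columns of Y;
# degenerate columns yield NA
.pair_sims <- function(Y, idx) {
  sds <- apply(Y, 2, stats::sd)
  vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (sds[i] == 0 || sds[j] == 0) NA_real_ else stats::cor(Y[, i], Y[, j])
  }, numeric(1))
}

.pair_index <- function(n_items, all_pairs) {
  if (all_pairs) t(utils::combn(n_items, 2)) else cbind(1L, 2:n_items)
}

#' Distortion experiment over the eleven coding schemes
#'
#' For each random network replication, encodes a prototype and its graded
#' distortions under all eleven models (vector space, gain control, matrix
#' multiplication, perceptron, and 2- to 8-layer random tanh networks — the
#' depth-k models reuse the first k layers of the replication's 8-layer
#' stack) and measures the Pearson similarity between the encoded prototype
#' and each encoded distortion. Averaged across networks this gives one
#' similarity-by-distortion curve per model.
#'
#' @param config an [experiment_config()].
#' @return an object of class `distortion_curves`: data.frame with
#'   `model_id`, `model_name`, `level`, `noise_sd`, `mean_similarity`,
#'   `sd_similarity`, `n_excluded`; attributes `sims` (networks x models x
#'   levels array) and `config`.
#' @export
run_distortion_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  roster <- model_roster()
  n_models <- nrow(roster)
  sims <- array(NA_real_,
                c(config$n_networks, n_models, config$n_distortions),
                dimnames = list(NULL, roster$model_name, NULL))
  idx <- cbind(1L, 1L + seq_len(config$n_distortions))
  for (n in seq_len(config$n_networks)) {
    inp <- .network_inputs(config, n)
    X <- t(stimulus_matrix(inp$set)) # dim x (1 + n_distortions)
    sims[n, 1, ] <- .pair_sims(X, idx)                        # vector space
    sims[n, 2, ] <- .pair_sims(encode_gain_control(X), idx)   # gain control
    lin <- encode_matrix_multiplication(X, inp$spec)
    sims[n, 3, ] <- .pair_sims(lin, idx)                      # matrix mult
    Y <- encode_gain_control(lin)                             # layer 1
    sims[n, 4, ] <- .pair_sims(Y, idx)                        # perceptron
    for (k in 2:config$max_depth) {
      Y <- tanh(inp$spec$weights[[k]] %*% Y)
      sims[n, 3 + k, ] <- .pair_sims(Y, idx)                  # k-layer model
    }
  }
  noise_sds <- config$sd_step * seq_len(config$n_distortions)
  out <- do.call(rbind, lapply(seq_len(n_models), function(m) {
    s <- sims[, m, , drop = FALSE]
    data.frame(model_id = roster$model_id[m],
               model_name = roster$model_name[m],
               level = seq_len(config$n_distortions),
               noise_sd = noise_sds,
               mean_similarity = apply(s, 3, mean, na.rm = TRUE),
               sd_similarity = apply(s, 3, stats::sd, na.rm = TRUE),
               n_excluded = apply(s, 3, function(v) sum(is.na(v))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("distortion_curves", "data.frame"),
            sims = sims, config = config)
}

#' Functional smoothness as a function of network depth
#'
#' For each replication, pushes the stimulus set through the shared random
#' stack layer by layer and computes the functional-smoothness statistic on
#' each depth's final representation. Depth 1 is the perceptron model.
#' Results are aggregated per `config$aggregation`; both aggregations are
#' always reported.
#'
#' @param config an [experiment_config()].
#' @return an object of class `smoothness_by_depth`: data.frame with `depth`,
#'   `statistic` (the configured aggregation), `mean_statistic`,
#'   `sd_across_networks`, `pooled_statistic`, `n_excluded_pairs`;
#'   attributes `per_network` (networks x depth matrix of raw statistics)
#'   and `config`.
#' @export
run_smoothness_by_depth <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  n_items <- 1L + config$n_distortions
  idx <- .pair_index(n_items, config$all_pairs)
  n_pairs <- nrow(idx)
  per_network <- matrix(NA_real_, config$n_networks, config$max_depth)
  ins <- array(NA_real_, c(config$n_networks, n_pairs))
  outs <- array(NA_real_, c(config$n_networks, config$max_depth, n_pairs))
  excluded <- matrix(0L, config$n_networks, config$max_depth)
  for (n in seq_len(config$n_networks)) {
    inp <- .network_inputs(config, n)
    X <- t(stimulus_matrix(inp$set))
    insim <- .pair_sims(X, idx)
    ins[n, ] <- insim
    Y <- X
    for (k in seq_len(config$max_depth)) {
      Y <- tanh(inp$spec$weights[[k]] %*% Y)
      osim <- .pair_sims(Y, idx)
      outs[n, k, ] <- osim
      keep <- !is.na(osim) & !is.na(insim)
      excluded[n, k] <- sum(!keep)
      if (sum(keep) >= 3) {
        per_network[n, k] <- stats::cor(insim[keep], osim[keep])
      }
    }
  }
  pooled <- vapply(seq_len(config$max_depth), function(k) {
    x <- as.vector(ins); y <- as.vector(outs[, k, ])
    keep <- !is.na(x) & !is.na(y)
    stats::cor(x[keep], y[keep])
  }, numeric(1))
  mean_stat <- colMeans(per_network, na.rm = TRUE)
  out <- data.frame(
    depth = seq_len(config$max_depth),
    statistic = if (config$aggregation == "pooled") pooled else mean_stat,
    mean_statistic = mean_stat,
    sd_across_networks = apply(per_network, 2, stats::sd, na.rm = TRUE),
    pooled_statistic = pooled,
    n_excluded_pairs = colSums(excluded)
  )
  structure(out, class = c("smoothness_by_depth", "data.frame"),
            per_network = per_network, config = config)
}

#' Verify the orthogonality proof of factorial-design coding
#'
#' Builds the 2^n full factorial design matrix, checks in integer arithmetic
#' that all distinct row pairs and column pairs have dot product exactly zero,
#' and checks that the sqrt(2^n)-normalized matrix `Q` satisfies
#' `Q %*% t(Q) == t(Q) %*% Q == I`. The orthogonality statement is a
#' dot-product statement, so the report also gives the range of row-wise
#' Pearson correlations over non-constant rows: these are also exactly 0,
#' because every non-constant row is orthogonal to the all-high (constant)
#' run and hence already centered; the constant run itself has undefined
#' Pearson similarity and is excluded from that range.
#'
#' @param n_factors number of factors, 1..12.
#' @return an object of class `factorial_proof`: list with `n_factors`,
#'   `n_row_pairs`, `max_abs_row_dot`, `max_abs_col_dot`, `max_dev_qqt`,
#'   `max_dev_qtq`, `orthogonal` (logical), `row_pearson_range`.
#' @export
run_factorial_proof <- function(n_factors = 3L) {
  design <- build_factorial_design(n_factors)
  M <- design$matrix
  G_rows <- M %*% t(M)
  G_cols <- t(M) %*% M
  # matrix products promote to double; the entries are exact small integers
  off <- function(G) { diag(G) <- 0; as.integer(max(abs(G))) }
  Q <- M / sqrt(2^design$n_factors)
  I <- diag(nrow(M))
  dev_qqt <- max(abs(Q %*% t(Q) - I))
  dev_qtq <- max(abs(t(Q) %*% Q - I))
  # Pearson on rows is only defined for non-constant rows (the all-high run
  # is constant +1); the orthogonality statement itself is about dot products
  nonconst <- apply(M, 1, function(r) stats::sd(r) > 0)
  row_pearson <- if (sum(nonconst) >= 2) {
    rp <- stats::cor(t(M[nonconst, , drop = FALSE]))
    range(rp[lower.tri(rp)])
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(n_factors = design$n_factors,
                 n_row_pairs = nrow(M) * (nrow(M) - 1L) / 2L,
                 max_abs_row_dot = off(G_rows),
                 max_abs_col_dot = off(G_cols),
                 max_dev_qqt = dev_qqt,
                 max_dev_qtq = dev_qtq,
                 orthogonal = off(G_rows) == 0 && off(G_cols) == 0 &&
                   dev_qqt < 1e-12 && dev_qtq < 1e-12,
                 row_pearson_range = row_pearson,
                 design = design),
            class = "factorial_proof")
}

#' @export
print.factorial_proof <- function(x, ...) {
  cat(sprintf(paste0("<factorial_proof> n=%d: %d row pairs, max |row dot|=%d, ",
                     "max |Q Qt - I|=%.2e -> %s\n"),
              x$n_factors, x$n_row_pairs, x$max_abs_row_dot, x$max_dev_qqt,
              if (x$orthogonal) "orthogonal" else "NOT orthogonal"))
  invisible(x)
}

#' Hash-coding failure demonstration
#'
#' Runs the distortion protocol through the SHA-1 hash encoder: for each
#' replication a prototype/distortion set is generated and hashed, and the
#' similarity curve plus the functional-smoothness statistic are computed.
#' Because hashing destroys input structure, the curve should be flat around
#' zero and the statistic indistinguishable from a shuffled-pair null. A
#' permutation null band accompanies both. The smoothness null shuffles each
#' replication's output-similarity list against its input list and averages
#' across replications, giving the null distribution of the *mean* statistic.
#' The curve null shuffles the elements of one representation in each pair
#' (destroying hash alignment while keeping the marginal value distribution);
#' per-level means of such null correlations are resampled and the band is
#' simultaneous at 95% across all levels (max-statistic construction), so
#' "every level inside the band" is a single family-wise test.
#'
#' @param config an [experiment_config()] (only `dim`, `n_distortions`,
#'   `sd_step`, `n_networks` — here: stimulus replications — and `seed` are
#'   used).
#' @param n_permutations permutations for the null bands (default 1000).
#' @return an object of class `hash_demo`: list with `curve` (data.frame:
#'   `level`, `noise_sd`, `mean_similarity`, `sd_similarity`, `null_lo`,
#'   `null_hi`), `mean_statistic`, `statistic_sd`, `statistic_null`
#'   (lo/hi 95% band), `inside_null_band` (logical), `n_replications`.
#' @export
run_hash_demo <- function(config = experiment_config(), n_permutations = 1000L) {
  stopifnot(inherits(config, "experiment_config"))
  n_rep <- config$n_networks
  n_lev <- config$n_distortions
  sims <- matrix(NA_real_, n_rep, n_lev)
  stats_obs <- rep(NA_real_, n_rep)
  ins_list <- vector("list", n_rep)
  outs_list <- vector("list", n_rep)
  rep_len <- 20L * config$dim
  proto_reps <- vector("list", n_rep)
  first_dist_reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    inp <- .network_inputs(config, r, with_weights = FALSE)
    X <- stimulus_matrix(inp$set)
    H <- t(apply(X, 1, encode_hash)) # items x (20 dim)
    insim <- vapply(seq_len(n_lev), function(i) stats::cor(X[1, ], X[i + 1, ]),
                    numeric(1))
    osim <- vapply(seq_len(n_lev), function(i) stats::cor(H[1, ], H[i + 1, ]),
                   numeric(1))
    sims[r, ] <- osim
    stats_obs[r] <- stats::cor(insim, osim)
    ins_list[[r]] <- insim
    outs_list[[r]] <- osim
    proto_reps[[r]] <- H[1, ]
    first_dist_reps[[r]] <- H[2, ]
  }
  # permutation nulls, reproducible from the master seed
  set.seed(derive_seed(config$seed, 999999L))
  # null for the MEAN smoothness statistic: shuffle pairings within every
  # replication, average across replications, repeat
  null_stats <- vapply(seq_len(n_permutations), function(p) {
    mean(vapply(seq_len(n_rep), function(r) {
      stats::cor(ins_list[[r]], sample(outs_list[[r]]))
    }, numeric(1)))
  }, numeric(1))
  stat_band <- stats::quantile(null_stats, c(0.025, 0.975), names = FALSE)
  # null pool of single-pair correlations under destroyed hash alignment
  null_pool <- vapply(seq_len(n_permutations), function(p) {
    r <- ((p - 1L) %% n_rep) + 1L
    stats::cor(proto_reps[[r]], sample(first_dist_reps[[r]]))
  }, numeric(1))
  # simultaneous 95% band for the per-level mean across replications:
  # resample level-means from the null pool and take the max over levels
  max_null <- vapply(seq_len(n_permutations), function(p) {
    means <- colMeans(matrix(sample(null_pool, n_rep * n_lev, replace = TRUE),
                             nrow = n_rep))
    max(abs(means))
  }, numeric(1))
  curve_half_width <- stats::quantile(max_null, 0.95, names = FALSE)
  curve <- data.frame(level = seq_len(n_lev),
                      noise_sd = config$sd_step * seq_len(n_lev),
                      mean_similarity = colMeans(sims),
                      sd_similarity = apply(sims, 2, stats::sd),
                      null_lo = -curve_half_width,
                      null_hi = curve_half_width)
  mean_stat <- mean(stats_obs)
  structure(list(curve = curve,
                 mean_statistic = mean_stat,
                 statistic_sd = stats::sd(stats_obs),
                 statistic_null = stat_band,
                 inside_null_band = mean_stat >= stat_band[1] &&
                   mean_stat <= stat_band[2],
                 n_replications = n_rep,
                 per_replication = stats_obs,
                 config = config),
            class = "hash_demo")
}

#' @export
print.hash_demo <- function(x, ...) {
  cat(sprintf(paste0("<hash_demo> %d replications: mean smoothness %.4f ",
                     "(95%% null band [%.4f, %.4f]) -> %s\n"),
              x$n_replications, x$mean_statistic,
              x$statistic_null[1], x$statistic_null[2],
              if (x$inside_null_band) "inside null band" else "OUTSIDE null band"))
  invisible(x)
}

#' Write a structured report of an experiment result
#'
#' Writes delimited tables of the result plus a JSON summary embedding the
#' configuration, master seed and package version. Re-running with the same
#' seed reproduces byte-identical tables.
#'
#' @param x a `distortion_curves`, `smoothness_by_depth`, `factorial_proof`
#'   or `hash_demo` object.
#' @param output_dir directory to write into (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(x, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(output_dir)) {
      stop_fmricode(sprintf("cannot create output directory '%s'", output_dir),
                    "fmricode_io_error")
    }
  }
  UseMethod("write_report")
}

.report_summary <- function(x, extra = list()) {
  config <- attr(x, "config") %||% x$config
  c(list(package_version = as.character(utils::packageVersion("fmricode")),
         config = if (!is.null(config)) unclass(config)), extra)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @export
write_report.distortion_curves <- function(x, output_dir) {
  files <- c(
    .write_tsv(as.data.frame(x), file.path(output_dir, "distortion_curves.tsv")))
  summary <- .report_summary(x, list(
    n_excluded_total = sum(x$n_excluded),
    models = unique(x$model_name)))
  jf <- file.path(output_dir, "distortion_curves_summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}

#' @export
write_report.smoothness_by_depth <- function(x, output_dir) {
  files <- c(
    .write_tsv(as.data.frame(x), file.path(output_dir, "smoothness_by_depth.tsv")))
  pn <- attr(x, "per_network")
  pn_df <- data.frame(network = seq_len(nrow(pn)), pn)
  colnames(pn_df) <- c("network", sprintf("depth_%d", seq_len(ncol(pn))))
  files <- c(files,
             .write_tsv(pn_df, file.path(output_dir, "smoothness_per_network.tsv")))
  summary <- .report_summary(x, list(
    n_excluded_pairs = as.list(stats::setNames(x$n_excluded_pairs,
                                               sprintf("depth_%d", x$depth))),
    mean_statistic = as.list(stats::setNames(x$mean_statistic,
                                             sprintf("depth_%d", x$depth))),
    pooled_statistic = as.list(stats::setNames(x$pooled_statistic,
                                               sprintf("depth_%d", x$depth)))))
  jf <- file.path(output_dir, "smoothness_summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}

#' @export
write_report.factorial_proof <- function(x, output_dir) {
  files <- .write_tsv(
    data.frame(run = rownames(x$design$matrix), x$design$matrix,
               check.names = FALSE),
    file.path(output_dir, "factorial_design.tsv"))
  summary <- x[c("n_factors", "n_row_pairs", "max_abs_row_dot",
                 "max_abs_col_dot", "max_dev_qqt", "max_dev_qtq",
                 "orthogonal", "row_pearson_range")]
  summary$package_version <- as.character(utils::packageVersion("fmricode"))
  jf <- file.path(output_dir, "factorial_proof.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}

#' @export
write_report.hash_demo <- function(x, output_dir) {
  files <- .write_tsv(x$curve, file.path(output_dir, "hash_similarity_curve.tsv"))
  summary <- .report_summary(x, list(
    mean_statistic = x$mean_statistic,
    statistic_sd = x$statistic_sd,
    statistic_null_band = x$statistic_null,
    inside_null_band = x$inside_null_band,
    n_replications = x$n_replications))
  jf <- file.path(output_dir, "hash_demo_summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, jf))
}

#' Plot similarity-by-distortion curves
#'
#' Line plot of the mean similarity to the prototype per distortion level for
#' every model, darker lines for simpler models. Requires ggplot2.
#'
#' @param curves a [run_distortion_experiment()] result.
#' @return a ggplot object.
#' @export
plot_distortion_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_fmricode("ggplot2 is required for plotting", "fmricode_missing_package")
  }
  df <- as.data.frame(curves)
  df$model <- stats::reorder(df$model_name, df$model_id)
  ggplot2::ggplot(df, ggplot2::aes(x = noise_sd, y = mean_similarity,
                                   colour = model, group = model)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_d(option = "mako", direction = -1) +
    ggplot2::labs(x = "distortion noise sd", y = "similarity to prototype",
                  colour = "model") +
    ggplot2::theme_minimal()
}
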