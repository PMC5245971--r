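test_that("pearson_similarity matches the explicit-sums oracle", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 9)
  # oracle: deviations (-1.5,-0.5,0.5,1.5) and (-3,-1,0,4);
  # r = 11 / sqrt(5 * 26) = 11 / sqrt(130)
  expect_equal(pearson_similarity(a, b), 11 / sqrt(130), tolerance = 1e-12)
  expect_equal(pearson_similarity(a, b), pearson_oracle(a, b), tolerance = 1e-15)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(pearson_similarity(x, y), pearson_oracle(x, y),
                 tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(pearson_similarity(x, x), 1)
  expect_equal(pearson_similarity(x, -x), -1)
  expect_error(pearson_similarity(rep(1, 5), rnorm(5)),
               class = "fmricode_degenerate_similarity")
  expect_error(pearson_similarity(rnorm(3), rnorm(4)),
               class = "fmricode_invalid_dimension")
})

test_that("representational similarity matrices are symmetric with unit diagonal", {
  reps <- lapply(1:6, function(i) rnorm(30))
  S <- representational_similarity_matrix(reps)
  expect_equal(unclass(S), t(unclass(S)), tolerance = 1e-12)
  expect_equal(unname(diag(S)), rep(1, 6))
  expect_true(all(S >= -1 & S <= 1))
  # two identical representations give a 2x2 matrix of ones
  S2 <- representational_similarity_matrix(list(a = reps[[1]], b = reps[[1]]))
  expect_equal(unname(unclass(S2)), matrix(1, 2, 2), ignore_attr = TRUE)
  # constant representations are flagged NA, never imputed as 0
  S3 <- representational_similarity_matrix(list(x = rnorm(5), y = rep(2, 5),
                                                z = rnorm(5)))
  expect_true(all(is.na(S3["y", ])))
  expect_identical(attr(S3, "degenerate"), "y")
  expect_false(any(is.na(S3[c("x", "z"), c("x", "z")])))
})

test_that("similarity matrices round-trip as labelled delimited text", {
  reps <- matrix(rnorm(40), nrow = 4,
                 dimnames = list(c("p", "d1", "d2", "d3"), NULL))
  S <- representational_similarity_matrix(reps)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(S, f)
  back <- read_similarity_matrix(f)
  expect_equal(unclass(back), unclass(S), tolerance = 1e-12)
})

test_that("external activation tables feed straight into RSA", {
  acts <- data.frame(stimulus = c("lion", "tiger", "robin", "banjo"),
                     matrix(rnorm(4 * 16), nrow = 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(acts, f, sep = "\t", quote = FALSE, row.names = FALSE)
  S <- rsa_from_activations(f)
  expect_equal(rownames(S), acts$stimulus)
  expect_equal(unname(diag(S)), rep(1, 4))
})

test_that("functional smoothness matches brute-force recomputation on small toys", {
  # first-principles oracle on <= 5 pairs of <= 6-dim vectors
  set.seed(55)
  pairs <- lapply(1:5, function(i) list(rnorm(6), rnorm(6)))
  spec <- init_network(6, 1, seed = 56)
  encoder <- function(x) encode_perceptron(x, spec)
  res <- functional_smoothness(pairs, encoder)
  ins <- sapply(pairs, function(p) pearson_oracle(p[[1]], p[[2]]))
  outs <- sapply(pairs, function(p) pearson_oracle(encoder(p[[1]]),
                                                   encoder(p[[2]])))
  expect_equal(res$input_sims, ins, tolerance = 1e-12)
  expect_equal(res$output_sims, outs, tolerance = 1e-12)
  expect_equal(res$statistic, pearson_oracle(ins, outs), tolerance = 1e-12)
  expect_equal(res$n_pairs, 5)
  # statistic recomputable from the stored lists
  expect_equal(res$statistic, cor(res$input_sims, res$output_sims))
})

test_that("functional smoothness is invariant to pair relabelling", {
  set.seed(57)
  pairs <- lapply(1:8, function(i) list(rnorm(10), rnorm(10)))
  enc <- function(x) tanh(x)
  r1 <- functional_smoothness(pairs, enc)
  r2 <- functional_smoothness(pairs[c(3, 1, 8, 2, 7, 4, 6, 5)], enc)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("stimulus sets supply prototype-distortion pairs (or all pairs)", {
  set <- generate_distortions(generate_prototype(30, seed = 58), seed = 59)
  res <- functional_smoothness(set, encode_vector_space)
  expect_equal(res$n_pairs, 19)
  res_all <- functional_smoothness(set, encode_vector_space, all_pairs = TRUE)
  expect_equal(res_all$n_pairs, choose(20, 2))
})

test_that("degenerate similarity inputs raise or are excluded with a count", {
  pairs <- lapply(1:2, function(i) list(rnorm(5), rnorm(5)))
  expect_error(functional_smoothness(pairs, identity),
               class = "fmricode_degenerate_statistic")
  # an encoder that collapses some inputs to constants: excluded pairwise
  collapse <- function(x) if (x[1] > 0) rep(0, length(x)) else x
  set.seed(60)
  pairs <- lapply(1:12, function(i) list(c(-abs(rnorm(1)), rnorm(9)),
                                         c(-abs(rnorm(1)), rnorm(9))))
  pairs[[1]][[1]][1] <- 2 # force one degenerate encoding
  res <- functional_smoothness(pairs, collapse)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$n_pairs, 11)
  # identical input similarities make the statistic undefined
  x <- rnorm(8)
  same <- lapply(1:4, function(i) list(x, x))
  expect_error(functional_smoothness(same, function(v) v + rnorm(8)),
               class = "fmricode_degenerate_statistic")
})

test_that("smoothness results serialize to a recomputable JSON report", {
  set <- generate_distortions(generate_prototype(20, seed = 61), seed = 62)
  res <- functional_smoothness(set, encode_gain_control)
  f <- withr::local_tempfile(fileext = ".json")
  write_smoothness_result(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(cor(back$input_sims, back$output_sims), back$statistic,
               tolerance = 1e-12)
})

test_that("gini_sparseness matches closed forms and the pairwise-difference oracle", {
  expect_equal(gini_sparseness(rep(3, 7)), 0)
  expect_equal(gini_sparseness(c(0, 0, 1)), 2 / 3)
  for (n in c(2, 5, 10, 100)) {
    onehot <- c(rep(0, n - 1), 1)
    expect_equal(gini_sparseness(onehot), (n - 1) / n)
  }
  set.seed(63)
  for (i in 1:10) {
    v <- rnorm(8)
    expect_equal(gini_sparseness(v), gini_oracle(v), tolerance = 1e-12)
    # scale invariance
    expect_equal(gini_sparseness(2.5 * v), gini_sparseness(v), tolerance = 1e-12)
  }
  expect_error(gini_sparseness(rep(0, 4)),
               class = "fmricode_undefined_sparseness")
})
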