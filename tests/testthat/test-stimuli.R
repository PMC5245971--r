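test_that("znormalize matches the hand-computed oracle and its contracts", {
  # (1,2,3): mean 2, population sd sqrt(2/3)
  expect_equal(znormalize(c(1, 2, 3)), c(-sqrt(3 / 2), 0, sqrt(3 / 2)),
               tolerance = 1e-12)
  # idempotence
  v <- znormalize(rnorm(50))
  expect_equal(znormalize(v), v, tolerance = 1e-9)
  # exact moments
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-12)
  # affine invariance for a > 0
  w <- rnorm(20)
  expect_equal(znormalize(3.7 * w - 11), znormalize(w), tolerance = 1e-9)
  # degenerate input
  expect_error(znormalize(c(5, 5, 5)), class = "fmricode_degenerate_input")
  expect_error(znormalize(1), class = "fmricode_invalid_dimension")
  # sample convention differs by the sqrt(n/(n-1)) factor
  expect_equal(znormalize(c(1, 2, 3), type = "sample"), c(-1, 0, 1))
})

test_that("generate_prototype draws normalized Gaussian prototypes deterministically", {
  p <- generate_prototype(100, seed = 11)
  expect_length(p$values, 100)
  expect_equal(mean(p$values), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(p$values^2)), 1, tolerance = 1e-9)
  # determinism
  expect_identical(p$values, generate_prototype(100, seed = 11)$values)
  expect_false(identical(p$values, generate_prototype(100, seed = 12)$values))
  # dim = 2: z-normalization forces (-1, +1) up to order
  for (s in 1:20) {
    q <- sort(generate_prototype(2, seed = s)$values)
    expect_equal(q, c(-1, 1), tolerance = 1e-12)
  }
  expect_error(generate_prototype(1, seed = 1), class = "fmricode_invalid_dimension")
})

test_that("distortion sets follow the incremental noise-sd schedule", {
  p <- generate_prototype(100, seed = 3)
  set <- generate_distortions(p, seed = 4)
  expect_equal(nrow(set$distortions), 19)
  expect_equal(set$noise_sds, 0.05 * 1:19)
  expect_true(all(diff(set$noise_sds) > 0))
  expect_equal(diff(set$noise_sds), rep(0.05, 18), tolerance = 1e-12)
  # every item normalized
  for (i in 1:19) {
    expect_equal(mean(set$distortions[i, ]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(set$distortions[i, ]^2)), 1, tolerance = 1e-9)
  }
  # determinism
  expect_identical(set$distortions,
                   generate_distortions(p, seed = 4)$distortions)
  expect_error(generate_distortions(p, sd_step = 0, seed = 1),
               class = "fmricode_invalid_parameter")
  expect_error(generate_distortions(p, sd_step = -0.1, seed = 1),
               class = "fmricode_invalid_parameter")
})

test_that("tiny sd_step leaves the distortion essentially equal to the prototype", {
  p <- generate_prototype(100, seed = 5)
  set <- generate_distortions(p, n_levels = 1, sd_step = 1e-12, seed = 6)
  expect_equal(as.numeric(set$distortions[1, ]), p$values, tolerance = 1e-9)
})

test_that("prototype-distortion similarity matches the 1/sqrt(1+sigma^2) law", {
  # Monte-Carlo oracle: for z-scored prototype x and distortion
  # znorm(x + noise(sd sigma)), E[Pearson] ~ 1/sqrt(1 + sigma^2) at large dim.
  # 10,000 fresh noise draws at dim = 100, level i = 10 (sigma = 0.5).
  # independent Monte-Carlo oracle: 10,000 fresh noise draws around one
  # z-scored prototype (z-normalizing the noisy copy leaves Pearson unchanged,
  # so the oracle needs no package internals)
  set.seed(101)
  p <- generate_prototype(100, seed = 101)$values
  sigma <- 0.5
  draws <- replicate(10000, cor(p, p + rnorm(100, sd = sigma)))
  oracle_mean <- mean(draws)
  oracle_se <- sd(draws) / sqrt(length(draws))
  # large-dim law holds up to finite-dimension terms of order 1/dim
  expect_lt(abs(oracle_mean - 1 / sqrt(1 + sigma^2)), 0.005)
  # the packaged generator agrees with the oracle within 3 combined s.e.
  sims <- sapply(1:200, function(s) {
    set <- generate_distortions(generate_prototype(100, seed = s),
                                n_levels = 10, seed = s + 5000)
    cor(set$prototype, set$distortions[10, ])
  })
  combined_se <- sqrt(oracle_se^2 + var(sims) / length(sims))
  expect_lt(abs(mean(sims) - oracle_mean), 3 * combined_se)
})

test_that("mean similarity to the prototype decays monotonically in level", {
  # the x-axis structure of the distortion experiment, over 100 replications
  sims <- sapply(1:100, function(s) {
    set <- generate_distortions(generate_prototype(100, seed = s),
                                seed = s + 10000)
    as.numeric(cor(set$prototype, t(set$distortions)))
  })
  mean_by_level <- rowMeans(sims)
  expect_true(all(diff(mean_by_level) < 0))
})

test_that("cumulative noise schedule is available and decays faster", {
  p <- generate_prototype(100, seed = 21)
  fresh <- generate_distortions(p, seed = 22)
  cum <- generate_distortions(p, seed = 22, cumulative = TRUE)
  expect_false(identical(fresh$distortions, cum$distortions))
  # random-walk distortions drift further from the prototype at high levels
  mean_last <- function(s) cor(s$prototype, s$distortions[19, ])
  reps <- sapply(1:50, function(i) {
    pr <- generate_prototype(100, seed = 100 + i)
    c(mean_last(generate_distortions(pr, seed = 200 + i)),
      mean_last(generate_distortions(pr, seed = 200 + i, cumulative = TRUE)))
  })
  expect_gt(mean(reps[1, ]), mean(reps[2, ]))
})

test_that("stimulus sets round-trip through delimited text", {
  set <- generate_distortions(generate_prototype(20, seed = 31), seed = 32)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stimulus_set(set, f)
  back <- read_stimulus_set(f)
  expect_equal(back$prototype, set$prototype, tolerance = 1e-12)
  expect_equal(unname(back$distortions), unname(set$distortions),
               tolerance = 1e-12)
  expect_equal(back$noise_sds, set$noise_sds)
})
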