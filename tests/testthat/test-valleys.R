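worked <- c(4, 10, 8, 2, 6, 12, 5)

test_that("valley detection finds minima between adjacent maxima above the drop threshold", {
  expect_equal(nrow(find_valleys(rep(5, 100))), 0)
  expect_equal(nrow(find_valleys(seq(1, 50))), 0)
  expect_equal(nrow(find_valleys(numeric(0))), 0)
  expect_equal(nrow(find_valleys(rep(0, 50))), 0)

  v <- find_valleys(worked)
  expect_equal(nrow(v), 1)
  expect_equal(v$left_max, 1)
  expect_equal(v$min_pos, 3)
  expect_equal(v$right_max, 5)
  expect_equal(v$left_drop, 8)
  expect_equal(v$right_drop, 10)
  expect_equal(v$water, 14)

  # drops below 10% of the mean are rejected
  shallow <- c(10, 10.1, 10, 10.1, 10)
  expect_equal(nrow(find_valleys(shallow)), 0)
})

test_that("plateau maxima take the leftmost index and endpoints bound valleys", {
  # plateau at the left end, valley, then rise to the right endpoint
  track <- c(8, 8, 8, 2, 2, 9)
  v <- find_valleys(track)
  expect_equal(nrow(v), 1)
  expect_equal(v$left_max, 0)   # leftmost index of the plateau
  expect_equal(v$min_pos, 3)    # leftmost minimum
  expect_equal(v$right_max, 5)  # track endpoint as bounding maximum
})

test_that("local valley score equals the per-base water oracle", {
  v <- find_valleys(worked)
  expect_equal(local_valley_score(v[1, ], worked), 14)
  expect_equal(local_valley_score(v[1, ], worked),
               oracle_water(worked, v$left_max, v$right_max))

  # symmetric V with zero depth relative to the lower peak holds no water
  flat_v <- c(5, 5, 5)
  expect_equal(nrow(find_valleys(flat_v)), 0)

  set.seed(14)
  n_checked <- 0
  for (rep in 1:200) {
    x <- as.numeric(rpois(sample(20:60, 1), 10))
    vs <- find_valleys(x)
    for (i in seq_len(nrow(vs))) {
      expect_equal(vs$water[i], oracle_water(x, vs$left_max[i], vs$right_max[i]))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("global valley score: worked example, nullity, scale invariance, monotonicity", {
  expect_equal(global_valley_score(rep(7, 300)), 0)
  expect_equal(global_valley_score(seq_len(300)), 0)
  expect_equal(global_valley_score(rep(0, 300)), 0)

  expect_equal(global_valley_score(worked, sigma = 0), 14 / 47, tolerance = 1e-12)

  set.seed(6)
  dip <- 70 * exp(-(seq_len(2000) - 1000)^2 / (2 * 180^2))
  x <- rpois(2000, 100 - dip)
  g1 <- global_valley_score(x)
  expect_gt(g1, 0)
  expect_equal(global_valley_score(3.7 * x), g1, tolerance = 1e-12)
  expect_equal(global_valley_score(x / 1000), g1, tolerance = 1e-9)

  # deepening a fixed-shape valley strictly increases the score
  base_track <- 100 - 0 * seq_len(1200)
  gvs_by_depth <- vapply(c(20, 40, 60, 80), function(depth) {
    dip <- depth * exp(-(seq_len(1200) - 600)^2 / (2 * 80^2))
    global_valley_score(base_track - dip)
  }, numeric(1))
  expect_true(all(diff(gvs_by_depth) > 0))
})

test_that("3' bias fit recovers known coefficients and zero for identical samples", {
  set.seed(31)
  lens <- sample(800:3000, 20)
  ref <- lapply(lens, function(L) rep(100, L) + runif(L))
  names(ref) <- paste0("g", seq_along(ref))
  fit0 <- fit_3prime_bias(ref, ref)
  expect_equal(fit0$beta_d, 0, tolerance = 1e-12)
  expect_equal(fit0$beta_r, 0, tolerance = 1e-12)
  expect_equal(fit0$beta_dr, 0, tolerance = 1e-12)
  expect_equal(fit0$beta0, 0, tolerance = 1e-12)

  # exact exponential decay in d is recovered exactly (noise-free)
  delta <- 0.001
  smp <- lapply(ref, function(v) {
    L <- length(v); d <- (L - 1) - (seq_len(L) - 1)
    v * exp(-delta * d)
  })
  fit <- fit_3prime_bias(smp, ref)
  expect_equal(fit$beta_d, -delta, tolerance = 1e-8)
  expect_equal(fit$beta_r, 0, tolerance = 1e-6)
  expect_equal(abs(fit$beta_dr) < 1e-8, TRUE)

  expect_error(fit_3prime_bias(list(rep(1, 3)), list(rep(1, 3))), "10")
})

test_that("OLS coefficients equal the normal-equation solution on a tiny design", {
  # two short genes of different lengths (the design needs length variation
  # to separate distance-from-3' from relative position)
  set.seed(12)
  lens <- c(7L, 9L)
  smp <- list(g1 = exp(rnorm(7)) * 50, g2 = exp(rnorm(9)) * 50)
  ref <- list(g1 = rep(50, 7), g2 = rep(50, 9))
  fit <- fit_3prime_bias(smp, ref)
  d <- unlist(lapply(lens, function(L) (L - 1) - (seq_len(L) - 1)))
  r <- unlist(lapply(lens, function(L) (seq_len(L) - 1) / L))
  X <- cbind(1, d, r, d * r)
  y <- log(unlist(smp) / unlist(ref))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$beta0, beta[1], tolerance = 1e-8)
  expect_equal(fit$beta_d, beta[2], tolerance = 1e-8)
  expect_equal(fit$beta_r, beta[3], tolerance = 1e-8)
  expect_equal(fit$beta_dr, beta[4], tolerance = 1e-8)

  # a single fixed-length gene makes the design aliased
  expect_error(fit_3prime_bias(list(g = exp(rnorm(20)) * 5 + 6),
                               list(g = rep(5, 20))),
               "collinear")
})

test_that("3' bias correction flattens decayed tracks and preserves positivity", {
  lens <- c(1600L, 2400L)
  decay <- function(L) {
    d <- (L - 1) - (seq_len(L) - 1)
    200 * exp(-0.001 * d)
  }
  ref <- lapply(lens, function(L) rep(200, L))
  smp <- lapply(lens, decay)
  names(ref) <- names(smp) <- c("g1", "g2")
  fit <- fit_3prime_bias(smp, ref)
  expect_equal(fit$beta_d, -0.001, tolerance = 1e-6)

  corrected <- correct_3prime_bias(coverage_track(smp$g1), fit)
  expect_equal(corrected$variant, "corrected")
  expect_true(all(corrected$values > 0))
  d1 <- (lens[1] - 1) - (seq_len(lens[1]) - 1)
  slope <- coef(lm(log(corrected$values) ~ d1))[2]
  expect_lt(abs(slope), 1e-6)

  fit0 <- fit
  fit0$beta0 <- 0; fit0$beta_d <- 0; fit0$beta_r <- 0; fit0$beta_dr <- 0
  same <- correct_3prime_bias(coverage_track(smp$g1), fit0)
  expect_equal(same$values, smp$g1)
})

test_that("region classification thirds: worked example and disjointness", {
  v <- find_valleys(worked)
  regions <- classify_regions(worked, v)
  # range 2..12: low cutoff 5.33 -> position 3; high cutoff 8.67 -> 1 and 5
  expect_equal(regions$low, cbind(start = 3, end = 4))
  expect_equal(regions$high, cbind(start = c(1, 5), end = c(2, 6)))

  const <- classify_regions(rep(4, 50), find_valleys(rep(4, 50)))
  expect_equal(nrow(const$low), 0)
  expect_equal(nrow(const$high), 0)

  set.seed(17)
  for (rep in 1:10) {
    x <- smooth_track(rpois(800, 30) + 40 * sin(seq_len(800) / 60), 30)$values
    reg <- classify_regions(x, find_valleys(x))
    low_pos <- unlist(apply(reg$low, 1, function(iv) seq.int(iv[1], iv[2] - 1), simplify = FALSE))
    high_pos <- unlist(apply(reg$high, 1, function(iv) seq.int(iv[1], iv[2] - 1), simplify = FALSE))
    expect_equal(length(intersect(low_pos, high_pos)), 0)
  }
})

test_that("valley tables serialize one row per valley with the gene score", {
  v <- find_valleys(worked)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_valley_table(list(gX = v), c(gX = 14 / 47), path)
  df <- read.delim(path)
  expect_equal(df$gene, "gX")
  expect_equal(df$water, 14)
  expect_equal(df$gvs, 14 / 47, tolerance = 1e-9)
})
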