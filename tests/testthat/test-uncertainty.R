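test_that("normal_from_ci recovers the implied standard deviation", {
  spec <- dist_normal_ci(-0.067, -0.101, -0.032)
  sd_implied <- (-0.032 - (-0.101)) / (2 * qnorm(0.975))
  expect_equal(sd_implied, 0.017602, tolerance = 1e-4)
  set.seed(1)
  x <- sample_dist(spec, 2e5)
  expect_equal(mean(x), -0.067, tolerance = 2e-4)
  expect_equal(sd(x), sd_implied, tolerance = 0.01)
})

test_that("the ±25 % Pert is centred on its mode and bounded", {
  spec <- dist_pert_pm25(10)
  expect_equal((spec$params$min + 4 * spec$params$mode + spec$params$max) / 6,
               10)   # Pert mean (min + 4 mode + max)/6
  set.seed(2)
  x <- sample_dist(spec, 2e5)
  expect_true(all(x >= 7.5 & x <= 12.5))
  expect_equal(mean(x), 10, tolerance = 0.01)
})

test_that("fixed distributions always return their value", {
  expect_identical(sample_dist(dist_fixed(42), 5), rep(42, 5))
})

test_that("invalid distribution parameters are rejected", {
  expect_error(dist_pert(5, 2, 10), "min <= mode <= max")
  expect_error(dist_normal_ci(0, 1, 1), "ci_low < ci_high")
})

test_that("Monte Carlo runs are bit-reproducible under a fixed seed", {
  specs <- list(a = dist_pert_pm25(10), b = dist_normal_ci(0, -1, 1))
  pipe <- function(p) c(y = 2 * p$a + p$b)
  d1 <- run_monte_carlo(pipe, specs, n_draws = 100, seed = 11)
  d2 <- run_monte_carlo(pipe, specs, n_draws = 100, seed = 11)
  expect_identical(d1$params, d2$params)
  expect_identical(d1$results, d2$results)
  expect_identical(summarise_draws(d1), summarise_draws(d2))
  d3 <- run_monte_carlo(pipe, specs, n_draws = 100, seed = 12)
  expect_false(identical(d1$results, d3$results))
})

test_that("each parameter has its own stream: adding one leaves others fixed", {
  specs <- list(a = dist_pert_pm25(10), b = dist_normal_ci(0, -1, 1))
  specs_plus <- c(specs, list(c = dist_pert_pm25(5)))
  pipe <- function(p) c(y = p$a)
  d1 <- run_monte_carlo(pipe, specs, n_draws = 50, seed = 4)
  d2 <- run_monte_carlo(pipe, specs_plus, n_draws = 50, seed = 4)
  expect_identical(d1$params[, "a"], d2$params[, "a"])
  expect_identical(d1$params[, "b"], d2$params[, "b"])
})

test_that("degenerate distributions collapse the uncertainty interval", {
  specs <- list(x = dist_fixed(3))
  d <- run_monte_carlo(function(p) c(y = 2 * p$x), specs, n_draws = 50,
                       seed = 1)
  s <- summarise_draws(d)
  expect_equal(s$mean, 6)
  expect_equal(s$lo, 6)
  expect_equal(s$hi, 6)
  d1 <- run_monte_carlo(function(p) c(y = p$x + 1), list(x = dist_fixed(2)),
                        n_draws = 1, seed = 9)
  s1 <- summarise_draws(d1)
  expect_equal(c(s1$mean, s1$lo, s1$hi), rep(3, 3))
})

test_that("a linear pipeline's Monte Carlo mean matches expectation", {
  specs <- list(x = dist_pert_pm25(10))
  d <- run_monte_carlo(function(p) c(y = 2 * p$x), specs, n_draws = 20000,
                       seed = 21)
  expect_equal(mean(d$results[, "y"]), 20, tolerance = 0.1 / 20)
})

test_that("percentiles use linear interpolation between order statistics", {
  s <- summarise_draws(matrix(1:100, ncol = 1, dimnames = list(NULL, "m")))
  expect_equal(s$lo, 3.475)
  expect_equal(s$hi, 97.525)
  ## symmetric draws: mean centred between symmetric percentiles
  x <- matrix(c(-(50:1), 50:1), ncol = 1, dimnames = list(NULL, "m"))
  ss <- summarise_draws(x)
  expect_equal(ss$mean, (ss$lo + ss$hi) / 2, tolerance = 1e-12)
})

test_that("uncertainty intervals behave like 95 % intervals", {
  ## pipeline returns a sampled standard normal unchanged; the empirical
  ## 2.5-97.5 interval from 100 draws should (a) cover the true mean in
  ## nearly every experiment and (b) cover an independent draw about 95 %
  ## of the time
  n_exp <- 200
  covers_mean <- covers_draw <- logical(n_exp)
  set.seed(31)
  fresh <- rnorm(n_exp)
  for (k in seq_len(n_exp)) {
    d <- run_monte_carlo(function(p) c(x = p$x),
                         list(x = dist_normal_ci(0, -qnorm(0.975), qnorm(0.975))),
                         n_draws = 100, seed = 1000 + k)
    s <- summarise_draws(d)
    covers_mean[k] <- s$lo <= 0 && 0 <= s$hi
    covers_draw[k] <- s$lo <= fresh[k] && fresh[k] <= s$hi
  }
  expect_gte(mean(covers_mean), 0.97)
  expect_gte(mean(covers_draw), 0.90)
  expect_lte(mean(covers_draw), 0.99)
})

test_that("model errors in draws are recorded and bounded", {
  specs <- list(x = dist_normal_ci(0, -1, 1))
  boom <- function(p) if (p$x > 0) stop("bad draw") else c(y = p$x)
  expect_error(run_monte_carlo(boom, specs, n_draws = 50, seed = 2),
               "draws raised model errors")
  lenient <- run_monte_carlo(boom, specs, n_draws = 50, seed = 2,
                             max_error_rate = 1)
  expect_gt(length(lenient$errors), 0)
  expect_true(all(lenient$results[, "y"] <= 0))
})
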