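# ---- univariate outlier gate -------------------------------------------

test_that("the 3-SD rule removes a mega-hit like value in a single pass", {
  set.seed(31)
  vals <- c(rnorm(23, 4, 1.2), 20.06)
  stopifnot(abs(20.06 - mean(vals)) > 3 * sd(vals))
  out <- remove_univariate_outliers(vals)
  expect_equal(out$removed_idx, 24L)
  expect_equal(length(out$kept), 23)

  expect_equal(remove_univariate_outliers(rep(2, 10))$removed_idx, integer())

  # single pass: removing the first extreme must not unmask the second
  vals2 <- c(rep(0, 20), 5, 100)
  out2 <- remove_univariate_outliers(vals2)
  expect_equal(out2$removed_idx, 22L)
  expect_true(5 %in% out2$kept)
  # brute-force check that 5 would be flagged only on a second pass
  expect_gt(abs(5 - mean(out2$kept)) / sd(out2$kept), 3)
})

test_that("the outlier rule is scale equivariant", {
  set.seed(37)
  for (rep in 1:5) {
    v <- rnorm(30); v[sample(30, 1)] <- 8
    a <- remove_univariate_outliers(v)$removed_idx
    b <- remove_univariate_outliers(v * 17.3)$removed_idx
    expect_identical(a, b)
  }
})

# ---- Mahalanobis screen -------------------------------------------------

test_that("Mahalanobis screen flags gross multivariate outliers, never the mean", {
  set.seed(41)
  x <- matrix(rnorm(2000), ncol = 2)
  x <- rbind(x, c(10, 10))
  scr <- mahalanobis_screen(x)
  expect_equal(which.max(scr$distance2), 1001L)
  expect_true(scr$flagged[1001])

  y <- rbind(x, colMeans(x))   # append the multivariate mean
  scr2 <- mahalanobis_screen(y)
  expect_equal(scr2$distance2[nrow(y)], 0, tolerance = 1e-12)
  expect_false(scr2$flagged[nrow(y)])
})

test_that("with identity covariance the distances are squared Euclidean", {
  a <- sqrt(1.5)   # four axis points whose sample covariance is exactly I
  x <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  expect_equal(cov(x), diag(2), tolerance = 1e-12)
  scr <- mahalanobis_screen(x)
  expect_equal(scr$distance2, rowSums(x^2), tolerance = 1e-12)
})

test_that("singular covariance is refused with advice", {
  x <- cbind(1:10, (1:10) * 2)
  expect_error(mahalanobis_screen(x), "singular|reduce")
})

# ---- normality-gated correlation ---------------------------------------

test_that("Bonferroni thresholds and branch choice follow the gates", {
  set.seed(43)
  x <- rnorm(50); y <- x + rnorm(50, sd = 1e-8)
  rep_ <- gated_correlation(x, y, alpha_family = 0.05, m_tests = 8)
  expect_equal(rep_$bonferroni_alpha, 0.00625)
  expect_equal(round(rep_$bonferroni_alpha, 3), 0.006)
  expect_equal(rep_$method, "pearson")
  expect_equal(rep_$statistic, 1, tolerance = 1e-6)
  expect_true(rep_$significant)

  z <- exp(rnorm(50, sd = 1.5))   # heavy-tailed partner forces Kendall
  rep2 <- gated_correlation(x, z, m_tests = 2)
  expect_equal(rep2$method, "kendall")
  expect_equal(rep2$bonferroni_alpha, 0.025)

  expect_error(gated_correlation(x, rep(1, 50)),
               class = "neurosync_input_error")
})

test_that("the Shapiro gate sends log-normal data to Kendall almost always", {
  set.seed(47)
  n_rep <- 50
  kendall <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(50); z <- exp(rnorm(50, sd = 1.5))
    kendall[r] <- gated_correlation(x, z)$method == "kendall"
  }
  expect_gte(mean(kendall), 0.95)
})

test_that("the Pearson branch rate under bivariate normality matches the gate calibration", {
  set.seed(53)
  n_rep <- 400
  pearson <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(50); y <- 0.5 * x + rnorm(50)
    pearson[r] <- gated_correlation(x, y)$method == "pearson"
  }
  # two independent Shapiro gates at alpha 0.05 -> about 0.95^2 = 0.9025
  expect_gt(mean(pearson), 0.85)
  expect_lt(mean(pearson), 0.96)
})

# ---- popularity regression ---------------------------------------------

make_stim_table <- function(n = 24, beta0 = -19, beta_synch = 0.7,
                            beta_single = 0.75, noise_sd = 0.3,
                            seed = 1) {
  set.seed(seed)
  synchrony <- 25 + 10 * runif(n, 0.2, 0.8)
  single <- seq_len(n) <= n / 3
  mu <- beta0 + beta_synch * synchrony + beta_single * single
  tibble::tibble(
    stimulus_id = sprintf("stim%02d", seq_len(n)),
    synchrony = synchrony, single = single,
    rating = pmin(5, pmax(1, 3 + rnorm(n, sd = 0.3))),
    streams_early = exp(mu + rnorm(n, sd = noise_sd)),
    streams_late = exp(mu + log(3.2) + rnorm(n, sd = noise_sd))
  )
}

test_that("a noiseless log-linear outcome is recovered exactly on the log scale", {
  tab <- make_stim_table(noise_sd = 0, seed = 59)
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(
    fit_popularity_model(tab, outcome = "early",
                         terms = c("synchrony", "single"),
                         force_transform = TRUE))
  expect_equal(unname(coef(fit$fit)),
               c(-19, 0.7, 0.75), tolerance = 1e-9)
  expect_equal(suppressWarnings(summary(fit$fit)$adj.r.squared), 1,
               tolerance = 1e-9)
  expect_equal(fit$transform, "log")
})

test_that("the diagnostic gate triggers the log transform only when violated", {
  tab <- make_stim_table(seed = 61)
  # outcome already linear-normal in the predictor: no transform
  tab$streams_early <- 5 + 0.5 * tab$synchrony + rnorm(24, sd = 0.4)
  fit_lin <- fit_popularity_model(tab, outcome = "early",
                                  terms = "synchrony")
  expect_equal(fit_lin$transform, "none")
  expect_equal(fit_lin$multipliers, coef(fit_lin$fit))

  # strongly multiplicative outcome: residual diagnostics fail, log kicks in
  set.seed(67)
  tab2 <- make_stim_table(seed = 67)
  tab2$streams_early <- exp(-19 + 0.7 * tab2$synchrony + rnorm(24, sd = 1.3))
  fit_log <- fit_popularity_model(tab2, outcome = "early",
                                  terms = "synchrony")
  expect_equal(fit_log$transform, "log")
  b <- coef(fit_log$fit)
  expect_equal(unname(fit_log$multipliers["synchrony"]),
               unname(exp(b["synchrony"] + fit_log$sigma2 / 2)))
})

test_that("exp(b + s2/2) matches the log-normal mean prediction ratio", {
  set.seed(71)
  n <- 4000
  x <- runif(n, 0, 4)
  y <- exp(0.2 + 0.5 * x + rnorm(n, sd = 0.6))
  tab <- tibble::tibble(streams_early = y, synchrony = x,
                        stimulus_id = as.character(seq_len(n)))
  fit <- fit_popularity_model(tab, outcome = "early", terms = "synchrony",
                              force_transform = TRUE)
  # brute-force oracle: mean outcome in a thin slice at x0+1 over the
  # median-scale prediction at x0
  b <- coef(fit$fit)
  x0 <- 1.5
  slice <- abs(x - (x0 + 1)) < 0.1
  oracle <- mean(y[slice]) / exp(b[1] + b[2] * x0)
  expect_equal(unname(fit$multipliers["synchrony"]), unname(oracle),
               tolerance = 0.1)
  # and the multiplier collapses to exp(b) as the residual variance vanishes
  tab0 <- make_stim_table(noise_sd = 1e-8, beta_single = 0, seed = 73)
  fit0 <- fit_popularity_model(tab0, outcome = "early", terms = "synchrony",
                               force_transform = TRUE)
  expect_equal(unname(fit0$multipliers["synchrony"]),
               unname(exp(coef(fit0$fit)["synchrony"])), tolerance = 1e-6)
})

test_that("perfect collinearity is refused with the term names", {
  tab <- make_stim_table(seed = 79)
  tab$dup <- tab$synchrony * 2
  expect_error(fit_popularity_model(tab, outcome = "early",
                                    terms = c("synchrony", "dup")),
               class = "neurosync_input_error")
})

# ---- nested model comparison -------------------------------------------

test_that("the partial F test is calibrated under the null", {
  set.seed(83)
  n_sim <- 400
  pvals <- numeric(n_sim)
  for (r in seq_len(n_sim)) {
    tab <- tibble::tibble(
      stimulus_id = as.character(1:20),
      synchrony = rnorm(20), noisecol = rnorm(20),
      streams_early = exp(rnorm(20)))
    base <- fit_popularity_model(tab, "early", "synchrony",
                                 force_transform = TRUE)
    ext <- fit_popularity_model(tab, "early", c("synchrony", "noisecol"),
                                force_transform = TRUE)
    pvals[r] <- compare_nested(base, ext)$p.value
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the F test detects a real single-release effect at n = 23", {
  n_rep <- 200
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- make_stim_table(n = 23, seed = 5000 + r)
    base <- fit_popularity_model(tab, "late", "synchrony",
                                 force_transform = TRUE)
    ext <- fit_popularity_model(tab, "late", c("synchrony", "single"),
                                force_transform = TRUE)
    reject[r] <- compare_nested(base, ext)$p.value < 0.05
  }
  expect_gt(mean(reject), 0.8)
})

test_that("nested comparison guards its preconditions and the F = 0 edge", {
  tab <- make_stim_table(seed = 89)
  base <- fit_popularity_model(tab, "early", "synchrony",
                               force_transform = TRUE)
  ext <- fit_popularity_model(tab, "early", c("synchrony", "single"),
                              force_transform = TRUE)
  expect_error(compare_nested(ext, base), class = "neurosync_input_error")
  other <- fit_popularity_model(tab, "late", c("synchrony", "single"),
                                force_transform = TRUE)
  expect_error(compare_nested(base, other), class = "neurosync_input_error")

  # F = 0 boundary: an added term constructed orthogonal to the base
  # residuals contributes exactly nothing
  base2 <- fit_popularity_model(tab, "early", "synchrony",
                                force_transform = TRUE)
  e <- residuals(base2$fit)
  set.seed(97)
  z <- rnorm(nrow(tab))
  tab$nullterm <- z - e * sum(z * e) / sum(e^2)
  ext2 <- fit_popularity_model(tab, "early", c("synchrony", "nullterm"),
                               force_transform = TRUE)
  cmp <- compare_nested(base2, ext2)
  expect_lt(cmp$statistic, 1e-10)
  expect_gt(cmp$p.value, 0.999)
})
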