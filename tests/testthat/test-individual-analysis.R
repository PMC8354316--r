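# all-subsets AIC oracle used against the stepwise search
all_subsets_aic <- function(data, outcome, candidates, family = "linear") {
  subsets <- unlist(lapply(0:length(candidates), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  vapply(subsets, function(terms) {
    fml <- stats::as.formula(paste(
      outcome, "~", if (length(terms)) paste(terms, collapse = "+") else "1"))
    if (family == "linear") stats::AIC(stats::lm(fml, data = data))
    else stats::AIC(stats::glm(fml, data = data, family = binomial()))
  }, numeric(1))
}

test_that("likeability correlations use Kendall with the 0.025 threshold", {
  set.seed(101)
  n <- 200
  responses <- tibble::tibble(
    rating = sample(1:5, n, replace = TRUE),
    engagement = runif(n)
  )
  responses$faa <- as.numeric(responses$rating)   # tau = 1 case
  reps <- likeability_correlations(responses)
  expect_equal(reps$bonferroni_alpha, rep(0.025, 2))
  expect_equal(reps$method, rep("kendall", 2))
  faa_row <- reps[reps$pair == "faa~rating", ]
  expect_equal(faa_row$statistic, 1)
  expect_true(faa_row$significant)
  expect_error(
    likeability_correlations(dplyr::mutate(responses, faa = 1)),
    class = "neurosync_input_error")
})

test_that("synthetic FAA shares valence with ratings strongly enough to detect", {
  n_seed <- 8
  ok <- logical(n_seed)
  for (s in seq_len(n_seed)) {
    cfg <- study_config(n_subjects = 8, n_stimuli = 24, duration_s = 4,
                        channels = c("F3", "F4"), artifact_rate = 0,
                        seed = 400 + s)
    sim <- simulate_eeg(cfg)
    tab <- simulate_outcomes(sim$truth, cfg)
    faa_tbl <- faa_study(band_power_study(sim$recordings))
    resp <- dplyr::left_join(tab$responses, faa_tbl,
                             by = c("subject_id", "stimulus_id"))
    rep_ <- likeability_correlations(resp, metrics = "faa", m_tests = 2)
    ok[s] <- rep_$statistic > 0 && rep_$p.value < 0.025
  }
  expect_gte(mean(ok), 7 / 8)
})

test_that("genre binarization counts pop-first subjects and enforces rank permutations", {
  genres <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:3),
                               genre = c("rock", "pop", "alternative",
                                         "hiphop_rap", "jazz_blues", "rnb"))
  # genre column order per subject: rock, pop, alternative, hiphop_rap,
  # jazz_blues, rnb -> s01 pop-first, s02 rock-first, s03 rnb-first
  genres$rank <- c(2, 1, 3, 4, 5, 6,  1:6,  6:1)
  flags <- binarize_genre(genres)
  expect_equal(flags$pop_fan, c(TRUE, FALSE, FALSE))

  tie <- genres
  tie$rank[tie$subject_id == "s02"] <- c(1, 1, 2, 3, 4, 5)
  expect_error(binarize_genre(tie), class = "neurosync_validation_error")
  unknown <- genres
  unknown$genre[1] <- "polka"
  expect_error(binarize_genre(unknown), class = "neurosync_validation_error")
})

test_that("a dominant orthogonal term is selected in one step with the global AIC minimum", {
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  x3 <- rep(c(-1, -1, 1, 1), times = n / 4)
  data <- tibble::tibble(rating = 3 + 2 * x1, x1 = x1, x2 = x2, x3 = x3)
  sw <- stepwise_aic(data, outcome = "rating",
                     candidates = c("x1", "x2", "x3"))
  expect_equal(sw$terms, "x1")
  expect_equal(nrow(sw$trace), 2)        # start + one addition
  expect_equal(sw$aic, min(all_subsets_aic(data, "rating",
                                           c("x1", "x2", "x3"))))
})

test_that("pure-noise candidates are rarely selected and stepwise matches all-subsets", {
  n_sim <- 200
  included <- matrix(NA, n_sim, 2)
  matches <- logical(n_sim)
  for (r in seq_len(n_sim)) {
    set.seed(6000 + r)
    data <- tibble::tibble(rating = rnorm(50), z1 = rnorm(50),
                           z2 = rnorm(50))
    sw <- stepwise_aic(data, outcome = "rating", candidates = c("z1", "z2"))
    included[r, ] <- c("z1", "z2") %in% sw$terms
    matches[r] <- isTRUE(all.equal(
      sw$aic, min(all_subsets_aic(data, "rating", c("z1", "z2")))))
  }
  expect_lt(mean(included), 0.25)        # AIC's known false-inclusion rate
  expect_gte(mean(matches), 0.95)
})

test_that("true effects are found and null effects excluded with strong signals", {
  n_seed <- 20
  hit <- logical(n_seed)
  for (s in seq_len(n_seed)) {
    set.seed(7000 + s)
    n <- 720
    data <- tibble::tibble(
      engagement = runif(n), faa = rnorm(n),
      single = sample(c(TRUE, FALSE), n, replace = TRUE),
      artist = sample(c("a", "b"), n, replace = TRUE),
      pop_fan = sample(c(TRUE, FALSE), n, replace = TRUE))
    data$rating <- 3 - 1.8 * data$engagement + 0.5 * data$single +
      rnorm(n, sd = 0.8)
    sw <- stepwise_aic(data, outcome = "rating")
    hit[s] <- all(c("engagement", "single") %in% sw$terms) &&
      !"faa" %in% sw$terms
  }
  expect_gte(mean(hit), 0.8)
})

test_that("selection is invariant to candidate ordering for orthogonal designs", {
  n <- 32
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  set.seed(103)
  data <- tibble::tibble(rating = 1.5 * x1 - 0.8 * x2 + rnorm(n, sd = 0.3),
                         x1 = x1, x2 = x2)
  a <- stepwise_aic(data, outcome = "rating", candidates = c("x1", "x2"))
  b <- stepwise_aic(data, outcome = "rating", candidates = c("x2", "x1"))
  expect_setequal(a$terms, b$terms)
  expect_equal(a$aic, b$aic)
})

test_that("the trace is monotone down to the final AIC", {
  cfg <- study_config(n_subjects = 10, n_stimuli = 12, duration_s = 2,
                      seed = 107)
  tab <- simulate_outcomes(simulate_eeg(cfg)$truth, cfg)
  data <- dplyr::left_join(tab$responses,
                           tab$stimuli[c("stimulus_id", "single", "artist")],
                           by = "stimulus_id")
  data$faa <- rnorm(nrow(data))
  sw <- stepwise_aic(data, outcome = "rating",
                     candidates = c("engagement", "faa", "single", "artist"))
  expect_true(all(diff(sw$trace$aic) < 0))
  expect_equal(sw$aic, min(sw$trace$aic))
})

test_that("logistic separation falls back to the linear family with a flag", {
  n <- 40
  x <- c(rnorm(20, -3), rnorm(20, 3))
  data <- tibble::tibble(rating = ifelse(x > 0, 5L, 1L), x = x,
                         z = rnorm(n))
  suppressWarnings(expect_warning(
    sw <- stepwise_aic(data, outcome = "rating", candidates = c("x", "z"),
                       family = "logistic"),
    "separation"))
  expect_equal(sw$family, "linear")
  expect_true(sw$fallback)

  # a well-behaved logistic problem stays logistic
  set.seed(109)
  x2 <- rnorm(300)
  data2 <- tibble::tibble(
    rating = ifelse(runif(300) < plogis(0.8 * x2), 5L, 2L),
    x = x2, z = rnorm(300))
  sw2 <- stepwise_aic(data2, outcome = "rating", candidates = c("x", "z"),
                      family = "logistic")
  expect_equal(sw2$family, "logistic")
  expect_false(sw2$fallback)
  expect_true("x" %in% sw2$terms)
})

test_that("the stepwise search agrees with the reference implementation", {
  set.seed(131)
  n <- 100
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$rating <- 2 + 1.2 * d$x1 - 0.7 * d$x2 + rnorm(n)
  sw <- stepwise_aic(d, outcome = "rating", candidates = c("x1", "x2", "x3"))
  ref <- MASS::stepAIC(lm(rating ~ 1, data = d),
                       scope = list(lower = ~1, upper = ~ x1 + x2 + x3),
                       direction = "both", trace = 0)
  expect_setequal(sw$terms, attr(terms(ref), "term.labels"))
})
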