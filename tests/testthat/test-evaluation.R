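test_that("horizon labels follow the event-by/event-free/inevaluable rule", {
  surv <- surv_df(time = c(2, 2, 3, 5, 3), event = c(1, 0, 0, 1, 1))
  lab <- horizon_labels(surv, 3)
  expect_equal(as.character(lab),
               c("event_by_t", "inevaluable", "event_free_at_t",
                 "event_free_at_t", "event_by_t"))
  expect_error(horizon_labels(surv, 0), "positive")
})

test_that("horizon AUC matches the pairwise-enumeration oracle, with sane boundary cases", {
  # perfect separation
  surv <- surv_df(time = c(1, 2, 5, 6), event = c(1, 1, 0, 0))
  surv$time <- c(1, 2, 5, 6)
  lab <- horizon_labels(surv, 4)
  hm <- horizon_metrics(c(9, 8, 1, 2), lab)
  expect_equal(hm$auc, 1)

  # constant scores: all ties
  expect_equal(horizon_metrics(rep(1, 4), lab)$auc, 0.5)

  # single class flagged
  surv1 <- surv_df(time = c(1, 2), event = c(1, 1))
  expect_true(horizon_metrics(c(1, 2), horizon_labels(surv1, 5))$flagged)

  # mixed 12-sample case vs brute-force pair counting
  set.seed(30)
  for (rep in 1:10) {
    n <- 12
    time <- runif(n, 0, 10)
    event <- rbinom(n, 1, 0.6)
    s <- sample(c(rnorm(n - 3), rnorm(3)))  # include some spread
    s[1:2] <- s[3:4]                        # force score ties
    surv <- surv_df(time, event)
    lab <- horizon_labels(surv, 5)
    ev <- lab != "inevaluable"
    y <- as.numeric(lab[ev] == "event_by_t")
    if (length(unique(y)) < 2) next
    hm <- horizon_metrics(s, lab)
    expect_equal(hm$auc, oracle_auc(s[ev], y))
    expect_true(hm$auc >= hm$auc_ci[1] && hm$auc <= hm$auc_ci[2])
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(31)
  surv <- surv_df(runif(30, 0, 10), rbinom(30, 1, 0.6))
  s <- rnorm(30)
  lab <- horizon_labels(surv, 5)
  a1 <- horizon_metrics(s, lab)$auc
  expect_equal(horizon_metrics(exp(2 * s), lab)$auc, a1)
  expect_equal(horizon_metrics(rank(s), lab)$auc, a1)
})

test_that("time-dependent AUC reduces to the horizon AUC without censoring", {
  set.seed(32)
  n <- 40
  s <- rnorm(n)
  time <- rexp(n, 0.2 * exp(0.8 * s))
  surv <- surv_df(time, rep(1, n))
  t0 <- stats::median(time)
  td <- time_dependent_auc(s, surv, t0)
  hm <- horizon_metrics(s, horizon_labels(surv, t0))
  expect_lt(abs(td$auc - hm$auc), 1e-10)
})

test_that("time-dependent AUC equals the hand-weighted IPCW oracle under censoring", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 25
    s <- rnorm(n)
    time <- rexp(n, 0.2 * exp(0.6 * s))
    cens <- rexp(n, 0.15)
    surv <- surv_df(pmin(time, cens), as.numeric(time <= cens))
    for (t0 in stats::quantile(surv$time, c(0.3, 0.6), names = FALSE)) {
      td <- time_dependent_auc(s, surv, t0)
      if (is.na(td$auc)) next
      expect_equal(td$auc, oracle_td_auc(s, surv$time, surv$event, t0),
                   tolerance = 1e-10)
    }
  }
  # grid times beyond follow-up are dropped with a warning
  surv <- surv_df(c(1, 2, 3), c(1, 1, 0))
  expect_warning(time_dependent_auc(c(3, 2, 1), surv, c(1.5, 99)),
                 "dropped")
})

test_that("null scores give time-dependent AUC near one half", {
  set.seed(34)
  aucs <- replicate(30, {
    n <- 120
    time <- rexp(n, 0.2)
    cens <- rexp(n, 0.1)
    surv <- surv_df(pmin(time, cens), as.numeric(time <= cens))
    mean(time_dependent_auc(rnorm(n), surv,
                            stats::quantile(surv$time, c(0.3, 0.5, 0.7),
                                            names = FALSE))$auc)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("prediction error has the right closed forms and matches the IPCW oracle", {
  # perfect predictions: error 0
  surv <- surv_df(c(1, 2, 6, 7), c(1, 1, 1, 1))
  S <- matrix(c(0, 0, 1, 1), ncol = 1)   # survival prob at t = 4
  pe <- prediction_error(surv, 4, surv_prob = S)
  expect_equal(pe$error, 0)

  # coin-flip predictions, no censoring: error 1/4
  Shalf <- matrix(0.5, nrow = 4, ncol = 1)
  pe2 <- prediction_error(surv, 4, surv_prob = Shalf)
  expect_equal(pe2$error, 0.25)

  # censored toy data vs hand-weighted oracle
  set.seed(35)
  for (rep in 1:5) {
    n <- 20
    s <- rnorm(n)
    time <- rexp(n, 0.2 * exp(0.5 * s))
    cens <- rexp(n, 0.15)
    surv <- surv_df(pmin(time, cens), as.numeric(time <= cens))
    t0 <- stats::median(surv$time)
    Sm <- matrix(stats::runif(n), ncol = 1)
    pe3 <- prediction_error(surv, t0, surv_prob = Sm)
    expect_equal(pe3$error, oracle_brier(Sm[, 1], surv$time, surv$event, t0),
                 tolerance = 1e-10)
  }

  # score-based path runs end to end
  set.seed(36)
  n <- 60
  s <- rnorm(n)
  time <- rexp(n, 0.2 * exp(0.7 * s))
  cens <- rexp(n, 0.1)
  surv <- surv_df(pmin(time, cens), as.numeric(time <= cens))
  pe4 <- prediction_error(surv, stats::quantile(surv$time, c(0.3, 0.6),
                                                names = FALSE), scores = s)
  expect_true(all(pe4$error >= 0 & pe4$error <= 1))
})

test_that("univariable odds ratios equal the cross-product ratio and the logistic fit", {
  # symmetric table: no association
  sym <- matrix(c(50, 50, 50, 50), nrow = 2,
                dimnames = list(c("neg", "pos"), NULL))
  expect_equal(unname(univariable_or(sym)$odds_ratio), 1)

  # random 2x2 tables: cross-product identity and glm agreement
  set.seed(37)
  for (rep in 1:8) {
    tab <- matrix(sample(5:200, 4), nrow = 2,
                  dimnames = list(c("a", "b"), NULL))
    res <- univariable_or(tab)
    expect_equal(unname(res$odds_ratio),
                 unname((tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])),
                 tolerance = 1e-12)
    # same numbers from raw vectors through the logistic route
    x <- rep(rep(c("a", "b"), each = 2), times = as.numeric(t(tab)))
    y <- rep(rep(c(0, 1), 2), times = as.numeric(t(tab)))
    fit <- stats::glm(y ~ factor(x), family = stats::binomial())
    expect_equal(unname(res$odds_ratio), unname(exp(coef(fit)[2])),
                 tolerance = 1e-6)
    expect_equal(unname(res$p),
                 unname(summary(fit)$coefficients[2, 4]), tolerance = 1e-6)
  }

  # k-level exposure with an explicit reference
  tab3 <- matrix(c(133, 221, 158, 36, 173, 116), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
  res3 <- univariable_or(tab3, reference = "g1")
  expect_equal(unname(res3$odds_ratio["g2"]), (173 * 133) / (36 * 221),
               tolerance = 1e-12)

  # zero cell: flagged, no continuity correction
  z <- matrix(c(10, 0, 5, 5), nrow = 2, dimnames = list(c("a", "b"), NULL))
  rz <- univariable_or(z)
  expect_true(rz$flagged)
  expect_true(is.infinite(rz$odds_ratio) || rz$odds_ratio == 0 ||
                is.nan(rz$odds_ratio))
})

test_that("evaluate_model assembles a coherent report", {
  set.seed(38)
  n <- 150
  node <- rbinom(n, 1, 0.2)
  s <- rnorm(n)
  time <- rexp(n, 0.12 * exp(0.8 * s + 0.5 * node))
  cens <- rexp(n, 0.07)
  surv <- surv_df(pmin(time, cens), as.numeric(time <= cens), node = node)
  scores <- data.frame(sample_id = surv$sample_id, score = s,
                       group = ifelse(s > 0, "high", "low"),
                       stringsAsFactors = FALSE)
  rep <- evaluate_model(scores, surv, horizons = c(3, 5, 10))
  expect_true(all(rep$horizons$auc >= 0 & rep$horizons$auc <= 1,
                  na.rm = TRUE))
  expect_true(all(rep$horizons$n_evaluable <= n))
  expect_gt(rep$risk_group$hr_high_vs_low, 1)
  expect_true(all(diff(rep$td_auc$time) > 0))
})
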