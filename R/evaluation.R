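#' Horizon classification labels for a censored outcome
#'
#' For a horizon `t` (years): `event_by_t` if the relapse happened at or
#' before `t`; `event_free_at_t` if follow-up reaches `t` without a prior
#' relapse; `inevaluable` if the sample was censored before `t` (its
#' status at the horizon is unknown).
#'
#' @param surv survival data.frame.
#' @param t horizon in years (> 0).
#' @return factor with levels `event_by_t`, `event_free_at_t`,
#'   `inevaluable`, one per row of `surv`.
#' @export
horizon_labels <- function(surv, t) {
  if (t <= 0) stop("horizon must be positive")
  lab <- ifelse(surv$event == 1 & surv$time <= t, "event_by_t",
                ifelse(surv$time >= t, "event_free_at_t", "inevaluable"))
  factor(lab, levels = c("event_by_t", "event_free_at_t", "inevaluable"))
}

#' Horizon accuracy and AUC of a risk score
#'
#' Discrimination of the score for the binary horizon outcome among
#' evaluable samples. AUC is the rank-based concordance (tied scores
#' count 1/2) with a Hanley-McNeil confidence interval; accuracy comes
#' from a logistic regression of the label on the score, classifying at
#' predicted probability 0.5.
#'
#' @param scores numeric score vector or `risk_scores` data.frame.
#' @param labels factor from [horizon_labels()] aligned with `scores`.
#' @param conf_level CI level for the AUC (default 0.95).
#' @return list: `n_evaluable`, `n_event`, `accuracy`, `auc`, `auc_ci`,
#'   `flagged` (TRUE when only one class is evaluable; AUC undefined).
#' @export
horizon_metrics <- function(scores, labels, conf_level = 0.95) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  if (length(s) != length(labels)) stop("scores and labels must align")
  ev <- labels != "inevaluable"
  s <- s[ev]
  y <- as.numeric(labels[ev] == "event_by_t")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    return(list(n_evaluable = length(y), n_event = n1, accuracy = NA_real_,
                auc = NA_real_, auc_ci = c(NA_real_, NA_real_),
                flagged = TRUE))
  auc <- rank_auc(s, y)
  # Hanley & McNeil variance for the CI
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * sqrt(max(v, 0))))
  fit <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial()))
  pred <- stats::predict(fit, type = "response") > 0.5
  list(n_evaluable = length(y), n_event = n1,
       accuracy = mean(pred == (y == 1)), auc = auc, auc_ci = ci,
       flagged = FALSE)
}

# Mann-Whitney AUC via midranks; ties between a case and a control
# contribute 1/2.
rank_auc <- function(s, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Kaplan-Meier estimate of the censoring survivor function G(t) =
# P(censoring time > t), evaluated by left-continuous lookup so that
# G(t-) weights are available at event times.
censoring_km <- function(surv) {
  cf <- survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
  step <- stats::stepfun(cf$time, c(1, cf$surv), right = FALSE)
  list(at = function(t) pmax(step(t), 1e-12),
       before = function(t) {
         # left limit G(t-)
         pmax(vapply(t, function(ti) {
           i <- cf$time < ti
           if (!any(i)) 1 else cf$surv[max(which(i))]
         }, numeric(1)), 1e-12)
       })
}

#' Time-dependent AUC curve under censoring (IPCW, cumulative/dynamic)
#'
#' At each grid time `t`, cases are samples with an observed relapse at
#' or before `t` (weighted by `1/G(T_i-)`) and controls are samples still
#' under observation beyond `t` (weighted by `1/G(t)`), where `G` is the
#' Kaplan-Meier estimate of the censoring distribution. The AUC is the
#' weighted concordance of the score over case-control pairs (ties 1/2).
#' With no censoring the weights collapse to 1 and the curve equals the
#' uncensored horizon AUC.
#'
#' @param scores numeric vector or `risk_scores` data.frame.
#' @param surv survival data.frame aligned with `scores`.
#' @param time_grid evaluation times; points beyond the last observed
#'   time are dropped with a warning.
#' @return data.frame `time`, `auc`, `n_case`, `n_control`.
#' @export
time_dependent_auc <- function(scores, surv, time_grid) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  if (length(s) != nrow(surv)) stop("scores and survival must align")
  tmax <- max(surv$time)
  drop <- time_grid > tmax
  if (any(drop)) {
    warning(sum(drop), " grid time(s) beyond the last observed time dropped")
    time_grid <- time_grid[!drop]
  }
  G <- censoring_km(surv)
  out <- lapply(time_grid, function(t) {
    case <- surv$event == 1 & surv$time <= t
    ctrl <- surv$time > t
    if (!any(case) || !any(ctrl))
      return(data.frame(time = t, auc = NA_real_, n_case = sum(case),
                        n_control = sum(ctrl)))
    wi <- 1 / G$before(surv$time[case])
    wj <- rep(1 / G$at(t), sum(ctrl))
    si <- s[case]; sj <- s[ctrl]
    conc <- outer(si, sj, ">") + 0.5 * outer(si, sj, "==")
    num <- sum(conc * outer(wi, wj))
    den <- sum(wi) * sum(wj)
    data.frame(time = t, auc = num / den, n_case = sum(case),
               n_control = sum(ctrl))
  })
  do.call(rbind, out)
}

#' IPCW prediction-error (Brier) curve
#'
#' Expected squared error of predicted survival probabilities at each
#' grid time, reweighted for censoring: samples observed past `t` compare
#' `1 - S_i(t)` squared with weight `1/G(t)`; samples with a relapse by
#' `t` compare `S_i(t)` squared with weight `1/G(T_i-)`; samples censored
#' before `t` contribute zero. Predicted survival either comes from a
#' supplied matrix or is derived from a Cox model of the outcome on the
#' score with a Breslow baseline.
#'
#' @param surv survival data.frame.
#' @param time_grid evaluation times.
#' @param surv_prob optional matrix (samples x grid times) of predicted
#'   survival probabilities; when `NULL`, derived from `scores`.
#' @param scores score vector or `risk_scores` data.frame (used when
#'   `surv_prob` is `NULL`).
#' @return data.frame `time`, `error`.
#' @export
prediction_error <- function(surv, time_grid, surv_prob = NULL,
                             scores = NULL) {
  tmax <- max(surv$time)
  drop <- time_grid > tmax
  if (any(drop)) {
    warning(sum(drop), " grid time(s) beyond the last observed time dropped")
    time_grid <- time_grid[!drop]
    if (!is.null(surv_prob)) surv_prob <- surv_prob[, !drop, drop = FALSE]
  }
  if (is.null(surv_prob)) {
    if (is.null(scores)) stop("provide surv_prob or scores")
    s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
    df <- data.frame(time = surv$time, event = surv$event, s = s)
    fit <- survival::coxph(survival::Surv(time, event) ~ s, data = df)
    sf <- survival::survfit(fit, newdata = df)
    surv_prob <- vapply(seq_along(time_grid), function(k) {
      as.numeric(summary(sf, times = time_grid[k], extend = TRUE)$surv)
    }, numeric(nrow(surv)))
    surv_prob <- matrix(surv_prob, nrow = nrow(surv))
  }
  G <- censoring_km(surv)
  err <- vapply(seq_along(time_grid), function(k) {
    t <- time_grid[k]
    S <- surv_prob[, k]
    w <- numeric(nrow(surv))
    alive <- surv$time > t
    dead <- surv$event == 1 & surv$time <= t
    w[alive] <- 1 / G$at(t)
    w[dead] <- 1 / G$before(surv$time[dead])
    contrib <- numeric(nrow(surv))
    contrib[alive] <- (1 - S[alive])^2
    contrib[dead] <- S[dead]^2
    sum(w * contrib) / nrow(surv)
  }, numeric(1))
  data.frame(time = time_grid, error = err)
}

#' Univariable odds ratio (contingency table / logistic regression)
#'
#' For a binary factor the OR is the exact cross-product ratio of the
#' 2x2 table, identical to the exponentiated univariable logistic
#' coefficient; for a k-level factor each non-reference level gets its OR
#' against the reference level. p-values are Wald tests from the
#' logistic fit.
#'
#' @param x exposure: factor/vector, or a counts matrix (levels x 2 with
#'   columns ordered `y = 0`, `y = 1`) when `y` is missing.
#' @param y binary outcome vector (0/1) aligned with `x`.
#' @param reference reference level of `x` (default: first level).
#' @return object of class `contingency_result`: `odds_ratio` (named, per
#'   non-reference level), `p`, `counts`, `reference`, `flagged` (zero
#'   cell).
#' @export
univariable_or <- function(x, y = NULL, reference = NULL) {
  if (is.null(y)) {
    counts <- as.matrix(x)
    if (ncol(counts) != 2) stop("counts matrix must have 2 outcome columns")
    if (is.null(rownames(counts)))
      rownames(counts) <- paste0("level", seq_len(nrow(counts)))
    colnames(counts) <- c("y0", "y1")
  } else {
    if (!all(y %in% c(0, 1))) stop("y must be 0/1")
    counts <- table(factor(x), factor(y, levels = c(0, 1)))
    counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                     dimnames = list(rownames(counts), c("y0", "y1")))
  }
  if (nrow(counts) < 2) stop("exposure needs at least 2 levels")
  if (any(colSums(counts) == 0)) stop("both outcome levels must be present")
  if (!is.null(reference)) {
    if (!reference %in% rownames(counts)) stop("unknown reference level")
    ord <- c(reference, setdiff(rownames(counts), reference))
    counts <- counts[ord, , drop = FALSE]
  }
  ref <- counts[1L, ]
  lev <- rownames(counts)[-1L]
  or <- vapply(lev, function(l) {
    (counts[l, "y1"] * ref[["y0"]]) / (counts[l, "y0"] * ref[["y1"]])
  }, numeric(1))
  flagged <- any(counts == 0)
  # Wald p from the logistic fit on expanded data
  expand <- data.frame(
    x = factor(rep(rownames(counts), times = rowSums(counts)),
               levels = rownames(counts)),
    y = unlist(lapply(rownames(counts), function(l)
      rep(c(0, 1), times = counts[l, ])))
  )
  p <- rep(NA_real_, length(lev))
  names(p) <- lev
  if (!flagged) {
    fit <- stats::glm(y ~ x, data = expand, family = stats::binomial())
    cf <- summary(fit)$coefficients
    rn <- paste0("x", lev)
    p[] <- cf[rn, "Pr(>|z|)"]
  }
  structure(list(odds_ratio = or, p = p, counts = counts,
                 reference = rownames(counts)[1L], flagged = flagged),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("univariable odds ratios (reference: ", x$reference, ")\n", sep = "")
  print(data.frame(OR = x$odds_ratio, p = x$p))
  invisible(x)
}

#' Full evaluation report for a risk-score model
#'
#' Convenience wrapper producing the per-horizon accuracy/AUC table, the
#' IPCW time-dependent AUC and prediction-error curves, and the
#' node-adjusted risk-group hazard ratios.
#'
#' @param scores `risk_scores` data.frame.
#' @param surv survival data.frame aligned with `scores`.
#' @param horizons horizon years (default `c(3, 5, 10, 15)`).
#' @param grid_n number of grid points for the time-dependent curves.
#' @param adjust adjustment covariates for the risk-group HRs.
#' @return list of class `evaluation_report`: `horizons` (data.frame),
#'   `td_auc`, `pred_error`, `risk_group`.
#' @export
evaluate_model <- function(scores, surv, horizons = c(3, 5, 10, 15),
                           grid_n = 25, adjust = "node") {
  surv <- surv[match(scores$sample_id, surv$sample_id), , drop = FALSE]
  horizons <- horizons[horizons <= max(surv$time)]
  htab <- do.call(rbind, lapply(horizons, function(t) {
    hm <- horizon_metrics(scores, horizon_labels(surv, t))
    data.frame(horizon = t, n_evaluable = hm$n_evaluable,
               accuracy = hm$accuracy, auc = hm$auc,
               auc_lo = hm$auc_ci[1], auc_hi = hm$auc_ci[2])
  }))
  grid <- seq(min(surv$time[surv$event == 1]), max(surv$time),
              length.out = grid_n)
  structure(list(horizons = htab,
                 td_auc = time_dependent_auc(scores, surv, grid),
                 pred_error = prediction_error(surv, grid, scores = scores),
                 risk_group = risk_group_hr(scores, surv, adjust = adjust)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("horizon metrics:\n")
  print(x$horizons, row.names = FALSE)
  cat(sprintf("risk groups: HR(high vs low) = %.3f, HR(continuous) = %.3f\n",
              x$risk_group$hr_high_vs_low, x$risk_group$hr_continuous))
  invisible(x)
}
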