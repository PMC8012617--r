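#' Partial Cox regression: mutually uncorrelated prognostic components
#'
#' Dimension reduction for censored outcomes in the spirit of partial
#' least squares. Genes are centered; at each step k every current
#' residual gene is regressed on the outcome by univariable Cox and the
#' component `chi_k` is the weight-averaged combination of the residual
#' genes (weights proportional to the univariable Cox coefficients,
#' normalized to unit length). Each gene is then residualized on `chi_k`
#' by least squares before the next step, which makes the in-sample
#' component scores exactly mutually uncorrelated. Each component gets a
#' univariable Cox p; components with p < 0.05 are selected and their
#' joint Cox fit supplies the coefficients `beta_k` of the risk score
#' `score_i = sum_k beta_k chi_ik`.
#'
#' @param X gene panel, either genes x samples (expression-matrix
#'   orientation, default) with gene row names, or samples x genes with
#'   `samples_in_rows = TRUE`.
#' @param surv survival data.frame aligned with the samples of `X`.
#' @param n_components number of components to extract (default
#'   `min(panel size, 5)`); extraction stops early on a degenerate
#'   all-zero-weight component, with the count recorded.
#' @param samples_in_rows orientation flag for `X`.
#' @param alpha component selection level (univariable Cox p), default
#'   0.05.
#' @return object of class `partial_cox`: `gene_names`, `center`
#'   (training means), `loadings` (genes x components: maps centered
#'   expression to component scores), `scores` (training samples x
#'   components), `component_beta`, `component_p`, `selected`, `cutoff`
#'   (0), `n_requested`, `n_extracted`.
#' @export
fit_partial_cox <- function(X, surv, n_components = NULL,
                            samples_in_rows = FALSE, alpha = 0.05) {
  Xs <- if (samples_in_rows) as.matrix(X) else t(as.matrix(X))
  if (is.null(colnames(Xs))) stop("gene panel needs gene names")
  if (nrow(Xs) != nrow(surv)) stop("panel samples must align with survival")
  if (sum(surv$event) < 2) stop("need at least 2 events")
  sds <- apply(Xs, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s) in panel: ",
         paste(colnames(Xs)[sds == 0], collapse = ", "))
  p_genes <- ncol(Xs)
  if (is.null(n_components)) n_components <- min(p_genes, 5L)
  if (n_components < 1 || n_components > p_genes)
    stop("n_components must be in 1..panel size")
  center <- colMeans(Xs)
  Xc <- sweep(Xs, 2L, center)
  ss <- survival::Surv(surv$time, surv$event)

  cur <- Xc                     # residualized working matrix
  B <- diag(p_genes)            # cur = Xc %*% B at every step
  loadings <- matrix(0, p_genes, 0)
  scores <- matrix(0, nrow(Xs), 0)
  for (k in seq_len(n_components)) {
    w <- vapply(seq_len(p_genes), function(j) {
      x <- cur[, j, drop = FALSE]
      if (stats::sd(x) < 1e-10) return(0)
      f <- tryCatch(univariable_coxfit(x, ss), error = function(e) NULL)
      if (is.null(f) || !is.finite(f$beta)) 0 else f$beta
    }, numeric(1))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break       # degenerate component: stop extraction
    w <- w / nw
    chi <- as.numeric(cur %*% w)
    if (stats::sd(chi) < 1e-12) break
    lk <- as.numeric(B %*% w)
    loadings <- cbind(loadings, lk)
    scores <- cbind(scores, chi)
    # residualize every gene on chi (keeps later components uncorrelated)
    cc <- as.numeric(crossprod(chi, cur) / sum(chi^2))
    cur <- cur - outer(chi, cc)
    B <- B - outer(lk, cc)
  }
  n_extracted <- ncol(loadings)
  if (!n_extracted) stop("no non-degenerate component could be extracted")
  colnames(loadings) <- colnames(scores) <-
    paste0("comp", seq_len(n_extracted))
  rownames(loadings) <- colnames(Xs)

  component_p <- vapply(seq_len(n_extracted), function(k) {
    univariable_coxfit(scores[, k, drop = FALSE], ss)$p
  }, numeric(1))
  model <- structure(list(gene_names = colnames(Xs), center = center,
                          loadings = loadings, scores = scores,
                          component_beta = rep(0, n_extracted),
                          component_p = component_p,
                          selected = rep(TRUE, n_extracted), cutoff = 0,
                          n_requested = n_components,
                          n_extracted = n_extracted,
                          surv = surv[c("sample_id", "time", "event")]),
                     class = "partial_cox")
  select_components(model, alpha = alpha)
}

# single-covariate Cox fit via the fast fitter; returns beta and Wald p
univariable_coxfit <- function(x, ss) {
  f <- survival::coxph.fit(x, ss, strata = NULL, offset = NULL,
                           init = NULL,
                           control = survival::coxph.control(eps = 1e-9,
                                                             iter.max = 100),
                           weights = NULL, method = "efron",
                           rownames = NULL)
  b <- as.numeric(f$coefficients)
  se <- sqrt(as.numeric(f$var))
  list(beta = b, se = se, p = 2 * stats::pnorm(-abs(b / se)))
}

#' Select partial-Cox components by univariable significance and refit
#'
#' Keeps components whose univariable Cox p is below `alpha` and refits
#' the joint Cox model on the retained component scores only. If no
#' component passes, the default behaviour is to retain the single
#' smallest-p component (with a warning); set `fallback = FALSE` to make
#' that situation an error instead.
#'
#' @param model fitted `partial_cox` object.
#' @param alpha selection level (default 0.05); `alpha = 1` keeps all.
#' @param fallback retain the smallest-p component when none passes.
#' @return the updated `partial_cox` model.
#' @export
select_components <- function(model, alpha = 0.05, fallback = TRUE) {
  stopifnot(inherits(model, "partial_cox"))
  sel <- model$component_p < alpha
  if (!any(sel)) {
    if (!fallback)
      stop("no component passes p < ", alpha,
           "; rerun with fallback = TRUE to retain the smallest-p component")
    warning("no component passes p < ", alpha,
            "; retaining the single smallest-p component")
    sel <- seq_along(sel) == which.min(model$component_p)
  }
  model$selected <- sel
  ss <- survival::Surv(model$surv$time, model$surv$event)
  Z <- model$scores[, sel, drop = FALSE]
  f <- survival::coxph.fit(Z, ss, strata = NULL, offset = NULL,
                           init = NULL,
                           control = survival::coxph.control(eps = 1e-9,
                                                             iter.max = 100),
                           weights = NULL, method = "efron",
                           rownames = NULL)
  beta <- rep(0, model$n_extracted)
  beta[sel] <- as.numeric(f$coefficients)
  model$component_beta <- beta
  model
}

#' @export
print.partial_cox <- function(x, ...) {
  cat(sprintf("partial Cox model: %d gene(s), %d component(s) (%d selected)\n",
              length(x$gene_names), x$n_extracted, sum(x$selected)))
  print(data.frame(beta = x$component_beta, p = x$component_p,
                   selected = x$selected,
                   row.names = colnames(x$loadings)))
  invisible(x)
}

#' Risk scores from a partial-Cox model
#'
#' `score_i = sum over selected components of beta_k * chi_ik`, where the
#' component scores of new samples are computed from expression centered
#' with the *training* means stored in the model. Patients are
#' dichotomized at the zero cut-off: `high` if score > 0, else `low`
#' (each selected component has training mean zero, so zero is the
#' natural split).
#'
#' @param model fitted `partial_cox` model.
#' @param X_new expression for the panel genes: genes x samples (default)
#'   or samples x genes with `samples_in_rows = TRUE`. All panel genes
#'   must be present.
#' @return data.frame of class `risk_scores`: `sample_id`, `score`,
#'   `group` (`"high"`/`"low"`).
#' @export
risk_score <- function(model, X_new, samples_in_rows = FALSE) {
  stopifnot(inherits(model, "partial_cox"))
  Xs <- if (samples_in_rows) as.matrix(X_new) else t(as.matrix(X_new))
  missing <- setdiff(model$gene_names, colnames(Xs))
  if (length(missing))
    stop("panel genes absent from new data: ",
         paste(missing, collapse = ", "))
  Xc <- sweep(Xs[, model$gene_names, drop = FALSE], 2L, model$center)
  sel <- model$selected
  chi <- Xc %*% model$loadings[, sel, drop = FALSE]
  score <- as.numeric(chi %*% model$component_beta[sel])
  ids <- rownames(Xs)
  if (is.null(ids)) ids <- paste0("sample", seq_along(score))
  out <- data.frame(sample_id = ids, score = score,
                    group = ifelse(score > model$cutoff, "high", "low"),
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_scores", "data.frame")
  out
}

#' Hazard ratios of a risk score, continuous and dichotomized
#'
#' Two node-adjusted Cox fits of the outcome on the risk score: once on
#' the continuous score and once on the high-vs-low indicator. If one
#' risk group is empty the categorical fit is flagged and only the
#' continuous HR is returned.
#'
#' @param scores `risk_scores` data.frame (sample_id, score, group).
#' @param surv survival data.frame.
#' @param adjust clinical adjustment columns in `surv` (default
#'   `"node"`); may be empty.
#' @return list: `hr_continuous`, `p_continuous`, `hr_high_vs_low`,
#'   `p_high_vs_low`, `fit_continuous`, `fit_group`, `degenerate_groups`.
#' @export
risk_group_hr <- function(scores, surv, adjust = "node") {
  surv <- surv[match(scores$sample_id, surv$sample_id), , drop = FALSE]
  if (anyNA(surv$time)) stop("scores contain samples absent from survival")
  adj <- if (length(adjust)) as.matrix(surv[, adjust, drop = FALSE]) else NULL
  ok <- if (is.null(adj)) rep(TRUE, nrow(surv)) else stats::complete.cases(adj)
  surv <- surv[ok, , drop = FALSE]
  sc <- scores[ok, , drop = FALSE]
  adj <- if (is.null(adj)) NULL else adj[ok, , drop = FALSE]
  Xc <- cbind(score = sc$score, adj)
  fc <- fit_cox(Xc, surv)
  degenerate <- length(unique(sc$group)) < 2
  if (!degenerate) {
    Xg <- cbind(high = as.numeric(sc$group == "high"), adj)
    fg <- fit_cox(Xg, surv)
  } else fg <- NULL
  list(hr_continuous = fc$hr[["score"]], p_continuous = fc$wald_p[["score"]],
       hr_high_vs_low = if (degenerate) NA_real_ else fg$hr[["high"]],
       p_high_vs_low = if (degenerate) NA_real_ else fg$wald_p[["high"]],
       fit_continuous = fc, fit_group = fg, degenerate_groups = degenerate)
}
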