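#' Fit a Cox proportional-hazards model
#'
#' Thin, validated wrapper around the partial-likelihood estimator with
#' Efron (default) or Breslow tie handling. Returns a compact fit object
#' used throughout the modeling layers: log-hazard coefficients, standard
#' errors from the observed information, two-sided Wald p-values, hazard
#' ratios, and log-likelihoods.
#'
#' @param X numeric covariate matrix, samples x covariates (column names
#'   required).
#' @param surv survival data.frame (see [validate_survival()]) whose rows
#'   align with the rows of `X`.
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_fit` with elements `covariates`, `beta`,
#'   `se`, `wald_p`, `hr`, `loglik` (c(null, fitted)), `ties`, `converged`,
#'   `n`, `n_event`.
#' @export
fit_cox <- function(X, surv, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) stop("covariate matrix needs column names")
  if (nrow(X) != nrow(surv)) stop("X rows must align with survival rows")
  if (sum(surv$event) < 2) stop("need at least 2 events to fit")
  if (any(!is.finite(X))) stop("covariates must be finite")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  fit <- survival::coxph.fit(X, survival::Surv(surv$time, surv$event),
                             strata = NULL, offset = NULL, init = NULL,
                             control = ctrl, weights = NULL,
                             method = ties, rownames = NULL)
  beta <- as.numeric(fit$coefficients)
  se <- suppressWarnings(sqrt(diag(as.matrix(fit$var))))
  # monotone likelihood / separation shows up as runaway coefficients;
  # singular designs as non-finite variance
  converged <- all(is.finite(beta)) && all(is.finite(se)) &&
    fit$iter < ctrl$iter.max && all(abs(beta) < 20)
  names(beta) <- names(se) <- colnames(X)
  structure(list(covariates = colnames(X), beta = beta, se = se,
                 wald_p = 2 * stats::pnorm(-abs(beta / se)),
                 hr = exp(beta), loglik = fit$loglik, ties = ties,
                 converged = converged, n = nrow(X),
                 n_event = sum(surv$event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties), n = %d, events = %d%s\n", x$ties, x$n,
              x$n_event, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(data.frame(beta = x$beta, se = x$se, HR = x$hr, p = x$wald_p))
  invisible(x)
}

#' Univariable Cox screen of every gene, adjusted for clinical covariates
#'
#' For each gene fits a Cox model containing the gene plus the adjuster
#' covariates (typically node status) and reports the gene's hazard ratio
#' and Wald p. Samples with missing adjuster values are dropped once for
#' the whole screen and counted. Per-gene failures are flagged, never
#' fatal.
#'
#' @param m genes x samples expression matrix.
#' @param surv survival data.frame.
#' @param adjust character vector of clinical column names in `surv` to
#'   control for (default `"node"`); may be empty.
#' @param genes subset of genes to screen (default all rows of `m`).
#' @return data.frame: gene, hr, p, beta, se, flagged; attribute
#'   `"n_dropped"` records samples lost to missing adjusters.
#' @export
univariable_screen <- function(m, surv, adjust = "node",
                               genes = rownames(m)) {
  al <- align_samples(m, surv)
  m <- al$m; surv <- al$surv
  adj <- as.matrix(surv[, adjust, drop = FALSE])
  ok <- stats::complete.cases(adj)
  n_dropped <- sum(!ok)
  m <- m[, ok, drop = FALSE]
  surv <- surv[ok, , drop = FALSE]
  adj <- adj[ok, , drop = FALSE]
  res <- lapply(genes, function(g) {
    X <- cbind(gene = m[g, ], adj)
    out <- tryCatch({
      f <- fit_cox(X, surv)
      data.frame(gene = g, hr = f$hr[["gene"]], p = f$wald_p[["gene"]],
                 beta = f$beta[["gene"]], se = f$se[["gene"]],
                 flagged = !f$converged, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gene = g, hr = NA_real_, p = NA_real_, beta = NA_real_,
                 se = NA_real_, flagged = TRUE, stringsAsFactors = FALSE)
    })
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the least-squares
#' regression of covariate j on the remaining covariates (with
#' intercept). Exactly collinear covariates get `Inf`.
#'
#' @param X numeric matrix, samples x covariates (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF needs at least 2 covariates")
  if (nrow(X) <= ncol(X)) stop("VIF needs more samples than covariates")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    y <- X[, j]
    tss <- sum((y - mean(y))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> v
  names(v) <- colnames(X)
  v
}

#' Stepwise forward Cox selection with entry/stay levels and a VIF guard
#'
#' Iterates: among candidates outside the model, find the one with the
#' smallest Wald p when added to the current model; enter it if p <= `sle`
#' and its VIF in the augmented design is <= `vif_max`; after each entry,
#' repeatedly remove the worst non-mandatory covariate with Wald p >
#' `sls`; stop when no candidate can enter. Mandatory covariates (node
#' status by default) are present from step 0 and never removed. The
#' procedure is fully deterministic.
#'
#' @param candidates character vector of candidate gene identifiers (rows
#'   of `m`).
#' @param m genes x samples expression matrix.
#' @param surv survival data.frame.
#' @param mandatory clinical column names in `surv` kept in every model
#'   (default `"node"`); samples missing a mandatory covariate are dropped
#'   with a recorded count.
#' @param sle significance level for entry (default 0.08).
#' @param sls significance level to stay (default 0.05).
#' @param vif_max maximum VIF allowed at entry (default 10).
#' @param ties tie method for the Cox fits.
#' @return list of class `stepwise_result`: `fit` (final [fit_cox()]
#'   object, or mandatory-only/`NULL` when nothing enters), `selected`
#'   (genes in the final model), `trace` (data.frame step/action/
#'   covariate/p_value/vif_at_entry), `n_dropped`.
#' @export
stepwise_forward <- function(candidates, m, surv, mandatory = "node",
                             sle = 0.08, sls = 0.05, vif_max = 10,
                             ties = "efron") {
  al <- align_samples(m, surv)
  m <- al$m; surv <- al$surv
  if (length(mandatory)) {
    mand <- as.matrix(surv[, mandatory, drop = FALSE])
    ok <- stats::complete.cases(mand)
  } else {
    mand <- NULL
    ok <- rep(TRUE, nrow(surv))
  }
  n_dropped <- sum(!ok)
  m <- m[, ok, drop = FALSE]
  surv <- surv[ok, , drop = FALSE]
  if (!is.null(mand)) mand <- mand[ok, , drop = FALSE]
  candidates <- unique(candidates)
  missing <- setdiff(candidates, rownames(m))
  if (length(missing))
    stop("candidate genes absent from matrix: ",
         paste(missing, collapse = ", "))

  design <- function(sel) {
    g <- if (length(sel)) t(m[sel, , drop = FALSE]) else NULL
    X <- cbind(g, mand)
    X
  }
  current <- character()
  pool <- candidates
  trace <- data.frame(step = integer(), action = character(),
                      covariate = character(), p_value = numeric(),
                      vif_at_entry = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(pool)) break
    # entry test: candidate's Wald p inside the augmented model
    entry <- vapply(pool, function(g) {
      X <- design(c(current, g))
      f <- tryCatch(suppressWarnings(fit_cox(X, surv, ties = ties)),
                    error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      f$wald_p[[g]]
    }, numeric(1))
    if (all(is.na(entry))) break
    # candidates in ascending p (ties by identifier); the first that passes
    # both SLE and the VIF guard enters; VIF-blocked candidates are skipped
    # for this pass and retried after the design changes
    ord <- order(entry, pool, na.last = TRUE)
    entered <- FALSE
    for (i in ord) {
      g <- pool[i]
      p <- entry[i]
      if (is.na(p) || p > sle) break  # sorted: nothing further can pass
      X <- design(c(current, g))
      v <- if (ncol(X) >= 2) vif(X)[[g]] else 1
      if (!is.finite(v) || v > vif_max) next
      step <- step + 1L
      current <- c(current, g)
      pool <- setdiff(pool, g)
      trace <- rbind(trace, data.frame(
        step = step, action = "enter", covariate = g, p_value = p,
        vif_at_entry = v, stringsAsFactors = FALSE))
      entered <- TRUE
      break
    }
    if (!entered) break
    # backward pruning at SLS: worst offender first
    repeat {
      if (!length(current)) break
      f <- fit_cox(design(current), surv, ties = ties)
      p_genes <- f$wald_p[current]
      worst <- which.max(p_genes)
      if (p_genes[worst] > sls) {
        step <- step + 1L
        g <- current[worst]
        trace <- rbind(trace, data.frame(
          step = step, action = "remove", covariate = g,
          p_value = p_genes[worst], vif_at_entry = NA_real_,
          stringsAsFactors = FALSE))
        current <- setdiff(current, g)
        pool <- setdiff(pool, g)  # removed genes do not re-enter
      } else break
    }
  }
  X <- design(current)
  fit <- if (!is.null(X) && ncol(X) >= 1 && any(apply(X, 2, stats::sd) > 0))
    fit_cox(X, surv, ties = ties) else NULL
  structure(list(fit = fit, selected = current, trace = trace,
                 mandatory = mandatory, sle = sle, sls = sls,
                 vif_max = vif_max, n_dropped = n_dropped),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("stepwise forward Cox: %d gene(s) selected (SLE %.3g, SLS %.3g, VIF < %.3g)\n",
              length(x$selected), x$sle, x$sls, x$vif_max))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
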