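#' Reference prognostic model from the seed genes only
#'
#' The baseline against which network-derived models are compared: the
#' candidate pool is exactly the seed-gene set. Genes are selected by
#' [stepwise_forward()] with node status mandatory, then condensed into a
#' [fit_partial_cox()] risk-score model.
#'
#' @param seeds character vector of seed gene identifiers.
#' @param m genes x samples expression matrix.
#' @param surv survival data.frame.
#' @param ... passed to [stepwise_forward()] (`sle`, `sls`, `vif_max`,
#'   `mandatory`).
#' @return object of class `gcn_model`: `provenance`, `threshold_r`,
#'   `pool`, `final_genes`, `stepwise`, `cox_fit`, `partial_cox`,
#'   `scores`.
#' @export
build_reference_model <- function(seeds, m, surv, ...) {
  check_seed_genes(seeds, m)
  finish_model(pool = sort(unique(seeds)), m = m, surv = surv,
               provenance = "seeds", threshold_r = NA_real_, ...)
}

#' Network-derived prognostic model at a correlation threshold
#'
#' Builds the recurrence-stratum co-expression network at `threshold_r`
#' (Spearman of seeds vs the whole matrix over samples with
#' `event == 1`), takes the union of its nodes plus all seeds as the
#' candidate pool, and fits the same stepwise + partial-Cox pipeline as
#' the reference model. Lower thresholds give larger pools; at
#' `threshold_r = 1` (no partner can qualify in continuous data) the
#' model reduces to the reference model.
#'
#' @inheritParams build_reference_model
#' @param threshold_r Spearman threshold in (0, 1].
#' @param stratum_mask logical sample mask defining the stratum the
#'   network is computed on; default is the recurrence stratum
#'   (`surv$event == 1` for samples of `m`).
#' @return `gcn_model` object (see [build_reference_model()]); also
#'   carries the `network`.
#' @export
build_gcn_model <- function(threshold_r, seeds, m, surv,
                            stratum_mask = NULL, ...) {
  check_seed_genes(seeds, m)
  al <- align_samples(m, surv)
  if (is.null(stratum_mask)) stratum_mask <- al$surv$event == 1
  rho <- spearman_profile(al$m, seeds, sample_mask = stratum_mask)
  net <- build_gcn(rho, threshold_r, stratum = "recurrence")
  pool <- sort(unique(c(network_gene_union(net), seeds)))
  res <- finish_model(pool = pool, m = m, surv = surv,
                      provenance = sprintf("gcn@%g", threshold_r),
                      threshold_r = threshold_r, ...)
  res$network <- net
  res
}

#' Stepwise network modeling (SNM)
#'
#' Pools the final genes of previously fitted models, keeps those passing
#' a node-adjusted univariable Cox filter -- p < `p_max` AND (HR >
#' `hr_hi` OR HR < `hr_lo`), strict inequalities -- and refits the
#' stepwise + partial-Cox pipeline on the survivors.
#'
#' @param models list of `gcn_model` objects.
#' @param m,surv expression matrix and survival table.
#' @param p_max univariable p ceiling (default 0.001).
#' @param hr_lo,hr_hi hazard-ratio window bounds (default 0.7 and 1.5);
#'   genes with HR inside `[hr_lo, hr_hi]` are dropped.
#' @param adjust adjustment covariates for the univariable screen.
#' @param ... passed to [stepwise_forward()].
#' @return `gcn_model` object; also carries `screen` (the univariable
#'   screen of the pooled genes) and `filtered_pool`.
#' @export
snm <- function(models, m, surv, p_max = 0.001, hr_lo = 0.7, hr_hi = 1.5,
                adjust = "node", ...) {
  if (inherits(models, "gcn_model")) models <- list(models)
  if (!length(models)) stop("need at least one input model")
  pool <- sort(unique(unlist(lapply(models, function(x) x$final_genes))))
  if (!length(pool)) stop("input models contain no selected genes")
  screen <- univariable_screen(m, surv, adjust = adjust, genes = pool)
  keep <- snm_filter(screen, p_max = p_max, hr_lo = hr_lo, hr_hi = hr_hi)
  if (!length(keep)) {
    near <- screen[order(screen$p), c("gene", "hr", "p")]
    stop("no gene passes the SNM filter; nearest misses:\n",
         paste(utils::capture.output(print(utils::head(near, 5))),
               collapse = "\n"))
  }
  res <- finish_model(pool = keep, m = m, surv = surv,
                      provenance = "snm-pool", threshold_r = NA_real_, ...)
  res$screen <- screen
  res$filtered_pool <- keep
  res
}

#' SNM gene filter on a univariable screen
#'
#' @param screen data.frame from [univariable_screen()] (columns `gene`,
#'   `hr`, `p`, `flagged`).
#' @param p_max,hr_lo,hr_hi filter parameters; strict inequalities.
#' @return character vector of passing genes (sorted).
#' @export
snm_filter <- function(screen, p_max = 0.001, hr_lo = 0.7, hr_hi = 1.5) {
  ok <- !screen$flagged & is.finite(screen$p) & is.finite(screen$hr) &
    screen$p < p_max & (screen$hr > hr_hi | screen$hr < hr_lo)
  sort(screen$gene[ok])
}

# Shared tail of every model builder: stepwise selection on the pool,
# partial-Cox risk model on the surviving genes, training-set scores.
finish_model <- function(pool, m, surv, provenance, threshold_r, ...) {
  al <- align_samples(m, surv)
  sw <- stepwise_forward(pool, al$m, al$surv, ...)
  final <- sort(sw$selected)
  if (length(final)) {
    # partial Cox sees the same samples the stepwise fit used
    keep <- if (length(sw$mandatory)) {
      stats::complete.cases(al$surv[, sw$mandatory, drop = FALSE])
    } else rep(TRUE, nrow(al$surv))
    m_fit <- al$m[, keep, drop = FALSE]
    s_fit <- al$surv[keep, , drop = FALSE]
    pc <- fit_partial_cox(m_fit[final, , drop = FALSE], s_fit)
    sc <- risk_score(pc, m_fit[final, , drop = FALSE])
  } else {
    pc <- NULL
    sc <- NULL
  }
  structure(list(provenance = provenance, threshold_r = threshold_r,
                 pool = pool, final_genes = final, stepwise = sw,
                 cox_fit = sw$fit, partial_cox = pc, scores = sc),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("prognostic model [%s]: pool %d gene(s) -> %d selected\n",
              x$provenance, length(x$pool), length(x$final_genes)))
  if (length(x$final_genes))
    cat("  ", paste(x$final_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted model (or partial-Cox model) to JSON
#'
#' Captures everything needed to score external samples: panel genes,
#' training means, loadings, component coefficients, selection mask and
#' cut-off, plus the stepwise trace when present. [read_model_json()]
#' restores a `partial_cox` object that [risk_score()] accepts.
#'
#' @param model `gcn_model` or `partial_cox` object.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  pc <- if (inherits(model, "gcn_model")) model$partial_cox else model
  stopifnot(inherits(pc, "partial_cox"))
  obj <- list(
    gene_names = pc$gene_names,
    center = as.list(pc$center),
    loadings = apply(pc$loadings, 2L, identity, simplify = FALSE),
    component_beta = pc$component_beta,
    component_p = pc$component_p,
    selected = pc$selected,
    cutoff = pc$cutoff)
  if (inherits(model, "gcn_model")) {
    obj$provenance <- model$provenance
    obj$final_genes <- model$final_genes
    if (!is.null(model$stepwise)) obj$trace <- model$stepwise$trace
    f <- model$cox_fit
    if (!is.null(f))
      obj$cox_fit <- list(covariates = f$covariates, beta = f$beta,
                          se = f$se, p = f$wald_p, hr = f$hr,
                          ties = f$ties)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json()` returns a `partial_cox` scoring object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- do.call(cbind, obj$loadings)
  rownames(loadings) <- obj$gene_names
  structure(list(gene_names = obj$gene_names,
                 center = unlist(obj$center),
                 loadings = loadings,
                 component_beta = obj$component_beta,
                 component_p = obj$component_p,
                 selected = obj$selected,
                 cutoff = obj$cutoff,
                 n_extracted = length(obj$component_beta)),
            class = "partial_cox")
}
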