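#' Configuration for the survival-expression simulator
#'
#' Describes a synthetic cohort with the statistical structure the
#' pipeline assumes: blocks of genes rank-correlated with seed genes at a
#' controllable Spearman strength, relapse times from a proportional-
#' hazards model driven by a known gene subset plus node status,
#' independent censoring calibrated to a target rate, and optional
#' additive batch shifts across datasets. Defaults mirror the study
#' conditions the pipeline targets: ~900 samples, 34 seed genes, a 38%
#' event (recurrence) fraction, 12% node-positive prevalence.
#'
#' @param n_samples number of samples (default 900).
#' @param n_genes total number of genes (default 300); must cover seeds
#'   and block partners.
#' @param n_seeds number of seed genes (default 34); seeds are named
#'   `"SEED01"`... and listed first.
#' @param correlation_blocks data.frame with columns `seed` (seed index
#'   or id), `n_partners`, `rho` (target Spearman of each partner with
#'   its seed). May be `NULL` (no correlated blocks).
#' @param prognostic data.frame with columns `gene` (id) and `log_hr`
#'   (true log hazard ratio per unit expression). May be `NULL`.
#' @param node_prevalence probability of positive node status
#'   (default 0.12).
#' @param node_log_hr log-HR of node positivity (default 0.7).
#' @param baseline list: `dist = "exponential"` with `rate` (events/year,
#'   default 0.08), or `dist = "weibull"` with `shape` and `scale`.
#' @param censoring_rate target fraction censored (default 0.62, i.e.
#'   a 38% event fraction).
#' @param n_datasets number of batches (default 1).
#' @param batch_shift additive mean shift step between consecutive
#'   batches (default 0).
#' @param rng_seed integer seed; identical configs reproduce identical
#'   datasets.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 900, n_genes = 300, n_seeds = 34,
                              correlation_blocks = NULL, prognostic = NULL,
                              node_prevalence = 0.12, node_log_hr = 0.7,
                              baseline = list(dist = "exponential",
                                              rate = 0.08),
                              censoring_rate = 0.62, n_datasets = 1,
                              batch_shift = 0, rng_seed = 1L) {
  stopifnot(n_samples >= 10, n_genes >= n_seeds, n_seeds >= 1,
            node_prevalence >= 0, node_prevalence <= 1,
            censoring_rate >= 0, censoring_rate < 1,
            n_datasets >= 1)
  if (!is.null(correlation_blocks)) {
    if (any(abs(correlation_blocks$rho) >= 1))
      stop("infeasible correlation target: |rho| must be < 1")
    if (any(correlation_blocks$n_partners < 1))
      stop("each block needs at least one partner")
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_seeds = n_seeds,
                 correlation_blocks = correlation_blocks,
                 prognostic = prognostic,
                 node_prevalence = node_prevalence,
                 node_log_hr = node_log_hr, baseline = baseline,
                 censoring_rate = censoring_rate, n_datasets = n_datasets,
                 batch_shift = batch_shift, rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# Gaussian-copula identity: the Pearson correlation of a bivariate normal
# whose Spearman correlation is rho_s.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate an expression matrix, survival table and ground truth
#'
#' Expression: independent standard Gaussians, except block partners
#' which share a latent factor with their seed; the factor loading is
#' chosen by the Gaussian-copula identity `r = 2 sin(pi rho_s / 6)` so
#' the *Spearman* correlation with the seed hits the configured target.
#' Survival: relapse times from the proportional-hazards model with
#' linear predictor `sum_g beta_g x_g + beta_node * node` on the
#' configured baseline; censoring times are exponential with the rate
#' solved numerically so the expected censored fraction (given the drawn
#' event times) equals the target. Batch shifts are additive mean offsets
#' per dataset. All randomness flows from `config$rng_seed`.
#'
#' @param config `sim_config` from [simulation_config()].
#' @return list: `expr` (genes x samples), `surv` (survival data.frame
#'   with `node` and `batch`), `truth` (list: `prognostic` data.frame,
#'   `blocks` data.frame of seed/partner memberships, `lp` true linear
#'   predictor, `censor_rate_param`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_samples
  p <- config$n_genes
  seeds <- sprintf("SEED%02d", seq_len(config$n_seeds))
  others <- sprintf("G%04d", seq_len(p - config$n_seeds))
  genes <- c(seeds, others)

  X <- matrix(stats::rnorm(p * n), nrow = p, dimnames = list(genes, NULL))
  blocks <- NULL
  cb <- config$correlation_blocks
  if (!is.null(cb)) {
    free <- others  # non-seed genes not yet claimed by a block
    rows <- list()
    for (b in seq_len(nrow(cb))) {
      seed_id <- cb$seed[b]
      if (is.numeric(seed_id)) seed_id <- seeds[seed_id]
      if (!seed_id %in% seeds) stop("unknown block seed: ", seed_id)
      k <- cb$n_partners[b]
      if (k > length(free)) stop("not enough free genes for blocks")
      partners <- free[seq_len(k)]
      free <- setdiff(free, partners)
      r <- spearman_to_pearson(cb$rho[b])
      for (g in partners)
        X[g, ] <- r * X[seed_id, ] + sqrt(1 - r^2) * stats::rnorm(n)
      rows[[b]] <- data.frame(seed = seed_id, partner = partners,
                              target_spearman = cb$rho[b],
                              stringsAsFactors = FALSE)
    }
    blocks <- do.call(rbind, rows)
  }

  node <- stats::rbinom(n, 1, config$node_prevalence)
  lp <- config$node_log_hr * node
  prog <- config$prognostic
  if (!is.null(prog)) {
    miss <- setdiff(prog$gene, genes)
    if (length(miss)) stop("prognostic genes not in panel: ",
                           paste(miss, collapse = ", "))
    for (i in seq_len(nrow(prog)))
      lp <- lp + prog$log_hr[i] * X[prog$gene[i], ]
  }

  u <- stats::runif(n)
  bl <- config$baseline
  T_event <- if (identical(bl$dist, "weibull")) {
    bl$scale * (-log(u) / exp(lp))^(1 / bl$shape)
  } else {
    -log(u) / (bl$rate * exp(lp))
  }
  # censoring: exponential rate theta solved so that the expected censored
  # fraction given the drawn event times matches the target
  # (P(C < t | T = t) = 1 - exp(-theta t))
  target <- config$censoring_rate
  if (target > 0) {
    froot <- function(theta) mean(1 - exp(-theta * T_event)) - target
    theta <- stats::uniroot(froot, lower = 1e-8, upper = 1e4,
                            extendInt = "upX")$root
    C_cens <- stats::rexp(n, rate = theta)
  } else {
    theta <- 0
    C_cens <- rep(Inf, n)
  }
  time <- pmin(T_event, C_cens)
  event <- as.numeric(T_event <= C_cens)

  batch <- rep_len(seq_len(config$n_datasets), n)
  if (config$batch_shift != 0) {
    offset <- (batch - mean(seq_len(config$n_datasets))) * config$batch_shift
    X <- X + matrix(offset, nrow = p, ncol = n, byrow = TRUE)
  }
  ids <- sprintf("S%04d", seq_len(n))
  colnames(X) <- ids
  surv <- data.frame(sample_id = ids, time = time, event = event,
                     node = node, batch = batch, stringsAsFactors = FALSE)
  truth <- list(prognostic = prog, blocks = blocks, lp = lp,
                censor_rate_param = theta, seeds = seeds)
  list(expr = X, surv = surv, truth = truth)
}

#' Canonical scenario: prognostic signal hidden outside the seed set
#'
#' A fixture encoding the mechanism the network-based models exploit:
#' most prognostic signal sits in non-seed genes that are strongly
#' rank-correlated (Spearman ~0.85) with seed genes, so a seed-only
#' model can reach it only through attenuated proxies while a
#' co-expression-network model at threshold 0.82 admits the true genes
#' into its candidate pool. 900 samples, 34 seeds, 300 genes, 38% event
#' fraction, one modestly prognostic seed (log-HR 0.4) and three strongly
#' prognostic block partners (log-HR 0.7 each); six further decoy blocks
#' at Spearman 0.80 carry no signal.
#'
#' @param rng_seed integer seed (default 20210331).
#' @return list as from [simulate_cohort()]; `truth$config` holds the
#'   generating configuration.
#' @export
make_paper_like_scenario <- function(rng_seed = 20210331) {
  blocks <- data.frame(
    seed = c(2, 3, 4, 5, 6, 7, 8, 9, 10),
    n_partners = c(4, 4, 4, 3, 3, 3, 3, 3, 3),
    rho = c(0.85, 0.85, 0.85, 0.80, 0.80, 0.80, 0.80, 0.80, 0.80))
  # first partner of each 0.85-block carries the true effect; partners are
  # assigned to blocks in order, so their ids are deterministic
  prognostic <- data.frame(
    gene = c("SEED01", "G0001", "G0005", "G0009"),
    log_hr = c(0.4, 0.7, 0.7, 0.7),
    stringsAsFactors = FALSE)
  config <- simulation_config(
    n_samples = 900, n_genes = 300, n_seeds = 34,
    correlation_blocks = blocks, prognostic = prognostic,
    node_prevalence = 0.12, node_log_hr = 0.7,
    censoring_rate = 0.62, rng_seed = rng_seed)
  out <- simulate_cohort(config)
  out$truth$config <- config
  out
}
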