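# Independent oracles and small data builders shared across tests.
# Each oracle re-derives the quantity from first principles so the tests
# never depend on the implementation path they check.

# quick survival table
surv_df <- function(time, event, node = NULL, ids = NULL) {
  n <- length(time)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  df <- data.frame(sample_id = ids, time = time, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(node)) df$node <- node
  df
}

# expression matrix with generated names
expr_mat <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# Cox partial log-likelihood for one covariate, no ties assumed
# (Efron = Breslow = exact in that case); brute-force maximizer.
oracle_cox_loglik <- function(beta, x, time, event) {
  lp <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + lp[i] - log(sum(exp(lp[risk])))
  }
  ll
}
oracle_cox_beta <- function(x, time, event, interval = c(-8, 8)) {
  stats::optimize(function(b) oracle_cox_loglik(b, x, time, event),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# exhaustive GCN pruning oracle: enumerate candidates, per-node top-2
# nominations (desc |rho|, ties by opposite endpoint id), union
oracle_gcn_edges <- function(rho, threshold) {
  cand <- list()
  for (s in rownames(rho)) for (g in colnames(rho)) {
    r <- rho[s, g]
    if (!is.na(r) && abs(r) >= threshold && s != g) {
      a <- min(s, g); b <- max(s, g)
      key <- paste(a, b, sep = "|")
      prev <- cand[[key]]
      if (is.null(prev) || abs(r) > abs(as.numeric(prev[["r"]])))
        cand[[key]] <- c(a = a, b = b, r = r)
    }
  }
  if (!length(cand)) return(character())
  keys <- names(cand)
  nodes <- unique(unlist(lapply(cand, function(e) c(e[["a"]], e[["b"]]))))
  nominated <- character()
  for (nd in nodes) {
    inc <- keys[vapply(cand, function(e)
      nd %in% c(e[["a"]], e[["b"]]), logical(1))]
    strength <- vapply(cand[inc], function(e) abs(as.numeric(e[["r"]])),
                       numeric(1))
    other <- vapply(cand[inc], function(e)
      setdiff(c(e[["a"]], e[["b"]]), nd)[1], character(1))
    inc <- inc[order(-strength, other)]
    nominated <- c(nominated, inc[seq_len(min(2, length(inc)))])
  }
  sort(unique(nominated))
}

# pairwise-enumeration AUC oracle (ties = 1/2)
oracle_auc <- function(score, y) {
  pos <- score[y == 1]; neg <- score[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Kaplan-Meier of the censoring distribution, left limit, by hand
oracle_G <- function(time, event, t, left = FALSE) {
  # product-limit over censoring "events"
  ut <- sort(unique(time[event == 0]))
  G <- 1
  for (s in ut) {
    if ((left && s < t) || (!left && s <= t)) {
      at_risk <- sum(time >= s)
      d <- sum(time == s & event == 0)
      G <- G * (1 - d / at_risk)
    }
  }
  G
}

# hand-computed IPCW cumulative/dynamic AUC at one horizon
oracle_td_auc <- function(score, time, event, t) {
  case <- which(event == 1 & time <= t)
  ctrl <- which(time > t)
  num <- 0; wi_sum <- 0; wj_sum <- 0
  wj <- 1 / oracle_G(time, event, t)
  for (i in case) {
    wi <- 1 / oracle_G(time, event, time[i], left = TRUE)
    wi_sum <- wi_sum + wi
    for (j in ctrl) {
      cc <- (score[i] > score[j]) + 0.5 * (score[i] == score[j])
      num <- num + wi * wj * cc
    }
  }
  num / (wi_sum * wj * length(ctrl))
}

# hand-computed IPCW Brier score at one horizon, given predicted survival
oracle_brier <- function(S, time, event, t) {
  n <- length(time)
  tot <- 0
  for (i in seq_len(n)) {
    if (time[i] > t) {
      tot <- tot + (1 - S[i])^2 / oracle_G(time, event, t)
    } else if (event[i] == 1) {
      tot <- tot + S[i]^2 / oracle_G(time, event, time[i], left = TRUE)
    }
  }
  tot / n
}
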