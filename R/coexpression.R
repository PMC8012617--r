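#' Spearman correlation profile of seed genes against the genome
#'
#' Computes the Spearman rank correlation of every seed gene with every
#' gene in the matrix over a subset of samples (e.g. the recurrence
#' stratum). Entries pairing a seed with itself are set to `NA` so they
#' never become edge candidates.
#'
#' @param m genes x samples expression matrix.
#' @param seeds character vector of seed gene identifiers (all must be
#'   present in `m`).
#' @param sample_mask logical vector over samples selecting the stratum;
#'   `NULL` uses all samples.
#' @return numeric matrix, seeds x genes, of Spearman rho.
#' @export
spearman_profile <- function(m, seeds, sample_mask = NULL) {
  validate_expression(m)
  check_seed_genes(seeds, m)
  if (is.null(sample_mask)) sample_mask <- rep(TRUE, ncol(m))
  if (length(sample_mask) != ncol(m))
    stop("sample_mask length must equal the number of samples")
  if (sum(sample_mask) < 3)
    stop("need at least 3 samples in the stratum")
  sub <- m[, sample_mask, drop = FALSE]
  # rank-transform once, then Pearson on ranks == Spearman (midrank ties)
  ranks <- apply(sub, 1L, rank)                  # samples x genes
  rho <- stats::cor(ranks[, seeds, drop = FALSE], ranks)
  rho <- matrix(rho, nrow = length(seeds),
                dimnames = list(seeds, rownames(m)))
  for (s in seeds) rho[s, s] <- NA_real_
  rho
}

#' Build a pruned seed-gene co-expression network
#'
#' Candidate edges are all seed-gene pairs whose correlation magnitude
#' reaches the threshold. Each node (seed or partner) then nominates its
#' strongest two candidate edges by descending `|rho|` (ties broken by the
#' partner identifier); the kept edge set is the union of nominations, so
#' an edge survives if either endpoint ranks it in its top two. Seed genes
#' are always nodes, even when isolated.
#'
#' @param rho seeds x genes Spearman matrix from [spearman_profile()].
#' @param threshold_r correlation threshold in (0, 1].
#' @param stratum label recorded on the network (e.g. `"recurrence"`,
#'   `"no_recurrence"`, `"all"`).
#' @param use_abs if `TRUE` (default) association strength is `|rho|`, so
#'   strong negative co-expression qualifies; `FALSE` restricts candidates
#'   to positive rho.
#' @return object of class `gcn_network`: list with `stratum`,
#'   `threshold_r`, `edges` (data.frame seed/partner/rho), `nodes`,
#'   `seeds`.
#' @export
build_gcn <- function(rho, threshold_r, stratum = "all", use_abs = TRUE) {
  if (!is.numeric(threshold_r) || threshold_r <= 0 || threshold_r > 1)
    stop("threshold_r must be in (0, 1]")
  seeds <- rownames(rho)
  strength <- if (use_abs) abs(rho) else rho
  idx <- which(!is.na(strength) & strength >= threshold_r, arr.ind = TRUE)
  cand <- data.frame(seed = seeds[idx[, 1L]],
                     partner = colnames(rho)[idx[, 2L]],
                     rho = rho[idx],
                     stringsAsFactors = FALSE)
  # a seed can also appear as another seed's partner; both directions of
  # the same unordered pair collapse to one candidate edge, keeping the
  # strongest direction (identical for a symmetric correlation matrix)
  ord <- order(-abs(cand$rho), cand$seed, cand$partner)
  cand <- cand[ord, , drop = FALSE]
  key <- ifelse(cand$seed < cand$partner,
                paste(cand$seed, cand$partner, sep = "\r"),
                paste(cand$partner, cand$seed, sep = "\r"))
  cand <- cand[!duplicated(key), , drop = FALSE]
  kept <- prune_top2(cand)
  nodes <- sort(unique(c(seeds, kept$seed, kept$partner)))
  structure(list(stratum = stratum, threshold_r = threshold_r,
                 edges = kept, nodes = nodes, seeds = sort(seeds)),
            class = "gcn_network")
}

# Per-node top-2 nomination: each incident node keeps its two strongest
# candidate edges (desc |rho|, then asc id of the opposite endpoint);
# the surviving set is the union of nominations.
prune_top2 <- function(cand) {
  empty <- data.frame(seed = character(), partner = character(),
                      rho = numeric(), stringsAsFactors = FALSE)
  if (!nrow(cand)) return(empty)
  eid <- seq_len(nrow(cand))
  incid <- rbind(data.frame(node = cand$seed, other = cand$partner,
                            s = abs(cand$rho), eid = eid),
                 data.frame(node = cand$partner, other = cand$seed,
                            s = abs(cand$rho), eid = eid))
  keep_ids <- unlist(lapply(split(incid, incid$node), function(d) {
    d <- d[order(-d$s, d$other), , drop = FALSE]
    d$eid[seq_len(min(2L, nrow(d)))]
  }), use.names = FALSE)
  kept <- cand[sort(unique(keep_ids)), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' @export
print.gcn_network <- function(x, ...) {
  cat(sprintf("co-expression network [%s], r >= %.3g: %d nodes, %d edges\n",
              x$stratum, x$threshold_r, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Union of gene nodes across networks
#'
#' @param networks list of `gcn_network` objects (a single network is
#'   accepted).
#' @return sorted unique character vector of node gene identifiers.
#' @export
network_gene_union <- function(networks) {
  if (inherits(networks, "gcn_network")) networks <- list(networks)
  if (!length(networks)) stop("need at least one network")
  sort(unique(unlist(lapply(networks, function(n) n$nodes))))
}

#' Write / read a network edge list as TSV
#'
#' Columns: seed, partner, rho, stratum, threshold. Round-trips with
#' [read_gcn_edges()] (isolated nodes are restored from the recorded seed
#' list).
#'
#' @param network `gcn_network` object.
#' @param path output path.
#' @export
write_gcn_edges <- function(network, path) {
  df <- network$edges
  df$stratum <- network$stratum
  df$threshold <- network$threshold_r
  df$is_seed_partner <- df$partner %in% network$seeds
  header <- paste0("# seeds=", paste(network$seeds, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gcn_edges
#' @return `read_gcn_edges()` returns the reconstructed `gcn_network`.
#' @export
read_gcn_edges <- function(path) {
  lines <- readLines(path)
  seeds <- sub("^# seeds=", "", lines[1L])
  seeds <- if (nzchar(seeds)) strsplit(seeds, ",")[[1L]] else character()
  df <- utils::read.table(text = lines[-1L], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  edges <- df[c("seed", "partner", "rho")]
  nodes <- sort(unique(c(seeds, edges$seed, edges$partner)))
  structure(list(stratum = if (nrow(df)) df$stratum[1L] else "all",
                 threshold_r = if (nrow(df)) df$threshold[1L] else NA_real_,
                 edges = edges, nodes = nodes, seeds = sort(seeds)),
            class = "gcn_network")
}
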