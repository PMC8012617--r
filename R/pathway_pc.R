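#' PC-stable skeleton over a gene panel
#'
#' Constraint-based skeleton discovery on the panel's Gaussian
#' correlation structure. Starting from the complete undirected graph,
#' edges (a, b) are removed when some conditioning set S drawn from the
#' current neighbors (|S| up to `max_order`) makes the Fisher-z partial
#' correlation test non-significant at `alpha`. The stable variant
#' snapshots the neighbor sets once per conditioning order, so the result
#' does not depend on the order genes are listed in.
#'
#' @param m genes x samples expression matrix restricted to the panel
#'   (or use `genes` to subset).
#' @param alpha significance level of the conditional-independence tests
#'   (default 0.01).
#' @param max_order largest conditioning-set size (default 3).
#' @param genes optional subset of row names of `m`.
#' @return object of class `pathway_graph`: `nodes`, `amat` (logical
#'   adjacency; `amat[a, b] & amat[b, a]` = undirected edge,
#'   `amat[a, b] & !amat[b, a]` = a -> b), `sepsets` (list keyed
#'   `"a|b"`), `alpha`, `n`, `oriented = FALSE`.
#' @export
pc_skeleton <- function(m, alpha = 0.01, max_order = 3, genes = rownames(m)) {
  m <- m[genes, , drop = FALSE]
  p <- nrow(m)
  n <- ncol(m)
  if (n <= p + max_order)
    stop("need more samples than panel size + max_order")
  C <- stats::cor(t(m))
  if (any(!is.finite(C))) {
    bad <- rownames(C)[apply(!is.finite(C), 1L, any)]
    stop("constant/collinear genes break the correlation matrix: ",
         paste(bad, collapse = ", "))
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    stop("singular correlation matrix; near-collinear genes: ",
         paste(collinear_genes(C), collapse = ", "))
  }
  amat <- matrix(TRUE, p, p, dimnames = list(genes, genes))
  diag(amat) <- FALSE
  sepsets <- list()
  for (ord in 0:max_order) {
    nb_snapshot <- lapply(seq_len(p), function(i) which(amat[i, ]))
    pairs <- which(amat & upper.tri(amat), arr.ind = TRUE)
    if (!nrow(pairs)) break
    if (max(vapply(nb_snapshot, length, integer(1))) - 1 < ord &&
        ord > 0) break
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      removed <- FALSE
      for (side in list(c(i, j), c(j, i))) {
        a <- side[1L]; b <- side[2L]
        nb <- setdiff(nb_snapshot[[a]], b)
        if (length(nb) < ord) next
        subsets <- if (ord == 0) list(integer()) else
          if (length(nb) == ord) list(nb) else
            utils::combn(nb, ord, simplify = FALSE)
        for (S in subsets) {
          pval <- fisher_z_test(C, a, b, S, n)
          if (pval > alpha) {
            amat[i, j] <- amat[j, i] <- FALSE
            key <- sepset_key(genes[i], genes[j])
            sepsets[[key]] <- genes[S]
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
  }
  structure(list(nodes = genes, amat = amat, sepsets = sepsets,
                 alpha = alpha, n = n, oriented = FALSE),
            class = "pathway_graph")
}

sepset_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

# Fisher-z conditional-independence test from a correlation matrix:
# z = atanh(partial r) * sqrt(n - |S| - 3), two-sided normal p.
fisher_z_test <- function(C, i, j, S, n) {
  r <- partial_cor(C, i, j, S)
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r) * sqrt(n - length(S) - 3)
  2 * stats::pnorm(-abs(z))
}

# Partial correlation of i and j given S via inversion of the relevant
# submatrix of the correlation matrix.
partial_cor <- function(C, i, j, S) {
  if (!length(S)) return(C[i, j])
  idx <- c(i, j, S)
  P <- solve(C[idx, idx])
  -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

collinear_genes <- function(C) {
  off <- abs(C - diag(nrow(C)))
  rownames(C)[apply(off > 1 - 1e-8, 1L, any)]
}

#' Orient a PC skeleton into a CPDAG
#'
#' Orients v-structures `a -> c <- b` for every nonadjacent pair (a, b)
#' with a common neighbor c not in their separating set, then applies the
#' Meek rules to closure. Conflicting orientation demands cancel: the
#' edge stays undirected and the conflict count is recorded.
#'
#' @param skeleton `pathway_graph` from [pc_skeleton()].
#' @return the graph with `oriented = TRUE` and directed entries in
#'   `amat`; attribute-level field `conflicts` counts cancelled
#'   orientations.
#' @export
orient_edges <- function(skeleton) {
  g <- skeleton
  a <- g$amat
  p <- length(g$nodes)
  arrow <- matrix(FALSE, p, p, dimnames = dimnames(a))  # arrow[i,j]: i->j
  conflicts <- 0L
  # v-structures
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j || a[i, j]) next
    common <- which(a[i, ] & a[j, ])
    if (!length(common)) next
    sep <- g$sepsets[[sepset_key(g$nodes[i], g$nodes[j])]]
    for (k in common) {
      if (!(g$nodes[k] %in% sep)) {
        if (arrow[k, i] || arrow[k, j]) {
          # conflicting head demanded on an already-oriented edge: cancel
          # the orientation, leave the edge undirected
          arrow[k, i] <- arrow[k, j] <- FALSE
          conflicts <- conflicts + 1L
          next
        }
        arrow[i, k] <- TRUE
        arrow[j, k] <- TRUE
      }
    }
  }
  # Meek rules to closure
  repeat {
    changed <- FALSE
    und <- which(a & !arrow & !t(arrow), arr.ind = TRUE)
    for (r in seq_len(nrow(und))) {
      i <- und[r, 1L]; j <- und[r, 2L]
      if (!a[i, j] || arrow[i, j] || arrow[j, i]) next
      orient <- FALSE
      # R1: k -> i, k not adjacent j  =>  i -> j
      if (any(arrow[, i] & !a[, j] & seq_len(p) != j))
        orient <- TRUE
      # R2: directed path i -> k -> j  =>  i -> j
      if (!orient && any(arrow[i, ] & arrow[, j])) orient <- TRUE
      # R3: i - k1 -> j and i - k2 -> j with k1, k2 nonadjacent => i -> j
      if (!orient) {
        ks <- which(a[i, ] & !arrow[i, ] & !arrow[, i] & arrow[, j])
        if (length(ks) >= 2) {
          for (x in seq_along(ks)) for (y in seq_along(ks)) {
            if (x < y && !a[ks[x], ks[y]]) { orient <- TRUE; break }
          }
        }
      }
      # R4: i - k -> l -> j with k adjacent... (covered by R1-R3 closure
      # for CPDAGs from v-structures; included for completeness)
      if (!orient) {
        ks <- which(a[i, ] & !arrow[i, ] & !arrow[, i])
        for (k in ks) {
          ls <- which(arrow[k, ] & arrow[, j] & a[i, ])
          if (length(ls)) { orient <- TRUE; break }
        }
      }
      if (orient) {
        arrow[i, j] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  amat <- a
  amat[arrow] <- TRUE
  amat[t(arrow)] <- FALSE
  amat[!a] <- FALSE
  g$amat <- amat
  g$oriented <- TRUE
  g$conflicts <- conflicts
  g
}

#' Edges of a pathway graph as a data.frame
#'
#' @param graph `pathway_graph`.
#' @return data.frame `from`, `to`, `directed` (undirected edges appear
#'   once with `from < to`).
#' @export
pathway_edges <- function(graph) {
  a <- graph$amat
  nodes <- graph$nodes
  out <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (a[i, j] && a[j, i] && i < j)
      out[[length(out) + 1L]] <- data.frame(from = nodes[i], to = nodes[j],
                                            directed = FALSE)
    if (a[i, j] && !a[j, i])
      out[[length(out) + 1L]] <- data.frame(from = nodes[i], to = nodes[j],
                                            directed = TRUE)
  }
  if (!length(out))
    return(data.frame(from = character(), to = character(),
                      directed = logical()))
  do.call(rbind, out)
}

#' @export
print.pathway_graph <- function(x, ...) {
  e <- pathway_edges(x)
  cat(sprintf("pathway graph (%s): %d nodes, %d edges (%d directed), alpha = %g\n",
              if (x$oriented) "CPDAG" else "skeleton", length(x$nodes),
              nrow(e), sum(e$directed), x$alpha))
  invisible(x)
}

#' Gene importance across fitted models (Wald chi-square shares)
#'
#' Within each model every selected gene's importance is its Wald
#' chi-square divided by the gene-level chi-square total of that model
#' (shares sum to 1). Genes are ranked by the sum of their shares across
#' models (ties broken by the mean share, then by identifier) and the top
#' `top_k` are returned for pathway plotting.
#'
#' @param models list of `gcn_model` objects (with fitted `cox_fit`s).
#' @param top_k how many genes to return (default 12).
#' @return data.frame `gene`, `sum_importance`, `mean_importance`,
#'   `n_models`, ranked; attribute `"per_model"` holds the share matrix.
#' @export
gene_importance <- function(models, top_k = 12) {
  if (inherits(models, "gcn_model")) models <- list(models)
  shares <- lapply(models, function(mod) {
    f <- mod$cox_fit
    if (is.null(f)) return(NULL)
    genes <- intersect(mod$final_genes, f$covariates)
    if (!length(genes)) return(NULL)
    chi <- (f$beta[genes] / f$se[genes])^2
    chi / sum(chi)
  })
  shares <- Filter(Negate(is.null), shares)
  if (!length(shares)) stop("no fitted gene-level models supplied")
  genes <- sort(unique(unlist(lapply(shares, names))))
  mat <- sapply(shares, function(s) s[genes])
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, paste0("model", seq_along(shares))))
  out <- data.frame(
    gene = genes,
    sum_importance = rowSums(mat, na.rm = TRUE),
    mean_importance = rowMeans(mat, na.rm = TRUE),
    n_models = rowSums(!is.na(mat)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$sum_importance, -out$mean_importance, out$gene), ]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  attr(out, "per_model") <- mat
  out
}
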