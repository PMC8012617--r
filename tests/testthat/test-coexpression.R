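test_that("spearman profile matches a rank-then-Pearson oracle and handles monotone transforms", {
  set.seed(3)
  m <- expr_mat(matrix(rnorm(6 * 10), nrow = 6),
                genes = c("s1", "s2", "g1", "g2", "g3", "g4"))
  m["g1", ] <- exp(m["s1", ])          # monotone increasing transform
  m["g2", ] <- -m["s2", ]              # reversed ranks
  rho <- spearman_profile(m, c("s1", "s2"))
  expect_equal(rho["s1", "g1"], 1)
  expect_equal(rho["s2", "g2"], -1)
  expect_true(is.na(rho["s1", "s1"]))

  # midrank-tie oracle on data with ties
  x <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 9)
  y <- rnorm(10)
  m2 <- expr_mat(rbind(x, y), genes = c("sx", "gy"))
  rho2 <- spearman_profile(m2, "sx")
  oracle <- stats::cor(rank(x), rank(y))
  expect_lt(abs(rho2["sx", "gy"] - oracle), 1e-12)

  expect_error(spearman_profile(m, c("s1", "nope")), "nope")
  expect_error(spearman_profile(m, "s1", sample_mask = c(TRUE, TRUE,
                                                         rep(FALSE, 8))),
               "at least 3")
})

test_that("network pruning keeps each node's top-2 nominations", {
  # one seed, three partners: the seed nominates only its strongest two,
  # but every partner nominates its single edge, so all three survive the
  # union rule
  rho <- matrix(NA_real_, 1, 4,
                dimnames = list("s1", c("s1", "a", "b", "c")))
  rho["s1", c("a", "b", "c")] <- c(0.85, 0.83, 0.80)
  net <- build_gcn(rho, 0.79)
  expect_setequal(net$edges$partner, c("a", "b", "c"))

  # an edge dropped by both endpoints' top-2 disappears: g has three seed
  # edges and s3 has two stronger partners, so (s3, g) is nominated by
  # neither
  seeds <- c("s1", "s2", "s3")
  cols <- c(seeds, "g", "h", "i", "j", "k")
  rho2 <- matrix(NA_real_, 3, length(cols), dimnames = list(seeds, cols))
  rho2["s1", c("g", "h", "i")] <- c(0.90, 0.95, 0.94)
  rho2["s2", c("g", "j", "k")] <- c(0.89, 0.95, 0.94)
  rho2["s3", c("g", "h", "k")] <- c(0.85, 0.93, 0.92)
  net2 <- build_gcn(rho2, 0.8)
  expect_false(any(net2$edges$seed == "s3" & net2$edges$partner == "g"))
  expect_true(any(net2$edges$seed == "s1" & net2$edges$partner == "g"))

  # below-threshold case: seeds stay as isolated nodes
  empty <- build_gcn(rho, 0.99)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$nodes, "s1")

  expect_error(build_gcn(rho, 0), "threshold")
})

test_that("pruned edge sets equal the exhaustive nomination oracle on random instances", {
  set.seed(21)
  for (rep in 1:5) {
    rho <- matrix(runif(5 * 40, -1, 1), nrow = 5,
                  dimnames = list(paste0("s", 1:5),
                                  c(paste0("s", 1:5), paste0("g", 1:35))))
    for (s in rownames(rho)) rho[s, s] <- NA
    for (thr in c(0.6, 0.75, 0.9)) {
      net <- build_gcn(rho, thr)
      got <- sort(paste(pmin(net$edges$seed, net$edges$partner),
                        pmax(net$edges$seed, net$edges$partner),
                        sep = "|"))
      expect_identical(got, oracle_gcn_edges(rho, thr))
    }
  }
})

test_that("kept edges and nodes are nested across thresholds", {
  set.seed(31)
  for (rep in 1:5) {
    rho <- matrix(runif(4 * 30, -1, 1), nrow = 4,
                  dimnames = list(paste0("s", 1:4),
                                  c(paste0("s", 1:4), paste0("g", 1:26))))
    for (s in rownames(rho)) rho[s, s] <- NA
    thrs <- sort(runif(3, 0.4, 0.95), decreasing = TRUE)
    nets <- lapply(thrs, function(t) build_gcn(rho, t))
    keys <- lapply(nets, function(n)
      paste(pmin(n$edges$seed, n$edges$partner),
            pmax(n$edges$seed, n$edges$partner), sep = "|"))
    for (i in 1:2) {
      expect_true(all(keys[[i]] %in% keys[[i + 1]]))
      expect_true(all(nets[[i]]$nodes %in% nets[[i + 1]]$nodes))
    }
  }
})

test_that("per-node nomination counts never exceed two", {
  set.seed(41)
  rho <- matrix(runif(6 * 50, -1, 1), nrow = 6,
                dimnames = list(paste0("s", 1:6),
                                c(paste0("s", 1:6), paste0("g", 1:44))))
  for (s in rownames(rho)) rho[s, s] <- NA
  net <- build_gcn(rho, 0.5)
  # a node with more than 2 incident edges must have nominated at most 2;
  # any extra incident edges must be nominations by the opposite endpoint
  inc <- table(c(net$edges$seed, net$edges$partner))
  for (nd in names(inc)) {
    if (inc[[nd]] <= 2) next
    es <- net$edges[net$edges$seed == nd | net$edges$partner == nd, ]
    others <- ifelse(es$seed == nd, es$partner, es$seed)
    ord <- order(-abs(es$rho), others)
    extra <- es[ord[-(1:2)], ]
    for (r in seq_len(nrow(extra))) {
      opp <- if (extra$seed[r] == nd) extra$partner[r] else extra$seed[r]
      opp_es <- net$edges[net$edges$seed == opp | net$edges$partner == opp, ]
      opp_others <- ifelse(opp_es$seed == opp, opp_es$partner, opp_es$seed)
      opp_rank <- order(-abs(opp_es$rho), opp_others)
      top2 <- opp_es[opp_rank[1:min(2, nrow(opp_es))], ]
      expect_true(any(top2$seed == extra$seed[r] &
                        top2$partner == extra$partner[r]))
    }
  }
})

test_that("stratified networks ignore sample order and use disjoint strata", {
  set.seed(51)
  m <- expr_mat(matrix(rnorm(8 * 40), nrow = 8),
                genes = c(paste0("s", 1:3), paste0("g", 1:5)))
  event <- rbinom(40, 1, 0.4)
  rec <- spearman_profile(m, paste0("s", 1:3), sample_mask = event == 1)
  nor <- spearman_profile(m, paste0("s", 1:3), sample_mask = event == 0)
  perm <- sample(40)
  rec_p <- spearman_profile(m[, perm], paste0("s", 1:3),
                            sample_mask = (event == 1)[perm])
  expect_equal(rec, rec_p)
  expect_false(isTRUE(all.equal(rec, nor)))
})

test_that("gene unions deduplicate with a stable order", {
  n1 <- build_gcn(matrix(NA_real_, 1, 1, dimnames = list("s1", "s1")), 0.9)
  expect_equal(network_gene_union(n1), "s1")

  rho <- matrix(c(NA, 0.95, 0.9), 1, 3,
                dimnames = list("a", c("a", "b", "c")))
  rho2 <- matrix(c(NA, 0.95, 0.9), 1, 3,
                 dimnames = list("x", c("x", "y", "z")))
  u <- network_gene_union(list(build_gcn(rho, 0.8), build_gcn(rho2, 0.8)))
  expect_equal(u, c("a", "b", "c", "x", "y", "z"))

  # overlap: union cardinality equals the set-union oracle
  rho3 <- matrix(c(NA, 0.95, 0.9), 1, 3,
                 dimnames = list("a", c("a", "b", "z")))
  nets <- list(build_gcn(rho, 0.8), build_gcn(rho3, 0.8))
  expect_equal(length(network_gene_union(nets)),
               length(unique(c(nets[[1]]$nodes, nets[[2]]$nodes))))
})

test_that("edge-list TSV writer round-trips", {
  rho <- matrix(c(NA, 0.95, -0.9, 0.7), 1, 4,
                dimnames = list("s1", c("s1", "b", "c", "d")))
  net <- build_gcn(rho, 0.8, stratum = "recurrence")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gcn_edges(net, p)
  back <- read_gcn_edges(p)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$stratum, "recurrence")
  expect_equal(back$threshold_r, 0.8)
})
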