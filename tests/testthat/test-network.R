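# locus weights, reduced-median preprocessing, median-joining networks

test_that("locus weights are inverse-variance, integer, in [1, 99]", {
  # variances (0.25, 1) -> raw inverse weights (4, 1), kept as-is
  h41 <- as_minht(cbind(A = c(10, 10, 10, 11),   # var 0.25
                        B = c(10, 10, 10, 12),   # var 1
                        C = c(10, 10, 10, 10)))  # var 0 -> cap
  w41 <- compute_locus_weights(h41)
  expect_equal(unname(w41), c(4L, 1L, 99L))

  # variances below 1 everywhere: scaled so the smallest weight is 1,
  # preserving the inverse-variance ratio (here 3:1)
  h21 <- as_minht(cbind(A = c(10, 10, 11, 11),   # var 1/3
                        B = c(10, 10, 10, 12)))  # var 1
  w21 <- compute_locus_weights(h21)
  expect_equal(unname(w21[1] / w21[2]), 3)

  # equal variances -> equal weights
  heq <- as_minht(cbind(A = c(10, 11, 12, 13), B = c(20, 21, 22, 23)))
  weq <- compute_locus_weights(heq)
  expect_equal(unname(weq[1]), unname(weq[2]))

  # bounds hold even for extreme variance ratios
  hx <- as_minht(cbind(A = rep(c(10L, 30L), 8), B = c(rep(10L, 15), 11L)))
  wx <- compute_locus_weights(hx)
  expect_true(all(wx >= 1 & wx <= 99))
  expect_error(compute_locus_weights(heq[1, , drop = FALSE]), "n >= 2")
})

test_that("the epsilon=0 spanning network equals the union of all MSTs", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    h <- matrix(sample(10:13, n * 3, replace = TRUE), n, 3)
    h <- unique(h)
    if (nrow(h) < 3) next
    w <- c(1L, 2L, 1L)
    d <- matrix(0, nrow(h), nrow(h))
    for (l in 1:3) d <- d + w[l] * abs(outer(h[, l], h[, l], "-"))
    got <- yhapq:::msn_edges(d, eps = 0)
    got_keys <- sort(paste(got$from, got$to, sep = "-"))
    oracle <- oracle_all_msts(d)
    expect_equal(got_keys, oracle$edges)
    # MST totals agree between Prim (package) and Kruskal (oracle)
    expect_equal(yhapq:::mst_total(d), oracle_mst(d))
  }
})

test_that("median_joining satisfies its basic contracts", {
  # two haplotypes: two nodes, one edge of length w1
  h <- as_minht(cbind(A = c(10, 11), B = c(10, 10), C = c(10, 10)))
  w <- c(A = 3L, B = 1L, C = 1L)
  net <- median_joining(h, weights = w)
  expect_equal(nrow(net$haplotypes), 2)
  expect_equal(net$edges$length, 3)

  # perfect star: three singletons around an unobserved center
  h3 <- as_minht(cbind(A = c(11, 10, 10), B = c(10, 11, 10),
                       C = c(10, 10, 11)))
  net3 <- median_joining(h3, weights = c(A = 1L, B = 1L, C = 1L))
  expect_equal(nrow(net3$haplotypes), 4)
  expect_true(any(apply(net3$haplotypes, 1,
                        function(r) all(r == c(10, 10, 10)))))
  expect_equal(sort(net3$edges$length), c(1, 1, 1))
  expect_equal(network_length(net3), 3)
  # the median vector has multiplicity 0, the observed nodes 1
  expect_equal(sort(net3$multiplicity), c(0, 1, 1, 1))

  # every observed haplotype is a node; the network is connected
  set.seed(7)
  off <- matrix(sample(-2:2, 5 * 7, replace = TRUE), 5, 7)
  hr <- haps_from_offsets(off)
  netr <- median_joining(hr)
  ok <- apply(unique(unclass(hr)), 1, function(r)
    any(apply(netr$haplotypes, 1, function(q) all(q == r))))
  expect_true(all(ok))
  # connectivity via the edge list
  nn <- nrow(netr$haplotypes)
  comp <- seq_len(nn)
  for (k in seq_len(nrow(netr$edges))) {
    i <- netr$edges$from[k]; j <- netr$edges$to[k]
    comp[comp == comp[j]] <- comp[i]
  }
  expect_equal(length(unique(comp)), 1)
  # medians never lengthen the network beyond the observed-haplotype MST
  d_obs <- yhapq:::hap_dist_matrix(unique(unclass(hr)), netr$weights)
  expect_lte(yhapq:::mst_total(
    yhapq:::hap_dist_matrix(netr$haplotypes, netr$weights)),
    yhapq:::mst_total(d_obs))
})

test_that("median_joining matches the brute-force oracle on small datasets", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    h <- matrix(sample(10:12, n * 3, replace = TRUE), n, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    w <- c(A = 1L, B = 1L, C = 2L)
    net <- median_joining(as_minht(h), weights = w)
    or <- oracle_mj(unique(h), w)
    expect_equal(network_node_keys(net), oracle_node_keys(or))
    expect_equal(network_edge_keys(net), or$edge_keys)
  }
})

test_that("epsilon enlarges the spanning network monotonically", {
  h <- as_minht(cbind(A = c(10, 11, 12, 14), B = c(10, 10, 11, 11)))
  w <- c(A = 1L, B = 1L)
  d <- yhapq:::hap_dist_matrix(unique(unclass(h)), w)
  e0 <- nrow(yhapq:::msn_edges(d, 0))
  e2 <- nrow(yhapq:::msn_edges(d, 2))
  e9 <- nrow(yhapq:::msn_edges(d, 9))
  expect_lte(e0, e2)
  expect_lte(e2, e9)
  expect_equal(e9, choose(nrow(d), 2))  # huge tolerance keeps every link
})

test_that("reduced_median returns a superset with r-monotone augmentation", {
  w3 <- c(A = 1L, B = 1L, C = 1L)
  # two haplotypes: nothing inferable
  h2 <- as_minht(cbind(A = c(10, 12), B = c(10, 11), C = c(10, 10)))
  rm2 <- reduced_median(h2, weights = w3)
  expect_equal(nrow(rm2), 2)
  expect_false(any(attr(rm2, "inferred")))

  # incompatible-site quartet (binary characters as 10/11 repeat states):
  # the documented criterion accepts the interior Steiner nodes
  hq <- as_minht(cbind(A = c(10, 10, 11), B = c(10, 11, 10),
                       C = c(10, 11, 11)))
  rmq <- reduced_median(hq, weights = w3, r = 1)
  expect_gte(nrow(rmq), 4)
  # superset of the input
  in_keys <- apply(unclass(hq), 1, paste, collapse = "|")
  out_keys <- apply(rmq, 1, paste, collapse = "|")
  expect_true(all(in_keys %in% out_keys))

  # r sweep: node count non-decreasing in r, r = 1 fewest
  set.seed(23)
  for (rep in 1:5) {
    h <- as_minht(matrix(sample(10:12, 5 * 3, replace = TRUE), 5, 3,
                         dimnames = list(NULL, c("A", "B", "C"))))
    sizes <- vapply(c(1, 2, 1000),
                    function(r) nrow(reduced_median(h, weights = w3, r = r)),
                    numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("reduced_median acceptance matches a brute-force check of the criterion", {
  # independent evaluation: for every triplet median of the starting set,
  # accept iff r * (mst(H) + d(m,H) - mst(H+m)) >= d(m,H) > 0
  w3 <- c(A = 1L, B = 1L, C = 1L)
  h <- unique(rbind(c(10, 10, 10), c(10, 11, 11), c(11, 10, 11)))
  colnames(h) <- c("A", "B", "C")
  r <- 1
  dmat <- function(hh) {
    d <- matrix(0, nrow(hh), nrow(hh))
    for (l in 1:3) d <- d + abs(outer(hh[, l], hh[, l], "-"))
    d
  }
  cands <- list()
  for (tri in combn(nrow(h), 3, simplify = FALSE)) {
    m <- apply(h[tri, , drop = FALSE], 2, function(v) sort(v)[2])
    if (!paste(m, collapse = "|") %in% apply(h, 1, paste, collapse = "|"))
      cands[[length(cands) + 1]] <- m
  }
  accepted <- Filter(function(m) {
    dm <- apply(h, 1, function(row) sum(abs(row - m)))
    ben <- oracle_mst(dmat(h)) + min(dm) -
      oracle_mst(rbind(cbind(dmat(h), dm), c(dm, 0)))
    r * ben >= min(dm) && min(dm) > 0
  }, cands)
  rm_out <- reduced_median(as_minht(h), weights = w3, r = 1)
  inferred <- rm_out[attr(rm_out, "inferred"), , drop = FALSE]
  # every first-round accepted candidate is present in the RM output
  for (m in accepted)
    expect_true(any(apply(inferred, 1, function(q) all(q == m))))
})

test_that("star-genealogy networks have the founder as modal node", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_star(sim_config("star", n = 25, T_g = 100,
                                    mu = 6.9e-4, seed = s))
    ht <- to_minht(sim$profiles)
    net <- median_joining(ht)
    modal <- net$haplotypes[which.max(net$multiplicity), ]
    if (all(modal == sim$truth$founder)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
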