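#' Inverse-variance locus weights
#'
#' Weights each locus proportionally to the inverse of its repeat-number
#' variance, so that volatile loci contribute less to network length.
#' Raw weights 1/Var are scaled so the smallest is at least 1, rounded to
#' integers and capped at 99; a zero-variance locus gets the cap.
#'
#' @param haplotypes a `minht` matrix, n >= 2.
#' @return named integer vector of weights in `[1, 99]`.
#' @export
compute_locus_weights <- function(haplotypes) {
  if (nrow(haplotypes) < 2) stop("locus weights need n >= 2")
  v <- apply(haplotypes, 2L, stats::var)
  w <- rep(99, length(v))
  pos <- v > 0
  if (any(pos)) {
    raw <- 1 / v[pos]
    if (min(raw) < 1) raw <- raw / min(raw)
    w[pos] <- pmin(99L, pmax(1L, as.integer(round(raw))))
  }
  stats::setNames(as.integer(w), colnames(haplotypes))
}

# weighted stepwise distance between haplotype rows: sum_l w_l |a_l - b_l|
hap_dist_matrix <- function(h, w) {
  n <- nrow(h)
  d <- matrix(0, n, n)
  for (l in seq_len(ncol(h)))
    d <- d + w[l] * abs(outer(h[, l], h[, l], "-"))
  d
}

# minimum-spanning-network edge list at tolerance eps: the edge (i, j) is
# kept iff i and j are not connected using only edges strictly shorter than
# d(i, j) - eps.  With eps = 0 this is the union of all minimum spanning
# trees (cycle property).  Single ascending pass with a growing union-find:
# the query threshold w - eps is monotone in w, so the prefix of strictly
# shorter edges only ever grows.
msn_edges <- function(d, eps = 0) {
  n <- nrow(d)
  if (n < 2)
    return(data.frame(from = integer(), to = integer(), length = numeric()))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  wts <- d[pairs]
  m <- nrow(pairs)

  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  keep <- logical(m)
  p <- 1L  # next edge to merge into the union-find
  for (k in seq_len(m)) {
    thr <- wts[k] - eps
    while (p <= m && wts[p] < thr) {
      ra <- find(pairs[p, 1]); rb <- find(pairs[p, 2])
      if (ra != rb) parent[ra] <- rb
      p <- p + 1L
    }
    keep[k] <- find(pairs[k, 1]) != find(pairs[k, 2])
  }
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2], length = wts[keep])
}

# total length of a minimum spanning tree (Prim) over a distance matrix
mst_total <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  total <- 0
  for (k in seq_len(n - 1)) {
    i <- which(!in_tree)[which.min(best[!in_tree])]
    total <- total + best[i]
    in_tree[i] <- TRUE
    best <- pmin(best, d[i, ])
  }
  total
}

# per-locus middle value of three haplotypes
triplet_median <- function(h3) apply(h3, 2L, function(v) sort(v)[2])

hap_key <- function(h) apply(h, 1L, paste, collapse = "|")

# deterministic ordering of haplotype rows (lexicographic by tuple)
hap_order <- function(h) do.call(order, as.data.frame(h))

#' Reduced-median preprocessing
#'
#' Augments a haplotype set with inferred intermediate nodes before
#' median-joining, resolving likely parallel mutations.  STR loci are
#' ordinal multistate; on the cumulative ("staircase") binary expansion the
#' per-character majority median of a triplet equals the per-locus middle
#' value, so the construction operates directly on repeat counts with the
#' weighted stepwise distance.  A candidate median `m` drawn from a triplet
#' of current nodes is accepted iff
#' `r * (mst(H) + d(m, H) - mst(H + m)) >= d(m, H)`, where `d(m, H)` is the
#' weighted distance from `m` to its nearest node: the reduction threshold
#' `r` (default 2) controls how much of its connection cost a median must
#' recover; `r = 1` retains fewest candidates and `r -> Inf` retains all.
#' Accepted candidates are added in rounds until a fixpoint.
#'
#' @param haplotypes a `minht` matrix (observed haplotypes; duplicates
#'   allowed).
#' @param weights integer locus weights, e.g. [compute_locus_weights()].
#' @param r reduction threshold, >= 1.
#' @return integer matrix of distinct haplotypes: the distinct input rows
#'   plus inferred nodes, with logical attribute `"inferred"` per row.
#' @export
reduced_median <- function(haplotypes,
                           weights = compute_locus_weights(haplotypes),
                           r = 2) {
  stopifnot(r >= 1)
  h <- unique_haps(haplotypes)$h
  n_obs <- nrow(h)
  inferred <- rep(FALSE, n_obs)
  repeat {
    d <- hap_dist_matrix(h, weights)
    base <- mst_total(d)
    cands <- candidate_medians(h, seq_len(nrow(h)), all_triples = TRUE)
    if (length(cands) == 0) break
    accepted <- list()
    for (m in cands) {
      dm <- apply(sweep(h, 2L, m), 1L, function(x) sum(weights * abs(x)))
      d_to_set <- min(dm)
      d2 <- rbind(cbind(d, dm), c(dm, 0))
      benefit <- base + d_to_set - mst_total(d2)
      if (r * benefit >= d_to_set && d_to_set > 0)
        accepted[[length(accepted) + 1L]] <- m
    }
    if (length(accepted) == 0) break
    add <- unique(do.call(rbind, accepted))
    add <- add[hap_order(add), , drop = FALSE]
    new <- !(hap_key(add) %in% hap_key(h))
    if (!any(new)) break
    h <- rbind(h, add[new, , drop = FALSE])
    inferred <- c(inferred, rep(TRUE, sum(new)))
  }
  colnames(h) <- colnames(haplotypes)
  attr(h, "inferred") <- inferred
  h
}

# distinct haplotypes with multiplicity, in deterministic lexicographic order
unique_haps <- function(haplotypes, groups = NULL) {
  h <- as.matrix(haplotypes)
  key <- hap_key(h)
  first <- !duplicated(key)
  hu <- h[first, , drop = FALSE]
  ord <- hap_order(hu)
  hu <- hu[ord, , drop = FALSE]
  mult <- as.integer(table(key)[hap_key(hu)])
  gtab <- NULL
  if (!is.null(groups)) {
    glev <- sort(unique(groups))
    gtab <- matrix(0L, nrow(hu), length(glev),
                   dimnames = list(NULL, glev))
    ku <- hap_key(hu)
    for (i in seq_len(nrow(hu)))
      gtab[i, ] <- as.integer(table(factor(groups[key == ku[i]],
                                           levels = glev)))
  }
  rownames(hu) <- NULL
  list(h = hu, mult = mult, groups = gtab)
}

# medians of connected triplets.  With an edge list, a triplet is connected
# iff its induced subgraph has >= 2 edges, so it always contains a node
# adjacent to the two others: enumerating (center, neighbor pair) covers all
# connected triplets without the cubic scan.  all_triples = TRUE enumerates
# every triplet regardless of edges (reduced-median preprocessing).
candidate_medians <- function(h, node_idx, edges = NULL, all_triples = FALSE) {
  n <- length(node_idx)
  if (n < 3) return(list())
  out <- list()
  existing <- hap_key(h)
  add_median <- function(tri) {
    m <- triplet_median(h[tri, , drop = FALSE])
    if (!paste(m, collapse = "|") %in% existing)
      out[[length(out) + 1L]] <<- m
  }
  if (all_triples) {
    combs <- utils::combn(node_idx, 3)
    for (c_i in seq_len(ncol(combs))) add_median(combs[, c_i])
  } else {
    if (is.null(edges) || nrow(edges) == 0) return(list())
    nbr <- split(c(edges$to, edges$from), c(edges$from, edges$to))
    seen <- character()
    for (v in as.integer(names(nbr))) {
      nb <- nbr[[as.character(v)]]
      if (length(nb) < 2) next
      prs <- utils::combn(sort(nb), 2)
      for (c_i in seq_len(ncol(prs))) {
        tri <- sort(c(v, prs[, c_i]))
        key <- paste(tri, collapse = "-")
        if (key %in% seen) next
        seen <- c(seen, key)
        add_median(tri)
      }
    }
  }
  if (length(out) == 0) return(list())
  um <- unique(do.call(rbind, out))
  um <- um[hap_order(um), , drop = FALSE]
  lapply(seq_len(nrow(um)), function(i) um[i, ])
}

#' Median-joining network
#'
#' Bandelt-style median-joining on multistate STR haplotypes: starting from
#' the distinct observed haplotypes, iteratively (1) build the minimum
#' spanning network at tolerance `epsilon` under the weighted stepwise
#' distance, (2) enumerate the per-locus middle-value medians of connected
#' triplets and add the candidate giving the largest strict reduction in
#' minimum-spanning-tree length (lexicographic tie-break), until no median
#' helps.  Unobserved medians whose network degree falls to 2 or less and
#' whose removal does not increase the spanning length are pruned.  The node
#' iteration order is lexicographic throughout, so the network is
#' deterministic.
#'
#' @param haplotypes a `minht` matrix of observed haplotypes (duplicates =
#'   multiplicity).
#' @param weights integer locus weights; default [compute_locus_weights()].
#' @param epsilon nonnegative integer tolerance of the spanning network
#'   (default 0, the conventional software default).
#' @param reduced apply [reduced_median()] preprocessing first.
#' @param r reduction threshold passed on when `reduced = TRUE`.
#' @param groups optional per-sample group labels (same order as
#'   `haplotypes`) tallied into the node table.
#' @return an object of class `haplo_network`: list with `haplotypes`
#'   (node x locus matrix), `multiplicity` (0 for inferred medians),
#'   `groups` (node x group count matrix or NULL), `edges` (data frame
#'   `from`, `to`, `length`, `loci`), `weights`, `epsilon`.
#' @export
median_joining <- function(haplotypes,
                           weights = compute_locus_weights(haplotypes),
                           epsilon = 0, reduced = FALSE, r = 2,
                           groups = NULL) {
  stopifnot(nrow(haplotypes) >= 2, epsilon >= 0)
  obs <- unique_haps(haplotypes, groups)
  h <- obs$h
  observed_key <- hap_key(h)
  if (reduced) {
    rm_out <- reduced_median(haplotypes, weights, r)
    extra <- !(hap_key(rm_out) %in% hap_key(h))
    h <- rbind(h, rm_out[extra, , drop = FALSE])
  }

  # median-joining fixpoint: greedily add the best cost-reducing median
  repeat {
    d <- hap_dist_matrix(h, weights)
    net <- msn_edges(d, epsilon)
    cands <- candidate_medians(h, seq_len(nrow(h)), edges = net)
    if (length(cands) == 0) break
    base <- mst_total(d)
    best <- NULL; best_gain <- 0
    for (m in cands) {
      dm <- apply(sweep(h, 2L, m), 1L, function(x) sum(weights * abs(x)))
      d2 <- rbind(cbind(d, dm), c(dm, 0))
      gain <- base - mst_total(d2)
      if (gain > best_gain + 1e-9) { best <- m; best_gain <- gain }
    }
    if (is.null(best)) break
    h <- rbind(h, best)
    rownames(h) <- NULL
  }

  # prune unobserved medians: degree <= 2 and removal does not lengthen
  repeat {
    d <- hap_dist_matrix(h, weights)
    net <- msn_edges(d, epsilon)
    deg <- tabulate(c(net$from, net$to), nbins = nrow(h))
    median_idx <- which(!(hap_key(h) %in% observed_key))
    removed <- FALSE
    for (i in median_idx[order(-median_idx)]) {
      if (deg[i] > 2) next
      keep <- setdiff(seq_len(nrow(h)), i)
      if (mst_total(d[keep, keep, drop = FALSE]) <= mst_total(d) + 1e-9) {
        h <- h[keep, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  d <- hap_dist_matrix(h, weights)
  net <- msn_edges(d, epsilon)
  loci <- colnames(haplotypes)
  net$loci <- vapply(seq_len(nrow(net)), function(k) {
    diff <- which(h[net$from[k], ] != h[net$to[k], ])
    paste(loci[diff], collapse = ",")
  }, character(1))

  key <- hap_key(h)
  mult <- integer(nrow(h))
  gmat <- NULL
  pos <- match(observed_key, key)
  mult[pos] <- obs$mult
  if (!is.null(obs$groups)) {
    gmat <- matrix(0L, nrow(h), ncol(obs$groups),
                   dimnames = list(NULL, colnames(obs$groups)))
    gmat[pos, ] <- obs$groups
  }
  colnames(h) <- colnames(haplotypes)
  structure(list(haplotypes = h, multiplicity = mult, groups = gmat,
                 edges = net, weights = weights, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  n_med <- sum(x$multiplicity == 0)
  cat("median-joining network:", nrow(x$haplotypes), "nodes (",
      n_med, "median vectors ),", nrow(x$edges), "edges, epsilon =",
      x$epsilon, "\n")
  cat("  total weighted length:", sum(x$edges$length), "\n")
  invisible(x)
}

#' Total weighted network length
#'
#' @param x a [median_joining()] network.
#' @return sum of edge lengths.
#' @export
network_length <- function(x) sum(x$edges$length)

#' Export a network as node and edge tables
#'
#' Writes two TSVs: a node table (node id, haplotype columns, multiplicity,
#' inferred flag, per-group counts) and an edge table (endpoints, weighted
#' length, mutated loci), a text graph format any plotting tool can read.
#'
#' @param x a [median_joining()] network.
#' @param node_path,edge_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_network <- function(x, node_path, edge_path) {
  nodes <- data.frame(node = seq_len(nrow(x$haplotypes)),
                      x$haplotypes,
                      multiplicity = x$multiplicity,
                      inferred = x$multiplicity == 0,
                      check.names = FALSE)
  if (!is.null(x$groups)) nodes <- cbind(nodes, x$groups)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = node_path, edges = edge_path))
}
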