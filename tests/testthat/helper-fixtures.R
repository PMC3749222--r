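# shared fixtures and independent oracles for the test suite

q_tree <- function() {
  read_haplogroup_tree(system.file("extdata", "haplogroup_q_tree.tsv",
                                   package = "yhapq"))
}

# published per-population lineage counts (frequency-table fixture)
q_counts <- function() {
  read.delim(system.file("extdata", "q_frequency_counts.tsv",
                         package = "yhapq"), sep = "\t",
             colClasses = c("character", "character", "character",
                            "integer"))
}

# expand the count fixture into one label row per sample
q_labels <- function(counts = q_counts()) {
  idx <- rep(seq_len(nrow(counts)), counts$count)
  data.frame(macro_area = counts$macro_area[idx],
             population = counts$population[idx],
             label = counts$label[idx])
}

# small profile table on the 7 minHt loci (+ optional extra columns)
make_profiles <- function(haps, population = "popA", region = population,
                          ids = sprintf("S%03d", seq_len(nrow(haps)))) {
  loci <- colnames(haps)
  catalog <- locus_catalog(loci = loci,
                           minht_loci = intersect(minht_locus_names(), loci))
  df <- data.frame(sample_id = ids, population = population,
                   region = region, haplogroup = "", check.names = FALSE)
  for (l in loci) df[[l]] <- as.character(haps[, l])
  str_profiles(df, catalog)
}

minht_names <- minht_locus_names()

base_hap <- c(DYS19 = 13, DYS389I = 13, DYS389B = 16, DYS390 = 24,
              DYS391 = 10, DYS392 = 14, DYS393 = 13)

# a minHt matrix around the modal haplotype with given per-row offsets
haps_from_offsets <- function(offsets) {
  m <- matrix(rep(base_hap, each = nrow(offsets)), nrow(offsets), 7,
              dimnames = list(NULL, minht_names))
  as_minht(m + offsets)
}

## ---- independent oracles -------------------------------------------------

# Kruskal MST total length (package uses Prim)
oracle_mst <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs])
  comp <- seq_len(n)
  total <- 0
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (comp[i] != comp[j]) {
      total <- total + d[i, j]
      comp[comp == comp[j]] <- comp[i]
    }
  }
  total
}

# all spanning trees by literal edge-subset enumeration (tiny n only)
oracle_all_msts <- function(d, tol = 1e-9) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  combs <- combn(m, n - 1)
  best <- Inf
  trees <- list()
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci]
    # connectivity check by label propagation
    comp <- seq_len(n)
    for (k in sel) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      comp[comp == comp[j]] <- comp[i]
    }
    if (length(unique(comp)) != 1) next
    tot <- sum(d[pairs[sel, , drop = FALSE]])
    if (tot < best - tol) { best <- tot; trees <- list(sel) }
    else if (abs(tot - best) <= tol) trees <- c(trees, list(sel))
  }
  # union of all MST edge index pairs, as a sorted "i-j" character set
  edges <- unique(unlist(lapply(trees, function(sel)
    paste(pairs[sel, 1], pairs[sel, 2], sep = "-"))))
  list(total = best, edges = sort(edges))
}

# independent re-derivation of the documented median-joining construction:
# Kruskal MST cost, all-triplet median enumeration with the connected-triplet
# filter, greedy best-gain addition, degree<=2 pruning
oracle_mj <- function(h, w, eps = 0) {
  dist_mat <- function(hh) {
    n <- nrow(hh)
    d <- matrix(0, n, n)
    for (l in seq_len(ncol(hh)))
      d <- d + w[l] * abs(outer(hh[, l], hh[, l], "-"))
    d
  }
  msn <- function(d) {
    n <- nrow(d)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      # connected using only edges strictly shorter than d(i,j) - eps?
      thr <- d[i, j] - eps
      comp <- seq_len(n)
      for (a in seq_len(n - 1)) for (b in (a + 1):n)
        if (d[a, b] < thr) comp[comp == comp[b]] <- comp[a]
      keep[i, j] <- comp[i] != comp[j]
    }
    keep
  }
  key <- function(hh) apply(hh, 1L, paste, collapse = "|")
  h <- unique(h)
  h <- h[do.call(order, as.data.frame(h)), , drop = FALSE]
  observed <- key(h)
  repeat {
    d <- dist_mat(h)
    adj <- msn(d)
    n <- nrow(h)
    cands <- list()
    if (n >= 3) {
      for (tri in combn(n, 3, simplify = FALSE)) {
        links <- adj[tri[1], tri[2]] + adj[tri[1], tri[3]] +
          adj[tri[2], tri[3]]
        if (links < 2) next
        m <- apply(h[tri, , drop = FALSE], 2, function(v) sort(v)[2])
        if (!paste(m, collapse = "|") %in% key(h))
          cands[[length(cands) + 1]] <- m
      }
    }
    if (length(cands) == 0) break
    cm <- unique(do.call(rbind, cands))
    cm <- cm[do.call(order, as.data.frame(cm)), , drop = FALSE]
    base <- oracle_mst(d)
    gains <- apply(cm, 1, function(m) {
      dm <- apply(h, 1, function(row) sum(w * abs(row - m)))
      base - oracle_mst(rbind(cbind(d, dm), c(dm, 0)))
    })
    if (max(gains) <= 1e-9) break
    h <- rbind(h, cm[which.max(gains), ])
    rownames(h) <- NULL
  }
  repeat {
    d <- dist_mat(h)
    adj <- msn(d)
    deg <- rowSums(adj | t(adj))
    med <- which(!(key(h) %in% observed))
    drop <- NA
    for (i in rev(med)) {
      if (deg[i] > 2) next
      keep <- setdiff(seq_len(nrow(h)), i)
      if (oracle_mst(d[keep, keep, drop = FALSE]) <= oracle_mst(d) + 1e-9) {
        drop <- i; break
      }
    }
    if (is.na(drop)) break
    h <- h[setdiff(seq_len(nrow(h)), drop), , drop = FALSE]
  }
  d <- dist_mat(h)
  adj <- msn(d)
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  list(haplotypes = h,
       edge_keys = sort(apply(edges, 1, function(e) {
         ab <- sort(c(paste(h[e[1], ], collapse = ","),
                      paste(h[e[2], ], collapse = ",")))
         paste(ab[1], ab[2], sep = "|")
       })))
}

network_edge_keys <- function(net) {
  h <- net$haplotypes
  sort(vapply(seq_len(nrow(net$edges)), function(k) {
    a <- paste(h[net$edges$from[k], ], collapse = ",")
    b <- paste(h[net$edges$to[k], ], collapse = ",")
    paste(sort(c(a, b))[1], sort(c(a, b))[2], sep = "|")
  }, character(1)))
}

network_node_keys <- function(net)
  sort(apply(net$haplotypes, 1, paste, collapse = ","))

oracle_node_keys <- function(or)
  sort(apply(or$haplotypes, 1, paste, collapse = ","))

# mean silhouette of a 1-d embedding with two groups
silhouette1d <- function(x, grp) {
  s <- vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[grp == grp[i] & seq_along(x) != i]))
    b <- mean(abs(x[i] - x[grp != grp[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
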