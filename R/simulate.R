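#' Simulation configuration
#'
#' Describes a synthetic Y-STR dataset: genealogy shape, per-locus
#' per-generation stepwise mutation rate, sample sizes, founder haplotype,
#' optional SNP placements and anomaly injection rates.  All randomness is
#' driven by one master seed; every stochastic operation derives a named
#' substream seed from it, so adding an operation never perturbs the others.
#'
#' @param genealogy `"star"` (independent lineages from one founder, the
#'   limiting shape of a rapid expansion) or `"coalescent"` (Kingman
#'   n-coalescent with effective size `Ne`).
#' @param n samples per population.
#' @param populations number of populations (star genealogy only).
#' @param divergence generations separating each population founder from the
#'   common founder (star genealogy only).
#' @param T_g depth in generations of each lineage (star genealogy).
#' @param Ne effective population size (coalescent genealogy); pairwise
#'   coalescence rate 1/(2*Ne) per generation, so E[TMRCA] = 2*Ne for n = 2.
#' @param mu per-locus per-generation stepwise mutation rate (default the
#'   evolutionary effective rate 6.9e-4).
#' @param loci locus names (default the 7 minHt loci).
#' @param founder founder haplotype (integer repeat counts; default a
#'   typical Native American modal minimal haplotype).
#' @param snp_branches optional named integer vector mapping marker names to
#'   internal-tree node indices (coalescent genealogy): every sample below
#'   that branch is derived.
#' @param anomaly_rates named numeric vector `c(microvariant = , duplication
#'   = )`, per-sample injection probabilities in `[0, 1]`.
#' @param seed master integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genealogy = c("star", "coalescent"),
                       n = 100,
                       populations = 1,
                       divergence = 0,
                       T_g = 1000,
                       Ne = 1000,
                       mu = 6.9e-4,
                       loci = minht_locus_names(),
                       founder = default_founder(loci),
                       snp_branches = NULL,
                       anomaly_rates = c(microvariant = 0, duplication = 0),
                       seed = 1L) {
  genealogy <- match.arg(genealogy)
  stopifnot(n >= 1, populations >= 1, mu >= 0, mu <= 1, T_g >= 0, Ne > 0,
            divergence >= 0, length(founder) == length(loci),
            all(anomaly_rates >= 0), all(anomaly_rates <= 1))
  structure(list(genealogy = genealogy, n = as.integer(n),
                 populations = as.integer(populations),
                 divergence = divergence, T_g = T_g, Ne = Ne, mu = mu,
                 loci = loci, founder = stats::setNames(as.integer(founder),
                                                        loci),
                 snp_branches = snp_branches,
                 anomaly_rates = anomaly_rates, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_founder <- function(loci = minht_locus_names()) {
  modal <- c(DYS19 = 13L, DYS389I = 13L, DYS389B = 16L, DYS390 = 24L,
             DYS391 = 10L, DYS392 = 14L, DYS393 = 13L)
  out <- modal[loci]
  out[is.na(out)] <- 14L  # generic mid-range repeat count for extra loci
  stats::setNames(as.integer(out), loci)
}

# named substream seed derived from the master seed (kept below 2^31)
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1013904223
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

# net displacement of a symmetric single-step walk after `events` mutations
net_steps <- function(events) {
  up <- stats::rbinom(length(events), events, 0.5)
  2L * up - events
}

# evolve each row of `h` for t generations under the per-generation
# Bernoulli(mu) single-step SMM; vectorized through the exact equivalence
# events ~ Binomial(t, mu)
smm_evolve <- function(h, t, mu) {
  if (t == 0 || mu == 0) return(h)
  events <- stats::rbinom(length(h), t, mu)
  h + matrix(net_steps(events), nrow(h), ncol(h))
}

#' Simulate a star-genealogy STR dataset
#'
#' Every sample descends independently from the founder: per generation each
#' locus mutates with probability `mu`, stepping the repeat count by +-1
#' with equal probability (symmetric single-step SMM, no range constraints).
#' With several populations, each population founder first diverges from the
#' common founder for `divergence` generations.  Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()] with `genealogy = "star"`.
#' @return a `sim_result` list: `profiles` (a [str_profiles()] table),
#'   `truth` (founder, per-population founders, `T_g`, population
#'   assignment).
#' @export
simulate_star <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$genealogy == "star")
  L <- length(config$loci)
  withr_seed(derive_seed(config$seed, "star"), {
    pf <- matrix(rep(config$founder, each = config$populations),
                 config$populations, L)
    pf <- smm_evolve(pf, config$divergence, config$mu)
    pops <- paste0("pop", seq_len(config$populations))
    h <- pf[rep(seq_len(config$populations), each = config$n), ,
            drop = FALSE]
    h <- smm_evolve(h, config$T_g, config$mu)
    colnames(h) <- config$loci
    population <- rep(pops, each = config$n)
    prof <- sim_profiles(h, population, config)
    structure(list(
      profiles = prof,
      truth = list(founder = config$founder,
                   pop_founders = structure(pf, dimnames = list(pops,
                                                                config$loci)),
                   T_g = config$T_g,
                   population = population)
    ), class = "sim_result")
  })
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  })
  code
}

# wrap a haplotype matrix into a str_profiles table
sim_profiles <- function(h, population, config, region = population) {
  catalog <- locus_catalog(loci = config$loci,
                           minht_loci = intersect(minht_locus_names(),
                                                  config$loci))
  df <- data.frame(sample_id = sprintf("S%04d", seq_len(nrow(h))),
                   population = population, region = region,
                   haplogroup = "", check.names = FALSE)
  for (j in seq_along(config$loci))
    df[[config$loci[j]]] <- format(h[, j], trim = TRUE)
  str_profiles(df, catalog)
}

#' Simulate a coalescent-genealogy STR dataset
#'
#' Draws a Kingman n-coalescent tree (pairwise coalescence rate `1/(2*Ne)`
#' per generation), drops STR mutations on branches as Poisson(mu x branch
#' generations) per locus (each mutation +-1 step), and places optional SNP
#' markers on configured branches, so that exactly the samples below a
#' marker's branch carry its derived state.
#'
#' @param config a [sim_config()] with `genealogy = "coalescent"`.
#' @return a `sim_result` list: `profiles`, and `truth` with the founder,
#'   the tree (`parent`, `branch_len` per node; leaves `1..n`, root
#'   `2n - 1`), `tmrca` (generations) and, when `snp_branches` is set, the
#'   logical `derived` matrix (samples x markers).
#' @export
simulate_coalescent <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$genealogy == "coalescent")
  n <- config$n
  L <- length(config$loci)
  withr_seed(derive_seed(config$seed, "coalescent"), {
    n_nodes <- 2L * n - 1L
    parent <- rep(NA_integer_, n_nodes)
    branch_len <- rep(0, n_nodes)
    node_time <- rep(0, n_nodes)
    active <- seq_len(n)
    nxt <- n + 1L
    t_now <- 0
    while (length(active) > 1) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2 / (2 * config$Ne))
      pair <- sample(active, 2)
      parent[pair] <- nxt
      branch_len[pair] <- t_now - node_time[pair]
      node_time[nxt] <- t_now
      active <- c(setdiff(active, pair), nxt)
      nxt <- nxt + 1L
    }
    root <- n_nodes

    # STR mutations per branch and locus, accumulated root-to-leaf
    disp <- matrix(0L, n_nodes, L)
    for (v in seq_len(n_nodes)) {
      if (v == root) next
      m <- stats::rpois(L, config$mu * branch_len[v])
      disp[v, ] <- net_steps(m)
    }
    topo <- order(node_time[seq_len(n_nodes)], decreasing = TRUE)
    state <- matrix(rep(config$founder, each = n_nodes), n_nodes, L)
    for (v in topo) {
      if (v == root) next
      state[v, ] <- state[parent[v], ] + disp[v, ]
    }
    h <- state[seq_len(n), , drop = FALSE]
    colnames(h) <- config$loci

    derived <- NULL
    if (!is.null(config$snp_branches)) {
      below <- function(v) {
        if (v <= n) return(v)
        kids <- which(parent == v)
        unlist(lapply(kids, below))
      }
      derived <- matrix(FALSE, n, length(config$snp_branches),
                        dimnames = list(NULL, names(config$snp_branches)))
      for (mk in names(config$snp_branches))
        derived[below(config$snp_branches[[mk]]), mk] <- TRUE
    }

    prof <- sim_profiles(h, rep("pop1", n), config)
    structure(list(
      profiles = prof,
      truth = list(founder = config$founder,
                   parent = parent, branch_len = branch_len,
                   tmrca = t_now, derived = derived)
    ), class = "sim_result")
  })
}

#' Simulate complete SNP calls on a haplogroup tree
#'
#' Assigns each sample a true tree node (uniformly among `nodes`) and emits
#' complete marker calls: every marker on the root-to-node path is derived,
#' every other tree marker ancestral.  With complete calls,
#' [classify_haplogroup()] must recover the generating node exactly.
#'
#' @param tree a [haplogroup_tree()].
#' @param n number of samples.
#' @param nodes candidate true nodes (default: all nodes).
#' @param seed integer seed.
#' @return list with `calls` (n x marker character matrix) and `node`
#'   (true node per sample).
#' @export
simulate_snp_calls <- function(tree, n, nodes = tree$nodes, seed = 1L) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  withr_seed(derive_seed(seed, "snp_calls"), {
    truth <- sample(nodes, n, replace = TRUE)
    markers <- names(tree$marker_node)
    calls <- matrix("ancestral", n, length(markers),
                    dimnames = list(NULL, markers))
    for (i in seq_len(n)) {
      path <- tree_path(tree, truth[i])
      on_path <- markers[tree$marker_node[markers] %in% path]
      calls[i, on_path] <- "derived"
    }
    list(calls = calls, node = truth)
  })
}

#' Inject atypical-allele anomalies
#'
#' Randomly gives samples a partial-repeat micro-variant (+0.2 on one
#' allele) or a second allele at a single-copy locus (duplication), the two
#' anomaly classes the atypical-allele filter must catch.  Reproducible
#' given the seed.
#'
#' @param x a [str_profiles()] object.
#' @param rates named numeric vector `c(microvariant = , duplication = )` of
#'   per-sample probabilities.
#' @param seed integer seed.
#' @param loci loci eligible for injection (default: the catalogue minHt
#'   loci present in the table).
#' @return the modified `str_profiles`; attribute `"n_injected"` holds the
#'   per-class injection counts.
#' @export
inject_anomalies <- function(x, rates = c(microvariant = 0, duplication = 0),
                             seed = 1L,
                             loci = intersect(profile_catalog(x)$minht_loci,
                                              names(x))) {
  stopifnot(inherits(x, "str_profiles"),
            all(rates >= 0), all(rates <= 1))
  mv_rate <- if ("microvariant" %in% names(rates)) rates[["microvariant"]] else 0
  dup_rate <- if ("duplication" %in% names(rates)) rates[["duplication"]] else 0
  withr_seed(derive_seed(seed, "anomalies"), {
    n_mv <- 0L; n_dup <- 0L
    for (i in seq_len(nrow(x))) {
      if (mv_rate > 0 && stats::runif(1) < mv_rate) {
        l <- if (length(loci) == 1) loci else sample(loci, 1)
        v <- parse_alleles(x[[l]][i])
        if (length(v) >= 1) {
          v[1] <- v[1] + 0.2
          x[[l]][i] <- paste(format(v, trim = TRUE), collapse = ",")
          n_mv <- n_mv + 1L
        }
      }
      if (dup_rate > 0 && stats::runif(1) < dup_rate) {
        l <- if (length(loci) == 1) loci else sample(loci, 1)
        v <- parse_alleles(x[[l]][i])
        if (length(v) == 1) {
          x[[l]][i] <- paste(format(c(v, v + 1), trim = TRUE),
                             collapse = ",")
          n_dup <- n_dup + 1L
        }
      }
    }
    attr(x, "n_injected") <- c(microvariant = n_mv, duplication = n_dup)
    x
  })
}

#' Write a simulated dataset
#'
#' Writes the profile table in the dialect [read_str_table()] reads, plus a
#' truth TSV (per-sample population and, for star genealogies, the founder
#' haplotype and depth as comments).
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the profile-table path.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "profiles.tsv")
  write_str_table(sim$profiles, p)
  tr <- data.frame(sample_id = sim$profiles$sample_id,
                   population = sim$profiles$population)
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(p)
}
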