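#' Read a per-sample SNP call table
#'
#' Tab-delimited, header-driven: `sample_id`, optional `population` /
#' `region`, then one column per marker with states `ancestral` / `derived`
#' / `untyped` (abbreviations `A` / `D` / `U` accepted; empty cells are
#' untyped).
#'
#' @param path file path.
#' @return a data frame; marker columns normalised to the full state words.
#' @export
read_snp_table <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(x))
    stop("missing required column: sample_id")
  meta <- intersect(c("sample_id", "population", "region"), names(x))
  map <- c(A = "ancestral", D = "derived", U = "untyped",
           ancestral = "ancestral", derived = "derived", untyped = "untyped")
  for (m in setdiff(names(x), meta)) {
    v <- trimws(x[[m]])
    v[v == "" | is.na(v)] <- "untyped"
    if (!all(v %in% names(map)))
      stop("invalid SNP state in column ", m, ": ",
           paste(unique(v[!v %in% names(map)]), collapse = ", "))
    x[[m]] <- unname(map[v])
  }
  x
}

#' Classify every row of a SNP call table
#'
#' @param snp a data frame from [read_snp_table()] (or with the same
#'   layout).
#' @param tree a [haplogroup_tree()].
#' @return data frame `sample_id`, `population`, `label`.
#' @export
classify_table <- function(snp, tree) {
  meta <- intersect(c("sample_id", "population", "region"), names(snp))
  markers <- setdiff(names(snp), meta)
  labels <- vapply(seq_len(nrow(snp)), function(i) {
    calls <- stats::setNames(unlist(snp[i, markers]), markers)
    classify_haplogroup(calls, tree)
  }, character(1))
  data.frame(sample_id = snp$sample_id,
             population = if ("population" %in% names(snp)) snp$population
                          else "",
             label = labels)
}

#' Analysis run configuration
#'
#' All parameters of [run_analysis()], every one with its documented
#' default.  Configurations round-trip through the key = value text format
#' of [read_run_config()] / [write_run_config()].
#'
#' @param input path to the input table (STR haplotypes, SNP calls or
#'   labels, depending on the subcommand).
#' @param tree path to a haplogroup-tree file; defaults to the packaged
#'   haplogroup-Q tree.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param mu_eff,gen_years ASD dating parameters.
#' @param epsilon,r,reduced median-joining / reduced-median parameters.
#' @param metric,axes distance metric and PCoA axis count.
#' @param group_by profile column used to group samples (`"population"` or
#'   `"region"`).
#' @param genealogy,n,T_g,Ne,populations,divergence,mu simulation
#'   parameters (subcommand `"simulate"`).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(input = NULL,
                       tree = system.file("extdata", "haplogroup_q_tree.tsv",
                                          package = "yhapq"),
                       out_dir = tempfile("yhapq_run_"),
                       seed = 1L,
                       mu_eff = 6.9e-4, gen_years = 25,
                       epsilon = 0, r = 2, reduced = FALSE,
                       metric = "squared", axes = 2,
                       group_by = "population",
                       genealogy = "star", n = 100, T_g = 1000, Ne = 1000,
                       populations = 1, divergence = 0, mu = 6.9e-4) {
  structure(list(input = input, tree = tree, out_dir = out_dir,
                 seed = as.integer(seed), mu_eff = mu_eff,
                 gen_years = gen_years, epsilon = epsilon, r = r,
                 reduced = reduced, metric = metric, axes = axes,
                 group_by = group_by, genealogy = genealogy, n = n,
                 T_g = T_g, Ne = Ne, populations = populations,
                 divergence = divergence, mu = mu),
            class = "run_config")
}

#' @rdname run_config
#' @param path a `key = value` text file (one pair per line, `#` comments).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  cfg <- run_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(cfg)) stop("unknown configuration key: ", k)
    old <- cfg[[k]]
    cfg[[k]] <- if (is.logical(old)) as.logical(vals[i])
                else if (is.numeric(old)) as.numeric(vals[i])
                else if (vals[i] == "") NULL
                else vals[i]
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config a `run_config` to serialise.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", if (is.null(v)) "" else format(v, scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run one analysis stage end-to-end
#'
#' Orchestrates the package's stages over files: reads the configured
#' inputs, runs the stage, writes its outputs plus a JSON run manifest
#' (parameters, seed, package version, exclusion counts) into
#' `config$out_dir`.  All sample exclusions (atypical alleles, missing
#' loci, out-of-tree labels) are reported in the manifest and in
#' `exclusions.tsv`, never silent.
#'
#' @param subcommand one of `"classify"`, `"freq"`, `"diversity"`,
#'   `"pcoa"`, `"network"`, `"date"`, `"simulate"`.
#' @param config a [run_config()].
#' @return invisibly, a named list of the files written.
#' @export
run_analysis <- function(subcommand = c("classify", "freq", "diversity",
                                        "pcoa", "network", "date",
                                        "simulate"),
                         config = run_config()) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  exclusions <- data.frame(sample_id = character(), locus = character(),
                           reason = character())

  need_input <- function() {
    if (is.null(config$input) || !file.exists(config$input))
      stop("input file not found: ",
           if (is.null(config$input)) "(not set)" else config$input)
  }

  if (subcommand == "simulate") {
    cfg <- sim_config(genealogy = config$genealogy, n = config$n,
                      populations = config$populations,
                      divergence = config$divergence, T_g = config$T_g,
                      Ne = config$Ne, mu = config$mu, seed = config$seed)
    sim <- if (config$genealogy == "star") simulate_star(cfg)
           else simulate_coalescent(cfg)
    out$profiles <- write_sim(sim, config$out_dir)
  } else if (subcommand %in% c("classify", "freq")) {
    need_input()
    tree <- read_haplogroup_tree(config$tree)
    labels <- classify_table(read_snp_table(config$input), tree)
    out$labels <- file.path(config$out_dir, "labels.tsv")
    utils::write.table(labels, out$labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (subcommand == "freq") {
      in_tree <- !startsWith(labels$label, "not-")
      if (any(!in_tree))
        exclusions <- rbind(exclusions, data.frame(
          sample_id = labels$sample_id[!in_tree], locus = "",
          reason = paste0("outside tree (", labels$label[!in_tree], ")")))
      ft <- frequency_table(labels[in_tree, ])
      out$frequencies <- file.path(config$out_dir, "frequencies.tsv")
      write_freq_table(ft, out$frequencies)
    }
  } else {
    need_input()
    profiles <- read_str_table(config$input, default_sim_catalog(config))
    groups <- profiles[[config$group_by]]

    if (subcommand == "pcoa") {
      # micro-variants are usable numerically; only duplicated alleles at
      # the analysis loci force exclusion here
      loci <- intersect(single_copy_loci(profile_catalog(profiles)),
                        profile_loci(profiles))
      scan <- scan_atypical(profiles, loci)
      dup <- scan[scan$reason == "duplicated locus", , drop = FALSE]
      keep <- setdiff(seq_len(nrow(profiles)), unique(dup$index))
      exclusions <- rbind(exclusions,
                          dup[, c("sample_id", "locus", "reason")])
      kept <- str_profiles(as.data.frame(profiles)[keep, , drop = FALSE],
                           profile_catalog(profiles))
      d <- str_distances(kept, loci, metric = config$metric)
      pc <- str_pcoa(d, axes = config$axes)
      out$distances <- file.path(config$out_dir, "distances.tsv")
      utils::write.table(d, out$distances, sep = "\t", quote = FALSE)
      out$coordinates <- file.path(config$out_dir, "pcoa.tsv")
      write_pcoa(pc, out$coordinates,
                 groups = data.frame(group = kept[[config$group_by]]))
    } else {
      flt <- filter_atypical(profiles)
      exclusions <- rbind(exclusions, flt$report)
      ht <- to_minht(flt$kept)
      grp <- flt$kept[[config$group_by]]

      if (subcommand == "diversity") {
        rows <- lapply(unique(grp), function(g)
          cbind(group = g, diversity_summary(ht[grp == g, , drop = FALSE])))
        out$diversity <- file.path(config$out_dir, "diversity.tsv")
        utils::write.table(do.call(rbind, rows), out$diversity, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      } else if (subcommand == "network") {
        net <- median_joining(ht, epsilon = config$epsilon,
                              reduced = config$reduced, r = config$r,
                              groups = grp)
        out$nodes <- file.path(config$out_dir, "network_nodes.tsv")
        out$edges <- file.path(config$out_dir, "network_edges.tsv")
        write_network(net, out$nodes, out$edges)
      } else if (subcommand == "date") {
        est <- lapply(stats::setNames(nm = unique(grp)), function(g) {
          hg <- ht[grp == g, , drop = FALSE]
          if (nrow(hg) < 2)
            stop("group '", g, "' has fewer than 2 usable samples; ",
                 "cannot estimate an age")
          estimate_age(hg, mu_eff = config$mu_eff,
                       gen_years = config$gen_years)
        })
        out$ages <- file.path(config$out_dir, "ages.tsv")
        write_age_report(est, out$ages)
      }
    }
  }

  out$exclusions <- file.path(config$out_dir, "exclusions.tsv")
  utils::write.table(exclusions, out$exclusions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    subcommand = subcommand,
    parameters = unclass(config),
    n_excluded = nrow(exclusions),
    package_version = as.character(utils::packageVersion("yhapq")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    conventions = list(
      dys389b = "DYS389B = DYS389II - DYS389I when not given directly",
      diversity = "unbiased gene diversity, n-1 denominators; V = mean of
        per-locus sample variances over the 7 minHt loci",
      distance = paste0("individual distance metric: ", config$metric),
      network = "epsilon and reduced-median threshold as configured",
      dating = "center = lower-median haplotype; SE = sd(per-locus ages)/sqrt(L)"
    )
  )
  out$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out)
}

# catalogue used when reading analysis input: the default panel, unless the
# table was produced by the simulator with a reduced locus set (detected by
# header on read; read_str_table keeps only known columns, so the default
# panel works for both)
default_sim_catalog <- function(config) default_catalog()
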