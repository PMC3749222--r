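#' Haplogroup trees
#'
#' A haplogroup tree is a rooted, marker-labelled tree in YCC-style
#' nomenclature: each non-root node is defined by one or more biallelic
#' markers (SNPs or small indels), and a chromosome belongs to the deepest
#' node whose defining markers it carries in the derived state.
#'
#' @param nodes a data frame with columns `node` (name), `parent` (name;
#'   empty or `NA` for the root) and `markers` (comma-separated marker
#'   names).
#' @return an object of class `haplogroup_tree`: a list with the node table
#'   and lookup maps.
#' @export
haplogroup_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("node", "parent", "markers") %in% names(nodes)))
  nodes$node <- as.character(nodes$node)
  nodes$parent <- as.character(nodes$parent)
  nodes$parent[is.na(nodes$parent) | nodes$parent %in% c("", "-")] <- NA
  if (anyDuplicated(nodes$node)) stop("duplicated node names")
  root <- nodes$node[is.na(nodes$parent)]
  if (length(root) != 1) stop("tree must have exactly one root")
  if (!all(stats::na.omit(nodes$parent) %in% nodes$node))
    stop("parent refers to unknown node")

  markers <- lapply(strsplit(as.character(nodes$markers), ","), trimws)
  markers <- lapply(markers, function(m) m[m != ""])
  names(markers) <- nodes$node
  if (any(lengths(markers) == 0 & nodes$node != root))
    stop("every non-root node needs at least one defining marker")
  all_markers <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(all_markers)) stop("marker names must be unique")

  parent <- stats::setNames(nodes$parent, nodes$node)
  # cycle check: walk every node to the root
  for (n in nodes$node) {
    seen <- character(); p <- n
    while (!is.na(p)) {
      if (p %in% seen) stop("cycle detected at node ", p)
      seen <- c(seen, p); p <- parent[[p]]
    }
  }
  marker_node <- stats::setNames(
    rep(nodes$node, lengths(markers)), all_markers)

  structure(list(nodes = nodes$node, root = root, parent = parent,
                 markers = markers, marker_node = marker_node),
            class = "haplogroup_tree")
}

#' @rdname haplogroup_tree
#' @param path a tab-delimited file with columns `node`, `parent`, `markers`.
#' @export
read_haplogroup_tree <- function(path) {
  haplogroup_tree(utils::read.delim(path, sep = "\t", header = TRUE,
                                    colClasses = "character"))
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("haplogroup tree:", length(x$nodes), "nodes, root", x$root,
      "(", paste(x$markers[[x$root]], collapse = ","), ")\n")
  invisible(x)
}

tree_children <- function(tree, node) {
  tree$nodes[!is.na(tree$parent) & tree$parent == node]
}

tree_path <- function(tree, node) {
  # node back to root, root first
  p <- node; out <- character()
  while (!is.na(p)) { out <- c(p, out); p <- tree$parent[[p]] }
  out
}

#' Descendants of a tree node
#'
#' @param tree a [haplogroup_tree()].
#' @param node node name.
#' @param include_self include the node itself (default `TRUE`).
#' @return character vector of node names.
#' @export
tree_descendants <- function(tree, node, include_self = TRUE) {
  if (!node %in% tree$nodes) stop("unknown node: ", node)
  out <- node
  frontier <- node
  while (length(frontier) > 0) {
    kids <- unlist(lapply(frontier, tree_children, tree = tree))
    out <- c(out, kids)
    frontier <- kids
  }
  if (include_self) out else setdiff(out, node)
}

# canonical label of a node: "<node>-<first marker>", root included
node_label <- function(tree, node, paragroup = FALSE) {
  paste0(node, "-", tree$markers[[node]][1], if (paragroup) "*")
}

# node name encoded in a classification label ("Q1a3a1a-M3*" -> "Q1a3a1a");
# NA for out-of-tree labels such as "not-Q"
label_node <- function(label) {
  ifelse(startsWith(label, "not-"), NA_character_,
         sub("-.*$", "", sub("\\*$", "", label)))
}

# per-node call state from marker states: "derived" if any defining marker
# derived, "ancestral" if any typed marker ancestral and none derived,
# otherwise "untyped"; conflicting calls on one node are an error
node_state <- function(tree, node, states) {
  mk <- tree$markers[[node]]
  st <- states[mk]
  st[is.na(st)] <- "untyped"
  if (any(st == "derived") && any(st == "ancestral"))
    stop("conflicting calls for equivalent markers on node ", node, ": ",
         paste(mk, collapse = ", "))
  if (any(st == "derived")) "derived"
  else if (any(st == "ancestral")) "ancestral"
  else "untyped"
}

#' Classify a sample into a haplogroup-tree node
#'
#' Hierarchical SNP classification: the sample is assigned to the deepest
#' node whose defining marker is derived and whose path from the root
#' contains no typed-ancestral node.  Untyped markers are treated as "not
#' examined" and block neither descent nor paragroup labelling.  The label is
#' `<node>-<marker>`, with a `*` suffix (paragroup) when at least one
#' child-defining marker was typed ancestral and no typed child marker is
#' derived, i.e. the chromosome is not assigned to any examined downstream
#' branch.
#'
#' @param calls named character vector of marker states, values
#'   `"ancestral"`, `"derived"` or `"untyped"`; markers absent from the tree
#'   are ignored with a warning.
#' @param tree a [haplogroup_tree()].
#' @return the classification label; `"not-<root>"` when the root marker is
#'   ancestral.
#' @examples
#' tr <- read_haplogroup_tree(system.file("extdata", "haplogroup_q_tree.tsv",
#'                                        package = "yhapq"))
#' classify_haplogroup(c(M242 = "derived", MEH2 = "derived",
#'                       M120 = "ancestral", M25 = "ancestral"), tr)
#' @export
classify_haplogroup <- function(calls, tree) {
  stopifnot(inherits(tree, "haplogroup_tree"))
  states <- as.character(calls)
  names(states) <- names(calls)
  if (!all(states %in% c("ancestral", "derived", "untyped")))
    stop("marker states must be 'ancestral', 'derived' or 'untyped'")
  extra <- setdiff(names(states), names(tree$marker_node))
  if (length(extra) > 0) {
    warning("ignoring markers not in the tree: ",
            paste(extra, collapse = ", "))
    states <- states[setdiff(names(states), extra)]
  }

  root_state <- node_state(tree, tree$root, states)
  if (root_state == "untyped")
    stop("no call for the root marker ",
         paste(tree$markers[[tree$root]], collapse = ","))
  if (root_state == "ancestral") return(paste0("not-", tree$root))

  ns <- vapply(tree$nodes, node_state, character(1),
               tree = tree, states = states)

  # consistency: a derived node below a typed-ancestral node on one path
  for (n in tree$nodes[ns == "derived"]) {
    anc <- setdiff(tree_path(tree, n), n)
    bad <- anc[ns[anc] == "ancestral"]
    if (length(bad) > 0)
      stop("phylogenetically inconsistent calls: ",
           paste(tree$markers[[n]], collapse = ","), " derived below ",
           paste(tree$markers[[bad[1]]], collapse = ","), " ancestral")
  }

  derived <- tree$nodes[ns == "derived"]
  depth <- vapply(derived, function(n) length(tree_path(tree, n)), integer(1))
  deepest <- derived[depth == max(depth)]
  if (length(deepest) > 1)
    stop("phylogenetically inconsistent calls: derived on diverging ",
         "branches ", paste(deepest, collapse = " and "))
  label <- deepest
  # all remaining derived nodes must lie on the path to the deepest
  if (!all(derived %in% tree_path(tree, label)))
    stop("phylogenetically inconsistent calls: derived on diverging ",
         "branches ", paste(setdiff(derived, tree_path(tree, label))[1],
                            "and", label))

  kid_states <- ns[tree_children(tree, label)]
  paragroup <- any(kid_states == "ancestral") && !any(kid_states == "derived")
  node_label(tree, label, paragroup)
}

#' Direct-count haplogroup frequency table
#'
#' Tallies classification labels by population and reports counts with
#' percentages relative to each population's classified total, rounded to
#' one decimal.
#'
#' @param labels a data frame with columns `population` and `label` (one row
#'   per sample), e.g. the output of classifying every sample.
#' @return an object of class `freq_table`: a list with integer matrix
#'   `counts` (populations x labels), matrix `pct`, and vector `totals`.
#' @export
frequency_table <- function(labels) {
  stopifnot(is.data.frame(labels),
            all(c("population", "label") %in% names(labels)))
  pops <- unique(labels$population)
  labs <- unique(labels$label)
  counts <- matrix(0L, length(pops), length(labs),
                   dimnames = list(pops, labs))
  for (i in seq_len(nrow(labels)))
    counts[labels$population[i], labels$label[i]] <-
      counts[labels$population[i], labels$label[i]] + 1L
  totals <- rowSums(counts)
  pct <- round(100 * counts / totals, 1)
  structure(list(counts = counts, pct = pct, totals = totals),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("haplogroup frequency table:", nrow(x$counts), "populations,",
      ncol(x$counts), "lineages\n")
  print(x$counts)
  invisible(x)
}

#' Write a frequency table as TSV
#'
#' One row per population; per-lineage cells formatted `count (pct)` as in
#' published frequency tables, plus a total column.
#'
#' @param x a [frequency_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(x, path) {
  stopifnot(inherits(x, "freq_table"))
  cells <- matrix(sprintf("%d (%.1f)", x$counts, x$pct),
                  nrow(x$counts), dimnames = dimnames(x$counts))
  cells[x$counts == 0] <- ""
  out <- data.frame(population = rownames(x$counts), total = x$totals,
                    cells, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate a frequency table over a clade
#'
#' Per-population count of samples classified into a node or any of its
#' descendants (paragroup labels count toward their own node).  Labels
#' outside the tree (e.g. `"not-Q"`) never contribute.
#'
#' @param x a [frequency_table()] result.
#' @param node clade root node name.
#' @param tree the [haplogroup_tree()] the labels came from.
#' @return a list with per-population `counts`, `totals` and `pct`
#'   (percentage of each population's classified total, 1 decimal).
#' @export
aggregate_clade <- function(x, node, tree) {
  stopifnot(inherits(x, "freq_table"), inherits(tree, "haplogroup_tree"))
  clade <- tree_descendants(tree, node)
  lab_nodes <- label_node(colnames(x$counts))
  in_clade <- !is.na(lab_nodes) & lab_nodes %in% clade
  counts <- rowSums(x$counts[, in_clade, drop = FALSE])
  list(counts = counts, totals = x$totals,
       pct = round(100 * counts / x$totals, 1))
}
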