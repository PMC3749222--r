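# SNP-tree classification, paragroup labels, frequency tables, clade sums

test_that("classify_haplogroup finds the deepest derived node with paragroup stars", {
  tr <- q_tree()
  # derived down to M3, all examined M3 children ancestral -> paragroup M3*
  calls <- c(M242 = "derived", L54 = "derived", M3 = "derived",
             M19 = "ancestral", M194 = "ancestral", M199 = "ancestral",
             SA01 = "ancestral", M557 = "ancestral", PV2 = "ancestral")
  expect_equal(classify_haplogroup(calls, tr), "Q1a3a1a-M3*")

  # MEH2 derived, children ancestral -> Q1a-MEH2*
  expect_equal(classify_haplogroup(
    c(M242 = "derived", MEH2 = "derived", M120 = "ancestral",
      M25 = "ancestral", M346 = "ancestral"), tr), "Q1a-MEH2*")

  # root ancestral -> not-Q
  expect_equal(classify_haplogroup(c(M242 = "ancestral"), tr), "not-Q")

  # no examined children -> no star; untyped children -> no star
  expect_equal(classify_haplogroup(
    c(M242 = "derived", M3 = "derived", M557 = "derived"), tr),
    "Q1a3a1a5-M557")
  expect_equal(classify_haplogroup(c(M242 = "derived", M3 = "derived"), tr),
               "Q1a3a1a-M3")

  # untyped intermediate markers do not block descent
  expect_equal(classify_haplogroup(
    c(M242 = "derived", SA01 = "derived"), tr), "Q1a3a1a4-SA01")

  # markers absent from the tree are ignored with a warning
  expect_warning(
    lab <- classify_haplogroup(c(M242 = "derived", XYZ9 = "derived"), tr),
    "XYZ9")
  expect_equal(lab, "Q-M242")
})

test_that("classification errors on inconsistent or missing calls", {
  tr <- q_tree()
  # derived below ancestral on one path
  expect_error(classify_haplogroup(
    c(M242 = "derived", L54 = "ancestral", M3 = "derived"), tr),
    "M3.*L54|L54.*M3")
  # derived on diverging branches
  expect_error(classify_haplogroup(
    c(M242 = "derived", M120 = "derived", M25 = "derived"), tr),
    "inconsistent")
  # no root call
  expect_error(classify_haplogroup(c(M3 = "derived"), tr), "M242")
  expect_error(classify_haplogroup(c(M242 = "odd"), tr), "state")
})

test_that("classification is monotone in added derived calls", {
  tr <- q_tree()
  calls <- c(M242 = "derived")
  depth_of <- function(lab) {
    node <- sub("-.*$", "", sub("\\*$", "", lab))
    length(yhapq::tree_descendants(tr, "Q")) -
      length(yhapq::tree_descendants(tr, node))
  }
  path <- c(MEH2 = "derived", M346 = "derived", L53 = "derived",
            L54 = "derived", M3 = "derived", M557 = "derived")
  prev_depth <- -1
  for (k in seq_along(path)) {
    lab <- classify_haplogroup(c(calls, path[seq_len(k)]), tr)
    d <- depth_of(lab)
    expect_gte(d, prev_depth)
    prev_depth <- d
  }
})

test_that("frequency_table tallies by direct counting with 1-decimal percentages", {
  labels <- data.frame(
    population = c(rep("Kamchatka", 5), rep("Panama", 37), "Chile"),
    label = c(rep("Q1a-MEH2*", 3), rep("Q1a3a1a-M3*", 2),
              rep("Q1a3a1a-M3*", 34), rep("Q1a3a1-L54*", 2), "Q1b-M378",
              "Q1a3a1a-M3*"))
  ft <- frequency_table(labels)
  expect_equal(ft$counts["Kamchatka", "Q1a-MEH2*"], 3)
  expect_equal(ft$pct["Kamchatka", "Q1a-MEH2*"], 60.0)
  expect_equal(ft$pct["Panama", "Q1a3a1a-M3*"], 91.9)
  expect_equal(ft$pct["Chile", "Q1a3a1a-M3*"], 100.0)
  expect_equal(unname(rowSums(ft$counts)), unname(ft$totals))
})

test_that("aggregate_clade sums a node and its descendants; root equals totals", {
  tr <- q_tree()
  ft <- frequency_table(q_labels()[, c("population", "label")])
  agg_root <- aggregate_clade(ft, "Q", tr)
  expect_equal(agg_root$counts, ft$totals)
  # a leaf aggregates to its own column
  agg_leaf <- aggregate_clade(ft, "Q1a3a1a5", tr)
  expect_equal(unname(agg_leaf$counts["Peru"]),
               unname(ft$counts["Peru", "Q1a3a1a5-M557"]))
  expect_error(aggregate_clade(ft, "Q9z", tr), "unknown node")
})

test_that("classification recovers the generating node on simulated complete calls", {
  tr <- q_tree()
  sim <- simulate_snp_calls(tr, n = 60, seed = 11)
  got <- vapply(seq_len(nrow(sim$calls)), function(i)
    classify_haplogroup(sim$calls[i, ], tr), character(1))
  got_node <- sub("-.*$", "", sub("\\*$", "", got))
  expect_identical(got_node, sim$node)
  # with complete calls every internal node is a paragroup label
  internal <- sim$node %in% c("Q", "Q1a", "Q1a3", "Q1a3a", "Q1a3a1",
                              "Q1a3a1a", "Q1b")
  expect_true(all(grepl("\\*$", got[internal])))
})
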