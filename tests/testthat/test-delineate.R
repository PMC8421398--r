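# unit-depth ultrametric trees: RED of an internal node equals its depth,
# so clade properties can be planted exactly in the newick string

annotate <- function(newick) {
  red_annotate(read_newick(newick, ufboot_first = TRUE), ufboot_first = TRUE)
}

test_that("a well-supported clade above both thresholds becomes a subgroup", {
  asg <- delineate_subgroups(
    annotate("((a1:0.55,a2:0.55)96/85:0.45,c:1);"))
  expect_equal(nrow(asg$subgroups), 1)
  got <- asg$leaves$subgroup[asg$leaves$leaf %in% c("a1", "a2")]
  expect_equal(got, c("A", "A"))
  expect_equal(asg$leaves$subgroup[asg$leaves$leaf == "c"], "UNGROUPED")

  # identical geometry, UFBOOT below 95: members stay ungrouped
  asg2 <- delineate_subgroups(
    annotate("((a1:0.55,a2:0.55)90/85:0.45,c:1);"))
  expect_equal(nrow(asg2$subgroups), 0)
  expect_true(all(asg2$leaves$subgroup == "UNGROUPED"))

  # missing support labels are treated as failing
  asg3 <- delineate_subgroups(
    red_annotate(read_newick("((a1:0.55,a2:0.55):0.45,c:1);",
                             support_dialect = "none")))
  expect_equal(nrow(asg3$subgroups), 0)
})

test_that("RED and stem thresholds are strict: exactly 0.40 is rejected", {
  at_threshold <- annotate("((a1:0.6,a2:0.6)100/100:0.4,c:1);")
  expect_equal(nrow(delineate_subgroups(at_threshold)$subgroups), 0)
  just_over <- annotate("((a1:0.59,a2:0.59)100/100:0.41,c:1);")
  expect_equal(nrow(delineate_subgroups(just_over)$subgroups), 1)
})

test_that("a qualifying ingroup root yields one subgroup with every ingroup leaf", {
  rt <- annotate("((a1:0.5,a2:0.5)95/80:0.5,(p1:0.5,p2:0.5)95/80:0.5);")
  asg <- delineate_subgroups(rt, outgroup = c("p1", "p2"))
  expect_equal(nrow(asg$subgroups), 1)
  expect_equal(sort(asg$leaves$leaf[asg$leaves$subgroup == "A"]),
               c("a1", "a2"))
  expect_equal(sort(asg$leaves$leaf[asg$leaves$subgroup == "OUTGROUP"]),
               c("p1", "p2"))
})

test_that("selection is maximal: a qualifying ancestor absorbs nested clades", {
  rt <- annotate(
    "(((a1:0.3,a2:0.3)100/100:0.25,a3:0.55)100/100:0.45,c:1);")
  asg <- delineate_subgroups(rt)
  expect_equal(nrow(asg$subgroups), 1)
  expect_equal(asg$subgroups$n_leaves, 3)
})

test_that("an anchor-set override lowers the RED threshold for one clade", {
  # RED on the original tree is 0.35 while the ultrametric stem is > 0.4
  nwk <- "((a1:1.857,a2:1.857)100/100:1,c:6);"
  rt <- annotate(nwk)
  n <- ape::getMRCA(rt$tree, c("a1", "a2"))
  expect_equal(rt$red[n], 1 / (1 + 1.857), tolerance = 1e-3)
  expect_gt(rt$stem[n], 0.4)

  expect_equal(nrow(delineate_subgroups(rt)$subgroups), 0)
  ov <- delineation_params(overrides = list(
    list(anchor = c("a1", "a2"), red_min = 0.3)))
  expect_equal(nrow(delineate_subgroups(rt, ov)$subgroups), 1)
})

test_that("planted clades are recovered exactly and outliers stay ungrouped", {
  for (seed in 1:10) {
    sim <- sim_tree_with_clades(small_sim_config(seed))
    asg <- delineate_subgroups(red_annotate(sim$tree))
    joined <- dplyr::inner_join(asg$leaves, sim$truth, by = "leaf",
                                suffix = c("_got", "_true"))
    planted <- joined[joined$subgroup_true != "UNGROUPED", ]
    # each planted clade maps to exactly one recovered label and vice versa
    expect_equal(nrow(asg$subgroups), 3)
    tab <- table(planted$subgroup_got, planted$subgroup_true)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
    expect_false("UNGROUPED" %in% planted$subgroup_got)
    outliers <- joined[joined$subgroup_true == "UNGROUPED", ]
    expect_true(all(outliers$subgroup_got == "UNGROUPED"))
  }
})

test_that("selected clades are disjoint and raising thresholds is monotone", {
  for (seed in 11:15) {
    rt <- red_annotate(sim_tree_with_clades(small_sim_config(seed))$tree)
    asg <- delineate_subgroups(rt)
    # disjoint: no leaf carries two labels by construction; check ancestry
    nodes <- asg$subgroups$node
    for (a in nodes) {
      desc <- phangorn::Descendants(rt$tree, a, "all")
      expect_length(intersect(desc, setdiff(nodes, a)), 0)
    }
    counts <- vapply(c(0.2, 0.4, 0.5, 0.7), function(th) {
      nrow(delineate_subgroups(rt, delineation_params(red_min = th))$subgroups)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    counts_stem <- vapply(c(0.2, 0.4, 0.6), function(th) {
      nrow(delineate_subgroups(rt,
                               delineation_params(stem_min = th))$subgroups)
    }, numeric(1))
    expect_true(all(diff(counts_stem) <= 0))
  }
})

test_that("16S cluster linkage counts shared leaves per pair", {
  rt <- annotate("((x:0.5,y:0.5)100/100:0.5,(w:0.55,z:0.55)100/100:0.45);")
  asg <- delineate_subgroups(rt)
  expect_equal(nrow(asg$subgroups), 2)

  tab <- map_to_16s_clusters(asg, c(x = "Woese-4"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$cluster, "Woese-4")
  expect_equal(tab$n_shared_leaves, 1)

  expect_equal(nrow(map_to_16s_clusters(asg, setNames(character(), character()))), 0)
  dup <- tibble::tibble(leaf = c("x", "x"), cluster = c("c1", "c2"))
  expect_error(map_to_16s_clusters(asg, dup), "multiple clusters")
})

test_that("degenerate inputs are rejected", {
  rt <- annotate("((a1:0.55,a2:0.55)96/85:0.45,c:1);")
  expect_error(delineate_subgroups(rt$tree), "red_tree")
  expect_error(delineate_subgroups(rt, outgroup = c("a1", "a2", "c")),
               "empty ingroup")
})
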