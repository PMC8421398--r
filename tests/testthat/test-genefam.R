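fam_matrix <- function(counts, genomes = NULL, families = NULL) {
  if (is.null(genomes)) genomes <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(families)) families <- sprintf("f%02d", seq_len(ncol(counts)))
  dplyr::bind_cols(tibble::tibble(genome = genomes),
                   tibble::as_tibble(`colnames<-`(counts, families)))
}

test_that("families below the minimum sequence count are removed", {
  fm <- fam_matrix(cbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(0L, 1L, 1L)))
  kept <- filter_families_min_size(fm, min_seqs = 4)
  expect_equal(names(kept)[-1], "f02")          # sums are 3, 4, 2
  expect_equal(names(filter_families_min_size(fm, 1))[-1],
               c("f01", "f02", "f03"))
  expect_warning(out <- filter_families_min_size(fm, 10), "below the minimum")
  expect_equal(ncol(out), 1)
})

test_that("single-copy occupancy filter honours both conditions", {
  counts <- matrix(1L, nrow = 20, ncol = 3)
  counts[18:20, 1] <- 0L              # f01 in 17/20 = 85%, single copy
  counts[18:20, 2] <- 0L
  counts[1, 2] <- 2L                  # f02 multicopy in g01
  counts[8:20, 3] <- 0L               # f03 in 7/20
  fm <- fam_matrix(counts)
  expect_equal(filter_single_copy_orthologs(fm, 0.85), "f01")
  expect_equal(filter_single_copy_orthologs(fm, 0.85,
                                            allow_multicopy_in = "g01"),
               c("f01", "f02"))
  expect_length(filter_single_copy_orthologs(fm, 1.0), 0)
})

test_that("the occupancy filter is antitone in the occupancy fraction", {
  set.seed(8)
  fm <- fam_matrix(matrix(rbinom(30 * 40, 2, 0.4), nrow = 30))
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0),
                  function(o) length(filter_single_copy_orthologs(fm, o)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("occurrence percentages are exact per subgroup", {
  counts <- cbind(c(1L, 1L, 1L, 0L, 0L, 0L),
                  c(0L, 0L, 0L, 0L, 0L, 0L),
                  c(1L, 1L, 1L, 1L, 2L, 1L))
  fm <- fam_matrix(counts)
  asg <- tibble::tibble(leaf = fm$genome,
                        subgroup = c("A", "A", "A", "A", "B", "B"))
  occ <- occurrence_by_subgroup(fm, asg)
  get <- function(f, s) occ$occurrence[occ$family == f & occ$subgroup == s]
  expect_equal(get("f01", "A"), 75)
  expect_equal(get("f01", "B"), 0)
  expect_equal(get("f02", "A"), 0)
  expect_equal(get("f02", "B"), 0)
  expect_equal(get("f03", "A"), 100)
  expect_equal(get("f03", "B"), 100)
  expect_equal(unique(occ$subgroup_size[occ$subgroup == "A"]), 4L)

  expect_error(occurrence_by_subgroup(fm, asg[-1, ]), "missing from assignment")
})

test_that("clade-enriched families show higher occurrence in their subgroup", {
  for (seed in 1:10) {
    sim <- sim_tree_with_clades(small_sim_config(seed))
    asg <- delineate_subgroups(red_annotate(sim$tree))
    fams <- sim_family_matrix(
      small_sim_config(seed, n_families = 60, n_enriched_per_subgroup = 2),
      asg)
    occ <- occurrence_by_subgroup(fams$matrix, asg)
    planted <- fams$truth[!is.na(fams$truth$enriched_in), ]
    for (k in seq_len(nrow(planted))) {
      rows <- occ[occ$family == planted$family[k], ]
      inside <- rows$occurrence[rows$subgroup == planted$enriched_in[k]]
      outside <- mean(rows$occurrence[rows$subgroup != planted$enriched_in[k]])
      expect_gt(inside, outside)
    }
  }
})

test_that("medoid selection matches brute force and breaks ties by id", {
  expect_equal(select_medoid(c(only = "MKVL")), "only")
  seqs <- c(s2 = "MKVLTDE", s1 = "MKVLTDE", s3 = "WWWWPPP")
  expect_equal(select_medoid(seqs), "s1")
  expect_error(select_medoid(c(a = "MKV", b = "MK1")), "sequence: b")

  set.seed(14)
  for (i in 1:5) {
    seqs <- random_aa_seqs(5)
    expect_equal(select_medoid(seqs), brute_force_medoid(seqs))
  }
})

test_that("category composition splits multi-letter annotations and sums to 1", {
  ann <- c(f1 = "E", f2 = "E", f3 = "E", f4 = "E", f5 = "EH",
           f6 = NA, f7 = "NA", f8 = "K", f9 = "K", f10 = "C")
  comp <- category_composition(names(ann), ann)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
  expect_equal(comp$fraction[comp$category == "E" & !is.na(comp$category)],
               0.4 + 0.05)
  expect_equal(comp$fraction[is.na(comp$category)], 0.2)
  expect_equal(comp$fraction[comp$category == "H" & !is.na(comp$category)],
               0.05)

  all_na <- category_composition(c("x", "y"), c(x = NA, y = NA))
  expect_equal(all_na$fraction, 1)
  expect_equal(nrow(category_composition(character(), ann)), 0)

  set.seed(3)
  for (i in 1:10) {
    fams <- sample(names(ann), sample(1:10, 1), replace = TRUE)
    expect_equal(sum(category_composition(fams, ann)$fraction), 1,
                 tolerance = 1e-12)
  }
})
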