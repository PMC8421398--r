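operon <- function(domains, strand = "+", contig = "c1") {
  n <- length(domains)
  strand <- rep(strand, length.out = n)
  tibble::tibble(contig = contig,
                 gene_id = sprintf("%s_g%d", contig, seq_len(n)),
                 strand = strand,
                 start = as.integer(seq(1, by = 1500, length.out = n)),
                 end = as.integer(seq(1000, by = 1500, length.out = n)),
                 domains = domains)
}

test_that("operon context determines the hydrogenase label", {
  trimeric <- operon(c("nuoE_like", "nuoF_like", "H_cluster"))
  expect_equal(classify_fefe_operons(trimeric)$label, "A3_trimeric")

  lone <- operon(c("other", "H_cluster", "other"))
  expect_equal(classify_fefe_operons(lone)$label, "A_untyped")

  none <- operon(c("other", "other"))
  expect_equal(classify_fefe_operons(none)$label, "not_fefe")

  # one intervening gene is allowed by default, two are not
  gap1 <- operon(c("nuoE_like", "other", "H_cluster", "nuoF_like"))
  expect_equal(classify_fefe_operons(gap1)$label, "A3_trimeric")
  gap2 <- operon(c("nuoE_like", "other", "other", "H_cluster", "nuoF_like"))
  expect_equal(classify_fefe_operons(gap2)$label, "A_untyped")
  expect_equal(classify_fefe_operons(gap2, max_gene_gap = 2)$label,
               "A3_trimeric")

  # strand requirement
  mixed <- operon(c("nuoE_like", "nuoF_like", "H_cluster"),
                  strand = c("+", "-", "+"))
  expect_equal(classify_fefe_operons(mixed)$label, "A_untyped")
  expect_equal(classify_fefe_operons(mixed, same_strand = FALSE)$label,
               "A3_trimeric")
})

test_that("classification is invariant under order reversal with strand flip", {
  set.seed(19)
  for (i in 1:20) {
    doms <- sample(c("H_cluster", "nuoF_like", "nuoE_like", "other"),
                   sample(2:6, 1), replace = TRUE)
    op <- operon(doms, strand = sample(c("+", "-"), length(doms),
                                       replace = TRUE))
    flipped <- op
    total <- max(op$end) + 1
    flipped$start <- as.integer(total - rev(op$end))
    flipped$end <- as.integer(total - rev(op$start))
    flipped$strand <- rev(ifelse(op$strand == "+", "-", "+"))
    flipped$domains <- rev(op$domains)
    flipped$gene_id <- rev(op$gene_id)
    expect_equal(classify_fefe_operons(op)$label,
                 classify_fefe_operons(flipped)$label)
  }
})

test_that("motif profiles are exact empirical frequencies", {
  aln <- c(a = "CCAA", b = "CCA-", c = "CSAA", d = "CSAA")
  prof <- extract_motif_profile(aln, list(P1 = 1:2, P2 = 3:4))
  p <- function(col, res) prof$prob[prof$column == col & prof$residue == res]
  expect_equal(p(1, "C"), 1)
  expect_equal(p(2, "C"), 0.5)
  expect_equal(p(2, "S"), 0.5)
  expect_equal(p(4, "-"), 0.25)
  sums <- tapply(prof$prob, prof$column, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  expect_error(extract_motif_profile(c(a = "CCAA", b = "CCA"),
                                     list(P1 = 1:2)),
               "ragged")
  expect_error(extract_motif_profile(aln, list(P1 = 4:5)), "bounds")
})

test_that("a seeded profile equals an independent tally", {
  set.seed(23)
  aln <- setNames(vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "V", "-"), 12, replace = TRUE),
          collapse = "")
  }, ""), sprintf("q%02d", 1:10))
  prof <- extract_motif_profile(aln, list(M = 3:7))
  chars <- do.call(rbind, strsplit(unname(aln), ""))
  for (col in 3:7) {
    for (res in unique(chars[, col])) {
      expect_equal(prof$prob[prof$column == col & prof$residue == res],
                   sum(chars[, col] == res) / 10)
    }
  }
})

test_that("reference comparison flags conserved sites and classifies the rest", {
  refs <- c(r1 = "CYW", r2 = "CYW", r3 = "CYW")
  aln <- c(q1 = "CYW", q2 = "CVW", q3 = "C-W")
  tab <- compare_to_references(aln, refs, list(P = 1:3))
  row <- function(id, col) tab[tab$seq_id == id & tab$column == col, ]
  expect_true(all(row("q1", 1)$conserved, row("q1", 2)$conserved))
  q2 <- row("q2", 2)
  expect_false(q2$conserved)
  expect_equal(q2$hydro_class, "hydrophobic")     # V replacing Y
  q3 <- row("q3", 2)
  expect_false(q3$conserved)
  expect_true(is.na(q3$hydro_class))

  # disagreeing references make conservation impossible
  refs2 <- c(r1 = "CYW", r2 = "CAW")
  tab2 <- compare_to_references(aln, refs2, list(P = 2))
  expect_false(any(tab2$conserved))
})

test_that("catalytic cysteine checks require C at every column", {
  aln <- c(ok = "ACWCA", sub = "ASWCA", gap = "AC-W-")
  got <- check_catalytic_cysteines(aln, c(2, 4))
  expect_equal(setNames(got$all_cys, got$seq_id),
               c(ok = TRUE, sub = FALSE, gap = FALSE))
  expect_error(check_catalytic_cysteines(aln, 9), "bounds")
})

test_that("hydrophobicity classes follow the Kyte-Doolittle scale", {
  expect_equal(hydrophobicity_class(c("I", "R", "G", "-")),
               c("hydrophobic", "hydrophilic", "neutral", NA))
  # a wider neutral band reclassifies weakly scored residues
  expect_equal(hydrophobicity_class("A", band = 2), "neutral")
})

test_that("planted motifs are recovered as modal residues up to rate 0.2", {
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, substitution_rate = 0.2, n_aln_seqs = 40)
    sim <- sim_operons_and_alignment(cfg)
    prof <- extract_motif_profile(sim$alignment, sim$windows)
    consensus <- strsplit(sim$consensus, "")[[1]]
    modal <- prof |>
      dplyr::group_by(motif, column) |>
      dplyr::slice_max(prob, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    expect_equal(modal$residue, consensus[modal$column])
  }
})
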