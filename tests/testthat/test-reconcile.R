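write_simple_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("family\tbranch\tD\tT\tL\tO\tcopies", rows), path)
  path
}

test_that("simple_tsv parsing fills absent cells with zeros", {
  path <- write_simple_tsv(c(
    "fam1\tb1\t0\t0.5\t0\t0.9\t1",
    "fam1\tb2\t0.2\t0\t0\t0\t0.4",
    "fam2\tb3\t0\t0\t0.8\t0\t0"))
  rt <- read_reconciliation(path, branches = c("b1", "b2", "b3"))
  expect_equal(nrow(rt), 6)                  # 2 families x 3 branches
  zero_cell <- rt[rt$family == "fam2" & rt$branch == "b1", ]
  expect_equal(unlist(zero_cell[c("D", "T", "L", "O", "copies")]),
               c(D = 0, T = 0, L = 0, O = 0, copies = 0))
})

test_that("malformed or invalid rows are reported with their line number", {
  bad <- write_simple_tsv(c("fam1\tb1\t0\t0.5\t0\t0.9\t1",
                            "fam1\tb2\t0.2\t0"))
  expect_error(read_reconciliation(bad), "line 3")
  neg <- write_simple_tsv("fam1\tb1\t-0.2\t0\t0\t0\t0")
  expect_error(read_reconciliation(neg), "line 2: negative")
  unknown <- write_simple_tsv("fam1\tbX\t0\t0\t0\t0\t0")
  expect_error(read_reconciliation(unknown, branches = c("b1")),
               "line 2: unknown branch id 'bX'")
  nohdr <- tempfile()
  writeLines("family\tbranch\tD\tT", nohdr)
  expect_error(read_reconciliation(nohdr), "line 1: expected header")
})

test_that("ale_uml per-family files parse to the hand-built table", {
  dir <- tempfile()
  dir.create(dir)
  f1 <- file.path(dir, "famA.uml_rec")
  writeLines(c(
    "#ALE using seed 42",
    "S:\t((g1:1,g2:1)n3:1);",
    "# of\t Duplications\tTransfers\tLosses\tOriginations\tcopies",
    "S_terminal_branch\tg1\t0\t0.4\t0\t0.8\t1",
    "S_terminal_branch\tg2\t0\t0\t0.6\t0\t0.2",
    "S_internal_branch\tn3\t0.35\t0\t0\t0\t1"), f1)
  f2 <- file.path(dir, "famB.uml_rec")
  writeLines(c(
    "#ALE",
    "S_terminal_branch\tg1\t0\t0\t0\t0.31\t0.31"), f2)

  rt <- read_reconciliation(c(f1, f2), dialect = "ale_uml")
  expect_setequal(unique(rt$family), c("famA", "famB"))
  expect_equal(rt$O[rt$family == "famA" & rt$branch == "g1"], 0.8)
  expect_equal(rt$D[rt$family == "famA" & rt$branch == "n3"], 0.35)
  # famB has no n3 row: completed with zeros
  expect_equal(rt$copies[rt$family == "famB" & rt$branch == "n3"], 0)
  expect_equal(nrow(rt), 6)
})

test_that("the 0.3 event threshold is strict", {
  path <- write_simple_tsv(c(
    "fam1\tb1\t0\t0\t0\t0.31\t0",
    "fam2\tb1\t0\t0\t0\t0.30\t0"))
  es <- threshold_events(read_reconciliation(path), tau = 0.3)
  expect_equal(es$branches$n_O, 1)
  expect_equal(es$gains$family, "fam1")
  # inclusive reading counts the boundary cell too
  es_inc <- threshold_events(read_reconciliation(path), tau = 0.3,
                             inclusive = TRUE)
  expect_equal(es_inc$branches$n_O, 2)
  # tau = 0 counts every positive frequency
  es0 <- threshold_events(read_reconciliation(path), tau = 0)
  expect_equal(es0$branches$n_O, 2)
})

test_that("event counts are monotone non-increasing in tau", {
  sim <- sim_reconciliation(sim_config(seed = 4, n_rec_families = 150,
                                       n_branches = 8))
  taus <- c(0.1, 0.3, 0.5, 0.9)
  totals <- vapply(taus, function(tau) {
    b <- threshold_events(sim$table, tau)$branches
    sum(b$n_D + b$n_T + b$n_L + b$n_O)
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("thresholding recovers the generator's planted events exactly", {
  for (seed in 1:10) {
    sim <- sim_reconciliation(sim_config(seed = seed, n_rec_families = 200,
                                         n_branches = 10))
    es <- threshold_events(sim$table, tau = 0.3)
    expect_equal(as.data.frame(es$branches[names(sim$truth)]),
                 as.data.frame(sim$truth))
    expect_equal(es$branches$n_gain,
                 es$branches$n_D + es$branches$n_T + es$branches$n_O)
  }
})

test_that("gain shares reproduce the origination/transfer split", {
  es <- structure(list(branches = tibble::tibble(
    branch = c("n82", "solo", "empty"),
    n_D = c(63, 0, 0), n_T = c(83, 0, 0), n_L = c(5, 0, 0),
    n_O = c(110, 1, 0), n_gain = c(256, 1, 0), n_copies = 0),
    gains = tibble::tibble(branch = character(), family = character()),
    tau = 0.3), class = "event_summary")
  g <- summarize_gains(es, "n82")
  expect_equal(g$share_O, 43)
  expect_equal(g$share_T, 32)
  expect_equal(g$share_D, 25)
  expect_equal(summarize_gains(es, "solo")$share_O, 100)
  expect_true(is.na(summarize_gains(es, "empty")$share_O))
  expect_error(summarize_gains(es, "nope"), "unknown branch")
})

test_that("gain composition delegates to category fractions", {
  path <- write_simple_tsv(c(
    sprintf("fam%02d\tb1\t0\t0\t0\t0.9\t0", 1:50)))
  es <- threshold_events(read_reconciliation(path))
  ann <- setNames(c(rep("E", 8), rep(NA, 42)), sprintf("fam%02d", 1:50))
  comp <- gain_composition(es, "b1", ann)
  expect_equal(comp$fraction[!is.na(comp$category) & comp$category == "E"],
               0.16)
  expect_error(gain_composition(es, "zz", ann), "unknown branch")

  none <- write_simple_tsv("famX\tb1\t0\t0\t0.9\t0\t0")
  es2 <- threshold_events(read_reconciliation(none))
  expect_equal(nrow(gain_composition(es2, "b1", ann)), 0)
})
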