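#' Configuration for the synthetic-data generators
#'
#' One `sim_config` drives every generator. Each generator derives its own
#' pseudo-random stream from the single integer `seed` and its name, so
#' regenerating one input never perturbs another, and the same config always
#' yields byte-identical outputs.
#'
#' The defaults emulate the statistical shape of a DPANN-style MAG study:
#' 152 tree leaves holding 10 planted subgroup clades (148 genomes), two
#' outlier genomes attached on poorly supported branches, planted clade stems
#' and RED targets clear of the 0.4 delineation thresholds by at least 0.05,
#' a 143-gene marker set, thousands of gene families of which a few per
#' subgroup are clade-enriched, reconciliation frequencies for 2320 families
#' thresholded at 0.3, and a mixture of trimeric (A3), untyped and
#' non-hydrogenase operons.
#'
#' @param seed Integer master seed.
#' @param n_leaves Total leaves of the simulated species tree (must allow the
#'   planted clades, outliers and two background leaves).
#' @param planted_clades Data frame with columns `size`, `stem_length`,
#'   `red_target`, `ufboot`, `shalrt`; one row per planted clade (size >= 2).
#' @param n_outliers Number of leaves attached on failing-support branches.
#' @param outlier_support,backbone_support Length-2 vectors
#'   `c(ufboot, shalrt)` written on outlier-attachment / backbone nodes.
#' @param n_genomes,n_markers,completeness,contamination Marker-matrix
#'   simulation: number of genomes and markers, true per-genome completeness
#'   (fractions; default uniform on \[0.5, 1\]) and per-genome duplicate-copy
#'   rates (default uniform on \[0, 0.1\]).
#' @param n_families,n_enriched_per_subgroup,p_in,p_out,annotation_probs
#'   Family-matrix simulation: total families, enriched families planted per
#'   subgroup, presence probability inside (`p_in`) and outside (`p_out`) the
#'   enriched subgroup, and the categorical distribution of COG category
#'   annotations (must include an `"NA"` mass).
#' @param n_rec_families,n_branches,event_rate,copy_rate,freq_noise_sd,tau,
#'   nonevent_noise_prob Reconciliation simulation: families, branches, true
#'   event probability per type, true copy probability, the truncated-normal
#'   noise scale, the frequency threshold the noise is separated around, and
#'   the probability that a non-event gets nonzero (sub-threshold) noise.
#' @param n_operons,class_mixture Operon simulation: number of loci and the
#'   mixture over `A3_trimeric`, `A_untyped`, `not_fefe`.
#' @param motif_consensus Named list of consensus motif strings (P1/P2/P3).
#' @param aln_length,n_aln_seqs,substitution_rate Motif-alignment simulation:
#'   alignment width, number of sequences, per-site substitution probability.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_leaves = 152,
                       planted_clades = default_planted_clades(),
                       n_outliers = 2,
                       outlier_support = c(ufboot = 90, shalrt = 70),
                       backbone_support = c(ufboot = 50, shalrt = 50),
                       n_genomes = 200,
                       n_markers = 143,
                       completeness = NULL,
                       contamination = NULL,
                       n_families = 4562,
                       n_enriched_per_subgroup = 20,
                       p_in = 0.9,
                       p_out = 0.1,
                       annotation_probs = default_annotation_probs(),
                       n_rec_families = 2320,
                       n_branches = 20,
                       event_rate = c(D = 0.005, T = 0.01, L = 0.02, O = 0.01),
                       copy_rate = 0.3,
                       freq_noise_sd = 0.1,
                       tau = 0.3,
                       nonevent_noise_prob = 0.05,
                       n_operons = 30,
                       class_mixture = c(A3_trimeric = 0.6, A_untyped = 0.2,
                                         not_fefe = 0.2),
                       motif_consensus = list(P1 = "TSCCPAW",
                                              P2 = "MPCTAKKAE",
                                              P3 = "ERMACPGGCING"),
                       aln_length = 120,
                       n_aln_seqs = 20,
                       substitution_rate = 0.05) {
  planted_clades <- as_tibble(planted_clades)
  stopifnot(all(planted_clades$size >= 2),
            all(planted_clades$stem_length > 0),
            all(planted_clades$red_target < 1),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            tau >= 0, substitution_rate >= 0, substitution_rate <= 1,
            abs(sum(class_mixture) - 1) < 1e-9,
            abs(sum(annotation_probs) - 1) < 1e-9)
  if (any(planted_clades$red_target - planted_clades$stem_length < -1e-12)) {
    abort("red_target must be >= stem_length (the stem must fit above the clade)")
  }
  min_leaves <- sum(planted_clades$size) + n_outliers + 2
  if (n_leaves < min_leaves) {
    abort(paste0("n_leaves must be at least ", min_leaves,
                 " (planted clades + outliers + 2 background leaves)"))
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_clades <- function() {
  tibble(size = c(26L, 20L, 18L, 16L, 15L, 14L, 12L, 10L, 9L, 8L),
         stem_length = 0.45,
         red_target = seq(0.46, 0.64, by = 0.02),
         ufboot = 100, shalrt = 100)
}

#' @rdname sim_config
#' @export
default_annotation_probs <- function() {
  c(C = 0.06, E = 0.09, F = 0.04, G = 0.05, H = 0.04, I = 0.03, J = 0.08,
    K = 0.05, L = 0.06, M = 0.04, N = 0.01, O = 0.03, P = 0.04, Q = 0.02,
    T = 0.02, U = 0.02, V = 0.02, "NA" = 0.30)
}

# independent, reproducible stream per generator name
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) %% 65521 * 32749 + h) %% 2147483647)
}

support_label <- function(ufboot, shalrt) {
  # default read convention: SH-aLRT first, UFBOOT second
  paste0(format(shalrt, trim = TRUE), "/", format(ufboot, trim = TRUE))
}

#' Simulate a species tree with planted, well-supported subgroup clades
#'
#' Builds a rooted, unit-depth ultrametric tree: a backbone ladder of
#' poorly supported nodes from which each planted clade hangs by a stem of
#' the configured length, with the clade MRCA placed at depth equal to its
#' RED target (on a unit-depth ultrametric tree, RED equals node depth, so
#' the planted RED is exact). Clade interiors are random coalescent subtrees.
#' Outliers are pendant leaves attached to failing-support backbone nodes;
#' two background leaves complete the root and the ladder tip, and extra
#' background leaves are added when `n_leaves` exceeds the planted total.
#'
#' @param cfg A [sim_config()].
#' @return A list: `newick` (string), `tree` (parsed `phylo`), `truth`
#'   (tibble `leaf`, `subgroup` with planted clade ids `clade01`, ... and
#'   `UNGROUPED` for outliers/background).
#' @export
sim_tree_with_clades <- function(cfg) {
  set.seed(stream_seed(cfg$seed, "tree"))
  pc <- cfg$planted_clades
  k <- nrow(pc)

  n_extra_bg <- cfg$n_leaves - sum(pc$size) - cfg$n_outliers - 2

  items <- vector("list", 0)
  truth <- vector("list", 0)
  for (i in seq_len(k)) {
    leaves <- sprintf("SG%02d_%03d", i, seq_len(pc$size[i]))
    sub <- ape::rcoal(pc$size[i], tip.label = leaves)
    h <- max(node_depths_all(sub))
    sub$edge.length <- sub$edge.length * (1 - pc$red_target[i]) / h
    sub$node.label <- rep(support_label(pc$ufboot[i], pc$shalrt[i]), sub$Nnode)
    body <- sub(";\\s*$", "", ape::write.tree(sub, digits = 10))
    items[[length(items) + 1]] <- list(
      attach = pc$red_target[i] - pc$stem_length[i],
      newick = function(a, body, red) {
        paste0(body, ":", format(red - a, digits = 10))
      },
      body = body, red = pc$red_target[i])
    truth[[length(truth) + 1]] <- tibble(leaf = leaves,
                                         subgroup = sprintf("clade%02d", i))
  }
  pendant <- function(name) list(
    attach = NA_real_, newick = function(a, body, red) {
      paste0(body, ":", format(1 - a, digits = 10))
    }, body = name, red = NA_real_)
  for (j in seq_len(cfg$n_outliers)) {
    it <- pendant(sprintf("OUT%02d", j))
    it$attach <- runif(1, 0.05, 0.6)
    items[[length(items) + 1]] <- it
    truth[[length(truth) + 1]] <- tibble(leaf = it$body, subgroup = "UNGROUPED")
  }
  if (n_extra_bg > 0) {
    for (j in seq_len(n_extra_bg)) {
      it <- pendant(sprintf("BGX%02d", j))
      it$attach <- runif(1, 0.05, 0.6)
      items[[length(items) + 1]] <- it
      truth[[length(truth) + 1]] <- tibble(leaf = it$body,
                                           subgroup = "UNGROUPED")
    }
  }

  # ladder order by attachment depth, strictly increasing (ties broken by
  # tiny downward nudges, which only lengthen stems, never shorten them)
  ord <- order(map_dbl(items, "attach"))
  items <- items[ord]
  attach <- map_dbl(items, "attach")
  m <- length(items)
  if (m > 1) {
    for (idx in (m - 1):1) {
      if (attach[idx] >= attach[idx + 1]) {
        attach[idx] <- attach[idx + 1] - 1e-7
      }
    }
  }
  if (attach[1] < 0 || any(diff(attach) <= 0)) {
    abort("planted attachment depths collide; spread the RED targets")
  }

  bb <- support_label(cfg$backbone_support["ufboot"],
                      cfg$backbone_support["shalrt"])
  inner <- paste0("BG2:", format(1 - attach[m], digits = 10))
  for (idx in rev(seq_len(m))) {
    it <- items[[idx]]
    sub_str <- it$newick(attach[idx], it$body, it$red)
    parent_depth <- if (idx == 1) 0 else attach[idx - 1]
    inner <- paste0("(", sub_str, ",", inner, ")", bb, ":",
                    format(attach[idx] - parent_depth, digits = 10))
  }
  newick <- paste0("(BG1:1,", inner, ");")

  truth <- bind_rows(truth) |>
    bind_rows(tibble(leaf = c("BG1", "BG2"), subgroup = "UNGROUPED"))
  tree <- read_newick(newick)
  list(newick = newick, tree = tree,
       truth = arrange(truth, .data$leaf))
}

#' Simulate a genome x marker matrix with known quality
#'
#' Each marker is present in a genome with probability equal to the genome's
#' true completeness; a present marker gains one duplicate copy with
#' probability equal to the genome's contamination rate.
#'
#' @param cfg A [sim_config()].
#' @return A list: `matrix` (genome x marker tibble) and `truth` (tibble
#'   `genome`, `completeness` in percent, `contamination_rate` as the
#'   per-marker duplicate probability).
#' @export
sim_marker_matrix <- function(cfg) {
  set.seed(stream_seed(cfg$seed, "markers"))
  ng <- cfg$n_genomes
  nm <- cfg$n_markers
  comp <- cfg$completeness %||% runif(ng, 0.5, 1)
  cont <- cfg$contamination %||% runif(ng, 0, 0.1)
  stopifnot(length(comp) == ng, length(cont) == ng)

  present <- matrix(rbinom(ng * nm, 1, rep(comp, nm)), nrow = ng)
  extra <- matrix(rbinom(ng * nm, 1, rep(cont, nm)), nrow = ng) * present
  counts <- present + extra
  genomes <- sprintf("g%03d", seq_len(ng))
  m <- as_tibble(counts, .name_repair = ~ sprintf("m%03d", seq_len(nm)))
  m <- dplyr::bind_cols(tibble(genome = genomes), m)
  list(matrix = m,
       truth = tibble(genome = genomes,
                      completeness = 100 * comp,
                      contamination_rate = cont))
}

#' Simulate a genome x family matrix with clade-enriched families
#'
#' Background families are present in any genome with probability `p_out`.
#' For each subgroup in the assignment, `n_enriched_per_subgroup` planted
#' families are present with probability `p_in` inside that subgroup and
#' `p_out` elsewhere. Annotations are drawn from the configured categorical
#' distribution (with an `"NA"` mass for unannotated families).
#'
#' @param cfg A [sim_config()].
#' @param assignment A [delineate_subgroups()] result or data frame with
#'   columns `leaf`, `subgroup`; its leaves become the matrix genomes.
#' @return A list: `matrix`, `annotations` (tibble `family`, `category`),
#'   `truth` (tibble `family`, `enriched_in` — `NA` for background families).
#' @export
sim_family_matrix <- function(cfg, assignment) {
  set.seed(stream_seed(cfg$seed, "families"))
  leaves <- if (inherits(assignment, "subgroup_assignment")) {
    assignment$leaves
  } else {
    as_tibble(assignment)
  }
  genomes <- leaves$leaf
  ng <- length(genomes)
  subgroups <- sort(setdiff(unique(leaves$subgroup),
                            c("UNGROUPED", "OUTGROUP")))
  n_planted <- length(subgroups) * cfg$n_enriched_per_subgroup
  if (n_planted > cfg$n_families) {
    abort("n_families too small for the planted enriched families")
  }

  fam_ids <- sprintf("fam%04d", seq_len(cfg$n_families))
  enriched_in <- rep(NA_character_, cfg$n_families)
  if (n_planted > 0) {
    enriched_in[seq_len(n_planted)] <-
      rep(subgroups, each = cfg$n_enriched_per_subgroup)
  }

  p <- matrix(cfg$p_out, nrow = ng, ncol = cfg$n_families)
  for (jj in which(!is.na(enriched_in))) {
    in_rows <- leaves$subgroup == enriched_in[jj]
    p[in_rows, jj] <- cfg$p_in
  }
  counts <- matrix(rbinom(ng * cfg$n_families, 1, as.vector(p)), nrow = ng)
  m <- as_tibble(counts, .name_repair = ~fam_ids)
  m <- dplyr::bind_cols(tibble(genome = genomes), m)

  cats <- sample(names(cfg$annotation_probs), cfg$n_families, replace = TRUE,
                 prob = cfg$annotation_probs)
  cats[cats == "NA"] <- NA_character_
  list(matrix = m,
       annotations = tibble(family = fam_ids, category = cats),
       truth = tibble(family = fam_ids, enriched_in = enriched_in))
}

#' Simulate a reconciliation frequency table with known events
#'
#' True events of each type are drawn per (family, branch) at the configured
#' rates. A true event reports frequency `1 - min(|N(0, sd)|, 1 - tau - 0.01)`
#' (always strictly above `tau`); a non-event reports 0, or with small
#' probability sub-threshold noise `min(|N(0, sd)|, tau)` (never above
#' `tau`). The truncation guarantees that thresholding at `tau` recovers the
#' planted events exactly.
#'
#' @param cfg A [sim_config()].
#' @param branches Branch ids; a `phylo` (tips + numbered internal nodes), a
#'   character vector, or `NULL` for `b01..b<n_branches>`.
#' @return A list: `table` (a `reconciliation_table`) and `truth` (tibble
#'   `branch`, `n_D`, `n_T`, `n_L`, `n_O`, `n_gain`, `n_copies` of planted
#'   counts).
#' @export
sim_reconciliation <- function(cfg, branches = NULL) {
  set.seed(stream_seed(cfg$seed, "reconciliation"))
  if (inherits(branches, "phylo")) {
    branches <- c(branches$tip.label,
                  sprintf("n%d", n_tips(branches) + seq_len(branches$Nnode)))
  }
  branches <- branches %||% sprintf("b%02d", seq_len(cfg$n_branches))
  nf <- cfg$n_rec_families
  nb <- length(branches)
  ncell <- nf * nb
  fam <- rep(sprintf("rf%04d", seq_len(nf)), each = nb)
  br <- rep(branches, times = nf)

  noisy_freq <- function(event) {
    n <- length(event)
    hi <- 1 - pmin(abs(rnorm(n, 0, cfg$freq_noise_sd)), 1 - cfg$tau - 0.01)
    lo <- ifelse(runif(n) < cfg$nonevent_noise_prob,
                 pmin(abs(rnorm(n, 0, cfg$freq_noise_sd)), cfg$tau), 0)
    ifelse(event == 1, hi, lo)
  }
  true_ev <- map(c(D = "D", T = "T", L = "L", O = "O"),
                 ~ rbinom(ncell, 1, cfg$event_rate[[.x]]))
  true_cp <- rbinom(ncell, 1, cfg$copy_rate)

  tab <- tibble(family = fam, branch = br,
                D = noisy_freq(true_ev$D), T = noisy_freq(true_ev$T),
                L = noisy_freq(true_ev$L), O = noisy_freq(true_ev$O),
                copies = noisy_freq(true_cp))
  truth <- tibble(branch = br,
                  d = true_ev$D, t = true_ev$T, l = true_ev$L,
                  o = true_ev$O, cp = true_cp) |>
    group_by(.data$branch) |>
    summarise(n_D = sum(.data$d), n_T = sum(.data$t), n_L = sum(.data$l),
              n_O = sum(.data$o), n_copies = sum(.data$cp),
              .groups = "drop") |>
    mutate(n_gain = .data$n_D + .data$n_T + .data$n_O) |>
    select("branch", "n_D", "n_T", "n_L", "n_O", "n_gain", "n_copies")
  list(table = new_reconciliation_table(tab), truth = truth)
}

#' Simulate operon tables and a motif alignment with known labels
#'
#' Operons are drawn from the configured class mixture: `A3_trimeric` loci
#' carry a contiguous same-strand nuoE-like / nuoF-like / catalytic
#' (H-cluster) trio plus random flanking genes, `A_untyped` loci a lone
#' catalytic gene, and `not_fefe` loci only unrelated genes. The alignment
#' holds the consensus motifs (P1/P2/P3) at fixed windows inside a random
#' background consensus, with independent per-site substitutions at the
#' configured rate.
#'
#' @param cfg A [sim_config()].
#' @return A list: `operons` (tibble), `truth` (tibble `contig`, `label`),
#'   `alignment` (named character), `refs` (three noise-free reference
#'   sequences), `windows` (named list of columns), `cys_columns`,
#'   `consensus` (full-length consensus string).
#' @export
sim_operons_and_alignment <- function(cfg) {
  set.seed(stream_seed(cfg$seed, "operons"))
  classes <- sample(names(cfg$class_mixture), cfg$n_operons, replace = TRUE,
                    prob = cfg$class_mixture)
  ops <- vector("list", cfg$n_operons)
  for (i in seq_len(cfg$n_operons)) {
    contig <- sprintf("ctg%03d", i)
    strand <- sample(c("+", "-"), 1)
    core <- switch(classes[i],
      A3_trimeric = tibble(domains = c("nuoE_like", "nuoF_like", "H_cluster"),
                           strand = strand),
      A_untyped = tibble(domains = "H_cluster", strand = strand),
      not_fefe = tibble(domains = rep("other", sample(2:4, 1)),
                        strand = sample(c("+", "-"), sample(2:4, 1),
                                        replace = TRUE)[1]))
    n_flank <- sample(0:2, 1)
    genes <- bind_rows(
      core,
      if (n_flank > 0) tibble(domains = rep("other", n_flank),
                              strand = sample(c("+", "-"), n_flank,
                                              replace = TRUE)))
    lens <- sample(600:1800, nrow(genes), replace = TRUE)
    gaps <- sample(20:200, nrow(genes), replace = TRUE)
    start <- cumsum(c(1, head(lens + gaps, -1)))
    ops[[i]] <- tibble(contig = contig,
                       gene_id = sprintf("%s_g%02d", contig,
                                         seq_len(nrow(genes))),
                       strand = genes$strand,
                       start = as.integer(start),
                       end = as.integer(start + lens - 1),
                       domains = genes$domains)
  }
  operons <- bind_rows(ops)

  aa <- Biostrings::AA_STANDARD
  consensus <- sample(aa, cfg$aln_length, replace = TRUE)
  windows <- list()
  pos <- 10
  for (mn in names(cfg$motif_consensus)) {
    motif <- strsplit(cfg$motif_consensus[[mn]], "")[[1]]
    cols <- pos + seq_along(motif) - 1
    if (max(cols) > cfg$aln_length) abort("alignment too short for motifs")
    consensus[cols] <- motif
    windows[[mn]] <- cols
    pos <- max(cols) + 15
  }
  cys_columns <- which(consensus == "C" &
                         seq_along(consensus) %in% unlist(windows))

  mutate_seq <- function() {
    s <- consensus
    hit <- runif(cfg$aln_length) < cfg$substitution_rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(r) sample(setdiff(aa, r), 1), "")
    }
    paste(s, collapse = "")
  }
  alignment <- setNames(vapply(seq_len(cfg$n_aln_seqs),
                               function(i) mutate_seq(), ""),
                        sprintf("seq%03d", seq_len(cfg$n_aln_seqs)))
  refs <- setNames(rep(paste(consensus, collapse = ""), 3),
                   c("synthetic_ref1", "synthetic_ref2", "synthetic_ref3"))
  list(operons = operons,
       truth = tibble(contig = sprintf("ctg%03d", seq_len(cfg$n_operons)),
                      label = classes),
       alignment = alignment, refs = refs, windows = windows,
       cys_columns = cys_columns,
       consensus = paste(consensus, collapse = ""))
}
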