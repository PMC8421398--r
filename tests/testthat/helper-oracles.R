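# Independent oracles, written naively on purpose so they share no code with
# the implementation paths they check.

# RED by direct recursion: distances recomputed by walking edges each time.
naive_red <- function(tree) {
  nt <- length(tree$tip.label)
  np <- nt + tree$Nnode
  kids <- lapply(seq_len(np), function(n) tree$edge[tree$edge[, 1] == n, 2])
  elen <- function(n) tree$edge.length[which(tree$edge[, 2] == n)]
  leaf_dists <- function(n) {
    if (n <= nt) return(0)
    unlist(lapply(kids[[n]], function(k) elen(k) + leaf_dists(k)))
  }
  red <- rep(NA_real_, np)
  assign_red <- function(n, p_red) {
    if (n <= nt) {
      red[n] <<- 1
      return(invisible(NULL))
    }
    if (is.na(p_red)) {
      red[n] <<- 0
    } else {
      d <- elen(n)
      u <- d + mean(leaf_dists(n))
      red[n] <<- if (u <= 0) p_red else p_red + (d / u) * (1 - p_red)
    }
    for (k in kids[[n]]) assign_red(k, red[n])
  }
  assign_red(nt + 1L, NA_real_)
  red
}

# medoid by an exhaustive double loop over ordered pairs
brute_force_medoid <- function(seqs, gap_open = 11, gap_ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  score <- function(a, b) {
    Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                  Biostrings::AAString(b),
                                  type = "global",
                                  substitutionMatrix = BLOSUM62,
                                  gapOpening = gap_open,
                                  gapExtension = gap_ext,
                                  scoreOnly = TRUE)
  }
  ids <- names(seqs)
  total <- setNames(numeric(length(ids)), ids)
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      total[a] <- total[a] +
        (1 - score(seqs[a], seqs[b]) / max(score(seqs[a], seqs[a]),
                                           score(seqs[b], seqs[b])))
    }
  }
  best <- names(total)[total <= min(total) + 1e-12]
  sort(best)[1]
}

random_aa_seqs <- function(k, len_range = c(20, 50)) {
  aa <- Biostrings::AA_STANDARD
  setNames(
    vapply(seq_len(k), function(i) {
      paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
            collapse = "")
    }, ""),
    sprintf("s%02d", seq_len(k)))
}

# random rooted tree with positive branch lengths
random_rooted_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 2)
  tr
}

# small study-shaped generator config used where full size is not the point
small_sim_config <- function(seed, ...) {
  sim_config(
    seed = seed,
    n_leaves = 26,
    planted_clades = tibble::tibble(
      size = c(6L, 5L, 4L), stem_length = 0.45,
      red_target = c(0.5, 0.55, 0.6), ufboot = 100, shalrt = 100),
    n_outliers = 2,
    ...)
}
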