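#' Kyte-Doolittle hydropathy scores
#'
#' @return Named numeric vector of the 20 standard amino-acid hydropathy
#'   values.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Classify residues as hydrophobic / neutral / hydrophilic
#'
#' @param residue Character vector of single residues (`"-"` or anything
#'   outside the 20-letter alphabet gives `NA`).
#' @param band Half-width of the neutral band around 0 on the Kyte-Doolittle
#'   scale. Default 0.5.
#' @return Character vector in `{"hydrophobic", "neutral", "hydrophilic"}`
#'   (or `NA`).
#' @export
hydrophobicity_class <- function(residue, band = 0.5) {
  kd <- kyte_doolittle()[residue]
  dplyr::case_when(is.na(kd) ~ NA_character_,
                   kd > band ~ "hydrophobic",
                   kd < -band ~ "hydrophilic",
                   TRUE ~ "neutral")
}

#' Read an operon gene-order table
#'
#' TSV columns: `contig`, `gene_id`, `strand` (+/-), `start`, `end` (1-based
#' inclusive nucleotide coordinates) and `domains` (semicolon-separated
#' labels, e.g. `H_cluster`, `nuoF_like`, `nuoE_like`, `other`).
#'
#' @param path TSV path.
#' @return A tibble sorted by contig and start.
#' @export
read_operons <- function(path) {
  op <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          contig = "c", gene_id = "c", strand = "c",
                          start = "i", end = "i", domains = "c"))
  validate_operons(op)
}

validate_operons <- function(op) {
  op <- as_tibble(op)
  needed <- c("contig", "gene_id", "strand", "start", "end", "domains")
  missing <- setdiff(needed, names(op))
  if (length(missing) > 0) {
    abort(paste0("operon table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(op$start < 1) || any(op$end < op$start)) {
    abort("coordinates must be positive with start <= end")
  }
  if (!all(op$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  arrange(op, .data$contig, .data$start)
}

#' Classify [FeFe]-hydrogenase operons from gene context
#'
#' Group A [FeFe] hydrogenases cannot be subtyped reliably by phylogeny and
#' are classified by genetic organisation instead. A locus is called
#' `A3_trimeric` when a catalytic-subunit gene (H-cluster domain) has both a
#' nuoF-like and a nuoE-like gene nearby — within `max_gene_gap` intervening
#' genes on the contig and, by default, on the same strand — the organisation
#' of the trimeric, electron-bifurcating group A3 enzymes. A catalytic
#' subunit without that context is `A_untyped`; a locus with no H-cluster
#' gene is `not_fefe`.
#'
#' @param op An operon table (see [read_operons()]); may hold several
#'   contigs.
#' @param max_gene_gap Maximum number of intervening genes between the
#'   H-cluster gene and each accessory subunit. Default 1.
#' @param same_strand Require the accessory genes on the H-cluster gene's
#'   strand. Default `TRUE`.
#' @return A tibble `(contig, label)` with one row per contig.
#' @export
classify_fefe_operons <- function(op, max_gene_gap = 1, same_strand = TRUE) {
  op <- validate_operons(op)
  op |>
    group_by(.data$contig) |>
    summarise(label = classify_one_operon(
      .data$strand, .data$domains, max_gene_gap, same_strand),
      .groups = "drop")
}

classify_one_operon <- function(strand, domains, max_gene_gap, same_strand) {
  dom <- strsplit(domains, ";", fixed = TRUE)
  has <- function(i, lab) lab %in% dom[[i]]
  h_idx <- which(map_lgl(seq_along(dom), has, "H_cluster"))
  if (length(h_idx) == 0) return("not_fefe")

  for (i in h_idx) {
    near <- which(abs(seq_along(dom) - i) - 1 <= max_gene_gap &
                    seq_along(dom) != i)
    if (same_strand) near <- near[strand[near] == strand[i]]
    if (any(map_lgl(near, has, "nuoF_like")) &&
        any(map_lgl(near, has, "nuoE_like"))) {
      return("A3_trimeric")
    }
  }
  "A_untyped"
}

# named character vector of equal-length aligned sequences
as_alignment <- function(aln) {
  if (inherits(aln, "AAStringSet")) {
    aln <- setNames(as.character(aln), names(aln))
  }
  if (is.null(names(aln)) || any(!nzchar(names(aln)))) {
    abort("aligned sequences must be named")
  }
  widths <- nchar(aln)
  if (length(unique(widths)) > 1) {
    abort("ragged alignment: sequences differ in aligned length")
  }
  aln
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Per-column residue probabilities of motif windows
#'
#' Computes the empirical per-column amino-acid probabilities (gap `-`
#' included) of each motif window in an alignment — the matrix behind a
#' sequence-logo display of motif conservation.
#'
#' @param aln Named character vector of aligned protein sequences (equal
#'   lengths), or an `AAStringSet`.
#' @param motif_windows Named list, motif name -> integer vector of alignment
#'   columns (e.g. `list(P1 = 10:16)`).
#' @return A `motif_profile` tibble `(motif, column, residue, prob, kd)`;
#'   probabilities sum to 1 within each (motif, column).
#' @export
extract_motif_profile <- function(aln, motif_windows) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  if (any(unlist(motif_windows) < 1) ||
      any(unlist(motif_windows) > ncol(m))) {
    abort("motif window outside alignment bounds")
  }
  out <- imap(motif_windows, function(cols, motif) {
    bind_rows(map(cols, function(col) {
      tab <- table(m[, col])
      tibble(motif = motif, column = col,
             residue = names(tab),
             prob = as.numeric(tab) / nrow(m))
    }))
  })
  out <- bind_rows(out) |>
    mutate(kd = unname(kyte_doolittle()[.data$residue]))
  class(out) <- c("motif_profile", class(out))
  out
}

#' @describeIn extract_motif_profile Logo-style stacked probability bars per
#'   column, coloured by hydrophobicity class.
#' @param object A `motif_profile`.
#' @param ... Unused.
#' @method autoplot motif_profile
#' @export
autoplot.motif_profile <- function(object, ...) {
  df <- mutate(object, class = hydrophobicity_class(.data$residue))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$column), y = .data$prob,
                                   fill = .data$class,
                                   label = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       size = 3) +
    ggplot2::facet_wrap(~motif, scales = "free_x") +
    ggplot2::labs(x = "alignment column", y = "probability",
                  fill = "hydrophobicity") +
    ggplot2::theme_minimal()
}

#' Compare query residues to reference sequences at motif columns
#'
#' A site is conserved when the query residue is identical to the residue of
#' every reference sequence at that column. Non-conserved residues are
#' classified by Kyte-Doolittle hydrophobicity; a gap in the query is never
#' conserved and has class `NA`.
#'
#' @inheritParams extract_motif_profile
#' @param refs Named character vector (or `AAStringSet`) of reference
#'   sequences in the same alignment coordinates.
#' @param band Neutral band for [hydrophobicity_class()].
#' @return A tibble `(seq_id, motif, column, residue, conserved,
#'   hydro_class)`.
#' @export
compare_to_references <- function(aln, refs, motif_windows, band = 0.5) {
  aln <- as_alignment(aln)
  refs <- as_alignment(refs)
  if (nchar(refs[1]) != nchar(aln[1])) {
    abort("query and reference alignments differ in length")
  }
  qm <- aln_matrix(aln)
  rm_ <- aln_matrix(refs)
  rows <- imap(motif_windows, function(cols, motif) {
    bind_rows(map(cols, function(col) {
      ref_res <- rm_[, col]
      tibble(seq_id = names(aln), motif = motif, column = col,
             residue = qm[, col],
             conserved = qm[, col] != "-" &
               map_lgl(qm[, col], ~ all(ref_res == .x)))
    }))
  })
  bind_rows(rows) |>
    mutate(hydro_class = hydrophobicity_class(.data$residue, band)) |>
    arrange(.data$motif, .data$column, .data$seq_id)
}

#' Check conservation of metal-binding cysteines
#'
#' The H-cluster of [FeFe] hydrogenases is coordinated by conserved cysteine
#' residues; their presence at the expected alignment columns is evidence of
#' an intact active site.
#'
#' @inheritParams extract_motif_profile
#' @param cys_columns Alignment columns expected to hold cysteine.
#' @return A tibble `(seq_id, all_cys)`; `all_cys` is `TRUE` only when the
#'   sequence has `C` at every listed column (a gap fails).
#' @export
check_catalytic_cysteines <- function(aln, cys_columns) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  if (any(cys_columns < 1) || any(cys_columns > ncol(m))) {
    abort("cysteine column outside alignment bounds")
  }
  tibble(seq_id = names(aln),
         all_cys = apply(m[, cys_columns, drop = FALSE] == "C", 1, all))
}
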