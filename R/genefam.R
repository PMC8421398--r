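#' Remove small gene families
#'
#' Families with fewer than `min_seqs` sequences in total (summed over
#' genomes) carry too little signal for tree-based downstream steps and are
#' dropped.
#'
#' @param fm A genome x family count matrix (see [read_count_matrix()]).
#' @param min_seqs Minimum total sequence count to keep a family. Default 4.
#' @return The matrix restricted to retained families.
#' @export
filter_families_min_size <- function(fm, min_seqs = 4) {
  validate_count_matrix(fm)
  stopifnot(min_seqs >= 1)
  fams <- names(fm)[-1]
  keep <- map_lgl(fm[fams], ~ sum(.x) >= min_seqs)
  if (!any(keep) && length(fams) > 0) {
    warn("every family falls below the minimum size; empty matrix returned")
  }
  fm[, c("genome", fams[keep]), drop = FALSE]
}

#' Select widely occupied single-copy orthologues
#'
#' A family is kept when it is present (count >= 1) in at least
#' `ceiling(occupancy * n_genomes)` genomes and single-copy (count <= 1) in
#' every genome outside `allow_multicopy_in`. The allowance exists because a
#' focal lineage may tolerate paralogues that would disqualify the family if
#' found elsewhere.
#'
#' @inheritParams filter_families_min_size
#' @param occupancy Required fraction of genomes containing the family, in
#'   (0, 1]. Default 0.85.
#' @param allow_multicopy_in Genome ids where copy number > 1 is tolerated.
#' @return Character vector of retained family ids.
#' @export
filter_single_copy_orthologs <- function(fm, occupancy = 0.85,
                                         allow_multicopy_in = character()) {
  validate_count_matrix(fm)
  stopifnot(occupancy > 0, occupancy <= 1)
  fams <- names(fm)[-1]
  need <- ceiling(occupancy * nrow(fm))
  strict_rows <- !fm$genome %in% allow_multicopy_in
  keep <- map_lgl(fm[fams], function(x) {
    sum(x >= 1) >= need && all(x[strict_rows] <= 1)
  })
  fams[keep]
}

#' Per-subgroup occurrence of gene families
#'
#' The occurrence of a gene family in a subgroup is the percentage of that
#' subgroup's genomes carrying at least one copy, computed from the
#' presence/absence view of the count matrix. `UNGROUPED` and `OUTGROUP`
#' genomes are not counted in any subgroup column.
#'
#' @inheritParams filter_families_min_size
#' @param assignment A [delineate_subgroups()] result (or any data frame with
#'   columns `leaf`, `subgroup`) covering every genome in `fm`.
#' @param families Families to profile; default all families in `fm`.
#' @return An `occurrence_table` tibble:
#'   `(family, subgroup, n_present, subgroup_size, occurrence)` with
#'   occurrence in percent.
#' @export
occurrence_by_subgroup <- function(fm, assignment, families = NULL) {
  validate_count_matrix(fm)
  leaves <- if (inherits(assignment, "subgroup_assignment")) {
    assignment$leaves
  } else {
    as_tibble(assignment)
  }
  missing <- setdiff(fm$genome, leaves$leaf)
  if (length(missing) > 0) {
    abort(paste0("genomes missing from assignment: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  families <- families %||% names(fm)[-1]
  unknown <- setdiff(families, names(fm)[-1])
  if (length(unknown) > 0) {
    abort(paste0("families not in matrix: ", paste(unknown, collapse = ", ")))
  }

  long <- fm |>
    select("genome", dplyr::all_of(families)) |>
    tidyr::pivot_longer(-"genome", names_to = "family", values_to = "count") |>
    left_join(leaves, by = c(genome = "leaf")) |>
    filter(!.data$subgroup %in% c("UNGROUPED", "OUTGROUP"))

  out <- long |>
    group_by(.data$family, .data$subgroup) |>
    summarise(n_present = sum(.data$count >= 1),
              subgroup_size = n(), .groups = "drop") |>
    mutate(occurrence = 100 * .data$n_present / .data$subgroup_size) |>
    arrange(.data$family, .data$subgroup)
  class(out) <- c("occurrence_table", class(out))
  out
}

#' @describeIn occurrence_by_subgroup Heatmap of occurrence (families x
#'   subgroups), the standard way these profiles are displayed.
#' @param object An `occurrence_table`.
#' @param ... Unused.
#' @method autoplot occurrence_table
#' @export
autoplot.occurrence_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$subgroup, y = .data$family,
                                       fill = .data$occurrence)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "subgroup", y = NULL, fill = "occurrence (%)") +
    ggplot2::theme_minimal()
}

#' Pick the medoid sequence of a protein family
#'
#' The medoid is the sequence minimising the summed distance to all other
#' sequences, with distance `d(a, b) = 1 - S(a, b) / max(S(a, a), S(b, b))`
#' where `S` is the global (Needleman-Wunsch) alignment score under a
#' substitution matrix. Gap penalties default to the common BLOSUM62 pairing
#' (open 11, extend 1); any monotone rescaling of the scores leaves the
#' argmin unchanged when self-scores are comparable, so the estimator is not
#' sensitive to this normalisation choice. Ties are broken by lexicographic
#' sequence id.
#'
#' @param seqs Named character vector of amino-acid sequences (standard
#'   20-letter alphabet), or a [Biostrings::AAStringSet].
#' @param matrix Substitution matrix name available in Biostrings.
#'   Default `"BLOSUM62"`.
#' @param gap_open,gap_ext Gap opening / extension penalties (positive).
#' @return The medoid's sequence id (a single string).
#' @export
select_medoid <- function(seqs, matrix = "BLOSUM62",
                          gap_open = 11, gap_ext = 1) {
  if (inherits(seqs, "AAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (length(seqs) == 0) abort("no sequences given")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("sequences must be named")
  }
  bad <- grepl(paste0("[^", paste(Biostrings::AA_STANDARD, collapse = ""), "]"),
               seqs)
  if (any(bad)) {
    abort(paste0("non-amino-acid characters in sequence: ",
                 paste(names(seqs)[bad], collapse = ", ")))
  }
  if (length(seqs) == 1) return(names(seqs))

  dist <- medoid_distances(seqs, matrix, gap_open, gap_ext)
  total <- rowSums(dist)
  ids <- names(seqs)
  candidates <- ids[total <= min(total) + 1e-12]
  sort(candidates)[1]
}

# full pairwise normalised-score distance matrix
medoid_distances <- function(seqs, matrix = "BLOSUM62",
                             gap_open = 11, gap_ext = 1) {
  subst <- get(utils::data(list = matrix, package = "Biostrings",
                           envir = environment()))
  aa <- Biostrings::AAStringSet(seqs)
  k <- length(seqs)
  self <- vapply(seq_len(k), function(i) {
    Biostrings::pairwiseAlignment(aa[[i]], aa[[i]], type = "global",
                                  substitutionMatrix = subst,
                                  gapOpening = gap_open,
                                  gapExtension = gap_ext, scoreOnly = TRUE)
  }, numeric(1))
  dist <- matrix(0, k, k, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- Biostrings::pairwiseAlignment(aa[[i]], aa[[j]], type = "global",
                                         substitutionMatrix = subst,
                                         gapOpening = gap_open,
                                         gapExtension = gap_ext,
                                         scoreOnly = TRUE)
      d <- 1 - s / max(self[i], self[j])
      dist[i, j] <- dist[j, i] <- d
    }
  }
  dist
}

#' Functional-category composition of a family set
#'
#' Fractions of one-letter COG categories over a set of families, with an
#' explicit `NA` class for unannotated families. A family annotated with
#' several category letters (e.g. `"EH"`) contributes fractionally to each
#' letter so the composition always sums to 1.
#'
#' @param families Character vector of family ids.
#' @param annotations A data frame with columns `family` and `category`, or a
#'   named character vector (names = family ids). Values are COG category
#'   letter strings or `NA`/`"NA"`.
#' @return A tibble `(category, fraction)`; fractions sum to 1 for non-empty
#'   input. Empty input gives an empty table.
#' @export
category_composition <- function(families, annotations) {
  if (is.data.frame(annotations)) {
    ann <- setNames(as.character(annotations$category), annotations$family)
  } else {
    ann <- annotations
  }
  if (length(families) == 0) {
    return(tibble(category = character(), fraction = double()))
  }
  cats <- unname(ann[families])
  cats[is.na(cats) | cats == "NA" | cats == ""] <- NA_character_

  per_family <- map(cats, function(x) {
    if (is.na(x)) return(tibble(category = NA_character_, weight = 1))
    letters_x <- strsplit(x, "")[[1]]
    tibble(category = letters_x, weight = 1 / length(letters_x))
  })
  bind_rows(per_family) |>
    group_by(.data$category) |>
    summarise(fraction = sum(.data$weight) / length(families),
              .groups = "drop") |>
    arrange(is.na(.data$category), .data$category)
}
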