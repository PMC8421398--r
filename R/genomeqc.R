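#' Read / write a genome-by-feature count matrix
#'
#' Count matrices (genome x marker, genome x gene family) are stored as TSV
#' with genomes as rows: first column `genome`, remaining columns one feature
#' each, integer copy counts.
#'
#' @param path TSV path.
#' @return A tibble with a `genome` character column and integer count
#'   columns.
#' @export
read_count_matrix <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  names(m)[1] <- "genome"
  validate_count_matrix(m)
  m
}

#' @rdname read_count_matrix
#' @param m A count-matrix tibble.
#' @export
write_count_matrix <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

validate_count_matrix <- function(m) {
  if (!is.data.frame(m) || names(m)[1] != "genome") {
    abort("count matrix must have 'genome' as its first column")
  }
  counts <- as.matrix(m[, -1, drop = FALSE])
  if (length(counts) > 0) {
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts))) {
      abort("counts must be non-negative integers")
    }
  }
  if (anyDuplicated(m$genome)) abort("duplicate genome ids")
  invisible(m)
}

#' Drop marker genes absent from every genome
#'
#' Lineage-specific genome sets can lack some markers of a domain-level
#' marker set entirely; keeping them deflates completeness for every genome.
#' This removes markers whose column is all zero.
#'
#' @param m A genome x marker count matrix (see [read_count_matrix()]).
#' @return A list with `retained` and `excluded` marker ids (original column
#'   order preserved) and `matrix`, the input restricted to retained markers.
#' @export
#' @examples
#' m <- tibble::tibble(genome = c("g1", "g2"), m1 = c(1L, 1L), m2 = c(0L, 0L))
#' refine_marker_set(m)$excluded
refine_marker_set <- function(m) {
  validate_count_matrix(m)
  if (nrow(m) < 1) abort("need at least one genome")
  markers <- names(m)[-1]
  absent <- map_lgl(m[markers], ~ all(.x == 0))
  if (all(absent) && length(markers) > 0) {
    warn("every marker is absent from every genome")
  }
  list(retained = markers[!absent],
       excluded = markers[absent],
       matrix = m[, c("genome", markers[!absent]), drop = FALSE])
}

#' Marker-based completeness and contamination estimates
#'
#' A deliberately simple flat-list estimator: completeness is the percentage
#' of markers present at least once; contamination is the percentage of
#' surplus copies, `100 * sum(max(0, count - 1)) / M`. Unlike collocated-set
#' estimators it ignores marker linkage, which is adequate when the marker
#' set has already been refined to the lineage (see [refine_marker_set()]).
#'
#' @param m A genome x marker count matrix.
#' @return A tibble `(genome, completeness, contamination)` in percent.
#' @export
estimate_quality <- function(m) {
  validate_count_matrix(m)
  counts <- as.matrix(m[, -1, drop = FALSE])
  n_markers <- ncol(counts)
  if (n_markers == 0) abort("no markers in matrix")
  tibble(genome = m$genome,
         completeness = 100 * rowSums(counts >= 1) / n_markers,
         contamination = 100 * rowSums(pmax(counts - 1, 0)) / n_markers)
}

#' Gate genomes on completeness and contamination
#'
#' Both strict and non-strict gates are used in practice ("completeness >= 50
#' and contamination <= 10" to admit genomes; "> 79 and < 5" to pick
#' high-quality representatives), so strictness is explicit per gate.
#'
#' @param quality A tibble from [estimate_quality()].
#' @param comp_min Completeness threshold (percent).
#' @param cont_max Contamination ceiling (percent).
#' @param comp_strict If `TRUE`, require completeness strictly `>` comp_min;
#'   otherwise `>=`. Default `FALSE`.
#' @param cont_strict If `TRUE`, require contamination strictly `<` cont_max;
#'   otherwise `<=`. Default `FALSE`.
#' @return Character vector of passing genome ids, input order preserved.
#' @export
filter_genomes <- function(quality, comp_min = 50, cont_max = 10,
                           comp_strict = FALSE, cont_strict = FALSE) {
  comp_ok <- if (comp_strict) quality$completeness > comp_min else
    quality$completeness >= comp_min
  cont_ok <- if (cont_strict) quality$contamination < cont_max else
    quality$contamination <= cont_max
  quality$genome[comp_ok & cont_ok]
}
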