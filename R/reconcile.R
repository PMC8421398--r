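#' Read gene-tree / species-tree reconciliation event frequencies
#'
#' Reads per-family, per-branch expected frequencies of duplications (D),
#' transfers within the sampled genomes (T), losses (L) and originations
#' (O — transfers from unsampled lineages or de novo genes), plus the
#' expected copy number at each node. Two dialects are supported:
#'
#' * `"simple_tsv"` — one file, tab-separated, header
#'   `family  branch  D  T  L  O  copies`, one row per (family, branch).
#' * `"ale_uml"` — one ALE 1.0 `*.uml_rec` file per family; the per-branch
#'   table rows beginning `S_terminal_branch` / `S_internal_branch` are read
#'   (columns: type, branch, Duplications, Transfers, Losses, Originations,
#'   copies) and the family id is the file name without its extension.
#'
#' Cells absent from the input are zero. All frequencies must be finite and
#' non-negative.
#'
#' @param path File path (`simple_tsv`) or vector of file paths (`ale_uml`).
#' @param dialect Input dialect.
#' @param branches Optional vector of valid branch ids; any other branch id in
#'   the input is an error reported with its line number.
#' @return A `reconciliation_table` tibble:
#'   `(family, branch, D, T, L, O, copies)`.
#' @export
read_reconciliation <- function(path, dialect = c("simple_tsv", "ale_uml"),
                                branches = NULL) {
  dialect <- match.arg(dialect)
  rt <- switch(dialect,
               simple_tsv = parse_simple_tsv(path, branches),
               ale_uml = parse_ale_uml(path, branches))
  new_reconciliation_table(rt)
}

new_reconciliation_table <- function(df) {
  df <- as_tibble(df)
  needed <- c("family", "branch", "D", "T", "L", "O", "copies")
  stopifnot(all(needed %in% names(df)))
  df <- df[needed]
  num <- as.matrix(df[c("D", "T", "L", "O", "copies")])
  if (any(!is.finite(num))) abort("frequencies must be finite")
  if (any(num < 0)) abort("negative frequency")
  # complete the family x branch grid with zeros
  df <- tidyr::complete(df, .data$family, .data$branch,
                        fill = list(D = 0, T = 0, L = 0, O = 0, copies = 0))
  class(df) <- c("reconciliation_table", class(df))
  df
}

parse_simple_tsv <- function(path, branches) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort("empty reconciliation file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("family", "branch", "D", "T", "L", "O", "copies")
  if (!identical(header, expected)) {
    abort(paste0("line 1: expected header '",
                 paste(expected, collapse = "\t"), "'"))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  parsed <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    lineno <- i + 1
    if (length(f) != 7) {
      abort(paste0("line ", lineno, ": expected 7 fields, found ", length(f)))
    }
    vals <- suppressWarnings(as.numeric(f[3:7]))
    if (any(is.na(vals))) {
      abort(paste0("line ", lineno, ": non-numeric frequency"))
    }
    if (any(vals < 0)) abort(paste0("line ", lineno, ": negative frequency"))
    if (!is.null(branches) && !f[2] %in% branches) {
      abort(paste0("line ", lineno, ": unknown branch id '", f[2], "'"))
    }
    parsed[[i]] <- tibble(family = f[1], branch = f[2],
                          D = vals[1], T = vals[2], L = vals[3],
                          O = vals[4], copies = vals[5])
  }
  bind_rows(parsed)
}

parse_ale_uml <- function(paths, branches) {
  out <- map(paths, function(p) {
    fam <- sub("\\.[^.]*$", "", basename(p))
    lines <- readLines(p, warn = FALSE)
    idx <- grep("^S_(terminal|internal)_branch\\b", lines)
    if (length(idx) == 0) {
      abort(paste0(p, ": no S_terminal_branch/S_internal_branch rows found"))
    }
    rows <- strsplit(lines[idx], "\t|[[:space:]]+")
    parsed <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      f <- rows[[k]]
      lineno <- idx[k]
      if (length(f) < 7) {
        abort(paste0(p, " line ", lineno, ": expected 7 fields"))
      }
      vals <- suppressWarnings(as.numeric(f[3:7]))
      if (any(is.na(vals))) {
        abort(paste0(p, " line ", lineno, ": non-numeric frequency"))
      }
      if (!is.null(branches) && !f[2] %in% branches) {
        abort(paste0(p, " line ", lineno, ": unknown branch id '", f[2], "'"))
      }
      parsed[[k]] <- tibble(family = fam, branch = f[2],
                            D = vals[1], T = vals[2], L = vals[3],
                            O = vals[4], copies = vals[5])
    }
    bind_rows(parsed)
  })
  bind_rows(out)
}

#' Count events above a frequency threshold
#'
#' Reconciliation frequencies are expectations over sampled reconciliations;
#' an event is counted as real on a branch when its frequency is strictly
#' over `tau` (default 0.3 — a deliberately relaxed threshold since
#' alignment and gene-tree noise dilute true event frequencies). Set
#' `inclusive = TRUE` for a `>=` reading. Gains on a branch are the union of
#' counted duplications, transfers and originations.
#'
#' @param rt A [read_reconciliation()] table.
#' @param tau Frequency threshold, `>= 0`. Default 0.3.
#' @param inclusive Count events with frequency exactly `tau` as well.
#' @return An `event_summary`: list with `branches` (tibble `branch`, `n_D`,
#'   `n_T`, `n_L`, `n_O`, `n_gain`, `n_copies`), `gains` (tibble `branch`,
#'   `family` of gained families) and `tau`.
#' @export
threshold_events <- function(rt, tau = 0.3, inclusive = FALSE) {
  stopifnot(tau >= 0)
  over <- if (inclusive) function(x) x >= tau else function(x) x > tau

  flagged <- rt |>
    mutate(d = over(.data$D), t = over(.data$T),
           l = over(.data$L), o = over(.data$O),
           cp = over(.data$copies))
  branches <- flagged |>
    group_by(.data$branch) |>
    summarise(n_D = sum(.data$d), n_T = sum(.data$t),
              n_L = sum(.data$l), n_O = sum(.data$o),
              n_copies = sum(.data$cp), .groups = "drop") |>
    mutate(n_gain = .data$n_D + .data$n_T + .data$n_O) |>
    select("branch", "n_D", "n_T", "n_L", "n_O", "n_gain", "n_copies")
  gains <- flagged |>
    filter(.data$d | .data$t | .data$o) |>
    select("branch", "family") |>
    arrange(.data$branch, .data$family)

  structure(list(branches = branches, gains = gains, tau = tau),
            class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat("<event_summary> tau = ", x$tau, ", ", nrow(x$branches),
      " branches, ", nrow(x$gains), " gain events\n", sep = "")
  print(x$branches)
  invisible(x)
}

#' @describeIn threshold_events Per-branch event counts as a tibble.
#' @param x An `event_summary`.
#' @param ... Unused.
#' @method tidy event_summary
#' @export
tidy.event_summary <- function(x, ...) x$branches

#' @describeIn threshold_events Totals over all branches.
#' @method glance event_summary
#' @export
glance.event_summary <- function(x, ...) {
  with(x$branches,
       tibble(n_branches = length(branch),
              total_D = sum(n_D), total_T = sum(n_T),
              total_L = sum(n_L), total_O = sum(n_O),
              total_gain = sum(n_gain)))
}

#' @describeIn threshold_events Stacked per-branch bar chart of counted
#'   duplication / transfer / loss / origination events.
#' @param object An `event_summary`.
#' @method autoplot event_summary
#' @export
autoplot.event_summary <- function(object, ...) {
  df <- object$branches |>
    tidyr::pivot_longer(c("n_D", "n_T", "n_L", "n_O"),
                        names_to = "event", values_to = "count") |>
    mutate(event = factor(.data$event, levels = c("n_O", "n_T", "n_D", "n_L"),
                          labels = c("origination", "transfer",
                                     "duplication", "loss")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$branch, y = .data$count,
                                   fill = .data$event)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "branch", y = "events counted", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Decompose gene gains on a branch
#'
#' Gains are originations + intra-transfers + duplications; shares are each
#' component over the total, reported to the nearest percent. With no gains
#' on the branch the shares are `NA`.
#'
#' @param es An [threshold_events()] summary.
#' @param branch Branch id(s); default all branches.
#' @return A tibble `(branch, n_O, n_T, n_D, n_gain, share_O, share_T,
#'   share_D)` with shares in whole percent.
#' @export
summarize_gains <- function(es, branch = NULL) {
  b <- es$branches
  if (!is.null(branch)) {
    missing <- setdiff(branch, b$branch)
    if (length(missing) > 0) {
      abort(paste0("unknown branch: ", paste(missing, collapse = ", ")))
    }
    b <- b[b$branch %in% branch, , drop = FALSE]
  }
  b |>
    mutate(share_O = ifelse(.data$n_gain > 0,
                            round(100 * .data$n_O / .data$n_gain), NA_real_),
           share_T = ifelse(.data$n_gain > 0,
                            round(100 * .data$n_T / .data$n_gain), NA_real_),
           share_D = ifelse(.data$n_gain > 0,
                            round(100 * .data$n_D / .data$n_gain), NA_real_)) |>
    select("branch", "n_O", "n_T", "n_D", "n_gain",
           "share_O", "share_T", "share_D")
}

#' Functional composition of the genes gained on a branch
#'
#' @inheritParams summarize_gains
#' @param branch A single branch id.
#' @param annotations Family annotations as in [category_composition()].
#' @return A tibble `(category, fraction)`; empty when the branch gained
#'   nothing.
#' @export
gain_composition <- function(es, branch, annotations) {
  if (!branch %in% es$branches$branch) {
    abort(paste0("unknown branch: ", branch))
  }
  fams <- es$gains$family[es$gains$branch == branch]
  category_composition(fams, annotations)
}
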