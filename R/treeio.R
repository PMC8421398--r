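#' Read a Newick tree with dual node-support labels
#'
#' Parses a Newick string (or file) into an [ape::phylo] object, validating
#' the structural invariants that downstream delineation relies on: unique
#' non-empty leaf names, non-negative branch lengths, and — when internal node
#' labels carry support values — supports within \[0, 100\].
#'
#' IQ-Tree runs that request both ultrafast bootstrap and SH-aLRT write the
#' two supports on one internal label, separated by a slash. Which value comes
#' first depends on the tool version, so the order is explicit here rather
#' than guessed: with the default `ufboot_first = FALSE` a label `"80/95"` is
#' read as SH-aLRT 80, UFBOOT 95.
#'
#' @param text A Newick string, or a path to a file containing one tree.
#' @param support_dialect How internal node labels encode support:
#'   `"slash_pair"` (two values, `x/y`), `"single"` (one numeric value, stored
#'   as UFBOOT), or `"none"` (labels ignored).
#' @param ufboot_first For `"slash_pair"`: is the first value the ultrafast
#'   bootstrap? Default `FALSE` (SH-aLRT first, matching IQ-Tree
#'   `-bb 1000 -alrt 1000` output).
#' @return A `phylo` object. Node labels are kept verbatim; use
#'   [node_supports()] to extract them as numbers.
#' @seealso [node_supports()], [root_by_outgroup()], [write_newick()]
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1)95/80:1,C:2);", ufboot_first = TRUE)
#' node_supports(tr, ufboot_first = TRUE)
read_newick <- function(text,
                        support_dialect = c("slash_pair", "single", "none"),
                        ufboot_first = FALSE) {
  support_dialect <- match.arg(support_dialect)
  if (length(text) == 1 && !grepl(";", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) abort("could not parse Newick string")

  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate leaf names: ", paste(dups, collapse = ", ")))
  }
  if (any(!nzchar(tree$tip.label))) abort("empty leaf name")

  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (any(!is.finite(tree$edge.length))) {
    warn("missing branch lengths set to 0")
    tree$edge.length[!is.finite(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")

  # validate supports eagerly so malformed labels fail at read time
  if (support_dialect != "none" && !is.null(tree$node.label)) {
    sup <- node_supports(tree, support_dialect, ufboot_first)
    bad <- stats::na.omit(c(sup$ufboot, sup$shalrt))
    if (any(bad < 0 | bad > 100)) {
      abort("support values must lie in [0, 100]")
    }
  }
  tree
}

# cheap structural scan so parse failures report a character offset,
# which ape::read.tree does not
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("malformed Newick: unbalanced ')' at character ", i))
      }
    }
  }
  if (depth != 0L) {
    abort(paste0("malformed Newick: ", depth,
                 " unclosed '(' at character ", length(chars)))
  }
  if (!grepl(";\\s*$", text)) {
    abort(paste0("malformed Newick: missing terminal ';' at character ",
                 length(chars)))
  }
  invisible(TRUE)
}

#' Extract numeric node supports from internal labels
#'
#' @param tree A `phylo` object with (optionally) internal node labels.
#' @inheritParams read_newick
#' @return A tibble with one row per internal node: `node` (ape node id),
#'   `label`, `ufboot`, `shalrt` (NA where absent or unparseable).
#' @export
node_supports <- function(tree,
                          support_dialect = c("slash_pair", "single", "none"),
                          ufboot_first = FALSE) {
  support_dialect <- match.arg(support_dialect)
  nt <- n_tips(tree)
  nodes <- nt + seq_len(tree$Nnode)
  labels <- tree$node.label %||% rep(NA_character_, tree$Nnode)
  labels[!nzchar(labels) | is.na(labels)] <- NA_character_

  out <- tibble(node = nodes, label = labels,
                ufboot = NA_real_, shalrt = NA_real_)
  if (support_dialect == "none") return(out)

  if (support_dialect == "single") {
    out$ufboot <- suppressWarnings(as.numeric(labels))
    return(out)
  }
  parts <- strsplit(labels, "/", fixed = TRUE)
  first <- suppressWarnings(as.numeric(map_chr(parts, ~ .x[1] %||% NA_character_)))
  second <- suppressWarnings(as.numeric(map_chr(parts, ~ .x[2] %||% NA_character_)))
  if (ufboot_first) {
    out$ufboot <- first
    out$shalrt <- second
  } else {
    out$shalrt <- first
    out$ufboot <- second
  }
  out
}

#' Write a tree to Newick
#'
#' Branch lengths are written with 9 significant digits so a
#' read-write-read round trip preserves them to well below the package's
#' numerical tolerances.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 9)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root a tree on the branch separating an outgroup
#'
#' @param tree A `phylo` object (rooted or unrooted; it is unrooted first).
#' @param outgroup_leaves Character vector of leaf names forming the outgroup.
#'   Must be a non-empty proper subset of the leaves and monophyletic in the
#'   unrooted topology.
#' @return A rooted `phylo` whose root has two children, one of which subtends
#'   exactly the outgroup. Total branch length and all leaf pairwise path
#'   distances are conserved. Internal node labels are carried as edge
#'   (branch) supports across the rerooting.
#' @export
root_by_outgroup <- function(tree, outgroup_leaves) {
  outgroup_leaves <- unique(outgroup_leaves)
  if (length(outgroup_leaves) == 0) abort("outgroup is empty")
  missing <- setdiff(outgroup_leaves, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("outgroup leaves not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(outgroup_leaves) >= n_tips(tree)) {
    abort("outgroup cannot contain every leaf")
  }

  ut <- ape::unroot(tree)
  if (!outgroup_is_monophyletic(ut, outgroup_leaves)) {
    abort(paste0("outgroup is not monophyletic: ",
                 paste(sort(outgroup_leaves), collapse = ", ")))
  }
  rt <- ape::root(ut, outgroup = outgroup_leaves,
                  resolve.root = TRUE, edgelabel = TRUE)
  # ape labels the created root node; drop that artefact
  if (!is.null(rt$node.label)) {
    rl <- rt$node.label[1]
    if (identical(rl, "Root")) rt$node.label[1] <- ""
  }
  rt
}

# monophyly of a leaf set in the unrooted topology: root anywhere outside the
# set; the set is monophyletic iff its MRCA subtends exactly the set
outgroup_is_monophyletic <- function(tree, leaves) {
  if (length(leaves) == 1) return(TRUE)
  anchor <- setdiff(tree$tip.label, leaves)[1]
  rt <- ape::root(tree, outgroup = anchor, resolve.root = TRUE)
  mrca <- ape::getMRCA(rt, leaves)
  setequal(clade_tip_labels(rt, mrca), leaves)
}
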