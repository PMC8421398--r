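#' Thresholds for subgroup delineation
#'
#' Default values follow the delineation rule used for Woesearchaeota
#' subgroups: a clade is a subgroup when its RED value and its stem length on
#' the unit-depth ultrametric tree both *exceed* 0.4 (strict), and its
#' monophyly is well supported (UFBOOT >= 95 and SH-aLRT >= 80, non-strict).
#' A per-clade override lets a named clade use a different RED threshold
#' (e.g. 0.3 for one deep-rooting subgroup) without post-hoc relabelling: an
#' override is keyed by an anchor leaf set and applies to the MRCA of those
#' leaves.
#'
#' @param red_min Minimum RED, strict `>`. Default 0.4.
#' @param stem_min Minimum stem length on the unit-depth ultrametric tree,
#'   strict `>`. Default 0.4.
#' @param ufboot_min Minimum ultrafast bootstrap support, `>=`. Default 95.
#' @param shalrt_min Minimum SH-aLRT support, `>=`. Default 80.
#' @param overrides List of `list(anchor = <leaf names>, red_min = <value>)`
#'   entries; each lowers (or raises) the RED threshold for the clade whose
#'   MRCA covers the anchor leaves.
#' @return A `delineation_params` list.
#' @export
delineation_params <- function(red_min = 0.4, stem_min = 0.4,
                               ufboot_min = 95, shalrt_min = 80,
                               overrides = list()) {
  stopifnot(red_min >= 0, red_min <= 1, stem_min >= 0, stem_min <= 1,
            ufboot_min >= 0, ufboot_min <= 100,
            shalrt_min >= 0, shalrt_min <= 100)
  for (ov in overrides) {
    if (is.null(ov$anchor) || is.null(ov$red_min)) {
      abort("each override needs an 'anchor' leaf set and a 'red_min'")
    }
  }
  structure(list(red_min = red_min, stem_min = stem_min,
                 ufboot_min = ufboot_min, shalrt_min = shalrt_min,
                 overrides = overrides),
            class = "delineation_params")
}

#' Delineate subgroups as maximal well-supported clades
#'
#' Traverses the annotated tree in preorder and selects every internal node
#' that (i) has both supports at or above their thresholds, (ii) has RED
#' strictly above its threshold (global or per-clade override), and (iii) has
#' a stem length on the unit-depth ultrametric tree strictly above the stem
#' threshold — provided none of its ancestors was already selected, so the
#' selected clades are maximal and mutually disjoint. Nodes lacking support
#' values are treated as failing. Leaves under selected clades are labelled
#' `A`, `B`, `C`, ... in preorder encounter order (children visited in order
#' of their lexicographically smallest descendant leaf name); all other
#' ingroup leaves are `UNGROUPED`, and outgroup leaves are `OUTGROUP`.
#'
#' @param red_tree A [red_annotate()] object.
#' @param params A [delineation_params()] object.
#' @param outgroup Leaf names to mark as outgroup; clades containing any of
#'   them are never selected.
#' @return A `subgroup_assignment`: list with `leaves` (tibble `leaf`,
#'   `subgroup`), `subgroups` (tibble `subgroup`, `node`, `n_leaves`, `red`,
#'   `stem_length`, `ufboot`, `shalrt`) and the `params` used.
#' @export
delineate_subgroups <- function(red_tree, params = delineation_params(),
                                outgroup = character()) {
  if (!inherits(red_tree, "red_tree")) {
    abort("red_tree must be a red_tree from red_annotate(); RED annotation is required")
  }
  if (!inherits(params, "delineation_params")) {
    abort("params must come from delineation_params()")
  }
  tree <- red_tree$tree
  nt <- n_tips(tree)
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(ingroup) == 0) abort("empty ingroup: every leaf is in the outgroup")

  sup <- red_tree$supports
  ufboot <- shalrt <- rep(NA_real_, nt + tree$Nnode)
  ufboot[sup$node] <- sup$ufboot
  shalrt[sup$node] <- sup$shalrt

  # per-node RED threshold, with anchor-set overrides applied at the MRCA
  red_min <- rep(params$red_min, nt + tree$Nnode)
  for (ov in params$overrides) {
    anchor <- ov$anchor
    missing <- setdiff(anchor, tree$tip.label)
    if (length(missing) > 0) {
      abort(paste0("override anchor leaves not in tree: ",
                   paste(missing, collapse = ", ")))
    }
    node <- if (length(anchor) == 1) {
      match(anchor, tree$tip.label)
    } else {
      ape::getMRCA(tree, anchor)
    }
    red_min[node] <- ov$red_min
  }

  children <- tree_children(tree)
  has_outgroup <- clade_has_leaf(tree, children, outgroup)
  min_leaf <- min_descendant_leaf(tree, children)

  qualifies <- function(nd) {
    nd > nt &&
      !has_outgroup[nd] &&
      !is.na(ufboot[nd]) && !is.na(shalrt[nd]) &&
      ufboot[nd] >= params$ufboot_min &&
      shalrt[nd] >= params$shalrt_min &&
      red_tree$red[nd] > red_min[nd] &&
      !is.na(red_tree$stem[nd]) &&
      red_tree$stem[nd] > params$stem_min
  }

  selected <- integer(0)
  stack <- root_node(tree)
  while (length(stack) > 0) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (qualifies(nd)) {
      selected <- c(selected, nd)
      next  # maximal: do not descend into a selected clade
    }
    kids <- children[[nd]]
    if (length(kids) > 0) {
      kids <- kids[order(min_leaf[kids])]       # deterministic label order
      stack <- c(stack, rev(kids))
    }
  }

  labels <- subgroup_labels(length(selected))
  leaf_label <- setNames(rep("UNGROUPED", nt), tree$tip.label)
  leaf_label[outgroup] <- "OUTGROUP"
  sub_rows <- vector("list", length(selected))
  for (i in seq_along(selected)) {
    nd <- selected[i]
    tips <- clade_tip_labels(tree, nd)
    leaf_label[tips] <- labels[i]
    sub_rows[[i]] <- tibble(
      subgroup = labels[i], node = nd, n_leaves = length(tips),
      red = red_tree$red[nd], stem_length = red_tree$stem[nd],
      ufboot = ufboot[nd], shalrt = shalrt[nd])
  }

  structure(
    list(leaves = tibble(leaf = tree$tip.label,
                         subgroup = unname(leaf_label[tree$tip.label])),
         subgroups = if (length(sub_rows)) bind_rows(sub_rows) else
           tibble(subgroup = character(), node = integer(),
                  n_leaves = integer(), red = double(),
                  stem_length = double(), ufboot = double(),
                  shalrt = double()),
         params = params),
    class = "subgroup_assignment")
}

# does the clade under each node contain any of the given leaves?
clade_has_leaf <- function(tree, children, leaves) {
  nt <- n_tips(tree)
  flag <- rep(FALSE, nt + tree$Nnode)
  flag[match(intersect(leaves, tree$tip.label), tree$tip.label)] <- TRUE
  for (nd in postorder_nodes(tree)) {
    kids <- children[[nd]]
    if (length(kids) > 0) flag[nd] <- any(flag[kids])
  }
  flag
}

# lexicographically smallest descendant leaf name per node
min_descendant_leaf <- function(tree, children) {
  nt <- n_tips(tree)
  mn <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  for (nd in postorder_nodes(tree)) {
    kids <- children[[nd]]
    if (length(kids) > 0) mn[nd] <- min(mn[kids])
  }
  mn
}

# A, B, ..., Z, AA, AB, ... — enough labels for any number of subgroups
subgroup_labels <- function(k) {
  if (k <= 26) return(LETTERS[seq_len(k)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(k)]
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat("<subgroup_assignment> ", nrow(x$subgroups), " subgroups, ",
      sum(x$leaves$subgroup == "UNGROUPED"), " ungrouped of ",
      nrow(x$leaves), " leaves\n", sep = "")
  print(x$subgroups)
  invisible(x)
}

#' @describeIn delineate_subgroups Leaf-level table: `leaf`, `subgroup`.
#' @param x A `subgroup_assignment`.
#' @param ... Unused.
#' @method tidy subgroup_assignment
#' @export
tidy.subgroup_assignment <- function(x, ...) x$leaves

#' @describeIn delineate_subgroups One-row summary: number of subgroups,
#'   grouped, ungrouped and outgroup leaves.
#' @method glance subgroup_assignment
#' @export
glance.subgroup_assignment <- function(x, ...) {
  tibble(n_subgroups = nrow(x$subgroups),
         n_grouped = sum(!x$leaves$subgroup %in% c("UNGROUPED", "OUTGROUP")),
         n_ungrouped = sum(x$leaves$subgroup == "UNGROUPED"),
         n_outgroup = sum(x$leaves$subgroup == "OUTGROUP"))
}

#' Cross-tabulate subgroups against externally defined 16S clusters
#'
#' Links tree-derived subgroups with previously described 16S rRNA gene
#' cluster labels available for a subset of the leaves.
#'
#' @param assignment A [delineate_subgroups()] result.
#' @param leaf_to_cluster A data frame with columns `leaf` and `cluster`, or a
#'   named character vector (names = leaves). The mapping must be
#'   single-valued; a leaf mapped to two clusters is an error. Leaves absent
#'   from the mapping are simply not counted.
#' @return A tibble `(subgroup, cluster, n_shared_leaves)` with one row per
#'   pair sharing at least one leaf, ordered by subgroup then cluster.
#' @export
map_to_16s_clusters <- function(assignment, leaf_to_cluster) {
  if (!is.data.frame(leaf_to_cluster)) {
    leaf_to_cluster <- tibble(leaf = names(leaf_to_cluster),
                              cluster = unname(leaf_to_cluster))
  }
  leaf_to_cluster <- distinct(as_tibble(leaf_to_cluster))
  dup <- leaf_to_cluster$leaf[duplicated(leaf_to_cluster$leaf)]
  if (length(dup) > 0) {
    abort(paste0("leaf mapped to multiple clusters: ",
                 paste(unique(dup), collapse = ", ")))
  }
  assignment$leaves |>
    filter(!.data$subgroup %in% c("UNGROUPED", "OUTGROUP")) |>
    inner_join(leaf_to_cluster, by = "leaf") |>
    count(.data$subgroup, .data$cluster, name = "n_shared_leaves") |>
    arrange(.data$subgroup, .data$cluster)
}
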