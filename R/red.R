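#' Convert a rooted tree to ultrametric form by mean-path-length smoothing
#'
#' Assigns every internal node an age equal to the mean path length from the
#' node to its descendant leaves (leaves have age 0), then clamps ages in a
#' top-down pass, `age(n) <- min(age(n), age(parent(n)))`, which guarantees
#' non-negative branch lengths and exact ultrametricity. The method is
#' deterministic and parameter-free; no rate model or calibrations are used.
#'
#' @param tree A rooted `phylo` with at least two leaves.
#' @param method Smoothing method; only `"mpl"` (mean path length) is
#'   implemented.
#' @return A `phylo` with identical topology in which every root-to-leaf path
#'   has the same length (the root age).
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:3):1,C:4);", support_dialect = "none")
#' write_newick(make_ultrametric(tr))
make_ultrametric <- function(tree, method = c("mpl")) {
  method <- match.arg(method)
  assert_rooted(tree)
  if (n_tips(tree) < 2) abort("tree must have at least 2 leaves")

  stats <- leaf_path_stats(tree)
  age <- stats$sum_len / stats$n_leaves   # MPL age; 0 at leaves
  parent <- tree_parent(tree)
  for (nd in preorder_nodes(tree)) {
    p <- parent[nd]
    if (!is.na(p) && age[nd] > age[p]) age[nd] <- age[p]
  }
  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  out
}

#' Rescale an ultrametric tree to unit root-to-tip depth
#'
#' Divides every branch length by the root-to-tip depth so that thresholds on
#' branch lengths (such as the 0.4 subgroup stem criterion) are scale-free.
#'
#' @param tree A rooted, ultrametric `phylo`.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return A `phylo` with root-to-tip depth 1.
#' @export
normalize_depth <- function(tree, tol = 1e-8) {
  assert_rooted(tree)
  if (!ape::is.ultrametric(tree, option = 2)) {
    abort("tree is not ultrametric; see make_ultrametric()")
  }
  depth <- max(node_depths_all(tree))
  if (depth <= tol) abort("tree has zero depth (all branch lengths 0)")
  out <- tree
  out$edge.length <- tree$edge.length / depth
  out
}

#' Relative evolutionary divergence (RED) of every node
#'
#' RED linearly interpolates divergence between the root (RED 0) and the
#' leaves (RED 1). In a preorder pass, a node `n` with parent `p` gets
#' `RED(n) = RED(p) + (d/u) * (1 - RED(p))`, where `d` is the branch length
#' from `p` to `n` and `u` is the mean path length from `p` to all leaves
#' descending through `n` (that is, `d` plus the mean node-to-leaf distance
#' below `n`). Leaves are pinned to 1 by convention. If `u = 0` (an all-zero
#' subtree) the node inherits its parent's RED with a warning.
#'
#' @param tree A rooted `phylo` with non-negative branch lengths.
#' @return A numeric vector of RED values indexed by ape node id
#'   (tips `1..N`, internals `N+1..N+Nnode`).
#' @export
compute_red <- function(tree) {
  assert_rooted(tree)
  if (any(tree$edge.length < 0)) abort("branch lengths must be non-negative")

  nt <- n_tips(tree)
  np <- nt + tree$Nnode
  stats <- leaf_path_stats(tree)
  mean_below <- stats$sum_len / stats$n_leaves
  len <- edge_len_to(tree)
  parent <- tree_parent(tree)

  red <- rep(NA_real_, np)
  red[root_node(tree)] <- 0
  zero_u <- FALSE
  for (nd in preorder_nodes(tree)) {
    p <- parent[nd]
    if (is.na(p)) next
    if (nd <= nt) {
      red[nd] <- 1
      next
    }
    u <- len[nd] + mean_below[nd]
    if (u <= 0) {
      red[nd] <- red[p]
      zero_u <- TRUE
    } else {
      red[nd] <- red[p] + (len[nd] / u) * (1 - red[p])
    }
  }
  if (zero_u) warn("all-zero subtree: RED set to parent value for some nodes")
  red
}

#' Annotate a rooted tree with RED, ultrametric depths and node supports
#'
#' Bundles everything subgroup delineation needs: RED values computed on the
#' original rooted tree (matching GTDB practice; set `red_on_ultrametric` to
#' compute them on the smoothed tree instead), the depth-normalised
#' ultrametric copy of the tree, per-node depths and stem lengths on that
#' copy, and the parsed dual node supports.
#'
#' @inheritParams read_newick
#' @param tree A rooted `phylo`.
#' @param red_on_ultrametric Compute RED on the normalised ultrametric tree
#'   rather than on the original branch lengths. Default `FALSE`.
#' @return An object of class `red_tree`: a list with elements `tree`,
#'   `ultra` (unit-depth ultrametric copy), `red`, `depth`, `stem`
#'   (normalised stem length above each node), `supports` (tibble), and
#'   `root_depth` (pre-normalisation root-to-tip depth).
#' @export
red_annotate <- function(tree,
                         support_dialect = c("slash_pair", "single", "none"),
                         ufboot_first = FALSE,
                         red_on_ultrametric = FALSE) {
  support_dialect <- match.arg(support_dialect)
  assert_rooted(tree)
  ultra <- make_ultrametric(tree)
  root_depth <- max(node_depths_all(ultra))
  ultra <- normalize_depth(ultra)
  red <- compute_red(if (red_on_ultrametric) ultra else tree)
  structure(
    list(tree = tree,
         ultra = ultra,
         red = red,
         depth = node_depths_all(ultra),
         stem = edge_len_to(ultra),
         supports = node_supports(tree, support_dialect, ufboot_first),
         root_depth = root_depth),
    class = "red_tree")
}

#' @export
print.red_tree <- function(x, ...) {
  cat("<red_tree> ", n_tips(x$tree), " leaves, ", x$tree$Nnode,
      " internal nodes, root depth ", format(x$root_depth, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn red_annotate One row per node: id, label, RED, ultrametric
#'   depth, stem length, supports, leaf flag.
#' @param x A `red_tree`.
#' @param ... Unused.
#' @method tidy red_tree
#' @export
tidy.red_tree <- function(x, ...) {
  nt <- n_tips(x$tree)
  np <- nt + x$tree$Nnode
  nodes <- seq_len(np)
  lbl <- c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode))
  tibble(node = nodes,
         label = lbl,
         is_leaf = nodes <= nt,
         red = x$red[nodes],
         depth = x$depth[nodes],
         stem_length = x$stem[nodes]) |>
    left_join(select(x$supports, "node", "ufboot", "shalrt"), by = "node")
}

#' @describeIn red_annotate One-row summary of the annotated tree.
#' @method glance red_tree
#' @export
glance.red_tree <- function(x, ...) {
  internal <- (n_tips(x$tree) + 1):(n_tips(x$tree) + x$tree$Nnode)
  tibble(n_leaves = n_tips(x$tree),
         n_internal = x$tree$Nnode,
         root_depth = x$root_depth,
         median_internal_red = stats::median(x$red[internal]))
}

#' @describeIn red_annotate Scatter of RED against normalised ultrametric
#'   node depth; on a clock-like tree points fall on the diagonal.
#' @param object A `red_tree`.
#' @method autoplot red_tree
#' @export
autoplot.red_tree <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$red,
                                   colour = .data$is_leaf)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "node depth (unit-depth ultrametric tree)",
                  y = "relative evolutionary divergence",
                  colour = "leaf") +
    ggplot2::theme_minimal()
}
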