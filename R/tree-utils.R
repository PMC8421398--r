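# Internal traversal helpers over ape "phylo" trees.
# Node numbering follows ape: tips 1..N, internals (N+1)..(N+Nnode), root N+1
# on a rooted tree.

n_tips <- function(tree) length(tree$tip.label)

root_node <- function(tree) n_tips(tree) + 1L

#' @noRd
tree_parent <- function(tree) {
  np <- n_tips(tree) + tree$Nnode
  parent <- rep(NA_integer_, np)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

#' @noRd
tree_children <- function(tree) {
  np <- n_tips(tree) + tree$Nnode
  ch <- vector("list", np)
  sp <- split(tree$edge[, 2], tree$edge[, 1])
  for (k in names(sp)) ch[[as.integer(k)]] <- as.integer(sp[[k]])
  ch
}

# branch length from parent, indexed by child node; NA at the root
edge_len_to <- function(tree) {
  np <- n_tips(tree) + tree$Nnode
  len <- rep(NA_real_, np)
  if (!is.null(tree$edge.length)) len[tree$edge[, 2]] <- tree$edge.length
  len
}

# nodes in preorder (parents before children)
preorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  c(root_node(tree), edge[, 2])
}

# nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  c(edge[, 2], root_node(tree))
}

# root-to-node path length for every node
node_depths_all <- function(tree) {
  np <- n_tips(tree) + tree$Nnode
  depth <- rep(0, np)
  len <- edge_len_to(tree)
  parent <- tree_parent(tree)
  for (nd in preorder_nodes(tree)) {
    if (!is.na(parent[nd])) depth[nd] <- depth[parent[nd]] + len[nd]
  }
  depth
}

# per node: number of descendant leaves and the sum of path lengths from the
# node down to each of them (a leaf counts itself at distance 0)
leaf_path_stats <- function(tree) {
  np <- n_tips(tree) + tree$Nnode
  nl <- rep(0L, np)
  sl <- rep(0, np)
  nl[seq_len(n_tips(tree))] <- 1L
  len <- edge_len_to(tree)
  parent <- tree_parent(tree)
  for (nd in postorder_nodes(tree)) {
    p <- parent[nd]
    if (!is.na(p)) {
      nl[p] <- nl[p] + nl[nd]
      sl[p] <- sl[p] + sl[nd] + nl[nd] * len[nd]
    }
  }
  list(n_leaves = nl, sum_len = sl)
}

# tip labels under a node (the node itself if a tip)
clade_tip_labels <- function(tree, node) {
  if (node <= n_tips(tree)) return(tree$tip.label[node])
  tips <- phangorn::Descendants(tree, node, type = "tips")[[1]]
  tree$tip.label[tips]
}

# all pairwise leaf path distances, used by rooting invariance checks
leaf_dist_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}

assert_rooted <- function(tree, hint = "root_by_outgroup()") {
  if (!ape::is.rooted(tree)) {
    abort(paste0("tree must be rooted; see ", hint))
  }
}
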