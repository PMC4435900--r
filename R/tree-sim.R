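#' Simulate a pure-birth (Yule) species tree
#'
#' Grows a rooted, strictly bifurcating tree forward in time under a constant
#' per-lineage birth rate. Starting from the root split (two lineages), while
#' `k` lineages are extant the waiting time to the next split is
#' Exponential(`k * birth_rate`) and the splitting lineage is chosen uniformly.
#' After the `n_taxa`-th lineage appears, one final Exponential(`n_taxa *
#' birth_rate`) epoch is added to every pending branch so that terminal
#' branches have positive length and sister species are separated by time.
#' Under this construction the expected root-to-tip height is
#' `sum(1 / (k * birth_rate))` for `k = 2 .. n_taxa`.
#'
#' Leaves are labelled `sp001, sp002, ...` and internal nodes `n001, n002,
#' ...`, both in preorder, so downstream node-level results are stable and
#' the Newick output always carries internal labels.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate per-lineage speciation rate (> 0), in the same time
#'   units as branch lengths.
#' @param seed integer seed; the tree is byte-identical for a fixed seed.
#' @return An [ape::phylo] object with `node.label` set.
#' @examples
#' tr <- sample_tree(8, birth_rate = 1, seed = 1)
#' ape::Ntip(tr)   # 8
#' ape::Nnode(tr)  # 7
#' @export
sample_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 2 ||
      n_taxa != round(n_taxa)) {
    stop("'n_taxa' must be a single integer >= 2")
  }
  if (!is.numeric(birth_rate) || length(birth_rate) != 1L || birth_rate <= 0) {
    stop("'birth_rate' must be a single positive number")
  }
  n_taxa <- as.integer(n_taxa)

  with_seed(seed, {
    # Node bookkeeping in creation order; node 1 is the root.
    max_nodes <- 2L * n_taxa - 1L
    parent <- integer(max_nodes)
    blen <- numeric(max_nodes)
    is_tip <- logical(max_nodes)
    next_id <- 1L
    parent[1L] <- 0L
    next_id <- 2L

    # Active lineages: parent node id and length accumulated so far.
    act_parent <- c(1L, 1L)
    act_len <- c(0, 0)
    k <- 2L
    while (k < n_taxa) {
      act_len <- act_len + stats::rexp(1L, k * birth_rate)
      i <- sample.int(k, 1L)
      v <- next_id
      next_id <- next_id + 1L
      parent[v] <- act_parent[i]
      blen[v] <- act_len[i]
      # lineage i is replaced by two fresh daughters of v
      act_parent[i] <- v
      act_len[i] <- 0
      act_parent <- c(act_parent, v)
      act_len <- c(act_len, 0)
      k <- k + 1L
    }
    act_len <- act_len + stats::rexp(1L, n_taxa * birth_rate)
    for (i in seq_len(n_taxa)) {
      v <- next_id
      next_id <- next_id + 1L
      parent[v] <- act_parent[i]
      blen[v] <- act_len[i]
      is_tip[v] <- TRUE
    }

    .as_phylo(parent, blen, is_tip)
  })
}

# Convert parent/branch-length/tip arrays (creation-order ids, root = id 1)
# into an ape "phylo" with preorder sp###/n### labels.
.as_phylo <- function(parent, blen, is_tip) {
  n_all <- length(parent)
  n_tip <- sum(is_tip)
  n_int <- n_all - n_tip
  kids <- vector("list", n_all)
  for (v in seq_len(n_all)[-1L]) {
    kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  }
  # iterative preorder DFS (children in creation order)
  ape_id <- integer(n_all)
  tip_i <- 0L
  int_i <- 0L
  edge <- matrix(0L, n_all - 1L, 2L)
  edge_len <- numeric(n_all - 1L)
  e_i <- 0L
  stack <- 1L
  order_tips <- integer(0)
  order_ints <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (is_tip[v]) {
      tip_i <- tip_i + 1L
      ape_id[v] <- tip_i
      order_tips <- c(order_tips, v)
    } else {
      int_i <- int_i + 1L
      ape_id[v] <- n_tip + int_i
      order_ints <- c(order_ints, v)
      stack <- c(kids[[v]], stack)
    }
  }
  # second pass for edges, preorder again
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    for (w in kids[[v]]) {
      e_i <- e_i + 1L
      edge[e_i, ] <- c(ape_id[v], ape_id[w])
      edge_len[e_i] <- blen[w]
    }
    if (!is_tip[v]) stack <- c(kids[[v]], stack)
  }
  tr <- list(
    edge = edge,
    edge.length = edge_len,
    tip.label = sprintf("sp%03d", seq_len(n_tip)),
    node.label = sprintf("n%03d", seq_len(n_int)),
    Nnode = n_int
  )
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Validate and index a species tree
#'
#' Checks the contract every tree-consuming function relies on — rooted,
#' strictly bifurcating, unique leaf labels, internal labels present,
#' nonnegative branch lengths — and precomputes traversal tables.
#'
#' @param tree an [ape::phylo].
#' @return A list with elements `n_tip`, `n_node`, `root`, `labels` (all
#'   nodes, tips first), `parent` (node -> parent ape id, 0 at root),
#'   `brlen` (branch above each node), `children` (list over internal
#'   nodes), `postorder` (internal ape ids, children-first).
#' @keywords internal
tree_index <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape \"phylo\" object")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels are not unique")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    stop("internal node labels are required; label all internal nodes ",
         "(e.g. with make_node_labels())")
  }
  if (n_node != n_tip - 1L) {
    stop("tree is not strictly bifurcating (or not rooted): found ", n_node,
         " internal nodes for ", n_tip, " leaves; polytomies are not supported")
  }
  n_all <- n_tip + n_node
  parent <- integer(n_all)
  brlen <- numeric(n_all)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  brlen[tree$edge[, 2L]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(root) != 1L) stop("tree must have exactly one root")
  children <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    children[[p]] <- c(children[[p]], tree$edge[i, 2L])
  }
  if (any(vapply(children[(n_tip + 1L):n_all], length, 1L) != 2L)) {
    stop("every internal node must have exactly two children")
  }
  # postorder: reverse preorder works for internal nodes
  po <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    po <- c(v, po)
    stack <- c(children[[v]][!children[[v]] <= n_tip], stack)
  }
  list(
    n_tip = n_tip, n_node = n_node, root = root,
    labels = c(tree$tip.label, tree$node.label),
    parent = parent, brlen = brlen, children = children,
    postorder = po
  )
}

#' Add default internal node labels to a tree
#'
#' Labels internal nodes `n001, n002, ...` in preorder, leaving existing
#' labels untouched unless `overwrite = TRUE`.
#'
#' @param tree an [ape::phylo].
#' @param overwrite replace existing labels?
#' @return The relabelled tree.
#' @export
make_node_labels <- function(tree, overwrite = FALSE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape \"phylo\" object")
  if (is.null(tree$node.label) || overwrite ||
      any(!nzchar(tree$node.label))) {
    tree$node.label <- sprintf("n%03d", seq_len(tree$Nnode))
  }
  tree
}

#' Read a species tree from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the package's tree
#' contract: rooted, bifurcating, branch lengths present, internal nodes
#' labelled (rejected with a clear message otherwise).
#'
#' @param path Newick file.
#' @return An [ape::phylo].
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse a tree from ", path)
  tree_index(tr) # validation side effect
  tr
}
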