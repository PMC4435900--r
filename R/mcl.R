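#' Markov Cluster Algorithm (MCL)
#'
#' Extracts dense communities from an unweighted, undirected graph by
#' alternating random-walk expansion (matrix power) and inflation
#' (entrywise power followed by column normalization) of a column-stochastic
#' matrix, the classic MCL iteration. Granularity grows with the inflation
#' exponent. Self-loops of weight `self_loops` are added before
#' normalization (standard practice; damps bipartite oscillation).
#'
#' After convergence, attractors are the nodes retaining mass on their own
#' diagonal; clusters are connected sets of attractors together with the
#' nodes they attract. A node attracted to several attractor sets is
#' assigned to the one receiving its largest incoming value (lexicographic
#' tie-break), so the result is always a strict partition.
#'
#' @param graph an [igraph::graph], a symmetric adjacency matrix, or a
#'   two-column edge-list data.frame/matrix of node names.
#' @param inflation inflation exponent (> 1); default 2.
#' @param expansion expansion power (integer >= 2); default 2.
#' @param self_loops self-loop weight added to the diagonal; default 1.
#' @param prune_below entries below this are zeroed after each inflation.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the max absolute matrix change.
#' @param keep_matrix also return the converged column-stochastic matrix.
#' @return A list: `membership` (named integer vector, cluster ids numbered
#'   by first appearance in node order), `n_clusters`, `converged`
#'   (logical), `iterations`, and (with `keep_matrix`) `matrix`.
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' igraph::V(g)$name <- letters[1:6]
#' mcl_cluster(g)$n_clusters  # 2
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2L,
                        self_loops = 1, prune_below = 1e-8,
                        max_iter = 200L, tol = 1e-8, keep_matrix = FALSE) {
  if (inflation <= 1) stop("'inflation' must be > 1")
  if (expansion < 2L || expansion != round(expansion)) {
    stop("'expansion' must be an integer >= 2")
  }
  A <- .as_adjacency(graph)
  n <- nrow(A)
  if (n == 0L) stop("graph is empty")
  nodes <- rownames(A)
  diag(A) <- diag(A) + self_loops
  M <- .col_norm(A)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M_old <- M
    # expand
    E <- M
    for (k in seq_len(expansion - 1L)) E <- E %*% M
    # inflate + prune + renormalize
    E <- E^inflation
    E[E < prune_below] <- 0
    M <- .col_norm(E)
    if (max(abs(M - M_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current clustering")
  }

  eps <- prune_below
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0L) attractors <- seq_len(n) # degenerate guard
  # attractor systems: attractors sharing support in any column are one system
  sys_id <- seq_along(attractors)
  sup <- M[attractors, , drop = FALSE] > eps
  for (j in seq_len(n)) {
    hit <- which(sup[, j])
    if (length(hit) > 1L) {
      tgt <- min(sys_id[hit])
      sys_id[sys_id %in% sys_id[hit]] <- tgt
    }
  }
  # assign every node to the system of its strongest attractor
  memb <- integer(n)
  ord <- order(nodes, method = "radix")
  for (j in seq_len(n)) {
    w <- M[attractors, j]
    if (max(w) <= 0) { # isolated numerical corner: node attracts itself
      memb[j] <- -j
      next
    }
    # largest incoming value; lexicographic node-name tie-break
    cand <- attractors[w == max(w)]
    cand <- cand[order(nodes[cand], method = "radix")][1L]
    memb[j] <- sys_id[match(cand, attractors)]
  }
  memb <- match(memb, unique(memb))
  out <- list(membership = stats::setNames(memb, nodes),
              n_clusters = length(unique(memb)),
              converged = converged, iterations = it)
  if (keep_matrix) out$matrix <- M
  out
}

.as_adjacency <- function(graph) {
  if (inherits(graph, "igraph")) {
    A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
    if (is.null(rownames(A))) {
      rownames(A) <- colnames(A) <- as.character(seq_len(nrow(A)))
    }
    return(A)
  }
  if (is.matrix(graph) && nrow(graph) == ncol(graph) && is.numeric(graph)) {
    if (!isTRUE(all.equal(graph, t(graph)))) {
      stop("adjacency matrix must be symmetric")
    }
    if (is.null(rownames(graph))) {
      rownames(graph) <- colnames(graph) <- as.character(seq_len(nrow(graph)))
    }
    return(graph)
  }
  # edge list: two columns of node names
  el <- as.matrix(graph[, 1:2])
  nodes <- sort(unique(as.character(el)), method = "radix")
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(el))) {
    a <- match(el[i, 1L], nodes); b <- match(el[i, 2L], nodes)
    A[a, b] <- 1; A[b, a] <- 1
  }
  A
}

.col_norm <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2L, cs, "/")
}

#' Summarize an MCL clustering as protein families
#'
#' @param membership named membership vector from [mcl_cluster()] with node
#'   names of the form `genome|protein`.
#' @return data.frame: `cluster`, `size`, `n_genomes`, `genomes`
#'   (comma-joined).
#' @export
family_summary <- function(membership) {
  genomes <- sub("\\|.*$", "", names(membership))
  rows <- lapply(sort(unique(membership)), function(cl) {
    g <- genomes[membership == cl]
    data.frame(cluster = cl, size = length(g),
               n_genomes = length(unique(g)),
               genomes = paste(sort(unique(g), method = "radix"),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
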