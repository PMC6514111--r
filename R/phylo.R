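#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration: repeatedly joins the pair minimizing
#' the Q-criterion `(n - 2) d_ij - R_i - R_j`, computes the two branch
#' lengths, and reduces the matrix with
#' `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`, returning a binary
#' unrooted tree over all input labels. Exact ties in the Q-criterion are
#' broken by the smallest (row, column) pair in current label order, with a
#' joined cluster inheriting the position of its first member — so runs are
#' exactly reproducible and independent of floating-point scan quirks.
#'
#' The input must already be finite — apply [replace_undefined()] first if
#' the matrix contains saturated cells. Negative branch lengths are
#' retained (they do not affect topology); clamp them at output time if
#' needed (see [write_newick()]).
#'
#' @param D symmetric numeric distance matrix with at least 3 labeled rows.
#' @return An unrooted `"phylo"` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(!is.finite(D)))
    stop("distance matrix has non-finite entries; apply replace_undefined() first",
         call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12 * (1 + max(abs(D))))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  tip_label <- rownames(D)

  n_edge <- 2L * n - 3L
  edge <- matrix(0L, n_edge, 2L)
  edge_len <- numeric(n_edge)
  n_used <- 0L
  add_edge <- function(parent, child, len) {
    n_used <<- n_used + 1L
    edge[n_used, ] <<- c(parent, child)
    edge_len[n_used] <<- len
  }

  reps <- seq_len(n)          # phylo node id of each active cluster
  m <- n                       # active cluster count
  next_node <- n + 1L
  while (m > 3L) {
    R <- rowSums(D)
    Q <- (m - 2L) * D - outer(R, R, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    # smallest (row, col) among exact minima: column-major which.min scans
    # columns first, so find the minimum and then the first row-major hit
    qmin <- min(Q)
    hits <- which(Q == qmin, arr.ind = TRUE)
    k <- order(hits[, 1L], hits[, 2L])[1L]
    i <- hits[k, 1L]; j <- hits[k, 2L]
    dij <- D[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2L))
    bj <- dij - bi
    add_edge(next_node, reps[i], bi)
    add_edge(next_node, reps[j], bj)
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    D[i, ] <- dnew
    D[, i] <- dnew
    D[i, i] <- 0
    reps[i] <- next_node
    next_node <- next_node + 1L
    D <- D[-j, -j, drop = FALSE]
    reps <- reps[-j]
    m <- m - 1L
  }
  # final star join of the three remaining clusters
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(next_node, reps[1L], b1)
  add_edge(next_node, reps[2L], b2)
  add_edge(next_node, reps[3L], b3)

  # renumber internal nodes so the final (root-of-unrooted) node is n + 1,
  # as ape expects edges to emanate from the basal node
  old_ids <- (n + 1L):next_node
  map <- seq_len(next_node)
  map[old_ids] <- c(old_ids[-1L], n + 1L)
  edge[] <- map[edge]
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = tip_label,
                         Nnode = next_node - n),
                    class = "phylo", order = NULL)
  ape::reorder.phylo(tree, "cladewise")
}

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf label sets", call. = FALSE)
}

#' Robinson–Foulds distance between two trees
#'
#' Size of the symmetric difference between the sets of nontrivial
#' bipartitions (internal edges) of the two unrooted trees. Rooted trees are
#' unrooted first (a degree-2 root is suppressed). The distance is 0 exactly
#' when the unrooted topologies are identical, and at most `2 (n - 3)` for
#' binary trees on `n` leaves.
#'
#' @param t1,t2 `"phylo"` trees over the same leaf label set.
#' @return Nonnegative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  check_same_leaves(t1, t2)
  if (ape::is.rooted(t1)) t1 <- ape::unroot(t1)
  if (ape::is.rooted(t2)) t2 <- ape::unroot(t2)
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Are two trees the same unrooted topology?
#'
#' `TRUE` iff the Robinson–Foulds distance between the unrooted topologies
#' is zero, i.e. the trees induce the same set of nontrivial bipartitions of
#' the shared leaf set. Branch lengths, rotations and root placement are
#' ignored.
#'
#' @inheritParams robinson_foulds
#' @return Logical scalar.
#' @export
unrooted_topologies_equal <- function(t1, t2) {
  robinson_foulds(t1, t2) == 0L
}

#' Perfect binary tree topology
#'
#' The rooted model topology used by the sequence-evolution benchmark: every
#' internal node has exactly two children and all `n_taxa` leaves sit at
#' depth `log2(n_taxa)`. Leaves are labeled `t1 ... tn` left to right, and
#' every edge has unit length (one "branch step").
#'
#' @param n_taxa leaf count, a power of 2 with `n_taxa >= 4`.
#' @return A rooted `"phylo"` tree.
#' @export
perfect_binary_tree <- function(n_taxa) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 4 ||
      bitwAnd(as.integer(n_taxa), as.integer(n_taxa) - 1L) != 0L)
    stop("'n_taxa' must be a power of 2, at least 4", call. = FALSE)
  build <- function(lo, hi) {
    if (lo == hi) return(paste0("t", lo))
    mid <- (lo + hi - 1L) %/% 2L
    paste0("(", build(lo, mid), ":1,", build(mid + 1L, hi), ":1)")
  }
  ape::read.tree(text = paste0(build(1L, as.integer(n_taxa)), ";"))
}
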