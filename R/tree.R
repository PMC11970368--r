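# Trees are built internally as nested lists (label, length-to-parent,
# children) and converted to ape-compatible "phylo" objects: tips numbered
# in order of appearance, root = n + 1, internal nodes in preorder. No ape
# code is involved; the class is shared so users can plot/compare with ape.

.tree_node <- function(label = NA_character_, length = NA_real_,
                       children = list()) {
  list(label = label, length = length, children = children)
}

.count_tips <- function(node) {
  if (length(node$children) == 0L) return(1L)
  sum(vapply(node$children, .count_tips, 0L))
}

# nested list -> phylo
.as_phylo <- function(root) {
  ntip <- .count_tips(root)
  nnode <- 0L
  count_internal <- function(nd) {
    if (length(nd$children) == 0L) return(invisible(NULL))
    nnode <<- nnode + 1L
    for (c in nd$children) count_internal(c)
  }
  count_internal(root)
  e <- new.env(parent = emptyenv())
  e$edge <- matrix(0L, nrow = ntip + nnode - 1L, ncol = 2L)
  e$elen <- rep(NA_real_, ntip + nnode - 1L)
  e$tip <- character(ntip)
  e$nlab <- character(nnode)
  e$tipc <- 0L
  e$nodec <- ntip
  e$edgec <- 0L
  assign_walk <- function(nd, parent_id) {
    if (length(nd$children) == 0L) {
      e$tipc <- e$tipc + 1L
      id <- e$tipc
      e$tip[id] <- nd$label
    } else {
      e$nodec <- e$nodec + 1L
      id <- e$nodec
      e$nlab[id - ntip] <- if (is.na(nd$label)) "" else nd$label
    }
    if (parent_id > 0L) {
      e$edgec <- e$edgec + 1L
      e$edge[e$edgec, ] <- c(parent_id, id)
      e$elen[e$edgec] <- nd$length
    }
    for (c in nd$children) assign_walk(c, id)
    invisible(NULL)
  }
  assign_walk(root, 0L)
  tr <- list(edge = e$edge, tip.label = e$tip, Nnode = nnode)
  if (any(!is.na(e$elen))) tr$edge.length <- e$elen
  if (any(nzchar(e$nlab))) tr$node.label <- e$nlab
  attr(tr, "order") <- "cladewise"
  class(tr) <- "phylo"
  tr
}

# phylo -> children lookup (list indexed by node id, in edge order) and
# branch lengths per child node
.phylo_children <- function(tr) {
  nnode <- tr$Nnode
  ntip <- length(tr$tip.label)
  kids <- vector("list", ntip + nnode)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]
    kids[[p]] <- c(kids[[p]], tr$edge[k, 2])
  }
  kids
}

.phylo_root <- function(tr) {
  setdiff(unique(tr$edge[, 1]), tr$edge[, 2])[1]
}

.check_tree_matrix <- function(D, min_n) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(D))) stop("D must carry sample names", call. = FALSE)
  if (nrow(D) < min_n) {
    stop("tree construction needs at least ", min_n, " samples, got ",
         nrow(D), call. = FALSE)
  }
  if (anyNA(D)) {
    stop("D contains undefined distances (pairs with no usable site); ",
         "tree construction is not possible", call. = FALSE)
  }
  invisible(D)
}

# lexicographically smallest (i, j), i < j, among minimizing entries
.argmin_pair <- function(M) {
  M[lower.tri(M, diag = TRUE)] <- Inf
  cand <- which(M == min(M), arr.ind = TRUE)
  o <- order(cand[, 1], cand[, 2])[1]
  c(cand[o, 1], cand[o, 2])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' Q(i, j) = (r - 2) D(i, j) - R_i - R_j, standard branch-length formulas,
#' and a final unrooted trifurcation. Ties in Q are broken by the
#' lexicographically smallest active index pair. Negative branch lengths
#' are retained as computed unless `clamp_negative` is set.
#'
#' @param D symmetric distance matrix with dimnames, n >= 3, no `NA`.
#' @param clamp_negative set negative branch lengths to zero.
#' @return an unrooted `phylo` tree (trifurcating root).
#' @export
nj_tree <- function(D, clamp_negative = FALSE) {
  .check_tree_matrix(D, 3L)
  d <- unname(as.matrix(D))
  nodes <- lapply(rownames(D), .tree_node)
  N <- nrow(d)
  while (N > 3L) {
    Rs <- rowSums(d)
    Q <- (N - 2) * d - outer(Rs, Rs, `+`)
    ij <- .argmin_pair(Q)
    i <- ij[1]; j <- ij[2]
    vi <- d[i, j] / 2 + (Rs[i] - Rs[j]) / (2 * (N - 2))
    vj <- d[i, j] - vi
    a <- nodes[[i]]; a$length <- vi
    b <- nodes[[j]]; b$length <- vj
    new_node <- .tree_node(children = list(a, b))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- dnew; d[, i] <- dnew; d[i, i] <- 0
    nodes[[i]] <- new_node
    d <- d[-j, -j, drop = FALSE]
    nodes[[j]] <- NULL
    N <- N - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  for (k in 1:3) nodes[[k]]$length <- c(l1, l2, l3)[k]
  tr <- .as_phylo(.tree_node(children = nodes[1:3]))
  if (clamp_negative) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with cluster-size-weighted distance
#' updates; the node created by merging clusters at distance d sits at
#' height d / 2, so the tree is rooted and ultrametric. Ties are broken by
#' the lexicographically smallest active index pair.
#'
#' @param D symmetric distance matrix with dimnames, n >= 2, no `NA`.
#' @return a rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(D) {
  .check_tree_matrix(D, 2L)
  d <- unname(as.matrix(D))
  nodes <- lapply(rownames(D), .tree_node)
  sizes <- rep(1L, nrow(d))
  heights <- rep(0, nrow(d))
  N <- nrow(d)
  while (N > 1L) {
    ij <- .argmin_pair(d)
    i <- ij[1]; j <- ij[2]
    h <- d[i, j] / 2
    a <- nodes[[i]]; a$length <- h - heights[i]
    b <- nodes[[j]]; b$length <- h - heights[j]
    new_node <- .tree_node(children = list(a, b))
    dnew <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
    d[i, ] <- dnew; d[, i] <- dnew; d[i, i] <- 0
    nodes[[i]] <- new_node
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    d <- d[-j, -j, drop = FALSE]
    nodes[[j]] <- NULL
    sizes <- sizes[-j]
    heights <- heights[-j]
    N <- N - 1L
  }
  .as_phylo(nodes[[1]])
}
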