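# Non-trivial bipartitions of a tree, as normalized membership keys over a
# fixed reference taxon order. Each split is encoded by the side NOT
# containing the first reference taxon, so identical unrooted splits from
# differently rooted trees collapse to the same key.
.tree_splits <- function(tr, ref) {
  ntip <- length(tr$tip.label)
  tipmap <- match(tr$tip.label, ref)
  kids <- .phylo_children(tr)
  root <- .phylo_root(tr)
  below <- vector("list", ntip + tr$Nnode)
  fill <- function(id) {
    if (id <= ntip) {
      below[[id]] <<- tipmap[id]
    } else {
      below[[id]] <<- sort(unlist(lapply(kids[[id]], function(c) {
        fill(c)
        below[[c]]
      })))
    }
    invisible(NULL)
  }
  fill(root)
  internal <- setdiff(which(!vapply(below, is.null, TRUE)), seq_len(ntip))
  internal <- setdiff(internal, root)
  keys <- character(0)
  for (id in internal) {
    side <- logical(length(ref))
    side[below[[id]]] <- TRUE
    if (side[1]) side <- !side   # normalize: ref[1] on the FALSE side
    sz <- sum(side)
    if (sz >= 2L && sz <= length(ref) - 2L) {
      keys <- c(keys, paste(which(side), collapse = ","))
    }
  }
  unique(keys)
}

#' Majority-rule consensus of a set of trees
#'
#' Collects the non-trivial bipartitions of each input tree and retains
#' those whose frequency strictly exceeds `threshold`; such splits are
#' pairwise compatible by construction, so the consensus tree always
#' exists. Retained splits carry integer support labels
#' `round(100 * frequency)`. Branch lengths are not assigned.
#'
#' @param trees list of `phylo` objects over the same leaf set.
#' @param threshold retention threshold as a frequency fraction; default
#'   0.5 (strict majority).
#' @return a `phylo` consensus tree with supports in `node.label`.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(is.list(trees), length(trees) >= 2L)
  if (threshold < 0.5 || threshold >= 1) {
    stop("threshold must be in [0.5, 1)", call. = FALSE)
  }
  ref <- sort(trees[[1]]$tip.label)
  for (k in seq_along(trees)) {
    tk <- sort(trees[[k]]$tip.label)
    if (!identical(tk, ref)) {
      bad <- c(setdiff(tk, ref), setdiff(ref, tk))
      stop("tree ", k, " has a different leaf set (discrepant taxa: ",
           paste(unique(bad), collapse = ", "), ")", call. = FALSE)
    }
  }
  counts <- table(unlist(lapply(trees, .tree_splits, ref = ref)))
  freq <- as.numeric(counts) / length(trees)
  keep <- freq > threshold
  splits <- lapply(names(counts)[keep],
                   function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  supports <- round(100 * freq[keep])
  o <- order(-lengths(splits))
  splits <- splits[o]
  supports <- supports[o]

  # start from a star tree and insert splits largest-first; with strict
  # majority every retained split nests cleanly into the current children
  root <- .tree_node(children = lapply(ref, .tree_node))
  leafset <- function(nd) {
    if (length(nd$children) == 0L) return(match(nd$label, ref))
    sort(unlist(lapply(nd$children, leafset)))
  }
  insert_split <- function(nd, split, support) {
    sets <- lapply(nd$children, leafset)
    inside <- vapply(sets, function(s) all(s %in% split), TRUE)
    overlap <- vapply(sets, function(s) any(s %in% split), TRUE)
    if (any(overlap & !inside)) {
      # split lives deeper: recurse into the single child containing it
      host <- which(overlap)
      if (length(host) != 1L) {
        stop("incompatible split in consensus construction", call. = FALSE)
      }
      nd$children[[host]] <- insert_split(nd$children[[host]], split, support)
      return(nd)
    }
    covered <- sort(unlist(sets[inside]))
    if (!identical(covered, split)) {
      host <- which(inside & vapply(sets, function(s) all(split %in% s), TRUE))
      if (length(host) == 1L) {
        nd$children[[host]] <- insert_split(nd$children[[host]], split, support)
        return(nd)
      }
      stop("incompatible split in consensus construction", call. = FALSE)
    }
    newc <- .tree_node(label = as.character(support),
                       children = nd$children[inside])
    nd$children <- c(nd$children[!inside], list(newc))
    nd
  }
  for (k in seq_along(splits)) {
    root <- insert_split(root, splits[[k]], supports[k])
  }
  .as_phylo(root)
}
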