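#' Cache a site stream for repeated (resampled) accumulation
#'
#' Materializes the parsed chunks of a stream so replicates can be computed
#' without re-reading the input. The cache stores compact integer arrays
#' (about `4 * ploidy * n` bytes per site).
#'
#' @param stream a `site_stream`.
#' @return a `site_cache` with `names`, `chunks` and `total_sites`.
#' @export
cache_sites <- function(stream) {
  stopifnot(inherits(stream, "site_stream"))
  chunks <- list()
  total <- 0L
  repeat {
    ch <- stream$next_chunk()
    if (is.null(ch)) break
    chunks[[length(chunks) + 1L]] <- ch
    total <- total + ch$n_sites
  }
  structure(list(names = stream$names, chunks = chunks, total_sites = total),
            class = "site_cache")
}

#' Define a site-resampling plan
#'
#' Each replicate draws `round(ratio * total_sites)` site indices (minimum
#' 1; R's round-half-even) uniformly with replacement; duplicates are kept
#' with multiplicity, the standard bootstrap convention. Identical
#' (seed, ratio, total_sites, n_replicates) give identical draws.
#'
#' @param ratio fraction of sites drawn per replicate, in (0, 1\];
#'   default 0.25.
#' @param n_replicates number of replicates (>= 1).
#' @param seed RNG seed.
#' @param total_sites number of sites available.
#' @return a `resample_plan`.
#' @export
resample_plan <- function(ratio = 0.25, n_replicates = 100L, seed = 1L,
                          total_sites) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio > 1) {
    stop("ratio must be in (0, 1]", call. = FALSE)
  }
  stopifnot(n_replicates >= 1L, total_sites >= 1L)
  structure(list(ratio = ratio, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), total_sites = as.integer(total_sites),
                 draws = max(1L, round(ratio * total_sites))),
            class = "resample_plan")
}

# Site-index draws for every replicate, as a list of index vectors.
.plan_draws <- function(plan) {
  set.seed(plan$seed)
  lapply(seq_len(plan$n_replicates), function(r) {
    sample.int(plan$total_sites, plan$draws, replace = TRUE)
  })
}

# Accumulate a cache under per-site multiplicity weights (NULL = all ones).
.accumulate_cache <- function(cache, weights = NULL, workers = 1L) {
  acc <- pair_accumulator(length(cache$names))
  at <- 0L
  for (ch in cache$chunks) {
    w <- if (is.null(weights)) NULL else weights[at + seq_len(ch$n_sites)]
    .acc_add_chunk(acc, ch, w, workers)
    at <- at + ch$n_sites
  }
  acc
}

#' Replicate p-distance matrices under site resampling
#'
#' For each replicate the drawn site multiset is accumulated with
#' multiplicity; the per-pair missing-data denominators apply within the
#' draw, so a pair's denominator is the (weighted) number of drawn sites
#' where both calls are present.
#'
#' @param cache a `site_cache` (or a `site_stream`, cached internally).
#' @param plan a `resample_plan`; its `total_sites` must match the cache.
#' @param workers pair-block partitions passed to the accumulator.
#' @return list of distance matrices, one per replicate.
#' @export
bootstrap_matrices <- function(cache, plan, workers = 1L) {
  if (inherits(cache, "site_stream")) cache <- cache_sites(cache)
  stopifnot(inherits(cache, "site_cache"), inherits(plan, "resample_plan"))
  if (plan$total_sites != cache$total_sites) {
    stop("plan covers ", plan$total_sites, " sites but cache holds ",
         cache$total_sites, call. = FALSE)
  }
  draws <- .plan_draws(plan)
  lapply(draws, function(idx) {
    w <- tabulate(idx, nbins = cache$total_sites)
    finalize_distances(.accumulate_cache(cache, w, workers), cache$names)
  })
}

#' Bootstrap consensus tree with support values
#'
#' Builds one NJ or UPGMA tree per resampling replicate and returns their
#' majority-rule consensus, with supports as percentages, together with the
#' replicate trees (writable to a one-tree-per-line Newick file for
#' external consensus programs).
#'
#' @param cache a `site_cache` or `site_stream`.
#' @param plan a `resample_plan`.
#' @param method `"nj"` or `"upgma"`.
#' @param threshold consensus retention threshold (default 0.5).
#' @param workers pair-block partitions.
#' @return list with elements `consensus` (a `phylo` with supports) and
#'   `replicates` (list of `phylo`).
#' @export
bootstrap_tree <- function(cache, plan, method = c("nj", "upgma"),
                           threshold = 0.5, workers = 1L) {
  method <- match.arg(method)
  if (inherits(cache, "site_stream")) cache <- cache_sites(cache)
  mats <- bootstrap_matrices(cache, plan, workers)
  build <- if (method == "nj") nj_tree else upgma_tree
  trees <- lapply(mats, build)
  cons <- if (length(trees) >= 2L) {
    majority_consensus(trees, threshold)
  } else {
    # degenerate single-replicate case: the replicate tree with unit support
    tr <- trees[[1]]
    ntip <- length(tr$tip.label)
    root <- .phylo_root(tr)
    lab <- rep("100", tr$Nnode)
    lab[root - ntip] <- ""
    tr$node.label <- lab
    tr
  }
  list(consensus = cons, replicates = trees)
}
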