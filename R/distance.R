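#' Create an empty pair accumulator
#'
#' Holds upper-triangle running sums of per-site distances (`sum_d`) and
#' per-pair usable-site counts (`used`), plus instrumentation counters:
#' pair-site comparisons attempted and mixed-ploidy skips. Pair (i, j) with
#' i < j is stored at index `i + (j - 1) * (j - 2) / 2` in column-major
#' upper-triangle order (the order `upper.tri` enumerates).
#'
#' @param n number of samples (>= 2).
#' @return a `pair_accumulator` environment.
#' @export
pair_accumulator <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  npair <- n * (n - 1L) / 2L
  e <- new.env(parent = emptyenv())
  e$n <- n
  e$sum_d <- numeric(npair)
  e$used <- numeric(npair)
  e$comparisons <- 0
  e$mixed_skips <- 0
  e$sites <- 0
  class(e) <- "pair_accumulator"
  e
}

# Add one parsed chunk into an accumulator, optionally with per-site
# weights (site multiplicities for bootstrap resampling).
.acc_add_chunk <- function(acc, ch, weights = NULL, workers = 1L) {
  if (is.null(weights)) weights <- rep(1, ch$n_sites)
  stopifnot(length(weights) == ch$n_sites)
  res <- .acc_chunk_cpp(ch$alleles, ch$ploidy, ch$phased, acc$n, ch$maxp,
                        ch$n_sites, as.numeric(weights), as.integer(workers))
  acc$sum_d <- acc$sum_d + res$sum_d
  acc$used <- acc$used + res$used
  acc$comparisons <- acc$comparisons + res$comparisons
  acc$mixed_skips <- acc$mixed_skips + res$mixed_skips
  acc$sites <- acc$sites + sum(weights > 0)
  invisible(acc)
}

#' Accumulate all sites of a stream into a pair accumulator
#'
#' Streams chunk by chunk; for every site and every pair i < j with both
#' calls non-missing, the per-site score is added to `sum_d` and the usable
#' count incremented. Pairs whose two calls have different ploidy at a site
#' skip that site (counted in `mixed_skips`). Results are bit-identical for
#' any `workers` value: pairs are partitioned into contiguous blocks and
#' each pair is accumulated by exactly one block, in stream order.
#'
#' @param stream a `site_stream`.
#' @param acc an existing `pair_accumulator`, or `NULL` to create one sized
#'   to the stream.
#' @param workers number of pair-blocks (simulated worker partitions).
#' @return the `pair_accumulator`, invisibly usable and returned.
#' @export
accumulate_sites <- function(stream, acc = NULL, workers = 1L) {
  stopifnot(inherits(stream, "site_stream"))
  n <- length(stream$names)
  if (is.null(acc)) acc <- pair_accumulator(n)
  if (acc$n != n) {
    stop("accumulator holds ", acc$n, " samples but stream has ", n,
         call. = FALSE)
  }
  repeat {
    ch <- stream$next_chunk()
    if (is.null(ch)) break
    .acc_add_chunk(acc, ch, NULL, workers)
  }
  acc
}

#' Merge two pair accumulators built from disjoint site blocks
#'
#' @param a,b `pair_accumulator`s over the same sample count.
#' @return a new merged `pair_accumulator`.
#' @export
merge_accumulators <- function(a, b) {
  stopifnot(inherits(a, "pair_accumulator"), inherits(b, "pair_accumulator"),
            a$n == b$n)
  out <- pair_accumulator(a$n)
  out$sum_d <- a$sum_d + b$sum_d
  out$used <- a$used + b$used
  out$comparisons <- a$comparisons + b$comparisons
  out$mixed_skips <- a$mixed_skips + b$mixed_skips
  out$sites <- a$sites + b$sites
  out
}

#' Per-site distance between two genotype calls
#'
#' If both calls are phased and of equal ploidy p, the score is the fraction
#' of haplotype positions whose allele indices differ. Otherwise the
#' unordered rule applies: d = 1 - |multiset intersection| / p. For
#' equal-ploidy diploids this yields exactly 0, 0.5 or 1; haploid pairs give
#' 0 or 1. A mixed-ploidy pair is not scorable and returns `NA`.
#'
#' @param a,b calls as returned by [parse_gt()]: lists with `alleles`
#'   (integer vector) and `phased` (logical).
#' @return score in \[0, 1\], or `NA_real_` for a mixed-ploidy pair.
#' @export
#' @examples
#' score_pair(parse_gt("0/0"), parse_gt("0/1"))  # 0.5
#' score_pair(parse_gt("1|0"), parse_gt("0|1"))  # 1
score_pair <- function(a, b) {
  if (is.null(a) || is.null(b)) {
    stop("score_pair requires two non-missing calls", call. = FALSE)
  }
  p <- length(a$alleles)
  if (p != length(b$alleles)) return(NA_real_)
  if (isTRUE(a$phased) && isTRUE(b$phased)) {
    return(sum(a$alleles != b$alleles) / p)
  }
  shared <- 0L
  bb <- b$alleles
  for (al in a$alleles) {
    hit <- match(al, bb)
    if (!is.na(hit)) {
      shared <- shared + 1L
      bb <- bb[-hit]
    }
  }
  1 - shared / p
}

#' Finalize an accumulator into a labeled p-distance matrix
#'
#' D\[i, j\] = sum_d\[i, j\] / used\[i, j\], the proportion of pairwise
#' comparable sites at which the two samples differ (pairwise deletion:
#' each pair's denominator counts only sites where both calls are present).
#' Pairs sharing no usable site are undefined and stored as `NA`.
#'
#' @param acc a `pair_accumulator`.
#' @param names sample labels, length `acc$n`.
#' @return a symmetric numeric matrix with zero diagonal, dimnames set to
#'   `names`, and the per-pair usable-site counts attached as attribute
#'   `used_sites`.
#' @export
finalize_distances <- function(acc, names) {
  stopifnot(inherits(acc, "pair_accumulator"), length(names) == acc$n)
  n <- acc$n
  D <- matrix(0, n, n, dimnames = list(names, names))
  U <- matrix(0, n, n, dimnames = list(names, names))
  ut <- upper.tri(D)
  vals <- ifelse(acc$used > 0, acc$sum_d / acc$used, NA_real_)
  D[ut] <- vals
  U[ut] <- acc$used
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  U[lower.tri(U)] <- t(U)[lower.tri(U)]
  attr(D, "used_sites") <- U
  D
}

#' Write a distance matrix in square Phylip format
#'
#' Line 1 holds the sample count; each following line holds the (padded)
#' sample name and n fixed-point distances separated by single spaces, a
#' layout MEGA, Phylip and FastTree all accept. Undefined distances are
#' written as the sentinel -1.
#'
#' @param D symmetric distance matrix with dimnames (as from
#'   [finalize_distances()]).
#' @param path output path.
#' @param decimals fixed-point decimals (default 6).
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(D, path, decimals = 6L) {
  nm <- rownames(D)
  stopifnot(!is.null(nm), nrow(D) == ncol(D))
  width <- max(10L, max(nchar(nm)) + 1L)
  vals <- apply(D, 1L, function(r) {
    paste(formatC(ifelse(is.na(r), -1, r), format = "f", digits = decimals),
          collapse = " ")
  })
  lines <- c(as.character(nrow(D)),
             paste0(formatC(nm, width = -width), vals))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Phylip distance matrix (square or lower-triangle)
#'
#' @param path matrix file path.
#' @return a symmetric matrix with dimnames; -1 sentinel entries become `NA`.
#'   Square input asymmetric beyond its printed precision is an error.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix file ", path, " is empty", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2L) {
    stop("matrix header of ", path, " must hold the sample count",
         call. = FALSE)
  }
  if (length(lines) - 1L != n) {
    stop("matrix file ", path, " declares ", n, " samples but has ",
         length(lines) - 1L, " rows", call. = FALSE)
  }
  rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  nm <- vapply(rows, `[[`, character(1), 1L)
  nv <- lengths(rows) - 1L
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  max_dec <- 0L
  if (all(nv == n)) {
    for (i in seq_len(n)) {
      v <- rows[[i]][-1]
      max_dec <- max(max_dec, nchar(sub("^[^.]*\\.?", "", v)))
      D[i, ] <- as.numeric(v)
    }
    tol <- 0.51 * 10^-max_dec
    if (max(abs(D - t(D))) > tol) {
      stop("matrix in ", path, " is asymmetric beyond its printed precision",
           call. = FALSE)
    }
    D <- (D + t(D)) / 2
    diag(D) <- 0
  } else if (all(nv == seq_len(n) - 1L) || all(nv == seq_len(n))) {
    with_diag <- all(nv == seq_len(n))
    for (i in seq_len(n)) {
      v <- as.numeric(rows[[i]][-1])
      k <- if (with_diag) i - 1L else i - 1L
      if (k > 0L) {
        D[i, seq_len(k)] <- v[seq_len(k)]
        D[seq_len(k), i] <- v[seq_len(k)]
      }
    }
  } else {
    stop("matrix file ", path, " row ", which(nv != n)[1],
         " has an unexpected number of entries", call. = FALSE)
  }
  D[D < 0] <- NA_real_
  D
}
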