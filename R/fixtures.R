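#' Describe a synthetic population for VCF simulation
#'
#' The generator plants group structure through a two-frequency site scheme
#' chosen so the expected pairwise p-distance has a closed form. At each
#' site every group carries a base allele (group 1 always allele 0; every
#' other group switches to allele 1 with probability `between_diff_prob`)
#' and each sample is independently heterozygous for a site-level deviant
#' allele with probability `within_diff_prob`. Multiallelic sites use a
#' third allele as the deviant; biallelic sites deviate to the opposite
#' allele.
#'
#' @param groups named integer vector of group sizes (>= 1 each).
#' @param m_sites number of variant sites.
#' @param within_diff_prob per-sample heterozygous-deviation probability.
#' @param between_diff_prob per-site probability that a non-reference
#'   group's base allele differs from group 1's.
#' @param phased_fraction fraction of calls written phased (`|`).
#' @param missing_rate fraction of calls written missing (`./.`).
#' @param multiallelic_fraction fraction of sites with three alleles.
#' @param seed RNG seed.
#' @return a `population_model`.
#' @export
population_model <- function(groups = c(A = 5L, B = 5L), m_sites = 1000L,
                             within_diff_prob = 0.05,
                             between_diff_prob = 0.3,
                             phased_fraction = 0.2, missing_rate = 0.05,
                             multiallelic_fraction = 0.05, seed = 1L) {
  probs <- c(within_diff_prob, between_diff_prob, phased_fraction,
             missing_rate, multiallelic_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector of sizes", call. = FALSE)
  }
  if (any(groups < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  structure(list(groups = groups, m_sites = as.integer(m_sites),
                 within_diff_prob = within_diff_prob,
                 between_diff_prob = between_diff_prob,
                 phased_fraction = phased_fraction,
                 missing_rate = missing_rate,
                 multiallelic_fraction = multiallelic_fraction,
                 seed = as.integer(seed)),
            class = "population_model")
}

# Closed-form expected pairwise p-distance under the generator's scheme.
# Within a group E[d] = w(1-w); across groups, conditional on differing
# bases, E[d] = 1-w at biallelic sites and 1 - w^2/2 at triallelic sites.
.expected_distance <- function(model) {
  w <- model$within_diff_prob
  pb <- model$between_diff_prob
  ma <- model$multiallelic_fraction
  e_same <- w * (1 - w)
  e_diff <- (1 - ma) * (1 - w) + ma * (1 - 0.5 * w^2)
  gid <- rep(seq_along(model$groups), model$groups)
  n <- length(gid)
  nm <- paste0(rep(names(model$groups), model$groups), "_",
               unlist(lapply(model$groups, seq_len)))
  E <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (gid[i] == gid[j]) {
        v <- e_same
      } else {
        p_diff <- if (min(gid[i], gid[j]) == 1L) pb else 2 * pb * (1 - pb)
        v <- p_diff * e_diff + (1 - p_diff) * e_same
      }
      E[i, j] <- v; E[j, i] <- v
    }
  }
  E
}

#' Simulate a VCF with planted group structure
#'
#' Writes a syntactically valid VCF under the scheme described in
#' [population_model()] and, alongside it, the exact expected p-distance
#' matrix (`<path>.expected.mat`, Phylip format). Fixed seeds give
#' byte-identical files.
#'
#' @param model a `population_model`.
#' @param path output VCF path.
#' @return invisibly, a list with `path`, `names`, `expected` (matrix) and
#'   `expected_path`.
#' @export
simulate_vcf <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  set.seed(model$seed)
  m <- model$m_sites
  gsz <- model$groups
  G <- length(gsz)
  n <- sum(gsz)
  gid <- rep(seq_len(G), gsz)
  nm <- paste0(rep(names(gsz), gsz), "_", unlist(lapply(gsz, seq_len)))

  k <- 2L + rbinom(m, 1L, model$multiallelic_fraction)        # alleles/site
  base_g <- matrix(0L, nrow = G, ncol = m)                     # group bases
  if (G > 1L) {
    base_g[-1L, ] <- rbinom((G - 1L) * m, 1L, model$between_diff_prob)
  }
  base <- base_g[gid, , drop = FALSE]                          # n x m
  dev <- ifelse(matrix(k == 3L, n, m, byrow = TRUE), 2L, 1L - base)
  het <- matrix(rbinom(n * m, 1L, model$within_diff_prob) == 1L, n, m)
  mis <- matrix(rbinom(n * m, 1L, model$missing_rate) == 1L, n, m)
  pha <- matrix(rbinom(n * m, 1L, model$phased_fraction) == 1L, n, m)

  a2 <- ifelse(het, dev, base)
  tok <- paste0(base, ifelse(pha, "|", "/"), a2)
  tok[mis] <- "./."
  dim(tok) <- c(n, m)

  alt <- ifelse(k == 3L, "C,G", "C")
  body <- paste(1L, seq_len(m), ".", "A", alt, ".", ".", ".", "GT",
                apply(tok, 2L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", nm), collapse = "\t"))
  writeLines(c(header, body), path)

  expected <- .expected_distance(model)
  expected_path <- paste0(path, ".expected.mat")
  write_phylip_matrix(expected, expected_path)
  invisible(list(path = path, names = nm, expected = expected,
                 expected_path = expected_path))
}

#' Simulate an aligned FASTA by evolving characters down a tree
#'
#' A symmetric 4-state substitution process (Jukes-Cantor style) runs along
#' each branch: a site changes to one of the three other bases with
#' probability `0.75 * (1 - exp(-4 * rate * t / 3))` over a branch of
#' length t, so expected pairwise p-distances increase monotonically with
#' path length. Rate 0 yields identical sequences.
#'
#' @param tree a `phylo` with branch lengths.
#' @param L alignment length.
#' @param rate substitution rate per unit branch length.
#' @param path output FASTA path.
#' @param seed RNG seed.
#' @return invisibly, the `alignment` written.
#' @export
simulate_alignment <- function(tree, L, rate, path, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), L >= 1L, rate >= 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  kids <- .phylo_children(tree)
  elen <- rep(0, ntip + tree$Nnode)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  seqs <- vector("list", ntip + tree$Nnode)
  root <- .phylo_root(tree)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  walk <- function(id) {
    for (c in kids[[id]]) {
      p_sub <- 0.75 * (1 - exp(-4 * rate * elen[c] / 3))
      s <- seqs[[id]]
      hit <- which(runif(L) < p_sub)
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
      }
      seqs[[c]] <<- s
      if (!is.null(kids[[c]])) walk(c)
    }
  }
  walk(root)
  rows <- vapply(seq_len(ntip),
                 function(i) paste(bases[seqs[[i]]], collapse = ""),
                 character(1))
  writeLines(paste0(">", tree$tip.label, "\n", rows), path)
  invisible(.new_alignment(tree$tip.label, rows))
}
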