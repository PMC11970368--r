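# Independent fixtures and oracles for the distance engine. Nothing here
# calls the package's parser or accumulator: tokens are generated directly,
# written as literal VCF text, and scored by a plain double loop.

# Random genotype token matrix (n samples x m sites) plus site allele counts.
rand_gt_tokens <- function(n, m, seed, missing_rate = 0.1, multi_frac = 0.2,
                           phased_frac = 0.3) {
  set.seed(seed)
  n_alleles <- 2L + rbinom(m, 1L, multi_frac)
  tok <- matrix("", nrow = n, ncol = m)
  for (l in seq_len(m)) {
    a1 <- sample.int(n_alleles[l], n, replace = TRUE) - 1L
    a2 <- sample.int(n_alleles[l], n, replace = TRUE) - 1L
    sep <- ifelse(runif(n) < phased_frac, "|", "/")
    g <- paste0(a1, sep, a2)
    mis <- runif(n) < missing_rate
    if (any(mis)) {
      # mix fully and half-missing forms; both drop the whole call
      g[mis] <- sample(c("./.", ".", "./1", "0/."), sum(mis), replace = TRUE)
    }
    tok[, l] <- g
  }
  list(tokens = tok, n_alleles = n_alleles)
}

# Write tokens as a literal VCF file; ALT gets n_alleles - 1 symbols.
write_tokens_vcf <- function(tok, n_alleles, path,
                             sample_names = paste0("S", seq_len(nrow(tok)))) {
  alt_syms <- c("C", "G", "T")
  alt <- vapply(n_alleles, function(k) {
    paste(alt_syms[seq_len(k - 1L)], collapse = ",")
  }, character(1))
  body <- paste("chr1", seq_len(ncol(tok)), ".", "A", alt, ".", ".", ".",
                "GT", apply(tok, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_names), collapse = "\t")),
             path)
  cat(body, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

# Straightforward token parse for the oracle (independent of parse_gt).
naive_call <- function(tok) {
  if (grepl(".", tok, fixed = TRUE)) return(NULL)
  parts <- strsplit(tok, "[/|]")[[1]]
  list(a = as.integer(parts),
       ph = grepl("|", tok, fixed = TRUE) && !grepl("/", tok, fixed = TRUE))
}

# Per-site score by first principles; NA = pair unusable at this site.
naive_d <- function(ca, cb) {
  if (is.null(ca) || is.null(cb)) return(NA_real_)
  p <- length(ca$a)
  if (p != length(cb$a)) return(NA_real_)
  if (ca$ph && cb$ph) return(mean(ca$a != cb$a))
  u <- unique(c(ca$a, cb$a))
  shared <- sum(pmin(tabulate(match(ca$a, u), length(u)),
                     tabulate(match(cb$a, u), length(u))))
  1 - shared / p
}

# All-pairs, all-sites double loop over a token matrix.
naive_p_matrix <- function(tok, sample_names = paste0("S", seq_len(nrow(tok)))) {
  n <- nrow(tok); m <- ncol(tok)
  calls <- lapply(seq_len(n), function(i) lapply(tok[i, ], naive_call))
  D <- matrix(0, n, n, dimnames = list(sample_names, sample_names))
  U <- matrix(0, n, n, dimnames = list(sample_names, sample_names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- vapply(seq_len(m),
                  function(l) naive_d(calls[[i]][[l]], calls[[j]][[l]]),
                  numeric(1))
      used <- as.numeric(sum(!is.na(d)))
      v <- if (used > 0) sum(d, na.rm = TRUE) / used else NA_real_
      D[i, j] <- v; D[j, i] <- v
      U[i, j] <- used; U[j, i] <- used
    }
  }
  attr(D, "used_sites") <- U
  D
}

# Full-path distance matrix through the package, from a VCF file.
pkg_p_matrix <- function(path, samples = NULL, workers = 1L,
                         chunk_sites = 10000L) {
  st <- vcf_site_stream(path, samples, chunk_sites = chunk_sites)
  finalize_distances(accumulate_sites(st, workers = workers), st$names)
}

# Unrooted bipartition keys of a phylo tree (for topology comparison),
# computed here from the edge matrix, independent of the package internals.
tree_bipartitions <- function(tr) {
  ref <- sort(tr$tip.label)
  ntip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  below <- function(id) {
    if (id <= ntip) return(match(tr$tip.label[id], ref))
    sort(unlist(lapply(kids[[as.character(id)]], below)))
  }
  root <- setdiff(unique(tr$edge[, 1]), tr$edge[, 2])
  keys <- character(0)
  for (id in setdiff(unique(tr$edge[, 1]), root)) {
    side <- logical(length(ref))
    side[below(id)] <- TRUE
    if (side[1]) side <- !side
    if (sum(side) >= 2 && sum(side) <= length(ref) - 2) {
      keys <- c(keys, paste(which(side), collapse = ","))
    }
  }
  sort(unique(keys))
}
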