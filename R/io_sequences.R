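# Characters treated as missing in alignment columns: gaps, unknowns and all
# IUPAC partial ambiguities. p-distance is only defined over characters that
# can actually be compared, so anything not a definite state is excluded
# pairwise, exactly like a missing genotype call.
.MISSING_CHARS <- c("-", ".", "N", "?", "X",
                    "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

.new_alignment <- function(names, rows) {
  structure(list(names = names, rows = toupper(rows)), class = "alignment")
}

.validate_alignment <- function(aln, where) {
  if (length(aln$names) < 2L) {
    stop("alignment in ", where, " has fewer than 2 records", call. = FALSE)
  }
  dup <- unique(aln$names[duplicated(aln$names)])
  if (length(dup)) {
    stop("duplicate record name(s) in ", where, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  len <- nchar(aln$rows)
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1])[1]
    stop("alignment in ", where, " is ragged: record '", aln$names[off],
         "' has length ", len[off], " but '", aln$names[1], "' has length ",
         len[1], call. = FALSE)
  }
  if (len[1] < 1L) stop("alignment in ", where, " has zero columns",
                        call. = FALSE)
  aln
}

#' Read an aligned FASTA file
#'
#' Multi-line sequences are supported; sequences are case-normalized to
#' upper case. All records must have identical length.
#'
#' @param path FASTA file path (plain or gzipped).
#' @return an `alignment` object with `names` and `rows`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  .validate_alignment(.new_alignment(nm, unname(as.character(set))), path)
}

#' Read a Phylip ("phy") alignment, sequential or interleaved
#'
#' The header line gives the record count n and alignment length L. Names
#' are relaxed: the first whitespace token of a record line, with no
#' 10-character truncation. Sequential files may wrap sequences over
#' several lines; interleaved files repeat n-line blocks.
#'
#' @param path phy file path.
#' @return an `alignment` object.
#' @export
read_phy <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("phy file ", path, " is empty", call. = FALSE)
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) < 2L || !all(grepl("^[0-9]+$", hdr[1:2]))) {
    stop("phy header of ", path, " must hold two integers (n and L)",
         call. = FALSE)
  }
  n <- as.integer(hdr[1]); L <- as.integer(hdr[2])
  body <- lines[-1]

  strip <- function(x) gsub("[[:space:]]", "", x)

  # sequential: name line, then continuation lines until the row reaches L
  try_sequential <- function() {
    nm <- character(0); rows <- character(0)
    i <- 1L
    while (i <= length(body)) {
      tk <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
      nm <- c(nm, tk[1])
      row <- paste0(tk[-1], collapse = "")
      i <- i + 1L
      while (nchar(row) < L && i <= length(body)) {
        row <- paste0(row, strip(body[i]))
        i <- i + 1L
      }
      rows <- c(rows, row)
    }
    if (length(nm) == n && all(nchar(rows) == L)) list(nm, rows) else NULL
  }

  # interleaved: first block carries names, later n-line blocks append
  try_interleaved <- function() {
    if (length(body) %% n != 0L || length(body) < n) return(NULL)
    first <- lapply(body[seq_len(n)],
                    function(x) strsplit(trimws(x), "[[:space:]]+")[[1]])
    nm <- vapply(first, `[[`, character(1), 1L)
    rows <- vapply(first, function(tk) paste0(tk[-1], collapse = ""),
                   character(1))
    extra <- body[-seq_len(n)]
    for (b in seq_len(length(extra) %/% n)) {
      blk <- extra[((b - 1L) * n + 1L):(b * n)]
      rows <- paste0(rows, vapply(blk, strip, character(1)))
    }
    if (all(nchar(rows) == L)) list(nm, rows) else NULL
  }

  res <- try_sequential()
  if (is.null(res)) res <- try_interleaved()
  if (is.null(res)) {
    stop("phy file ", path, " does not match its header (expected ", n,
         " sequences of length ", L, ")", call. = FALSE)
  }
  .validate_alignment(.new_alignment(res[[1]], res[[2]]), path)
}

#' Convert a Phylip alignment file to FASTA
#'
#' @param phy_path input phy file.
#' @param fasta_path output FASTA path.
#' @return `fasta_path`, invisibly.
#' @export
phy_to_fasta <- function(phy_path, fasta_path) {
  aln <- read_phy(phy_path)
  writeLines(paste0(">", aln$names, "\n", aln$rows), fasta_path)
  invisible(fasta_path)
}

#' Expose an alignment as a stream of haploid genotype sites
#'
#' Each column becomes one site: the distinct non-missing characters observed
#' in the column define the allele set (sorted, so allele indices are
#' deterministic) and every sample's call is a haploid 1-tuple. Gap,
#' unknown and IUPAC-ambiguous characters are missing calls. The finalized
#' pairwise distance over such a stream is exactly the proportion of
#' columns, compared pairwise, at which the two sequences differ.
#'
#' @param aln an `alignment`.
#' @param chunk_sites number of columns converted per chunk.
#' @return a `site_stream` over the alignment columns.
#' @export
alignment_site_stream <- function(aln, chunk_sites = 10000L) {
  stopifnot(inherits(aln, "alignment"))
  n <- length(aln$names)
  L <- nchar(aln$rows[1])
  chars <- matrix(unlist(strsplit(aln$rows, "", fixed = TRUE),
                         use.names = FALSE), nrow = L, ncol = n)  # L x n

  e <- new.env(parent = emptyenv())
  e$at <- 0L
  e$sites <- 0L
  e$max_buffered <- 0L

  next_chunk <- function() {
    if (e$at >= L) return(NULL)
    idx <- (e$at + 1L):min(L, e$at + chunk_sites)
    e$at <- e$at + length(idx)
    s <- length(idx)
    e$max_buffered <- max(e$max_buffered, s)
    alleles <- integer(n * s)
    ploidy <- matrix(0L, nrow = n, ncol = s)
    n_alleles <- integer(s)
    for (k in seq_len(s)) {
      col <- chars[idx[k], ]
      ok <- !(col %in% .MISSING_CHARS)
      lev <- sort(unique(col[ok]))
      n_alleles[k] <- max(1L, length(lev))
      ai <- rep(-1L, n)
      ai[ok] <- match(col[ok], lev) - 1L
      alleles[(k - 1L) * n + seq_len(n)] <- ai
      ploidy[ok, k] <- 1L
    }
    e$sites <- e$sites + s
    list(chrom = rep("aln", s), pos = idx, n_alleles = n_alleles,
         alleles = alleles, ploidy = ploidy,
         phased = matrix(FALSE, nrow = n, ncol = s), maxp = 1L, n_sites = s)
  }

  structure(list(
    names = aln$names,
    next_chunk = next_chunk,
    stats = function() list(sites = e$sites, max_buffered = e$max_buffered,
                            chunk_sites = chunk_sites),
    close = function() invisible(NULL)
  ), class = "site_stream")
}
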