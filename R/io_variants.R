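#' @useDynLib vcfpdist, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif setNames
#' @importFrom utils head tail
NULL

# Maximum ploidy the accumulation kernel supports (fixed-size scratch).
.MAX_PLOIDY <- 8L

#' Open a text file, transparently decompressing gzip/bgzip
#'
#' Compression is detected from the two-byte gzip magic number, not the file
#' extension; bgzip files carry the same magic and are handled identically.
#'
#' @param path file path.
#' @return an open read-mode text connection.
#' @keywords internal
open_text_auto <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
}

#' Read a sample-subset list file
#'
#' One sample per line; the first whitespace-delimited token of each
#' non-empty, non-comment (`#`) line is taken as the sample name, so files
#' with trailing annotation columns are accepted. Order is preserved and
#' defines the row/column order of all downstream output.
#'
#' @param path path to a plain-text sample list.
#' @return an object of class `sample_selection` with element `names`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("S1", "S3 groupA"), f)
#' read_sample_list(f)$names
read_sample_list <- function(path) {
  if (!file.exists(path)) stop("sample list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nm <- vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
  if (length(nm) == 0L) stop("sample list is empty: ", path, call. = FALSE)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicate sample name(s) in list: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(list(names = nm), class = "sample_selection")
}

#' Parse a single VCF GT token
#'
#' `/`-separated alleles are unphased, `|`-separated phased, a bare allele is
#' a haploid call. A call containing any missing component (`.`) is treated
#' as missing in its entirety (half-missing calls such as `./1` are dropped
#' whole: the whole-call rule is conservative and symmetric between the pair
#' members).
#'
#' @param token the GT sub-field of one sample column (e.g. `"0/1"`).
#' @return `NULL` if the call is missing, otherwise a list with integer
#'   vector `alleles` and logical `phased`.
#' @export
#' @examples
#' parse_gt("0|1")
#' parse_gt("./1")  # NULL: whole call missing
parse_gt <- function(token) {
  parts <- strsplit(token, "[/|]")[[1]]
  if (length(parts) == 0L || any(parts %in% c(".", ""))) return(NULL)
  if (!all(grepl("^[0-9]+$", parts))) {
    stop("cannot parse GT field '", token, "'", call. = FALSE)
  }
  if (length(parts) > .MAX_PLOIDY) {
    stop("ploidy ", length(parts), " exceeds supported maximum ", .MAX_PLOIDY,
         call. = FALSE)
  }
  phased <- grepl("|", token, fixed = TRUE) && !grepl("/", token, fixed = TRUE)
  list(alleles = as.integer(parts), phased = phased)
}

# Parse a vector of unique GT tokens into columnar form:
# al (maxp x K, -1 padded), pl (K, 0 = missing), ph (K), amax (K, max allele
# index or -1 for missing). Errors on non-numeric tokens.
.parse_gt_table <- function(tokens) {
  calls <- lapply(tokens, parse_gt)
  pl <- vapply(calls, function(x) if (is.null(x)) 0L else length(x$alleles), 0L)
  maxp <- max(1L, pl)
  al <- matrix(-1L, nrow = maxp, ncol = length(tokens))
  ph <- logical(length(tokens))
  amax <- rep(-1L, length(tokens))
  for (k in seq_along(calls)) {
    if (pl[k] > 0L) {
      al[seq_len(pl[k]), k] <- calls[[k]]$alleles
      ph[k] <- calls[[k]]$phased
      amax[k] <- max(calls[[k]]$alleles)
    }
  }
  list(al = al, pl = pl, ph = ph, amax = amax, maxp = maxp)
}

# Parse one chunk of VCF data lines into the columnar site-chunk layout the
# accumulation kernel consumes. sel_cols are absolute tab-field indices of
# the selected sample columns; line_offset is the 1-based line number of the
# line preceding `lines` in `path` (for error messages).
.parse_vcf_chunk <- function(lines, sel_cols, path, line_offset) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 10L)
  if (length(bad)) {
    stop("malformed VCF data line ", line_offset + bad[1], " in ", path,
         ": expected at least 10 tab-delimited fields, found ", nf[bad[1]],
         call. = FALSE)
  }
  if (max(sel_cols) > min(nf)) {
    short <- which(nf < max(sel_cols))[1]
    stop("VCF data line ", line_offset + short, " in ", path,
         " has fewer sample columns than the header", call. = FALSE)
  }
  s <- length(lines)
  nsel <- length(sel_cols)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 2L))
  alt <- vapply(fields, `[[`, character(1), 5L)
  fmt <- vapply(fields, `[[`, character(1), 9L)
  n_alleles <- 1L + ifelse(alt == "." | alt == "", 0L,
                           lengths(strsplit(alt, ",", fixed = TRUE)))

  # locate GT within FORMAT (usually first; cache per distinct FORMAT string)
  ufmt <- unique(fmt)
  gpos <- vapply(strsplit(ufmt, ":", fixed = TRUE),
                 function(p) match("GT", p, nomatch = NA_integer_), NA_integer_)
  if (anyNA(gpos)) {
    miss <- ufmt[which(is.na(gpos))[1]]
    stop("FORMAT '", miss, "' in ", path, " has no GT key", call. = FALSE)
  }
  gidx <- gpos[match(fmt, ufmt)]

  tok <- matrix(unlist(lapply(fields, `[`, sel_cols), use.names = FALSE),
                nrow = nsel, ncol = s)
  simple <- gidx == 1L
  if (any(simple)) {
    tok[, simple] <- sub(":.*", "", tok[, simple, drop = FALSE])
  }
  if (!all(simple)) {
    for (l in which(!simple)) {
      parts <- strsplit(tok[, l], ":", fixed = TRUE)
      if (any(lengths(parts) < gidx[l])) {
        stop("sample column on line ", line_offset + l, " in ", path,
             " has fewer sub-fields than FORMAT declares", call. = FALSE)
      }
      tok[, l] <- vapply(parts, `[[`, character(1), gidx[l])
    }
  }

  ut <- unique(as.vector(tok))
  tab <- .parse_gt_table(ut)
  ti <- matrix(match(tok, ut), nrow = nsel, ncol = s)

  ploidy <- matrix(tab$pl[ti], nrow = nsel, ncol = s)
  phased <- matrix(tab$ph[ti], nrow = nsel, ncol = s)
  alleles <- tab$al[, as.vector(ti), drop = FALSE]  # maxp x (nsel*s)
  dim(alleles) <- c(tab$maxp, nsel, s)

  site_amax <- apply(matrix(tab$amax[ti], nrow = nsel, ncol = s), 2L, max)
  viol <- which(site_amax >= n_alleles)
  if (length(viol)) {
    stop("allele index out of range at ", chrom[viol[1]], ":", pos[viol[1]],
         " in ", path, " (GT references allele ", site_amax[viol[1]],
         " but the site has ", n_alleles[viol[1]], " alleles)", call. = FALSE)
  }

  list(chrom = chrom, pos = pos, n_alleles = n_alleles,
       alleles = as.integer(alleles), ploidy = ploidy, phased = phased,
       maxp = tab$maxp, n_sites = s)
}

# Read a VCF header from an open connection; returns sample names and the
# number of header lines consumed. Errors if no #CHROM line is present.
.read_vcf_header <- function(con, path) {
  consumed <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) {
      stop("no #CHROM header line found in ", path, call. = FALSE)
    }
    consumed <- consumed + 1L
    if (startsWith(line, "#CHROM")) {
      cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(cols) < 10L) {
        stop("VCF header of ", path, " defines no sample columns",
             call. = FALSE)
      }
      return(list(samples = cols[-seq_len(9L)], consumed = consumed))
    }
    if (!startsWith(line, "#")) {
      stop("data line before #CHROM header in ", path, call. = FALSE)
    }
  }
}

#' Stream per-site genotypes from one or more VCF files
#'
#' Files are concatenated in the order given and read line by line in chunks,
#' so resident memory is bounded by `chunk_sites` times the selected sample
#' count, independent of the total number of variants. No filtering is
#' applied: QUAL/FILTER/INFO are ignored, and SNPs, indels and multiallelic
#' sites are all streamed as genotype-index calls.
#'
#' @param paths character vector of VCF paths (plain, gzip or bgzip).
#' @param samples a `sample_selection`, a character vector of sample names,
#'   or `NULL` for all samples of the first file. Every name must be present
#'   in every input file's header; output order is selection order.
#' @param chunk_sites maximum number of variant records buffered at once.
#' @return a `site_stream` object with elements `names` (selected sample
#'   names), `next_chunk()` (returns a parsed chunk or `NULL` at end of
#'   stream) and `stats()` (sites streamed, maximum buffered records).
#' @export
vcf_site_stream <- function(paths, samples = NULL, chunk_sites = 10000L) {
  stopifnot(length(paths) >= 1L, chunk_sites >= 1L)
  for (p in paths) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  sel_names <- if (inherits(samples, "sample_selection")) samples$names else samples

  e <- new.env(parent = emptyenv())
  e$file_i <- 0L
  e$con <- NULL
  e$line_no <- 0L
  e$sel_cols <- NULL
  e$sites <- 0L
  e$max_buffered <- 0L
  # close quietly if a stream is abandoned mid-read (e.g. after an error)
  reg.finalizer(e, function(env) {
    if (!is.null(env$con)) try(close(env$con), silent = TRUE)
  })

  open_next <- function() {
    if (!is.null(e$con)) { close(e$con); e$con <- NULL }
    e$file_i <- e$file_i + 1L
    if (e$file_i > length(paths)) return(FALSE)
    e$con <- open_text_auto(paths[e$file_i])
    tryCatch({
      hdr <- .read_vcf_header(e$con, paths[e$file_i])
      e$line_no <- hdr$consumed
      if (is.null(sel_names)) sel_names <<- hdr$samples
      idx <- match(sel_names, hdr$samples)
      if (anyNA(idx)) {
        missing_nm <- sel_names[is.na(idx)]
        stop("sample(s) ", paste(missing_nm, collapse = ", "),
             " not present in header of ", paths[e$file_i], call. = FALSE)
      }
      e$sel_cols <- 9L + idx
    }, error = function(err) {
      close(e$con)
      e$con <- NULL
      stop(err)
    })
    TRUE
  }
  if (!open_next()) stop("no input files", call. = FALSE)
  nm <- sel_names
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stop("duplicate sample name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  next_chunk <- function() {
    repeat {
      if (is.null(e$con)) return(NULL)
      lines <- readLines(e$con, n = chunk_sites, warn = FALSE)
      if (length(lines) == 0L) {
        if (!open_next()) return(NULL)
        next
      }
      e$max_buffered <- max(e$max_buffered, length(lines))
      ch <- tryCatch(.parse_vcf_chunk(lines, e$sel_cols, paths[e$file_i],
                                      e$line_no),
                     error = function(err) {
                       close(e$con)
                       e$con <- NULL
                       stop(err)
                     })
      e$line_no <- e$line_no + length(lines)
      e$sites <- e$sites + ch$n_sites
      return(ch)
    }
  }

  structure(list(
    names = nm,
    next_chunk = next_chunk,
    stats = function() list(sites = e$sites, max_buffered = e$max_buffered,
                            chunk_sites = chunk_sites),
    close = function() { if (!is.null(e$con)) { close(e$con); e$con <- NULL } }
  ), class = "site_stream")
}

#' Materialize a site stream as a list of per-site records
#'
#' Intended for small inputs (inspection, testing); each record carries
#' `chrom`, `pos`, `n_alleles` and a `genotypes` list with one entry per
#' selected sample: `NULL` for a missing call, otherwise
#' `list(alleles =, phased =)`.
#'
#' @param stream a `site_stream`.
#' @return list of site records.
#' @export
collect_sites <- function(stream) {
  out <- list()
  repeat {
    ch <- stream$next_chunk()
    if (is.null(ch)) break
    n <- length(stream$names)
    al <- array(ch$alleles, dim = c(ch$maxp, n, ch$n_sites))
    for (l in seq_len(ch$n_sites)) {
      g <- vector("list", n)
      for (i in seq_len(n)) {
        p <- ch$ploidy[i, l]
        if (p > 0L) {
          g[[i]] <- list(alleles = al[seq_len(p), i, l],
                         phased = ch$phased[i, l])
        }
      }
      out[[length(out) + 1L]] <- list(chrom = ch$chrom[l], pos = ch$pos[l],
                                      n_alleles = ch$n_alleles[l],
                                      genotypes = g)
    }
  }
  out
}
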