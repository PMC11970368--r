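.NWK_SPECIAL <- "[][(),:;'[:space:]]"

.quote_label <- function(x) {
  need <- grepl(.NWK_SPECIAL, x)
  x[need] <- paste0("'", gsub("'", "''", x[need]), "'")
  x
}

#' Serialize a tree to Newick text
#'
#' Branch lengths are written fixed-point; internal support values (node
#' labels), when present, are written as internal node labels after the
#' closing parenthesis. Leaf names containing Newick metacharacters are
#' single-quoted with `''` escaping.
#'
#' @param tree a `phylo` object.
#' @param file optional path; if given the text is written there.
#' @param decimals fixed-point decimals for branch lengths (default 6).
#' @return the Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL, decimals = 6L) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- .phylo_children(tree)
  elen <- tree$edge.length
  len_of <- rep(NA_real_, ntip + tree$Nnode)
  if (!is.null(elen)) len_of[tree$edge[, 2]] <- elen
  lab_of <- function(id) {
    if (id <= ntip) return(.quote_label(tree$tip.label[id]))
    if (is.null(tree$node.label)) return("")
    lb <- tree$node.label[id - ntip]
    if (is.na(lb) || !nzchar(lb)) "" else .quote_label(lb)
  }
  fmt <- function(id) {
    s <- if (is.null(kids[[id]])) {
      lab_of(id)
    } else {
      paste0("(", paste(vapply(kids[[id]], fmt, character(1)), collapse = ","),
             ")", lab_of(id))
    }
    if (!is.na(len_of[id])) {
      s <- paste0(s, ":", formatC(len_of[id], format = "f", digits = decimals))
    }
    s
  }
  txt <- paste0(fmt(.phylo_root(tree)), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Parse a Newick string into a tree
#'
#' Tolerates missing branch lengths; internal labels become `node.label`
#' (typically bootstrap supports). Single-quoted labels (with `''` escapes)
#' are supported. Unbalanced parentheses or trailing garbage are fatal.
#'
#' @param text a Newick string (one tree, terminated by `;`).
#' @return a `phylo` object.
#' @export
parse_newick <- function(text) {
  s <- trimws(text)
  if (!nzchar(s)) stop("empty Newick string", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$pos <- 1L
  n <- nchar(s)
  peek <- function() if (e$pos <= n) substr(s, e$pos, e$pos) else ""
  advance <- function() e$pos <- e$pos + 1L
  skip_ws <- function() while (e$pos <= n && grepl("^[[:space:]]$", peek())) advance()

  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        if (e$pos > n) stop("unterminated quoted label in Newick",
                            call. = FALSE)
        ch <- peek(); advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      return(paste(out, collapse = ""))
    }
    start <- e$pos
    while (e$pos <= n && !grepl("[](),:;[[:space:]]", peek())) advance()
    substr(s, start, e$pos - 1L)
  }

  read_length <- function() {
    skip_ws()
    if (peek() != ":") return(NA_real_)
    advance()
    skip_ws()
    start <- e$pos
    while (e$pos <= n && grepl("[-+0-9.eE]", peek())) advance()
    v <- suppressWarnings(as.numeric(substr(s, start, e$pos - 1L)))
    if (is.na(v)) stop("malformed branch length in Newick near position ",
                       start, call. = FALSE)
    v
  }

  read_clade <- function() {
    skip_ws()
    if (peek() == "(") {
      advance()
      children <- list(read_clade())
      repeat {
        skip_ws()
        if (peek() == ",") { advance(); children <- c(children, list(read_clade())) }
        else if (peek() == ")") { advance(); break }
        else stop("unbalanced parentheses in Newick near position ", e$pos,
                  call. = FALSE)
      }
      lab <- read_label()
      .tree_node(label = if (nzchar(lab)) lab else NA_character_,
                 length = read_length(), children = children)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) {
        stop("expected a taxon label in Newick near position ", e$pos,
             call. = FALSE)
      }
      .tree_node(label = lab, length = read_length())
    }
  }

  root <- read_clade()
  skip_ws()
  if (peek() != ";") {
    stop("malformed Newick: expected ';' near position ", e$pos, call. = FALSE)
  }
  advance()
  skip_ws()
  if (e$pos <= n) stop("trailing characters after ';' in Newick", call. = FALSE)
  if (length(root$children) == 0L) {
    stop("Newick tree has a single taxon", call. = FALSE)
  }
  .as_phylo(root)
}

#' Read a multi-tree Newick file (one tree per line)
#'
#' @param path file with one Newick tree per line.
#' @return list of `phylo` objects.
#' @export
read_newick_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in ", path, call. = FALSE)
  lapply(lines, parse_newick)
}
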