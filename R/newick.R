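## Newick I/O and the tree representation.
##
## Trees are stored as ape-style "phylo" objects (edge matrix, tip.label,
## node.label, edge.length).  Absent branch lengths are stored as NA, never 0;
## internal-node labels are kept verbatim (numeric labels are interpreted as
## branch supports only where scoring needs them).  A one-leaf tree, which
## "phylo" cannot represent, is returned as a degenerate object of class
## c("qstree_leaf", "phylo") understood by write_newick().

#' Parse a Newick string
#'
#' Parses one Newick tree. Polytomies are preserved, quoted labels (single
#' quotes, with `''` as an escape) are accepted, bracketed comments are
#' ignored, and branch lengths are optional per branch. Internal-node labels
#' are stored verbatim in `node.label`; whether a label is treated as a
#' support value is decided downstream (see [gene_tree_set()]).
#' Unary (degree-2) internal nodes are suppressed, summing branch lengths.
#'
#' @param text a single Newick string, terminated by `;` (the terminator may
#'   be omitted).
#' @return an object of class `phylo` (or `c("qstree_leaf","phylo")` for a
#'   single-leaf tree).
#' @examples
#' tr <- parse_newick("((a:1,b:2)0.9:0.5,c:1,d:1);")
#' tr$node.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)      # strip [comments]
  toks <- newick_tokens(text)
  if (length(toks) == 0L)
    stop("parse error: empty tree", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$toks <- toks
  node <- nwk_subtree(env)
  if (env$i <= length(env$toks)) {
    tk <- env$toks[env$i]
    if (tk != ";")
      stop(sprintf("parse error at token %d ('%s'): expected ';' or end of input",
                   env$i, tk), call. = FALSE)
    env$i <- env$i + 1L
    if (env$i <= length(env$toks))
      stop(sprintf("parse error at token %d ('%s'): trailing input after ';'",
                   env$i, env$toks[env$i]), call. = FALSE)
  }
  node <- collapse_unary(node)
  tr <- nested_to_phylo(node)
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    stop("parse error: duplicate leaf labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  tr
}

newick_tokens <- function(text) {
  m <- gregexpr("'(?:[^']|'')*'|[(),;:]|[^(),;:'[:space:]]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(text, list(m))[[1]]
  ## anything not consumed (other than whitespace) is an error
  covered <- sum(attr(m, "match.length"))
  rest <- gsub("[[:space:]]", "", text)
  if (nchar(paste(toks, collapse = "")) != nchar(rest) && any(grepl("'", rest, fixed = TRUE)) == FALSE)
    stop("parse error: unrecognized characters in input", call. = FALSE)
  toks
}

nwk_peek <- function(env) if (env$i <= length(env$toks)) env$toks[env$i] else NA_character_

nwk_subtree <- function(env) {
  tk <- nwk_peek(env)
  if (is.na(tk))
    stop("parse error: unexpected end of input (unbalanced parentheses?)", call. = FALSE)
  if (tk == "(") {
    env$i <- env$i + 1L
    children <- list(nwk_subtree(env))
    repeat {
      tk <- nwk_peek(env)
      if (is.na(tk))
        stop("parse error: unexpected end of input inside '(' (unbalanced parentheses)",
             call. = FALSE)
      if (tk == ",") {
        env$i <- env$i + 1L
        children[[length(children) + 1L]] <- nwk_subtree(env)
      } else if (tk == ")") {
        env$i <- env$i + 1L
        break
      } else {
        stop(sprintf("parse error at token %d ('%s'): expected ',' or ')'", env$i, tk),
             call. = FALSE)
      }
    }
    node <- list(children = children, label = nwk_label(env), length = nwk_length(env))
  } else if (tk %in% c(")", ",", ";", ":")) {
    stop(sprintf("parse error at token %d ('%s'): expected a label or '('", env$i, tk),
         call. = FALSE)
  } else {
    env$i <- env$i + 1L
    node <- list(children = list(), label = nwk_unquote(tk), length = nwk_length(env))
  }
  node
}

nwk_label <- function(env) {
  tk <- nwk_peek(env)
  if (is.na(tk) || tk %in% c("(", ")", ",", ";", ":")) return("")
  env$i <- env$i + 1L
  nwk_unquote(tk)
}

nwk_length <- function(env) {
  tk <- nwk_peek(env)
  if (is.na(tk) || tk != ":") return(NA_real_)
  env$i <- env$i + 1L
  tk <- nwk_peek(env)
  val <- suppressWarnings(as.numeric(tk))
  if (is.na(tk) || is.na(val))
    stop(sprintf("parse error at token %d ('%s'): expected a branch length after ':'",
                 env$i, if (is.na(tk)) "<end>" else tk), call. = FALSE)
  env$i <- env$i + 1L
  val
}

nwk_unquote <- function(tk) {
  if (startsWith(tk, "'") && endsWith(tk, "'") && nchar(tk) >= 2L)
    gsub("''", "'", substr(tk, 2L, nchar(tk) - 1L), fixed = TRUE)
  else
    tk
}

## suppress degree-2 internal nodes, summing branch lengths (NA = missing)
collapse_unary <- function(node) {
  if (length(node$children) == 0L) return(node)
  node$children <- lapply(node$children, collapse_unary)
  while (length(node$children) == 1L && length(node$children[[1]]$children) > 0L) {
    ch <- node$children[[1]]
    ln <- if (is.na(node$length) && is.na(ch$length)) NA_real_ else
      sum(c(node$length, ch$length), na.rm = TRUE)
    lab <- if (nzchar(node$label)) node$label else ch$label
    node <- list(children = ch$children, label = lab, length = ln)
  }
  if (length(node$children) == 1L) {          # single leaf child
    ch <- node$children[[1]]
    ln <- if (is.na(node$length) && is.na(ch$length)) NA_real_ else
      sum(c(node$length, ch$length), na.rm = TRUE)
    node <- list(children = list(), label = ch$label, length = ln)
  }
  node
}

## nested list -> phylo.  Tips numbered in input order, internals in preorder.
nested_to_phylo <- function(root) {
  if (length(root$children) == 0L) {
    tr <- list(edge = matrix(integer(0), 0L, 2L), tip.label = root$label,
               Nnode = 0L, node.label = character(0))
    class(tr) <- c("qstree_leaf", "phylo")
    return(tr)
  }
  n_tip <- 0L; n_int <- 0L
  count <- function(nd) {
    if (length(nd$children) == 0L) n_tip <<- n_tip + 1L else {
      n_int <<- n_int + 1L
      for (c in nd$children) count(c)
    }
  }
  count(root)
  edge <- matrix(0L, n_tip + n_int - 1L, 2L)
  elen <- rep(NA_real_, nrow(edge))
  tip.label <- character(n_tip)
  node.label <- character(n_int)
  ti <- 0L; ii <- 0L; ei <- 0L
  walk <- function(nd) {
    if (length(nd$children) == 0L) {
      ti <<- ti + 1L
      tip.label[ti] <<- nd$label
      ti
    } else {
      ii <<- ii + 1L
      my <- n_tip + ii
      node.label[ii] <<- nd$label
      my_rows <- integer(0)
      for (c in nd$children) {
        ei <<- ei + 1L
        row <- ei
        edge[row, 1L] <<- my
        elen[row] <<- c$length
        cid <- walk(c)
        edge[row, 2L] <<- cid
      }
      my
    }
  }
  walk(root)
  tr <- list(edge = edge, tip.label = tip.label, Nnode = n_int,
             node.label = node.label)
  if (!all(is.na(elen))) tr$edge.length <- elen
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

#' Serialize a tree to Newick
#'
#' Writes a `phylo` object as a Newick string. Labels containing Newick
#' metacharacters (including `;` used by annotation labels) are single-quoted;
#' `NA` branch lengths are omitted rather than written as 0.
#'
#' @param tree a `phylo` (possibly with `node.label` / `edge.length`).
#' @param digits significant digits for branch lengths.
#' @return a single Newick string ending in `;`.
#' @export
write_newick <- function(tree, digits = 10) {
  if (inherits(tree, "qstree_leaf") || (is.null(tree$edge) || nrow(tree$edge) == 0L))
    return(paste0(nwk_quote(tree$tip.label[1L]), ";"))
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  elen <- tree$edge.length
  fmt_len <- function(row) {
    if (is.null(elen) || is.na(elen[row])) "" else
      paste0(":", format(elen[row], digits = digits, scientific = FALSE, trim = TRUE))
  }
  rec <- function(node, row) {
    suffix <- if (is.null(row)) "" else fmt_len(row)
    if (node <= n)
      return(paste0(nwk_quote(tree$tip.label[node]), suffix))
    rows <- kids[[as.character(node)]]
    inner <- vapply(rows, function(r) rec(tree$edge[r, 2L], r), character(1))
    lab <- if (!is.null(tree$node.label) && length(tree$node.label) >= node - n)
      tree$node.label[node - n] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(inner, collapse = ","), ")", nwk_quote(lab, empty_ok = TRUE), suffix)
  }
  paste0(rec(root, NULL), ";")
}

nwk_quote <- function(lab, empty_ok = FALSE) {
  if (is.na(lab) || (!nzchar(lab) && empty_ok)) return("")
  if (grepl("[](),:;'[[:space:]]", lab))
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  else lab
}

#' Read gene trees from a Newick file (one tree per line)
#'
#' Empty lines are skipped. Returns a plain list of `phylo` trees; use
#' [gene_tree_set()] to build a scoring-ready object.
#'
#' @param path file with one Newick string per line.
#' @return list of `phylo` objects.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no trees in file: ", path, call. = FALSE)
  lapply(lines, parse_newick)
}

#' Write a list of trees to a Newick file
#'
#' @param trees a `phylo` or list of `phylo`.
#' @param path output path.
#' @param digits significant digits for branch lengths.
#' @return invisibly, `path`.
#' @export
write_newick_file <- function(trees, path, digits = 10) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1), digits = digits), path)
  invisible(path)
}
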