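## Tree surgery and canonical bipartitions.
##
## All scoring treats trees as unrooted; a degree-2 root is suppressed first.
## Bipartitions are canonicalized so that the block containing the
## lexicographically smallest taxon label is block A.

phylo_to_nested <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  elen <- tree$edge.length
  rec <- function(node, row) {
    len <- if (is.null(row) || is.null(elen)) NA_real_ else elen[row]
    if (node <= n)
      return(list(children = list(), label = tree$tip.label[node], length = len))
    rows <- kids[[as.character(node)]]
    lab <- if (!is.null(tree$node.label)) tree$node.label[node - n] else ""
    if (is.na(lab)) lab <- ""
    list(children = lapply(rows, function(r) rec(tree$edge[r, 2L], r)),
         label = lab, length = len)
  }
  rec(n + 1L, NULL)
}

n_tips <- function(tree) length(tree$tip.label)

root_children <- function(tree) {
  n <- n_tips(tree)
  tree$edge[tree$edge[, 1L] == n + 1L, 2L]
}

#' Is a tree rooted (degree-2 root)?
#' @param tree a `phylo`.
#' @return logical.
#' @export
is_rooted_tree <- function(tree) {
  if (n_tips(tree) < 3L) return(TRUE)
  length(root_children(tree)) == 2L
}

#' Unroot a tree
#'
#' Suppresses a degree-2 root, merging the two root branches (lengths are
#' summed treating a pair of missing lengths as missing; the surviving branch
#' keeps the non-empty support label). Trees that are already unrooted are
#' returned unchanged.
#'
#' @param tree a `phylo`.
#' @return an unrooted `phylo` (basal multifurcation).
#' @export
unroot_tree <- function(tree) {
  if (n_tips(tree) < 3L || !is_rooted_tree(tree)) return(tree)
  nd <- phylo_to_nested(tree)
  ints <- which(vapply(nd$children, function(c) length(c$children) > 0L, logical(1)))
  if (length(ints) == 0L) return(tree)   # 2 leaves: cannot unroot
  ci <- nd$children[[ints[1L]]]
  co <- nd$children[[if (ints[1L] == 1L) 2L else 1L]]
  ln <- if (is.na(ci$length) && is.na(co$length)) NA_real_ else
    sum(c(ci$length, co$length), na.rm = TRUE)
  co$length <- ln
  if (!nzchar(co$label) && length(co$children) > 0L && nzchar(ci$label))
    co$label <- ci$label
  newroot <- list(children = c(ci$children, list(co)), label = "", length = NA_real_)
  nested_to_phylo(newroot)
}

#' Is a tree a fully resolved unrooted tree?
#' @param tree a `phylo`.
#' @return logical: every internal node has degree 3 in the unrooted view.
#' @export
is_binary_unrooted <- function(tree) {
  tree <- unroot_tree(tree)
  n <- n_tips(tree)
  if (n < 4L) return(tree$Nnode == max(1L, n - 2L))
  deg <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  all(deg[(n + 2L):(n + tree$Nnode)] == 2L) && deg[n + 1L] == 3L &&
    tree$Nnode == n - 2L
}

## per-node descendant tip sets (list over all node ids); works for any edge
## row order (trees from surgery are not in preorder)
node_sets_generic <- function(tree, leaf_value) {
  n <- n_tips(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  sets <- vector("list", n + tree$Nnode)
  rec <- function(node) {
    if (node <= n) { sets[[node]] <<- leaf_value(node); return(sets[[node]]) }
    acc <- NULL
    for (r in kids[[as.character(node)]])
      acc <- c(acc, rec(tree$edge[r, 2L]))
    sets[[node]] <<- acc
    acc
  }
  rec(n + 1L)
  sets
}

## per-node descendant tip label sets (list over all node ids)
node_tipsets <- function(tree) {
  node_sets_generic(tree, function(i) tree$tip.label[i])
}

bip_key <- function(A, B, all_min) {
  a <- paste(sort(A), collapse = ",")
  b <- paste(sort(B), collapse = ",")
  if (all_min %in% A) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' One canonical bipartition per internal branch of the unrooted tree
#' (branches with fewer than two taxa on a side are trivial and skipped).
#' A binary tree on n leaves yields n-3 bipartitions; a star yields none.
#'
#' @param tree a `phylo`.
#' @return a list of `bipartition` objects (fields `A`, `B`, `key`), with the
#'   block containing the lexicographically smallest taxon as `A`.
#' @export
tree_bipartitions <- function(tree) {
  tree <- unroot_tree(tree)
  n <- n_tips(tree)
  if (n < 4L || tree$Nnode < 2L) return(list())
  all_lab <- sort(tree$tip.label)
  sets <- node_tipsets(tree)
  out <- list(); seen <- character(0)
  for (r in seq_len(nrow(tree$edge))) {
    child <- tree$edge[r, 2L]
    if (child <= n) next
    blk <- sets[[child]]
    oth <- setdiff(tree$tip.label, blk)
    if (length(blk) < 2L || length(oth) < 2L) next
    key <- bip_key(blk, oth, all_lab[1L])
    if (key %in% seen) next
    seen <- c(seen, key)
    if (all_lab[1L] %in% blk) {
      A <- sort(blk); B <- sort(oth)
    } else {
      A <- sort(oth); B <- sort(blk)
    }
    out[[length(out) + 1L]] <- structure(list(A = A, B = B, key = key),
                                         class = "bipartition")
  }
  out
}

#' Canonical bipartition keys of a tree
#' @param tree a `phylo`.
#' @return character vector of canonical `"A|B"` keys (sorted).
#' @export
bipartition_keys <- function(tree) {
  sort(vapply(tree_bipartitions(tree), function(b) b$key, character(1)))
}

#' Topology equality of two unrooted trees
#' @param a,b `phylo` objects.
#' @return TRUE when leaf sets and non-trivial bipartition sets coincide.
#' @export
same_topology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) &&
    identical(bipartition_keys(a), bipartition_keys(b))
}

## deterministic canonical key for tie-breaking (leaves + bipartitions)
canonical_key <- function(tree) {
  paste(c(paste(sort(tree$tip.label), collapse = ","), bipartition_keys(tree)),
        collapse = ";")
}

numeric_labels <- function(labels) {
  out <- suppressWarnings(as.numeric(labels))
  out[!nzchar(labels) | is.na(labels)] <- NA_real_
  out
}

#' Collapse poorly supported branches
#'
#' Every internal branch whose numeric support label is strictly below
#' `threshold` is collapsed into a polytomy. Branches without a (numeric)
#' support are kept; leaf branches are never contracted. The support scale is
#' auto-detected: if any numeric label exceeds 1 the tree is assumed to carry
#' percent-scale supports (e.g. bootstrap) and both supports and threshold
#' are normalized to `[0,1]` before comparison; set `scale` to `"prob"` or
#' `"percent"` to override.
#'
#' @param tree a `phylo`.
#' @param threshold non-negative support threshold.
#' @param scale `"auto"`, `"prob"` or `"percent"`.
#' @return a `phylo`, possibly multifurcating.
#' @export
contract_low_support <- function(tree, threshold, scale = c("auto", "prob", "percent")) {
  scale <- match.arg(scale)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  sup <- numeric_labels(tree$node.label)
  pct <- switch(scale, percent = TRUE, prob = FALSE,
                auto = any(sup > 1, na.rm = TRUE))
  if (pct) sup <- sup / 100
  thr <- if (threshold > 1) threshold / 100 else threshold
  nd <- phylo_to_nested(tree)
  sup_of <- function(lab) {
    v <- numeric_labels(lab)
    if (pct) v / 100 else v
  }
  rec <- function(node) {
    if (length(node$children) == 0L) return(node)
    node$children <- lapply(node$children, rec)
    keep <- list()
    for (ch in node$children) {
      s <- sup_of(ch$label)
      if (length(ch$children) > 0L && !is.na(s) && s < thr) {
        keep <- c(keep, ch$children)      # splice: collapse the branch
      } else keep <- c(keep, list(ch))
    }
    node$children <- keep
    node
  }
  nested_to_phylo(rec(nd))
}

#' Read an individual-to-species map
#'
#' Plain-text map with one `individual species` pair (whitespace-separated)
#' per non-empty line.
#'
#' @param path file path.
#' @return a named character vector (class `taxon_map`): species labels named
#'   by individual labels.
#' @export
read_taxon_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("taxon map: line ", bad[1L], " does not have two columns", call. = FALSE)
  taxon_map(vapply(parts, `[[`, character(1), 1L),
            vapply(parts, `[[`, character(1), 2L))
}

#' Construct an individual-to-species map
#' @param individuals character vector of individual (gene-tree leaf) labels.
#' @param species character vector of species labels, same length.
#' @return a `taxon_map` (named character vector).
#' @export
taxon_map <- function(individuals, species) {
  stopifnot(length(individuals) == length(species))
  dup <- duplicated(individuals)
  if (any(dup)) {
    for (i in which(dup)) {
      first <- species[match(individuals[i], individuals)]
      if (first != species[i])
        stop("taxon map: individual '", individuals[i],
             "' mapped to conflicting species ('", first, "' vs '",
             species[i], "')", call. = FALSE)
    }
    species <- species[!dup]; individuals <- individuals[!dup]
  }
  structure(stats::setNames(as.character(species), as.character(individuals)),
            class = "taxon_map")
}

## ---- tree construction / rearrangement -------------------------------------

#' Star tree on a set of labels
#' @param labels at least 3 tip labels.
#' @return an unrooted star `phylo`.
#' @export
star_tree <- function(labels) {
  stopifnot(length(labels) >= 3L)
  nested_to_phylo(list(children = lapply(labels, function(l)
    list(children = list(), label = l, length = NA_real_)),
    label = "", length = NA_real_))
}

#' Attach a new leaf on an edge
#'
#' Subdivides edge `edge_row` of `tree` with a new internal node and hangs a
#' new leaf labelled `label` from it. Branch lengths of the new edges are
#' missing.
#'
#' @param tree a `phylo`.
#' @param edge_row row index into `tree$edge`.
#' @param label new tip label.
#' @return a `phylo` with one more leaf.
#' @export
attach_leaf <- function(tree, edge_row, label) {
  n <- n_tips(tree); m <- tree$Nnode
  stopifnot(edge_row >= 1L, edge_row <= nrow(tree$edge))
  remap <- function(v) ifelse(v > n, v + 1L, v)   # internals shift by one tip
  e <- cbind(remap(tree$edge[, 1L]), remap(tree$edge[, 2L]))
  w <- n + m + 2L                                  # new internal node (last)
  newtip <- n + 1L
  tgt <- e[edge_row, ]
  e[edge_row, 2L] <- w
  e <- rbind(e, c(w, tgt[2L]), c(w, newtip))
  elen <- tree$edge.length
  if (!is.null(elen)) elen <- c(elen, NA_real_, NA_real_)
  nl <- tree$node.label
  if (!is.null(nl)) nl <- c(nl, "")
  tr <- list(edge = e, tip.label = c(tree$tip.label, label),
             Nnode = m + 1L, node.label = nl)
  if (!is.null(elen)) tr$edge.length <- elen
  class(tr) <- "phylo"
  tr
}

#' All nearest-neighbor-interchange neighbors
#'
#' For a binary unrooted tree on n leaves returns the 2(n-3) trees one NNI
#' move away, in a deterministic order. Node labels are dropped (they would
#' refer to stale splits); branch lengths travel with their subtrees.
#'
#' @param tree a binary unrooted `phylo` (a rooted binary tree is unrooted
#'   first).
#' @return list of `phylo` trees.
#' @export
nni_neighbors <- function(tree) {
  tree <- unroot_tree(tree)
  if (!is_binary_unrooted(tree))
    stop("nni_neighbors requires a binary unrooted tree", call. = FALSE)
  n <- n_tips(tree)
  if (!is.null(tree$node.label)) tree$node.label[] <- ""
  out <- list()
  for (r in seq_len(nrow(tree$edge))) {
    v <- tree$edge[r, 2L]
    if (v <= n) next                       # internal edges only
    u <- tree$edge[r, 1L]
    sib_rows <- which(tree$edge[, 1L] == u & seq_len(nrow(tree$edge)) != r)
    s <- sib_rows[1L]                      # one sibling suffices for both NNIs
    v_rows <- which(tree$edge[, 1L] == v)
    for (cr in v_rows) {
      tr2 <- tree
      tmp <- tr2$edge[s, 2L]
      tr2$edge[s, 2L] <- tr2$edge[cr, 2L]
      tr2$edge[cr, 2L] <- tmp
      if (!is.null(tr2$edge.length)) {
        tl <- tr2$edge.length[s]
        tr2$edge.length[s] <- tr2$edge.length[cr]
        tr2$edge.length[cr] <- tl
      }
      out[[length(out) + 1L]] <- tr2
    }
  }
  out
}

## block assignment matrices used by the C++ scoring kernel -------------------

## one row per internal node of the unrooted binary species tree; entries
## 0,1,2 = tripartition block of each species, 3 = species absent
species_tripartitions <- function(tree, species) {
  tree <- unroot_tree(tree)
  n <- n_tips(tree)
  sets <- node_tipsets(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  nodes <- (n + 1L):(n + tree$Nnode)
  out <- matrix(3L, length(nodes), length(species),
                dimnames = list(NULL, species))
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    comps <- lapply(kids[[as.character(nd)]], function(r) sets[[tree$edge[r, 2L]]])
    if (nd != n + 1L)
      comps <- c(comps, list(setdiff(tree$tip.label, sets[[nd]])))
    if (length(comps) != 3L)
      stop("species tree must be binary (fully resolved) for scoring",
           call. = FALSE)
    for (b in 1:3) out[i, match(comps[[b]], species)] <- b - 1L
  }
  out
}

## quadripartition around each internal edge: blocks 0,1 on one side and 2,3
## on the other; 4 = absent.  Returns list(blocks=matrix, child=node ids)
species_quadripartitions <- function(tree, species) {
  tree <- unroot_tree(tree)
  n <- n_tips(tree)
  if (!is_binary_unrooted(tree))
    stop("species tree must be binary for branch annotation", call. = FALSE)
  sets <- node_tipsets(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  rows <- which(tree$edge[, 2L] > n)
  blocks <- matrix(4L, length(rows), length(species),
                   dimnames = list(NULL, species))
  for (i in seq_along(rows)) {
    r <- rows[i]
    u <- tree$edge[r, 1L]; v <- tree$edge[r, 2L]
    u_rows <- setdiff(kids[[as.character(u)]], r)
    ucomps <- lapply(u_rows, function(rr) sets[[tree$edge[rr, 2L]]])
    if (u != n + 1L)
      ucomps <- c(ucomps, list(setdiff(tree$tip.label, sets[[u]])))
    vcomps <- lapply(kids[[as.character(v)]], function(rr) sets[[tree$edge[rr, 2L]]])
    comps <- c(ucomps, vcomps)              # A, B | C, D
    for (b in 1:4) blocks[i, match(comps[[b]], species)] <- b - 1L
  }
  list(blocks = blocks, child = tree$edge[rows, 2L], rows = rows, tree = tree)
}
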