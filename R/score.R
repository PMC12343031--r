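## Quartet topologies, weights, and the two scoring routes.
##
## The brute-force route enumerates species quadruples and evaluates each via
## edge bipartition masks; the fast route aggregates per-tripartition anchored
## counts in C++.  Their exact agreement (unit mode) / 1e-9 relative agreement
## (weighted modes) is the central correctness contract of the package.

## edge-side masks and per-edge annotations of one unrooted tree
tree_sides <- function(tree, norm_sup = NULL) {
  n <- n_tips(tree)
  ne <- nrow(tree$edge)
  side <- matrix(FALSE, ne, n)
  sets <- node_tipsets_idx(tree)
  for (r in seq_len(ne)) side[r, sets[[tree$edge[r, 2L]]]] <- TRUE
  if (is.null(norm_sup)) {
    sup <- rep(NA_real_, ne)
    nl <- numeric_labels(tree$node.label)
    if (any(nl > 1, na.rm = TRUE)) nl <- nl / 100     # per-tree auto scale
    int_child <- tree$edge[, 2L] > n
    sup[int_child] <- nl[tree$edge[int_child, 2L] - n]
  } else sup <- norm_sup
  len <- if (is.null(tree$edge.length)) rep(NA_real_, ne) else tree$edge.length
  list(side = side, sup = sup, len = len, n = n)
}

## like node_tipsets() but tip indices, not labels
node_tipsets_idx <- function(tree) {
  node_sets_generic(tree, identity)
}

## pairing of 4 leaves: 0 unresolved, 1 = l1l2|l3l4, 2 = l1l3|l2l4, 3 = l1l4|l2l3
## also support product over internal-path edges and total terminal length L
eval_quartet <- function(sides, leaves, default_sup = 1) {
  sub <- sides$side[, leaves, drop = FALSE]
  rs <- sub[, 1L] + sub[, 2L] + sub[, 3L] + sub[, 4L]
  mid <- which(rs == 2L)
  if (length(mid) == 0L) return(list(code = 0L, wsup = 0, L = 0))
  s <- sub[mid[1L], ]
  code <- if (s[1L] == s[2L]) 1L else if (s[1L] == s[3L]) 2L else 3L
  sup <- sides$sup[mid]
  sup[is.na(sup)] <- default_sup
  term <- rs == 1L | rs == 3L
  L <- sum(sides$len[term], na.rm = TRUE)
  list(code = code, wsup = prod(sup), L = L)
}

scheme_weight <- function(ev, scheme) {
  switch(scheme$mode,
         unit = 1,
         support = ev$wsup,
         hybrid = ev$wsup * exp(-ev$L))
}

#' Quartet topology induced by a tree
#'
#' For four species present in a tree, which of the three pairings the tree
#' displays, or unresolved when the four leaves meet at a polytomy.
#'
#' @param tree a `phylo` whose tip labels are the species.
#' @param quad character vector of 4 distinct species.
#' @return object of class `quartet_topology` with fields `species` (sorted),
#'   `code` (0 = unresolved, 1 = `s1s2|s3s4`, 2 = `s1s3|s2s4`,
#'   3 = `s1s4|s2s3`, `NA` = a species is missing from the tree) and
#'   `pairing` (human-readable string).
#' @export
induced_quartet <- function(tree, quad) {
  stopifnot(length(quad) == 4L, !anyDuplicated(quad))
  tree <- unroot_tree(tree)
  sq <- sort(quad)
  leaves <- match(sq, tree$tip.label)
  if (anyNA(leaves)) {
    out <- list(species = sq, code = NA_integer_, pairing = "missing")
    class(out) <- "quartet_topology"
    return(out)
  }
  ev <- eval_quartet(tree_sides(tree), leaves)
  out <- list(species = sq, code = ev$code, pairing = pairing_string(sq, ev$code))
  class(out) <- "quartet_topology"
  out
}

pairing_string <- function(sq, code) {
  if (is.na(code)) return("missing")
  switch(code + 1L,
         "unresolved",
         sprintf("%s,%s|%s,%s", sq[1], sq[2], sq[3], sq[4]),
         sprintf("%s,%s|%s,%s", sq[1], sq[3], sq[2], sq[4]),
         sprintf("%s,%s|%s,%s", sq[1], sq[4], sq[2], sq[3]))
}

#' @export
print.quartet_topology <- function(x, ...) {
  cat("quartet {", paste(x$species, collapse = ","), "}: ", x$pairing, "\n",
      sep = "")
  invisible(x)
}

#' Weight of one gene-tree quartet
#'
#' Unit mode gives 1 for any resolved quartet; support mode multiplies the
#' supports of the internal branches on the path connecting the quartet's two
#' pairs; hybrid mode additionally multiplies by `exp(-L)` with `L` the sum of
#' the four terminal path lengths. Unresolved or missing quartets weigh 0.
#' Percent-scale supports in the tree are normalized automatically.
#'
#' @param tree a `phylo`.
#' @param quad 4 distinct species labels.
#' @param scheme a [weight_scheme()] (or mode string).
#' @return a non-negative number.
#' @export
quartet_weight <- function(tree, quad, scheme = weight_scheme("unit")) {
  scheme <- as_weight_scheme(scheme)
  tree <- unroot_tree(tree)
  sq <- sort(quad)
  leaves <- match(sq, tree$tip.label)
  if (anyNA(leaves)) return(0)
  sides <- tree_sides(tree)
  if (any(sides$sup < 0 | sides$sup > 1, na.rm = TRUE))
    stop("branch supports outside [0,1] after scale normalization", call. = FALSE)
  ev <- eval_quartet(sides, leaves, scheme$default_missing_support)
  if (ev$code == 0L) return(0)
  scheme_weight(ev, scheme)
}

#' Per-tree quartet topology masses with multiple individuals per species
#'
#' For four distinct species, averages the induced quartet topology over all
#' choices of one individual per species present in each gene tree, returning
#' the probability mass each tree puts on the three pairings (rows may sum to
#' less than 1 when some individual choices are unresolved; a row is `NA` when
#' a species is absent from that tree).
#'
#' @param genes a [gene_tree_set()].
#' @param quad 4 distinct species labels.
#' @return a `k x 3` matrix; column `j` is the mass on pairing `j` of the
#'   sorted quadruple (see [induced_quartet()] for the pairing codes).
#' @export
multi_individual_quartet <- function(genes, quad) {
  stopifnot(inherits(genes, "gene_tree_set"), length(quad) == 4L)
  sq <- sort(quad)
  if (!all(sq %in% genes$species))
    stop("unknown species: ", paste(setdiff(sq, genes$species), collapse = ", "),
         call. = FALSE)
  out <- matrix(NA_real_, genes$k, 3L,
                dimnames = list(NULL, vapply(1:3, function(c)
                  pairing_string(sq, c), character(1))))
  for (k in seq_len(genes$k)) {
    tr <- genes$trees[[k]]
    spv <- unname(genes$species_of[[k]])
    inds <- lapply(sq, function(s) which(spv == s))
    if (any(lengths(inds) == 0L)) next
    sides <- tree_sides(tr, norm_sup = genes$flat[[k]]$sup)
    mass <- c(0, 0, 0)
    unit <- 1 / prod(lengths(inds))
    for (i1 in inds[[1]]) for (i2 in inds[[2]])
      for (i3 in inds[[3]]) for (i4 in inds[[4]]) {
        ev <- eval_quartet(sides, c(i1, i2, i3, i4))
        if (ev$code > 0L) mass[ev$code] <- mass[ev$code] + unit
      }
    out[k, ] <- mass
  }
  out
}

## ---- scoring ---------------------------------------------------------------

#' Quartet support score of a species tree
#'
#' Sums, over gene trees and species quadruples present and resolved in both
#' trees, the quartet weight of quadruples on which the gene tree agrees with
#' the species tree. The normalization denominator is the total weight of all
#' resolved, co-present quartets regardless of agreement, so
#' `normalized = value / denom` lies in `[0,1]` (reported `NaN` when no
#' quartet is resolved). With multiple individuals per species, each
#' quadruple's contribution is averaged over choices of one individual per
#' species.
#'
#' `method = "fast"` aggregates per-tripartition anchored counts (each
#' agreeing quartet is counted at the two species-tree nodes where its pairs
#' coalesce, and the total halved) without enumerating quartets; runtime is
#' polynomial in the number of species and linear in the number of trees.
#' `method = "brute"` enumerates all quadruples and is the independent oracle.
#'
#' @param species_tree a binary (fully resolved) `phylo`; its leaf set must be
#'   a subset of the gene-tree species universe. Species absent from the
#'   species tree are ignored.
#' @param genes a [gene_tree_set()].
#' @param scheme a [weight_scheme()] or mode string.
#' @param method `"fast"` or `"brute"`.
#' @param denom compute the normalization denominator (set `FALSE` to skip).
#' @return object of class `quartet_score`: fields `value`, `denom`,
#'   `normalized`, `method`, `ops` (kernel operation count, fast method only).
#' @export
quartet_score <- function(species_tree, genes, scheme = weight_scheme("unit"),
                          method = c("fast", "brute"), denom = TRUE) {
  method <- match.arg(method)
  scheme <- as_weight_scheme(scheme)
  stopifnot(inherits(genes, "gene_tree_set"))
  species_tree <- unroot_tree(species_tree)
  if (!all(species_tree$tip.label %in% genes$species))
    stop("species tree contains taxa not in the gene-tree species universe: ",
         paste(setdiff(species_tree$tip.label, genes$species), collapse = ", "),
         call. = FALSE)
  if (!is_binary_unrooted(species_tree))
    stop("species tree must be binary (fully resolved)", call. = FALSE)
  if (method == "fast") {
    trips <- species_tripartitions(species_tree, genes$species)
    present <- as.integer(genes$species %in% species_tree$tip.label)
    res <- qs_score(pp_for_scheme(genes, scheme), trips, scheme$code,
                    denom, present)
    out <- list(value = res$value, denom = if (denom) res$denom else NA_real_,
                ops = res$ops)
  } else {
    out <- brute_score(species_tree, genes, scheme)
    out$ops <- NA_real_
  }
  out$normalized <- if (isTRUE(out$denom > 0)) out$value / out$denom else NaN
  out$method <- method
  out$scheme <- scheme$mode
  class(out) <- "quartet_score"
  out
}

#' @export
print.quartet_score <- function(x, ...) {
  cat(sprintf("quartet score (%s, %s): value %.10g / denom %.10g = %.6f\n",
              x$method, x$scheme, x$value, x$denom, x$normalized))
  invisible(x)
}

brute_score <- function(species_tree, genes, scheme) {
  st <- species_tree
  st_sides <- tree_sides(st)
  st_species <- st$tip.label
  value <- 0; denomv <- 0
  for (k in seq_len(genes$k)) {
    tr <- genes$trees[[k]]
    spv <- unname(genes$species_of[[k]])
    shared <- intersect(st_species, unique(spv))
    if (length(shared) < 4L) next
    sides <- tree_sides(tr, norm_sup = genes$flat[[k]]$sup)
    shared <- sort(shared)
    quads <- utils::combn(shared, 4L)
    inds_of <- lapply(stats::setNames(nm = shared), function(s) which(spv == s))
    for (qi in seq_len(ncol(quads))) {
      sq <- quads[, qi]
      st_code <- eval_quartet(st_sides, match(sq, st$tip.label))$code
      inds <- inds_of[sq]
      unit <- 1 / prod(lengths(inds))
      for (i1 in inds[[1]]) for (i2 in inds[[2]])
        for (i3 in inds[[3]]) for (i4 in inds[[4]]) {
          ev <- eval_quartet(sides, c(i1, i2, i3, i4),
                             scheme$default_missing_support)
          if (ev$code == 0L) next
          w <- scheme_weight(ev, scheme) * unit
          denomv <- denomv + w
          if (ev$code == st_code) value <- value + w
        }
    }
  }
  list(value = value, denom = denomv)
}

#' Additive score contribution of a tripartition
#'
#' The anchored agreeing-quartet mass of an internal species-tree node whose
#' three subtrees contain the given species blocks: quartets with two species
#' split across two blocks and two (distinct) species together in the third,
#' displayed identically by a gene tree, counted at this anchor. Summing the
#' gains of all internal nodes of a binary species tree and halving the total
#' reproduces the fast quartet score; this additivity is what the constrained
#' dynamic program optimizes over.
#'
#' @param trip list of three disjoint, non-empty character vectors of species.
#' @param genes a [gene_tree_set()].
#' @param scheme a [weight_scheme()] or mode string.
#' @return a non-negative number, invariant under block permutation.
#' @export
tripartition_gain <- function(trip, genes, scheme = weight_scheme("unit")) {
  scheme <- as_weight_scheme(scheme)
  stopifnot(inherits(genes, "gene_tree_set"), length(trip) == 3L)
  if (any(lengths(trip) == 0L))
    stop("tripartition blocks must be non-empty", call. = FALSE)
  allb <- unlist(trip)
  if (anyDuplicated(allb))
    stop("tripartition blocks overlap", call. = FALSE)
  if (!all(allb %in% genes$species))
    stop("unknown species in tripartition", call. = FALSE)
  blocks <- rep(3L, length(genes$species))
  for (b in 1:3) blocks[match(trip[[b]], genes$species)] <- b - 1L
  qs_gain(pp_for_scheme(genes, scheme), blocks, scheme$code)
}
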