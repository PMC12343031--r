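## Species-tree search: greedy stepwise placement builds initial trees, NNI
## hill climbing refines them, and a dynamic program over the tripartitions
## drawn from their bipartition union (plus a one-round closure) returns the
## constrained optimum.

#' Search configuration
#'
#' @param n_init number of initial trees from independent random placement
#'   orders (default 4).
#' @param seed integer seed; all search randomness flows from it.
#' @param nni_max_rounds maximum best-improvement NNI sweeps per initial tree.
#' @param scheme a [weight_scheme()] or mode string.
#' @return object of class `search_config`.
#' @export
search_config <- function(n_init = 4, seed = 1, nni_max_rounds = 50,
                          scheme = weight_scheme("unit")) {
  stopifnot(n_init >= 1, nni_max_rounds >= 0)
  structure(list(n_init = as.integer(n_init), seed = as.integer(seed),
                 nni_max_rounds = as.integer(nni_max_rounds),
                 scheme = as_weight_scheme(scheme)),
            class = "search_config")
}

## raw score value (numerator only) of a possibly partial species tree
qs_value <- function(tree, genes, scheme, pp = NULL) {
  if (is.null(pp)) pp <- pp_for_scheme(genes, scheme)
  trips <- species_tripartitions(tree, genes$species)
  qs_score(pp, trips, scheme$code, FALSE, integer(length(genes$species)))$value
}

rel_tol <- function(x) 1e-9 * max(1, abs(x))

## canonical key of an edge: sorted child-side labels
edge_keys <- function(tree) {
  sets <- node_tipsets(tree)
  vapply(seq_len(nrow(tree$edge)), function(r)
    paste(sort(sets[[tree$edge[r, 2L]]]), collapse = ","), character(1))
}

#' Greedy placement of one species
#'
#' Attaches `species` to the edge of the growing binary tree that maximizes
#' the quartet score restricted to the placed taxa; ties go to the edge with
#' the lexicographically smallest canonical (child-side) key.
#'
#' @param partial binary unrooted `phylo` on a subset of the species.
#' @param species the species label to place.
#' @param genes a [gene_tree_set()].
#' @param scheme a [weight_scheme()] or mode string.
#' @return a `phylo` with the new leaf attached.
#' @export
place_taxon <- function(partial, species, genes, scheme = weight_scheme("unit")) {
  scheme <- as_weight_scheme(scheme)
  stopifnot(!(species %in% partial$tip.label))
  pp <- pp_for_scheme(genes, scheme)
  vals <- numeric(nrow(partial$edge))
  cands <- vector("list", nrow(partial$edge))
  for (r in seq_len(nrow(partial$edge))) {
    cands[[r]] <- attach_leaf(partial, r, species)
    vals[r] <- qs_value(cands[[r]], genes, scheme, pp)
  }
  best <- max(vals)
  ties <- which(vals >= best - rel_tol(best))
  if (length(ties) > 1L) {
    keys <- edge_keys(partial)[ties]
    ties <- ties[order(keys)][1L]
  }
  cands[[ties[1L]]]
}

#' Build initial trees by random-order stepwise placement
#'
#' Each initial tree starts from a star on the first three species of an
#' independent uniform random placement order and adds the remaining species
#' greedily with [place_taxon()]. Deterministic given the seed.
#'
#' @param genes a [gene_tree_set()].
#' @param config a [search_config()].
#' @return list of binary unrooted `phylo` trees (length `config$n_init`).
#' @export
build_initial_trees <- function(genes, config = search_config()) {
  stopifnot(inherits(genes, "gene_tree_set"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_init), function(r) {
      ord <- sample(genes$species)
      tr <- star_tree(ord[1:3])
      for (s in ord[-(1:3)])
        tr <- place_taxon(tr, s, genes, config$scheme)
      tr
    })
  })
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hill-climb a tree by nearest-neighbor interchanges
#'
#' Repeated best-improvement sweeps over all NNI neighbors, accepting only
#' strict score improvements, until a local optimum or `max_rounds` sweeps.
#' The returned tree carries its score in `attr(, "score")`, which is always
#' `>=` the input tree's score.
#'
#' @param tree binary unrooted `phylo` on the full species set.
#' @param genes a [gene_tree_set()].
#' @param scheme a [weight_scheme()] or mode string.
#' @param max_rounds maximum sweeps (default 50).
#' @return a `phylo` with attribute `score`.
#' @export
nni_improve <- function(tree, genes, scheme = weight_scheme("unit"),
                        max_rounds = 50) {
  scheme <- as_weight_scheme(scheme)
  pp <- pp_for_scheme(genes, scheme)
  cur <- unroot_tree(tree)
  cur_val <- qs_value(cur, genes, scheme, pp)
  for (round in seq_len(max_rounds)) {
    nb <- nni_neighbors(cur)
    vals <- vapply(nb, qs_value, numeric(1), genes, scheme, pp)
    best <- max(vals)
    if (best <= cur_val + rel_tol(cur_val)) break
    ties <- which(vals >= best - rel_tol(best))
    if (length(ties) > 1L)
      ties <- ties[order(vapply(nb[ties], canonical_key, character(1)))][1L]
    cur <- nb[[ties[1L]]]
    cur_val <- best
  }
  attr(cur, "score") <- cur_val
  cur
}

## ---- constraint set and dynamic program ------------------------------------

popcount <- function(x) {
  n <- 0L
  while (any(x > 0L)) { n <- n + (x %% 2L); x <- x %/% 2L }
  n
}

#' Build the DP constraint set from initial trees
#'
#' The union of all (non-trivial) bipartitions of the input trees, encoded as
#' clusters (the side not containing the reference taxon, the
#' lexicographically smallest species), plus all trivial clusters, plus a
#' one-round closure adding pairwise intersections and differences of the
#' union when non-empty. Every binary tree the DP assembles draws its
#' bipartitions from this set.
#'
#' @param trees list of binary `phylo` trees on the same full species set.
#' @return object of class `constraint_set` with fields `species`, `ref`,
#'   `clusters` (sorted integer bitmasks over `species[-1]`).
#' @export
build_constraint_set <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  species <- sort(trees[[1L]]$tip.label)
  if (length(species) > 31L)
    stop("constrained search supports at most 31 species", call. = FALSE)
  for (tr in trees)
    if (!setequal(tr$tip.label, species))
      stop("all input trees must share the same species set", call. = FALSE)
  nonref <- species[-1L]
  mask_of <- function(labs) {
    bits <- match(labs, nonref)
    sum(bitwShiftL(1L, bits - 1L))
  }
  full <- bitwShiftL(1L, length(nonref)) - 1L
  base <- integer(0)
  for (tr in trees) {
    for (b in tree_bipartitions(tr)) {
      blk <- if (species[1L] %in% b$A) b$B else b$A
      base <- c(base, mask_of(blk))
    }
  }
  base <- unique(base)
  ## one-round closure: pairwise intersections and differences
  extra <- integer(0)
  if (length(base) > 1L) {
    for (i in seq_along(base)) for (j in seq_along(base)) {
      if (i >= j) next
      a <- base[i]; b <- base[j]
      extra <- c(extra, bitwAnd(a, b), bitwAnd(a, bitwNot(b)),
                 bitwAnd(b, bitwNot(a)))
    }
  }
  cl <- unique(c(base, extra, bitwShiftL(1L, seq_along(nonref) - 1L), full))
  cl <- sort(cl[cl > 0L & cl <= full])
  structure(list(species = species, ref = species[1L], clusters = cl),
            class = "constraint_set")
}

#' Exhaustive constraint set (all bipartitions)
#'
#' All `2^(n-1) - 1` clusters, making [dp_optimal_tree()] an exact global
#' optimizer. Usable only at small n.
#'
#' @param species character vector of species labels.
#' @return a `constraint_set`.
#' @export
full_constraint_set <- function(species) {
  species <- sort(species)
  n1 <- length(species) - 1L
  if (n1 > 20L) stop("full constraint set is limited to 21 species", call. = FALSE)
  structure(list(species = species, ref = species[1L],
                 clusters = seq_len(bitwShiftL(1L, n1) - 1L)),
            class = "constraint_set")
}

#' Optimal species tree within a constraint set
#'
#' Dynamic program over clusters: `best(A)` is the maximum over splits of `A`
#' into two constituent clusters of the sum of their bests plus the gain of
#' the tripartition (A1, A2, complement). Returns the binary tree, all of
#' whose bipartitions lie in the constraint set, maximizing the quartet
#' score; provably optimal within the set.
#'
#' @param X a [build_constraint_set()] / [full_constraint_set()] result.
#' @param genes a [gene_tree_set()].
#' @param scheme a [weight_scheme()] or mode string.
#' @return a binary unrooted `phylo` with attribute `score` (the quartet
#'   score value of the returned tree).
#' @export
dp_optimal_tree <- function(X, genes, scheme = weight_scheme("unit")) {
  scheme <- as_weight_scheme(scheme)
  stopifnot(inherits(X, "constraint_set"), inherits(genes, "gene_tree_set"))
  if (!all(X$species %in% genes$species))
    stop("constraint set species must be in the gene-tree universe", call. = FALSE)
  pp <- pp_for_scheme(genes, scheme)
  nonref <- X$species[-1L]
  full <- bitwShiftL(1L, length(nonref)) - 1L
  cl <- sort(unique(c(X$clusters, full)))
  sizes <- vapply(cl, popcount, integer(1))
  ord <- order(sizes, cl)
  cl <- cl[ord]; sizes <- sizes[ord]
  best <- rep(-Inf, length(cl))
  bp <- vector("list", length(cl))
  names(best) <- as.character(cl)
  idx <- stats::setNames(seq_along(cl), as.character(cl))
  best[sizes == 1L] <- 0

  sp_idx <- match(X$species, genes$species)
  blocks_of <- function(m1, m2) {
    blocks <- rep(3L, length(genes$species))
    blocks[sp_idx] <- 2L                      # complement (includes ref)
    b1 <- which(bitwAnd(m1, bitwShiftL(1L, seq_along(nonref) - 1L)) > 0L)
    b2 <- which(bitwAnd(m2, bitwShiftL(1L, seq_along(nonref) - 1L)) > 0L)
    blocks[match(nonref[b1], genes$species)] <- 0L
    blocks[match(nonref[b2], genes$species)] <- 1L
    blocks
  }

  for (i in which(sizes >= 2L)) {
    A <- cl[i]
    for (j in which(sizes < sizes[i])) {
      c1 <- cl[j]
      if (bitwAnd(c1, A) != c1) next
      c2 <- bitwAnd(A, bitwNot(c1))
      if (c2 < c1) next                       # each unordered split once
      i2 <- idx[as.character(c2)]
      if (is.na(i2)) next
      if (!is.finite(best[j]) || !is.finite(best[i2])) next
      g <- qs_gain(pp, blocks_of(c1, c2), scheme$code)
      cand <- best[j] + best[i2] + g
      if (cand > best[i]) {
        best[i] <- cand
        bp[[i]] <- c(c1, c2)
      }
    }
  }
  fi <- idx[as.character(full)]
  if (!is.finite(best[fi]))
    stop("constraint set admits no binary tree; add more initial trees",
         call. = FALSE)
  rec <- function(mask) {
    i <- idx[as.character(mask)]
    if (sizes[i] == 1L) {
      lab <- nonref[which(bitwAnd(mask, bitwShiftL(1L, seq_along(nonref) - 1L)) > 0L)]
      return(list(children = list(), label = lab, length = NA_real_))
    }
    ch <- bp[[i]]
    list(children = list(rec(ch[1L]), rec(ch[2L])), label = "", length = NA_real_)
  }
  top <- bp[[fi]]
  root <- list(children = list(rec(top[1L]), rec(top[2L]),
                               list(children = list(), label = X$ref,
                                    length = NA_real_)),
               label = "", length = NA_real_)
  out <- nested_to_phylo(root)
  attr(out, "score") <- unname(best[fi]) / 2
  out
}

#' Infer a species tree from gene trees
#'
#' The full pipeline: random-order stepwise placement builds `n_init` initial
#' trees, each is improved by NNI hill climbing, their bipartitions (plus a
#' one-round closure) form the constraint set, and the dynamic program
#' returns the constrained optimum, which is at least as good as every
#' initial tree. Deterministic given `config$seed`. The result is annotated
#' with quartet support, coalescent-unit lengths and local posterior
#' probabilities unless `annotate = FALSE`.
#'
#' @param genes a [gene_tree_set()] (at least 4 species).
#' @param config a [search_config()].
#' @param annotate annotate the final tree (default TRUE).
#' @param verbose log per-stage scores with `message()`.
#' @return a binary unrooted `phylo` with attributes `score` (quartet score
#'   value), `normalized` (normalized score) and `stage_scores`.
#' @export
infer_species_tree <- function(genes, config = search_config(),
                               annotate = TRUE, verbose = FALSE) {
  stopifnot(inherits(genes, "gene_tree_set"))
  if (length(genes$species) < 4L)
    stop("need at least 4 species to infer a tree", call. = FALSE)
  scheme <- config$scheme
  init <- build_initial_trees(genes, config)
  init_scores <- vapply(init, qs_value, numeric(1), genes, scheme)
  if (verbose) message("initial tree scores: ",
                       paste(format(init_scores), collapse = ", "))
  impr <- lapply(init, nni_improve, genes = genes, scheme = scheme,
                 max_rounds = config$nni_max_rounds)
  nni_scores <- vapply(impr, function(t) attr(t, "score"), numeric(1))
  if (verbose) message("after NNI: ", paste(format(nni_scores), collapse = ", "))
  X <- build_constraint_set(impr)
  out <- dp_optimal_tree(X, genes, scheme)
  if (verbose) message("DP score: ", format(attr(out, "score")))
  sc <- quartet_score(out, genes, scheme)
  attr(out, "normalized") <- sc$normalized
  attr(out, "stage_scores") <- list(initial = init_scores, nni = nni_scores,
                                    dp = attr(out, "score"))
  if (annotate) {
    keep <- attributes(out)[c("score", "normalized", "stage_scores")]
    out <- annotate_tree(out, genes, scheme)
    for (nm in names(keep)) attr(out, nm) <- keep[[nm]]
  }
  out
}
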