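## GeneTreeSet: parsed gene trees + species index + preprocessed counting
## structures for the C++ kernel.

#' Build a gene-tree set for scoring
#'
#' Collects gene trees, applies an optional individual-to-species map, indexes
#' the species universe, normalizes branch supports to `[0,1]` (auto-detecting
#' percent-scale supports across the whole set), and precomputes the
#' per-tree structures used by the fast quartet-counting kernel. Trees are
#' treated as unrooted; a species may be absent from any tree (quartets
#' touching it are simply skipped for that tree).
#'
#' @param trees a list of `phylo` objects, a single `phylo`, or a character
#'   vector of Newick strings.
#' @param taxon_map optional [taxon_map()]; when supplied, every gene-tree
#'   leaf must appear in it. Without a map each leaf is its own species.
#' @param support_scale `"auto"` (divide by 100 if any support exceeds 1),
#'   `"prob"` or `"percent"`.
#' @param default_missing_support support substituted for branches lacking a
#'   numeric support label (see [weight_scheme()]).
#' @return an object of class `gene_tree_set`.
#' @export
gene_tree_set <- function(trees, taxon_map = NULL,
                          support_scale = c("auto", "prob", "percent"),
                          default_missing_support = 1) {
  support_scale <- match.arg(support_scale)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.character(trees)) trees <- lapply(trees, parse_newick)
  if (!is.list(trees) || length(trees) < 1L)
    stop("need at least one gene tree", call. = FALSE)
  trees <- lapply(trees, unroot_tree)

  ## leaf -> species
  species_of <- lapply(trees, function(tr) {
    labs <- tr$tip.label
    if (is.null(taxon_map)) return(stats::setNames(labs, labs))
    miss <- setdiff(labs, names(taxon_map))
    if (length(miss))
      stop("taxon map is missing gene-tree leaves: ",
           paste(miss, collapse = ", "), call. = FALSE)
    stats::setNames(unname(taxon_map[labs]), labs)
  })
  species <- sort(unique(unlist(species_of, use.names = FALSE)))
  if (length(species) < 4L)
    stop("need at least 4 distinct species across the gene trees", call. = FALSE)

  ## support scale detection across the whole input
  raw_sup <- lapply(trees, function(tr) numeric_labels(tr$node.label))
  pct <- switch(support_scale, percent = TRUE, prob = FALSE,
                auto = any(unlist(raw_sup) > 1, na.rm = TRUE))
  norm_sup <- lapply(raw_sup, function(s) if (pct) s / 100 else s)
  allsup <- unlist(norm_sup)
  allsup <- allsup[!is.na(allsup)]
  rng <- if (length(allsup)) range(allsup) else c(NA_real_, NA_real_)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("branch supports outside [0,1] after scale normalization (",
         "range ", rng[1], "..", rng[2], ")", call. = FALSE)

  flat <- vector("list", length(trees))
  presence <- matrix(FALSE, length(trees), length(species),
                     dimnames = list(NULL, species))
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    n <- n_tips(tr)
    sp_idx <- match(unname(species_of[[k]]), species)
    presence[k, unique(sp_idx)] <- TRUE
    if (is.null(tr$edge) || nrow(tr$edge) == 0L) {   # 1-leaf tree
      flat[[k]] <- list(edge = matrix(integer(0), 0L, 2L), ntip = n, nnode = 0L,
                        leafSpecies = sp_idx, sup = numeric(0), len = numeric(0))
      next
    }
    sup <- rep(NA_real_, nrow(tr$edge))
    int_child <- tr$edge[, 2L] > n
    sup[int_child] <- norm_sup[[k]][tr$edge[int_child, 2L] - n]
    len <- if (is.null(tr$edge.length)) rep(NA_real_, nrow(tr$edge)) else tr$edge.length
    flat[[k]] <- list(edge = tr$edge, ntip = n, nnode = tr$Nnode,
                      leafSpecies = sp_idx, sup = sup, len = len)
  }

  obj <- structure(list(trees = trees, species = species, k = length(trees),
                        presence = presence, flat = flat,
                        species_of = species_of,
                        percent_scale = pct,
                        default_missing_support = default_missing_support),
                   class = "gene_tree_set")
  obj$pp <- preprocess_set(obj, default_missing_support)
  obj
}

preprocess_set <- function(genes, default_sup) {
  lapply(genes$flat, function(f) {
    sup <- f$sup; sup[is.na(sup)] <- default_sup
    len <- f$len; len[is.na(len)] <- 0
    qs_preprocess(f$edge, f$ntip, f$nnode, f$leafSpecies, sup, len,
                  length(genes$species))
  })
}

## preprocessed structures matching a scheme's missing-support default
pp_for_scheme <- function(genes, scheme) {
  if (isTRUE(all.equal(scheme$default_missing_support,
                       genes$default_missing_support)))
    genes$pp
  else
    preprocess_set(genes, scheme$default_missing_support)
}

#' Read a gene-tree file into a gene-tree set
#'
#' @param path Newick file, one gene tree per line.
#' @param taxon_map optional map file path or [taxon_map()] object.
#' @param ... passed to [gene_tree_set()].
#' @return a `gene_tree_set`.
#' @export
read_gene_trees <- function(path, taxon_map = NULL, ...) {
  if (is.character(taxon_map)) taxon_map <- read_taxon_map(taxon_map)
  gene_tree_set(read_newick(path), taxon_map = taxon_map, ...)
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat(sprintf("gene_tree_set: %d trees, %d species%s\n", x$k,
              length(x$species),
              if (x$percent_scale) " (percent-scale supports)" else ""))
  miss <- 1 - mean(x$presence)
  if (miss > 0) cat(sprintf("  missing species fraction: %.3f\n", miss))
  invisible(x)
}
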