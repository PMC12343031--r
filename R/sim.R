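## Multispecies-coalescent gene tree simulation, with an optional error model
## (random NNI, synthetic supports, missing species) for fixture realism.

#' Gene-tree error model
#'
#' @param nni_prob probability that a simulated gene tree is perturbed by one
#'   uniform random NNI.
#' @param p_miss probability that each species is dropped from each gene tree
#'   (independently), never reducing a tree below 4 leaves.
#' @param supports attach synthetic branch supports (default TRUE when any
#'   perturbation is active): branches agreeing with the pre-error tree draw
#'   from `Beta(beta_correct)`, disagreeing branches from `Beta(beta_wrong)`.
#' @param beta_correct,beta_wrong shape parameters of the two Beta support
#'   distributions; the defaults (20,1) and (2,2) emulate approximate-Bayes
#'   supports (median about 0.97 for correct branches).
#' @return object of class `error_model`.
#' @export
error_model <- function(nni_prob = 0, p_miss = 0, supports = TRUE,
                        beta_correct = c(20, 1), beta_wrong = c(2, 2)) {
  stopifnot(nni_prob >= 0, nni_prob <= 1, p_miss >= 0, p_miss <= 1)
  structure(list(nni_prob = nni_prob, p_miss = p_miss, supports = supports,
                 beta_correct = beta_correct, beta_wrong = beta_wrong),
            class = "error_model")
}

## node heights (time above the deepest tip level, increasing rootward)
species_heights <- function(tree, term_default = 1) {
  n <- n_tips(tree)
  len <- tree$edge.length
  if (is.null(len)) stop("species tree needs branch lengths in coalescent units",
                         call. = FALSE)
  tip_edge <- tree$edge[, 2L] <= n
  len[tip_edge & is.na(len)] <- term_default
  if (anyNA(len))
    stop("species tree has internal branches without lengths", call. = FALSE)
  if (any(len < 0)) stop("negative branch lengths", call. = FALSE)
  ## height(parent) = max(height(child) + len); edge-order independent
  h <- numeric(n + tree$Nnode)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  rec <- function(node) {
    for (r in kids[[as.character(node)]]) {
      c <- tree$edge[r, 2L]
      if (c > n) rec(c)
      h[node] <<- max(h[node], h[c] + len[r])
    }
  }
  rec(n + 1L)
  list(h = h, len = len)
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Standard coalescent-within-species-tree: within each branch (lengths in
#' coalescent units, time/2Ne generations), from the tips rootward, pairs of
#' active lineages merge after exponential waiting times at rate j(j-1)/2 for
#' j lineages, truncated at the branch length; all remaining lineages
#' coalesce above the root. One lineage enters per species unless
#' `individuals > 1`, in which case gene-tree leaves are labelled
#' `species_i`. Uses R's RNG (seed with `set.seed()`).
#'
#' @param species_tree rooted binary `phylo` with coalescent-unit branch
#'   lengths (missing terminal lengths default to 1).
#' @param individuals lineages sampled per species.
#' @return a rooted binary `phylo` gene tree with coalescent-unit lengths.
#' @export
simulate_gene_tree <- function(species_tree, individuals = 1) {
  tr <- species_tree
  if (!is_rooted_tree(tr))
    stop("simulation needs a rooted species tree", call. = FALSE)
  n <- n_tips(tr)
  hh <- species_heights(tr)
  h <- hh$h; len <- hh$len
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])

  coalesce_in <- function(lineages, t0, cap) {
    j <- length(lineages)
    t <- t0
    while (j >= 2L) {
      t <- t + stats::rexp(1L, rate = j * (j - 1) / 2)
      if (t > cap) break
      pick <- sample.int(j, 2L)
      a <- lineages[[pick[1L]]]; b <- lineages[[pick[2L]]]
      ca <- a$node; ca$length <- t - a$time
      cb <- b$node; cb$length <- t - b$time
      node <- list(children = list(ca, cb), label = "", length = NA_real_)
      lineages[pick] <- NULL
      lineages[[length(lineages) + 1L]] <- list(node = node, time = t)
      j <- j - 1L
    }
    lineages
  }

  tip_lineages <- function(node) {
    labs <- if (individuals == 1L) tr$tip.label[node] else
      paste(tr$tip.label[node], seq_len(individuals), sep = "_")
    lapply(labs, function(l)
      list(node = list(children = list(), label = l, length = NA_real_),
           time = h[node]))
  }

  process <- function(node) {  # lineages surviving to the top of node's branch
    if (node <= n) {
      lin <- tip_lineages(node)
    } else {
      lin <- list()
      for (r in kids[[as.character(node)]])
        lin <- c(lin, process(tr$edge[r, 2L]))
    }
    row <- which(tr$edge[, 2L] == node)
    if (length(row) == 0L)            # root: coalesce everything
      return(coalesce_in(lin, h[node], Inf))
    coalesce_in(lin, h[node], h[node] + len[row])
  }

  lin <- process(n + 1L)
  stopifnot(length(lin) == 1L)
  g <- lin[[1L]]$node
  nested_to_phylo(g)
}

## prune a tree to a subset of leaves (lengths summed across removed nodes)
prune_taxa <- function(tree, keep) {
  nd <- phylo_to_nested(tree)
  rec <- function(node) {
    if (length(node$children) == 0L)
      return(if (node$label %in% keep) node else NULL)
    ch <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(ch) == 0L) return(NULL)
    node$children <- ch
    node
  }
  out <- rec(nd)
  if (is.null(out)) stop("pruning removed all leaves", call. = FALSE)
  out <- collapse_unary(out)
  out$length <- NA_real_
  nested_to_phylo(out)
}

#' Apply a gene-tree error model
#'
#' Optionally perturbs the topology by one uniform random NNI, drops species
#' under the missing-data model (never below 4 leaves), and attaches
#' synthetic supports: internal branches whose bipartition is present in the
#' (pruned) pre-error tree draw from the high-support distribution, others
#' from the low-support distribution.
#'
#' @param tree a binary gene tree (`phylo`).
#' @param err an [error_model()].
#' @return a `phylo`, unrooted, possibly pruned, with support node labels.
#' @export
apply_error <- function(tree, err) {
  stopifnot(inherits(err, "error_model"))
  truth <- unroot_tree(tree)
  out <- truth
  if (n_tips(out) >= 4L && err$nni_prob > 0 && stats::runif(1L) < err$nni_prob) {
    nb <- nni_neighbors(out)
    out <- nb[[sample.int(length(nb), 1L)]]
  }
  if (err$p_miss > 0) {
    drop <- which(stats::runif(n_tips(out)) < err$p_miss)
    max_drop <- n_tips(out) - 4L
    if (length(drop) > max_drop)
      drop <- drop[sample.int(length(drop))][seq_len(max(0L, max_drop))]
    if (length(drop) > 0L) {
      keep <- setdiff(out$tip.label, out$tip.label[drop])
      out <- prune_taxa(out, keep)
      truth <- prune_taxa(truth, keep)
    }
  }
  if (isTRUE(err$supports)) {
    true_keys <- bipartition_keys(truth)
    out <- unroot_tree(out)
    n <- n_tips(out)
    sets <- node_tipsets(out)
    labs <- rep("", out$Nnode)
    for (r in seq_len(nrow(out$edge))) {
      v <- out$edge[r, 2L]
      if (v <= n) next
      blk <- sets[[v]]; oth <- setdiff(out$tip.label, blk)
      if (length(blk) < 2L || length(oth) < 2L) next
      key <- bip_key(blk, oth, sort(out$tip.label)[1L])
      par <- if (key %in% true_keys) err$beta_correct else err$beta_wrong
      labs[v - n] <- sprintf("%.4f", stats::rbeta(1L, par[1L], par[2L]))
    }
    out$node.label <- labs
  }
  out
}

#' Simulate a gene-tree dataset
#'
#' `k` independent coalescent gene trees from the species-tree model, passed
#' through the error model, returned as a scoring-ready [gene_tree_set()]
#' (with the individual-to-species map applied when `individuals > 1`).
#'
#' @param species_tree rooted binary `phylo`, coalescent-unit lengths.
#' @param k number of gene trees (>= 1).
#' @param err optional [error_model()].
#' @param individuals lineages per species.
#' @param file optional path: also write the trees, one Newick per line.
#' @return a `gene_tree_set`; the generating species tree is attached as
#'   `attr(, "true_tree")`.
#' @export
simulate_dataset <- function(species_tree, k, err = NULL, individuals = 1,
                             file = NULL) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  k <- as.integer(k)
  trees <- vector("list", k)
  for (i in seq_len(k)) {
    g <- simulate_gene_tree(species_tree, individuals)
    if (!is.null(err)) g <- apply_error(g, err)
    trees[[i]] <- g
  }
  if (!is.null(file)) write_newick_file(trees, file)
  map <- NULL
  if (individuals > 1L) {
    sp <- species_tree$tip.label
    ind <- as.vector(vapply(sp, function(s)
      paste(s, seq_len(individuals), sep = "_"), character(individuals)))
    map <- taxon_map(ind, rep(sp, each = individuals))
  }
  out <- gene_tree_set(trees, taxon_map = map)
  attr(out, "true_tree") <- species_tree
  out
}
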