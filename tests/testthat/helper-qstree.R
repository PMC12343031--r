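# shared fixture builders (everything generated in code; no data files)

# random binary unrooted tree by stepwise attachment at random edges
rand_bin_tree <- function(labels) {
  t <- star_tree(labels[1:3])
  for (s in labels[-(1:3)])
    t <- attach_leaf(t, sample(nrow(t$edge), 1L), s)
  t
}

# rooted caterpillar Newick with given internal/terminal lengths (CU)
caterpillar_newick <- function(labels, internal = 0.5, terminal = 1) {
  core <- sprintf("(%s:%g,%s:%g)", labels[1], terminal, labels[2], terminal)
  for (s in labels[-(1:2)])
    core <- sprintf("(%s:%g,%s:%g)", core, internal, s, terminal)
  paste0(core, ";")
}

# all unrooted binary trees on a label set (3,15,105,945,... trees)
all_unrooted_trees <- function(labels) {
  stopifnot(length(labels) >= 3L)
  trees <- list(star_tree(labels[1:3]))
  for (s in labels[-(1:3)]) {
    nxt <- list()
    for (t in trees)
      for (r in seq_len(nrow(t$edge)))
        nxt[[length(nxt) + 1L]] <- attach_leaf(t, r, s)
    trees <- nxt
  }
  trees
}

# random gene-tree set: subsets of species, optional polytomies / supports /
# lengths, for oracle-equivalence stress tests
random_gene_set <- function(n, k, p_poly = 0.4, p_missing = 0.4) {
  sp <- paste0("s", seq_len(n))
  gts <- lapply(seq_len(k), function(i) {
    m <- if (stats::runif(1) < p_missing && n > 4L) sample(4:n, 1L) else n
    present <- sp[sort(sample(n, m))]
    t <- rand_bin_tree(sample(present))
    t$node.label <- c("", sprintf("%.2f", stats::runif(t$Nnode - 1L)))
    if (stats::runif(1) < p_poly)
      t <- contract_low_support(t, stats::runif(1, 0, 0.5))
    t$edge.length <- stats::runif(nrow(t$edge), 0, 2)
    t
  })
  gene_tree_set(gts)
}

expect_same_topology <- function(a, b) {
  expect_true(same_topology(a, b),
              info = paste("trees differ:", write_newick(a), "vs", write_newick(b)))
}

# evaluate expr, collecting message() texts
capture_condition_messages <- function(expr) {
  msgs <- character(0)
  withCallingHandlers(expr, message = function(m) {
    msgs <<- c(msgs, conditionMessage(m))
    invokeRestart("muffleMessage")
  })
  msgs
}

# canonical pairing string for pair {a,b} vs {c,d}
pairs_key <- function(a, b, c, d) {
  sq <- sort(c(a, b, c, d))
  partner <- if (sq[1] %in% c(a, b)) setdiff(c(a, b), sq[1]) else
    setdiff(c(c, d), sq[1])
  qstree:::pairing_string(sq, match(partner, sq) - 1L)
}

# reverse every child list: same unrooted topology, different representation
rotate_tree <- function(tree) {
  nd <- qstree:::phylo_to_nested(tree)
  rec <- function(node) {
    if (length(node$children)) node$children <- rev(lapply(node$children, rec))
    node
  }
  qstree:::nested_to_phylo(rec(nd))
}
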