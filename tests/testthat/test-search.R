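test_that("place_taxon recovers the scoring edge and breaks ties canonically", {
  g <- gene_tree_set(c("((a,b),(c,d));"))
  placed <- place_taxon(star_tree(c("a", "b", "c")), "d", g)
  expect_same_topology(placed, parse_newick("((a,b),(c,d));"))
  # no informative quartets: every edge ties; lowest canonical edge key wins
  gstar <- gene_tree_set(c("(a,b,c,d);"))
  p1 <- place_taxon(star_tree(c("b", "c", "a")), "d", gstar)
  p2 <- place_taxon(star_tree(c("c", "a", "b")), "d", gstar)
  expect_same_topology(p1, p2)
})

test_that("stepwise placement recovers the common gene tree from any order", {
  set.seed(501)
  sp <- paste0("s", 1:6)
  truth <- rand_bin_tree(sample(sp))
  g <- gene_tree_set(rep(list(truth), 5))
  for (i in 1:4) {
    ord <- sample(sp)
    t <- star_tree(ord[1:3])
    for (s in ord[-(1:3)]) t <- place_taxon(t, s, g)
    expect_same_topology(t, truth)
  }
})

test_that("build_initial_trees is deterministic under the seed", {
  set.seed(502)
  g <- random_gene_set(n = 6, k = 4, p_poly = 0, p_missing = 0)
  cfg <- search_config(n_init = 4, seed = 99)
  a <- build_initial_trees(g, cfg)
  b <- build_initial_trees(g, cfg)
  expect_length(a, 4L)
  for (i in 1:4) expect_identical(write_newick(a[[i]]), write_newick(b[[i]]))
  # congruent complete gene trees, one round: the true tree
  truth <- rand_bin_tree(sample(g$species))
  gc <- gene_tree_set(rep(list(truth), 3))
  one <- build_initial_trees(gc, search_config(n_init = 1, seed = 7))
  expect_same_topology(one[[1]], truth)
})

test_that("nni_improve climbs monotonically and fixes a single perturbation", {
  set.seed(503)
  sp <- paste0("s", 1:7)
  truth <- rand_bin_tree(sample(sp))
  g <- gene_tree_set(rep(list(truth), 200))
  # already optimal: unchanged
  out <- nni_improve(truth, g)
  expect_same_topology(out, truth)
  # one random NNI away, strong signal: truth recovered
  for (i in 1:5) {
    nb <- nni_neighbors(truth)
    start <- nb[[sample(length(nb), 1)]]
    rec <- nni_improve(start, g)
    expect_same_topology(rec, truth)
    expect_gte(attr(rec, "score"), qstree:::qs_value(start, g, weight_scheme("unit")))
  }
  # score never decreases on arbitrary data
  gr <- random_gene_set(n = 7, k = 6)
  t0 <- rand_bin_tree(sample(gr$species))
  before <- qstree:::qs_value(t0, gr, weight_scheme("unit"))
  expect_gte(attr(nni_improve(t0, gr), "score"), before)
})

test_that("nni_neighbors enumerates 2(n-3) distinct well-formed trees", {
  set.seed(504)
  for (n in c(4, 6, 9)) {
    t <- rand_bin_tree(sample(paste0("x", 1:n)))
    nb <- nni_neighbors(t)
    expect_length(nb, 2 * (n - 3))
    keys <- vapply(nb, qstree:::canonical_key, character(1))
    expect_false(qstree:::canonical_key(t) %in% keys)
    expect_equal(anyDuplicated(keys), 0L)
    for (x in nb) expect_true(is_binary_unrooted(x))
  }
})

test_that("build_constraint_set unions bipartitions with closure", {
  set.seed(505)
  sp <- sort(paste0("s", 1:7))
  t1 <- rand_bin_tree(sample(sp))
  X1 <- build_constraint_set(list(t1))
  # n-3 non-trivial + n-1 singletons + full cluster
  expect_length(X1$clusters, (7 - 3) + (7 - 1) + 1)
  expect_identical(build_constraint_set(list(t1, t1))$clusters, X1$clusters)
  nb <- nni_neighbors(t1)[[1]]
  X2 <- build_constraint_set(list(t1, nb))
  expect_gt(length(X2$clusters), length(X1$clusters))
  expect_true(all(X1$clusters %in% X2$clusters))
})

test_that("dp_optimal_tree returns the constrained optimum", {
  set.seed(506)
  g <- random_gene_set(n = 6, k = 5, p_poly = 0.3)
  sp <- g$species
  # X from a single tree: that tree comes back
  t1 <- rand_bin_tree(sample(sp))
  back <- dp_optimal_tree(build_constraint_set(list(t1)), g)
  expect_same_topology(back, t1)
  expect_equal(attr(back, "score"), quartet_score(t1, g)$value)
  # DP score >= every initial tree feeding X
  trees <- lapply(1:3, function(i) rand_bin_tree(sample(sp)))
  dp <- dp_optimal_tree(build_constraint_set(trees), g)
  for (t in trees)
    expect_gte(attr(dp, "score") + 1e-9, quartet_score(t, g)$value)
  # full constraint set at n=5: equals exhaustive enumeration over 15 trees
  g5 <- random_gene_set(n = 5, k = 6, p_poly = 0.3)
  allt <- all_unrooted_trees(sort(g5$species))
  expect_length(allt, 15L)
  scores <- vapply(allt, function(t) quartet_score(t, g5)$value, numeric(1))
  dp5 <- dp_optimal_tree(full_constraint_set(g5$species), g5)
  expect_equal(attr(dp5, "score"), max(scores), tolerance = 1e-12)
})

test_that("infer recovers congruent topologies and is order-invariant", {
  set.seed(507)
  sp <- paste0("s", 1:7)
  truth <- rand_bin_tree(sample(sp))
  g <- gene_tree_set(rep(list(truth), 10))
  out <- infer_species_tree(g, search_config(seed = 5), annotate = FALSE)
  expect_same_topology(out, truth)
  expect_equal(attr(out, "normalized"), 1)
  # stage scores are monotone non-decreasing
  st <- attr(out, "stage_scores")
  expect_gte(min(st$nni - st$initial), 0)
  expect_gte(st$dp + 1e-9, max(st$nni))
  # gene-tree order and leaf rotation do not change the result
  gr <- random_gene_set(n = 6, k = 8)
  r1 <- infer_species_tree(gr, search_config(seed = 2), annotate = FALSE)
  g_perm <- gene_tree_set(lapply(gr$trees[sample(gr$k)], rotate_tree))
  r2 <- infer_species_tree(g_perm, search_config(seed = 2), annotate = FALSE)
  expect_same_topology(r1, r2)
  # fewer than 4 species is rejected at construction
  expect_error(gene_tree_set(c("((a,b),c);")), "at least 4")
})
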