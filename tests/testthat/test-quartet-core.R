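test_that("induced_quartet resolves, detects polytomies, flags missing", {
  t <- parse_newick("((a,b),(c,d));")
  expect_equal(induced_quartet(t, c("a", "b", "c", "d"))$pairing, "a,b|c,d")
  expect_equal(induced_quartet(parse_newick("(a,b,c,d);"),
                               c("a", "b", "c", "d"))$code, 0L)
  # pruned caterpillar: quartet {a,c,d,e} of (((a,b),c),(d,e)) displays ac|de
  t5 <- parse_newick("(((a,b),c),(d,e));")
  q <- induced_quartet(t5, c("a", "c", "d", "e"))
  expect_equal(q$pairing, "a,c|d,e")
  expect_equal(induced_quartet(t5, c("a", "b", "d", "e"))$pairing, "a,b|d,e")
  expect_true(is.na(induced_quartet(t5, c("a", "b", "c", "z"))$code))
})

test_that("quartet_weight multiplies supports along the separating path", {
  w1 <- quartet_weight(parse_newick("((a,b)0.8,(c,d));"), c("a", "b", "c", "d"),
                       "support")
  expect_equal(w1, 0.8)
  cat5 <- parse_newick("((((a,b)0.9,c)0.5,d),e);")
  expect_equal(quartet_weight(cat5, c("a", "b", "d", "e"), "support"), 0.45)
  expect_equal(quartet_weight(cat5, c("a", "b", "c", "d"), "support"), 0.9)
  expect_equal(quartet_weight(cat5, c("a", "b", "d", "e"), "unit"), 1)
  # all supports 1 -> weight 1 in support mode
  allone <- parse_newick("((((a,b)1,c)1,d),e);")
  expect_equal(quartet_weight(allone, c("a", "c", "d", "e"), "support"), 1)
  # hybrid: exp(-L) with L the four terminal path lengths
  hl <- parse_newick("((a:1,b:2)0.5:10,(c:3,d:4));")
  expect_equal(quartet_weight(hl, c("a", "b", "c", "d"), "hybrid"),
               0.5 * exp(-10))
  # missing lengths contribute nothing
  expect_equal(quartet_weight(parse_newick("((a,b)0.5,(c,d));"),
                              c("a", "b", "c", "d"), "hybrid"), 0.5)
})

test_that("brute-force score matches per-quartet enumeration by induced_quartet", {
  # independent cross-check of the two desk-scale routes on 3 random 6-taxon
  # datasets: quartet-by-quartet accumulation vs brute_score internals
  set.seed(401)
  sp <- paste0("s", 1:6)
  for (rep in 1:3) {
    gts <- lapply(1:3, function(i) rand_bin_tree(sample(sp)))
    g <- gene_tree_set(gts)
    st <- rand_bin_tree(sample(sp))
    hand <- 0
    for (quad in utils::combn(sp, 4, simplify = FALSE)) {
      stq <- induced_quartet(st, quad)
      for (t in gts) {
        gq <- induced_quartet(t, quad)
        if (!is.na(gq$code) && gq$code > 0L && gq$code == stq$code)
          hand <- hand + 1
      }
    }
    expect_equal(quartet_score(st, g, "unit", method = "brute")$value, hand)
    expect_equal(quartet_score(st, g, "unit", method = "fast")$value, hand)
  }
})

test_that("identical gene trees give value k*C(n,4) and normalized 1", {
  set.seed(402)
  for (n in c(5, 8)) {
    sp <- paste0("t", 1:n)
    st <- rand_bin_tree(sample(sp))
    g <- gene_tree_set(rep(list(st), 7))
    sc <- quartet_score(st, g, "unit")
    expect_equal(sc$value, 7 * choose(n, 4))
    expect_equal(sc$normalized, 1)
  }
  # all-star gene trees: zero numerator and denominator, NaN normalized
  gstar <- gene_tree_set(rep("(a,b,c,d,e);", 3))
  sc <- quartet_score(rand_bin_tree(letters[1:5]), gstar, "unit")
  expect_equal(sc$value, 0)
  expect_equal(sc$denom, 0)
  expect_true(is.nan(sc$normalized))
})

test_that("fast equals brute on random instances in every mode", {
  # desk-size slice of the oracle-equivalence contract (the full 200-instance
  # sweep runs in test-acceptance.R)
  set.seed(403)
  for (rep in 1:25) {
    g <- random_gene_set(n = sample(4:9, 1L), k = sample(1:5, 1L))
    st <- rand_bin_tree(sample(g$species))
    for (m in c("unit", "support", "hybrid")) {
      f <- quartet_score(st, g, m, method = "fast")
      b <- quartet_score(st, g, m, method = "brute")
      if (m == "unit") {
        expect_identical(f$value, round(f$value))   # exact integer
        expect_equal(f$value, b$value)
        expect_equal(f$denom, b$denom)
      } else {
        expect_equal(f$value, b$value, tolerance = 1e-9)
        expect_equal(f$denom, b$denom, tolerance = 1e-9)
      }
    }
  }
})

test_that("score is invariant to rooting, rotation and input order", {
  skip_if_not_installed("ape")
  set.seed(404)
  sp <- paste0("s", 1:7)
  gts <- lapply(1:6, function(i) rand_bin_tree(sample(sp)))
  st <- rand_bin_tree(sample(sp))
  ref <- quartet_score(st, gene_tree_set(gts), "unit")$value
  # re-root each gene tree at a random internal edge
  rerooted <- lapply(gts, function(t) {
    ape::root(t, outgroup = sample(t$tip.label, 1L), resolve.root = TRUE)
  })
  expect_equal(quartet_score(st, gene_tree_set(rerooted), "unit")$value, ref)
  # rotate child order everywhere
  rotated <- lapply(gts, rotate_tree)
  expect_equal(quartet_score(st, gene_tree_set(rotated), "unit")$value, ref)
  # permute the input file order
  expect_equal(quartet_score(st, gene_tree_set(gts[sample(6)]), "unit")$value, ref)
  # rotate the species tree representation
  expect_equal(quartet_score(rotate_tree(st), gene_tree_set(gts), "unit")$value, ref)
})

test_that("adding a congruent gene tree adds exactly C(n',4)", {
  set.seed(405)
  sp <- paste0("s", 1:8)
  g0 <- lapply(1:5, function(i) rand_bin_tree(sample(sp)))
  st <- rand_bin_tree(sample(sp))
  v0 <- quartet_score(st, gene_tree_set(g0), "unit")$value
  v1 <- quartet_score(st, gene_tree_set(c(g0, list(st))), "unit")$value
  expect_equal(v1 - v0, choose(8, 4))
  # congruent tree on a taxon subset adds C(n',4)
  sub <- qstree:::prune_taxa(st, sp[1:6])
  v2 <- quartet_score(st, gene_tree_set(c(g0, list(sub))), "unit")$value
  expect_equal(v2 - v0, choose(6, 4))
})

test_that("tripartition_gain is anchored counting and block-symmetric", {
  g1 <- gene_tree_set(c("((a,b),(c,d));"))
  expect_equal(tripartition_gain(list("a", "b", c("c", "d")), g1), 1)
  expect_equal(tripartition_gain(list(c("c", "d"), "a", "b"), g1), 1)
  expect_equal(tripartition_gain(list("a", "c", c("b", "d")), g1), 0)
  expect_equal(tripartition_gain(list("a", "b", c("c", "d")),
                                 gene_tree_set(c("(a,b,c,d);"))), 0)
  expect_error(tripartition_gain(list("a", "a", "b"), g1), "overlap")

  # summing gains over the species tree nodes and halving equals fast_score
  set.seed(406)
  for (rep in 1:10) {
    g <- random_gene_set(n = 7, k = 3)
    st <- rand_bin_tree(sample(g$species))
    sets <- qstree:::node_tipsets(st)
    n <- length(st$tip.label)
    kids <- split(seq_len(nrow(st$edge)), st$edge[, 1])
    total <- 0
    for (nd in (n + 1L):(n + st$Nnode)) {
      comps <- lapply(kids[[as.character(nd)]], function(r) sets[[st$edge[r, 2]]])
      if (nd != n + 1L) comps <- c(comps, list(setdiff(st$tip.label, sets[[nd]])))
      total <- total + tripartition_gain(comps, g, "support")
    }
    expect_equal(total / 2, quartet_score(st, g, "support")$value,
                 tolerance = 1e-9)
  }
})

test_that("multi-individual masses average over individual choices", {
  map <- taxon_map(c("a1", "a2", "b", "c1", "c2", "d"),
                   c("A", "A", "B", "C", "C", "D"))
  # 3 of 4 individual choices give AB|CD, one gives AD|BC
  g <- gene_tree_set(c("((a1,b),(c1,(a2,(c2,d))));"), taxon_map = map)
  m <- multi_individual_quartet(g, c("A", "B", "C", "D"))
  expect_equal(unname(m[1, ]), c(0.75, 0, 0.25))

  # one individual per species reduces to induced_quartet
  g1 <- gene_tree_set(c("((a,b),(c,d));"))
  expect_equal(unname(multi_individual_quartet(g1, c("a", "b", "c", "d"))[1, ]),
               c(1, 0, 0))
  # both individuals of A placed with B: full mass on AB|CD
  g2 <- gene_tree_set(c("(((a1,a2),b),(c1,d));"),
                      taxon_map = map[c("a1", "a2", "b", "c1", "d")])
  expect_equal(unname(multi_individual_quartet(g2, c("A", "B", "C", "D"))[1, ]),
               c(1, 0, 0))

  # property: masses equal enumeration over pruned single-individual trees
  set.seed(407)
  for (rep in 1:5) {
    sp <- paste0("S", 1:5)
    ind <- unlist(lapply(sp, function(s)
      paste(s, seq_len(sample(1:2, 1L)), sep = "_")))
    gt <- rand_bin_tree(sample(ind))
    mp <- taxon_map(ind, sub("_.*", "", ind))
    g <- gene_tree_set(list(gt), taxon_map = mp)
    quad <- sort(sample(sp, 4))
    m <- multi_individual_quartet(g, quad)[1, ]
    inds <- lapply(quad, function(s) ind[sub("_.*", "", ind) == s])
    combos <- expand.grid(inds, stringsAsFactors = FALSE)
    oracle <- c(0, 0, 0)
    for (i in seq_len(nrow(combos))) {
      four <- unlist(combos[i, ])
      pruned <- qstree:::prune_taxa(gt, four)
      pruned$tip.label <- sub("_.*", "", pruned$tip.label)
      code <- induced_quartet(pruned, quad)$code
      if (code > 0) oracle[code] <- oracle[code] + 1 / nrow(combos)
    }
    expect_equal(unname(m), oracle)
  }
})

test_that("kernel work grows linearly in the number of gene trees", {
  set.seed(408)
  g1 <- random_gene_set(n = 6, k = 5, p_poly = 0, p_missing = 0)
  g2 <- gene_tree_set(c(g1$trees, g1$trees))        # 2k copies
  st <- rand_bin_tree(sample(g1$species))
  o1 <- quartet_score(st, g1, "unit")$ops
  o2 <- quartet_score(st, g2, "unit")$ops
  expect_equal(o2, 2 * o1)
})
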