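test_that("parse_newick handles supports, lengths, polytomies and quoting", {
  tr <- parse_newick("((a,b),(c,d));")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("a", "b", "c", "d"))
  expect_equal(bipartition_keys(tr), "a,b|c,d")

  tr2 <- parse_newick("((a:1,b:2)0.9:0.5,c:1,d:1);")
  expect_equal(tr2$node.label, c("", "0.9"))
  iedge <- which(tr2$edge[, 2] == length(tr2$tip.label) + 2L)
  expect_equal(tr2$edge.length[iedge], 0.5)

  star <- parse_newick("(a,b,c,d);")
  expect_length(tree_bipartitions(star), 0L)

  q <- parse_newick("('a b','don''t',(c,d)x);")
  expect_true(all(c("a b", "don't") %in% q$tip.label))
  expect_true("x" %in% q$node.label)

  # comments ignored; unary nodes collapsed with summed lengths
  u <- parse_newick("[c1](a:1,((b:1):2)n:3,c:1);")
  expect_equal(n_tips(u), 3L)
  expect_equal(u$edge.length[u$edge[, 2] == which(u$tip.label == "b")], 6)
})

test_that("parse errors name the offending token", {
  expect_error(parse_newick("((a,b);"), "token|unbalanced|unexpected")
  expect_error(parse_newick("(a,b))x;"), "token")
  expect_error(parse_newick("(a,a,b,c);"), "duplicate.*a")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("(a:x,b,c);"), "branch length")
})

test_that("write_newick round-trips the spec examples", {
  s <- "((a,b),(c,d));"
  expect_same_topology(parse_newick(write_newick(parse_newick(s))), parse_newick(s))
  withsup <- parse_newick("((a,b)0.8,(c,d)0.9);")
  expect_match(write_newick(withsup), "0.8")
  expect_equal(write_newick(parse_newick("a;")), "a;")
  # labels with metacharacters survive via quoting
  ann <- parse_newick("((a,b)'q1=0.5;pp=1',c,d);")
  expect_equal(parse_newick(write_newick(ann))$node.label[2], "q1=0.5;pp=1")
})

test_that("Newick round-trip is the identity on 1000 random trees", {
  skip_if_not_installed("ape")
  set.seed(301)
  for (i in 1:1000) {
    n <- sample(4:50, 1L)
    t0 <- ape::rtree(n)
    s1 <- write_newick(t0)
    t1 <- parse_newick(s1)
    expect_identical(sort(t1$tip.label), sort(t0$tip.label))
    expect_identical(bipartition_keys(t1), bipartition_keys(t0))
    # lengths preserved to printed precision
    t2 <- parse_newick(write_newick(t1))
    expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-8)
  }
})

test_that("bipartition counts match branch counts on random trees", {
  set.seed(302)
  for (i in 1:50) {
    n <- sample(4:15, 1L)
    t <- rand_bin_tree(sample(paste0("t", 1:n)))
    expect_length(tree_bipartitions(t), n - 3L)     # binary: n-3 internal branches
    t$node.label <- c("", sprintf("%.2f", runif(t$Nnode - 1L)))
    tp <- contract_low_support(t, runif(1, 0.2, 0.8))
    # one bipartition per remaining internal branch
    expect_length(tree_bipartitions(tp), tp$Nnode - 1L)
  }
  expect_length(tree_bipartitions(parse_newick("(a,b,c,d,e);")), 0L)
})

test_that("contract_low_support follows the threshold contract", {
  full <- parse_newick("((((a,b)0.95,c)0.95,d)0.95,e);")
  expect_same_topology(contract_low_support(full, 0.9), full)
  expect_same_topology(contract_low_support(full, 0), full)

  one_low <- parse_newick("((((a,b)0.5,c)0.95,d)0.95,e);")
  ctr <- contract_low_support(one_low, 0.9)
  expect_length(tree_bipartitions(ctr), 1L)
  expect_false("a,b|c,d,e" %in% bipartition_keys(ctr))

  # threshold above every support collapses to the star
  set.seed(303)
  for (i in 1:20) {
    t <- rand_bin_tree(sample(paste0("x", 1:7)))
    t$node.label <- c("", sprintf("%.3f", runif(t$Nnode - 1L, 0, 0.9)))
    expect_length(tree_bipartitions(contract_low_support(t, 0.95)), 0L)
  }

  # percent-scale autodetection: only the 40%-support branch collapses
  pct <- parse_newick("((((a,b)40,c)95,d)95,e);")
  ctr50 <- contract_low_support(pct, 50)
  expect_identical(bipartition_keys(ctr50), "a,b,c|d,e")
  expect_error(contract_low_support(full, -1), "non-negative")
})

test_that("taxon maps validate and default to identity", {
  f <- tempfile()
  writeLines(c("i1 S1", "i2\tS1", "i3 S2"), f)
  m <- read_taxon_map(f)
  expect_length(m, 3L)
  expect_equal(unname(m[c("i1", "i2", "i3")]), c("S1", "S1", "S2"))
  expect_error(taxon_map(c("i1", "i1"), c("S1", "S2")), "conflicting")
  # identity mapping when no map is given
  g <- gene_tree_set(c("((a,b),(c,d));"))
  expect_equal(g$species, c("a", "b", "c", "d"))
  # leaves absent from a supplied map are an error naming them
  expect_error(gene_tree_set(c("((a,b),(c,zz));"),
                             taxon_map = taxon_map(c("a", "b", "c"), c("A", "B", "C"))),
               "zz")
})

test_that("unroot_tree suppresses a degree-2 root and keeps annotations", {
  r <- parse_newick("(((a:1,b:1)0.7:2,c:1):0.5,(d:1,e:1)0.9:0.25);")
  u <- unroot_tree(r)
  expect_false(is_rooted_tree(u))
  expect_setequal(bipartition_keys(u), bipartition_keys(r))
  # the two root branches merge into one; total length is conserved
  expect_equal(nrow(u$edge), nrow(r$edge) - 1L)
  expect_equal(sum(u$edge.length), sum(r$edge.length))
  expect_true("0.9" %in% u$node.label)
  expect_true("0.7" %in% u$node.label)
})
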