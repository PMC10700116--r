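test_that("Newick round-trips preserve topology, supports, and lengths", {
  tr <- readSupportTree("((A:1,B:1)95:1,C:2);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_true("95" %in% tr$node.label)
  back <- readSupportTree(writeSupportTree(tr))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  expect_equal(back$node.label, tr$node.label)

  expect_error(readSupportTree("((A,B),(A,C));"), "duplicate leaf")
  expect_error(readSupportTree("((A,B,C);"), "unbalanced")
})

test_that("midpoint rooting equalizes the two farthest leaves", {
  tr <- readSupportTree("((A:1,B:3):0,C:0);")
  r <- midpointRoot(tr)
  d <- ape::dist.nodes(r)
  root <- ape::Ntip(r) + 1L
  dA <- d[root, match("A", r$tip.label)]
  dB <- d[root, match("B", r$tip.label)]
  expect_equal(dA, 2, tolerance = 1e-9)
  expect_equal(dB, 2, tolerance = 1e-9)

  # the symmetric two-leaf case roots at the existing bipartition midpoint
  r2 <- midpointRoot(readSupportTree("(A:1,B:1);"))
  d2 <- ape::dist.nodes(r2)
  expect_equal(unname(d2[3, 1]), unname(d2[3, 2]))

  expect_error(midpointRoot(readSupportTree("((A,B),C);")),
               "branch lengths")
})

test_that("midpoint rooting is invariant to input leaf order", {
  t1 <- midpointRoot(readSupportTree("((A:1,B:3):0.5,(C:2,D:0.2):1);"))
  t2 <- midpointRoot(readSupportTree("((D:0.2,C:2):1,(B:3,A:1):0.5);"))
  d1 <- ape::cophenetic.phylo(t1); d2 <- ape::cophenetic.phylo(t2)
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-9)
  # rooting never changes the unrooted topology
  t0 <- readSupportTree("((A:1,B:3):0.5,(C:2,D:0.2):1);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t0), ape::unroot(t1))), 0)
})

test_that("low-support collapse contracts exactly the weak edges", {
  tr <- readSupportTree("(((A:1,B:1)80:1,C:1)99:1,(D:1,E:1)99:1,F:1);")
  cc <- collapseLowSupport(tr, 95)
  expect_equal(sort(cc$tip.label), sort(tr$tip.label))
  expect_equal(cc$Nnode, tr$Nnode - 1L)
  sup <- suppressWarnings(as.numeric(cc$node.label))
  expect_false(any(sup < 95, na.rm = TRUE))

  # already-strong trees are untouched; all-weak trees become stars
  strong <- readSupportTree("((A:1,B:1)99:1,(C:1,D:1)97:1,E:1);")
  expect_equal(collapseLowSupport(strong, 95)$Nnode, strong$Nnode)
  weak <- readSupportTree("((A:1,B:1)10:1,(C:1,D:1)20:1,E:1);")
  star <- collapseLowSupport(weak, 95)
  expect_equal(star$Nnode, 1L)
  # idempotence
  expect_equal(collapseLowSupport(cc, 95), cc)
})

# brute force: smallest internal non-root clade containing the query,
# then the same class rule
bruteSupport <- function(tree, query, classes) {
  nt <- ape::Ntip(tree)
  qi <- match(query, tree$tip.label)
  nodes <- setdiff(unique(tree$edge[, 1]), nt + 1L)
  best <- NULL; bestSize <- Inf
  for (nd in nodes) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    if (query %in% tips && length(tips) < bestSize) {
      best <- tips; bestSize <- length(tips)
    }
  }
  if (is.null(best)) return(FALSE)
  cls <- classes[setdiff(best, query)]
  cls <- cls[cls != "skip"]
  any(cls == "other") && !any(cls == "recipient")
}

test_that("the HGT support check finds donor-nested queries", {
  cls <- c(v1 = "other", v2 = "other", m1 = "recipient", m2 = "recipient",
           s1 = "skip", b1 = "other")
  # query nested among viral leaves, metazoans outside -> supported
  tr <- readSupportTree(
    "(((Q:0.1,v1:0.1)99:0.1,v2:0.1)98:0.2,(m1:0.1,m2:0.1)97:0.3,b1:0.5);")
  chk <- hgtSupportCheck(tr, "Q", cls)
  expect_true(chk$supported)
  expect_setequal(chk$clade, "v1")
  # query sister to a metazoan -> unsupported
  tr2 <- readSupportTree(
    "(((Q:0.1,m1:0.1)99:0.1,v2:0.1)98:0.2,(v1:0.1,m2:0.1)97:0.3,b1:0.5);")
  expect_false(hgtSupportCheck(tr2, "Q", cls)$supported)
  # a fully collapsed star has no non-trivial clade
  star <- collapseLowSupport(readSupportTree(
    "((Q:1,v1:1)10:1,(m1:1,v2:1)20:1,b1:1);"), 95)
  expect_false(hgtSupportCheck(star, "Q", cls)$supported)
  # skip-lineage leaves are ignored inside the clade
  tr3 <- readSupportTree(
    "(((Q:0.1,s1:0.1,v1:0.1)99:0.1,v2:0.1)98:0.2,(m1:0.1,m2:0.1)97:0.3,b1:0.5);")
  expect_true(hgtSupportCheck(tr3, "Q", cls)$supported)
  expect_error(hgtSupportCheck(tr, "ZZ", cls), "not in tree")
  expect_error(hgtSupportCheck(tr, "Q", cls[-1]), "without a taxon class")
})

test_that("the support check matches a brute-force clade scan", {
  set.seed(55)
  for (rep in 1:15) {
    tr <- ape::rtree(sample(5:10, 1))
    tr$tip.label[1] <- "Q"
    tr$node.label <- as.character(sample(c(50, 80, 96, 99), tr$Nnode,
                                         replace = TRUE))
    classes <- setNames(sample(c("recipient", "skip", "other"),
                               ape::Ntip(tr) - 1, replace = TRUE),
                        setdiff(tr$tip.label, "Q"))
    cc <- collapseLowSupport(tr, 95)
    expect_equal(hgtSupportCheck(cc, "Q", classes)$supported,
                 bruteSupport(cc, "Q", classes))
  }
})
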