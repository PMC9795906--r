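test_that("constraint extraction collapses weak splits", {
  tr <- read_newick("(((A:1,B:1)0.9:1,(C:1,D:1)0.5:1)0.95:1,E:3);")
  cons <- constraint_from_support(tr, min_support = 0.7)
  expect_null(cons$edge.length)
  # the 0.5 split collapses, the 0.9 split survives
  expect_equal(cons$Nnode, tr$Nnode - 1)
  lab <- cons$tip.label
  keep_clade <- ape::prop.part(cons)
  expect_true(any(vapply(keep_clade, function(p)
    setequal(lab[p], c("A", "B")), logical(1))))
  expect_false(any(vapply(keep_clade, function(p)
    setequal(lab[p], c("C", "D")), logical(1))))

  # all supports above threshold: topology unchanged
  tr2 <- read_newick("(((A:1,B:1)0.9:1,(C:1,D:1)0.8:1)0.7:1,E:3);")
  cons2 <- constraint_from_support(tr2, 0.7)
  expect_equal(cons2$Nnode, tr2$Nnode)

  # star tree in, star tree out
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(constraint_from_support(star, 0.7)$Nnode, 1)

  # missing supports are treated as unsupported, with a message
  tr3 <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  expect_message(cons3 <- constraint_from_support(tr3, 0.7), "without support")
  expect_equal(cons3$Nnode, 1)
})

test_that("graft rescales the subtree into the replaced clade", {
  bb <- read_newick("(((A:0.2,B:0.2):0.3,C:0.5):0.5,(D:0.6,E:0.6):0.4);")
  bb$edge.length <- bb$edge.length  # root age 1
  sub <- read_newick("((X:0.5,Y:0.5):0.5,Z:1);")
  shared <- data.frame(backbone = c("A", "B"), subtree = c("X", "Y"))
  g <- graft(bb, sub, shared)
  expect_true(mkareas:::is_ultrametric_tol(g, 1e-9))
  expect_equal(root_age(g), 1, tolerance = 1e-9)
  # bookkeeping: 5 - 2 + 3 tips
  expect_equal(ape::Ntip(g), 6)
  # grafted clade crown sits at the replaced crown age 0.2; tip Z attaches at it
  ages <- node_ages(g)
  mrca <- ape::getMRCA(g, c("X", "Y", "Z"))
  expect_equal(unname(ages[mrca]), 0.2, tolerance = 1e-9)
  # locality: ages outside the replaced clade unchanged
  expect_equal(unname(ages[ape::getMRCA(g, c("D", "E"))]), 0.6, tolerance = 1e-9)
  expect_equal(unname(ages[ape::getMRCA(g, c("X", "C"))]), 0.5, tolerance = 1e-9)
})

test_that("grafting an identical prescaled clade is a no-op", {
  set.seed(52)
  bb <- random_unit_tree(12)
  tips <- ape::extract.clade(bb, ape::getMRCA(bb, c(bb$tip.label[1:4])))$tip.label
  mrca <- ape::getMRCA(bb, tips)
  clade <- ape::extract.clade(bb, mrca)
  crown <- node_ages(bb)[mrca]
  sub <- clade
  sub$edge.length <- sub$edge.length / crown   # renormalize to root age 1
  g <- graft(bb, sub, data.frame(backbone = clade$tip.label,
                                 subtree = clade$tip.label))
  d1 <- ape::cophenetic.phylo(bb)
  d2 <- ape::cophenetic.phylo(g)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
})

test_that("graft rejects non-monophyletic shared tips and bad inputs", {
  bb <- read_newick("(((A:0.2,B:0.2):0.3,C:0.5):0.5,(D:0.6,E:0.6):0.4);")
  sub <- read_newick("(X:1,Y:1);")
  expect_error(graft(bb, sub, data.frame(backbone = c("A", "C"),
                                         subtree = c("X", "Y"))),
               "intruding tips: B")
  expect_error(graft(bb, sub, data.frame(backbone = c("A", "B"),
                                         subtree = c("X", "Q"))),
               "missing shared tip")
  # non-unit subtree root age is normalized with a message
  sub2 <- sub; sub2$edge.length <- sub2$edge.length * 2
  expect_message(graft(bb, sub2, data.frame(backbone = c("A", "B"),
                                            subtree = c("X", "Y"))),
                 "normalized")
})

test_that("long terminal branches are flagged against the median", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:20):1);")
  expect_equal(flag_long_branches(tr, factor = 10), "D")
  tr2 <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(flag_long_branches(tr2, 10)), 0)
  expect_equal(length(flag_long_branches(tr, factor = Inf)), 0)
})

test_that("scale_absolute multiplies ages by the calibration triple", {
  tr <- random_unit_tree(8)
  calib <- calibration_spec(60, 57, 64)
  sc <- scale_absolute(tr, calib)
  expect_equal(root_age(sc$point), 60, tolerance = 1e-9)
  expect_equal(root_age(sc$low), 57, tolerance = 1e-9)
  expect_equal(root_age(sc$high), 64, tolerance = 1e-9)
  # low/point ratio exact for every node
  nz <- sc$ages$age_point > 0
  expect_equal(sc$ages$age_low[nz] / sc$ages$age_point[nz],
               rep(57 / 60, sum(nz)), tolerance = 1e-12)
  expect_error(scale_absolute(sc$point, calib), "root age must be 1")
  expect_error(calibration_spec(60, 61, 64))
})

test_that("scaling commutes with grafting", {
  set.seed(77)
  bb <- random_unit_tree(10)
  tips <- ape::extract.clade(bb, ape::getMRCA(bb, bb$tip.label[1:3]))$tip.label
  if (length(tips) < ape::Ntip(bb)) {
    sub <- random_unit_tree(length(tips) + 2)
    sub$tip.label <- c(tips, paste0("new", 1:2))
    shared <- data.frame(backbone = tips, subtree = tips)
    calib <- calibration_spec(60, 57, 64)
    g_then_s <- scale_absolute(graft(bb, sub, shared), calib)$point
    s_first <- scale_absolute(bb, calib)$point
    # rescale to unit root, graft, scale back: node ages must agree
    s_first$edge.length <- s_first$edge.length / 60
    g2 <- graft(s_first, sub, shared)
    g2$edge.length <- g2$edge.length * 60
    d1 <- ape::cophenetic.phylo(g_then_s)
    d2 <- ape::cophenetic.phylo(g2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
  }
})

test_that("age triples format like the summary tables", {
  calib <- calibration_spec(60, 57, 64)
  expect_equal(format_age_triple(0.70667, calib), "42.4 (40.3–45.2)")
  expect_equal(format_age_triple(0, calib), "0 (0–0)")
  # whole numbers print without decimals
  expect_equal(format_age_triple(0.25, calib), "15 (14.3–16)")
})
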