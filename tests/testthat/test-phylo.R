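test_that("NJ recovers the additive 4-taxon worked example exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)
  expect_s3_class(tr, "phylo")
  # topology AB|CD
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(rfDistance(tr, truth)$rf, 0)
  # exact branch lengths: terminal edges 1,2,3,4 and one internal edge 1
  tip_len <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
  names(tip_len) <- tr$tip.label
  expect_equal(tip_len[LETTERS[1:4]],
               c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(sum(internal), 1)
})

test_that("3-taxon NJ gives the closed-form limb lengths", {
  d <- matrix(c(0, 2, 3,
                2, 0, 4,
                3, 4, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- neighborJoining(d)
  tip_len <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
  names(tip_len) <- tr$tip.label
  expect_equal(tip_len["a"], c(a = (2 + 3 - 4) / 2))
  expect_equal(tip_len["b"], c(b = (2 + 4 - 3) / 2))
  expect_equal(tip_len["c"], c(c = (3 + 4 - 2) / 2))
  expect_error(neighborJoining(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers random additive trees (noise-free property)", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    perm <- sample(rownames(dm))
    rec <- neighborJoining(dm[perm, perm])
    expect_equal(rfDistance(rec, tr)$rf, 0)
  }
  # ultrametric balanced 8-leaf tree
  bal <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  expect_equal(rfDistance(neighborJoining(ape::cophenetic.phylo(bal)), bal)$rf, 0)
})

test_that("RF comparison counts non-trivial bipartitions with max 2n-6", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(rfDistance(t1, t1), list(n = 4L, rf = 0, max_rf = 2,
                                        relative_rf = 0))
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  cmp <- rfDistance(t1, t2)
  expect_equal(cmp$rf, 2)
  expect_equal(cmp$max_rf, 2)
  expect_equal(cmp$relative_rf, 1.0)
  t3 <- ape::read.tree(text = "((A:1,E:1):1,(B:1,D:1):1);")
  expect_error(rfDistance(t1, t3), "leaf")
})

test_that("RF is a metric on random binary trees", {
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    labs <- paste0("t", seq_len(n))
    t1 <- ape::rtree(n, tip.label = labs)
    t2 <- ape::rtree(n, tip.label = sample(labs))
    t3 <- ape::rtree(n, tip.label = sample(labs))
    d12 <- rfDistance(t1, t2)$rf
    d21 <- rfDistance(t2, t1)$rf
    expect_identical(d12, d21)
    expect_equal(rfDistance(t1, t1)$rf, 0)
    expect_lte(rfDistance(t1, t3)$rf, d12 + rfDistance(t2, t3)$rf)
    r <- rfDistance(t1, t2)$relative_rf
    expect_gte(r, 0)
    expect_lte(r, 1)
    expect_equal(d12 %% 2, 0) # even for fully resolved binary trees
  }
})

test_that("relative RF arithmetic rounds half up to two decimals", {
  expect_equal(relativeRF(6, 19), 0.19)   # 6/32 = 0.1875
  expect_equal(relativeRF(4, 29), 0.08)   # 4/52
  expect_equal(relativeRF(6, 19, digits = NULL), 0.1875)
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(-0.125, 2), -0.13)
})

test_that("Newick i/o round-trips topology, lengths, and sanitized labels", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2,(C:3,D:4):1);", f)
  tr <- readNewick(f)
  expect_equal(ape::Ntip(tr), 4L)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f2)
  tr2 <- readNewick(f2)
  expect_equal(rfDistance(tr, tr2)$rf, 0)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length), tolerance = 1e-6)
  lab <- sanitizeTaxonName("Escherichia coli (K-12)")
  tr$tip.label[1] <- lab
  writeNewick(tr, f2)
  expect_true(lab %in% readNewick(f2)$tip.label)
  writeLines("((A:1,B:2", f)
  expect_error(suppressWarnings(readNewick(f)))
})
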