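test_that("Kimura correction matches its closed form and limits", {
  expect_equal(kimuraDistance(0), 0)
  expect_equal(kimuraDistance(0.2), -log(1 - 0.2 - 0.2 * 0.04))
  expect_equal(kimuraDistance(0.5), -log(0.45))
  # strictly increasing, d/p -> 1 as p -> 0
  p <- seq(0, 0.85, by = 0.01)
  expect_true(all(diff(kimuraDistance(p)) > 0))
  expect_equal(kimuraDistance(1e-8) / 1e-8, 1, tolerance = 1e-6)
  # saturation at the positive root of 1 - p - 0.2 p^2
  psat <- kimuraSaturation()
  expect_equal(1 - psat - 0.2 * psat^2, 0)
  expect_warning(expect_true(is.na(kimuraDistance(psat + 1e-9))), "saturation")
  expect_silent(kimuraDistance(psat - 1e-6))
})

test_that("pair distance pools mismatches and columns across matches", {
  # two matches with 40 don't-care columns each: (4 + 6) / 80
  cmp <- list(matches = data.frame(mismatches = c(4L, 6L)),
              dontcareColumns = 40L, taxa = c("A", "B"))
  est <- estimatePairDistance(cmp)
  expect_equal(est$p, 0.125)
  expect_equal(est$d, -log(1 - 0.125 - 0.2 * 0.125^2))
  expect_equal(est$status, "ok")
  # no matches -> ceiling + flag
  cmp0 <- list(matches = data.frame(mismatches = integer(0)),
               dontcareColumns = 40L, taxa = c("A", "B"))
  est0 <- estimatePairDistance(cmp0, ceiling = 10)
  expect_equal(est0$d, 10)
  expect_equal(est0$status, "no_matches")
  # saturated p -> ceiling + flag
  cmps <- list(matches = data.frame(mismatches = c(39L, 39L)),
               dontcareColumns = 40L, taxa = c("A", "B"))
  ests <- estimatePairDistance(cmps, ceiling = 10)
  expect_equal(ests$status, "saturated")
  expect_equal(ests$d, 10)
})

test_that("pooled estimation is order-invariant", {
  mm <- c(0L, 3L, 7L, 1L, 5L)
  base <- list(dontcareColumns = 10L, taxa = c("A", "B"))
  d1 <- estimatePairDistance(c(base, list(matches = data.frame(mismatches = mm))))
  d2 <- estimatePairDistance(c(base, list(matches = data.frame(mismatches = rev(mm)))))
  expect_identical(d1$d, d2$d)
})

test_that("distance matrices are symmetric with zero diagonal and self-distance zero", {
  ps <- generatePatternSet(2, 3, 8, seed = 2, iterations = 200)
  s <- random_protein(400, seed = 51)
  prs <- list(proteome(c(s = s), "same1"),
              proteome(c(s = s), "same2"),
              proteome(c(s = random_protein(400, seed = 52)), "other"))
  sdm <- distanceMatrix(prs, ps)
  m <- distances(sdm)
  expect_equal(dim(m), c(3L, 3L))
  expect_identical(m, t(m))
  expect_equal(diag(m), c(same1 = 0, same2 = 0, other = 0))
  # identical proteomes under two names have distance zero
  expect_equal(m["same1", "same2"], 0)
  expect_equal(nrow(pairReport(sdm)), 3L)
  expect_error(distanceMatrix(prs[1], ps), "two")
  expect_error(distanceMatrix(list(prs[[1]], prs[[1]]), ps), "duplicate")
})

test_that("matrix construction is invariant to taxon input order", {
  ps <- generatePatternSet(2, 3, 10, seed = 3, iterations = 200)
  prs <- lapply(1:4, function(i) {
    proteome(c(s = random_protein(300, seed = 60 + i)), paste0("t", i))
  })
  m1 <- suppressWarnings(distances(distanceMatrix(prs, ps)))
  m2 <- suppressWarnings(distances(distanceMatrix(rev(prs), ps)))
  expect_identical(m1, m2[rownames(m1), colnames(m1)])
})

test_that("simulated pairs estimate close to the alignment oracle", {
  ps <- generatePatternSet(5, 6, 46, seed = 42, iterations = 1500)
  sp <- simulatePair(20000, 0.5, rateModel("jtt"), seed = 77)
  est <- estimatePairDistance(compareProteomes(
    proteome(c(s = sp$seq1), "A"), proteome(c(s = sp$seq2), "B"), ps))
  oracle <- alignmentKimuraOracle(sp$seq1, sp$seq2)
  expect_equal(est$status, "ok")
  expect_lt(abs(est$d - oracle), 0.05)
})

test_that("PHYLIP output round-trips and strict mode truncates deterministically", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
              dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  f <- withr::local_tempfile(fileext = ".phy")
  writePhylip(m, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 2L)
  back <- readPhylip(f)
  expect_equal(back[rownames(m), colnames(m)], m, tolerance = 1e-6)
  # strict mode: 10-character fields, collision detection
  long <- matrix(0, 2, 2, dimnames = list(c("abcdefghijk", "abcdefghijZ"),
                                          c("abcdefghijk", "abcdefghijZ")))
  f2 <- withr::local_tempfile(fileext = ".phy")
  expect_error(writePhylip(long, f2, strict = TRUE), "collision")
  long2 <- matrix(c(0, 1, 1, 0), 2, 2,
                  dimnames = list(c("abcdefghijk", "zyx"),
                                  c("abcdefghijk", "zyx")))
  writePhylip(long2, f2, strict = TRUE)
  expect_equal(rownames(readPhylip(f2)), c("abcdefghij", "zyx"))
})
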