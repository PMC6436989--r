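test_that("spaced-word extraction reproduces the worked example", {
  pr <- proteome(c(s1 = "ATNQRDAP"), "toy")
  occ <- extractSpacedWords(pr, spacedPattern("1100101"))
  # the spaced word TN**D*P occurs at 1-based position 2
  expect_true(any(occ$offset == 2 & occ$key == "TNDP"))
  expect_equal(nrow(occ), 2L) # positions 1 and 2 are the only full windows

  pr2 <- proteome(c(s = "ACD"), "tiny")
  occ2 <- extractSpacedWords(pr2, spacedPattern("111"))
  expect_equal(nrow(occ2), 1L)
  expect_equal(occ2$key, "ACD")
  expect_equal(nrow(extractSpacedWords(proteome(c(s = "ACDE"), "x"),
                                       spacedPattern("11111"))), 0L)
})

test_that("windows never span sequence boundaries or ambiguous residues", {
  pr <- proteome(c(a = "ACDEF", b = "GHIKL"), "multi")
  occ <- extractSpacedWords(pr, spacedPattern("111"))
  expect_equal(nrow(occ), 6L) # 3 per record, none across the boundary
  expect_true(all(occ$offset + 2 <= 5))
  prx <- proteome(c(s = "ACXDEF"), "amb")
  occx <- extractSpacedWords(prx, spacedPattern("111"))
  expect_equal(occx$offset, 4L) # only DEF avoids the X
})

test_that("match scores come from BLOSUM62 over don't-care columns", {
  expect_equal(scoreMatch("ACD", "AWD", spacedPattern("101")),
               list(score = -2L, mismatches = 1L))
  expect_equal(scoreMatch("ACD", "ACD", spacedPattern("101")),
               list(score = 9L, mismatches = 0L))
  expect_equal(scoreMatch("ACD", "ACD", spacedPattern("111")),
               list(score = 0L, mismatches = 0L))
  expect_error(scoreMatch("ACD", "WCD", spacedPattern("101")), "match position")
})

test_that("the embedded BLOSUM62 equals the Biostrings reference", {
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  b <- blosum62()
  expect_identical(unname(b), unname(ref[rownames(b), colnames(b)]))
})

test_that("greedy one-to-one selection follows descending scores", {
  # 2x1 bucket: the higher-scoring candidate wins
  cand <- data.frame(score = c(5, 7), g1 = c(1, 2), g2 = c(10, 10))
  sel <- selectOneToOne(cand, threshold = 0)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$g1, 2)
  # 2x2 worked trace: (a1,b1)=9 then (a2,b2)=1
  cand2 <- data.frame(score = c(9, 8, 7, 1),
                      g1 = c(1, 1, 2, 2), g2 = c(10, 20, 10, 20))
  sel2 <- selectOneToOne(cand2, threshold = 0)
  expect_equal(sel2$score, c(9, 1))
  # single candidate above threshold is kept; below is discarded
  expect_equal(nrow(selectOneToOne(data.frame(score = 3, g1 = 1, g2 = 1),
                                   threshold = 0)), 1L)
  expect_equal(nrow(selectOneToOne(data.frame(score = -3, g1 = 1, g2 = 1),
                                   threshold = 0)), 0L)
})

test_that("selection equals the sequential reference on random buckets", {
  set.seed(21)
  for (rep in 1:25) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    cand <- expand.grid(g1 = seq_len(n1), g2 = 100 + seq_len(n2))
    cand$score <- sample(-5:10, nrow(cand), replace = TRUE)
    thr <- sample(-2:4, 1)
    sel <- selectOneToOne(cand, threshold = thr)
    ref <- greedy_reference(data.frame(i1 = cand$g1, i2 = cand$g2,
                                       score = cand$score), threshold = thr)
    expect_equal(sel$score, ref$score)
    expect_equal(sel$g1, ref$i1)
    expect_equal(sel$g2, ref$i2)
    # matching property and maximality
    expect_false(anyDuplicated(sel$g1) > 0)
    expect_false(anyDuplicated(sel$g2) > 0)
    left <- cand[cand$score >= thr &
                   !(cand$g1 %in% sel$g1) & !(cand$g2 %in% sel$g2), ]
    expect_equal(nrow(left), 0L)
  }
})

test_that("proteome comparison equals brute force on small random pairs", {
  mat <- blosum62()
  set.seed(31)
  for (rep in 1:12) {
    s1 <- random_protein(sample(40:120, 1))
    s2 <- random_protein(sample(40:120, 1))
    pat <- random_pattern_string(sample(4:7, 1), sample(2:3, 1))
    p1 <- proteome(c(s = s1), "A")
    p2 <- proteome(c(s = s2), "B")
    ps <- spacedPatternSet(pat)
    cmp <- compareProteomes(p1, p2, ps, threshold = -Inf)
    ref_cand <- brute_candidates(s1, s2, pat, mat)
    ref_sel <- greedy_reference(ref_cand)
    expect_equal(nrow(cmp$matches), nrow(ref_sel))
    got <- cmp$matches[order(cmp$matches$offset1, cmp$matches$offset2), ]
    want <- ref_sel[order(ref_sel$i1, ref_sel$i2), ]
    expect_equal(got$offset1, want$i1)
    expect_equal(got$offset2, want$i2)
    expect_equal(got$score, want$score)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("comparison is symmetric and disjoint keys give empty results", {
  ps <- spacedPatternSet("1101")
  s1 <- random_protein(150, seed = 5)
  s2 <- random_protein(150, seed = 6)
  a <- proteome(c(s = s1), "A")
  b <- proteome(c(s = s2), "B")
  ab <- compareProteomes(a, b, ps, threshold = -Inf)
  ba <- compareProteomes(b, a, ps, threshold = -Inf)
  key <- function(m) paste(sort(paste(m$score, m$mismatches)), collapse = "|")
  expect_identical(key(ab$matches), key(ba$matches))
  expect_identical(ab$spamogram, ba$spamogram)
  # sides are swapped consistently
  expect_equal(sort(ab$matches$offset1), sort(ba$matches$offset2))
  # no shared spaced words at all
  poly_a <- proteome(c(s = strrep("A", 30)), "pa")
  poly_w <- proteome(c(s = strrep("W", 30)), "pw")
  empty <- compareProteomes(poly_a, poly_w, ps, threshold = -Inf)
  expect_equal(nrow(empty$matches), 0L)
  expect_equal(nrow(empty$spamogram), 0L)
})

test_that("self-comparison of a repeat-free sequence selects every window at maximal score", {
  # all 20 residues once: every window unique, so one self-match per window
  s <- paste(AA20, collapse = "")
  pr <- proteome(c(s = s), "selfA")
  pr2 <- proteome(c(s = s), "selfB")
  pat <- spacedPattern("1011")
  cmp <- compareProteomes(pr, pr2, spacedPatternSet(list(pat)))
  n_windows <- nchar(s) - patternLength(pat) + 1
  expect_equal(nrow(cmp$matches), n_windows)
  expect_true(all(cmp$matches$mismatches == 0))
  # spamogram mass concentrated at per-window diagonal scores
  expect_equal(sum(cmp$spamogram$count), n_windows)
})

test_that("heavy patterns use the string-key fallback consistently", {
  # base-20 packing is exact only up to w = 12; w = 13 exercises the
  # character-key path
  s <- random_protein(120, seed = 91)
  pr <- proteome(c(s = s), "A")
  pat <- spacedPattern(strrep("1", 13))
  occ <- extractSpacedWords(pr, pat)
  expect_equal(nrow(occ), nchar(s) - 13 + 1)
  expect_equal(occ$key, sort(substring(s, 1:(nchar(s) - 12), 13:nchar(s))))
  cmp <- compareProteomes(pr, proteome(c(s = s), "B"),
                          spacedPatternSet(list(pat)))
  expect_equal(nrow(cmp$matches), nrow(occ))
})

test_that("spamogram counts pre-threshold selected matches and raising T only removes matches", {
  s1 <- random_protein(300, seed = 41)
  s2 <- random_protein(300, seed = 42)
  p1 <- proteome(c(s = s1), "A")
  p2 <- proteome(c(s = s2), "B")
  ps <- spacedPatternSet("11011")
  thresholds <- c(-Inf, -5, 0, 5, 10)
  counts <- vapply(thresholds, function(T) {
    nrow(compareProteomes(p1, p2, ps, threshold = T)$matches)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  cmp <- compareProteomes(p1, p2, ps, threshold = 0)
  expect_equal(sum(cmp$spamogram$count), counts[1]) # pre-threshold total
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSpamogram(cmp, f)
  tab <- read.delim(f)
  expect_equal(tab$count, cmp$spamogram$count)
  expect_false(is.unsorted(tab$score))
})
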