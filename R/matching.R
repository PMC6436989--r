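# Spaced-word extraction, match scoring, greedy one-to-one selection.
#
# Internally each proteome is concatenated into one integer-coded vector
# with a single NA separator between records; windows containing NA (either
# a record boundary or an ambiguous residue) are excluded, so occurrences
# never span sequences and never touch ambiguous positions. Global
# positions are mapped back to (sequence index, 1-based offset) only at the
# reporting boundary.

#' @importFrom data.table data.table setkey
NULL

.concatCodes <- function(prot) {
  codes <- prot@codes
  n <- length(codes)
  if (n == 1L) {
    cat_codes <- codes[[1L]]
    starts <- 1L
  } else {
    with_sep <- vector("list", 2L * n - 1L)
    with_sep[seq(1L, 2L * n - 1L, by = 2L)] <- codes
    with_sep[seq(2L, 2L * n - 2L, by = 2L)] <- list(NA_integer_)
    cat_codes <- unlist(with_sep, use.names = FALSE)
    starts <- cumsum(c(1L, lengths(codes)[-n] + 1L))
  }
  list(codes = cat_codes, starts = starts)
}

# map global start positions to (seq_index, 1-based offset)
.globalToLocal <- function(g, starts) {
  si <- findInterval(g, starts)
  list(seq_index = si, offset = g - starts[si] + 1L)
}

# all spaced-word occurrences of one pattern in a concatenated code vector:
# global start positions and packed keys (base-20 double for w <= 12,
# character fallback above)
.occurrences <- function(cat_codes, pat) {
  mp <- which(pat@bits)
  ell <- length(pat@bits)
  w <- length(mp)
  n <- length(cat_codes)
  if (n < ell) return(list(g = integer(0), key = numeric(0)))
  nw <- n - ell + 1L
  cs <- c(0L, cumsum(is.na(cat_codes)))
  valid <- (cs[seq_len(nw) + ell] - cs[seq_len(nw)]) == 0L
  g <- which(valid)
  if (length(g) == 0L) return(list(g = integer(0), key = numeric(0)))
  if (w <= 12L) {
    key <- 0
    for (j in seq_len(w)) key <- key * 20 + (cat_codes[g + mp[j] - 1L] - 1)
  } else {
    chunk <- matrix(AA_ORDER[cat_codes[rep(g, each = w) + rep(mp - 1L, length(g))]],
                    nrow = w)
    key <- apply(chunk, 2L, paste, collapse = "")
  }
  list(g = g, key = key)
}

#' Extract spaced-word occurrences from a proteome
#'
#' Lists every occurrence of a spaced word with respect to `pattern`: one
#' row per length-\eqn{\ell} window that lies fully inside a single
#' sequence and is free of ambiguous residues. The key is the ordered
#' string of residues at the pattern's match positions. Offsets are
#' 1-based.
#'
#' @param x a [Proteome-class].
#' @param pattern a [SpacedPattern-class].
#' @return data.frame with columns `seq_index`, `offset`, `key`, sorted by
#'   key, then sequence index, then offset.
#' @export
#' @examples
#' pr <- proteome(c(s1 = "ATNQRDAP"), "toy")
#' extractSpacedWords(pr, spacedPattern("1100101"))
extractSpacedWords <- function(x, pattern) {
  cc <- .concatCodes(x)
  occ <- .occurrences(cc$codes, pattern)
  loc <- .globalToLocal(occ$g, cc$starts)
  mp <- which(pattern@bits)
  w <- length(mp)
  keystr <- if (length(occ$g)) {
    vapply(seq_along(occ$g), function(i) {
      paste(AA_ORDER[cc$codes[occ$g[i] + mp - 1L]], collapse = "")
    }, character(1))
  } else character(0)
  out <- data.frame(seq_index = loc$seq_index, offset = loc$offset,
                    key = keystr, stringsAsFactors = FALSE)
  out[order(out$key, out$seq_index, out$offset), , drop = FALSE]
}

#' Score a spaced-word match over its don't-care columns
#'
#' The score of a spaced-word match is the sum of substitution scores of
#' the residue pairs aligned at the pattern's don't-care positions;
#' `mismatches` counts the don't-care columns whose residues differ.
#'
#' @param window1,window2 residue strings of length \eqn{\ell} (the two
#'   matched windows); their residues at the match positions must agree.
#' @param pattern a [SpacedPattern-class].
#' @param scoringMatrix substitution matrix (default [blosum62()]).
#' @return list with integer `score` and `mismatches`.
#' @export
#' @examples
#' scoreMatch("ACD", "AWD", spacedPattern("101")) # score -2, 1 mismatch
scoreMatch <- function(window1, window2, pattern,
                       scoringMatrix = blosum62()) {
  a <- encodeResidues(window1)
  b <- encodeResidues(window2)
  stopifnot(length(a) == patternLength(pattern),
            length(b) == patternLength(pattern))
  mp <- which(pattern@bits)
  if (!identical(a[mp], b[mp])) {
    stop("windows disagree at match positions; not a spaced-word match")
  }
  dc <- which(!pattern@bits)
  if (length(dc) == 0L) return(list(score = 0L, mismatches = 0L))
  if (anyNA(a[dc]) || anyNA(b[dc])) {
    stop("ambiguous residue in don't-care column")
  }
  list(score = sum(scoringMatrix[cbind(a[dc], b[dc])]),
       mismatches = sum(a[dc] != b[dc]))
}

# Sequential greedy one-to-one selection, implemented as repeated
# vectorized passes. Candidates are processed in descending score with
# deterministic tie-break on (g1, g2); a candidate is accepted iff neither
# endpoint occurrence was used by an earlier accepted candidate. A pass
# accepts every remaining candidate that is the first remaining occurrence
# of both its endpoints, which reproduces the sequential rule exactly.
# Returns indices into the input vectors, in acceptance (descending-score)
# order.
.selectGreedyIdx <- function(score, g1, g2) {
  ord <- order(-score, g1, g2)
  a <- g1[ord]
  b <- g2[ord]
  keep <- integer(0)
  idx <- seq_along(a)
  while (length(idx)) {
    acc <- idx[!duplicated(a[idx]) & !duplicated(b[idx])]
    keep <- c(keep, acc)
    idx <- idx[!(a[idx] %in% a[acc]) & !(b[idx] %in% b[acc])]
  }
  ord[sort(keep)]
}

#' Greedy one-to-one selection of candidate matches
#'
#' Given all candidate spaced-word matches of one bucket (occurrences
#' sharing one spaced word under one pattern), discards candidates scoring
#' below `threshold` and then selects the rest one by one in descending
#' score order (ties broken on occurrence coordinates, ascending), accepting
#' a candidate only if neither of its two occurrences is already used. The
#' result is a matching: each occurrence participates in at most one
#' selected match, so repeat regions are not over-counted.
#'
#' @param candidates data.frame with numeric columns `score`, `g1`, `g2`
#'   (occurrence identifiers on side 1 and 2) and any further columns.
#' @param threshold minimum score (default 0).
#' @return the selected subset of `candidates` (rows in descending score
#'   order).
#' @export
selectOneToOne <- function(candidates, threshold = 0) {
  keep <- candidates$score >= threshold
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand[.selectGreedyIdx(cand$score, cand$g1, cand$g2), , drop = FALSE]
}

# Candidate enumeration + scoring + greedy selection for one pattern,
# operating on precomputed occurrence tables. Returns per-candidate
# selected rows (score-sorted): g1, g2, score, mismatches -- for ALL
# selected matches regardless of threshold (thresholding is a prefix of the
# descending order and is applied by the caller).
.patternMatches <- function(occ1, occ2, codes1, codes2, pat, svec) {
  if (length(occ1$g) == 0L || length(occ2$g) == 0L) {
    return(list(g1 = integer(0), g2 = integer(0),
                score = integer(0), mismatches = integer(0)))
  }
  d1 <- data.table::data.table(k = occ1$key, g1 = occ1$g)
  d2 <- data.table::data.table(k = occ2$key, g2 = occ2$g)
  cand <- d1[d2, on = "k", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0L) {
    return(list(g1 = integer(0), g2 = integer(0),
                score = integer(0), mismatches = integer(0)))
  }
  g1 <- cand$g1
  g2 <- cand$g2
  dc <- which(!pat@bits)
  score <- integer(length(g1))
  mism <- integer(length(g1))
  for (k in dc) {
    a <- codes1[g1 + k - 1L]
    b <- codes2[g2 + k - 1L]
    score <- score + svec[a + 20L * (b - 1L)]
    mism <- mism + (a != b)
  }
  sel <- .selectGreedyIdx(score, g1, g2)
  list(g1 = g1[sel], g2 = g2[sel], score = score[sel], mismatches = mism[sel])
}

#' Compare two proteomes by filtered spaced-word matches
#'
#' Runs the full matching stage for one proteome pair: for every pattern in
#' `patternSet` independently, all spaced-word occurrences are bucketed by
#' their spaced word, candidate matches are scored with the substitution
#' matrix over the don't-care columns, and a greedy one-to-one selection is
#' applied. Matches from all patterns are pooled. The returned match table
#' contains only matches scoring at least `threshold`; the spamogram (score
#' histogram) is built from the one-to-one-selected matches *before*
#' thresholding, so both the background peak and the homologous peak are
#' visible.
#'
#' The comparison is symmetric: the pair is internally oriented by taxon
#' name, so `compareProteomes(a, b)` and `compareProteomes(b, a)` select
#' identical match sets (with sides swapped in the report).
#'
#' @param x,y [Proteome-class] objects.
#' @param patternSet a [SpacedPatternSet-class].
#' @param scoringMatrix 20x20 substitution matrix (default [blosum62()]).
#' @param threshold score threshold `T` (default 0); matches scoring below
#'   it are treated as random background and discarded.
#' @return list with elements
#'   \describe{
#'     \item{matches}{data.frame: `pattern_index`, `seq1`, `offset1`,
#'       `seq2`, `offset2`, `score`, `mismatches` (thresholded).}
#'     \item{spamogram}{data.frame `score`, `count` (ascending score;
#'       pre-threshold selected matches).}
#'     \item{dontcareColumns}{don't-care columns per match, \eqn{\ell - w}.}
#'     \item{taxa}{the two taxon names, in input order.}
#'   }
#' @export
compareProteomes <- function(x, y, patternSet,
                             scoringMatrix = blosum62(), threshold = 0) {
  swapped <- taxonName(x) > taxonName(y)
  p1 <- if (swapped) y else x
  p2 <- if (swapped) x else y
  cc1 <- .concatCodes(p1)
  cc2 <- .concatCodes(p2)
  svec <- as.integer(scoringMatrix)
  pats <- patternSet@patterns
  per_pat <- lapply(seq_along(pats), function(pi) {
    pat <- pats[[pi]]
    m <- .patternMatches(.occurrences(cc1$codes, pat),
                         .occurrences(cc2$codes, pat),
                         cc1$codes, cc2$codes, pat, svec)
    m$pattern_index <- rep.int(pi, length(m$g1))
    m
  })
  g1 <- unlist(lapply(per_pat, `[[`, "g1"), use.names = FALSE)
  g2 <- unlist(lapply(per_pat, `[[`, "g2"), use.names = FALSE)
  score <- unlist(lapply(per_pat, `[[`, "score"), use.names = FALSE)
  mismatches <- unlist(lapply(per_pat, `[[`, "mismatches"), use.names = FALSE)
  pattern_index <- unlist(lapply(per_pat, `[[`, "pattern_index"),
                          use.names = FALSE)
  spam <- if (length(score)) {
    tab <- table(score)
    data.frame(score = as.integer(names(tab)), count = as.integer(tab))
  } else {
    data.frame(score = integer(0), count = integer(0))
  }
  keep <- score >= threshold
  loc1 <- .globalToLocal(g1[keep], cc1$starts)
  loc2 <- .globalToLocal(g2[keep], cc2$starts)
  matches <- data.frame(pattern_index = pattern_index[keep],
                        seq1 = loc1$seq_index, offset1 = loc1$offset,
                        seq2 = loc2$seq_index, offset2 = loc2$offset,
                        score = score[keep], mismatches = mismatches[keep])
  if (swapped) {
    matches <- matches[, c("pattern_index", "seq2", "offset2",
                           "seq1", "offset1", "score", "mismatches")]
    names(matches) <- c("pattern_index", "seq1", "offset1",
                        "seq2", "offset2", "score", "mismatches")
  }
  list(matches = matches, spamogram = spam,
       dontcareColumns = patternLength(patternSet) - patternWeight(patternSet),
       taxa = c(taxonName(x), taxonName(y)))
}

#' Write a spamogram as TSV
#'
#' Two-column tab-separated output `score`, `count`, ascending score.
#'
#' @param comparison result of [compareProteomes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpamogram <- function(comparison, path) {
  utils::write.table(comparison$spamogram, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
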