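#' Create a spaced pattern
#'
#' @param x either a 0/1 character string (`"1100101"`, 1 = match position)
#'   or a logical vector (`TRUE` = match).
#' @return a [SpacedPattern-class].
#' @export
#' @examples
#' spacedPattern("1100101")
spacedPattern <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    ch <- strsplit(x, "")[[1L]]
    if (!all(ch %in% c("0", "1"))) {
      stop("pattern string must contain only '0' and '1'")
    }
    bits <- ch == "1"
  } else {
    bits <- as.logical(x)
  }
  new("SpacedPattern", bits = bits)
}

#' Create a pattern set from explicit patterns
#'
#' @param patterns character vector of 0/1 strings or a list of
#'   [SpacedPattern-class] objects.
#' @param seed optional integer recorded as the generation seed.
#' @return a [SpacedPatternSet-class].
#' @export
spacedPatternSet <- function(patterns, seed = NA_integer_) {
  if (is.character(patterns)) patterns <- lapply(patterns, spacedPattern)
  new("SpacedPatternSet", patterns = patterns, seed = as.integer(seed))
}

# sigma(s) = number of coinciding match positions of p and q at relative
# shift s, for every s in [-(l_q - 1), l_p - 1]; returns sum over shifts of
# 2^sigma(s). Shifts with sigma = 0 contribute 1 each. For the self pair the
# s = 0 term (the constant 2^w) is excluded entirely.
.ocPair <- function(mp, mq, lp, lq, self = FALSE) {
  shifts <- (-(lq - 1L)):(lp - 1L)
  diffs <- as.vector(outer(mp, mq, "-"))
  sigma <- tabulate(diffs - shifts[1L] + 1L, nbins = length(shifts))
  if (self) sigma <- sigma[shifts != 0L]
  sum(2^sigma)
}

#' Overlap complexity of patterns and pattern sets
#'
#' The overlap complexity of a pattern pair is
#' \eqn{\sum_s 2^{\sigma(s)}} over all relative shifts \eqn{s}, where
#' \eqn{\sigma(s)} counts coinciding match positions at shift \eqn{s}. For a
#' pattern against itself (one-argument form, and the diagonal terms of a
#' set) the zero-shift term is excluded: it is the constant \eqn{2^w} for
#' every pattern of weight \eqn{w} and cannot affect optimization. The
#' overlap complexity of a set is the sum over all unordered pairs including
#' the self terms. Pattern sets with low overlap complexity spread their
#' match positions so the patterns hit complementary positions, which is what
#' the hill-climbing generator minimizes.
#'
#' @param x a [SpacedPattern-class] or [SpacedPatternSet-class].
#' @param y a second [SpacedPattern-class] (omit for the self convention).
#' @return a nonnegative number.
#' @name overlapComplexity
#' @examples
#' overlapComplexity(spacedPattern("11"), spacedPattern("11")) # 8
#' overlapComplexity(spacedPattern("11"))                      # 4 (self)
NULL

#' @rdname overlapComplexity
setMethod("overlapComplexity", signature("SpacedPattern", "SpacedPattern"),
          function(x, y) {
  .ocPair(which(x@bits), which(y@bits), length(x@bits), length(y@bits))
})

#' @rdname overlapComplexity
setMethod("overlapComplexity", signature("SpacedPattern", "missing"),
          function(x, y) {
  mp <- which(x@bits)
  .ocPair(mp, mp, length(x@bits), length(x@bits), self = TRUE)
})

#' @rdname overlapComplexity
setMethod("overlapComplexity", signature("SpacedPatternSet", "missing"),
          function(x, y) {
  mps <- lapply(x@patterns, function(p) which(p@bits))
  ell <- patternLength(x)
  m <- length(mps)
  total <- 0
  for (i in seq_len(m)) {
    total <- total + .ocPair(mps[[i]], mps[[i]], ell, ell, self = TRUE)
    if (i < m) {
      for (j in (i + 1L):m) {
        total <- total + .ocPair(mps[[i]], mps[[j]], ell, ell)
      }
    }
  }
  total
})

# objective contribution of pattern k (its self term plus cross terms
# against every other pattern), given match-position lists
.ocContribution <- function(mps, k, ell) {
  total <- .ocPair(mps[[k]], mps[[k]], ell, ell, self = TRUE)
  for (j in seq_along(mps)) {
    if (j != k) total <- total + .ocPair(mps[[k]], mps[[j]], ell, ell)
  }
  total
}

#' Generate an optimized pattern set by hill climbing
#'
#' Draws `m` distinct random canonical patterns (position 1 is always a
#' match position) of the requested shape and then minimizes the set's
#' overlap complexity by hill climbing: each proposal swaps one randomly
#' chosen match position (never position 1) of one randomly chosen pattern
#' with one randomly chosen don't-care position, and is accepted iff the
#' objective strictly decreases and the moved pattern stays distinct from
#' the others. The run is deterministic for a given seed.
#'
#' @param m number of patterns (default 5).
#' @param weight number of match positions \eqn{w} (default 6).
#' @param length total pattern length \eqn{\ell} (default 46, i.e. 40
#'   don't-care positions).
#' @param seed integer RNG seed (default 42).
#' @param iterations number of swap proposals (default 5000).
#' @return a [SpacedPatternSet-class]; its overlap complexity is never larger
#'   than that of the random initial set.
#' @export
#' @examples
#' ps <- generatePatternSet(m = 2, weight = 3, length = 8, seed = 1,
#'                          iterations = 200)
#' overlapComplexity(ps)
generatePatternSet <- function(m = 5L, weight = 6L, length = 46L,
                               seed = 42L, iterations = 5000L) {
  m <- as.integer(m); w <- as.integer(weight); ell <- as.integer(length)
  seed <- as.integer(seed)
  if (w < 1L || w > ell) stop("need 1 <= weight <= length")
  if (m < 1L) stop("need m >= 1")
  n_avail <- choose(ell - 1L, w - 1L)
  if (m > n_avail) {
    stop(sprintf("only %d distinct canonical patterns of weight %d, length %d exist; cannot draw %d",
                 n_avail, w, ell, m))
  }
  withSeed(seed, {
    # random distinct initialization, position 1 always a match
    mps <- list()
    keys <- character(0)
    while (base::length(mps) < m) {
      mp <- if (w > 1L) {
        sort(c(1L, (2:ell)[sample.int(ell - 1L, w - 1L)]))
      } else 1L
      key <- paste(mp, collapse = ",")
      if (!(key %in% keys)) {
        mps[[base::length(mps) + 1L]] <- mp
        keys <- c(keys, key)
      }
    }
    # hill climbing on swap moves
    contrib <- vapply(seq_len(m), function(k) .ocContribution(mps, k, ell),
                      numeric(1))
    if (w > 1L && w < ell) {
      for (it in seq_len(iterations)) {
        k <- if (m > 1L) sample.int(m, 1L) else 1L
        mp <- mps[[k]]
        movable <- mp[mp != 1L]
        dc <- setdiff(2:ell, mp)
        out_pos <- movable[sample.int(base::length(movable), 1L)]
        in_pos <- dc[sample.int(base::length(dc), 1L)]
        new_mp <- sort(c(setdiff(mp, out_pos), in_pos))
        key <- paste(new_mp, collapse = ",")
        if (key %in% keys[-k]) next
        trial <- mps
        trial[[k]] <- new_mp
        new_contrib <- .ocContribution(trial, k, ell)
        if (new_contrib < contrib[k]) {
          mps <- trial
          keys[k] <- key
          contrib[k] <- new_contrib
          # cross terms of the other patterns changed too; refresh lazily
          if (m > 1L) {
            contrib <- vapply(seq_len(m),
                              function(kk) .ocContribution(mps, kk, ell),
                              numeric(1))
          }
        }
      }
    }
    pats <- lapply(mps, function(mp) {
      bits <- rep(FALSE, ell)
      bits[mp] <- TRUE
      new("SpacedPattern", bits = bits)
    })
    new("SpacedPatternSet", patterns = pats, seed = seed)
  })
}

#' Read and write pattern files
#'
#' Plain-text format: one pattern per line as a 0/1 string (1 = match
#' position); lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return `readPatterns` returns a [SpacedPatternSet-class];
#'   `writePatterns` returns `path` invisibly.
#' @export
readPatterns <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no patterns found in ", path)
  spacedPatternSet(lines)
}

#' @rdname readPatterns
#' @param ps a [SpacedPatternSet-class] to write.
#' @export
writePatterns <- function(ps, path) {
  writeLines(patternString(ps), path)
  invisible(path)
}
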