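# Independent brute-force oracles used to check the fast implementations.
# These deliberately share no code with the package internals.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# overlap complexity of two 0/1 pattern strings by literal shift enumeration
oc_pair_brute <- function(pstr, qstr, self = FALSE) {
  p <- strsplit(pstr, "")[[1]] == "1"
  q <- strsplit(qstr, "")[[1]] == "1"
  lp <- length(p)
  lq <- length(q)
  total <- 0
  for (s in (-(lq - 1)):(lp - 1)) {
    if (self && s == 0) next
    sigma <- 0
    for (i in seq_len(lp)) {
      j <- i - s
      if (j >= 1 && j <= lq && p[i] && q[j]) sigma <- sigma + 1
    }
    total <- total + 2^sigma
  }
  total
}

oc_set_brute <- function(pstrs) {
  m <- length(pstrs)
  total <- 0
  for (i in seq_len(m)) {
    for (j in i:m) {
      total <- total + oc_pair_brute(pstrs[i], pstrs[j], self = (i == j))
    }
  }
  total
}

# O(n * n' * l) spaced-word candidate enumeration between two single
# sequences: every pair of ambiguity-free windows whose residues agree at
# all match positions, with BLOSUM score and mismatch count over the
# don't-care positions. 1-based window starts.
brute_candidates <- function(s1, s2, patstr, mat) {
  bits <- strsplit(patstr, "")[[1]] == "1"
  ell <- length(bits)
  mp <- which(bits)
  dc <- which(!bits)
  a1 <- match(strsplit(toupper(s1), "")[[1]], AA20)
  a2 <- match(strsplit(toupper(s2), "")[[1]], AA20)
  out <- list()
  n <- 0
  for (i1 in seq_len(max(0, length(a1) - ell + 1))) {
    w1 <- a1[i1:(i1 + ell - 1)]
    if (anyNA(w1)) next
    for (i2 in seq_len(max(0, length(a2) - ell + 1))) {
      w2 <- a2[i2:(i2 + ell - 1)]
      if (anyNA(w2)) next
      if (!all(w1[mp] == w2[mp])) next
      sc <- 0
      mm <- 0
      for (k in dc) {
        sc <- sc + mat[w1[k], w2[k]]
        mm <- mm + (w1[k] != w2[k])
      }
      n <- n + 1
      out[[n]] <- c(i1 = i1, i2 = i2, score = sc, mismatches = mm)
    }
  }
  if (n == 0) {
    return(data.frame(i1 = integer(0), i2 = integer(0),
                      score = integer(0), mismatches = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# literal sequential greedy one-to-one selection over a candidate table:
# descending score, ties broken on (i1, i2) ascending
greedy_reference <- function(cand, threshold = -Inf) {
  cand <- cand[cand$score >= threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$score, cand$i1, cand$i2), , drop = FALSE]
  used1 <- integer(0)
  used2 <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!(cand$i1[r] %in% used1) && !(cand$i2[r] %in% used2)) {
      keep[r] <- TRUE
      used1 <- c(used1, cand$i1[r])
      used2 <- c(used2, cand$i2[r])
    }
  }
  cand[keep, , drop = FALSE]
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_pattern_string <- function(len, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bits <- rep(0L, len)
  bits[1] <- 1L
  if (w > 1) bits[sample(2:len, w - 1)] <- 1L
  paste(bits, collapse = "")
}
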