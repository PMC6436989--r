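# Indel-free protein pair simulation under 20-state continuous-time Markov
# substitution models, plus the alignment-based Kimura oracle used as the
# "true" distance in accuracy evaluations.

#' RateModel: a scaled amino-acid substitution model
#'
#' A reversible 20-state continuous-time Markov model given by symmetric
#' exchangeabilities and stationary frequencies, with the generator scaled
#' so that the expected number of substitutions per site per unit time is 1
#' (so the time parameter *is* the distance in substitutions per site).
#' The spectral decomposition of the pi-symmetrized generator is
#' precomputed so transition matrices for arbitrary distances are cheap.
#'
#' @slot name `"jtt"` or `"poisson"`.
#' @slot frequencies stationary frequencies (sum 1).
#' @slot generator scaled generator matrix Q (rows sum to 0).
#' @slot eigenValues,eigenVectors spectral decomposition of
#'   \eqn{\Pi^{1/2} Q \Pi^{-1/2}}.
#' @export
setClass("RateModel",
         representation(name = "character", frequencies = "numeric",
                        generator = "matrix", eigenValues = "numeric",
                        eigenVectors = "matrix"))

setValidity("RateModel", function(object) {
  pi <- object@frequencies
  Q <- object@generator
  if (length(pi) != 20L || abs(sum(pi) - 1) > 1e-8) {
    return("frequencies must be 20 values summing to 1")
  }
  if (max(abs(rowSums(Q))) > 1e-8) return("generator rows must sum to 0")
  if (abs(sum(pi * -diag(Q)) - 1) > 1e-8) {
    return("generator must be scaled to 1 expected substitution per site")
  }
  TRUE
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel '%s' (20 states, scaled to 1 substitution/site/unit time)\n",
              object@name))
})

#' Construct a substitution rate model
#'
#' `"jtt"` uses the amino-acid replacement model of Jones, Taylor &
#' Thornton (1992) (exchangeabilities and stationary frequencies embedded
#' as published constants). `"poisson"` is the uniform-rate, uniform-
#' frequency model; it admits a closed form for the mismatch fraction,
#' \eqn{E[p] = \frac{19}{20}(1 - e^{-20 d / 19})}, and exists mainly for
#' exact testing.
#'
#' @param name `"jtt"` (default) or `"poisson"`.
#' @return a [RateModel-class].
#' @export
#' @examples
#' rateModel("poisson")
rateModel <- function(name = c("jtt", "poisson")) {
  name <- match.arg(name)
  if (name == "jtt") {
    S <- matrix(0, 20L, 20L)
    S[lower.tri(S)] <- .jtt_exchangeabilities
    S <- S + t(S)
    pi <- .jtt_frequencies / sum(.jtt_frequencies)
  } else {
    S <- matrix(1, 20L, 20L)
    diag(S) <- 0
    pi <- rep(1 / 20, 20L)
  }
  Q <- S * rep(pi, each = 20L)      # Q_ab = S_ab * pi_b for a != b
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- sum(pi * -diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(AA_ORDER, AA_ORDER)
  sp <- sqrt(pi)
  B <- Q * outer(sp, 1 / sp)        # symmetric for a reversible model
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  new("RateModel", name = name, frequencies = pi, generator = Q,
      eigenValues = eig$values, eigenVectors = eig$vectors)
}

#' Transition probability matrix of a rate model
#'
#' Computes \eqn{P(d) = \exp(Q d)} from the precomputed spectral
#' decomposition of the scaled generator.
#'
#' @param model a [RateModel-class].
#' @param d distance (substitutions per site), `d >= 0`.
#' @return 20x20 stochastic matrix.
#' @export
transitionMatrix <- function(model, d) {
  stopifnot(d >= 0)
  sp <- sqrt(model@frequencies)
  U <- model@eigenVectors
  P <- outer(1 / sp, sp) * (U %*% (exp(model@eigenValues * d) * t(U)))
  P[P < 0] <- 0                     # clip floating-point noise
  P / rowSums(P)
}

#' Expected mismatch fraction at a given distance
#'
#' The model's p-versus-d curve: \eqn{E[p](d) = 1 - \sum_a \pi_a P_{aa}(d)}.
#'
#' @param model a [RateModel-class].
#' @param d distance(s).
#' @return expected mismatch fraction(s).
#' @export
expectedMismatch <- function(model, d) {
  vapply(d, function(dd) {
    1 - sum(model@frequencies * diag(transitionMatrix(model, dd)))
  }, numeric(1))
}

#' Simulate an aligned, indel-free protein sequence pair
#'
#' Draws the first sequence site-wise from the model's stationary
#' frequencies and evolves every site independently for time `d` using the
#' transition matrix \eqn{\exp(Qd)}. The two sequences are equal length and
#' indel-free, so their alignment is the identity; `d = 0` returns an exact
#' copy. Reproducible for a fixed seed.
#'
#' @param length number of residues.
#' @param d distance in substitutions per site (`>= 0`).
#' @param model a [RateModel-class] (default JTT).
#' @param seed integer RNG seed.
#' @return list with residue strings `seq1`, `seq2` and the generator
#'   distance `d`.
#' @export
#' @examples
#' sp <- simulatePair(100, 0.3, rateModel("poisson"), seed = 1)
#' nchar(sp$seq1)
simulatePair <- function(length, d, model = rateModel("jtt"), seed = 1L) {
  stopifnot(length >= 1, d >= 0)
  withSeed(seed, {
    s1 <- sample.int(20L, length, replace = TRUE, prob = model@frequencies)
    s2 <- if (d == 0) {
      s1
    } else {
      P <- transitionMatrix(model, d)
      out <- integer(length)
      for (a in seq_len(20L)) {
        idx <- which(s1 == a)
        if (base::length(idx)) {
          out[idx] <- sample.int(20L, base::length(idx), replace = TRUE,
                                 prob = P[a, ])
        }
      }
      out
    }
    list(seq1 = paste(AA_ORDER[s1], collapse = ""),
         seq2 = paste(AA_ORDER[s2], collapse = ""),
         d = d)
  })
}

#' Alignment-based Kimura distance oracle
#'
#' For an aligned, equal-length sequence pair (such as simulator output,
#' whose alignment is the identity), computes the per-column mismatch
#' fraction and applies [kimuraDistance()]. This is the reference
#' ("true") distance the spaced-word estimator is evaluated against, the
#' same quantity PHYLIP's protdist reports under the Kimura model.
#'
#' @param seq1,seq2 equal-length residue strings.
#' @return Kimura distance (`NA` with a warning when saturated).
#' @export
#' @examples
#' alignmentKimuraOracle("ACDEF", "ACDEW") # p = 0.2
alignmentKimuraOracle <- function(seq1, seq2) {
  a <- encodeResidues(seq1)
  b <- encodeResidues(seq2)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no comparable columns")
  p <- sum(a[ok] != b[ok]) / sum(ok)
  kimuraDistance(p)
}

#' Accuracy sweep: estimator versus alignment oracle over a distance grid
#'
#' For every distance on the grid, simulates `replicates` independent
#' aligned pairs, runs the full spaced-word estimator (pattern set
#' optimized once per sweep with the given shape, shared by all
#' replicates) and the alignment-based Kimura oracle on each pair, and
#' tabulates means and standard deviations. This is the package's
#' simulation-based evaluation protocol.
#'
#' @param dGrid distances to simulate at.
#' @param length sequence length per pair (default 20000).
#' @param replicates pairs per grid point (default 20).
#' @param m,weight,patternLength pattern set shape (defaults 5, 6, 46).
#' @param threshold score threshold `T` (default 0).
#' @param model a [RateModel-class] (default JTT).
#' @param seed integer seed controlling pattern optimization and all
#'   simulated pairs.
#' @return data.frame: `d_generator`, `mean_dhat`, `sd_dhat`,
#'   `mean_oracle`, `sd_oracle`, `n_ok` (replicates with status `ok`).
#' @export
runAccuracySweep <- function(dGrid, length = 20000L, replicates = 20L,
                             m = 5L, weight = 6L, patternLength = 46L,
                             threshold = 0, model = rateModel("jtt"),
                             seed = 42L) {
  ps <- generatePatternSet(m = m, weight = weight, length = patternLength,
                           seed = seed)
  pair_seeds <- withSeed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L,
                      base::length(dGrid) * replicates),
           nrow = replicates)
  })
  mat <- blosum62()
  rows <- lapply(seq_along(dGrid), function(gi) {
    d <- dGrid[gi]
    dhat <- numeric(replicates)
    dora <- numeric(replicates)
    ok <- logical(replicates)
    for (r in seq_len(replicates)) {
      sp <- simulatePair(length, d, model, seed = pair_seeds[r, gi])
      p1 <- proteome(c(s1 = sp$seq1), "A")
      p2 <- proteome(c(s2 = sp$seq2), "B")
      cmp <- compareProteomes(p1, p2, ps, mat, threshold)
      est <- estimatePairDistance(cmp)
      dhat[r] <- est$d
      ok[r] <- est$status == "ok"
      dora[r] <- suppressWarnings(alignmentKimuraOracle(sp$seq1, sp$seq2))
    }
    data.frame(d_generator = d,
               mean_dhat = mean(dhat[ok]),
               sd_dhat = stats::sd(dhat[ok]),
               mean_oracle = mean(dora, na.rm = TRUE),
               sd_oracle = stats::sd(dora, na.rm = TRUE),
               n_ok = sum(ok))
  })
  do.call(rbind, rows)
}
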