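#' End-to-end distance pipeline
#'
#' Orchestrates the whole analysis for a set of proteome FASTA files:
#' pattern-set generation (or loading), pairwise spaced-word comparison,
#' Kimura-corrected distance matrix assembly, optional PHYLIP/spamogram
#' output and an optional neighbor-joining tree. The run is fully
#' deterministic for a fixed configuration and seed, and its output does
#' not depend on `threads`.
#'
#' Defaults follow the method's published parameterization: patterns of
#' weight 6 with 40 don't-care positions (length 46), sets of m = 5
#' patterns, and score threshold T = 0.
#'
#' @param inputs character vector of FASTA paths (or one directory), or a
#'   list of [Proteome-class] objects.
#' @param weight match positions per pattern (default 6).
#' @param dontcare don't-care positions per pattern (default 40).
#' @param m number of patterns (default 5).
#' @param threshold score threshold T (default 0).
#' @param seed integer seed for pattern optimization (default 42; pass a
#'   random value to emulate run-to-run pattern variability).
#' @param threads worker processes for independent pairs (default 1).
#' @param taxonNames optional labels overriding file basenames.
#' @param patternsFile optional pattern file; when given, pattern
#'   generation is skipped and the file's patterns are used.
#' @param outMatrix optional path for the PHYLIP distance matrix.
#' @param outTree optional path for the Newick NJ tree (needs >= 3 taxa).
#' @param spamogramDir optional directory for per-pair spamogram TSVs.
#' @param strictPhylip use strict 10-character PHYLIP names.
#' @param maxDistance ceiling assigned to unestimable pairs (default 10).
#' @param clampNegative set negative NJ branch lengths to zero.
#' @param verbose log configuration and per-pair summaries via `message()`.
#' @return (invisibly) list with `distances` (a
#'   [SpacedDistanceMatrix-class]), `tree` (`ape::phylo` or `NULL`) and
#'   `patternSet`.
#' @export
runDistancePipeline <- function(inputs,
                                weight = 6L, dontcare = 40L, m = 5L,
                                threshold = 0, seed = 42L, threads = 1L,
                                taxonNames = NULL, patternsFile = NULL,
                                outMatrix = NULL, outTree = NULL,
                                spamogramDir = NULL, strictPhylip = FALSE,
                                maxDistance = 10, clampNegative = FALSE,
                                verbose = TRUE) {
  log <- function(...) if (verbose) message(...)
  proteomes <- if (is.list(inputs) && all(vapply(inputs, is, logical(1),
                                                 "Proteome"))) {
    inputs
  } else {
    readProteomes(inputs, names = taxonNames)
  }
  if (length(proteomes) < 2L) stop("need at least two proteomes")
  log(sprintf("swphylo %s | taxa=%d w=%d dontcare=%d m=%d T=%s seed=%d threads=%d",
              as.character(utils::packageVersion("swphylo")),
              length(proteomes), weight, dontcare, m,
              format(threshold), seed, threads))
  ps <- if (!is.null(patternsFile)) {
    out <- readPatterns(patternsFile)
    log("patterns supplied via file (generation skipped):")
    out
  } else {
    generatePatternSet(m = m, weight = weight, length = weight + dontcare,
                       seed = seed)
  }
  for (s in patternString(ps)) log("  pattern ", s)
  sdm <- distanceMatrix(proteomes, ps, threshold = threshold,
                        ceiling = maxDistance, threads = threads,
                        spamogramDir = spamogramDir)
  rep <- pairReport(sdm)
  for (i in seq_len(nrow(rep))) {
    log(sprintf("  %s / %s: %d matches, p=%s, d=%s%s",
                rep$taxon1[i], rep$taxon2[i], rep$n_matches[i],
                format(rep$p[i], digits = 4), format(rep$d[i], digits = 4),
                if (rep$status[i] != "ok") paste0(" [", rep$status[i], "]")
                else ""))
  }
  if (!is.null(outMatrix)) {
    writePhylip(sdm, outMatrix, strict = strictPhylip)
    log("wrote distance matrix: ", outMatrix)
  }
  tree <- NULL
  if (nrow(distances(sdm)) >= 3L) {
    tree <- neighborJoining(sdm, clampNegative = clampNegative)
    if (!is.null(outTree)) {
      writeNewick(tree, outTree)
      log("wrote tree: ", outTree)
    }
  } else if (!is.null(outTree)) {
    log("fewer than 3 taxa; no tree written")
  }
  invisible(list(distances = sdm, tree = tree, patternSet = ps))
}
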