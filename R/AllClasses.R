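#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

#' SpacedPattern: a binary match/don't-care pattern
#'
#' A binary pattern of length \eqn{\ell} over \{match, don't-care\}; the
#' number of match positions is its weight \eqn{w}. A spaced word with
#' respect to the pattern carries residues only at the match positions.
#' Patterns used in sets are kept in canonical form: position 1 is a match
#' position (shift-equivalent duplicates are thereby removed); trailing
#' positions may be don't-care because don't-care columns carry scoring
#' information.
#'
#' @slot bits logical vector; `TRUE` = match position, `FALSE` = don't-care.
#' @export
setClass("SpacedPattern", representation(bits = "logical"))

setValidity("SpacedPattern", function(object) {
  b <- object@bits
  if (length(b) < 1L) return("pattern must have length >= 1")
  if (anyNA(b)) return("pattern bits must not contain NA")
  if (sum(b) < 1L) return("pattern must have weight >= 1")
  TRUE
})

#' SpacedPatternSet: a set of patterns of common length and weight
#'
#' A set \eqn{\mathcal{P} = \{P_1, \dots, P_m\}} of distinct binary patterns
#' sharing one length and one weight, as used to pool spaced-word matches
#' over several match-position layouts.
#'
#' @slot patterns list of [SpacedPattern-class] objects.
#' @slot seed integer seed used for generation (`NA` for hand-built sets).
#' @export
setClass("SpacedPatternSet",
         representation(patterns = "list", seed = "integer"),
         prototype(seed = NA_integer_))

setValidity("SpacedPatternSet", function(object) {
  ps <- object@patterns
  if (length(ps) < 1L) return("pattern set must contain at least one pattern")
  if (!all(vapply(ps, is, logical(1), "SpacedPattern"))) {
    return("all elements must be SpacedPattern objects")
  }
  lens <- vapply(ps, function(p) length(p@bits), integer(1))
  wts <- vapply(ps, function(p) sum(p@bits), integer(1))
  if (length(unique(lens)) != 1L) return("all patterns must share one length")
  if (length(unique(wts)) != 1L) return("all patterns must share one weight")
  if (!all(vapply(ps, function(p) p@bits[1L], logical(1)))) {
    return("patterns in a set must be canonical (position 1 is a match position)")
  }
  keys <- vapply(ps, function(p) paste(as.integer(p@bits), collapse = ""),
                 character(1))
  if (anyDuplicated(keys)) return("patterns must be pairwise distinct")
  TRUE
})

#' Proteome: one taxon's protein sequences
#'
#' All protein sequences of one taxon (a complete or incomplete proteome)
#' over the 20-letter amino-acid alphabet. Non-canonical residues are kept
#' in place but flagged ambiguous: any spaced-word window containing one is
#' excluded from extraction and scoring, so coordinates are never shifted.
#'
#' @slot taxonName single sanitized taxon label.
#' @slot sequences an [Biostrings::AAStringSet] holding the records.
#' @slot codes list of integer vectors (1..20, `NA` = ambiguous), one per
#'   sequence; the precomputed encoding used by the matching engine.
#' @export
setClass("Proteome",
         representation(taxonName = "character",
                        sequences = "AAStringSet",
                        codes = "list"))

setValidity("Proteome", function(object) {
  if (length(object@taxonName) != 1L || !nzchar(object@taxonName)) {
    return("taxonName must be a single non-empty string")
  }
  if (length(object@sequences) < 1L) return("proteome must contain >= 1 sequence")
  if (any(Biostrings::width(object@sequences) == 0L)) {
    return("proteome contains an empty sequence record")
  }
  if (length(object@codes) != length(object@sequences)) {
    return("codes and sequences differ in length")
  }
  TRUE
})

#' SpacedDistanceMatrix: pairwise distances with estimation status
#'
#' A symmetric matrix of Kimura-corrected pairwise distances (substitutions
#' per site) with a per-cell status flag: `"ok"`, `"no_matches"` (no
#' spaced-word match survived filtering; distance set to the configured
#' ceiling) or `"saturated"` (mismatch fraction beyond the Kimura domain;
#' ceiling used as well).
#'
#' @slot distances numeric symmetric matrix, zero diagonal, taxon names on
#'   both dimnames.
#' @slot status character matrix of the same shape.
#' @slot pairs data.frame with one row per unordered pair: taxon1, taxon2,
#'   n_matches, columns, mismatches, p, d, status.
#' @export
setClass("SpacedDistanceMatrix",
         representation(distances = "matrix", status = "matrix",
                        pairs = "data.frame"))

setValidity("SpacedDistanceMatrix", function(object) {
  d <- object@distances
  if (nrow(d) != ncol(d)) return("matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    return("dimnames must be identical taxon names on rows and columns")
  }
  if (anyDuplicated(rownames(d))) return("taxon names must be unique")
  if (!isTRUE(all.equal(d, t(d)))) return("matrix must be symmetric")
  if (any(diag(d) != 0)) return("diagonal must be zero")
  if (any(d < 0)) return("distances must be nonnegative")
  if (!identical(dim(object@status), dim(d))) {
    return("status matrix must match distance matrix shape")
  }
  TRUE
})
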