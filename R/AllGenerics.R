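#' @rdname patternAccessors
#' @export
setGeneric("patternLength", function(x) standardGeneric("patternLength"))

#' @rdname patternAccessors
#' @export
setGeneric("patternWeight", function(x) standardGeneric("patternWeight"))

#' @rdname patternAccessors
#' @export
setGeneric("patternString", function(x) standardGeneric("patternString"))

#' @rdname patternAccessors
#' @export
setGeneric("matchPositions", function(x) standardGeneric("matchPositions"))

#' @rdname overlapComplexity
#' @export
setGeneric("overlapComplexity", function(x, y) standardGeneric("overlapComplexity"))

#' @rdname proteomeAccessors
#' @export
setGeneric("taxonName", function(x) standardGeneric("taxonName"))

#' @rdname proteomeAccessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname distanceAccessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname distanceAccessors
#' @export
setGeneric("pairStatus", function(x) standardGeneric("pairStatus"))

#' @rdname distanceAccessors
#' @export
setGeneric("pairReport", function(x) standardGeneric("pairReport"))

## ---- pattern accessors ------------------------------------------------

#' Accessors for spaced patterns and pattern sets
#'
#' `patternLength` returns \eqn{\ell}, `patternWeight` the number of match
#' positions \eqn{w}, `patternString` the 0/1 text form (1 = match) and
#' `matchPositions` the 1-based match-position indices.
#'
#' @param x a [SpacedPattern-class] or [SpacedPatternSet-class].
#' @return integer scalar(s) or character vector as appropriate.
#' @name patternAccessors
#' @examples
#' p <- spacedPattern("1100101")
#' patternWeight(p) # 4
NULL

#' @rdname patternAccessors
setMethod("patternLength", "SpacedPattern", function(x) length(x@bits))
#' @rdname patternAccessors
setMethod("patternWeight", "SpacedPattern", function(x) sum(x@bits))
#' @rdname patternAccessors
setMethod("patternString", "SpacedPattern",
          function(x) paste(as.integer(x@bits), collapse = ""))
#' @rdname patternAccessors
setMethod("matchPositions", "SpacedPattern", function(x) which(x@bits))

#' @rdname patternAccessors
setMethod("patternLength", "SpacedPatternSet",
          function(x) patternLength(x@patterns[[1L]]))
#' @rdname patternAccessors
setMethod("patternWeight", "SpacedPatternSet",
          function(x) patternWeight(x@patterns[[1L]]))
#' @rdname patternAccessors
setMethod("patternString", "SpacedPatternSet",
          function(x) vapply(x@patterns, patternString, character(1)))

#' Number of patterns in a set
#' @param x a [SpacedPatternSet-class].
#' @export
setMethod("length", "SpacedPatternSet", function(x) length(x@patterns))

#' Extract one pattern from a set
#' @param x a [SpacedPatternSet-class].
#' @param i index.
#' @param j,... unused.
#' @export
setMethod("[[", "SpacedPatternSet", function(x, i, j, ...) x@patterns[[i]])

setMethod("show", "SpacedPattern", function(object) {
  cat("SpacedPattern  ", patternString(object),
      sprintf("  (length %d, weight %d)\n",
              patternLength(object), patternWeight(object)))
})

setMethod("show", "SpacedPatternSet", function(object) {
  cat(sprintf("SpacedPatternSet of %d pattern(s), length %d, weight %d\n",
              length(object), patternLength(object), patternWeight(object)))
  for (s in patternString(object)) cat(" ", s, "\n")
  if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
})

## ---- proteome accessors -----------------------------------------------

#' Accessors for proteomes
#'
#' `taxonName` returns the taxon label; `totalLength` the summed residue
#' count over all records (ambiguous residues included — flagging never
#' deletes positions).
#'
#' @param x a [Proteome-class].
#' @name proteomeAccessors
NULL

#' @rdname proteomeAccessors
setMethod("taxonName", "Proteome", function(x) x@taxonName)
#' @rdname proteomeAccessors
setMethod("totalLength", "Proteome",
          function(x) sum(Biostrings::width(x@sequences)))

#' Number of sequences in a proteome
#' @param x a [Proteome-class].
#' @export
setMethod("length", "Proteome", function(x) length(x@sequences))

setMethod("show", "Proteome", function(object) {
  n_amb <- sum(vapply(object@codes, function(z) sum(is.na(z)), integer(1)))
  cat(sprintf("Proteome '%s': %d sequence(s), %d residues (%d ambiguous)\n",
              taxonName(object), length(object), totalLength(object), n_amb))
})

## ---- distance matrix accessors ----------------------------------------

#' Accessors for distance matrices
#'
#' `distances` returns the numeric symmetric matrix, `pairStatus` the
#' per-cell status flags and `pairReport` the long-format per-pair table
#' (match counts, pooled columns/mismatches, p, d, status).
#'
#' @param x a [SpacedDistanceMatrix-class].
#' @name distanceAccessors
NULL

#' @rdname distanceAccessors
setMethod("distances", "SpacedDistanceMatrix", function(x) x@distances)
#' @rdname distanceAccessors
setMethod("pairStatus", "SpacedDistanceMatrix", function(x) x@status)
#' @rdname distanceAccessors
setMethod("pairReport", "SpacedDistanceMatrix", function(x) x@pairs)

#' Number of taxa in a distance matrix
#' @param x a [SpacedDistanceMatrix-class].
#' @export
setMethod("dim", "SpacedDistanceMatrix", function(x) dim(x@distances))

setMethod("show", "SpacedDistanceMatrix", function(object) {
  n <- nrow(object@distances)
  flagged <- sum(object@pairs$status != "ok")
  cat(sprintf("SpacedDistanceMatrix: %d taxa, %d pair(s)%s\n",
              n, nrow(object@pairs),
              if (flagged) sprintf(", %d flagged", flagged) else ""))
  print(round(object@distances, 4))
})
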