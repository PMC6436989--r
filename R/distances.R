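#' Kimura correction for protein distances
#'
#' Converts a mismatch fraction \eqn{p} into an estimate of substitutions
#' per site via the Kimura approximation of the PAM distance,
#' \deqn{d = -\ln(1 - p - 0.2 p^2),}
#' the same closed form used by PHYLIP's protdist with the Kimura option.
#' The formula is defined for \eqn{p} below the positive root of
#' \eqn{1 - p - 0.2 p^2 = 0} (about 0.8541); at or beyond that root the
#' distance is saturated and `NA` is returned with a warning (callers encode
#' this as a `saturated` status).
#'
#' @param p mismatch fraction(s) in `[0, 1]`.
#' @return numeric vector of distances; `NA` where saturated.
#' @export
#' @examples
#' kimuraDistance(0.2) # -log(0.792)
kimuraDistance <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  arg <- 1 - p - 0.2 * p^2
  out <- ifelse(arg > 0, -log(arg), NA_real_)
  # clamp tiny negative zero from floating point at p = 0
  out[p == 0] <- 0
  if (anyNA(out)) warning("mismatch fraction at or beyond saturation (p >= ",
                          format(kimuraSaturation(), digits = 6), ")")
  out
}

#' Saturation point of the Kimura correction
#'
#' The positive root of \eqn{1 - p - 0.2 p^2 = 0}; mismatch fractions at or
#' above it have no finite Kimura distance.
#'
#' @return a number, about 0.85410.
#' @export
kimuraSaturation <- function() {
  (sqrt(1.8) - 1) / 0.4
}

#' Estimate the distance of one proteome pair from its selected matches
#'
#' Pools the don't-care columns of all selected spaced-word matches of all
#' patterns, computes the pooled mismatch fraction
#' \eqn{p = \mathrm{mismatches} / \mathrm{columns}} and applies
#' [kimuraDistance()]. Pairs with no selected matches get status
#' `no_matches`, saturated pairs get status `saturated`; in both cases the
#' distance is set to `ceiling` so heterogeneous datasets still yield a
#' complete matrix (the flag is preserved).
#'
#' @param comparison result of [compareProteomes()].
#' @param ceiling distance assigned to unestimable pairs (default 10).
#' @return list: `taxon1`, `taxon2`, `n_matches`, `columns`, `mismatches`,
#'   `p`, `d`, `status`.
#' @export
estimatePairDistance <- function(comparison, ceiling = 10) {
  m <- comparison$matches
  n_matches <- nrow(m)
  columns <- n_matches * comparison$dontcareColumns
  mismatches <- sum(m$mismatches)
  if (n_matches == 0L || columns == 0L) {
    return(list(taxon1 = comparison$taxa[1L], taxon2 = comparison$taxa[2L],
                n_matches = n_matches, columns = columns,
                mismatches = mismatches, p = NA_real_, d = ceiling,
                status = "no_matches"))
  }
  p <- mismatches / columns
  d <- suppressWarnings(kimuraDistance(p))
  if (is.na(d)) {
    return(list(taxon1 = comparison$taxa[1L], taxon2 = comparison$taxa[2L],
                n_matches = n_matches, columns = columns,
                mismatches = mismatches, p = p, d = ceiling,
                status = "saturated"))
  }
  list(taxon1 = comparison$taxa[1L], taxon2 = comparison$taxa[2L],
       n_matches = n_matches, columns = columns, mismatches = mismatches,
       p = p, d = d, status = "ok")
}

#' Pairwise distance matrix over a set of proteomes
#'
#' Computes all unordered pairwise distances between the given proteomes:
#' each pair is compared once (oriented by taxon name), matches are pooled
#' over all patterns, and the pooled mismatch fraction is Kimura-corrected.
#' The result is symmetric with zero diagonal by construction and is
#' invariant to the input order of the taxa (up to simultaneous row/column
#' permutation) and to the number of worker threads.
#'
#' @param proteomes list of at least two [Proteome-class] objects with
#'   distinct taxon names.
#' @param patternSet a [SpacedPatternSet-class].
#' @param scoringMatrix substitution matrix (default [blosum62()]).
#' @param threshold score threshold `T` (default 0).
#' @param ceiling distance for unestimable pairs (default 10).
#' @param threads number of worker processes for independent pairs
#'   (default 1; results are identical for any value).
#' @param spamogramDir if non-`NULL`, a directory into which one spamogram
#'   TSV per pair is written (`<taxon1>__<taxon2>.tsv`).
#' @return a [SpacedDistanceMatrix-class].
#' @export
distanceMatrix <- function(proteomes, patternSet,
                           scoringMatrix = blosum62(), threshold = 0,
                           ceiling = 10, threads = 1L, spamogramDir = NULL) {
  if (length(proteomes) < 2L) stop("need at least two proteomes")
  nms <- vapply(proteomes, taxonName, character(1))
  if (anyDuplicated(nms)) stop("duplicate taxon names")
  n <- length(proteomes)
  pair_idx <- utils::combn(n, 2L, simplify = FALSE)
  if (!is.null(spamogramDir) && !dir.exists(spamogramDir)) {
    dir.create(spamogramDir, recursive = TRUE)
  }
  run_one <- function(ij) {
    cmp <- compareProteomes(proteomes[[ij[1L]]], proteomes[[ij[2L]]],
                            patternSet, scoringMatrix, threshold)
    if (!is.null(spamogramDir)) {
      writeSpamogram(cmp, file.path(spamogramDir,
                                    paste0(cmp$taxa[1L], "__", cmp$taxa[2L],
                                           ".tsv")))
    }
    estimatePairDistance(cmp, ceiling)
  }
  results <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(pair_idx, run_one, mc.cores = threads)
  } else {
    lapply(pair_idx, run_one)
  }
  dm <- matrix(0, n, n, dimnames = list(nms, nms))
  st <- matrix("ok", n, n, dimnames = list(nms, nms))
  for (k in seq_along(pair_idx)) {
    ij <- pair_idx[[k]]
    r <- results[[k]]
    dm[ij[1L], ij[2L]] <- dm[ij[2L], ij[1L]] <- r$d
    st[ij[1L], ij[2L]] <- st[ij[2L], ij[1L]] <- r$status
    if (r$status != "ok") {
      warning(sprintf("pair %s / %s: %s; distance set to ceiling %.3g",
                      r$taxon1, r$taxon2, r$status, ceiling))
    }
  }
  pairs <- do.call(rbind, lapply(results, function(r) {
    data.frame(taxon1 = r$taxon1, taxon2 = r$taxon2,
               n_matches = r$n_matches, columns = r$columns,
               mismatches = r$mismatches, p = r$p, d = r$d,
               status = r$status, stringsAsFactors = FALSE)
  }))
  new("SpacedDistanceMatrix", distances = dm, status = st, pairs = pairs)
}

#' @importFrom parallel mclapply
NULL

#' Write a distance matrix in square PHYLIP format
#'
#' First line is the taxon count; each following line is a taxon name and
#' its full row of distances rendered with six decimals. By default names
#' are written in full (relaxed PHYLIP); `strict = TRUE` pads or truncates
#' names to 10 characters and fails on a name collision after truncation.
#'
#' @param x a [SpacedDistanceMatrix-class] or plain symmetric matrix with
#'   dimnames.
#' @param path output path.
#' @param strict use the strict 10-character name field (default `FALSE`).
#' @return `path`, invisibly.
#' @export
writePhylip <- function(x, path, strict = FALSE) {
  m <- if (is(x, "SpacedDistanceMatrix")) distances(x) else x
  nms <- rownames(m)
  if (strict) {
    nms <- sprintf("%-10.10s", nms)
    if (anyDuplicated(nms)) {
      stop("taxon name collision after truncation to 10 characters")
    }
    nms <- paste0(nms, "  ")
  } else {
    nms <- sprintf("%s  ", nms)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(nms[i], paste(sprintf("%.6f", m[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path path to a square-format PHYLIP distance file.
#' @return numeric matrix with taxon dimnames.
#' @export
readPhylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  rows <- lines[1L + seq_len(n)]
  nms <- character(n)
  vals <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(rows[i]), "[[:space:]]+")[[1L]]
    nms[i] <- f[1L]
    vals[i, ] <- as.numeric(f[-1L])
  }
  nms <- trimws(nms)
  dimnames(vals) <- list(nms, nms)
  vals
}

#' Write the long-format per-pair report as TSV
#'
#' One row per unordered pair: taxon1, taxon2, n_matches, columns,
#' mismatches, p, d, status.
#'
#' @param x a [SpacedDistanceMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePairReport <- function(x, path) {
  utils::write.table(pairReport(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
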