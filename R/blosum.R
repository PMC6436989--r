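# BLOSUM62 scoring matrix, read from the plain-text copy shipped with the
# package (inst/extdata/blosum62.txt, the NCBI standard half-bit scores).

.blosum_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Returns the 20x20 integer BLOSUM62 matrix in the package's canonical
#' residue order, loaded once from the plain-text copy shipped with the
#' package. The matrix is symmetric and every diagonal entry is at least as
#' large as every off-diagonal entry in its row (both asserted at load).
#' Spaced-word match scores are sums of these entries over the don't-care
#' columns of the match.
#'
#' @return symmetric 20x20 integer matrix with residue dimnames.
#' @export
#' @examples
#' blosum62()["C", "W"] # -2
blosum62 <- function() {
  if (!is.null(.blosum_cache$mat)) return(.blosum_cache$mat)
  path <- system.file("extdata", "blosum62.txt", package = "swphylo",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  stopifnot(identical(header, AA_ORDER))
  rows <- lapply(lines[-1L], function(l) {
    f <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
    as.integer(f[-1L])
  })
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(AA_ORDER, AA_ORDER)
  stopifnot(identical(mat, t(mat)),
            all(diag(mat) >= apply(mat - diag(diag(mat)), 1L, max)))
  .blosum_cache$mat <- mat
  mat
}
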