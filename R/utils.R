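# Shared internals: residue alphabet, integer encoding, small helpers.

# Canonical residue order used throughout the package (PAML convention);
# BLOSUM62 and the substitution models are stored in this order.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# 256-slot lookup: byte value of an (uppercased) residue -> code 1..20,
# NA for everything non-canonical (B, J, O, U, X, Z, *, -, ., digits, ...).
.aa_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(AA_ORDER, collapse = "")) + 1L] <- seq_len(20L)
  lut
})

#' Encode a residue string as integer codes
#'
#' Maps each character to its index in the canonical 20-letter amino-acid
#' alphabet; ambiguous or non-canonical characters (B, J, O, U, X, Z, stop,
#' gap, ...) become `NA` so that positions are preserved and coordinates stay
#' stable.
#'
#' @param x a single character string (uppercased internally).
#' @return integer vector of codes in 1..20 with `NA` at ambiguous positions.
#' @keywords internal
#' @noRd
encodeResidues <- function(x) {
  .aa_lut[utf8ToInt(toupper(x)) + 1L]
}

decodeResidues <- function(codes) {
  out <- rep("X", length(codes))
  ok <- !is.na(codes)
  out[ok] <- AA_ORDER[codes[ok]]
  paste(out, collapse = "")
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so package functions never disturb the
# user's random stream.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' `round()` in R rounds half to even; published tables conventionally round
#' half up, so relative Robinson-Foulds values are rendered with this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(0.1875, 2) # 0.19
roundHalfUp <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Sanitize a taxon name for PHYLIP/Newick output
#'
#' Replaces whitespace and the characters `:;(),'` (which have syntactic
#' meaning in Newick and PHYLIP files) with underscores.
#'
#' @param x character vector of names.
#' @return sanitized character vector.
#' @export
sanitizeTaxonName <- function(x) {
  gsub("[[:space:]:;(),']", "_", x)
}
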