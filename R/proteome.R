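#' Construct a proteome from residue strings
#'
#' @param sequences named or unnamed character vector of residue strings.
#' @param taxonName single taxon label; sanitized for downstream PHYLIP and
#'   Newick output.
#' @return a [Proteome-class].
#' @export
#' @examples
#' pr <- proteome(c(s1 = "ACDEF", s2 = "WXYVW"), "toy")
#' totalLength(pr) # 10
proteome <- function(sequences, taxonName) {
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop("empty sequence record")
  # AAStringSet rejects characters outside its alphabet; keep ambiguity
  # classes by mapping anything non-canonical and non-IUPAC to X first
  safe <- vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1L]]
    bad <- !(ch %in% c(AA_ORDER, "B", "J", "O", "U", "X", "Z", "*", "-", "."))
    ch[bad] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  aas <- Biostrings::AAStringSet(safe)
  names(aas) <- if (!is.null(names(sequences))) names(sequences) else
    paste0("seq", seq_along(sequences))
  codes <- lapply(sequences, encodeResidues)
  names(codes) <- NULL
  new("Proteome", taxonName = sanitizeTaxonName(taxonName),
      sequences = aas, codes = codes)
}

#' Read a proteome from a multi-FASTA file
#'
#' Reads every record of a (plain or gzipped) protein FASTA file into a
#' [Proteome-class]. Record order is preserved and characters are
#' uppercased. The 20 canonical residues are kept; anything else (B, J, O,
#' U, X, Z, stop `*`, gaps, unknown symbols) is flagged ambiguous but never
#' deleted, so sequence coordinates are stable. Windows containing an
#' ambiguous residue are later excluded from spaced-word extraction.
#'
#' @param path path to a FASTA file with at least one record.
#' @param name optional taxon label; defaults to the file basename without
#'   extension.
#' @return a [Proteome-class].
#' @export
readProteome <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read proteome file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in ", path)
  if (any(Biostrings::width(aas) == 0L)) {
    stop("record with empty sequence in ", path)
  }
  if (is.null(name)) {
    name <- sub("\\.(fa|fasta|faa|fas)(\\.gz)?$", "", basename(path),
                ignore.case = TRUE)
    name <- sub("\\.gz$", "", name)
  }
  seqs <- as.character(aas)
  names(seqs) <- names(aas)
  proteome(seqs, name)
}

#' Read a set of proteome files
#'
#' @param paths character vector of FASTA paths, or a single directory whose
#'   `*.fa/*.fasta/*.faa` files are read (one taxon per file).
#' @param names optional taxon labels matching `paths`.
#' @return list of [Proteome-class] objects with unique taxon names.
#' @export
readProteomes <- function(paths, names = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.(fa|fasta|faa|fas)(\\.gz)?$",
                             full.names = TRUE, ignore.case = TRUE))
  }
  if (length(paths) < 1L) stop("no proteome files found")
  out <- lapply(seq_along(paths), function(i) {
    readProteome(paths[i], name = if (is.null(names)) NULL else names[i])
  })
  nms <- vapply(out, taxonName, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate taxon names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  out
}

#' Write a proteome to FASTA
#'
#' @param x a [Proteome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(x, path) {
  Biostrings::writeXStringSet(x@sequences, path)
  invisible(path)
}
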