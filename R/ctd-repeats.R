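#' Decompose a CTD sequence into heptad repeats
#'
#' Splits the C-terminal domain of the RNA polymerase II large subunit into
#' consecutive non-overlapping 7-mers starting at `start_offset` (0-based
#' residues into the supplied sequence).  The mammalian consensus heptad is
#' `YSPTSPS`; position-7 substitutions — most notably lysine (K7) — are the
#' non-consensus residues of interest.  A trailing remainder shorter than 7
#' residues is reported via the `remainder` attribute, not as a repeat.
#' Repeat numbering is positional (1-based from the first full heptad), so
#' the caller must supply the offset that aligns the published repeat
#' numbering; [frame_ctd_start()] offers a Y-anchored guess.
#'
#' @param sequence Amino-acid sequence (character scalar or anything
#'   coercible with `as.character`, e.g. a `Biostrings::AAString`).
#' @param start_offset 0-based offset of the first heptad.
#' @return A tibble: `index`, `residues`, `position7`, `is_consensus`;
#'   attribute `remainder` holds the unparsed tail.
#' @examples
#' parse_heptads(strrep("YSPTSPS", 3))
#' @export
parse_heptads <- function(sequence, start_offset = 0) {
  seq <- toupper(as.character(sequence))
  if (length(seq) != 1 || nchar(seq) == 0) abort("empty sequence")
  body <- substring(seq, start_offset + 1)
  if (nchar(body) < 7) abort("fewer than 7 residues after start_offset")
  n_rep <- nchar(body) %/% 7
  starts <- (seq_len(n_rep) - 1) * 7 + 1
  residues <- substring(body, starts, starts + 6)
  out <- tibble(index = seq_len(n_rep),
                residues = residues,
                position7 = substring(residues, 7, 7),
                is_consensus = residues == "YSPTSPS")
  attr(out, "remainder") <- substring(body, n_rep * 7 + 1)
  out
}

#' Find lysine-7 (K7) repeats
#'
#' @param repeats Tibble from [parse_heptads()].
#' @return Sorted integer vector of repeat indices whose position-7 residue
#'   is lysine; its length is the K7 count.
#' @examples
#' find_k7(parse_heptads("YSPTSPSYSPTSPK"))  # 2
#' @export
find_k7 <- function(repeats) {
  sort(repeats$index[repeats$position7 == "K"])
}

#' Guess the heptad frame from the first tyrosine
#'
#' Positional helper (not the default framing): returns the 0-based offset
#' of the first `Y` in the sequence, the canonical heptad anchor residue.
#'
#' @inheritParams parse_heptads
#' @return Integer offset, or an error when the sequence lacks tyrosine.
#' @export
frame_ctd_start <- function(sequence) {
  seq <- toupper(as.character(sequence))
  pos <- regexpr("Y", seq, fixed = TRUE)
  if (pos < 0) abort("no tyrosine found; cannot frame heptads")
  as.integer(pos - 1)
}

#' Read a protein sequence from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning the first
#' record as a plain character string for [parse_heptads()].
#'
#' @param path FASTA file path.
#' @return Character scalar.
#' @export
read_ctd_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  as.character(Biostrings::readAAStringSet(path)[[1]])
}
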