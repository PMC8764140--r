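# Window extraction around candidate lysine sites.

#' Enumerate candidate crotonylation sites
#'
#' Every lysine (`'K'`) residue is a candidate Kcr site.
#'
#' @param protein A single sequence string.
#' @return Ascending integer vector of 1-based lysine positions.
#' @examples
#' enumerate_candidate_sites("MKKA")  # 2 3
#' @export
enumerate_candidate_sites <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  which(strsplit(toupper(protein), "", fixed = TRUE)[[1L]] == "K")
}

#' Extract a sequence window around a lysine site
#'
#' Returns the `2n + 1` residues centered on `position`; positions
#' falling before the start or after the end of the sequence are filled
#' with the pad symbol `'-'`.  Pad positions are excluded from all
#' composition counts downstream.
#'
#' @param protein A single sequence string.
#' @param position 1-based site position; the residue there must be
#'   `'K'`.
#' @param n Half-width (window size); the segment has length `2n + 1`.
#'   The window sizes used throughout this package's reference protocol
#'   are 10, 15, 20, 25 and 30, but any `n >= 1` is accepted.
#' @param protein_id Optional identifier stored on the segment.
#' @return A `kcr_segment`: list with elements `protein_id`, `center`,
#'   `n`, `residues` (string of length `2n + 1`) and `positions`
#'   (1-based sequence positions, `NA` at pads).
#' @examples
#' extract_segment("KAAA", 1, 3)$residues  # "---KAAA"
#' @export
extract_segment <- function(protein, position, n, protein_id = NA_character_) {
  stopifnot(is.character(protein), length(protein) == 1L,
            n >= 1L, position >= 1L)
  L <- nchar(protein)
  if (position > L) stop("position ", position, " beyond sequence length ", L)
  if (substr(protein, position, position) != "K")
    stop("residue at position ", position, " is '",
         substr(protein, position, position), "', expected 'K'")
  pos <- (position - n):(position + n)
  inside <- pos >= 1L & pos <= L
  ch <- rep(PAD, 2L * n + 1L)
  ch[inside] <- strsplit(substr(protein, max(1L, position - n),
                                min(L, position + n)), "", fixed = TRUE)[[1L]]
  structure(list(protein_id = protein_id,
                 center = as.integer(position),
                 n = as.integer(n),
                 residues = paste(ch, collapse = ""),
                 positions = ifelse(inside, pos, NA_integer_)),
            class = "kcr_segment")
}

#' @export
print.kcr_segment <- function(x, ...) {
  cat("<kcr_segment> ", x$protein_id, " center=", x$center,
      " n=", x$n, "\n  ", x$residues, "\n", sep = "")
  invisible(x)
}
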