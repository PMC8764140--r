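# Contact-aware encoders: contact thresholding, window expansion with
# spatially contacting residues, RRC and RRPC.
#
# A predicted contact qualifies for a site's window when at least one of
# its two endpoints lies among the window's covered sequence positions.
# For RRC, the residue at the endpoint *outside* the window is appended
# to the tail of the segment (a contact with both endpoints inside
# appends nothing: those residues are already in the segment).  For
# RRPC, every qualifying contact contributes one ordered residue pair,
# the residue at the smaller sequence index first.

#' Threshold a contact map
#'
#' Keeps exactly the records whose probability is strictly greater than
#' the threshold (two residues are regarded as contacted when the
#' predictor's probability is higher than the threshold; 0.80 is the
#' reference value).
#'
#' @param cmap A `contact_map`.
#' @param threshold Probability threshold in `[0, 1]` (default 0.80).
#' @return A `contact_map` with the retained records.
#' @export
filter_contacts <- function(cmap, threshold = 0.8) {
  stopifnot(inherits(cmap, "contact_map"),
            threshold >= 0, threshold <= 1)
  structure(cmap[cmap$prob > threshold, , drop = FALSE],
            protein_id = attr(cmap, "protein_id"),
            class = class(cmap))
}

#' Select the contacts qualifying for a window
#'
#' @param cmap A (thresholded) `contact_map`.
#' @param segment A `kcr_segment`.
#' @return The records of `cmap` with at least one endpoint among the
#'   segment's covered positions.
#' @export
select_window_contacts <- function(cmap, segment) {
  stopifnot(inherits(cmap, "contact_map"),
            inherits(segment, "kcr_segment"))
  covered <- segment$positions[!is.na(segment$positions)]
  keep <- cmap$i %in% covered | cmap$j %in% covered
  structure(cmap[keep, , drop = FALSE],
            protein_id = attr(cmap, "protein_id"),
            class = class(cmap))
}

#' Expand a segment with its contacting residues
#'
#' For each qualifying contact with exactly one endpoint inside the
#' window, the residue at the outside endpoint is appended at the tail
#' of the segment.  Duplicate outside positions are appended once, in
#' ascending sequence-position order; contacts with both endpoints
#' inside append nothing.
#'
#' @param segment A `kcr_segment`.
#' @param contacts Qualifying contacts for this segment
#'   (see [select_window_contacts()]).
#' @param protein The segment's full sequence string.
#' @return A `kcr_expanded_segment`: list with `base` (the segment),
#'   `appended_positions`, `appended_residues` and `contacts`.
#' @export
expand_segment <- function(segment, contacts, protein) {
  stopifnot(inherits(segment, "kcr_segment"))
  L <- nchar(protein)
  if (nrow(contacts) && any(contacts$i > L | contacts$j > L))
    stop("contact endpoint beyond protein length ", L)
  covered <- segment$positions[!is.na(segment$positions)]
  outside <- integer(0)
  if (nrow(contacts)) {
    ii <- contacts$i %in% covered
    jj <- contacts$j %in% covered
    if (any(!ii & !jj))
      stop("contact does not qualify for this window")
    outside <- c(contacts$j[ii & !jj], contacts$i[jj & !ii])
    outside <- sort(unique(outside))
  }
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  structure(list(base = segment,
                 appended_positions = outside,
                 appended_residues = if (length(outside)) ch[outside]
                                     else character(0),
                 contacts = contacts),
            class = "kcr_expanded_segment")
}

#' @export
print.kcr_expanded_segment <- function(x, ...) {
  cat("<kcr_expanded_segment> ", x$base$protein_id, " center=",
      x$base$center, " n=", x$base$n, "\n  ", x$base$residues, " + [",
      paste(x$appended_residues, collapse = ""), "]\n", sep = "")
  invisible(x)
}

#' Residue-residue composition (RRC)
#'
#' AAC computed over the window's real residues plus the residues
#' spatially contacting the window (the appended tail of an expanded
#' segment).  With an empty contact map RRC reduces exactly to AAC.
#'
#' @param expanded A `kcr_expanded_segment` from [expand_segment()].
#' @return Named numeric vector of length 20.
#' @export
encode_rrc <- function(expanded) {
  stopifnot(inherits(expanded, "kcr_expanded_segment"))
  ch <- c(seg_chars(expanded$base), expanded$appended_residues)
  real <- ch[ch %in% AA20]
  if (length(real) == 0L) stop("expanded segment has no real residues")
  v <- tabulate(factor(real, levels = AA20), nbins = 20L) / length(real)
  names(v) <- AA20
  v
}

#' Residue-residue pair composition (RRPC)
#'
#' Each qualifying contact `(i, j)` with `i < j` contributes the ordered
#' residue pair `(residue(i), residue(j))` -- lower sequence index
#' first.  Counts are normalized by the number of contributing contacts;
#' when no contact qualifies the 400-dimensional vector is all zero.
#' Pairs involving an unknown residue (`'X'`) are not countable and are
#' skipped.
#'
#' @param segment A `kcr_segment` (defines the window the contacts
#'   qualified for).
#' @param contacts Qualifying contacts (see [select_window_contacts()]).
#' @param protein The full sequence string.
#' @return Named numeric vector of length 400.
#' @export
encode_rrpc <- function(segment, contacts, protein) {
  stopifnot(inherits(segment, "kcr_segment"))
  v <- numeric(400L)
  names(v) <- AA_PAIRS
  if (nrow(contacts) == 0L) return(v)
  L <- nchar(protein)
  if (any(contacts$i > L | contacts$j > L))
    stop("contact endpoint beyond protein length ", L)
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  a <- ch[pmin(contacts$i, contacts$j)]
  b <- ch[pmax(contacts$i, contacts$j)]
  ok <- a %in% AA20 & b %in% AA20
  if (!any(ok)) return(v)
  idx <- (match(a[ok], AA20) - 1L) * 20L + match(b[ok], AA20)
  v[] <- tabulate(idx, nbins = 400L) / sum(ok)
  v
}
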