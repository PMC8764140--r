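# Sequence-window feature encoders.
#
# All composition-style encoders count only "real" residues: pads ('-')
# and unknowns ('X') are excluded from both numerator and denominator,
# so every composition block is a proper probability distribution (or an
# all-zero block when nothing is countable).  Dimensions follow the
# fixed alphabetical amino-acid order ACDEFGHIKLMNPQRSTVWY.

real_mask <- function(ch) ch %in% AA20

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 amino acids among the real residues of a
#' segment: `P(a) = n(a) / D`, where `D` is the number of non-pad,
#' non-`'X'` residues.
#'
#' @param segment A `kcr_segment` or a plain residue string (pads as
#'   `'-'`).
#' @return Named numeric vector of length 20.
#' @examples
#' encode_aac("---KA")  # K and A each 0.5
#' @export
encode_aac <- function(segment) {
  ch <- seg_chars(segment)
  real <- ch[real_mask(ch)]
  if (length(real) == 0L) stop("segment has no real residues")
  v <- tabulate(factor(real, levels = AA20), nbins = 20L) / length(real)
  names(v) <- AA20
  v
}

#' Amino-acid pair composition (AAPC)
#'
#' Frequency of each ordered amino-acid pair over all ordered pairs of
#' distinct positions: `P(a,b) = n(a,b) / (D * (D - 1))` with `D` the
#' real-residue count, so the 400-dimensional vector sums to 1.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400 (names `"AA"`, `"AC"`, ...).
#' @export
encode_aapc <- function(segment) {
  ch <- seg_chars(segment)
  real <- ch[real_mask(ch)]
  D <- length(real)
  if (D < 2L) stop("segment has fewer than 2 real residues")
  cnt <- tabulate(factor(real, levels = AA20), nbins = 20L)
  pair <- outer(cnt, cnt)        # n_a * n_b ordered position pairs
  diag(pair) <- cnt * (cnt - 1L) # same letter: exclude p == q
  v <- as.vector(t(pair)) / (D * (D - 1L))
  names(v) <- AA_PAIRS
  v
}

#' Binary (one-hot) encoding
#'
#' One 20-slot one-hot block per window position; pad and `'X'`
#' positions encode as all-zero blocks.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length `20 * length(segment)`
#'   (names `"p1.A"`, ...).
#' @export
encode_binary <- function(segment) {
  ch <- seg_chars(segment)
  m <- matrix(0, nrow = length(ch), ncol = 20L,
              dimnames = list(NULL, AA20))
  idx <- match(ch, AA20)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  v <- as.vector(t(m))
  names(v) <- paste0("p", rep(seq_along(ch), each = 20L), ".",
                     rep(AA20, times = length(ch)))
  v
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap `k`, counts residue pairs at positions `(p, p + k + 1)`
#' with both residues real, normalized by the number of valid pairs at
#' that gap.  A gap with no valid pair yields an all-zero block.
#'
#' @inheritParams encode_aac
#' @param gaps Integer vector of gap sizes `k` (default `c(1, 2, 3)`).
#' @return Named numeric vector of length `400 * length(gaps)`
#'   (names `"k1.AA"`, ...).
#' @export
encode_cksaap <- function(segment, gaps = c(1L, 2L, 3L)) {
  if (length(gaps) == 0L) stop("gaps must be non-empty")
  gaps <- as.integer(gaps)
  if (any(gaps < 0L)) stop("gaps must be >= 0")
  ch <- seg_chars(segment)
  L <- length(ch)
  if (max(gaps) + 1L >= L)
    stop("max gap ", max(gaps), " too large for segment length ", L)
  out <- numeric(0)
  for (k in gaps) {
    p <- seq_len(L - k - 1L)
    a <- ch[p]; b <- ch[p + k + 1L]
    ok <- real_mask(a) & real_mask(b)
    block <- numeric(400L)
    if (any(ok)) {
      idx <- (match(a[ok], AA20) - 1L) * 20L + match(b[ok], AA20)
      block <- tabulate(idx, nbins = 400L) / sum(ok)
    }
    names(block) <- paste0("k", k, ".", AA_PAIRS)
    out <- c(out, block)
  }
  out
}

#' Enhanced amino-acid composition (EAAC)
#'
#' AAC computed in every sliding sub-window of the given size across the
#' segment, blocks concatenated left to right.  A sub-window with no
#' real residue yields an all-zero block.
#'
#' @inheritParams encode_aac
#' @param subwindow Sliding sub-window size (default 5).
#' @return Named numeric vector of length
#'   `20 * (length(segment) - subwindow + 1)`.
#' @export
encode_eaac <- function(segment, subwindow = 5L) {
  subwindow <- as.integer(subwindow)
  if (subwindow < 1L) stop("subwindow must be >= 1")
  ch <- seg_chars(segment)
  L <- length(ch)
  if (subwindow > L) stop("subwindow ", subwindow,
                          " larger than segment length ", L)
  nw <- L - subwindow + 1L
  out <- numeric(20L * nw)
  nm <- character(20L * nw)
  for (w in seq_len(nw)) {
    sub <- ch[w:(w + subwindow - 1L)]
    real <- sub[real_mask(sub)]
    block <- if (length(real)) {
      tabulate(factor(real, levels = AA20), nbins = 20L) / length(real)
    } else numeric(20L)
    out[(w - 1L) * 20L + 1:20] <- block
    nm[(w - 1L) * 20L + 1:20] <- paste0("w", w, ".", AA20)
  }
  names(out) <- nm
  out
}

#' Enhanced grouped amino-acid composition (EGAAC)
#'
#' As [encode_eaac()] but residues are first mapped to five
#' physicochemical groups: aliphatic \{G,A,V,L,M,I\}, aromatic
#' \{F,Y,W\}, positively charged \{K,R,H\}, negatively charged \{D,E\},
#' uncharged \{S,T,C,P,N,Q\}.
#'
#' @inheritParams encode_eaac
#' @return Named numeric vector of length
#'   `5 * (length(segment) - subwindow + 1)`.
#' @export
encode_egaac <- function(segment, subwindow = 5L) {
  subwindow <- as.integer(subwindow)
  if (subwindow < 1L) stop("subwindow must be >= 1")
  ch <- seg_chars(segment)
  L <- length(ch)
  if (subwindow > L) stop("subwindow ", subwindow,
                          " larger than segment length ", L)
  gnames <- names(AA_GROUPS)
  grp <- rep(NA_integer_, length(ch))
  for (g in seq_along(AA_GROUPS)) grp[ch %in% AA_GROUPS[[g]]] <- g
  nw <- L - subwindow + 1L
  out <- numeric(5L * nw)
  nm <- character(5L * nw)
  for (w in seq_len(nw)) {
    sub <- grp[w:(w + subwindow - 1L)]
    sub <- sub[!is.na(sub)]
    block <- if (length(sub)) tabulate(sub, nbins = 5L) / length(sub)
             else numeric(5L)
    out[(w - 1L) * 5L + 1:5] <- block
    nm[(w - 1L) * 5L + 1:5] <- paste0("w", w, ".", gnames)
  }
  names(out) <- nm
  out
}

#' PSSM window encoding
#'
#' Flattens the PSSM rows at the segment's real positions in window
#' order; pad positions contribute a zero row.
#'
#' @param segment A `kcr_segment` (positions are required).
#' @param pssm `L x 20` matrix from [read_pssm()]; its `protein_id`
#'   attribute must match the segment's.
#' @return Named numeric vector of length `20 * (2n + 1)`.
#' @export
encode_pssm_window <- function(segment, pssm) {
  if (!inherits(segment, "kcr_segment"))
    stop("encode_pssm_window needs a kcr_segment (with positions)")
  pid <- attr(pssm, "protein_id")
  if (!is.na(segment$protein_id) && !is.null(pid) && !is.na(pid) &&
      pid != segment$protein_id)
    stop("PSSM belongs to '", pid, "', segment to '",
         segment$protein_id, "'")
  L <- length(segment$positions)
  m <- matrix(0, nrow = L, ncol = 20L)
  inside <- !is.na(segment$positions)
  if (any(segment$positions[inside] > nrow(pssm)))
    stop("segment position beyond PSSM rows")
  m[inside, ] <- pssm[segment$positions[inside], , drop = FALSE]
  v <- as.vector(t(m))
  names(v) <- paste0("p", rep(seq_len(L), each = 20L), ".",
                     rep(AA20, times = L))
  v
}

#' Construct a labeled feature matrix
#'
#' @param x Numeric matrix, one row per sample, unique column names.
#' @param label Sample labels (`positive`/`negative` in any standard
#'   encoding).
#' @param sample_id Character vector of sample identifiers.
#' @return A `kcr_features` object: list with `x`, `label` (factor with
#'   levels negative/positive) and `sample_id`.
#' @export
kcr_features <- function(x, label, sample_id = rownames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(sample_id)) sample_id <- as.character(seq_len(nrow(x)))
  if (nrow(x) != length(label) || nrow(x) != length(sample_id))
    stop("row / label / id counts disagree")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("feature matrix needs unique column names")
  if (any(!is.finite(x))) stop("non-finite feature value")
  structure(list(x = x, label = label_factor(label),
                 sample_id = as.character(sample_id)),
            class = "kcr_features")
}

#' @export
print.kcr_features <- function(x, ...) {
  cat("<kcr_features> ", nrow(x$x), " samples x ", ncol(x$x),
      " dimensions (", sum(x$label == "positive"), " positive / ",
      sum(x$label == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' @export
`[.kcr_features` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  kcr_features(x$x[i, j, drop = FALSE], x$label[i], x$sample_id[i])
}

#' Encode labeled sites into a feature matrix
#'
#' Runs one or more encoders over every site and concatenates the
#' resulting vectors column-wise, prefixing dimension names with the
#' encoder name.  Contact-aware encoders (`"rrc"`, `"rrpc"`) use the
#' per-protein contact maps, thresholded at `contact_threshold` before
#' qualification.
#'
#' @param proteins Named character vector of sequences.
#' @param sites `data.frame` with columns `protein_id`, `position`,
#'   `label` (as from [read_site_labels()]).
#' @param encoders Character vector from `aac`, `aapc`, `binary`,
#'   `cksaap`, `eaac`, `egaac`, `pssm`, `rrc`, `rrpc`; several names
#'   mean concatenation in the listed order.
#' @param n Window half-width (default 10).
#' @param contacts Named list of `contact_map`s keyed by protein id
#'   (needed for `rrc`/`rrpc`).
#' @param pssms Named list of PSSM matrices keyed by protein id (needed
#'   for `pssm`).
#' @param contact_threshold Contact probability threshold; records with
#'   probability strictly greater are kept (default 0.80).
#' @param gaps CKSAAP gap set (default `c(1, 2, 3)`).
#' @param subwindow EAAC/EGAAC sliding sub-window size (default 5).
#' @return A `kcr_features` object; sample ids are
#'   `<protein_id>_<position>`.
#' @export
build_feature_matrix <- function(proteins, sites,
                                 encoders = "aac", n = 10L,
                                 contacts = NULL, pssms = NULL,
                                 contact_threshold = 0.8,
                                 gaps = c(1L, 2L, 3L), subwindow = 5L) {
  known <- c("aac", "aapc", "binary", "cksaap", "eaac", "egaac",
             "pssm", "rrc", "rrpc")
  encoders <- unlist(strsplit(encoders, ",", fixed = TRUE))
  bad <- setdiff(encoders, known)
  if (length(bad)) stop("unknown encoder(s): ", paste(bad, collapse = ", "))
  if (nrow(sites) == 0L) stop("no samples to encode")
  needs_contacts <- any(encoders %in% c("rrc", "rrpc"))
  if (needs_contacts && is.null(contacts))
    stop("encoders rrc/rrpc need contact maps")
  if ("pssm" %in% encoders && is.null(pssms))
    stop("encoder pssm needs PSSM profiles")

  # threshold each protein's contact map once
  fmap <- NULL
  if (needs_contacts) {
    fmap <- lapply(contacts, filter_contacts, threshold = contact_threshold)
  }

  encode_one <- function(pid, pos) {
    seg <- extract_segment(proteins[[pid]], pos, n, protein_id = pid)
    parts <- lapply(encoders, function(e) {
      v <- switch(e,
        aac    = encode_aac(seg),
        aapc   = encode_aapc(seg),
        binary = encode_binary(seg),
        cksaap = encode_cksaap(seg, gaps = gaps),
        eaac   = encode_eaac(seg, subwindow = subwindow),
        egaac  = encode_egaac(seg, subwindow = subwindow),
        pssm   = {
          pm <- pssms[[pid]]
          if (is.null(pm)) stop("no PSSM for protein '", pid, "'")
          encode_pssm_window(seg, pm)
        },
        rrc    = {
          cm <- fmap[[pid]]
          if (is.null(cm)) cm <- contact_map(
            data.frame(i = integer(), j = integer(), prob = numeric()), pid)
          qc <- select_window_contacts(cm, seg)
          encode_rrc(expand_segment(seg, qc, proteins[[pid]]))
        },
        rrpc   = {
          cm <- fmap[[pid]]
          if (is.null(cm)) cm <- contact_map(
            data.frame(i = integer(), j = integer(), prob = numeric()), pid)
          qc <- select_window_contacts(cm, seg)
          encode_rrpc(seg, qc, proteins[[pid]])
        })
      names(v) <- paste0(e, ".", names(v))
      v
    })
    unlist(parts)
  }

  first <- tryCatch(encode_one(sites$protein_id[1L], sites$position[1L]),
                    error = function(e) stop("sample ", sites$protein_id[1L],
                      "_", sites$position[1L], ": ", conditionMessage(e)))
  out <- matrix(NA_real_, nrow = nrow(sites), ncol = length(first),
                dimnames = list(NULL, names(first)))
  out[1L, ] <- first
  if (nrow(sites) > 1L) {
    for (r in 2:nrow(sites)) {
      out[r, ] <- tryCatch(encode_one(sites$protein_id[r], sites$position[r]),
                           error = function(e) stop("sample ",
                             sites$protein_id[r], "_", sites$position[r],
                             ": ", conditionMessage(e)))
    }
  }
  kcr_features(out, sites$label,
               paste(sites$protein_id, sites$position, sep = "_"))
}
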