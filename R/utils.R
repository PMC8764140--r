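# Shared constants and small internal helpers.

# Fixed alphabetical amino-acid order used for every feature dimension.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 400 ordered residue pairs, first residue varying slowest: AA, AC, ...
AA_PAIRS <- paste0(rep(AA20, each = 20L), rep(AA20, times = 20L))

# Five physicochemical groups used by EGAAC.
AA_GROUPS <- list(
  g1.aliphatic = c("G", "A", "V", "L", "M", "I"),
  g2.aromatic  = c("F", "Y", "W"),
  g3.positive  = c("K", "R", "H"),
  g4.negative  = c("D", "E"),
  g5.uncharged = c("S", "T", "C", "P", "N", "Q")
)

PAD <- "-"

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Normalize assorted label encodings to logical is-positive.
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  x <- tolower(as.character(labels))
  pos <- x %in% c("positive", "pos", "1", "true")
  neg <- x %in% c("negative", "neg", "0", "false")
  if (!all(pos | neg)) {
    stop("labels must be positive/negative (or pos/neg, 0/1, TRUE/FALSE); got: ",
         paste(unique(x[!(pos | neg)]), collapse = ", "))
  }
  pos
}

label_factor <- function(labels) {
  factor(ifelse(as_positive(labels), "positive", "negative"),
         levels = c("negative", "positive"))
}

# Split a segment (kcr_segment or plain string) into single characters.
seg_chars <- function(segment) {
  if (inherits(segment, "kcr_segment")) {
    strsplit(segment$residues, "", fixed = TRUE)[[1L]]
  } else if (is.character(segment) && length(segment) == 1L) {
    strsplit(toupper(segment), "", fixed = TRUE)[[1L]]
  } else {
    stop("segment must be a kcr_segment or a single character string")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
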