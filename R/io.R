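# Readers and writers for the on-disk formats the pipeline consumes:
# FASTA sequences, site-label tables, 6-column contact tables,
# PSI-BLAST ASCII PSSM profiles, and CSV feature matrices.
# File coordinates are 1-based throughout, matching the conventions of
# contact predictors and PSI-BLAST.

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and any character outside the 20 standard
#' one-letter amino-acid codes is mapped to `'X'` (unknown residue) with
#' a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the FASTA
#'   identifiers (first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKKA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE),
    error = function(e) stop("could not parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  ids <- names(recs)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(gsub("[[:space:]]", "", unlist(recs, use.names = FALSE)))
  bad <- gsub(paste0("[", paste(AA20, collapse = ""), "]"), "", seqs)
  if (any(nzchar(bad))) {
    warning("non-standard residue(s) ",
            paste(sort(unique(strsplit(paste(bad, collapse = ""), "")[[1L]])),
                  collapse = ", "),
            " mapped to 'X'")
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      ch[!(ch %in% AA20)] <- "X"
      paste(ch, collapse = "")
    }, character(1L), USE.NAMES = FALSE)
  }
  if (any(!nzchar(seqs))) stop("empty sequence for id(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  seqinr::write.fasta(as.list(unname(proteins)), names = names(proteins),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a site-label table
#'
#' Reads a tab- or comma-separated table with columns
#' `protein_id`, `position` (1-based) and `label`
#' (`positive`/`negative`), and validates every row against the given
#' proteins: the position must be in range and the residue there must be
#' a lysine (`'K'`), since only lysines can carry crotonylation.
#'
#' @param path Path to the table.  A header row is detected
#'   automatically.
#' @param proteins Named character vector of sequences
#'   (as from [read_fasta()]).
#' @return A `data.frame` with columns `protein_id`, `position`,
#'   `label`.
#' @export
read_site_labels <- function(path, proteins) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- read.table(path, sep = sep, header = FALSE,
                    stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(raw) < 3L) stop("site-label table needs >= 3 columns ",
                           "(protein_id, position, label)")
  off <- 0L
  if (suppressWarnings(is.na(as.numeric(raw[1L, 2L])))) { # header row
    raw <- raw[-1L, , drop = FALSE]
    off <- 1L
  }
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  out <- data.frame(protein_id = as.character(raw[[1L]]),
                    position = as.integer(raw[[2L]]),
                    label = tolower(as.character(raw[[3L]])),
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    row_no <- r + off
    pid <- out$protein_id[r]
    if (!pid %in% names(proteins))
      stop("row ", row_no, ": unknown protein '", pid, "'")
    pos <- out$position[r]
    if (is.na(pos) || pos < 1L || pos > nchar(proteins[[pid]]))
      stop("row ", row_no, ": position ", raw[r, 2L],
           " out of range for protein '", pid, "'")
    res <- substr(proteins[[pid]], pos, pos)
    if (res != "K")
      stop("row ", row_no, ": residue at position ", pos, " of '", pid,
           "' is '", res, "', expected 'K'")
    if (!out$label[r] %in% c("positive", "negative"))
      stop("row ", row_no, ": label must be positive/negative, got '",
           out$label[r], "'")
  }
  out
}

#' Read a residue-residue contact prediction table
#'
#' Parses the 6-column whitespace-delimited table emitted by contact
#' predictors: columns 1 and 2 hold the 1-based indices of the two
#' residues, column 5 the probability that they are in contact; the
#' remaining columns are ignored.  Pairs are canonicalized to `i < j`
#' and symmetric duplicates are merged keeping the maximum probability.
#'
#' @param path Path to the table.  Header rows whose first token is not
#'   numeric are skipped.
#' @param protein_id Identifier to attach; defaults to the file name
#'   without its `.contacts` extension.
#' @return A `contact_map`: a `data.frame` with columns `i`, `j`,
#'   `prob`, sorted by `(i, j)`, with attribute `protein_id`.
#' @export
read_contact_table <- function(path,
                               protein_id = sub("\\.contacts$", "",
                                                basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  first <- vapply(toks, `[[`, character(1L), 1L)
  keep <- !is.na(suppressWarnings(as.numeric(first)))
  toks <- toks[keep]
  if (length(toks) == 0L) {
    return(contact_map(data.frame(i = integer(), j = integer(),
                                  prob = numeric()), protein_id))
  }
  ncols <- lengths(toks)
  if (any(ncols < 6L))
    stop("contact table '", path, "': data row with fewer than 6 columns")
  i <- as.integer(vapply(toks, `[[`, character(1L), 1L))
  j <- as.integer(vapply(toks, `[[`, character(1L), 2L))
  p <- as.numeric(vapply(toks, `[[`, character(1L), 5L))
  if (anyNA(i) || anyNA(j) || any(i < 1L) || any(j < 1L))
    stop("contact table '", path, "': non-positive or non-integer index")
  if (any(i == j))
    stop("contact table '", path, "': self-contact (i == j) at i = ",
         i[which(i == j)[1L]])
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("contact table '", path, "': probability outside [0, 1]")
  contact_map(data.frame(i = i, j = j, prob = p), protein_id)
}

#' Construct a contact map from (i, j, probability) records
#'
#' Canonicalizes pairs to `i < j` and merges duplicates keeping the
#' maximum probability.
#'
#' @param records `data.frame` with columns `i`, `j`, `prob`.
#' @param protein_id Protein identifier.
#' @return A `contact_map` (see [read_contact_table()]).
#' @export
contact_map <- function(records, protein_id = NA_character_) {
  stopifnot(all(c("i", "j", "prob") %in% names(records)))
  i <- pmin(records$i, records$j)
  j <- pmax(records$i, records$j)
  if (any(i == j)) stop("self-contact (i == j) not allowed")
  if (any(records$prob < 0 | records$prob > 1))
    stop("contact probability outside [0, 1]")
  d <- data.frame(i = as.integer(i), j = as.integer(j),
                  prob = as.numeric(records$prob))
  if (nrow(d)) {
    key <- paste(d$i, d$j)
    d <- do.call(rbind, lapply(split(d, key), function(g) {
      g[which.max(g$prob), , drop = FALSE]
    }))
    d <- d[order(d$i, d$j), , drop = FALSE]
    rownames(d) <- NULL
  }
  structure(d, protein_id = protein_id,
            class = c("contact_map", "data.frame"))
}

#' Write a contact map in the 6-column predictor table format
#'
#' Columns 3, 4 and 6 (unused by the pipeline) are written as 0, 8 and 0.
#'
#' @param cmap A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(cmap, path) {
  stopifnot(inherits(cmap, "contact_map"))
  lines <- sprintf("%d %d 0 8 %.10g 0", cmap$i, cmap$j, cmap$prob)
  writeLines(lines, path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the classic ASCII profile: a header line of 20 amino-acid
#' letters naming the score columns, then one row per sequence position
#' (`position residue score1 ... score20 ...`).  Only the first 20 score
#' columns are used and they are reordered to the fixed alphabetical
#' amino-acid order regardless of the order in the file.
#'
#' @param path Path to the profile.
#' @param sequence Optional protein sequence; if given, the row count
#'   must equal its length.
#' @param protein_id Identifier to attach; defaults to the file name
#'   without its `.pssm` extension.
#' @return `L x 20` numeric matrix, columns in alphabetical amino-acid
#'   order, with attributes `protein_id` and `residues` (the residue
#'   column of the file).
#' @export
read_pssm <- function(path, sequence = NULL,
                      protein_id = sub("\\.pssm$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1L]])
  # header: the first line whose first 20 tokens are all amino-acid letters
  hdr <- NULL
  for (t in toks) {
    if (length(t) >= 20L && all(t[1:20] %in% AA20) &&
        !anyDuplicated(t[1:20])) { hdr <- t[1:20]; break }
  }
  if (is.null(hdr)) stop("PSSM '", path, "': no 20-letter column header found")
  rows <- Filter(function(t) {
    length(t) >= 22L && !is.na(suppressWarnings(as.integer(t[1L]))) &&
      t[2L] %in% c(AA20, "X")
  }, toks)
  if (length(rows) == 0L) stop("PSSM '", path, "': no data rows")
  pos <- vapply(rows, function(t) as.integer(t[1L]), integer(1L))
  if (!identical(pos, seq_along(pos)))
    stop("PSSM '", path, "': positions not consecutive from 1")
  res <- vapply(rows, `[[`, character(1L), 2L)
  sc <- t(vapply(rows, function(t) as.numeric(t[3:22]), numeric(20L)))
  if (anyNA(sc)) stop("PSSM '", path, "': non-numeric score")
  colnames(sc) <- hdr
  sc <- sc[, AA20, drop = FALSE]
  if (!is.null(sequence) && nrow(sc) != nchar(sequence))
    stop("PSSM '", path, "': ", nrow(sc), " rows but sequence length ",
         nchar(sequence))
  structure(sc, protein_id = protein_id, residues = paste(res, collapse = ""))
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Emits scores in the conventional PSI-BLAST column order
#' (`ARNDCQEGHILKMFPSTVWY`), which [read_pssm()] maps back to
#' alphabetical order.
#'
#' @param pssm `L x 20` matrix with alphabetical columns.
#' @param residues Sequence of length `L` (string).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, residues, path) {
  stopifnot(ncol(pssm) == 20L, nchar(residues) == nrow(pssm))
  blast_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")
  m <- pssm[, blast_order, drop = FALSE]
  ch <- strsplit(residues, "", fixed = TRUE)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("      ", paste(sprintf("%3s", blast_order),
                                      collapse = " "))), con)
  for (r in seq_len(nrow(m))) {
    writeLines(paste0(sprintf("%5d %s ", r, ch[r]),
                      paste(sprintf("%3d", round(m[r, ])), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Write a feature matrix to CSV
#'
#' First columns are `sample_id` and `label`, then one column per
#' feature dimension.  Numeric values are written with 17 significant
#' digits so that [read_feature_matrix()] round-trips them losslessly.
#'
#' @param fm A `kcr_features` object (see [kcr_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "kcr_features"))
  cn <- c("sample_id", "label", colnames(fm$x))
  if (anyDuplicated(cn))
    stop("duplicate column name(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  vals <- apply(fm$x, 2L, function(v) sprintf("%.17g", v))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(fm$x))
  tab <- cbind(fm$sample_id, as.character(fm$label), vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cn, collapse = ","), con)
  writeLines(apply(tab, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A `kcr_features` object.
#' @export
read_feature_matrix <- function(path) {
  d <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(d)[1:2]))
    stop("not a feature-matrix CSV: ", path)
  x <- as.matrix(d[, -(1:2), drop = FALSE])
  storage.mode(x) <- "double"
  kcr_features(x, d$label, d$sample_id)
}
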