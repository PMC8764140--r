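# Synthetic data generator: protein sequences, lysine site labels,
# contact tables and PSSM profiles with controllable planted signal, so
# every pipeline stage is testable without external data.
#
# Two independent signal channels distinguish positive from negative
# sites:
#   * motif_tilt  -- sequence-level: window residues near a positive
#     site are re-drawn from the motif residues with this probability,
#     which linear encoders (AAC, binary, ...) can pick up;
#   * contact enrichment -- spatial-level: positive-site windows receive
#     planted high-probability contacts to a designated residue type,
#     which only the contact-aware encoders (RRC/RRPC) can pick up.
# Setting one (or both) to zero yields single-channel or null datasets.

#' Configuration for the synthetic Kcr dataset generator
#'
#' Defaults emulate the structure of a typical curated Kcr dataset:
#' a few hundred proteins with lysine sites at roughly 1:10
#' positive:negative imbalance, and per-protein contact tables whose
#' probabilities lie in `[0, 1]` with background contact density
#' decaying in sequence separation.
#'
#' @param n_proteins Number of proteins (default 250).
#' @param length_range Min/max protein length (default `c(120, 250)`).
#' @param positive_fraction Probability that a lysine site is labeled
#'   positive (default 0.1).
#' @param motif_tilt Probability that a window residue near a positive
#'   site is replaced by a motif residue (default 0.25; 0 disables the
#'   sequence channel).
#' @param motif_residues Residues the tilt draws from (default
#'   `c("E", "D")`).
#' @param motif_span Offsets around the site subject to the tilt
#'   (default `1:4` on each side).
#' @param contact_base_rate Background contact probability at minimum
#'   separation (default 0.08), decaying as
#'   `exp(-(sep - min_sep) / contact_decay)`.
#' @param contact_decay Separation decay length (default 20).
#' @param contact_enrichment Probability that each intended planted
#'   contact is emitted (default 1; 0 disables the spatial channel).
#' @param planted_per_site Planted contacts per positive site
#'   (default 4).
#' @param planted_residue Residue type the planted contacts point to
#'   (default `"L"`).
#' @param prob_noise Gaussian jitter added to emitted probabilities,
#'   clamped to `[0, 1]` (default 0.02).
#' @param min_sep Minimum sequence separation of synthetic contacts
#'   (default 3).
#' @param n Window half-width used when planting contacts around
#'   positive sites (default 10).
#' @param seed Integer seed (default 1).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_proteins = 250L, length_range = c(120L, 250L),
                         positive_fraction = 0.1, motif_tilt = 0.25,
                         motif_residues = c("E", "D"), motif_span = 1:4,
                         contact_base_rate = 0.08, contact_decay = 20,
                         contact_enrichment = 1, planted_per_site = 4L,
                         planted_residue = "L", prob_noise = 0.02,
                         min_sep = 3L, n = 10L, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              positive_fraction = positive_fraction,
              motif_tilt = motif_tilt, motif_residues = motif_residues,
              motif_span = as.integer(motif_span),
              contact_base_rate = contact_base_rate,
              contact_decay = contact_decay,
              contact_enrichment = contact_enrichment,
              planted_per_site = as.integer(planted_per_site),
              planted_residue = planted_residue,
              prob_noise = prob_noise, min_sep = as.integer(min_sep),
              n = as.integer(n), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_proteins >= 1L, length(length_range) == 2L,
              length_range[1L] >= 10L,
              length_range[2L] >= length_range[1L],
              positive_fraction > 0, positive_fraction < 1,
              motif_tilt >= 0, motif_tilt <= 1,
              all(motif_residues %in% setdiff(AA20, "K")),
              contact_base_rate >= 0, contact_base_rate <= 1,
              contact_decay > 0,
              contact_enrichment >= 0, contact_enrichment <= 1,
              planted_per_site >= 0L, planted_residue %in% AA20,
              prob_noise >= 0, min_sep >= 1L, n >= 1L)
  })
  structure(cfg, class = "synth_config")
}

# Background residue frequencies: near-uniform, with lysine at a
# proteome-like ~4% (candidate windows stay sparse enough that planted
# contacts can avoid neighboring sites' windows) and the planted
# residue mildly enriched so partners exist in every protein.
background_freq <- function(cfg) {
  w <- rep(1, 20L)
  names(w) <- AA20
  w["K"] <- 0.9
  w[cfg$planted_residue] <- 1.5
  w / sum(w)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# One protein: sequence, site labels, planted-contact endpoints.
synth_protein <- function(cfg, freq) {
  L <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
  ch <- sample(AA20, L, replace = TRUE, prob = freq)
  if (!any(ch == "K")) ch[sample.int(L, 1L)] <- "K"
  ksites <- which(ch == "K")
  is_pos <- runif(length(ksites)) < cfg$positive_fraction
  # sequence channel: tilt window residues around positive sites
  if (cfg$motif_tilt > 0 && any(is_pos)) {
    for (s in ksites[is_pos]) {
      off <- c(-cfg$motif_span, cfg$motif_span)
      tgt <- s + off
      tgt <- tgt[tgt >= 1L & tgt <= L]
      tgt <- tgt[!tgt %in% ksites]    # never overwrite a candidate site
      hit <- tgt[runif(length(tgt)) < cfg$motif_tilt]
      if (length(hit))
        ch[hit] <- sample(cfg$motif_residues, length(hit), replace = TRUE)
    }
  }
  list(seq = paste(ch, collapse = ""), ksites = ksites, is_pos = is_pos)
}

#' Generate a synthetic contact table for one protein
#'
#' Background contacts: every pair with separation at least `min_sep`
#' exists with probability `contact_base_rate *
#' exp(-(sep - min_sep) / contact_decay)`; existing pairs are emitted
#' with a `Beta(1, 3)` probability plus noise -- mostly low-confidence,
#' as contact predictors produce, with an occasional high-confidence
#' background contact above the 0.8 threshold.
#' Planted contacts: for each positive site, `planted_per_site` pairs
#' between a window position and an out-of-window position carrying the
#' planted residue, emitted with probability drawn from `[0.85, 0.98]`
#' plus noise (above the 0.8 reference threshold).  Both endpoints are
#' chosen outside every *other* candidate lysine's window, so the
#' planted signal qualifies only for the window of the site it marks --
#' the property that makes the spatial channel a clean benchmark signal.
#'
#' @param protein Sequence string.
#' @param config A `synth_config`.
#' @param positive_sites 1-based positions of positive sites in this
#'   protein (planting is skipped when empty or when
#'   `contact_enrichment` is 0).
#' @param all_sites 1-based positions of all candidate lysine sites;
#'   planted endpoints avoid the windows of sites other than the one
#'   being marked.
#' @param protein_id Identifier for the returned map.
#' @return A `contact_map`.
#' @export
generate_contact_table <- function(protein, config,
                                   positive_sites = integer(0),
                                   all_sites = positive_sites,
                                   protein_id = NA_character_) {
  stopifnot(inherits(config, "synth_config"))
  L <- nchar(protein)
  ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
  # background pairs
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  sep <- pairs[, 2L] - pairs[, 1L]
  ok <- sep >= config$min_sep
  pairs <- pairs[ok, , drop = FALSE]; sep <- sep[ok]
  p_exist <- config$contact_base_rate *
    exp(-(sep - config$min_sep) / config$contact_decay)
  hit <- runif(length(sep)) < p_exist
  bi <- pairs[hit, 1L]; bj <- pairs[hit, 2L]
  bp <- clamp01(stats::rbeta(sum(hit), 1, 3) +
                rnorm(sum(hit), 0, config$prob_noise))
  # planted pairs around positive sites
  pi_ <- pj <- integer(0); pp <- numeric(0)
  if (config$contact_enrichment > 0 && config$planted_per_site > 0L &&
      length(positive_sites)) {
    for (s in positive_sites) {
      others <- setdiff(all_sites, s)
      clear_of_others <- function(p) {
        !length(others) || all(abs(outer(p, others, "-")) > config$n)
      }
      win <- max(1L, s - config$n):min(L, s + config$n)
      anchors_ok <- win[vapply(win, clear_of_others, logical(1L))]
      if (!length(anchors_ok)) anchors_ok <- win   # fallback: crowded region
      cand <- which(ch == config$planted_residue)
      cand <- cand[abs(cand - s) > config$n]     # out of this window
      cand_clean <- cand[vapply(cand, clear_of_others, logical(1L))]
      if (length(cand_clean)) cand <- cand_clean
      if (!length(cand)) next
      k <- min(config$planted_per_site, length(cand))
      partners <- sample(cand, k)
      anchors <- sample(anchors_ok, k, replace = TRUE)
      emit <- runif(k) < config$contact_enrichment
      keep <- emit & abs(partners - anchors) >= config$min_sep
      if (!any(keep)) next
      pi_ <- c(pi_, pmin(anchors[keep], partners[keep]))
      pj <- c(pj, pmax(anchors[keep], partners[keep]))
      pp <- c(pp, clamp01(runif(sum(keep), 0.85, 0.98) +
                          rnorm(sum(keep), 0, config$prob_noise)))
    }
  }
  contact_map(data.frame(i = c(bi, pi_), j = c(bj, pj),
                         prob = c(bp, pp)),
              protein_id = protein_id)
}

# PSSM stand-in derived from local residue frequencies: log2-odds of the
# smoothed composition in a +/-5 window against the background
# frequencies, plus Gaussian noise.  Synthetic -- it emulates the shape
# of a profile-search matrix, not its evolutionary content.
synth_pssm <- function(sequence, freq, noise = 0.5) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  onehot <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  idx <- match(ch, AA20)
  ok <- !is.na(idx)
  onehot[cbind(which(ok), idx[ok])] <- 1
  sc <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  for (r in seq_len(L)) {
    win <- max(1L, r - 5L):min(L, r + 5L)
    f <- (colSums(onehot[win, , drop = FALSE]) + 0.5) / (length(win) + 10)
    sc[r, ] <- round(log2(f / freq) * 2 + rnorm(20L, 0, noise))
  }
  sc
}

#' Generate a complete synthetic Kcr dataset
#'
#' Produces proteins, site labels, per-protein contact maps and PSSM
#' profiles under the given configuration; deterministic given the
#' configuration seed.  When `dir` is given the dataset is also written
#' in the pipeline's input formats (`proteins.fasta`, `sites.tsv`,
#' `contacts/<id>.contacts`, `pssm/<id>.pssm`).
#'
#' @param config A `synth_config`.
#' @param dir Optional output directory.
#' @param pssm Generate PSSM profiles (default `FALSE`; they are the
#'   slowest part and only needed for the `pssm` encoder).
#' @return List with `proteins` (named character vector), `sites`
#'   (`data.frame`: `protein_id`, `position`, `label`), `contacts`
#'   (named list of `contact_map`), `pssms` (named list or `NULL`) and
#'   the `config`.
#' @export
generate_dataset <- function(config, dir = NULL, pssm = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  freq <- background_freq(config)
  with_seed(config$seed, {
    ids <- sprintf("sp%04d", seq_len(config$n_proteins))
    proteins <- character(config$n_proteins)
    names(proteins) <- ids
    sites <- vector("list", config$n_proteins)
    contacts <- vector("list", config$n_proteins)
    names(contacts) <- ids
    pssms <- if (pssm) structure(vector("list", config$n_proteins),
                                 names = ids) else NULL
    for (p in seq_len(config$n_proteins)) {
      pr <- synth_protein(config, freq)
      proteins[p] <- pr$seq
      sites[[p]] <- data.frame(
        protein_id = ids[p], position = pr$ksites,
        label = ifelse(pr$is_pos, "positive", "negative"),
        stringsAsFactors = FALSE)
      contacts[[p]] <- generate_contact_table(
        pr$seq, config, positive_sites = pr$ksites[pr$is_pos],
        all_sites = pr$ksites, protein_id = ids[p])
      if (pssm) pssms[[p]] <- structure(synth_pssm(pr$seq, freq),
                                        protein_id = ids[p])
    }
    sites <- do.call(rbind, sites)
    out <- list(proteins = proteins, sites = sites, contacts = contacts,
                pssms = pssms, config = config)
    if (!is.null(dir)) write_dataset(out, dir)
    out
  })
}

write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "contacts"), showWarnings = FALSE)
  write_fasta(dataset$proteins, file.path(dir, "proteins.fasta"))
  write.table(dataset$sites, file.path(dir, "sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (id in names(dataset$contacts)) {
    write_contact_table(dataset$contacts[[id]],
                        file.path(dir, "contacts",
                                  paste0(id, ".contacts")))
  }
  if (!is.null(dataset$pssms)) {
    dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
    for (id in names(dataset$pssms)) {
      write_pssm(dataset$pssms[[id]], dataset$proteins[[id]],
                 file.path(dir, "pssm", paste0(id, ".pssm")))
    }
  }
  invisible(dir)
}
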