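# End-to-end orchestration: split -> undersample(train) -> encode ->
# select(train-fitted) -> grid-search train -> score test -> report.
#
# The test split never influences undersampling, selection fitting or
# grid search: all three see the training rows only.  Sub-seeds for the
# split, the undersampling draw and the classifier are derived from the
# single configured seed, so a rerun with the same config reproduces the
# report byte for byte.

#' Run the full Kcr prediction pipeline
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized fields (defaults in parentheses):
#'   \describe{
#'     \item{`data`}{in-memory dataset as returned by
#'       [generate_dataset()] -- `proteins`, `sites`, `contacts`,
#'       `pssms`.  Alternatively give paths:}
#'     \item{`fasta`, `sites`, `contacts_dir`, `pssm_dir`}{input files;
#'       contact tables are resolved per protein as
#'       `<contacts_dir>/<protein_id>.contacts`, profiles as
#'       `<pssm_dir>/<protein_id>.pssm`.}
#'     \item{`encoders`}{encoder name(s), comma-joined or vector
#'       (`"rrpc"`).}
#'     \item{`n`}{window half-width (10).}
#'     \item{`contact_threshold`}{contact probability threshold (0.80).}
#'     \item{`selection`}{`"none"` (default), `"chi2"` or `"ig"`.}
#'     \item{`alpha`, `ig_bins`, `top_k`}{selection parameters (0.05, 2,
#'       `NULL`).}
#'     \item{`classifier`}{`"svm"`, `"rf"` or `"lr"` (`"svm"`).}
#'     \item{`grid`}{optional grid `data.frame` override.}
#'     \item{`split_fraction`}{training fraction (0.8).}
#'     \item{`cv_k`}{cross-validation folds (5).}
#'     \item{`cutoff`}{decision cutoff (0.5).}
#'     \item{`seed`}{master seed (required).}
#'     \item{`out_dir`}{optional artifact directory.}
#'   }
#' @param quiet Suppress per-stage messages (default `FALSE`).
#' @return A `kcr_run`: list with `report` (a `kcr_eval`), `model`
#'   (a `kcr_fit`), `selection` (or `NULL`), `counts` (samples per
#'   stage) and the resolved `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is required")
  cfg <- list(
    encoders = config$encoders %||% "rrpc",
    n = as.integer(config$n %||% 10L),
    contact_threshold = config$contact_threshold %||% 0.8,
    selection = config$selection %||% "none",
    alpha = config$alpha %||% 0.05,
    ig_bins = as.integer(config$ig_bins %||% 2L),
    top_k = config$top_k,
    classifier = config$classifier %||% "svm",
    grid = config$grid,
    split_fraction = config$split_fraction %||% 0.8,
    cv_k = as.integer(config$cv_k %||% 5L),
    cutoff = config$cutoff %||% 0.5,
    seed = as.integer(config$seed),
    out_dir = config$out_dir)
  say <- function(...) if (!quiet) message("[kcrcontact] ", ...)

  # --- load inputs ---------------------------------------------------
  if (!is.null(config$data)) {
    proteins <- config$data$proteins
    sites <- config$data$sites
    contacts <- config$data$contacts
    pssms <- config$data$pssms
  } else {
    proteins <- read_fasta(config$fasta)
    sites <- read_site_labels(config$sites, proteins)
    contacts <- pssms <- NULL
    need <- unlist(strsplit(cfg$encoders, ",", fixed = TRUE))
    if (any(need %in% c("rrc", "rrpc"))) {
      if (is.null(config$contacts_dir))
        stop("encoders rrc/rrpc need config$contacts_dir")
      ids <- unique(sites$protein_id)
      contacts <- lapply(ids, function(id)
        read_contact_table(file.path(config$contacts_dir,
                                     paste0(id, ".contacts")), id))
      names(contacts) <- ids
    }
    if ("pssm" %in% need) {
      if (is.null(config$pssm_dir))
        stop("encoder pssm needs config$pssm_dir")
      ids <- unique(sites$protein_id)
      pssms <- lapply(ids, function(id)
        read_pssm(file.path(config$pssm_dir, paste0(id, ".pssm")),
                  sequence = proteins[[id]], protein_id = id))
      names(pssms) <- ids
    }
  }
  say(length(proteins), " proteins, ", nrow(sites), " sites (",
      sum(sites$label == "positive"), " positive)")

  # --- encode --------------------------------------------------------
  fm <- build_feature_matrix(proteins, sites, encoders = cfg$encoders,
                             n = cfg$n, contacts = contacts,
                             pssms = pssms,
                             contact_threshold = cfg$contact_threshold)
  say("encoded ", nrow(fm$x), " samples x ", ncol(fm$x), " dimensions (",
      paste(cfg$encoders, collapse = "+"), ")")

  # --- split / balance / select (train side only) --------------------
  sp <- train_test_split(fm, fraction = cfg$split_fraction,
                         seed = cfg$seed)
  say("split: ", nrow(sp$train$x), " train / ", nrow(sp$test$x), " test")
  train <- undersample_balance(sp$train, seed = cfg$seed + 1L)
  say("undersampled train: ", sum(train$label == "positive"), ":",
      sum(train$label == "negative"), " (pos:neg)")
  sel <- NULL
  test <- sp$test
  if (cfg$selection != "none") {
    sel <- switch(cfg$selection,
      chi2 = chi_square_select(train, alpha = cfg$alpha),
      ig = information_gain_select(train, bins = cfg$ig_bins,
                                   top_k = cfg$top_k),
      stop("unknown selection method '", cfg$selection, "'"))
    train <- apply_selection(train, sel)
    test <- apply_selection(test, sel)
    say("selection (", cfg$selection, "): ", sum(sel$kept),
        " dimensions kept")
  }

  # --- fit / score / report ------------------------------------------
  fit <- kcr_fit(train, classifier = cfg$classifier, grid = cfg$grid,
                 k = cfg$cv_k, seed = cfg$seed + 2L, cutoff = cfg$cutoff)
  say("fit ", cfg$classifier, ": best ",
      paste(names(fit$best), unlist(fit$best), sep = "=", collapse = ", "))
  scores <- predict(fit, test)
  report <- kcr_evaluate(scores, test$label, cutoff = cfg$cutoff)
  say(sprintf("test: Acc=%.3f AUC=%.3f MCC=%.3f", report$Acc,
              report$AUC, report$MCC))

  counts <- list(proteins = length(proteins), sites = nrow(sites),
                 train = nrow(sp$train$x), test = nrow(sp$test$x),
                 train_balanced = nrow(train$x),
                 dimensions = ncol(fm$x),
                 dimensions_kept = ncol(train$x))
  out <- structure(list(report = report, model = fit, selection = sel,
                        counts = counts, config = cfg),
                   class = "kcr_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_matrix(fm, file.path(cfg$out_dir, "features.csv"))
    eval_report_json(report, file.path(cfg$out_dir, "report.json"))
    saveRDS(fit, file.path(cfg$out_dir, "model.rds"))
    yaml::write_yaml(cfg[setdiff(names(cfg), "grid")],
                     file.path(cfg$out_dir, "config.yaml"))
    if (!is.null(sel))
      write.table(data.frame(name = sel$names, score = sel$score,
                             p_value = sel$p_value, kept = sel$kept),
                  file.path(cfg$out_dir, "selection.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.kcr_run <- function(x, ...) {
  cat("<kcr_run> ", paste(x$config$encoders, collapse = "+"), " + ",
      x$config$classifier, "\n", sep = "")
  cat("  ", x$counts$proteins, " proteins; ", x$counts$sites,
      " sites; train ", x$counts$train, " (balanced ",
      x$counts$train_balanced, ") / test ", x$counts$test, "\n",
      sep = "")
  print(x$report)
  invisible(x)
}
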