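#' End-to-end training pipeline
#'
#' Runs the full stack on a cohort directory: read inputs through the
#' standard parsers, assemble the 58-feature table, optionally reduce
#' redundancy at 35% identity and filter low-MAF neutral records, run
#' greedy feature selection, and cross-validate the selected model.
#' Written artifacts carry a provenance header (config hash + seed), and
#' reruns with the same config are identical.
#'
#' @param dir Cohort directory (layout of [write_cohort()]).
#' @param n_window Half-window size for feature extraction.
#' @param C,gamma SVM parameters.
#' @param k Cross-validation folds.
#' @param seed Integer seed.
#' @param select Run greedy feature selection (default `TRUE`; when
#'   `FALSE` all 58 features are used).
#' @param reduce_redundancy Drop indels on non-representative proteins of
#'   35%-identity clusters.
#' @param maf_threshold Optional MAF threshold for [maf_filter()] (NULL =
#'   no filtering).
#' @param out Optional output directory for TSV artifacts.
#' @return List with `features` (the feature table), `trace`
#'   (`nfs_trace` or NULL), `cv` (`nfs_cv`), `model` (`nfs_model` trained
#'   on all records with the selected features).
#' @export
run_training_pipeline <- function(dir, n_window = 2, C = 1, gamma = NULL,
                                  k = 10, seed = 1, select = TRUE,
                                  reduce_redundancy = FALSE,
                                  maf_threshold = NULL, out = NULL) {
  for (f in c("indels.vcf", "transcripts.gtf", "proteins.fasta",
              "conservation.bedGraph")) {
    if (!file.exists(file.path(dir, f))) {
      stop("Missing input: ", file.path(dir, f), call. = FALSE)
    }
  }
  co <- load_cohort(dir)
  feats <- assemble_features(co$indels, co$transcripts, co$cons_track,
                             co$residue_tracks, co$profiles,
                             n_window = n_window)
  feats$maf <- co$indels$maf[match(feats$id, co$indels$id)]
  feats$protein_id <- co$transcripts$protein_id[
    match(co$indels$transcript_id[match(feats$id, co$indels$id)],
          co$transcripts$transcript_id)]
  if (reduce_redundancy) {
    seqs <- stats::setNames(co$transcripts$protein_seq,
                            co$transcripts$protein_id)
    clusters <- cluster_at_identity(seqs, threshold = 35)
    feats <- select_representatives(clusters, feats)
  }
  if (!is.null(maf_threshold)) feats <- maf_filter(feats, maf_threshold)
  fnames <- feature_names()
  if (is.null(gamma)) gamma <- 1 / length(fnames)
  trace <- NULL
  selected <- fnames
  if (select) {
    trace <- greedy_select(feats, fnames, C = C, gamma = gamma, k = k,
                           seed = seed)
    selected <- trace$selected
  }
  cv <- suppressWarnings(
    kfold_cv(feats, selected, C = C, gamma = gamma, k = k, seed = seed))
  model <- suppressWarnings(
    train_svm(feats, selected, C = C, gamma = gamma, seed = seed))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stamp <- paste0("# config_hash=", rlang::hash(list(
      n_window = n_window, C = C, gamma = gamma, k = k, seed = seed,
      select = select, reduce_redundancy = reduce_redundancy,
      maf_threshold = maf_threshold)), " seed=", seed)
    write_stamped <- function(tab, path) {
      writeLines(stamp, path)
      suppressMessages(readr::write_tsv(tab, path, append = TRUE,
                                        col_names = TRUE))
    }
    write_stamped(feats, file.path(out, "features.tsv"))
    write_stamped(cv$predictions, file.path(out, "cv_predictions.tsv"))
    if (!is.null(trace)) write_stamped(trace$trace,
                                       file.path(out, "selection.tsv"))
    save_model(model, file.path(out, "model.json"))
  }
  list(features = feats, trace = trace, cv = cv, model = model)
}

#' Independent train/test evaluation
#'
#' Fits on one record set and evaluates on a disjoint one — the protocol
#' used to test a deletion-trained model on insertions and vice versa.
#' Overlapping record ids are refused.
#'
#' @param train,test Feature tibbles with `id`, `label` and the feature
#'   columns.
#' @param features Feature names to use.
#' @inheritParams train_svm
#' @return List with `model`, `counts`, `metrics`, `predictions`.
#' @export
run_independent_test <- function(train, test, features, C = 1,
                                 gamma = 1 / length(features), seed = 1) {
  overlap <- intersect(train$id, test$id)
  if (length(overlap) > 0) {
    stop("Train and test sets share record id(s): ",
         paste(utils::head(overlap, 10), collapse = ", "), call. = FALSE)
  }
  model <- suppressWarnings(
    train_svm(train, features, C = C, gamma = gamma, seed = seed))
  dv <- stats::predict(model, test, type = "decision")
  pred <- ifelse(dv > 0, "disease", "neutral")
  counts <- confusion(test$label, pred)
  metrics <- list(
    mcc = mcc(counts),
    auc = roc_auc(dv, test$label)$auc,
    precision = tryCatch(precision(counts), error = function(e) NA_real_),
    recall = tryCatch(recall(counts), error = function(e) NA_real_),
    accuracy = accuracy(counts))
  list(model = model,
       counts = counts, metrics = metrics,
       predictions = tibble::tibble(id = test$id, label = test$label,
                                    decision = dv, pred = pred))
}

#' Evaluation stratified by site conservation (relative entropy)
#'
#' Splits records into the high / median / low RE strata and reports
#' per-stratum true-positive rate, false-positive rate and MCC. Highly
#' conserved sites typically show both elevated TPR and elevated FPR.
#'
#' @param data Feature tibble with `label` and `re_stratum` columns (as
#'   produced by [assemble_features()]).
#' @param model An `nfs_model`.
#' @return Tibble with one row per non-empty stratum: `stratum`, `n`,
#'   `tpr`, `fpr`, `mcc`.
#' @export
run_re_stratified_eval <- function(data, model) {
  stopifnot("re_stratum" %in% names(data))
  pred <- stats::predict(model, data, type = "class")
  purrr::map_dfr(c("high", "median", "low"), function(s) {
    sel <- data$re_stratum == s
    if (!any(sel)) return(NULL)  # empty stratum: absent, not an error
    cnt <- confusion(data$label[sel], pred[sel])
    tibble::tibble(
      stratum = s, n = sum(sel),
      tpr = if (cnt$tp + cnt$fn > 0) cnt$tp / (cnt$tp + cnt$fn) else NA_real_,
      fpr = if (cnt$fp + cnt$tn > 0) cnt$fp / (cnt$fp + cnt$tn) else NA_real_,
      mcc = mcc(cnt))
  })
}
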