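#' SVM parameter grid
#'
#' The tuning grid: log2(C) from -5 to 15 and log2(gamma) from -15 to 3 in
#' steps of 2, crossed with half-window sizes 0..7 — 11 x 10 x 8 = 880
#' points.
#'
#' @param log2C,log2gamma,n_window Grid axes; defaults as above.
#' @return A tibble with columns `n_window`, `log2C`, `log2gamma`, `C`,
#'   `gamma`, ordered lexicographically by (n_window, log2C, log2gamma).
#' @export
svm_grid <- function(log2C = seq(-5, 15, by = 2),
                     log2gamma = seq(-15, 3, by = 2),
                     n_window = 0:7) {
  g <- tidyr::expand_grid(n_window = n_window, log2C = log2C,
                          log2gamma = log2gamma)
  dplyr::mutate(g, C = 2^.data$log2C, gamma = 2^.data$log2gamma)
}

feature_matrix <- function(data, features) {
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop("Feature column(s) absent from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(data[, features, drop = FALSE])
}

#' Standardize a training feature matrix
#'
#' Centers and scales each feature to mean 0 and unit standard deviation
#' on the training data; constant features are dropped with a warning.
#' Test data must be transformed with the training parameters, never its
#' own (use the returned `center`/`scale`).
#'
#' @param x Numeric matrix (rows = records) with at least 2 rows.
#' @return A list with `x` (scaled matrix over kept features), `center`,
#'   `scale` (named vectors), `kept` (feature names retained).
#' @export
standardize <- function(x) {
  if (nrow(x) < 2) stop("standardize() needs at least 2 rows.", call. = FALSE)
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("All features are constant.", call. = FALSE)
  if (any(!keep)) {
    warning("Dropping constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
  }
  x <- x[, keep, drop = FALSE]
  list(x = scale(x, center = ctr[keep], scale = sdv[keep]),
       center = ctr[keep], scale = sdv[keep], kept = colnames(x))
}

apply_scaling <- function(x, center, scale_) {
  scale(x[, names(center), drop = FALSE], center = center, scale = scale_)
}

check_labels <- function(y) {
  y <- as.character(y)
  if (!all(y %in% c("disease", "neutral"))) {
    stop("Labels must be 'disease' or 'neutral'.", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("Both classes must be present to train.", call. = FALSE)
  }
  factor(y, levels = c("neutral", "disease"))
}

# fit an RBF SVM on pre-scaled x; returns the e1071 fit plus the sign that
# orients decision values so larger = more disease-like
fit_rbf <- function(x, y, C, gamma) {
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  pr <- stats::predict(fit, x, decision.values = TRUE)
  cn <- colnames(attr(pr, "decision.values"))
  sign <- if (identical(cn, "disease/neutral")) 1 else -1
  list(fit = fit, sign = sign)
}

rbf_decision <- function(fitted, x) {
  pr <- stats::predict(fitted$fit, x, decision.values = TRUE)
  dv <- fitted$sign * as.numeric(attr(pr, "decision.values"))
  list(decision = dv, class = as.character(pr))
}

platt_sigmoid <- function(decision, y) {
  # sigmoid p(disease | d) = 1 / (1 + exp(-(A d + B))) fitted by binomial GLM
  df <- data.frame(d = decision, y = as.integer(y == "disease"))
  fit <- suppressWarnings(stats::glm(y ~ d, family = stats::binomial(),
                                     data = df))
  c(A = unname(stats::coef(fit)[2]), B = unname(stats::coef(fit)[1]))
}

sigmoid_prob <- function(decision, calib) {
  stats::plogis(calib["A"] * decision + calib["B"])
}

#' Train an RBF-SVM indel classifier
#'
#' Standardizes the selected features on the training data, fits a
#' soft-margin radial-basis-function SVM (LIBSVM via e1071), and
#' calibrates a sigmoid mapping from decision values to disease
#' probabilities on internally cross-validated decision values.
#'
#' @param data Feature tibble with a `label` column
#'   (`disease`/`neutral`) and the feature columns.
#' @param features Character vector of feature names to use.
#' @param C,gamma SVM cost and RBF width.
#' @param seed Integer seed controlling the internal calibration folds.
#' @param calibrate Fit the probability sigmoid (default `TRUE`; skipped
#'   in inner tuning loops for speed).
#' @return An object of class `nfs_model`.
#' @export
train_svm <- function(data, features, C = 1, gamma = 1 / length(features),
                      seed = 1, calibrate = TRUE) {
  y <- check_labels(data$label)
  sc <- standardize(feature_matrix(data, features))
  fitted <- fit_rbf(sc$x, y, C, gamma)
  calib <- NULL
  if (calibrate) {
    set.seed(seed)
    k <- min(5L, as.integer(min(table(y))))
    folds <- sample(rep_len(seq_len(max(k, 2L)), length(y)))
    dv <- rep(NA_real_, length(y))
    for (f in unique(folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      ff <- fit_rbf(sc$x[tr, , drop = FALSE], y[tr], C, gamma)
      dv[!tr] <- rbf_decision(ff, sc$x[!tr, , drop = FALSE])$decision
    }
    ok <- !is.na(dv)
    calib <- platt_sigmoid(dv[ok], as.character(y)[ok])
  }
  structure(
    list(version = 1L, features = sc$kept, center = sc$center,
         scale = sc$scale, C = C, gamma = gamma,
         sv = unclass(fitted$fit$SV), coefs = as.numeric(fitted$fit$coefs),
         rho = fitted$fit$rho, sign = fitted$sign, calib = calib,
         seed = seed, data_hash = rlang::hash(data[order(data$label), ])),
    class = "nfs_model")
}

#' @export
print.nfs_model <- function(x, ...) {
  cat("RBF-SVM indel classifier (", length(x$features), " features, ",
      nrow(x$sv), " support vectors)\n", sep = "")
  cat("  C = ", x$C, ", gamma = ", format(x$gamma, digits = 4),
      if (!is.null(x$calib)) ", sigmoid-calibrated" else "", "\n", sep = "")
  invisible(x)
}

# decision function recomputed from the serialized pieces, so predictions
# survive a plain-text round trip exactly
model_decision <- function(object, newdata) {
  x <- apply_scaling(feature_matrix(newdata, object$features),
                     object$center, object$scale)
  d2 <- outer(rowSums(x^2), rowSums(object$sv^2), "+") -
    2 * x %*% t(object$sv)
  k <- exp(-object$gamma * t(d2))
  object$sign * (as.numeric(object$coefs %*% k) - object$rho)
}

#' Predict with a trained indel classifier
#'
#' @param object An `nfs_model`.
#' @param newdata Feature tibble containing the model's feature columns.
#' @param type `"class"` (default), `"decision"` or `"prob"` (requires a
#'   calibrated model).
#' @param ... Unused.
#' @return Character classes, numeric decision values, or disease
#'   probabilities.
#' @export
predict.nfs_model <- function(object, newdata,
                              type = c("class", "decision", "prob"), ...) {
  type <- match.arg(type)
  dv <- model_decision(object, newdata)
  switch(type,
         decision = dv,
         class = ifelse(dv > 0, "disease", "neutral"),
         prob = {
           if (is.null(object$calib)) {
             stop("Model was trained with calibrate = FALSE; ",
                  "probabilities unavailable.", call. = FALSE)
           }
           unname(sigmoid_prob(dv, object$calib))
         })
}

draw_folds <- function(y, k, seed, max_retries = 25L) {
  set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    folds <- sample(rep_len(seq_len(k), length(y)))
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[folds != f])) == 2
    }, TRUE))
    if (ok) return(folds)
  }
  stop("Could not draw a ", k, "-fold partition with both classes in ",
       "every training set.", call. = FALSE)
}

#' k-fold cross-validation of the RBF-SVM
#'
#' Randomly partitions the records into `k` folds (simple random, seeded),
#' trains on k-1 folds and predicts the held-out fold, so every record
#' receives exactly one out-of-fold prediction. Metrics are pooled over
#' folds; probabilities come from a sigmoid fitted to the pooled
#' out-of-fold decision values.
#'
#' @inheritParams train_svm
#' @param k Number of folds (default 10).
#' @param folds Optional pre-drawn fold assignment (used by
#'   [greedy_select()] to hold the partition fixed across steps).
#' @return An object of class `nfs_cv`: list with `predictions` (tibble:
#'   `id`, `label`, `fold`, `decision`, `prob`, `pred`), `counts`,
#'   `metrics` (mcc, auc, precision, recall, accuracy), `k`, `seed`.
#' @export
kfold_cv <- function(data, features, C = 1, gamma = 1 / length(features),
                     k = 10, seed = 1, folds = NULL) {
  y <- check_labels(data$label)
  if (nrow(data) < k) stop("Need at least k records.", call. = FALSE)
  if (is.null(folds)) folds <- draw_folds(as.character(y), k, seed)
  x_all <- feature_matrix(data, features)
  dv <- rep(NA_real_, nrow(data))
  pred <- rep(NA_character_, nrow(data))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    sc <- withCallingHandlers(
      standardize(x_all[tr, , drop = FALSE]),
      warning = function(w) invokeRestart("muffleWarning"))
    fitted <- fit_rbf(sc$x, y[tr], C, gamma)
    te <- apply_scaling(x_all[!tr, , drop = FALSE], sc$center, sc$scale)
    out <- rbf_decision(fitted, te)
    dv[!tr] <- out$decision
    pred[!tr] <- out$class
  }
  calib <- platt_sigmoid(dv, as.character(y))
  counts <- confusion(as.character(y), pred)
  metrics <- list(
    mcc = mcc(counts),
    auc = roc_auc(dv, as.character(y))$auc,
    precision = tryCatch(precision(counts), error = function(e) NA_real_),
    recall = tryCatch(recall(counts), error = function(e) NA_real_),
    accuracy = accuracy(counts))
  structure(
    list(predictions = tibble::tibble(
      id = if ("id" %in% names(data)) data$id else seq_len(nrow(data)),
      label = as.character(y), fold = folds, decision = dv,
      prob = unname(sigmoid_prob(dv, calib)), pred = pred),
      counts = counts, metrics = metrics, k = k, seed = seed,
      features = features, C = C, gamma = gamma),
    class = "nfs_cv")
}

#' @export
print.nfs_cv <- function(x, ...) {
  m <- x$metrics
  cat(x$k, "-fold cross-validation (", nrow(x$predictions), " records, ",
      length(x$features), " features)\n", sep = "")
  cat(sprintf("  MCC %.3f  AUC %.3f  precision %.3f  recall %.3f  accuracy %.3f\n",
              m$mcc, m$auc, m$precision, m$recall, m$accuracy))
  invisible(x)
}

#' Grid search for SVM parameters
#'
#' Evaluates 10-fold cross-validated MCC at every grid point and returns
#' the best parameters; ties break toward the smallest
#' (n_window, log2C, log2gamma) lexicographically. Because the half-window
#' changes the features themselves, `data` may be a named list of feature
#' tibbles keyed by window size (`"0"`..`"7"`); a single tibble restricts
#' the search to the grid's C/gamma axes.
#'
#' @param data Feature tibble, or named list of tibbles keyed by
#'   `n_window`.
#' @param features Feature names.
#' @param grid Tibble from [svm_grid()] (default: the full 880-point grid).
#' @param k,seed Cross-validation folds and seed (the same fold partition
#'   is reused at every grid point for comparability).
#' @return List with `best` (one-row tibble) and `table` (grid with an
#'   `mcc` column).
#' @export
grid_search <- function(data, features, grid = svm_grid(), k = 10, seed = 1) {
  single <- is.data.frame(data)
  if (single) {
    grid <- dplyr::distinct(grid, .data$log2C, .data$log2gamma,
                            .keep_all = TRUE)
  }
  get_data <- function(w) {
    if (single) return(data)
    d <- data[[as.character(w)]]
    if (is.null(d)) stop("No feature tibble for n_window = ", w,
                         call. = FALSE)
    d
  }
  folds_by_w <- list()
  mccs <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    w <- as.character(grid$n_window[i])
    d <- get_data(w)
    if (is.null(folds_by_w[[w]])) {
      folds_by_w[[w]] <<- draw_folds(as.character(d$label), k, seed)
    }
    cv <- kfold_cv(d, features, C = grid$C[i], gamma = grid$gamma[i],
                   k = k, seed = seed, folds = folds_by_w[[w]])
    cv$metrics$mcc
  })
  tab <- dplyr::mutate(grid, mcc = mccs)
  ord <- order(-tab$mcc, tab$n_window, tab$log2C, tab$log2gamma)
  list(best = tab[ord[1], ], table = tab)
}

cv_mcc_fixed <- function(data, features, C, gamma, k, folds) {
  kfold_cv(data, features, C = C, gamma = gamma, k = k,
           folds = folds)$metrics$mcc
}

#' Greedy forward feature selection by cross-validated MCC
#'
#' Starts from the single feature with the highest 10-fold CV MCC, then
#' repeatedly adds the remaining feature whose inclusion raises the MCC
#' the most, halting when no candidate increases it. The fold partition is
#' drawn once and held fixed across steps so MCC differences reflect the
#' features, not partition noise.
#'
#' @inheritParams kfold_cv
#' @param max_features Optional cap on the subset size.
#' @return An object of class `nfs_trace`: tibble `trace` (`step`,
#'   `feature`, `mcc`), `selected`, `stop_reason`.
#' @export
greedy_select <- function(data, features, C = 1,
                          gamma = 1 / length(features), k = 10, seed = 1,
                          max_features = Inf) {
  stopifnot(length(features) >= 2)
  folds <- draw_folds(as.character(check_labels(data$label)), k, seed)
  selected <- character()
  remaining <- features
  trace <- list()
  best_mcc <- -Inf
  stop_reason <- "all features used"
  while (length(remaining) > 0 && length(selected) < max_features) {
    cand_mcc <- vapply(remaining, function(f) {
      suppressWarnings(
        cv_mcc_fixed(data, c(selected, f), C, gamma, k, folds))
    }, 0)
    # ties break toward canonical (input) feature order
    best_i <- which(cand_mcc == max(cand_mcc))[1]
    if (cand_mcc[best_i] <= best_mcc) {
      stop_reason <- "no improvement"
      break
    }
    best_mcc <- cand_mcc[best_i]
    selected <- c(selected, remaining[best_i])
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(selected), feature = remaining[best_i], mcc = best_mcc)
    remaining <- remaining[-best_i]
  }
  if (length(remaining) == 0 && stop_reason != "no improvement") {
    stop_reason <- "all features used"
  } else if (length(selected) >= max_features &&
             stop_reason != "no improvement") {
    stop_reason <- "max features reached"
  }
  structure(list(trace = dplyr::bind_rows(trace), selected = selected,
                 stop_reason = stop_reason, k = k, seed = seed),
            class = "nfs_trace")
}

#' @export
print.nfs_trace <- function(x, ...) {
  cat("Greedy feature selection: ", length(x$selected), " feature(s), ",
      "stopped: ", x$stop_reason, "\n", sep = "")
  print(x$trace)
  invisible(x)
}

#' Label-noise robustness experiment
#'
#' Per repeat, draws a fresh k-fold partition; within each fold's training
#' set, flips `round(rate * n_train)` labels chosen uniformly at random
#' (disease to neutral and vice versa), trains, and records the MCC on the
#' untouched test fold. Mimics annotation error in the training data.
#'
#' @inheritParams kfold_cv
#' @param rate Flip rate in \[0, 0.5).
#' @param repeats Number of repeats (default 10).
#' @return List with `mean_mcc`, `sd_mcc` and `per_fold` (tibble of
#'   `repeat_`, `fold`, `mcc`).
#' @export
label_noise_experiment <- function(data, features, rate, C = 1,
                                   gamma = 1 / length(features), k = 10,
                                   repeats = 10, seed = 1) {
  stopifnot(rate >= 0, rate < 0.5)
  y <- as.character(check_labels(data$label))
  x_all <- feature_matrix(data, features)
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- draw_folds(y, k, seed + r)
    set.seed(seed * 1000L + r)
    for (f in sort(unique(folds))) {
      tr <- which(folds != f)
      y_tr <- y[tr]
      n_flip <- round(rate * length(tr))
      if (n_flip > 0) {
        flip <- sample(length(tr), n_flip)
        y_tr[flip] <- ifelse(y_tr[flip] == "disease", "neutral", "disease")
      }
      if (length(unique(y_tr)) < 2) next
      sc <- withCallingHandlers(
        standardize(x_all[tr, , drop = FALSE]),
        warning = function(w) invokeRestart("muffleWarning"))
      fitted <- fit_rbf(sc$x, factor(y_tr, levels = c("neutral", "disease")),
                        C, gamma)
      te <- apply_scaling(x_all[folds == f, , drop = FALSE],
                          sc$center, sc$scale)
      out <- rbf_decision(fitted, te)
      rows[[length(rows) + 1]] <- tibble::tibble(
        repeat_ = r, fold = f,
        mcc = mcc(confusion(y[folds == f], out$class)))
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  list(mean_mcc = mean(per_fold$mcc), sd_mcc = stats::sd(per_fold$mcc),
       per_fold = per_fold)
}

#' Remove low-frequency neutral variants
#'
#' Drops neutral records whose minor allele frequency is strictly below
#' the threshold (default 2%), the filter used to probe sensitivity to
#' potential false negatives among rare putatively neutral variants.
#' Disease records are never filtered.
#'
#' @param data Tibble with `label` and `maf` columns.
#' @param threshold MAF threshold (default 0.02); strictly-below records
#'   are removed.
#' @return Filtered tibble.
#' @export
maf_filter <- function(data, threshold = 0.02) {
  neutral <- data$label == "neutral"
  no_maf <- neutral & is.na(data$maf)
  if (any(no_maf)) {
    stop("Neutral record(s) without MAF: ",
         paste(data$id[no_maf], collapse = ", "), call. = FALSE)
  }
  data[!(neutral & data$maf < threshold), ]
}

#' Save / load a trained model as versioned plain text
#'
#' The model is written as JSON holding the scaled support vectors, dual
#' coefficients, bias, kernel parameters, feature scaling and sigmoid
#' calibration, with full numeric precision, so `load_model(save_model(m))`
#' reproduces identical predictions.
#'
#' @param model An `nfs_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `nfs_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nfs_model"))
  out <- model
  out$sv <- lapply(seq_len(nrow(model$sv)),
                   function(i) unname(model$sv[i, ]))
  jsonlite::write_json(unclass(out), path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("Cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(raw$version) || raw$version != 1L) {
    stop("Unsupported model file version: ",
         if (is.null(raw$version)) "<missing>" else raw$version,
         call. = FALSE)
  }
  if (is.list(raw$sv)) raw$sv <- do.call(rbind, lapply(raw$sv, unlist))
  raw$sv <- matrix(as.numeric(raw$sv), nrow = nrow(raw$sv),
                   dimnames = list(NULL, raw$features))
  raw$center <- stats::setNames(unlist(raw$center), raw$features)
  raw$scale <- stats::setNames(unlist(raw$scale), raw$features)
  if (!is.null(raw$calib)) {
    raw$calib <- stats::setNames(unlist(raw$calib), c("A", "B"))
  }
  structure(raw, class = "nfs_model")
}
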