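#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x An `nfs_cv`.
#' @param ... Unused.
#' @return The per-record out-of-fold prediction tibble.
#' @export
tidy.nfs_cv <- function(x, ...) x$predictions

#' One-row summary of a cross-validation result
#'
#' @param x An `nfs_cv`.
#' @param ... Unused.
#' @return Tibble with `mcc`, `auc`, `precision`, `recall`, `accuracy`,
#'   `k`, `n_features`, `n`.
#' @export
glance.nfs_cv <- function(x, ...) {
  tibble::tibble(mcc = x$metrics$mcc, auc = x$metrics$auc,
                 precision = x$metrics$precision, recall = x$metrics$recall,
                 accuracy = x$metrics$accuracy, k = x$k,
                 n_features = length(x$features), n = nrow(x$predictions))
}

#' Tidy a feature-selection trace
#'
#' @param x An `nfs_trace`.
#' @param ... Unused.
#' @return The `step`/`feature`/`mcc` tibble.
#' @export
tidy.nfs_trace <- function(x, ...) x$trace

#' One-row summary of a feature-selection trace
#'
#' @param x An `nfs_trace`.
#' @param ... Unused.
#' @export
glance.nfs_trace <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 final_mcc = if (nrow(x$trace)) max(x$trace$mcc) else NA_real_,
                 stop_reason = x$stop_reason)
}

#' Tidy a trained model
#'
#' @param x An `nfs_model`.
#' @param ... Unused.
#' @return Tibble of the model's features with their training scaling.
#' @export
tidy.nfs_model <- function(x, ...) {
  tibble::tibble(feature = x$features, center = unname(x$center),
                 scale = unname(x$scale))
}

#' One-row summary of a trained model
#'
#' @param x An `nfs_model`.
#' @param ... Unused.
#' @export
glance.nfs_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features), n_sv = nrow(x$sv),
                 C = x$C, gamma = x$gamma, calibrated = !is.null(x$calib))
}

#' Tidy a MAF bin report
#'
#' @param x An `nfs_maf_bins`.
#' @param ... Unused.
#' @return The per-bin tibble.
#' @export
tidy.nfs_maf_bins <- function(x, ...) x$bins

#' One-row summary of a MAF bin report
#'
#' @param x An `nfs_maf_bins`.
#' @param ... Unused.
#' @export
glance.nfs_maf_bins <- function(x, ...) {
  tibble::tibble(r = x$r, slope = x$slope, intercept = x$intercept,
                 n_filled = sum(x$bins$n > 0))
}
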