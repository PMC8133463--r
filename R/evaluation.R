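# Spatially blocked validation: the study region is split into k equal-angle
# radial sectors about the presence centroid, models are refitted leaving one
# sector out at a time, and the pooled out-of-sector predictions are scored
# with AUC-ROC. Variable importance is the drop in pooled AUC when each
# covariate is left out of the refits (delta AUC), standardised to shares.

#' Assign records to radial segments
#'
#' Each record is assigned to one of `k` equal-angle sectors by the planar
#' bearing of its point from the centre (default: the centroid of the
#' presence records). Sector 0 starts at `offset` degrees measured
#' counter-clockwise from due east. Every record — including pseudo-absences
#' — receives a segment; a record exactly at the centre goes to sector 0.
#'
#' @param records Tibble with `lon`, `lat` and optionally `label` columns.
#' @param k Number of sectors (>= 2).
#' @param center Optional named numeric `lon`, `lat`; defaults to the mean
#'   position of rows with `label == "presence"` (all rows if no labels).
#' @param offset Angular offset of the first sector boundary, degrees.
#' @return A `segment_assignment` list: `segment` (0-based integer per
#'   record), `center`, `k`, `offset`, `boundaries`.
#' @export
radial_segments <- function(records, k, center = NULL, offset = 0) {
  if (k < 2) {
    rlang::abort("`k` must be >= 2", class = "climenvelope_config_error")
  }
  if (nrow(records) == 0) {
    rlang::abort("`records` is empty", class = "climenvelope_config_error")
  }
  if (is.null(center)) {
    ref <- if ("label" %in% names(records) && any(records$label == "presence")) {
      records[records$label == "presence", ]
    } else records
    center <- c(lon = mean(ref$lon), lat = mean(ref$lat))
  }
  dlon <- records$lon - center[["lon"]]
  dlat <- records$lat - center[["lat"]]
  ang <- (atan2(dlat, dlon) * 180 / pi) %% 360
  seg <- as.integer(floor(((ang - offset) %% 360) / (360 / k)))
  seg[dlon == 0 & dlat == 0] <- 0L
  structure(list(
    segment = seg, center = center, k = as.integer(k), offset = offset,
    boundaries = (offset + (0:(k - 1)) * 360 / k) %% 360
  ), class = "segment_assignment")
}

#' @exportS3Method base::print
print.segment_assignment <- function(x, ...) {
  cat(sprintf("<segment_assignment> k = %d about (%.3f, %.3f); sizes: %s\n",
              x$k, x$center[["lon"]], x$center[["lat"]],
              paste(tabulate(x$segment + 1L, x$k), collapse = ", ")))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance: the probability that a randomly chosen presence
#' scores above a randomly chosen absence, with ties counting one half.
#' Computed by the midrank formulation, which is exactly the all-pairs
#' enumeration.
#'
#' @param observed Binary vector (1 = presence).
#' @param predicted Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  n1 <- sum(observed == 1)
  n0 <- sum(observed == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("AUC is undefined with a single class",
                 class = "climenvelope_degenerate_error")
  }
  r <- rank(predicted, ties.method = "average")
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-segment-out cross-validated predictions
#'
#' For each of the `k` radial segments, fits the model on the other `k - 1`
#' segments and predicts the held-out one, so every record is predicted
#' exactly once by a model that never saw its segment. The pooled held-out
#' predictions across all segments are scored with a single AUC.
#'
#' @param table Feature table.
#' @param spec An [algorithm_spec()].
#' @param segments A [radial_segments()] assignment for the rows of `table`.
#' @param covariates Covariates to use (default all five).
#' @return A `cv_evaluation` tibble: `row`, `segment`, `response`,
#'   `prediction`, with the pooled AUC as attribute `auc` (see
#'   [glance.cv_evaluation()]).
#' @export
loocv_predict <- function(table, spec, segments, covariates = bioclim_vars()) {
  stopifnot(length(segments$segment) == nrow(table))
  seg <- segments$segment
  pred <- rep(NA_real_, nrow(table))
  for (s in sort(unique(seg))) {
    hold <- seg == s
    train <- table[!hold, ]
    if (length(unique(train$response)) < 2) {
      rlang::abort(sprintf("fold %d leaves a single-class training set", s),
                   class = "climenvelope_degenerate_fold_error")
    }
    model <- fit_sdm(train, spec, covariates)
    pred[hold] <- predict(model, table[hold, ])
  }
  out <- tibble(row = seq_len(nrow(table)), segment = seg,
                response = table$response, prediction = pred)
  attr(out, "auc") <- auc_roc(out$response, out$prediction)
  attr(out, "algorithm") <- spec$id
  attr(out, "k") <- segments$k
  class(out) <- c("cv_evaluation", class(tibble()))
  out
}

#' @rdname loocv_predict
#' @param x A `cv_evaluation`.
#' @param ... Unused.
#' @export
glance.cv_evaluation <- function(x, ...) {
  tibble(algorithm = attr(x, "algorithm"), k = attr(x, "k"),
         n = nrow(x), auc = attr(x, "auc"))
}

#' Delta-AUC variable importance
#'
#' Refits the model with each covariate left out in turn, using the same
#' leave-one-segment-out folds, and reports per covariate the drop in pooled
#' cross-validated AUC (`delta_auc = auc_full - auc_without`). Deltas are
#' standardised to shares by dividing by their sum; shares are reported as
#' `NA` when the summed delta is not positive (raw deltas stay intact).
#'
#' @inheritParams loocv_predict
#' @return A `variable_importance` tibble: `variable`, `delta_auc`, `share`,
#'   with the full-model AUC as attribute `auc_full`.
#' @export
delta_auc_importance <- function(table, spec, segments,
                                 covariates = bioclim_vars()) {
  full <- loocv_predict(table, spec, segments, covariates)
  auc_full <- attr(full, "auc")
  deltas <- vapply(covariates, function(v) {
    cv <- loocv_predict(table, spec, segments, setdiff(covariates, v))
    auc_full - attr(cv, "auc")
  }, numeric(1))
  total <- sum(deltas)
  shares <- if (total > 0) deltas / total else {
    rlang::inform("summed delta AUC is not positive; shares undefined")
    rep(NA_real_, length(deltas))
  }
  out <- tibble(variable = covariates, delta_auc = as.numeric(deltas),
                share = as.numeric(shares))
  attr(out, "auc_full") <- auc_full
  attr(out, "algorithm") <- spec$id
  class(out) <- c("variable_importance", class(tibble()))
  out
}

#' Maximum-kappa threshold selection
#'
#' Computes Cohen's kappa for binarisation at every candidate threshold (all
#' distinct predicted values plus 0 and 1, comparator `>=`) and returns the
#' threshold maximising kappa; ties break toward the smallest threshold.
#'
#' @param observed Binary vector (1 = presence).
#' @param predicted Numeric probabilities.
#' @return A `threshold_result` list: `threshold`, `kappa` and the confusion
#'   counts `tp`, `fp`, `fn`, `tn` at the selected threshold.
#' @export
max_kappa_threshold <- function(observed, predicted) {
  n1 <- sum(observed == 1); n0 <- sum(observed == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("kappa is undefined with a single class",
                 class = "climenvelope_degenerate_error")
  }
  n <- length(observed)
  cand <- sort(unique(c(0, predicted, 1)))
  # counts of each class at values >= t, via suffix sums over sorted values
  ord <- order(predicted)
  ps <- predicted[ord]; os <- observed[ord]
  tp <- rev(cumsum(rev(os)))        # suffix sums of presences
  fp <- rev(cumsum(rev(1 - os)))    # suffix sums of absences
  first_ge <- findInterval(cand - 1e-15, ps) + 1  # index of first value >= t
  TP <- ifelse(first_ge <= n, tp[pmin(first_ge, n)], 0)
  FP <- ifelse(first_ge <= n, fp[pmin(first_ge, n)], 0)
  FN <- n1 - TP
  TN <- n0 - FP
  po <- (TP + TN) / n
  pe <- ((TP + FP) * n1 + (FN + TN) * n0) / n^2
  kappa <- ifelse(abs(1 - pe) < 1e-12, 0, (po - pe) / (1 - pe))
  best <- which.max(kappa)  # which.max returns the first (smallest) maximiser
  structure(list(threshold = cand[best], kappa = kappa[best],
                 tp = as.integer(TP[best]), fp = as.integer(FP[best]),
                 fn = as.integer(FN[best]), tn = as.integer(TN[best])),
            class = "threshold_result")
}

#' @exportS3Method base::print
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> threshold = %.4f, kappa = %.4f (tp %d fp %d fn %d tn %d)\n",
              x$threshold, x$kappa, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @rdname delta_auc_importance
#' @param x A `variable_importance`.
#' @param ... Unused.
#' @export
tidy.variable_importance <- function(x, ...) as_tibble(x)

#' @rdname delta_auc_importance
#' @export
glance.variable_importance <- function(x, ...) {
  tibble(algorithm = attr(x, "algorithm"), auc_full = attr(x, "auc_full"),
         sum_delta = sum(x$delta_auc))
}
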