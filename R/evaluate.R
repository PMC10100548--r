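#' Threshold detection probabilities into predicted flags
#'
#' @param p Detection probabilities in `[0, 1]` (typically posterior
#'   medians).
#' @param threshold Classification threshold; `p >= threshold` is a
#'   predicted detect (the boundary counts as a detect).
#' @return Logical vector of predicted detection flags.
#' @export
classify <- function(p, threshold = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("probabilities must lie in [0, 1]")
  p >= threshold
}

#' Confusion-matrix metrics
#'
#' @param predicted,observed Logical vectors of equal length (`n >= 1`).
#' @return A list with counts `tp`, `fp`, `tn`, `fn` and rates `accuracy`,
#'   `tpr`, `tnr`; a rate whose class is empty in `observed` is `NA`.
#' @export
confusion_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length")
  }
  if (length(observed) < 1L) abort("need at least one case")
  tp <- sum(predicted & observed)
  fp <- sum(predicted & !observed)
  tn <- sum(!predicted & !observed)
  fn <- sum(!predicted & observed)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(observed),
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the probability that a
#' random detect scores above a random nondetect, with ties credited 0.5.
#'
#' @param p Scores (e.g., median detection probabilities).
#' @param observed Logical detection flags; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(p, observed) {
  n1 <- sum(observed)
  n0 <- sum(!observed)
  if (n1 == 0L || n0 == 0L) abort("AUC requires both classes present")
  r <- rank(p)  # average ranks give 0.5 credit per tied pair
  (sum(r[observed]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' RMSE of concentration predictions on true positives
#'
#' @param pred,obs Predicted and observed log10 mg/m3 concentrations.
#' @param mask Logical mask selecting the true positives (empirically
#'   detected and predicted detected); must select at least one case.
#' @return Root-mean-square error on the log10 scale.
#' @export
rmse_true_positives <- function(pred, obs, mask) {
  if (!any(mask)) abort("`mask` selects no cases")
  sqrt(mean((pred[mask] - obs[mask])^2))
}

#' Fraction of predictions within k orders of magnitude
#'
#' @param pred,obs Log10-scale predictions and observations.
#' @param k Allowed absolute error in orders of magnitude; an error of
#'   exactly `k` counts as within.
#' @return Fraction in `[0, 1]`.
#' @export
frac_within_k_orders <- function(pred, obs, k = 1) {
  if (length(pred) < 1L) abort("need at least one case")
  mean(abs(pred - obs) <= k)
}

#' Combined hurdle accuracy
#'
#' A case is a success when either (a) it is an observed nondetect and
#' predicted nondetect, or (b) it is an observed detect, predicted detect,
#' and the predicted concentration is within `k` orders of magnitude of the
#' observed one.
#'
#' @param pred_flags,obs_flags Logical detection flags.
#' @param pred_conc,obs_conc Log10 concentrations (used on detect cases).
#' @param k Orders-of-magnitude tolerance.
#' @return Fraction of successful cases.
#' @export
combined_hurdle_accuracy <- function(pred_flags, pred_conc, obs_flags,
                                     obs_conc, k = 1) {
  both_nondetect <- !obs_flags & !pred_flags
  hit <- obs_flags & pred_flags & !is.na(obs_conc) &
    abs(pred_conc - obs_conc) <= k
  mean(both_nondetect | hit)
}

#' Null baseline from the training set
#'
#' The null predictor assigns every case the training set's overall
#' detection rate as detection probability and the training mean of detected
#' log10 concentrations as concentration. Its AUC is 0.5 by construction
#' (constant scores). Two classification variants are available downstream:
#' thresholding the constant rate (deterministic) and sampling detection
#' flags at the base rate (stochastic).
#'
#' @param train Training observation table (`detected`, `log10_conc`).
#' @return A list of class `null_exposure_model` with `p_detect` and
#'   `conc_mean` (`NA` when the training set has no detects).
#' @export
null_model <- function(train) {
  if (nrow(train) < 1L) abort("training set is empty")
  structure(
    list(p_detect = mean(train$detected),
         conc_mean = if (any(train$detected)) {
           mean(train$log10_conc[train$detected])
         } else {
           NA_real_
         }),
    class = "null_exposure_model"
  )
}

#' Predicted detection flags from the null baseline
#'
#' @param null A [null_model()].
#' @param n Number of cases.
#' @param mode `"threshold"` (deterministic majority-class prediction) or
#'   `"sample"` (flags drawn Bernoulli at the training base rate).
#' @param threshold Threshold for the deterministic mode.
#' @param seed Seed for the sampling mode.
#' @return Logical vector of length `n`.
#' @export
null_flags <- function(null, n, mode = c("threshold", "sample"),
                       threshold = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "threshold") {
    rep(null$p_detect >= threshold, n)
  } else {
    with_seed(seed, stats::runif(n) < null$p_detect)
  }
}

#' Side-by-side evaluation of model and null predictions
#'
#' Computes the full metric set — confusion counts, accuracy, TPR, TNR, AUC,
#' RMSE on true positives, fraction of true positives within `k` orders of
#' magnitude and the combined hurdle accuracy — for the model and for the
#' null baseline on the same cases.
#'
#' @param p_median Model median detection probability per case.
#' @param conc_median Model median log10 concentration per case.
#' @param observations Observation table with `detected` and `log10_conc`.
#' @param null A [null_model()].
#' @param threshold Classification threshold.
#' @param k Orders-of-magnitude tolerance.
#' @param null_mode Null classification variant (see [null_flags()]).
#' @param seed Seed for the sampling null.
#' @return Data.frame with columns `metric`, `model`, `null`.
#' @export
evaluation_report <- function(p_median, conc_median, observations, null,
                              threshold = 0.5, k = 1,
                              null_mode = "threshold", seed = 1L) {
  obs_flags <- observations$detected
  obs_conc <- observations$log10_conc
  n <- length(obs_flags)

  model_flags <- classify(p_median, threshold)
  nflags <- null_flags(null, n, mode = null_mode, threshold = threshold,
                       seed = seed)
  nconc <- rep(null$conc_mean, n)

  one_side <- function(flags, conc, p_scores) {
    cm <- confusion_metrics(flags, obs_flags)
    tp_mask <- flags & obs_flags
    c(unlist(cm),
      auc = auc(p_scores, obs_flags),
      rmse_tp = if (any(tp_mask)) {
        rmse_true_positives(conc, obs_conc, tp_mask)
      } else {
        NA_real_
      },
      frac_within_k = if (any(tp_mask)) {
        frac_within_k_orders(conc[tp_mask], obs_conc[tp_mask], k)
      } else {
        NA_real_
      },
      combined_accuracy = combined_hurdle_accuracy(flags, conc, obs_flags,
                                                   obs_conc, k))
  }
  m <- one_side(model_flags, conc_median, p_median)
  b <- one_side(nflags, nconc, rep(null$p_detect, n))
  data.frame(metric = names(m), model = unname(m), null = unname(b),
             stringsAsFactors = FALSE)
}
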