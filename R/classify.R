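# Threshold-based DLM classification.
#
# Screening thresholds in routine use: a knee is discoid when the minimum
# body width of the lateral meniscus reaches a fifth of the tibial width
# (RMT >= 0.20, inclusive); a complete discoid additionally exceeds
# RMT > 0.32 (strict). PCM >= 0.75 is reported as an auxiliary positivity
# flag rather than a second inclusion criterion.

#' Classification thresholds
#'
#' @param rmt_dlm RMT at or above which a knee is classified DLM (inclusive).
#' @param rmt_complete RMT above which a DLM is complete (strict).
#' @param pcm_cut PCM positivity cutoff (inclusive).
#' @export
dlm_thresholds <- function(rmt_dlm = 0.20, rmt_complete = 0.32,
                           pcm_cut = 0.75) {
  stopifnot(rmt_dlm > 0, rmt_complete >= rmt_dlm, pcm_cut > 0)
  list(rmt_dlm = rmt_dlm, rmt_complete = rmt_complete, pcm_cut = pcm_cut)
}

#' Classify a measured knee
#'
#' Applies the diagnostic thresholds to a [compute_indices()] result:
#' `is_dlm` iff RMT >= `rmt_dlm` (inclusive); a DLM is `complete` iff
#' RMT > `rmt_complete` (strict), otherwise `incomplete`; non-DLM knees get
#' `dlm_type = "na"`. `pcm_positive` iff PCM >= `pcm_cut`.
#'
#' @param res a `morphometry_result`, or any list with finite `rmt` and `pcm`.
#' @param thresholds a [dlm_thresholds()] list; recorded in the output.
#' @return object of class `dlm_classification`.
#' @export
classify_dlm <- function(res, thresholds = dlm_thresholds()) {
  rmt <- res$rmt
  pcm <- res$pcm
  if (!is.finite(rmt) || !is.finite(pcm)) {
    stop("classify_invalid: rmt and pcm must be finite", call. = FALSE)
  }
  is_dlm <- rmt >= thresholds$rmt_dlm
  dlm_type <- if (!is_dlm) "na" else if (rmt > thresholds$rmt_complete) {
    "complete"
  } else "incomplete"
  structure(list(is_dlm = is_dlm, dlm_type = dlm_type,
                 pcm_positive = pcm >= thresholds$pcm_cut,
                 thresholds = thresholds),
            class = "dlm_classification")
}

#' @export
print.dlm_classification <- function(x, ...) {
  cat("<dlm_classification> ",
      if (x$is_dlm) paste0("DLM (", x$dlm_type, ")") else "non-DLM",
      if (x$pcm_positive) ", PCM-positive" else "",
      sprintf("  [RMT >= %.2f, complete > %.2f, PCM >= %.2f]\n",
              x$thresholds$rmt_dlm, x$thresholds$rmt_complete,
              x$thresholds$pcm_cut), sep = "")
  invisible(x)
}
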