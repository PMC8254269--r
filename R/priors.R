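## High-confidence prior estimation and the two-pass decode workflow.

#' Tally of a preliminary decoding run
#'
#' Counts feeding the high-confidence prior estimator: S_eps, the reads
#' rejected by the noise filter; S_b, the reads classified to each barcode b
#' with confidence above the threshold (passed both filters); and the
#' low-confidence reads (passed the noise filter, failed the confidence
#' filter), which the estimator deliberately ignores under the assumption
#' that low- and high-confidence reads come from the same distribution.
#'
#' @param noise_rejected Count of noise-filter rejections (S_eps).
#' @param high_confidence Named integer vector of per-class high-confidence
#'   counts (S_b).
#' @param low_confidence Optional named integer vector of qc-fail counts.
#' @return An object of class `tally_counts`.
#' @export
tally_counts <- function(noise_rejected, high_confidence,
                         low_confidence = integer(0)) {
  if (noise_rejected < 0 || any(high_confidence < 0) || any(low_confidence < 0))
    stop("counts must be non-negative")
  if (length(high_confidence) && is.null(names(high_confidence)))
    stop("high_confidence must be named by barcode id")
  structure(list(noise_rejected = noise_rejected,
                 high_confidence = high_confidence,
                 low_confidence = low_confidence),
            class = "tally_counts")
}

#' Tally decoded results for prior estimation
#'
#' @param results Decode data.frame from [pamld_decode()].
#' @param set The [barcode_set()] that was decoded against.
#' @return A [tally_counts()].
#' @export
tally_decodes <- function(results, set) {
  rejected <- results$assigned == UNDETERMINED
  hi <- !rejected & !results$qc_fail
  lo <- !rejected & results$qc_fail
  count_by <- function(mask) {
    tab <- table(factor(results$assigned[mask], levels = set$ids))
    stats::setNames(as.integer(tab), set$ids)
  }
  tally_counts(sum(rejected), count_by(hi), count_by(lo))
}

#' High-confidence prior estimator
#'
#' Estimates the noise prior as S_eps / (S_eps + S_B) and each class prior
#' as S_b / (S_eps + S_B), where S_B is the total high-confidence count.
#' Low-confidence (qc-fail) reads are excluded from both numerator and
#' denominator, so the result sums to exactly 1 by construction.
#'
#' Classes with no high-confidence reads receive a prior of exactly 0 (and a
#' warning naming them): in a subsequent pass their posterior is 0. Supply
#' user-devised priors instead if that is not acceptable.
#'
#' @param tally A [tally_counts()].
#' @return A [prior_distribution()].
#' @examples
#' estimate_priors(tally_counts(10, c(b1 = 90)))
#' @export
estimate_priors <- function(tally) {
  stopifnot(inherits(tally, "tally_counts"))
  s_eps <- tally$noise_rejected
  s_b <- tally$high_confidence
  total <- s_eps + sum(s_b)
  if (total <= 0)
    stop("cannot estimate priors from an all-zero tally")
  zero <- names(s_b)[s_b == 0]
  if (length(zero))
    warning("classes with no high-confidence reads receive prior 0: ",
            paste(zero, collapse = ", "), call. = FALSE)
  prior_distribution(s_b / total, s_eps / total)
}

#' Two-pass decoding with estimated priors
#'
#' Pass 1 decodes with uniform class priors (1 - noise) / |B| and the given
#' preliminary noise prior (defaults: confidence threshold 0.95, noise prior
#' 0.05), tallies the filter outcomes, and applies the high-confidence
#' estimator; pass 2 re-decodes every read with the estimated priors.
#'
#' @param obs An [observed_barcodes()] batch (both passes run on the same
#'   buffered observations).
#' @param set A [barcode_set()].
#' @param config A [decoder_config()] used in both passes.
#' @param preliminary_noise_prior Noise prior of the uniform pass-1 decode.
#' @return List with `priors` (the estimate), `results` (pass-2 decode
#'   frame), and `pass1_tally`.
#' @export
two_pass_decode <- function(obs, set, config = decoder_config(),
                            preliminary_noise_prior = 0.05) {
  stopifnot(inherits(obs, "observed_barcodes"))
  LL <- loglik_matrix(obs, set)
  pass1 <- pamld_from_loglik(LL, set,
                             uniform_priors(set, preliminary_noise_prior),
                             config)
  tally <- tally_decodes(pass1, set)
  priors <- estimate_priors(tally)
  results <- pamld_from_loglik(LL, set, priors, config)
  list(priors = priors, results = results, pass1_tally = tally)
}
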