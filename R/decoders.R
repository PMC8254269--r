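## The three decision functions: PAMLD (full posterior + filters),
## minimum-distance (Hamming), and the uniform-prior ML baseline.

check_priors_cover <- function(priors, set) {
  stopifnot(inherits(priors, "prior_distribution"),
            inherits(set, "barcode_set"))
  missing <- setdiff(set$ids, names(priors$class_priors))
  if (length(missing))
    stop("prior missing for barcode(s): ", paste(missing, collapse = ", "))
  priors$class_priors[set$ids]
}

# Row-wise log-sum-exp of cbind(score_matrix, extra_column).
row_logsumexp <- function(score, jmax, extra) {
  mx <- pmax(score[cbind(seq_len(nrow(score)), jmax)], extra)
  mx + log(rowSums(exp(score - mx)) + exp(extra - mx))
}

# Order used for deterministic argmax tie-breaking: lexicographically
# smallest barcode id wins on exactly equal scores.
id_order <- function(set) order(set$ids, method = "radix")

#' Phred-adjusted maximum-likelihood decoding (PAMLD)
#'
#' Computes the full posterior P(b|r) for every barcode b by Bayes' rule,
#' with the denominator including an explicit noise term: the likelihood of
#' a maximum-entropy random sequence (1/4^n, see [noise_likelihood()]) times
#' the noise prior. The class maximizing the posterior is selected, then two
#' filters apply:
#'
#' * noise filter: when the best conditional P(r|b-hat) is below the noise
#'   likelihood, the evidence is inferior to that of a random sequence and
#'   the read is rejected as [UNDETERMINED] without further consideration;
#' * confidence filter: when the posterior does not exceed the confidence
#'   threshold C the read keeps its assignment but is flagged `qc_fail`.
#'
#' The decoding error is 1 - P(b-hat|r). Exactly equal posteriors are broken
#' towards the lexicographically smallest barcode id.
#'
#' @param r An [observed_barcode()] or [observed_barcodes()] batch.
#' @param set A [barcode_set()].
#' @param priors A [prior_distribution()] covering every barcode in the set.
#' @param config A [decoder_config()].
#' @return For a single observation, a `decode_result`; for a batch, a
#'   data.frame with columns `assigned`, `conditional`, `posterior`,
#'   `qc_fail`, `decoding_error`.
#' @examples
#' set <- barcode_set(c(a = "AA", b = "CC"))
#' pr <- prior_distribution(c(a = 0.475, b = 0.475), 0.05)
#' pamld_decode(observed_barcode("AA", c(30, 30)), set, pr)
#' @export
pamld_decode <- function(r, set, priors, config = decoder_config()) {
  UseMethod("pamld_decode")
}

#' @export
pamld_decode.observed_barcode <- function(r, set, priors,
                                          config = decoder_config()) {
  obs <- observed_barcodes(r$sequence, matrix(r$qualities, nrow = 1L))
  as_decode_result(pamld_decode(obs, set, priors, config))
}

#' @export
pamld_decode.observed_barcodes <- function(r, set, priors,
                                           config = decoder_config()) {
  LL <- loglik_matrix(r, set)
  pamld_from_loglik(LL, set, priors, config)
}

# Core PAMLD decision given a precomputed log-likelihood matrix; reused by
# the benchmark so one likelihood evaluation serves several prior settings.
pamld_from_loglik <- function(LL, set, priors, config = decoder_config()) {
  p <- check_priors_cover(priors, set)
  ord <- id_order(set)
  LL <- LL[, ord, drop = FALSE]
  lp <- log(p[ord])
  nreads <- nrow(LL)
  if (nreads == 0L) return(empty_decode_frame())
  score <- sweep(LL, 2L, lp, `+`)
  j <- max.col(score, ties.method = "first")
  idx <- cbind(seq_len(nreads), j)
  log_noise_lik <- log(noise_likelihood(set$length, config))
  noise_term <- log_noise_lik + log(priors$noise_prior)
  logdenom <- row_logsumexp(score, j, rep(noise_term, nreads))
  posterior <- exp(score[idx] - logdenom)
  conditional <- exp(LL[idx])
  assigned <- set$ids[ord][j]
  rejected <- LL[idx] < log_noise_lik
  qc_fail <- !rejected & posterior <= config$confidence_threshold
  assigned[rejected] <- UNDETERMINED
  posterior[rejected] <- NA_real_
  data.frame(assigned = assigned, conditional = conditional,
             posterior = posterior, qc_fail = qc_fail,
             decoding_error = 1 - posterior,
             stringsAsFactors = FALSE)
}

empty_decode_frame <- function() {
  data.frame(assigned = character(0), conditional = numeric(0),
             posterior = numeric(0), qc_fail = logical(0),
             decoding_error = numeric(0), stringsAsFactors = FALSE)
}

as_decode_result <- function(df) {
  decode_result(df$assigned[1L], df$conditional[1L], df$posterior[1L],
                df$qc_fail[1L])
}

#' Minimum-distance (Hamming) decoding
#'
#' Assigns the unique barcode within Hamming distance `tolerance` of the
#' observation (uncalled N bases count as mismatches). Returns
#' [UNDETERMINED] when no barcode is within tolerance or when two barcodes
#' tie at the minimum distance. No posterior is computed: quality scores are
#' ignored, and `posterior`/`decoding_error` are reported as `NA`.
#'
#' The default tolerance is floor((d_min - 1) / 2), the guaranteed-unique
#' correction radius of the codebook.
#'
#' @inheritParams pamld_decode
#' @param tolerance Integer Hamming radius; `NULL` for the codebook default.
#' @return As [pamld_decode()], plus a `distance` column.
#' @export
mdd_decode <- function(r, set, tolerance = NULL) UseMethod("mdd_decode")

#' @export
mdd_decode.observed_barcode <- function(r, set, tolerance = NULL) {
  obs <- observed_barcodes(r$sequence, matrix(r$qualities, nrow = 1L))
  df <- mdd_decode(obs, set, tolerance)
  res <- decode_result(df$assigned[1L], NA_real_, NA_real_, FALSE)
  res$distance <- df$distance[1L]
  res
}

#' @export
mdd_decode.observed_barcodes <- function(r, set, tolerance = NULL) {
  if (is.null(tolerance))
    tolerance <- mdd_default_tolerance(set)
  D <- hamming_matrix(r, set)
  ord <- id_order(set)
  D <- D[, ord, drop = FALSE]
  nreads <- nrow(D)
  if (nreads == 0L) {
    out <- empty_decode_frame()
    out$distance <- integer(0)
    return(out)
  }
  j <- max.col(-D, ties.method = "first")
  idx <- cbind(seq_len(nreads), j)
  dmin_read <- D[idx]
  ties <- rowSums(D == dmin_read) > 1L
  assigned <- set$ids[ord][j]
  assigned[ties | dmin_read > tolerance] <- UNDETERMINED
  data.frame(assigned = assigned, conditional = NA_real_,
             posterior = NA_real_, qc_fail = FALSE,
             decoding_error = NA_real_, distance = as.integer(dmin_read),
             stringsAsFactors = FALSE)
}

#' Default minimum-distance tolerance of a codebook
#'
#' floor((d_min - 1) / 2): the largest radius at which decoding is
#' guaranteed unambiguous.
#'
#' @param set A [barcode_set()].
#' @return Integer tolerance.
#' @export
mdd_default_tolerance <- function(set) {
  as.integer((set$min_pairwise_distance - 1) %/% 2)
}

#' Uniform-prior maximum-likelihood decoding
#'
#' The simple baseline that assumes barcodes are uniformly pooled and noise
#' is negligibly rare, so the posterior is proportional to the conditional
#' and the decoder just maximizes P(r|b). No noise or confidence filter is
#' applied: the decoder never rejects a read. For diagnostics a
#' pseudo-posterior P(r|b-hat) / sum of P(r|b') is reported.
#'
#' @inheritParams pamld_decode
#' @return As [pamld_decode()]; `qc_fail` is always `FALSE`.
#' @export
uniform_ml_decode <- function(r, set) UseMethod("uniform_ml_decode")

#' @export
uniform_ml_decode.observed_barcode <- function(r, set) {
  obs <- observed_barcodes(r$sequence, matrix(r$qualities, nrow = 1L))
  as_decode_result(uniform_ml_decode(obs, set))
}

#' @export
uniform_ml_decode.observed_barcodes <- function(r, set) {
  LL <- loglik_matrix(r, set)
  uniform_ml_from_loglik(LL, set)
}

uniform_ml_from_loglik <- function(LL, set) {
  ord <- id_order(set)
  LL <- LL[, ord, drop = FALSE]
  nreads <- nrow(LL)
  if (nreads == 0L) return(empty_decode_frame())
  j <- max.col(LL, ties.method = "first")
  idx <- cbind(seq_len(nreads), j)
  logdenom <- row_logsumexp(LL, j, rep(-Inf, nreads))
  pseudo <- exp(LL[idx] - logdenom)
  data.frame(assigned = set$ids[ord][j], conditional = exp(LL[idx]),
             posterior = pseudo, qc_fail = FALSE,
             decoding_error = 1 - pseudo, stringsAsFactors = FALSE)
}

#' Combine component confidences of a combinatorial barcode
#'
#' For a combinatorial barcode made of several independently decoded
#' components, the overall confidence is the product of the component
#' posteriors, and the reported error is one minus that product.
#'
#' @param posteriors Numeric vector of component posteriors in \[0, 1\].
#' @return List with `confidence` and `error`.
#' @examples
#' combine_confidences(c(0.99, 0.98))
#' @export
combine_confidences <- function(posteriors) {
  if (length(posteriors) == 0L)
    stop("at least one component posterior is required")
  if (any(is.na(posteriors)) || any(posteriors < 0) || any(posteriors > 1))
    stop("posteriors must lie in [0, 1]")
  confidence <- prod(posteriors)
  list(confidence = confidence, error = 1 - confidence)
}

# Full posterior vector (classes + noise) for one observation; used by
# normalization tests and diagnostics.
posterior_distribution <- function(r, set, priors,
                                   config = decoder_config()) {
  stopifnot(inherits(r, "observed_barcode"))
  obs <- observed_barcodes(r$sequence, matrix(r$qualities, nrow = 1L))
  LL <- loglik_matrix(obs, set)[1L, ]
  p <- check_priors_cover(priors, set)
  noise_term <- noise_likelihood(set$length, config) * priors$noise_prior
  num <- exp(LL) * p
  denom <- noise_term + sum(num)
  c(stats::setNames(num / denom, set$ids), noise = noise_term / denom)
}
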