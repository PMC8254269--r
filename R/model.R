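#' pamld: probabilistic barcode decoding and demultiplexing
#'
#' Demultiplexing assigns pooled sequencing reads to their sample, cell or
#' molecule of origin by decoding short barcode sequences. This package
#' implements the Phred-adjusted maximum-likelihood decoder (PAMLD): for an
#' observed barcode r with basecall quality scores, it computes the full
#' posterior probability P(b|r) for every expected barcode b, accounting for
#' class priors P(b) and an explicit noise prior for indeterminate sequences,
#' then applies a noise filter (reject reads whose best conditional likelihood
#' is below that of a maximum-entropy random sequence) and a confidence filter
#' (flag reads whose posterior does not exceed a threshold C as qc-fail).
#' A minimum-distance (Hamming) decoder and a uniform-prior maximum-likelihood
#' baseline are provided for comparison, together with a high-confidence prior
#' estimator, a semi-synthetic read simulator, accuracy metrics, FASTQ/SAM IO
#' and a command-line interface.
#'
#' @keywords internal
#' @aliases pamld-package
"_PACKAGE"

# Class label used for decoder rejections and for the noise class in metrics.
#' Reserved class labels
#'
#' `UNDETERMINED` is the label a decoder assigns to reads it rejects;
#' `NOISE_CLASS` is the ground-truth label for indeterminate (noise) reads.
#' In classification metrics both map to the same binary "noise" classifier.
#'
#' @format Character constants.
#' @export
UNDETERMINED <- "undetermined"

#' @rdname UNDETERMINED
#' @export
NOISE_CLASS <- "noise"

# Maximum per-base error probability used in likelihoods. Above 3/4 a
# mismatch would be more likely than a match, inverting the decoder.
PHRED_ERROR_CLAMP <- 0.75

BASE_ALPHABET <- c("A", "C", "G", "T")

## ---------------------------------------------------------------------------
## Domain types
## ---------------------------------------------------------------------------

#' Observed barcode: a called sequence with its Phred quality scores
#'
#' The observation r decoded against a barcode set: a nucleotide string over
#' \{A,C,G,T,N\} together with one Phred-scaled quality score per base
#' (q encodes basecall error probability 10^(-q/10)).
#'
#' @param sequence Single nucleotide string over A, C, G, T, N.
#' @param qualities Integer vector of Phred scores in \[0, 93\], one per base.
#' @return An object of class `observed_barcode` with fields `sequence`,
#'   `qualities` and `length`.
#' @examples
#' observed_barcode("ACGT", c(30, 30, 30, 30))
#' @export
observed_barcode <- function(sequence, qualities) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  qualities <- as.integer(qualities)
  n <- nchar(sequence)
  if (length(qualities) != n)
    stop("qualities length (", length(qualities),
         ") does not match sequence length (", n, ")")
  if (any(qualities < 0L) || any(qualities > 93L))
    stop("Phred scores must lie in [0, 93]")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence may only contain A, C, G, T, N: ", sequence)
  structure(list(sequence = sequence, qualities = qualities, length = n),
            class = "observed_barcode")
}

#' A batch of equal-length observed barcodes
#'
#' Columnar container used by the vectorised decoders: all observations share
#' one length (as extracted by a fixed set of transform tokens).
#'
#' @param sequences Character vector of equal-length strings over A,C,G,T,N.
#' @param qualities Integer matrix (reads x positions) of Phred scores, or a
#'   character vector of Phred+33 quality strings.
#' @return An object of class `observed_barcodes` holding the integer-encoded
#'   base matrix and the quality matrix.
#' @export
observed_barcodes <- function(sequences, qualities) {
  n <- unique(nchar(sequences))
  if (length(n) > 1L)
    stop("all observations must have the same length")
  if (length(n) == 0L)
    n <- if (is.matrix(qualities)) ncol(qualities) else 0L
  if (is.character(qualities)) qualities <- decode_phred_strings(qualities)
  qualities <- as.matrix(qualities)
  storage.mode(qualities) <- "integer"
  if (nrow(qualities) != length(sequences) || ncol(qualities) != n)
    stop("quality matrix must be reads x positions and match the sequences")
  if (any(qualities < 0L) || any(qualities > 93L))
    stop("Phred scores must lie in [0, 93]")
  structure(list(bases = encode_base_matrix(sequences, n),
                 qualities = qualities,
                 sequences = sequences,
                 length = n),
            class = "observed_barcodes")
}

#' @export
length.observed_barcodes <- function(x) length(x$sequences)

#' Expected barcode (codeword)
#'
#' One expected barcode b identifying a class: an id and one or more
#' nucleotide segments (e.g. i7 and i5 for dual indexing). Segments are
#' concatenated for decoding.
#'
#' @param id Class label.
#' @param segments Character vector of nucleotide strings over A,C,G,T (no N).
#' @return An object of class `barcode`.
#' @export
barcode <- function(id, segments) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  segments <- as.character(segments)
  if (any(grepl("[^ACGT]", segments)))
    stop("barcode segments may only contain A, C, G, T: ", id)
  structure(list(id = id, segments = segments,
                 concatenated = paste(segments, collapse = ""),
                 concatenated_length = sum(nchar(segments))),
            class = "barcode")
}

#' Barcode set (codebook)
#'
#' The set B of distinct expected barcodes sharing one segment layout. The
#' minimum pairwise Hamming distance d_min over the concatenated sequences is
#' computed on construction; it determines the default correction radius of
#' the minimum-distance decoder, floor((d_min - 1) / 2).
#'
#' @param barcodes List of [barcode()] objects, or a named character vector /
#'   named list of segment vectors (names become ids).
#' @return An object of class `barcode_set` with fields `barcodes`, `ids`,
#'   `length` (concatenated barcode length) and `min_pairwise_distance`.
#' @examples
#' barcode_set(c(s1 = "ACGT", s2 = "TTTT"))
#' @export
barcode_set <- function(barcodes) {
  if (!is.list(barcodes) || !is.null(names(barcodes))) {
    nm <- names(barcodes)
    if (is.null(nm) || any(!nzchar(nm))) stop("barcodes must be named")
    barcodes <- lapply(seq_along(barcodes),
                       function(i) barcode(nm[i], barcodes[[i]]))
  }
  if (!all(vapply(barcodes, inherits, logical(1), "barcode")))
    stop("barcodes must be barcode objects")
  ids <- vapply(barcodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("barcode ids must be distinct")
  concat <- vapply(barcodes, `[[`, character(1), "concatenated")
  if (anyDuplicated(concat)) stop("barcode sequences must be distinct")
  lens <- vapply(barcodes, `[[`, numeric(1), "concatenated_length")
  if (length(unique(lens)) != 1L)
    stop("all barcodes must have the same concatenated length")
  layout <- lapply(barcodes, function(b) nchar(b$segments))
  if (length(unique(layout)) != 1L)
    stop("all barcodes must share the same segment-length layout")
  n <- as.integer(lens[[1L]])
  bmat <- encode_base_matrix(concat, n)
  dmin <- if (length(barcodes) > 1L) min_pairwise_hamming(bmat) else n
  structure(list(barcodes = barcodes, ids = ids, sequences = concat,
                 base_matrix = bmat, length = n,
                 segment_lengths = layout[[1L]],
                 min_pairwise_distance = dmin),
            class = "barcode_set")
}

#' @export
length.barcode_set <- function(x) length(x$ids)

#' @export
print.barcode_set <- function(x, ...) {
  cat("barcode_set:", length(x$ids), "barcodes of", x$length, "nt (",
      length(x$segment_lengths), "segment(s) ), d_min =",
      x$min_pairwise_distance, "\n")
  invisible(x)
}

#' Prior distribution over barcode classes and noise
#'
#' Holds the class priors P(b) and the noise prior for indeterminate
#' sequences. The priors must form a distribution: every value lies in
#' \[0, 1\] and noise + sum of class priors equals 1 (tolerance 1e-9).
#'
#' @param class_priors Named numeric vector, one prior per barcode id.
#' @param noise_prior Prior probability of an indeterminate (noise) read.
#' @return An object of class `prior_distribution`.
#' @examples
#' prior_distribution(c(a = 0.475, b = 0.475), noise_prior = 0.05)
#' @export
prior_distribution <- function(class_priors, noise_prior = 0) {
  class_priors <- unlist(class_priors)
  if (is.null(names(class_priors)) || any(!nzchar(names(class_priors))))
    stop("class_priors must be named by barcode id")
  if (any(class_priors < 0) || any(class_priors > 1) ||
      noise_prior < 0 || noise_prior > 1)
    stop("priors must lie in [0, 1]")
  total <- noise_prior + sum(class_priors)
  if (abs(total - 1) > 1e-9)
    stop(sprintf("priors must sum to 1 (got %.12f)", total))
  structure(list(class_priors = class_priors, noise_prior = noise_prior),
            class = "prior_distribution")
}

#' Uniform priors over a barcode set
#'
#' The default preliminary-pass prior: P(b) = (1 - noise_prior) / |B| for
#' every class.
#'
#' @param set A [barcode_set()].
#' @param noise_prior Noise prior (default 0.05, the preliminary-pass default).
#' @return A [prior_distribution()].
#' @export
uniform_priors <- function(set, noise_prior = 0.05) {
  p <- rep((1 - noise_prior) / length(set$ids), length(set$ids))
  names(p) <- set$ids
  prior_distribution(p, noise_prior)
}

#' Decoder configuration
#'
#' @param confidence_threshold Minimum acceptable posterior C in \[0, 1);
#'   reads with posterior <= C are flagged qc-fail. Default 0.95.
#' @param noise_floor_override Optional value in (0, 1\] replacing the
#'   maximum-entropy noise likelihood 1/4^n (for refined noise models).
#' @param mdd_tolerance Optional integer Hamming radius for the
#'   minimum-distance decoder; default floor((d_min - 1) / 2).
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(confidence_threshold = 0.95,
                           noise_floor_override = NULL,
                           mdd_tolerance = NULL) {
  if (confidence_threshold < 0 || confidence_threshold >= 1)
    stop("confidence_threshold must lie in [0, 1)")
  if (!is.null(noise_floor_override) &&
      (noise_floor_override <= 0 || noise_floor_override > 1))
    stop("noise_floor_override must lie in (0, 1]")
  if (!is.null(mdd_tolerance) && mdd_tolerance < 0)
    stop("mdd_tolerance must be >= 0")
  structure(list(confidence_threshold = confidence_threshold,
                 noise_floor_override = noise_floor_override,
                 mdd_tolerance = mdd_tolerance),
            class = "decoder_config")
}

decode_result <- function(assigned, conditional, posterior, qc_fail) {
  structure(list(assigned = assigned, conditional = conditional,
                 posterior = posterior, qc_fail = qc_fail,
                 decoding_error = if (is.na(posterior)) NA_real_
                                  else 1 - posterior),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat("decode_result: assigned =", x$assigned,
      if (isTRUE(x$qc_fail)) "(qc fail)" else "",
      "\n  conditional P(r|b) =", format(x$conditional),
      "\n  posterior   P(b|r) =", format(x$posterior),
      "\n  decoding error     =", format(x$decoding_error), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Phred arithmetic and likelihoods
## ---------------------------------------------------------------------------

#' Convert a Phred score to a basecall error probability
#'
#' Returns 10^(-q/10), clamped to at most 0.75 for use in likelihoods: an
#' error probability above 3/4 would make a mismatch more likely than a
#' match, so the clamp preserves decoder ordering (and handles q = 0, where
#' the basecall carries no information and all four bases are equally likely).
#'
#' @param q Vector of non-negative Phred scores.
#' @return Error probabilities in (0, 0.75\].
#' @examples
#' phred_to_error_probability(c(30, 10, 0))
#' @export
phred_to_error_probability <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  pmin(10^(-q / 10), PHRED_ERROR_CLAMP)
}

#' Log-likelihood of an observation given a barcode
#'
#' Computes log P(r|b) from the per-base quality scores: position i
#' contributes (1 - p_i) on a match, p_i / 3 on a mismatch (the error is
#' equally likely to produce any of the three alternative bases), and 1/4
#' when the observed base is N (an uncalled base is a maximum-entropy
#' observation carrying no evidence). p_i is the clamped error probability
#' of [phred_to_error_probability()].
#'
#' @param r An [observed_barcode()].
#' @param b A [barcode()] of the same concatenated length.
#' @return log P(r|b), a non-positive number.
#' @examples
#' log_likelihood(observed_barcode("AA", c(30, 30)), barcode("x", "AA"))
#' @export
log_likelihood <- function(r, b) {
  stopifnot(inherits(r, "observed_barcode"), inherits(b, "barcode"))
  if (r$length != b$concatenated_length)
    stop("observation length (", r$length, ") does not match barcode length (",
         b$concatenated_length, ")")
  rb <- strsplit(r$sequence, "", fixed = TRUE)[[1L]]
  bb <- strsplit(b$concatenated, "", fixed = TRUE)[[1L]]
  p <- phred_to_error_probability(r$qualities)
  f <- ifelse(rb == "N", 0.25, ifelse(rb == bb, 1 - p, p / 3))
  sum(log(f))
}

#' Likelihood of a maximum-entropy noise sequence
#'
#' The conditional probability P(r | b not in B) of observing a particular
#' indeterminate sequence of length n, assumed to occur with maximum entropy:
#' 1/4^n. Real noise has lower entropy, so advanced users may override this
#' floor with an empirically refined value.
#'
#' @param n Barcode length (>= 1).
#' @param config Optional [decoder_config()]; its `noise_floor_override`, when
#'   set, replaces the maximum-entropy value.
#' @return A probability.
#' @examples
#' noise_likelihood(8)
#' @export
noise_likelihood <- function(n, config = NULL) {
  if (n < 1) stop("barcode length must be >= 1")
  if (!is.null(config) && !is.null(config$noise_floor_override))
    return(config$noise_floor_override)
  0.25^n
}

## ---------------------------------------------------------------------------
## Internal vectorised machinery
## ---------------------------------------------------------------------------

# Encode a vector of equal-length sequences as an integer matrix
# (reads x positions): A=1, C=2, G=3, T=4, N=0.
encode_base_matrix <- function(sequences, n) {
  if (length(sequences) == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = n))
  codes <- utf8ToInt(paste(sequences, collapse = ""))
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 0L
  bad <- setdiff(unique(codes), c(65L, 67L, 71L, 84L, 78L))  # A C G T N
  if (length(bad))
    stop("sequences may only contain A, C, G, T, N (found: ",
         intToUtf8(bad, multiple = FALSE), ")")
  matrix(lut[codes], ncol = n, byrow = TRUE)
}

decode_base_matrix <- function(m) {
  letters5 <- c("N", BASE_ALPHABET)
  if (nrow(m) == 0L) return(character(0))
  chars <- letters5[m + 1L]
  dim(chars) <- dim(m)
  apply(chars, 1L, paste, collapse = "")
}

# Phred+33 quality strings -> integer matrix (reads x positions).
decode_phred_strings <- function(qual_strings) {
  n <- unique(nchar(qual_strings))
  if (length(n) > 1L) stop("quality strings must have equal length")
  if (length(qual_strings) == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = if (length(n)) n else 0L))
  matrix(utf8ToInt(paste(qual_strings, collapse = "")) - 33L,
         ncol = n, byrow = TRUE)
}

encode_phred_strings <- function(qmat) {
  if (nrow(qmat) == 0L) return(character(0))
  chars <- intToUtf8(t(qmat) + 33L, multiple = FALSE)
  substring(chars, seq(1L, nchar(chars), by = ncol(qmat)),
            seq(ncol(qmat), nchar(chars), by = ncol(qmat)))
}

min_pairwise_hamming <- function(bmat) {
  k <- nrow(bmat)
  # matches via one-hot product; distances = n - matches
  match_counts <- matrix(0L, k, k)
  for (base in 1:4) {
    ind <- (bmat == base) * 1L
    match_counts <- match_counts + tcrossprod(ind)
  }
  d <- ncol(bmat) - match_counts
  min(d[upper.tri(d)])
}

# Per-read x per-class log-likelihood matrix, computed with four one-hot
# matrix products so the cost is BLAS-bound.
loglik_matrix <- function(obs, set) {
  stopifnot(inherits(obs, "observed_barcodes"), inherits(set, "barcode_set"))
  if (obs$length != set$length)
    stop("observation length (", obs$length,
         ") does not match barcode length (", set$length, ")")
  M <- obs$bases
  p <- phred_to_error_probability(obs$qualities)
  lmatch <- log1p(-p)
  lmis <- log(p / 3)
  isN <- M == 0L
  base_term <- lmis
  base_term[isN] <- log(0.25)
  const <- rowSums(base_term)
  D <- lmatch - lmis          # added when observed base matches barcode base
  LL <- matrix(const, nrow = nrow(M), ncol = length(set$ids))
  B <- set$base_matrix        # classes x positions
  for (baseval in 1:4) {
    Ik <- t((B == baseval) * 1)             # positions x classes
    LL <- LL + (D * (M == baseval)) %*% Ik
  }
  colnames(LL) <- set$ids
  LL
}

# Hamming distance matrix reads x classes (N counts as a mismatch).
hamming_matrix <- function(obs, set) {
  if (obs$length != set$length)
    stop("observation length does not match barcode length")
  M <- obs$bases
  matches <- matrix(0, nrow = nrow(M), ncol = length(set$ids))
  B <- set$base_matrix
  for (baseval in 1:4) {
    Ik <- t((B == baseval) * 1)
    matches <- matches + ((M == baseval) * 1) %*% Ik
  }
  d <- obs$length - matches
  colnames(d) <- set$ids
  d
}
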