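# Independent linear-space oracles used to check the log-space decoders,
# plus small fixture builders. The oracles are deliberately naive: per-base
# loops and direct evaluation of the posterior ratio, no shared code with
# the implementation.

oracle_base_prob <- function(obs_base, bc_base, q) {
  p <- min(10^(-q / 10), 0.75)
  if (obs_base == "N") return(0.25)
  if (obs_base == bc_base) 1 - p else p / 3
}

oracle_likelihood <- function(seq, quals, bc) {
  ob <- strsplit(seq, "")[[1]]
  bb <- strsplit(bc, "")[[1]]
  out <- 1
  for (i in seq_along(ob)) out <- out * oracle_base_prob(ob[i], bb[i], quals[i])
  out
}

# Posterior of each class plus the noise pseudo-class, evaluated directly in
# linear space from the Bayes ratio.
oracle_posteriors <- function(seq, quals, barcodes, class_priors, noise_prior,
                              noise_floor = NULL) {
  lik <- vapply(barcodes, function(b) oracle_likelihood(seq, quals, b),
                numeric(1))
  n <- nchar(seq)
  floor_ <- if (is.null(noise_floor)) 0.25^n else noise_floor
  denom <- floor_ * noise_prior + sum(lik * class_priors)
  c(lik * class_priors / denom, noise = floor_ * noise_prior / denom)
}

# Full PAMLD decision replicated independently: argmax, noise filter,
# confidence filter.
oracle_pamld <- function(seq, quals, barcodes, class_priors, noise_prior,
                         confidence = 0.95, noise_floor = NULL) {
  post <- oracle_posteriors(seq, quals, barcodes, class_priors, noise_prior,
                            noise_floor)
  cls <- post[names(barcodes)]
  ids <- sort(names(barcodes))
  cls <- cls[ids]
  best <- ids[which.max(cls)]
  lik <- oracle_likelihood(seq, quals, barcodes[[best]])
  n <- nchar(seq)
  floor_ <- if (is.null(noise_floor)) 0.25^n else noise_floor
  if (lik < floor_)
    return(list(assigned = "undetermined", posterior = NA_real_,
                qc_fail = FALSE))
  list(assigned = best, posterior = unname(cls[best]),
       qc_fail = unname(cls[best]) <= confidence)
}

all_sequences <- function(n) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), n),
                              stringsAsFactors = FALSE))
}

random_sequences <- function(k, n) {
  vapply(seq_len(k), function(i)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

# Two-class toy codebook used across decoder tests.
toy_set <- function() barcode_set(c(a = "AA", b = "CC"))
toy_priors <- function() prior_distribution(c(a = 0.475, b = 0.475), 0.05)

obs1 <- function(seq, q) {
  observed_barcode(seq, rep(q, nchar(seq)))
}
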