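## Evaluation harness: per-class binary classification counts, micro-averaged
## FDR / miss rate / F-score, abundance bins, and read partitions.

#' Per-class classification counts
#'
#' Evaluates each barcode class and the noise class as a binary classifier:
#' a correct assignment is a true positive for its class; an incorrect
#' assignment is a false negative for the correct class and a false positive
#' for the incorrectly assigned class. Decoder rejections ([UNDETERMINED])
#' count as assignments to the noise class, and, by default, so do qc-fail
#' reads (their classification is deliberately set aside).
#'
#' @param truth Character vector of true class labels ([NOISE_CLASS] for
#'   noise reads).
#' @param results Decode data.frame (columns `assigned`, `qc_fail`), or a
#'   character vector of assigned labels.
#' @param treat_qcfail_as_noise Count qc-fail reads as noise assignments
#'   (default TRUE).
#' @param partition Restrict the tally to one read partition: `"all"`,
#'   `"classified"` (reads assigned to a real barcode), `"classifiable"`
#'   (reads whose true class is a real barcode) or `"unclassified"` (reads
#'   that are noise or failed quality control).
#' @return An object of class `class_counts`: data.frame with columns
#'   `class`, `TP`, `FP`, `FN` (one row per class plus the noise class).
#' @export
tally_classification <- function(truth, results,
                                 treat_qcfail_as_noise = TRUE,
                                 partition = c("all", "classified",
                                               "classifiable",
                                               "unclassified")) {
  partition <- match.arg(partition)
  if (is.data.frame(results)) {
    predicted <- results$assigned
    qc_fail <- results$qc_fail
  } else {
    predicted <- as.character(results)
    qc_fail <- rep(FALSE, length(predicted))
  }
  if (length(predicted) != length(truth))
    stop("decoded results and truth differ in length")
  predicted[predicted == UNDETERMINED] <- NOISE_CLASS
  if (treat_qcfail_as_noise) predicted[qc_fail] <- NOISE_CLASS
  keep <- switch(partition,
    all = rep(TRUE, length(truth)),
    classified = predicted != NOISE_CLASS,
    classifiable = truth != NOISE_CLASS,
    unclassified = truth == NOISE_CLASS | predicted == NOISE_CLASS)
  truth <- truth[keep]; predicted <- predicted[keep]
  classes <- sort(unique(c(truth, predicted, NOISE_CLASS)))
  tl <- factor(truth, levels = classes)
  pl <- factor(predicted, levels = classes)
  correct <- tl == pl
  tp <- table(tl[correct])
  fn <- table(tl[!correct])
  fp <- table(pl[!correct])
  structure(data.frame(class = classes, TP = as.integer(tp),
                       FP = as.integer(fp), FN = as.integer(fn),
                       stringsAsFactors = FALSE),
            class = c("class_counts", "data.frame"))
}

#' Micro-averaged classification metrics
#'
#' Sums TP/FP/FN over the classes in scope and reports precision, recall,
#' FDR (1 - precision), miss rate (1 - recall), and the F-score (harmonic
#' mean of precision and recall). With an empty scope (or no positives) the
#' metrics are reported as `NA`, not 0.
#'
#' @param counts A [tally_classification()] result.
#' @param classes Optional character vector restricting the summation to a
#'   subset of classes (e.g. one abundance bin). Default: all classes in the
#'   table, including the noise class.
#' @return A one-row data.frame with columns `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `fdr`, `miss_rate`, `f_score`.
#' @examples
#' counts <- tally_classification(c("a", "a", "b"), c("a", "b", "b"))
#' summarize_metrics(counts)
#' @export
summarize_metrics <- function(counts, classes = NULL) {
  stopifnot(inherits(counts, "class_counts"))
  if (!is.null(classes)) counts <- counts[counts$class %in% classes, ]
  tp <- sum(counts$TP); fp <- sum(counts$FP); fn <- sum(counts$FN)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  data.frame(TP = tp, FP = fp, FN = fn, precision = precision,
             recall = recall, fdr = 1 - precision, miss_rate = 1 - recall,
             f_score = f)
}

#' Bin barcode classes by relative abundance
#'
#' Bins follow the benchmark convention: very low (< 0.1% of reads), low
#' (0.1-0.3%), similar to uniform (0.3-3%) and overrepresented (> 3%).
#' Boundaries are closed on the left, open on the right.
#'
#' @param priors A [prior_distribution()]; classes are binned by their true
#'   prior.
#' @return Named character vector of bin labels (`very_low`, `low`,
#'   `uniform_like`, `overrepresented`), one per class.
#' @export
abundance_bins <- function(priors) {
  stopifnot(inherits(priors, "prior_distribution"))
  p <- priors$class_priors
  bins <- cut(p, breaks = c(-Inf, 0.001, 0.003, 0.03, Inf), right = FALSE,
              labels = c("very_low", "low", "uniform_like", "overrepresented"))
  stats::setNames(as.character(bins), names(p))
}

#' Decode a simulated run with every decoder configuration
#'
#' Runs the five benchmark decoders on one simulated run, reusing a single
#' likelihood evaluation: minimum-distance (`mdd`), the uniform-prior ML
#' baseline without filters (`uniform_ml`), and PAMLD with uniform priors
#' (`pamld_uniform`), with the simulation's true priors (`pamld_true`), and
#' with high-confidence estimated priors from a preliminary uniform pass
#' (`pamld_estimated`).
#'
#' @param sim A [simulate_run()] result.
#' @param config A [decoder_config()].
#' @param decoders Character vector choosing which decoders to run.
#' @return Named list of decode data.frames.
#' @export
decode_with_all <- function(sim, config = decoder_config(),
                            decoders = c("mdd", "uniform_ml",
                                         "pamld_uniform", "pamld_true",
                                         "pamld_estimated")) {
  stopifnot(inherits(sim, "simulated_run"))
  set <- sim$barcode_set
  obs <- sim$observations
  needs_ll <- any(decoders != "mdd")
  LL <- if (needs_ll) loglik_matrix(obs, set) else NULL
  out <- list()
  for (d in decoders) {
    out[[d]] <- switch(d,
      mdd = mdd_decode(obs, set),
      uniform_ml = uniform_ml_from_loglik(LL, set),
      pamld_uniform = pamld_from_loglik(LL, set, uniform_priors(set), config),
      pamld_true = pamld_from_loglik(LL, set, sim$true_priors, config),
      pamld_estimated = {
        pass1 <- pamld_from_loglik(LL, set, uniform_priors(set), config)
        est <- suppressWarnings(estimate_priors(tally_decodes(pass1, set)))
        res <- pamld_from_loglik(LL, set, est, config)
        attr(res, "estimated_priors") <- est
        res
      },
      stop("unknown decoder: ", d))
  }
  out
}

#' Compare decoders across an error-rate sweep
#'
#' Reproduces the accuracy-benchmark experiment shape: for every
#' (error rate, seed) cell a run is simulated, decoded with every decoder,
#' and micro-averaged metrics are computed for the requested partitions and
#' abundance bins.
#'
#' @param composition List with `set` and `priors` (see
#'   [benchmark_composition()]).
#' @param error_rates Numeric vector of target substitution rates.
#' @param seeds Integer vector of simulation seeds.
#' @param read_count Reads per simulated run.
#' @param config A [decoder_config()].
#' @param partitions Character vector of read partitions to report.
#' @param bins Also report metrics per abundance bin (classes only).
#' @param decoders Which decoders to include.
#' @return A long data.frame: one row per (error_rate, seed, decoder,
#'   partition, bin) with the metric columns of [summarize_metrics()].
#' @export
compare_decoders <- function(composition, error_rates, seeds,
                             read_count = 10000L,
                             config = decoder_config(),
                             partitions = "all", bins = FALSE,
                             decoders = c("mdd", "uniform_ml",
                                          "pamld_uniform", "pamld_true",
                                          "pamld_estimated")) {
  bin_map <- abundance_bins(composition$priors)
  rows <- list()
  for (rate in error_rates) {
    for (seed in seeds) {
      cfg <- simulation_config(composition$set, composition$priors,
                               read_count = read_count,
                               target_error_rate = rate, seed = seed)
      sim <- simulate_run(cfg)
      decoded <- decode_with_all(sim, config, decoders)
      for (d in names(decoded)) {
        for (part in partitions) {
          counts <- tally_classification(sim$truth, decoded[[d]],
                                         partition = part)
          scopes <- list(all = NULL)
          if (bins)
            for (b in unique(bin_map))
              scopes[[b]] <- names(bin_map)[bin_map == b]
          for (scope_name in names(scopes)) {
            m <- summarize_metrics(counts, scopes[[scope_name]])
            rows[[length(rows) + 1L]] <-
              cbind(data.frame(error_rate = rate, seed = seed, decoder = d,
                               partition = part, bin = scope_name,
                               stringsAsFactors = FALSE), m)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
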