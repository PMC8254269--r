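test_that("tallying counts TP/FP/FN per class including noise", {
  truth <- c("a", "a", "b", NOISE_CLASS)
  counts <- tally_classification(truth, c("a", "a", "b", NOISE_CLASS))
  expect_equal(sum(counts$FP), 0)
  expect_equal(sum(counts$FN), 0)
  expect_equal(counts$TP[counts$class == "a"], 2L)

  # a true-a read assigned to b: FN for a, FP for b
  counts <- tally_classification(truth, c("b", "a", "b", NOISE_CLASS))
  expect_equal(counts$FN[counts$class == "a"], 1L)
  expect_equal(counts$FP[counts$class == "b"], 1L)

  # a noise read assigned to b: FP for b, FN for noise
  counts <- tally_classification(truth, c("a", "a", "b", "b"))
  expect_equal(counts$FP[counts$class == "b"], 1L)
  expect_equal(counts$FN[counts$class == NOISE_CLASS], 1L)

  # undetermined and qc-fail predictions count as noise
  res <- data.frame(assigned = c(UNDETERMINED, "a", "b", NOISE_CLASS),
                    qc_fail = c(FALSE, TRUE, FALSE, FALSE))
  counts <- tally_classification(truth, res)
  expect_equal(counts$TP[counts$class == NOISE_CLASS], 1L)
  expect_equal(counts$FN[counts$class == "a"], 2L)
  counts_keep <- tally_classification(truth, res,
                                      treat_qcfail_as_noise = FALSE)
  expect_equal(counts_keep$TP[counts_keep$class == "a"], 1L)
})

test_that("metrics arithmetic matches the closed forms", {
  counts <- structure(data.frame(class = "x", TP = 8L, FP = 2L, FN = 2L),
                      class = c("class_counts", "data.frame"))
  m <- summarize_metrics(counts)
  expect_equal(m$fdr, 0.2)
  expect_equal(m$miss_rate, 0.2)
  expect_equal(m$f_score, 0.8)

  perfect <- tally_classification(c("a", "b"), c("a", "b"))
  expect_equal(summarize_metrics(perfect)$f_score, 1)

  # empty scope: metrics undefined, not zero
  empty <- summarize_metrics(perfect, classes = "zzz")
  expect_true(is.na(empty$f_score))
})

test_that("conservation invariants hold on a benchmark run", {
  comp <- benchmark_composition()
  sim <- simulate_run(simulation_config(comp$set, comp$priors, 5000, 0.02,
                                        seed = 14))
  res <- pamld_decode(sim$observations, comp$set, comp$priors)
  counts <- tally_classification(sim$truth, res)
  # TP + FN per class equals the manifest count
  manifest_counts <- table(factor(sim$truth, levels = counts$class))
  expect_equal(counts$TP + counts$FN, as.integer(manifest_counts))
  # every misassignment is one FP and one FN
  expect_equal(sum(counts$FP), sum(counts$FN))
  expect_equal(sum(counts$TP) + sum(counts$FN), 5000L)
})

test_that("abundance bins use left-closed right-open boundaries", {
  pr <- prior_distribution(
    c(vl = 0.0005, lo = 0.0025, edge_lo = 0.001, un = 0.02,
      edge_un = 0.003, ov = 0.32, edge_ov = 0.03),
    1 - 0.377)
  bins <- abundance_bins(pr)
  expect_equal(unname(bins["vl"]), "very_low")
  expect_equal(unname(bins["lo"]), "low")
  expect_equal(unname(bins["edge_lo"]), "low")
  expect_equal(unname(bins["un"]), "uniform_like")
  expect_equal(unname(bins["edge_un"]), "uniform_like")
  expect_equal(unname(bins["ov"]), "overrepresented")
  expect_equal(unname(bins["edge_ov"]), "overrepresented")
})

test_that("read partitions restrict the tally as defined", {
  truth <- c("a", "a", "b", NOISE_CLASS, NOISE_CLASS)
  res <- data.frame(
    assigned = c("a", UNDETERMINED, "a", "b", UNDETERMINED),
    qc_fail = FALSE)
  # classified: reads assigned to a real barcode
  cl <- tally_classification(truth, res, partition = "classified")
  expect_equal(sum(cl$TP) + sum(cl$FP), 3L)
  # classifiable: reads whose truth is a real barcode
  cf <- tally_classification(truth, res, partition = "classifiable")
  expect_equal(sum(cf$TP) + sum(cf$FN), 3L)
  # unclassified: noise reads or reads sent to noise
  un <- tally_classification(truth, res, partition = "unclassified")
  expect_equal(sum(un$TP) + sum(un$FN), 3L)
})

test_that("every decoder is perfect on clean noiseless data", {
  comp <- benchmark_composition()
  scaled <- comp$priors$class_priors / sum(comp$priors$class_priors)
  noiseless <- list(set = comp$set,
                    priors = prior_distribution(scaled, 0))
  tab <- compare_decoders(noiseless, error_rates = 1e-4, seeds = 1,
                          read_count = 1500)
  # at error 1e-4 and 1500 reads, misdecodes are overwhelmingly unlikely
  expect_true(all(tab$f_score > 0.999))
})

test_that("the decoder comparison table has the experiment shape", {
  comp <- benchmark_composition()
  tab <- compare_decoders(comp, error_rates = c(0.001, 0.05), seeds = 1:2,
                          read_count = 800, bins = TRUE,
                          decoders = c("mdd", "pamld_true"))
  expect_setequal(unique(tab$decoder), c("mdd", "pamld_true"))
  expect_equal(nrow(tab), 2 * 2 * 2 * 5)  # rates x seeds x decoders x bins+all
  expect_true(all(tab$bin %in% c("all", "very_low", "low", "uniform_like",
                                 "overrepresented")))
})

test_that("probabilistic decoding beats minimum distance at high error", {
  comp <- benchmark_composition()
  tab <- compare_decoders(comp, error_rates = 0.05, seeds = 21:23,
                          read_count = 4000,
                          decoders = c("mdd", "pamld_true", "uniform_ml"))
  f <- tapply(tab$f_score, tab$decoder, mean)
  expect_gt(f["pamld_true"], f["mdd"])
  expect_gt(f["uniform_ml"], f["mdd"])
})
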