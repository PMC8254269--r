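test_that("PAMLD posterior matches the hand-evaluated Bayes ratio", {
  res <- pamld_decode(obs1("AA", 30), toy_set(), toy_priors())
  lik_match <- 0.999^2
  lik_mis <- (0.001 / 3)^2
  expected <- (lik_match * 0.475) /
    (0.0625 * 0.05 + lik_match * 0.475 + lik_mis * 0.475)
  expect_equal(res$assigned, "a")
  expect_equal(res$posterior, expected, tolerance = 1e-12)
  expect_equal(res$posterior, 0.9935, tolerance = 1e-3)
  expect_equal(res$conditional, lik_match, tolerance = 1e-12)
  expect_equal(res$decoding_error, 1 - expected, tolerance = 1e-12)
  expect_false(res$qc_fail)
})

test_that("a single class with zero noise prior has posterior exactly 1", {
  set <- barcode_set(c(only = "AA"))
  pr <- prior_distribution(c(only = 1), 0)
  res <- pamld_decode(obs1("AA", 40), set, pr)
  expect_equal(res$posterior, 1)
  expect_false(res$qc_fail)
})

test_that("the noise filter rejects reads weaker than a random sequence", {
  # max P(r|b) = (0.001/3)^2 < 1/16
  res <- pamld_decode(obs1("GT", 30), toy_set(), toy_priors())
  expect_equal(res$assigned, UNDETERMINED)
  expect_true(is.na(res$posterior))
  expect_lt((0.001 / 3)^2, 1 / 16)
})

test_that("the confidence filter flags but keeps low-posterior assignments", {
  # one low-quality mismatch against each barcode -> ambiguous posterior
  set <- barcode_set(c(a = "AA", b = "AC"))
  pr <- prior_distribution(c(a = 0.5, b = 0.5), 0)
  res <- pamld_decode(observed_barcode("AA", c(40, 3)), set, pr)
  expect_equal(res$assigned, "a")
  expect_true(res$qc_fail)
  expect_lte(res$posterior, 0.95)
})

test_that("a 2-mismatch dual-index read is rejected by MDD, decoded by PAMLD", {
  comp <- benchmark_composition()
  true_bc <- comp$set$sequences[match("BC050", comp$set$ids)]
  mutated <- true_bc
  substring(mutated, 3, 3) <- if (substring(true_bc, 3, 3) == "A") "C" else "A"
  substring(mutated, 11, 11) <- if (substring(true_bc, 11, 11) == "G") "T" else "G"
  # miscalled bases carry low quality scores; the rest are high quality
  q <- rep(38L, 16)
  q[c(3, 11)] <- 10L
  r <- observed_barcode(mutated, q)
  expect_equal(mdd_decode(r, comp$set)$assigned, UNDETERMINED)
  res <- pamld_decode(r, comp$set, comp$priors)
  expect_equal(res$assigned, "BC050")
  expect_gt(res$posterior, 0.999)
  expect_false(res$qc_fail)
})

test_that("MDD assigns within tolerance and rejects ties", {
  set <- barcode_set(c(a = "AAAA", b = "TTTT"))   # d_min 4, tolerance 1
  expect_equal(mdd_default_tolerance(set), 1L)
  r <- mdd_decode(obs1("AAAA", 30), set)
  expect_equal(r$assigned, "a")
  expect_equal(r$distance, 0L)
  expect_true(is.na(r$posterior))
  expect_equal(mdd_decode(obs1("AAAT", 30), set)$assigned, "a")
  expect_equal(mdd_decode(obs1("AATT", 30), set)$assigned, UNDETERMINED)
  expect_equal(mdd_decode(obs1("AATT", 30), set, tolerance = 2)$assigned,
               UNDETERMINED)  # distance 2 to both: tie
  expect_equal(mdd_decode(obs1("ANAA", 30), set)$assigned, "a") # N mismatches
})

test_that("uniform-ML never rejects and breaks ties lexicographically", {
  set <- toy_set()
  res <- uniform_ml_decode(obs1("AA", 35), set)
  expect_equal(res$assigned, "a")
  # symmetric observation: equal likelihoods, tie to smaller id
  res <- uniform_ml_decode(obs1("AC", 30), set)
  expect_equal(res$assigned, "a")
  # a hopeless noise read is still assigned to something
  comp <- benchmark_composition()
  res <- uniform_ml_decode(obs1(paste(rep("A", 16), collapse = ""), 30),
                           comp$set)
  expect_false(res$assigned == UNDETERMINED)
  expect_false(res$qc_fail)
})

test_that("combinatorial confidence is the product of component posteriors", {
  expect_equal(combine_confidences(c(1, 1)), list(confidence = 1, error = 0))
  got <- combine_confidences(c(0.99, 0.98))
  expect_equal(got$confidence, 0.9702)
  expect_equal(got$error, 0.0298)
  expect_equal(combine_confidences(0.9), list(confidence = 0.9, error = 0.1),
               tolerance = 1e-12)
  expect_error(combine_confidences(numeric(0)), "at least one")
  expect_error(combine_confidences(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("posterior plus noise term normalizes to one", {
  set.seed(31)
  set <- barcode_set(c(a = "ACGT", b = "TTGA", c = "GGCC", d = "ATAT"))
  pr <- prior_distribution(c(a = 0.4, b = 0.3, c = 0.2, d = 0.05), 0.05)
  for (i in 1:20) {
    r <- observed_barcode(random_sequences(1, 4), sample(2:41, 4, TRUE))
    post <- pamld:::posterior_distribution(r, set, pr)
    expect_equal(sum(post), 1, tolerance = 1e-9)
  }
})

test_that("raising the confidence threshold only shrinks the passing set", {
  set.seed(32)
  comp <- benchmark_composition()
  sim <- simulate_run(simulation_config(comp$set, comp$priors, 2000, 0.02,
                                        seed = 5))
  thresholds <- c(0.5, 0.8, 0.95, 0.99)
  passing <- lapply(thresholds, function(C) {
    res <- pamld_decode(sim$observations, comp$set, comp$priors,
                        decoder_config(confidence_threshold = C))
    which(res$assigned != UNDETERMINED & !res$qc_fail)
  })
  for (k in seq_along(thresholds)[-1]) {
    expect_true(all(passing[[k]] %in% passing[[k - 1]]))
  }
})

test_that("increasing a class prior never decreases its posterior", {
  set.seed(33)
  set <- barcode_set(c(a = "ACGT", b = "TTGA", c = "GGCC"))
  r <- observed_barcode(random_sequences(1, 4), sample(10:35, 4, TRUE))
  for (w in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    pr_lo <- prior_distribution(c(a = w * 0.95, b = (1 - w) * 0.95 / 2,
                                  c = (1 - w) * 0.95 / 2), 0.05)
    post <- pamld:::posterior_distribution(r, set, pr_lo)["a"]
    if (w > 0.1) expect_gte(post, prev)
    prev <- post
  }
})

test_that("all three decoders agree on error-free exact reads", {
  comp <- benchmark_composition()
  ids <- c("BC001", "BC021", "BC121")
  for (id in ids) {
    r <- obs1(comp$set$sequences[match(id, comp$set$ids)], 38)
    expect_equal(pamld_decode(r, comp$set, comp$priors)$assigned, id)
    expect_equal(mdd_decode(r, comp$set)$assigned, id)
    expect_equal(uniform_ml_decode(r, comp$set)$assigned, id)
  }
})

test_that("batch decoding equals scalar decoding read by read", {
  set.seed(34)
  set <- barcode_set(c(a = "ACGTAC", b = "TTGACA", c = "GGCCTT"))
  pr <- prior_distribution(c(a = 0.5, b = 0.3, c = 0.15), 0.05)
  seqs <- random_sequences(25, 6)
  quals <- matrix(sample(2:41, 25 * 6, TRUE), nrow = 25)
  obs <- observed_barcodes(seqs, quals)
  batch <- pamld_decode(obs, set, pr)
  batch_mdd <- mdd_decode(obs, set)
  batch_uml <- uniform_ml_decode(obs, set)
  for (i in 1:25) {
    r <- observed_barcode(seqs[i], quals[i, ])
    s <- pamld_decode(r, set, pr)
    expect_equal(batch$assigned[i], s$assigned)
    expect_equal(batch$posterior[i], s$posterior, tolerance = 1e-12)
    expect_equal(batch$qc_fail[i], s$qc_fail)
    expect_equal(batch_mdd$assigned[i], mdd_decode(r, set)$assigned)
    expect_equal(batch_uml$assigned[i], uniform_ml_decode(r, set)$assigned)
  }
})

test_that("PAMLD matches the independent linear-space oracle", {
  set.seed(35)
  barcodes <- c(a = "ACG", b = "TGA", c = "GCT", d = "ATA")
  set <- barcode_set(barcodes)
  pr <- prior_distribution(c(a = 0.4, b = 0.25, c = 0.2, d = 0.1), 0.05)
  for (i in 1:30) {
    s <- random_sequences(1, 3)
    q <- sample(2:41, 3, TRUE)
    got <- pamld_decode(observed_barcode(s, q), set, pr)
    want <- oracle_pamld(s, q, as.list(barcodes), pr$class_priors[names(barcodes)],
                         0.05)
    expect_equal(got$assigned, want$assigned)
    if (!is.na(want$posterior))
      expect_equal(got$posterior, want$posterior, tolerance = 1e-9)
    expect_equal(got$qc_fail, want$qc_fail)
  }
})
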