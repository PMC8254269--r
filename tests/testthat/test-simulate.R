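test_that("the stand-in noise genome has the requested length and GC", {
  g <- generate_noise_genome(seed = 3)
  expect_equal(nchar(g), 5386L)
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / nchar(g)
  expect_lt(abs(gc - 0.45), 0.02)
  expect_identical(generate_noise_genome(seed = 3), g)
  expect_false(identical(generate_noise_genome(seed = 4), g))
  g2 <- generate_noise_genome(100, 1.0, seed = 1)
  expect_true(grepl("^[GC]+$", g2))
})

test_that("true class labels follow the prior distribution", {
  comp <- benchmark_composition()
  set.seed(6)
  all_noise <- sample_true_barcodes(
    prior_distribution(c(x = 0), 1), 100)
  expect_true(all(all_noise == NOISE_CLASS))
  draws <- sample_true_barcodes(comp$priors, 1e5)
  counts <- table(factor(draws, levels = c(comp$set$ids, NOISE_CLASS)))
  p <- c(comp$priors$class_priors, comp$priors$noise_prior)
  gof <- suppressWarnings(stats::chisq.test(as.integer(counts), p = p))
  expect_gt(gof$p.value, 1e-3)
})

test_that("quality recalibration hits the target mean error by bisection", {
  set.seed(7)
  q <- matrix(rnorm(5e4, 30, 4), ncol = 10)
  out <- recalibrate_qualities(q, 0.05)
  expect_true(is.integer(out))
  expect_true(all(out >= 2L & out <= 41L))
  expect_lt(abs(mean(10^(-out / 10)) - 0.05) / 0.05, 0.01)

  # already at target: identity shift
  qi <- matrix(rep(20L, 100), ncol = 10)
  out2 <- recalibrate_qualities(qi, 0.01)
  expect_equal(attr(out2, "shift"), 0)
  expect_equal(unclass(out2), unclass(qi), ignore_attr = TRUE)

  # monotone: a higher target error never raises any score
  lo <- recalibrate_qualities(q, 0.01)
  hi <- recalibrate_qualities(q, 0.1)
  expect_true(all(hi <= lo))

  expect_error(recalibrate_qualities(q, 0.7), "unreachable")
})

test_that("substitution errors follow the per-base quality probabilities", {
  set.seed(8)
  # at the representation ceiling errors are (essentially) never injected
  obs_hi <- observed_barcodes(random_sequences(100, 10),
                              matrix(93L, 100, 10))
  expect_equal(nrow(inject_substitution_errors(obs_hi)$positions), 0)

  # Q20 -> rate 0.01 within 3 binomial SE over 1e6 bases
  obs <- observed_barcodes(random_sequences(1e4, 100),
                           matrix(20L, 1e4, 100))
  res <- inject_substitution_errors(obs)
  rate <- nrow(res$positions) / 1e6
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 1e6))
  # qualities untouched, substituted bases differ from the originals
  expect_identical(res$observations$qualities, obs$qualities)
  expect_true(all(res$positions$from != res$positions$to))

  # uniform matrix: the three alternatives are equally frequent
  tab <- table(res$positions$to[res$positions$from == "A"])
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("simulated runs are deterministic and internally consistent", {
  comp <- benchmark_composition()
  cfg <- simulation_config(comp$set, comp$priors, 5000, 0.01, seed = 11)
  sim1 <- simulate_run(cfg)
  sim2 <- simulate_run(cfg)
  expect_identical(sim1$observations$sequences, sim2$observations$sequences)
  expect_identical(sim1$observations$qualities, sim2$observations$qualities)
  expect_identical(sim1$truth, sim2$truth)

  # every read appears in the manifest exactly once
  expect_equal(nrow(sim1$manifest), 5000L)
  expect_false(anyDuplicated(sim1$manifest$read) > 0)

  # realized error rate within 3 binomial SE of the target
  n_bases <- 5000 * comp$set$length
  expect_lt(abs(sim1$realized_error_rate - 0.01),
            3 * sqrt(0.01 * 0.99 / n_bases) + 0.01 * 0.01)

  # manifest class frequencies within 3 SE of the true priors
  freq <- table(factor(sim1$truth, levels = c(comp$set$ids, NOISE_CLASS))) / 5000
  p <- c(comp$priors$class_priors, comp$priors$noise_prior)
  se <- sqrt(p * (1 - p) / 5000)
  expect_true(all(abs(as.numeric(freq) - p) <= 3 * se + 1e-9))
})

test_that("noise reads are substrings of the noise genome", {
  comp <- benchmark_composition()
  genome <- generate_noise_genome(500, 0.45, seed = 21)
  cfg <- simulation_config(comp$set, comp$priors, 800, 0.001,
                           noise_genome = genome, seed = 12)
  sim <- simulate_run(cfg)
  noise_idx <- which(sim$truth == NOISE_CLASS)
  expect_gt(length(noise_idx), 0)
  # errors may mutate noise reads; check the error-free ones
  errored <- unique(sim$error_positions$read)
  clean <- setdiff(noise_idx, errored)
  for (i in clean)
    expect_true(grepl(sim$observations$sequences[i], genome, fixed = TRUE))
})

test_that("an empty run still yields valid outputs", {
  comp <- benchmark_composition()
  cfg <- simulation_config(comp$set, comp$priors, 0, 0.01, seed = 1)
  sim <- simulate_run(cfg)
  expect_equal(length(sim$observations), 0L)
  expect_equal(nrow(sim$manifest), 0L)
  dir <- withr::local_tempdir()
  paths <- write_simulated_run(sim, dir, gzip = FALSE)
  expect_true(all(file.exists(paths)))
})

test_that("written runs round-trip through FASTQ", {
  comp <- benchmark_composition()
  cfg <- simulation_config(comp$set, comp$priors, 200, 0.01, seed = 13)
  sim <- simulate_run(cfg)
  dir <- withr::local_tempdir()
  write_simulated_run(sim, dir)
  block <- read_multisegment(file.path(dir, c("segment_1.fastq.gz",
                                              "segment_2.fastq.gz")))
  expect_equal(block$names, sim$manifest$read)
  expect_equal(paste0(block$segments[[1]]$seq, block$segments[[2]]$seq),
               sim$observations$sequences)
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(manifest$true_class, sim$truth)
  pr <- jsonlite::read_json(file.path(dir, "true_priors.json"))
  expect_equal(pr$noise, 0.09)
})
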