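## Semi-synthetic benchmark read simulator: barcode injection from a known
## prior, noise reads drawn from a stand-in phage genome, per-cycle quality
## profiles, quality recalibration to a target mean error rate, and
## quality-driven substitution errors. Ground truth is exact by construction.

# Fixed dual-index codebooks used by the bundled benchmark composition.
# Generated once (greedy search, per-segment pairwise Hamming distance >= 3);
# the 121 i7 x i5 combinations have a combined minimum distance of 3, so the
# default minimum-distance tolerance is 1, the conventional one-mismatch
# setting.
BENCH_I7 <- c("CAAAAATC", "TTCGTCTG", "CTCATAAG", "AGGGCTGG", "GCGCGGAT",
              "AAATGTGT", "TCGATGTA", "ACCTGCTC", "AGCAATGC", "TGGAGCGG",
              "CACGGACC")
BENCH_I5 <- c("ACATGCAT", "TGTTAGAG", "CAACAGGC", "CAAGTTCA", "CGCGGTAG",
              "CGATAGAC", "GCGTCGCG", "TATCACGG", "AGTACTCG", "CAAATGAA",
              "GGGCATTC")

#' Bundled benchmark class composition
#'
#' The canned class-abundance distribution used by the accuracy benchmark:
#' 121 dual 8nt-index barcode classes where one overrepresented control
#' class holds 32% of the reads, noise holds 9%, and the remaining 59% is
#' spread so that all abundance bins are populated - 20 classes at 2.4%
#' (similar-to-uniform bin, 0.3-3%), 30 at 0.25% (low bin, 0.1-0.3%) and 70
#' at 0.05% (very-low bin, < 0.1%).
#'
#' @return List with `set` (a [barcode_set()]), `priors` (the true
#'   [prior_distribution()], noise prior 0.09) and `control_id`.
#' @examples
#' comp <- benchmark_composition()
#' comp$priors$class_priors[comp$control_id]
#' @export
benchmark_composition <- function() {
  ids <- sprintf("BC%03d", seq_len(121L))
  combos <- expand.grid(i7 = BENCH_I7, i5 = BENCH_I5,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bcs <- lapply(seq_len(121L),
                function(i) barcode(ids[i], c(combos$i7[i], combos$i5[i])))
  set <- barcode_set(bcs)
  p <- c(0.32, rep(0.024, 20L), rep(0.0025, 30L), rep(0.0005, 70L))
  names(p) <- ids
  list(set = set, priors = prior_distribution(p, noise_prior = 0.09),
       control_id = ids[1L])
}

#' Simulation configuration
#'
#' @param barcode_set A [barcode_set()] of true barcodes.
#' @param true_priors The true [prior_distribution()] (its noise prior is the
#'   fraction of indeterminate reads).
#' @param read_count Number of reads to simulate.
#' @param target_error_rate Mean per-base substitution probability after
#'   quality recalibration, in (0, 0.75).
#' @param quality_mean,quality_sd Per-cycle Gaussian quality profile in Phred
#'   space before recalibration (defaults 33 and 4, clamped to \[2, 41\]).
#' @param substitution_matrix 4x4 conditional base-substitution matrix
#'   (rows/cols ordered A, C, G, T; zero diagonal, rows summing to 1).
#'   Default: uniform, each alternative base 1/3.
#' @param noise_genome Nucleotide string noise reads are sampled from; `NULL`
#'   generates a seeded 5386 nt, 45% GC stand-in phage genome. A genuine
#'   genome read from FASTA may be supplied for fidelity.
#' @param seed Integer seed; the run is fully deterministic given the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(barcode_set, true_priors, read_count,
                              target_error_rate,
                              quality_mean = 33, quality_sd = 4,
                              substitution_matrix = uniform_substitution_matrix(),
                              noise_genome = NULL, seed = 1L) {
  stopifnot(inherits(barcode_set, "barcode_set"),
            inherits(true_priors, "prior_distribution"))
  check_priors_cover(true_priors, barcode_set)
  if (read_count < 0) stop("read_count must be >= 0")
  if (target_error_rate <= 0 || target_error_rate >= 0.75)
    stop("target_error_rate must lie in (0, 0.75)")
  validate_substitution_matrix(substitution_matrix)
  if (!is.null(noise_genome) && nchar(noise_genome) < barcode_set$length)
    stop("noise_genome must be at least as long as the barcode")
  structure(list(barcode_set = barcode_set, true_priors = true_priors,
                 read_count = as.integer(read_count),
                 target_error_rate = target_error_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 substitution_matrix = substitution_matrix,
                 noise_genome = noise_genome, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Uniform substitution matrix
#'
#' Each erroneous basecall is equally likely to produce any of the three
#' alternative bases.
#'
#' @return A 4x4 matrix (A, C, G, T) with zero diagonal and 1/3 elsewhere.
#' @export
uniform_substitution_matrix <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(BASE_ALPHABET, BASE_ALPHABET))
  diag(m) <- 0
  m
}

validate_substitution_matrix <- function(m) {
  if (!is.matrix(m) || any(dim(m) != c(4L, 4L)))
    stop("substitution_matrix must be 4x4")
  if (any(diag(m) != 0))
    stop("substitution_matrix must have a zero diagonal")
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
    stop("substitution_matrix rows must sum to 1")
  invisible(m)
}

#' Generate a stand-in noise genome
#'
#' A seeded random nucleotide sequence standing in for the phage genome that
#' noise reads are sampled from (the real spike-in control genome is 5386 nt
#' at ~45% GC; noise reads only need to resemble barcodes by chance, so a
#' random sequence with the same length and composition serves). Marked
#' synthetic: supply a genuine genome via `simulation_config(noise_genome=)`
#' for full fidelity.
#'
#' @param length Genome length (default 5386).
#' @param gc_content Expected GC fraction in (0, 1\] (default 0.45).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return A nucleotide string.
#' @examples
#' g <- generate_noise_genome(100, 0.5, seed = 7)
#' @export
generate_noise_genome <- function(length = 5386L, gc_content = 0.45,
                                  seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (gc_content <= 0 || gc_content > 1) stop("gc_content must be in (0, 1]")
  draw <- function() {
    prob <- c((1 - gc_content) / 2, gc_content / 2,
              gc_content / 2, (1 - gc_content) / 2)
    paste(sample(BASE_ALPHABET, length, replace = TRUE, prob = prob),
          collapse = "")
  }
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw()
}

#' Sample true class labels from a prior
#'
#' Draws `n` ground-truth labels: [NOISE_CLASS] with probability equal to
#' the noise prior, otherwise a barcode id with its class prior. Uses the
#' current RNG state.
#'
#' @param priors A [prior_distribution()].
#' @param n Number of draws.
#' @return Character vector of class labels.
#' @export
sample_true_barcodes <- function(priors, n) {
  stopifnot(inherits(priors, "prior_distribution"))
  sample(c(names(priors$class_priors), NOISE_CLASS), n, replace = TRUE,
         prob = c(priors$class_priors, priors$noise_prior))
}

#' Recalibrate quality scores to a target mean error rate
#'
#' Applies a uniform additive shift in Phred space - the shifted scores are
#' rounded and clamped to \[2, 41\] - such that the mean basecall error
#' probability 10^(-q/10) over all bases matches the target within 1%
#' relative. The shift is found by bisection. A uniform shift is monotone:
#' a higher target error never yields a higher score at any position.
#'
#' @param qualities Integer matrix (or vector) of Phred scores.
#' @param target_error_rate Desired mean error probability.
#' @return Recalibrated qualities with the same shape, with attribute
#'   `shift` (the continuous Phred-space shift applied).
#' @export
recalibrate_qualities <- function(qualities, target_error_rate) {
  if (target_error_rate <= 0 || target_error_rate >= 0.75)
    stop("target_error_rate must lie in (0, 0.75)")
  mean_err <- function(q) mean(10^(-q / 10))
  apply_shift <- function(delta) pmin(pmax(round(qualities + delta), 2), 41)
  current <- mean_err(apply_shift(0))
  if (abs(current - target_error_rate) / target_error_rate <= 0.01) {
    out <- apply_shift(0)
    storage.mode(out) <- "integer"
    attr(out, "shift") <- 0
    return(out)
  }
  lo <- -60; hi <- 60
  if (mean_err(apply_shift(lo)) < target_error_rate ||
      mean_err(apply_shift(hi)) > target_error_rate)
    stop("target error rate ", target_error_rate,
         " is unreachable within the quality clamp range [2, 41]")
  best <- NULL; best_err <- Inf
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    e <- mean_err(apply_shift(mid))
    rel <- abs(e - target_error_rate) / target_error_rate
    if (rel < best_err) { best_err <- rel; best <- mid }
    if (rel <= 0.01) break
    if (e > target_error_rate) lo <- mid else hi <- mid
  }
  if (best_err > 0.01)
    stop("bisection failed to reach the target error rate within 1%")
  out <- apply_shift(best)
  storage.mode(out) <- "integer"
  attr(out, "shift") <- best
  out
}

#' Inject quality-driven substitution errors
#'
#' Each base is independently substituted with probability 10^(-q/10) given
#' its quality score; the replacement base is drawn from the substitution
#' matrix row of the true base. Quality scores are left untouched (the
#' simulated miscall keeps its reported confidence). Uses the current RNG
#' state.
#'
#' @param obs An [observed_barcodes()] batch of error-free reads.
#' @param substitution_matrix 4x4 substitution matrix (see
#'   [simulation_config()]).
#' @return List with `observations` (mutated batch) and `positions`, a
#'   data.frame of (read, position, from, to) for every injected error.
#' @export
inject_substitution_errors <- function(obs,
                                       substitution_matrix = uniform_substitution_matrix()) {
  stopifnot(inherits(obs, "observed_barcodes"))
  validate_substitution_matrix(substitution_matrix)
  M <- obs$bases
  p <- 10^(-obs$qualities / 10)
  hit <- matrix(stats::runif(length(p)) < p, nrow = nrow(p))
  hit[M == 0L] <- FALSE          # uncalled bases are left as N
  idx <- which(hit)
  newM <- M
  from <- M[idx]
  to <- integer(length(idx))
  for (baseval in 1:4) {
    sel <- from == baseval
    if (any(sel))
      to[sel] <- sample(1:4, sum(sel), replace = TRUE,
                        prob = substitution_matrix[baseval, ])
  }
  newM[idx] <- to
  pos <- arrayInd(idx, dim(M))
  out <- obs
  out$bases <- newM
  out$sequences <- decode_base_matrix(newM)
  list(observations = out,
       positions = data.frame(read = pos[, 1L], position = pos[, 2L],
                              from = BASE_ALPHABET[from],
                              to = BASE_ALPHABET[to]))
}

#' Simulate a benchmark run
#'
#' Full protocol: sample a ground-truth class for every read from the true
#' priors; emit the perfect barcode sequence for barcode classes, or a
#' random-offset forward-strand substring of the noise genome for noise
#' reads; draw per-cycle Gaussian quality scores; recalibrate them to the
#' target mean error rate; and inject quality-driven substitution errors.
#' Deterministic given `config$seed`; ground truth is exact by construction.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_run`: `observations`
#'   ([observed_barcodes()]), `truth` (class label per read), `manifest`
#'   (data.frame read name / true class), `true_priors`, `barcode_set`,
#'   `error_positions`, `realized_error_rate` and `config`.
#' @examples
#' comp <- benchmark_composition()
#' cfg <- simulation_config(comp$set, comp$priors, read_count = 100,
#'                          target_error_rate = 0.001, seed = 7)
#' sim <- simulate_run(cfg)
#' table(sim$truth == NOISE_CLASS)
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  set <- config$barcode_set
  n <- set$length
  nreads <- config$read_count
  genome <- if (is.null(config$noise_genome))
    generate_noise_genome(5386L, 0.45) else config$noise_genome
  truth <- if (nreads > 0L) sample_true_barcodes(config$true_priors, nreads)
           else character(0)
  seqs <- character(nreads)
  is_noise <- truth == NOISE_CLASS
  if (any(!is_noise))
    seqs[!is_noise] <- set$sequences[match(truth[!is_noise], set$ids)]
  if (any(is_noise)) {
    offsets <- sample.int(nchar(genome) - n + 1L, sum(is_noise),
                          replace = TRUE)
    seqs[is_noise] <- substring(genome, offsets, offsets + n - 1L)
  }
  # continuous Phred draws; recalibration rounds and clamps to [2, 41]
  qual <- matrix(stats::rnorm(nreads * n, config$quality_mean,
                              config$quality_sd),
                 nrow = nreads, ncol = n)
  if (nreads > 0L) {
    qual <- recalibrate_qualities(qual, config$target_error_rate)
  } else {
    qual <- matrix(integer(0), nrow = 0L, ncol = n)
  }
  obs <- observed_barcodes(seqs, qual)
  err <- inject_substitution_errors(obs, config$substitution_matrix)
  names_ <- sprintf("SIM%07d", seq_len(nreads))
  structure(list(observations = err$observations, truth = truth,
                 manifest = data.frame(read = names_, true_class = truth,
                                       stringsAsFactors = FALSE),
                 true_priors = config$true_priors, barcode_set = set,
                 error_positions = err$positions,
                 realized_error_rate = if (nreads > 0L)
                   nrow(err$positions) / (nreads * n) else NA_real_,
                 config = config),
            class = "simulated_run")
}

#' Write a simulated run to disk
#'
#' Emits the reads as one FASTQ file per barcode segment (gzip by default)
#' or as a single unaligned SAM file, plus a tab-separated ground-truth
#' manifest (read name, true class) and the true priors as JSON.
#'
#' @param sim A [simulated_run()][simulate_run].
#' @param dir Output directory (created if missing).
#' @param format `"fastq"` or `"sam"`.
#' @param gzip Compress FASTQ output.
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulated_run <- function(sim, dir, format = c("fastq", "sam"),
                                gzip = TRUE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set <- sim$barcode_set
  seg_lens <- set$segment_lengths
  ends <- cumsum(seg_lens)
  starts <- ends - seg_lens + 1L
  seqs <- sim$observations$sequences
  quals <- encode_phred_strings(sim$observations$qualities)
  names_ <- sim$manifest$read
  paths <- character(0)
  if (format == "fastq") {
    for (k in seq_along(seg_lens)) {
      path <- file.path(dir, sprintf("segment_%d.fastq%s", k,
                                     if (gzip) ".gz" else ""))
      write_fastq(path, names_, substring(seqs, starts[k], ends[k]),
                  substring(quals, starts[k], ends[k]))
      paths <- c(paths, path)
    }
  } else {
    path <- file.path(dir, "reads.sam")
    block <- list(names = names_,
                  segments = lapply(seq_along(seg_lens), function(k)
                    list(seq = substring(seqs, starts[k], ends[k]),
                         qual = substring(quals, starts[k], ends[k]))))
    write_sam_block(path, block)
    paths <- c(paths, path)
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(sim$manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  priors_path <- file.path(dir, "true_priors.json")
  jsonlite::write_json(list(noise = sim$true_priors$noise_prior,
                            classes = as.list(sim$true_priors$class_priors)),
                       priors_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest_path, priors_path))
}
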