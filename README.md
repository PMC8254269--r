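# pamld — Phred-adjusted maximum-likelihood barcode decoding

Demultiplexing assigns pooled sequencing reads to their sample, cell or
molecule of origin by decoding short barcode tags. Most demultiplexers use
minimum Hamming distance with a fixed mismatch budget, which ignores
basecall quality, class abundance, and the fact that many reads (spike-in
controls, contamination) carry no valid barcode at all. This package is for
anyone building or evaluating sequencing pipelines who wants probabilistic,
quality-aware demultiplexing with per-read confidence scores — and a fully
controlled benchmark to measure decoder accuracy.

At its core is the **Phred-adjusted maximum-likelihood decoder (PAMLD)**,
which picks the barcode maximizing the full posterior

    P(b|r) = P(r|b) P(b) / [ P(r|b∉B) P_ε + Σ_b' P(r|b') P(b') ]

with `P(r|b)` computed from the Phred scores (match `1−p_i`, mismatch
`p_i/3`, `N` contributes `1/4`), a noise term `P(r|b∉B) = 1/4^n` for
maximum-entropy indeterminate sequences with prior `P_ε`, a **noise filter**
(reject reads whose best conditional is below the random-sequence
likelihood) and a **confidence filter** (flag reads with posterior ≤ C as
qc-fail; C defaults to 0.95). The decoding error `1 − P(b̂|r)` is reported
per read, and component posteriors multiply for combinatorial barcodes.
Also included: a minimum-distance decoder, a uniform-prior ML baseline, a
high-confidence prior estimator with a two-pass workflow
(`P̂_ε = S_ε/(S_ε+S_B)`, `P̂(b) = S_b/(S_ε+S_B)`), a deterministic
semi-synthetic read simulator, FDR/miss-rate/F-score evaluation, FASTQ/SAM
IO with SAM auxiliary barcode tags (`BC/QT/XB`, `CR/CY/CB/XC`, `RX/QX`),
and a CLI.

## Worked example

Decode one observation whose last base is a low-quality mismatch:

```r
library(pamld)
set    <- barcode_set(c(sample01 = "ACGT", sample02 = "TTGA"))
priors <- prior_distribution(c(sample01 = 0.6, sample02 = 0.35),
                             noise_prior = 0.05)
pamld_decode(observed_barcode("ACGA", c(35, 35, 35, 12)), set, priors)
#> decode_result: assigned = sample01
#>   conditional P(r|b) = 0.02101197
#>   posterior   P(b|r) = 0.9847439
#>   decoding error     = 0.0152561
```

Despite the mismatch, the read is assigned to `sample01` with posterior
0.985 — above the noise floor (1/256) and above the 0.95 confidence
threshold, so it passes both filters; the `XB` SAM tag would carry the
decoding error 0.0153.

Benchmark the decoders on simulated reads with known ground truth, using
the bundled class composition (121 dual 8 nt indices: a 32% control class,
9% noise, the rest spread across abundance bins) at substitution rate 0.05:

```r
comp <- benchmark_composition()
sim  <- simulate_run(simulation_config(comp$set, comp$priors,
                                       read_count = 20000,
                                       target_error_rate = 0.05, seed = 42))
decoded <- decode_with_all(sim)
for (d in names(decoded)) {
  m <- summarize_metrics(tally_classification(sim$truth, decoded[[d]]))
  cat(sprintf("%-16s F = %.4f  FDR = %.4f  MR = %.4f\n",
              d, m$f_score, m$fdr, m$miss_rate))
}
#> mdd              F = 0.8295  FDR = 0.1705  MR = 0.1705
#> uniform_ml       F = 0.9059  FDR = 0.0941  MR = 0.0941
#> pamld_uniform    F = 0.9938  FDR = 0.0062  MR = 0.0062
#> pamld_true       F = 0.9963  FDR = 0.0037  MR = 0.0037
#> pamld_estimated  F = 0.9966  FDR = 0.0034  MR = 0.0034
```

Posterior decoding dominates: the minimum-distance decoder discards every
read with more than one mismatch, the filter-free ML baseline force-assigns
all noise reads, and PAMLD with estimated priors performs essentially as
well as with the true priors.

## Command line

```sh
pamld simulate  --out simdir --reads 100000 --error-rate 0.01 --seed 1
pamld demux     --config run.json --threads 4     # threads accepted, output identical
pamld estimate  --config run.json --out priors.json
pamld benchmark --error-rates 0.001,0.05 --seeds 1,2,3 --reads 20000 --out sweep.tsv
pamld report    --report report.json
```

The JSON configuration names the input files and segment layout, transform
tokens (`"segment:start:end"`, trailing `~` for reverse complement), one
decoder block per barcode type (codewords, priors — explicit, `"uniform"`,
or `"estimate"` for the two-pass workflow — algorithm, confidence and noise
settings), and output/report paths. Validation collects every failure at
once. See `vignettes/decoding-model.Rmd` for the model, parameter and
design details.

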