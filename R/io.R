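## FASTQ / SAM readers and writers, JSON run configuration, and the
## demultiplex pipeline with its run report.

#' Read a FASTQ file
#'
#' Sanger / Illumina 1.8+ encoding (Phred+33); gzip is transparent.
#'
#' @param path FASTQ file, plain or gzip.
#' @return List with `names`, `seq` (character vector) and `qual`
#'   (Phred+33 quality strings).
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      # harmless notice about dropped metadata columns on FASTQ ingestion
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(names = sub("[ \t].*$", "", names(x)),
       seq = unname(as.character(x)),
       qual = unname(as.character(Biostrings::quality(x))))
}

#' Write a FASTQ file
#'
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param names,seqs,quals Parallel vectors of read names, sequences and
#'   Phred+33 quality strings.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(path, names, seqs, quals) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(names))
    writeLines(as.vector(rbind(paste0("@", names), seqs, "+", quals)), con)
  invisible(path)
}

## Plain SAM text records (the portable contract; BAM/CRAM out of scope) ----

sam_header <- function(read_groups = character(0)) {
  c("@HD\tVN:1.6\tSO:unknown",
    if (length(read_groups))
      paste0("@RG\tID:", read_groups, "\tSM:", read_groups),
    paste0("@PG\tID:pamld\tPN:pamld\tVN:",
           as.character(utils::packageVersion("pamld"))))
}

# block: list(names, segments = list of list(seq, qual)); optional tags:
# character vector (one tab-joined tag string per read) and flags overrides.
write_sam_block <- function(path, block, read_groups = character(0),
                            tags = NULL, qc_fail = NULL) {
  nseg <- length(block$segments)
  nreads <- length(block$names)
  lines <- sam_header(read_groups)
  if (nreads) {
    recs <- vector("list", nseg)
    for (k in seq_len(nseg)) {
      flag <- if (nseg == 1L) 4L
              else bitwOr(bitwOr(13L, if (k == 1L) 64L else 0L),
                          if (k == nseg) 128L else 0L)
      flags <- rep(flag, nreads)
      if (!is.null(qc_fail)) flags <- flags + 512L * qc_fail
      recs[[k]] <- paste(block$names, flags, "*", 0L, 0L, "*", "*", 0L, 0L,
                         block$segments[[k]]$seq, block$segments[[k]]$qual,
                         sep = "\t")
      if (!is.null(tags)) recs[[k]] <- paste(recs[[k]], tags, sep = "\t")
    }
    # interleave: all segments of a read adjacent, input order preserved
    mat <- do.call(rbind, recs)
    lines <- c(lines, as.vector(mat))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read unaligned SAM records as multi-segment reads
#'
#' Parses plain SAM text; records sharing a name form one read, with
#' segment order taken from the 0x40 (first) / 0x80 (last) flags when set
#' and file order otherwise. Auxiliary tags are returned verbatim.
#'
#' @param path SAM file path.
#' @return List with `names`, `segments` (list of `list(seq, qual)` columnar
#'   blocks) and `tags` (character vector per record group).
#' @export
read_sam_block <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(list(names = character(0), segments = list(), tags = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  seqs <- vapply(fields, `[[`, character(1), 10L)
  quals <- vapply(fields, `[[`, character(1), 11L)
  tags <- vapply(fields, function(f)
    if (length(f) > 11L) paste(f[12:length(f)], collapse = "\t") else "",
    character(1))
  grp <- match(qname, unique(qname))
  ord <- order(grp,
               ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                      ifelse(bitwAnd(flag, 128L) > 0L, 3L, 2L)),
               seq_along(grp))
  qname <- qname[ord]; seqs <- seqs[ord]; quals <- quals[ord]
  tags <- tags[ord]; grp <- grp[ord]
  nseg <- unique(as.vector(table(grp)))
  if (length(nseg) != 1L)
    stop("SAM records per read name are not constant; segment layout ambiguous")
  names_ <- unique(qname)
  segments <- lapply(seq_len(nseg), function(k) {
    sel <- seq(k, length(qname), by = nseg)
    list(seq = seqs[sel], qual = quals[sel])
  })
  list(names = names_, segments = segments,
       tags = tags[seq(1L, length(qname), by = nseg)])
}

#' Read multi-segment reads from FASTQ files or a SAM file
#'
#' FASTQ: one file per segment, indexed in order (e.g. 0 = Read1,
#' 1 = Index1, 2 = Index2, 3 = Read2); all files must yield the same read
#' count with agreeing names (up to `/1`-style suffixes) at every position -
#' a desynchronized input is a hard error naming the first offending record,
#' since silent misjoins corrupt classification. SAM: a single file of
#' unaligned multi-segment records. gzip is transparent for FASTQ.
#'
#' @param paths Character vector of FASTQ paths, or one SAM path.
#' @param format `"auto"` (by extension), `"fastq"` or `"sam"`.
#' @return A columnar read block: list with `names` and `segments`.
#' @export
read_multisegment <- function(paths, format = c("auto", "fastq", "sam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (length(paths) == 1L && grepl("\\.sam$", paths)) "sam"
              else "fastq"
  if (format == "sam") return(read_sam_block(paths))
  parts <- lapply(paths, read_fastq)
  counts <- vapply(parts, function(p) length(p$names), integer(1))
  if (length(unique(counts)) != 1L)
    stop("input files yield different read counts: ",
         paste(counts, collapse = ", "),
         " (truncated input at record ", min(counts) + 1L, ")")
  strip <- function(nm) sub("/[12]$", "", nm)
  base_names <- strip(parts[[1L]]$names)
  for (k in seq_along(parts)[-1L]) {
    mism <- which(strip(parts[[k]]$names) != base_names)
    if (length(mism))
      stop("read name desynchronization between segment files at record ",
           mism[1L], ": \"", parts[[k]]$names[mism[1L]], "\" vs \"",
           parts[[1L]]$names[mism[1L]], "\"")
  }
  list(names = base_names,
       segments = lapply(parts, function(p) list(seq = p$seq, qual = p$qual)))
}

## Configuration ------------------------------------------------------------

#' Validate and normalize a run configuration
#'
#' Accepts a parsed JSON document (or a path to one) describing input files
#' and segment layout, the transform specification, one decoder block per
#' barcode type, output and report paths. All validation failures are
#' collected and reported together, each naming the offending key. Defaults
#' are filled in: algorithm `pamld`, confidence threshold 0.95, noise prior
#' 0.05, uniform priors.
#'
#' @param config A list (parsed JSON) or a JSON file path.
#' @return A normalized run configuration list (class `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))

  input <- unlist(config$input)
  if (is.null(input)) note("input: required")
  else for (p in input) if (p != "-" && !file.exists(p))
    note("input: file not found: ", p)

  tr <- config$transform
  if (is.null(tr$template)) note("transform.template: required")
  spec <- tryCatch(
    transform_spec(unlist(tr$template), unlist(tr$sample),
                   unlist(tr$cellular), unlist(tr$molecular)),
    error = function(e) { note("transform: ", conditionMessage(e)); NULL })

  out <- config$output
  out_format <- if (is.null(out$format)) "sam" else out$format
  if (!out_format %in% c("sam", "fastq"))
    note("output.format: must be \"sam\" or \"fastq\" (got \"",
         out_format, "\")")
  if (is.null(out$path)) note("output.path: required")

  decoders <- list()
  if (!is.null(spec)) {
    for (type in barcode_types(spec)) {
      block <- config$decoders[[type]]
      if (is.null(block)) {
        if (type != "molecular")   # molecular barcodes pass through raw
          note("decoders.", type, ": required (", type,
               " tokens are present in the transform)")
        next
      }
      d <- normalize_decoder_block(block, type, spec, note)
      if (!is.null(d)) decoders[[type]] <- d
    }
  }

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(list(input = input,
                 input_format = if (is.null(config$format)) "auto"
                                else config$format,
                 transform = spec, decoders = decoders,
                 output = list(format = out_format, path = out$path,
                               gzip = isTRUE(out$gzip)),
                 report = config$report,
                 seed = if (is.null(config$seed)) 1L
                        else as.integer(config$seed)),
            class = "run_config")
}

normalize_decoder_block <- function(block, type, spec, note) {
  algorithm <- if (is.null(block$algorithm)) "pamld" else block$algorithm
  if (!algorithm %in% c("pamld", "mdd", "uniform-ml")) {
    note("decoders.", type, ".algorithm: unknown algorithm \"", algorithm, "\"")
    return(NULL)
  }
  if (is.null(block$barcodes) || !length(block$barcodes)) {
    note("decoders.", type, ".barcodes: required")
    return(NULL)
  }
  set <- tryCatch(barcode_set(lapply(names(block$barcodes), function(id)
           barcode(id, unlist(block$barcodes[[id]])))),
         error = function(e) {
           note("decoders.", type, ".barcodes: ", conditionMessage(e)); NULL })
  if (is.null(set)) return(NULL)
  token_len <- token_extraction_length(spec[[type]])
  if (!is.na(token_len) && token_len != set$length) {
    note("decoders.", type, ": barcode length ", set$length,
         " does not match the ", type, " token extraction length ", token_len)
    return(NULL)
  }
  confidence <- if (is.null(block$confidence)) 0.95 else block$confidence
  noise <- if (is.null(block$noise)) 0.05 else block$noise
  cfg <- tryCatch(decoder_config(confidence, block$noise_floor,
                                 block$tolerance),
                  error = function(e) {
                    note("decoders.", type, ": ", conditionMessage(e)); NULL })
  if (is.null(cfg)) return(NULL)
  priors_spec <- if (is.null(block$priors)) "uniform" else block$priors
  priors <- NULL
  if (is.character(priors_spec)) {
    if (!priors_spec %in% c("uniform", "estimate")) {
      note("decoders.", type, ".priors: must be \"uniform\", \"estimate\" ",
           "or an explicit {noise, classes} object")
      return(NULL)
    }
    if (priors_spec == "uniform") priors <- uniform_priors(set, noise)
  } else {
    priors <- tryCatch(
      prior_distribution(unlist(priors_spec$classes), priors_spec$noise),
      error = function(e) {
        note("decoders.", type, ".priors: ", conditionMessage(e)); NULL })
    if (is.null(priors)) return(NULL)
    if (length(setdiff(set$ids, names(priors$class_priors)))) {
      note("decoders.", type, ".priors: missing classes: ",
           paste(setdiff(set$ids, names(priors$class_priors)), collapse = ", "))
      return(NULL)
    }
  }
  list(type = type, algorithm = algorithm, set = set,
       priors_mode = if (is.character(priors_spec)) priors_spec else "explicit",
       priors = priors, config = cfg)
}

# Total extraction length of a token list, NA when any token is open-ended.
token_extraction_length <- function(tokens) {
  lens <- vapply(tokens, function(tok) {
    if (is.na(tok$end) || tok$start < 0 || tok$end < 0) return(NA_integer_)
    tok$end - tok$start
  }, integer(1))
  if (any(is.na(lens))) NA_integer_ else sum(lens)
}

## Demultiplex pipeline -----------------------------------------------------

#' Demultiplex a run
#'
#' Reads multi-segment reads, extracts barcode observations with the
#' transform tokens, decodes each barcode type with its configured decoder
#' (priors `"estimate"` triggers the two-pass workflow), and writes decoded
#' output plus a JSON run report. SAM output carries one unaligned record
#' per template segment with a read group per sample class, the qc-fail flag
#' (0x200) for confidence-filter failures, and auxiliary tags (BC/QT raw
#' sample and XB decoding error; CR/CY raw, CB decoded, XC error for
#' cellular; RX/QX raw molecular). FASTQ output is split by sample class,
#' with rejected reads in `undetermined` files. Output order equals input
#' order, so identical inputs and configuration give byte-identical outputs.
#'
#' @param config A config list / JSON path (passed to [validate_config()]),
#'   or a `run_config`.
#' @return Invisibly, the run report list.
#' @export
demux_run <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  block <- read_multisegment(config$input, config$input_format)
  nreads <- length(block$names)
  seg_lens <- if (nreads) vapply(block$segments,
                                 function(s) nchar(s$seq[1L]), integer(1))
              else integer(0)
  if (nreads) lint_token_overlap(config$transform, as.list(seg_lens))

  decoded <- list(); raw_obs <- list(); estimated <- list()
  for (type in barcode_types(config$transform)) {
    obs <- extract_tokens_block(block, config$transform[[type]])
    raw_obs[[type]] <- obs
    d <- config$decoders[[type]]
    if (is.null(d)) next
    decoded[[type]] <- switch(d$algorithm,
      mdd = mdd_decode(obs, d$set, d$config$mdd_tolerance),
      "uniform-ml" = uniform_ml_decode(obs, d$set),
      pamld = if (d$priors_mode == "estimate") {
        tp <- two_pass_decode(obs, d$set, d$config)
        estimated[[type]] <- tp$priors
        tp$results
      } else pamld_decode(obs, d$set, d$priors, d$config))
  }

  template <- lapply(config$transform$template, function(tok)
    extract_tokens_block(block, list(tok)))
  tmpl_segments <- lapply(template, function(ob)
    list(seq = ob$sequences, qual = encode_phred_strings(ob$qualities)))

  sample_class <- if (!is.null(decoded$sample)) decoded$sample$assigned
                  else rep(UNDETERMINED, nreads)
  qc_fail <- if (!is.null(decoded$sample)) decoded$sample$qc_fail
             else rep(FALSE, nreads)

  if (config$output$format == "sam") {
    tags <- build_sam_tags(sample_class, decoded, raw_obs, config$transform)
    rg <- if (!is.null(config$decoders$sample))
      c(sort(config$decoders$sample$set$ids), UNDETERMINED)
    else UNDETERMINED
    write_sam_block(config$output$path,
                    list(names = block$names, segments = tmpl_segments),
                    read_groups = rg, tags = tags, qc_fail = qc_fail)
  } else {
    write_split_fastq(config$output$path, block$names, tmpl_segments,
                      sample_class, qc_fail, gzip = config$output$gzip)
  }

  report <- build_run_report(config, nreads, decoded, estimated)
  if (!is.null(config$report))
    jsonlite::write_json(report, config$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}

build_sam_tags <- function(sample_class, decoded, raw_obs, spec) {
  n <- length(sample_class)
  tags <- paste0("RG:Z:", sample_class)
  join_tokens <- function(obs, tokens, sep) {
    pn <- obs$piece_nchar
    if (is.null(pn) || ncol(pn) <= 1L)
      return(list(seq = obs$sequences,
                  qual = encode_phred_strings(obs$qualities)))
    # row-wise cumulative slice boundaries (reads x tokens)
    ut <- upper.tri(diag(ncol(pn)), diag = TRUE) * 1
    ends <- pn %*% ut
    starts <- ends - pn + 1L
    qual <- encode_phred_strings(obs$qualities)
    seq_cols <- lapply(seq_len(ncol(pn)), function(k)
      substring(obs$sequences, starts[, k], ends[, k]))
    qual_cols <- lapply(seq_len(ncol(pn)), function(k)
      substring(qual, starts[, k], ends[, k]))
    list(seq = do.call(paste, c(seq_cols, sep = sep[1L])),
         qual = do.call(paste, c(qual_cols, sep = sep[2L])))
  }
  if (!is.null(raw_obs$sample)) {
    raw <- join_tokens(raw_obs$sample, spec$sample, c("-", " "))
    tags <- paste0(tags, "\tBC:Z:", raw$seq, "\tQT:Z:", raw$qual)
    if (!is.null(decoded$sample)) {
      err <- decoded$sample$decoding_error
      tags <- paste0(tags, ifelse(is.na(err), "",
                                  paste0("\tXB:f:", format(err, digits = 7,
                                                           scientific = FALSE,
                                                           trim = TRUE))))
    }
  }
  if (!is.null(raw_obs$cellular)) {
    raw <- join_tokens(raw_obs$cellular, spec$cellular, c("-", " "))
    tags <- paste0(tags, "\tCR:Z:", raw$seq, "\tCY:Z:", raw$qual)
    if (!is.null(decoded$cellular)) {
      cb <- decoded$cellular$assigned
      tags <- paste0(tags, "\tCB:Z:", cb,
                     ifelse(is.na(decoded$cellular$decoding_error), "",
                            paste0("\tXC:f:",
                                   format(decoded$cellular$decoding_error,
                                          digits = 7, scientific = FALSE,
                                          trim = TRUE))))
    }
  }
  if (!is.null(raw_obs$molecular)) {
    raw <- join_tokens(raw_obs$molecular, spec$molecular, c("-", " "))
    tags <- paste0(tags, "\tRX:Z:", raw$seq, "\tQX:Z:", raw$qual)
  }
  tags
}

write_split_fastq <- function(dir, names_, tmpl_segments, sample_class,
                              qc_fail, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  names_out <- ifelse(qc_fail, paste0(names_, " QC:fail"), names_)
  for (cls in unique(sample_class)) {
    sel <- sample_class == cls
    for (k in seq_along(tmpl_segments)) {
      path <- file.path(dir, sprintf("%s_%d.fastq%s", cls, k,
                                     if (gzip) ".gz" else ""))
      write_fastq(path, names_out[sel], tmpl_segments[[k]]$seq[sel],
                  tmpl_segments[[k]]$qual[sel])
    }
  }
  invisible(dir)
}

build_run_report <- function(config, nreads, decoded, estimated) {
  report <- list(total_reads = nreads,
                 parameters = list(
                   confidence_threshold = lapply(config$decoders,
                                                 function(d) d$config$confidence_threshold),
                   algorithms = lapply(config$decoders, `[[`, "algorithm"),
                   seed = config$seed))
  for (type in names(decoded)) {
    res <- decoded[[type]]
    rejected <- res$assigned == UNDETERMINED
    hi <- !rejected & !res$qc_fail
    lo <- !rejected & res$qc_fail
    ids <- sort(unique(res$assigned[!rejected]))
    count_tab <- function(mask) {
      tab <- table(factor(res$assigned[mask], levels = ids))
      as.list(stats::setNames(as.integer(tab), ids))
    }
    report[[type]] <- list(noise_rejected = sum(rejected),
                           high_confidence = count_tab(hi),
                           low_confidence = count_tab(lo))
    if (!is.null(estimated[[type]]))
      report[[type]]$estimated_priors <-
        list(noise = estimated[[type]]$noise_prior,
             classes = as.list(estimated[[type]]$class_priors))
  }
  report
}
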