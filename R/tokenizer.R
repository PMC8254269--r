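## Transform directives: slicing barcode and template tokens out of
## multi-segment reads.

#' Parse a transform token
#'
#' A token is a `"segment:start:end"` directive selecting a slice of one read
#' segment. Coordinates are zero-based and half-open (start inclusive, end
#' exclusive); an empty start defaults to 0 and an empty end to the end of the
#' segment. Negative coordinates count from the segment end (-k resolves to
#' length - k), supporting 3'-anchored barcodes on variable-length segments.
#' A trailing `"~"` requests the reverse complement of the slice (with
#' reversed qualities).
#'
#' @param text Token string, e.g. `"0:0:31"`, `"1::"`, `"2:-8:~"`.
#' @return An object of class `token` with fields `segment_index`, `start`,
#'   `end` (NA for "end of segment") and `reverse_complement`.
#' @examples
#' parse_token("0:12:24")
#' parse_token("1::")
#' @export
parse_token <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([0-9]+):(-?[0-9]*):(-?[0-9]*)(~?)$", text))[[1L]]
  if (length(m) == 0L)
    stop("malformed transform token: \"", text,
         "\" (expected \"segment:start:end\" with optional trailing ~)")
  start <- if (m[3L] == "") 0L else as.integer(m[3L])
  end <- if (m[4L] == "") NA_integer_ else as.integer(m[4L])
  structure(list(segment_index = as.integer(m[2L]), start = start, end = end,
                 reverse_complement = m[5L] == "~", text = text),
            class = "token")
}

as_token <- function(x) if (inherits(x, "token")) x else parse_token(x)

# Resolve token coordinates against a segment length; returns 1-based
# inclusive [from, to] for substring().
resolve_token <- function(token, segment_length) {
  start <- token$start
  end <- if (is.na(token$end)) segment_length else token$end
  if (start < 0) start <- segment_length + start
  if (end < 0) end <- segment_length + end
  if (start < 0 || end > segment_length || start >= end)
    stop("token \"", token$text, "\" resolves to an empty or out-of-range ",
         "slice [", start, ", ", end, ") on a segment of length ",
         segment_length)
  c(from = start + 1L, to = end)
}

#' Transform specification
#'
#' Maps raw read segments to the output template and to the sample, cellular
#' and molecular barcode observations. Each entry is a list of tokens (or
#' token strings) whose extractions are concatenated in order; any barcode
#' list may be empty. Overlapping tokens are permitted (a base may feed both
#' a barcode and the template); overlap is reported with a lint warning at
#' demultiplex time.
#'
#' @param template_tokens,sample_tokens,cellular_tokens,molecular_tokens
#'   Character vectors or lists of tokens.
#' @return An object of class `transform_spec`.
#' @examples
#' transform_spec(template_tokens = c("0:24:", "3::"),
#'                sample_tokens = c("1::", "2::"),
#'                cellular_tokens = "0:0:12", molecular_tokens = "0:12:24")
#' @export
transform_spec <- function(template_tokens = character(),
                           sample_tokens = character(),
                           cellular_tokens = character(),
                           molecular_tokens = character()) {
  spec <- list(template = lapply(template_tokens, as_token),
               sample = lapply(sample_tokens, as_token),
               cellular = lapply(cellular_tokens, as_token),
               molecular = lapply(molecular_tokens, as_token))
  structure(spec, class = "transform_spec")
}

barcode_types <- function(spec) {
  names(which(vapply(spec[c("sample", "cellular", "molecular")],
                     function(x) length(x) > 0L, logical(1))))
}

#' A multi-segment read
#'
#' One sequencer read as a list of segments (e.g. 0 = Read1, 1 = Index1,
#' 2 = Index2, 3 = Read2), each a (sequence, qualities) pair.
#'
#' @param name Read name.
#' @param segments List of `list(sequence =, qualities =)` pairs; qualities
#'   are integer Phred scores of the same length as the sequence.
#' @return An object of class `multiread`.
#' @export
multiread <- function(name, segments) {
  for (s in segments)
    if (nchar(s$sequence) != length(s$qualities))
      stop("segment sequence and qualities differ in length for read ", name)
  structure(list(name = name, segments = segments), class = "multiread")
}

revcomp_string <- function(x) {
  vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s)))), character(1),
    USE.NAMES = FALSE)
}

#' Extract a barcode observation from a read
#'
#' Concatenates the token slices in order. Reverse-complement tokens
#' contribute the reverse complement of their slice, with the quality scores
#' reversed to stay aligned with the bases.
#'
#' @param read A [multiread()].
#' @param tokens List of tokens (or token strings).
#' @return An [observed_barcode()] (with `sequence` and `qualities`).
#' @export
extract_tokens <- function(read, tokens) {
  tokens <- lapply(tokens, as_token)
  seqs <- character(length(tokens))
  quals <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[[i]]
    if (tok$segment_index + 1L > length(read$segments))
      stop("token \"", tok$text, "\" references segment ", tok$segment_index,
           " but read ", read$name, " has ", length(read$segments),
           " segments")
    seg <- read$segments[[tok$segment_index + 1L]]
    rng <- resolve_token(tok, nchar(seg$sequence))
    s <- substring(seg$sequence, rng["from"], rng["to"])
    q <- seg$qualities[rng["from"]:rng["to"]]
    if (tok$reverse_complement) {
      s <- revcomp_string(s)
      q <- rev(q)
    }
    seqs[i] <- s
    quals[[i]] <- q
  }
  observed_barcode(paste(seqs, collapse = ""), unlist(quals))
}

#' Build the output template read
#'
#' Applies the template tokens of a [transform_spec()] to a read: the output
#' read's segments are exactly the template extractions (barcode bases
#' removed unless a template token covers them too); the read name is
#' preserved.
#'
#' @param read A [multiread()].
#' @param spec A [transform_spec()].
#' @return A [multiread()] whose segments are the template token extractions.
#' @export
build_output_template <- function(read, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  segs <- lapply(spec$template, function(tok) {
    ob <- extract_tokens(read, list(tok))
    list(sequence = ob$sequence, qualities = ob$qualities)
  })
  multiread(read$name, segs)
}

## Columnar (vectorised) extraction used by the demultiplex pipeline --------

# read_block: list(names = chr, segments = list of list(seq = chr vec,
# qual = chr vec of phred+33 strings)). Returns observed_barcodes.
extract_tokens_block <- function(block, tokens) {
  tokens <- lapply(tokens, as_token)
  nreads <- length(block$names)
  pieces_seq <- vector("list", length(tokens))
  pieces_qual <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[[i]]
    if (tok$segment_index + 1L > length(block$segments))
      stop("token \"", tok$text, "\" references segment ", tok$segment_index,
           " but the input layout has ", length(block$segments), " segments")
    seg <- block$segments[[tok$segment_index + 1L]]
    lens <- nchar(seg$seq)
    start <- tok$start
    end <- if (is.na(tok$end)) lens else tok$end
    from <- ifelse(rep(start < 0, nreads), lens + start, start) + 1L
    to <- ifelse(end < 0, lens + end, end)
    if (any(from < 1L) || any(to > lens) || any(from > to))
      stop("token \"", tok$text, "\" resolves out of range for at least one read")
    s <- substring(seg$seq, from, to)
    q <- substring(seg$qual, from, to)
    if (tok$reverse_complement) {
      s <- revcomp_string(s)
      q <- vapply(q, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
                  USE.NAMES = FALSE)
    }
    pieces_seq[[i]] <- s
    pieces_qual[[i]] <- q
  }
  seqs <- do.call(paste0, pieces_seq)
  quals <- do.call(paste0, pieces_qual)
  out <- observed_barcodes(seqs, quals)
  # per-read per-token slice widths, kept for multi-token SAM tag emission
  out$piece_nchar <- do.call(cbind, lapply(pieces_seq, nchar))
  out
}

# Lint check: warn (once per run) when tokens reuse a base of a segment.
lint_token_overlap <- function(spec, segment_lengths) {
  all_tokens <- c(spec$template, spec$sample, spec$cellular, spec$molecular)
  used <- lapply(segment_lengths, function(n) integer(n))
  for (tok in all_tokens) {
    idx <- tok$segment_index + 1L
    if (idx > length(segment_lengths)) next
    rng <- tryCatch(resolve_token(tok, segment_lengths[[idx]]),
                    error = function(e) NULL)
    if (is.null(rng)) next
    used[[idx]][rng["from"]:rng["to"]] <- used[[idx]][rng["from"]:rng["to"]] + 1L
  }
  if (any(vapply(used, function(u) any(u > 1L), logical(1))))
    warning("transform tokens overlap: some bases feed more than one output",
            call. = FALSE)
  invisible(NULL)
}
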