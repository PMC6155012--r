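# Read-level processing of IgH amplicon data (quality filter, MID
# demultiplex, primer mask/trim, duplicate collapse) and sequence-level QC
# (functionality and chimera filters, mutation counting).

#' Read a FASTQ file into a reads data frame
#'
#' @param path FASTQ path (Sanger Phred+33).
#' @return Data frame: `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a reads data frame as FASTQ
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

mean_phred <- function(quality) {
  vapply(phred_scores(quality), mean, numeric(1))
}

qc_log <- function(stage, reason, n) {
  data.frame(stage = stage, reason = reason, n = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Length and mean-quality read filter
#'
#' Removes reads of length strictly less than `min_length` or mean Phred
#' score strictly less than `min_mean_q` (so a read at exactly the boundary
#' is retained).  Mean quality is computed on the raw Phred scores.
#'
#' @param reads Reads data frame.
#' @param min_length Minimum length, default 250.
#' @param min_mean_q Minimum mean Phred, default 20.
#' @return List: `reads` (retained, order preserved), `log` (counts per
#'   removal reason).
#' @export
quality_filter <- function(reads, min_length = 250, min_mean_q = 20) {
  if (!nrow(reads)) {
    return(list(reads = reads,
                log = qc_log("quality_filter", c("short", "low_quality", "retained"),
                             c(0L, 0L, 0L))))
  }
  len_ok <- nchar(reads$sequence) >= min_length
  q_ok <- mean_phred(reads$quality) >= min_mean_q
  keep <- len_ok & q_ok
  list(
    reads = reads[keep, , drop = FALSE],
    log = qc_log("quality_filter",
                 c("short", "low_quality", "retained"),
                 c(sum(!len_ok), sum(len_ok & !q_ok), sum(keep)))
  )
}

#' Demultiplex reads by exact MID match at both ends
#'
#' The expected layout is `MID + body + revcomp(MID')`.  The 10-nt prefix
#' and (reverse-complemented) 10-nt suffix must each exactly match a MID in
#' the set; reads without exact matches at both ends are removed.  Both MIDs
#' are recorded (`mid`, `mid3`) and excised; `mid_consistent` flags whether
#' the two ends carry the same tag (inconsistent tags suggest chimeras and
#' are resolved later by [functionality_filter()]).
#'
#' @param reads Reads data frame.
#' @param mids Named character vector of unique 10-nt MIDs.
#' @return List: `reads` (with `mid`, `mid3`, `mid_consistent`; sequence and
#'   quality trimmed), `log`.
#' @export
demux_mid <- function(reads, mids) {
  if (anyDuplicated(mids)) stopf("duplicate MIDs in set")
  stopifnot(all(nchar(mids) == 10L))
  pre <- substr(reads$sequence, 1L, 10L)
  len <- nchar(reads$sequence)
  suf <- substr(reads$sequence, len - 9L, len)
  mid5 <- names(mids)[match(pre, mids)]
  mid3 <- names(mids)[match(revcomp(suf), mids)]
  keep <- !is.na(mid5) & !is.na(mid3) & len > 20L
  out <- reads[keep, , drop = FALSE]
  out$mid <- mid5[keep]
  out$mid3 <- mid3[keep]
  out$mid_consistent <- out$mid == out$mid3
  out$sequence <- substr(out$sequence, 11L, len[keep] - 10L)
  out$quality <- substr(out$quality, 11L, len[keep] - 10L)
  list(reads = out,
       log = qc_log("demux_mid", c("no_mid_match", "retained"),
                    c(sum(!keep), sum(keep))))
}

mismatch_fraction <- function(seqs, primer, from_end = FALSE) {
  pl <- nchar(primer)
  region <- if (from_end) {
    substr(seqs, nchar(seqs) - pl + 1L, nchar(seqs))
  } else {
    substr(seqs, 1L, pl)
  }
  pm <- strsplit(primer, "")[[1]]
  vapply(strsplit(region, ""), function(b) {
    if (length(b) < pl) return(1)
    sum(b != pm) / pl
  }, numeric(1))
}

#' Match, mask and trim amplification primers
#'
#' The best-scoring forward (V-region) primer at the 5' end and reverse
#' (constant-region) primer at the 3' end are accepted when their ungapped
#' mismatch fraction is at most `max_error` (inclusive).  The forward-primer
#' region is masked with Ns (length preserved); the reverse-primer region is
#' trimmed.  The isotype is inferred from the reverse primer id.  Reads with
#' no primer within the error budget are removed and logged.
#'
#' @param reads Demultiplexed reads data frame.
#' @param fwd_primers,rev_primers Named character vectors.
#' @param max_error Maximum mismatch fraction, default 0.2.
#' @return List: `reads` (with `fwd_primer`, `rev_primer`, `c_call`), `log`.
#' @export
match_primers <- function(reads, fwd_primers, rev_primers, max_error = 0.2) {
  stopifnot(length(fwd_primers) > 0, length(rev_primers) > 0)
  n <- nrow(reads)
  if (!n) {
    return(list(reads = reads,
                log = qc_log("match_primers", c("no_fwd", "no_rev", "retained"),
                             c(0L, 0L, 0L))))
  }
  fmat <- vapply(fwd_primers, function(p) mismatch_fraction(reads$sequence, p),
                 numeric(n))
  rmat <- vapply(rev_primers, function(p) mismatch_fraction(reads$sequence, p,
                                                            from_end = TRUE),
                 numeric(n))
  fmat <- matrix(fmat, nrow = n); rmat <- matrix(rmat, nrow = n)
  fbest <- max.col(-fmat, ties.method = "first")
  rbest <- max.col(-rmat, ties.method = "first")
  f_ok <- fmat[cbind(seq_len(n), fbest)] <= max_error
  r_ok <- rmat[cbind(seq_len(n), rbest)] <= max_error
  keep <- f_ok & r_ok
  out <- reads[keep, , drop = FALSE]
  out$fwd_primer <- names(fwd_primers)[fbest[keep]]
  out$rev_primer <- names(rev_primers)[rbest[keep]]
  out$c_call <- out$rev_primer
  flen <- nchar(fwd_primers)[fbest[keep]]
  rlen <- nchar(rev_primers)[rbest[keep]]
  out$sequence <- paste0(strrep("N", flen),
                         substr(out$sequence, flen + 1L, nchar(out$sequence) - rlen))
  out$quality <- substr(out$quality, 1L, nchar(out$sequence))
  list(reads = out,
       log = qc_log("match_primers", c("no_fwd", "no_rev", "retained"),
                    c(sum(!f_ok), sum(f_ok & !r_ok), sum(keep))))
}

#' Collapse duplicate reads into unique sequences
#'
#' Grouping key: (sequence, MID, forward primer, reverse primer).  The sum
#' of duplicate counts equals the number of input reads.
#'
#' @param reads Primer-annotated reads data frame.
#' @return Data frame of unique sequences with `duplicate_count`; one row
#'   per group, first-seen order, carrying the first read's annotations.
#' @export
collapse_duplicates <- function(reads) {
  if (!nrow(reads)) {
    reads$duplicate_count <- integer(0)
    return(reads)
  }
  key <- paste(reads$sequence, reads$mid, reads$fwd_primer, reads$rev_primer,
               sep = "\r")
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$duplicate_count <- as.integer(table(factor(key, levels = key[first])))
  rownames(out) <- NULL
  out
}

#' Remove non-functional and MID-inconsistent rearrangements
#'
#' Retains records flagged functional whose 5'/3' MIDs agree; records with
#' mismatched MIDs are removed as suspected chimeras.
#'
#' @param records Data frame with logical `functional` and `mid_consistent`.
#' @return List: `records` (retained), `log`.
#' @export
functionality_filter <- function(records) {
  if (is.null(records$functional) || is.null(records$mid_consistent)) {
    stopf("records must carry 'functional' and 'mid_consistent' flags")
  }
  keep <- records$functional & records$mid_consistent
  list(records = records[keep, , drop = FALSE],
       log = qc_log("functionality_filter",
                    c("non_functional", "mid_mismatch", "retained"),
                    c(sum(!records$functional),
                      sum(records$functional & !records$mid_consistent),
                      sum(keep))))
}

# 0/1 mismatch vector between two aligned strings; positions where either
# base is N are NA (not evaluable).
mismatch_vector <- function(seq, germline) {
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(germline, "")[[1]]
  if (length(a) != length(b)) stopf("sequence/germline length mismatch")
  m <- as.integer(a != b)
  m[a == "N" | b == "N"] <- NA_integer_
  m
}

#' Sliding-window chimera filter
#'
#' A sequence is removed when any full-length window of `window` aligned
#' positions contains strictly more than `max_mut` mismatches against the
#' germline.  Windows slide by one position; trailing windows shorter than
#' `window` are not evaluated.  N positions (in either string) do not count
#' as mismatches.
#'
#' @param sequence,germline Equal-length aligned strings.
#' @param window Window width, default 10.
#' @param max_mut Maximum tolerated mismatches per window, default 5.
#' @return `TRUE` to keep, `FALSE` to remove.
#' @export
chimera_window_filter <- function(sequence, germline, window = 10, max_mut = 5) {
  m <- mismatch_vector(sequence, germline)
  m[is.na(m)] <- 0L
  L <- length(m)
  if (L < window) return(TRUE)
  cs <- c(0L, cumsum(m))
  wins <- cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]
  all(wins <= max_mut)
}

#' Apply the chimera window filter to annotated records
#'
#' @param records Data frame with `sequence` and `germline_alignment`.
#' @param window,max_mut See [chimera_window_filter()].
#' @return List: `records` (kept), `removed`, `log`.
#' @export
chimera_filter_records <- function(records, window = 10, max_mut = 5) {
  keep <- vapply(seq_len(nrow(records)), function(i) {
    chimera_window_filter(records$sequence[i], records$germline_alignment[i],
                          window = window, max_mut = max_mut)
  }, logical(1))
  list(records = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       log = qc_log("chimera_window_filter", c("chimeric", "retained"),
                    c(sum(!keep), sum(keep))))
}

#' Mutation count and frequency against the germline
#'
#' Counts positional mismatches over germline-templated positions, i.e.
#' excluding positions where either string is N (masked primer regions and
#' the junction N region).  Frequency = count / evaluated length.
#'
#' @param sequence,germline Equal-length aligned strings.
#' @return List: `mutation_count`, `mutation_freq`, `evaluated_length`.
#' @export
mutation_frequency <- function(sequence, germline) {
  m <- mismatch_vector(sequence, germline)
  ev <- sum(!is.na(m))
  if (ev == 0) stopf("zero evaluated length")
  list(mutation_count = sum(m, na.rm = TRUE),
       mutation_freq = sum(m, na.rm = TRUE) / ev,
       evaluated_length = ev)
}

#' Annotate records with mutation statistics
#'
#' @param records Data frame with `sequence` and `germline_alignment`.
#' @return `records` with `mutation_count` and `mutation_freq` columns.
#' @export
add_mutation_stats <- function(records) {
  stats_list <- lapply(seq_len(nrow(records)), function(i) {
    mutation_frequency(records$sequence[i], records$germline_alignment[i])
  })
  records$mutation_count <- vapply(stats_list, `[[`, numeric(1), "mutation_count")
  records$mutation_freq <- vapply(stats_list, `[[`, numeric(1), "mutation_freq")
  records
}

#' Read / write AIRR-style rearrangement TSV
#'
#' Plain tab-separated files with a header row; logical columns are written
#' as TRUE/FALSE.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_airr <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_airr
#' @param records Data frame to write.
#' @export
write_airr <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
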