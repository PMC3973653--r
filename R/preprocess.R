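#' Trim the 3' adapter from raw reads
#'
#' The adapter is removed at its leftmost occurrence in each read. Two kinds
#' of occurrence are recognised: the full adapter anywhere in the read, and a
#' prefix of the adapter (at least \code{min_overlap} nt) ending flush with
#' the 3' end of the read (adapter read-through into short inserts). Reads
#' with no adapter occurrence are returned unchanged. Reads still containing
#' N after trimming are discarded (\code{NA} in the output).
#'
#' @param seqs character vector of raw read sequences (DNA alphabet).
#' @param adapter3 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length recognised at the read
#'   end.
#' @return character vector, same length as \code{seqs}; \code{NA} marks
#'   discarded reads.
#' @export
trim_reads <- function(seqs, adapter3, min_overlap = 6L) {
  stopifnot(nzchar(adapter3))
  adapter3 <- normalize_alphabet(adapter3)
  seqs <- normalize_alphabet(seqs)
  n <- length(seqs)
  if (!n) return(character())
  len <- nchar(seqs)
  # leftmost full-adapter occurrence
  cut <- regexpr(adapter3, seqs, fixed = TRUE)
  cut[cut < 0L] <- NA_integer_
  # terminal partial occurrence: longest adapter prefix that is a read
  # suffix gives the leftmost terminal cut
  la <- nchar(adapter3)
  for (l in seq(min(la, max(len)), min_overlap)) {
    pref <- substr(adapter3, 1L, l)
    hit <- endsWith(seqs, pref)
    pos <- len - l + 1L
    cut <- ifelse(hit & (is.na(cut) | pos < cut), pos, cut)
  }
  out <- ifelse(is.na(cut), seqs, substr(seqs, 1L, cut - 1L))
  out[grepl("N", out, fixed = TRUE)] <- NA_character_
  out[!nzchar(out) & !is.na(out)] <- NA_character_
  out
}

#' Length-window filter
#'
#' @param seqs character vector of sequences.
#' @param l_min,l_max inclusive length window in nt.
#' @return logical vector: TRUE iff \code{l_min <= nchar(seq) <= l_max}.
#' @export
pass_length <- function(seqs, l_min = 18L, l_max = 28L) {
  n <- nchar(seqs)
  n >= l_min & n <= l_max
}

#' Low-complexity filter
#'
#' A read passes iff it contains at least \code{min_bases} distinct bases.
#' The test is invariant under reversal and complementation.
#'
#' @param seqs character vector over \{A,C,G,T\}.
#' @param min_bases minimum number of distinct bases.
#' @return logical vector.
#' @export
pass_complexity <- function(seqs, min_bases = 3L) {
  if (!length(seqs)) return(logical())
  distinct <- grepl("A", seqs, fixed = TRUE) +
    grepl("C", seqs, fixed = TRUE) +
    grepl("G", seqs, fixed = TRUE) +
    grepl("T", seqs, fixed = TRUE)
  distinct >= min_bases
}

# All substrings of x with lengths in l_min..l_max. Used to hash contaminant
# and reference windows for exact membership tests.
seq_windows <- function(x, l_min, l_max) {
  out <- vector("list", length(x) * (l_max - l_min + 1L))
  k <- 0L
  for (s in x) {
    n <- nchar(s)
    for (l in l_min:l_max) {
      if (n < l) next
      k <- k + 1L
      out[[k]] <- substring(s, 1:(n - l + 1L), l:n)
    }
  }
  unique(unlist(out[seq_len(k)]))
}

#' Remove t/rRNA-like contaminant reads
#'
#' A read is removed iff it occurs as an exact ungapped substring of any
#' contaminant sequence or of its reverse complement (sense and antisense
#' matches). Counts of surviving reads are untouched.
#'
#' @param reads data.frame with a \code{sequence} column (and any count
#'   columns).
#' @param contaminants character vector of contaminant sequences (e.g.
#'   t/rRNA, snoRNA).
#' @param l_min,l_max read length window; only windows in this range are
#'   indexed.
#' @return \code{reads} restricted to surviving rows.
#' @export
remove_contaminants <- function(reads, contaminants, l_min = 18L,
                                l_max = 28L) {
  stopifnot(length(contaminants) > 0L)
  if (!nrow(reads)) return(reads)
  refs <- c(normalize_alphabet(contaminants),
            revcomp(normalize_alphabet(contaminants)))
  windows <- seq_windows(refs, l_min, l_max)
  keep <- !(reads$sequence %in% windows)
  reads[keep, , drop = FALSE]
}

#' Collapse reads into unique sequences with counts
#'
#' @param seqs character vector of (already filtered) read sequences.
#' @param counts integer multiplicities, recycled if length 1.
#' @return data.frame \code{sequence}, \code{count}, sorted by decreasing
#'   count then sequence.
#' @export
collapse_reads <- function(seqs, counts = 1L) {
  if (!length(seqs)) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- rep_len(as.integer(counts), length(seqs))
  agg <- rowsum(counts, group = seqs)
  out <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1L]),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$sequence), , drop = FALSE]
}

#' Clean one raw library into the filtered unique-read set
#'
#' Applies the fixed filter order: adapter/N trim, length window,
#' low-complexity filter, sense+antisense contaminant removal, collapsing.
#' Each stage count in the report is less than or equal to the previous.
#'
#' @param raw data.frame from \code{\link{read_sequences}} (columns
#'   \code{sequence}, \code{count}).
#' @param contaminants character vector of contaminant sequences.
#' @param config an \code{srna_config} list.
#' @return list with \code{reads} (collapsed data.frame) and \code{report}
#'   (one-row data.frame: input_reads, after_trim, after_length,
#'   after_complexity, after_contaminant, unique_sequences).
#' @export
preprocess_library <- function(raw, contaminants, config = pipeline_config()) {
  n_in <- sum(raw$count)
  trimmed <- trim_reads(raw$sequence, config$adapter3,
                        config$min_adapter_overlap)
  keep <- !is.na(trimmed)
  seqs <- trimmed[keep]
  cnt <- raw$count[keep]
  n_trim <- sum(cnt)

  keep <- pass_length(seqs, config$l_min, config$l_max)
  seqs <- seqs[keep]; cnt <- cnt[keep]
  n_len <- sum(cnt)

  keep <- pass_complexity(seqs, config$complexity_min_bases)
  seqs <- seqs[keep]; cnt <- cnt[keep]
  n_cplx <- sum(cnt)

  collapsed <- collapse_reads(seqs, cnt)
  collapsed <- remove_contaminants(collapsed, contaminants,
                                   config$l_min, config$l_max)
  n_cont <- sum(collapsed$count)

  report <- data.frame(
    input_reads = as.integer(n_in),
    after_trim = as.integer(n_trim),
    after_length = as.integer(n_len),
    after_complexity = as.integer(n_cplx),
    after_contaminant = as.integer(n_cont),
    unique_sequences = nrow(collapsed)
  )
  list(reads = collapsed, report = report)
}
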