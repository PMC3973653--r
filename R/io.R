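#' Read small-RNA sequences with multiplicities
#'
#' Reads raw sequences from FASTQ, FASTA or collapsed-FASTA. Sequences are
#' uppercased and U is mapped to T so that reads, references and transcripts
#' share one DNA alphabet. For FASTQ and plain FASTA every record has
#' multiplicity 1; collapsed-FASTA headers follow the de facto small-RNA
#' convention \code{>id_count}, where the integer suffix is the read count.
#'
#' @param path input file (plain or gzip-compressed).
#' @param format one of \code{"auto"}, \code{"fastq"}, \code{"fasta"},
#'   \code{"collapsed-fasta"}. \code{"auto"} picks FASTQ for
#'   \code{.fastq}/\code{.fq} extensions, collapsed-FASTA when every header
#'   carries an integer \code{_count} suffix, and FASTA otherwise.
#' @return A data.frame with columns \code{sequence} (character) and
#'   \code{count} (integer). Empty inputs give a zero-row data.frame.
#' @export
read_sequences <- function(path, format = c("auto", "fastq", "fasta",
                                            "collapsed-fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto" &&
      grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    format <- "fastq"
  }
  if (format == "fastq") {
    # BString: RNA letters and lowercase are normalized afterwards
    ss <- Biostrings::readBStringSet(path, format = "fastq")
    seqs <- normalize_alphabet(as.character(ss))
    bad <- grep("[^ACGTN]", seqs)
    if (length(bad)) {
      stop("malformed FASTQ record: unexpected characters in record ",
           bad[1L], " of ", path)
    }
    return(data.frame(sequence = unname(seqs),
                      count = rep.int(1L, length(seqs)),
                      stringsAsFactors = FALSE))
  }
  # FASTA dialects: read as raw lines so RNA letters and count suffixes are
  # handled uniformly and malformed records can name their line.
  con <- file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx) || hdr_idx[1L] != 1L) {
    stop("malformed FASTA: line 1 does not start a record in ", path)
  }
  bad <- setdiff(seq_along(lines), hdr_idx)
  bad <- bad[grepl("[^ACGTUNacgtun]", lines[bad])]
  if (length(bad)) {
    stop("malformed FASTA record: unexpected characters at line ", bad[1L],
         " of ", path)
  }
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  if (any(starts > ends)) {
    stop("malformed FASTA: empty record at line ",
         hdr_idx[which(starts > ends)[1L]], " of ", path)
  }
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  seqs <- normalize_alphabet(seqs)
  headers <- sub("^>", "", lines[hdr_idx])
  ids <- sub("\\s.*$", "", headers)

  if (format == "auto" &&
      all(grepl("^[^_]*(_[^_]*)*_[0-9]+$", ids))) {
    format <- "collapsed-fasta"
  } else if (format == "auto") {
    format <- "fasta"
  }
  if (format == "collapsed-fasta") {
    m <- regmatches(ids, regexpr("_-?[0-9]+$", ids))
    ok <- lengths(regmatches(ids, gregexpr("_-?[0-9]+$", ids))) == 1L
    if (!all(ok)) {
      stop("collapsed-FASTA header without _count suffix at line ",
           hdr_idx[which(!ok)[1L]], " of ", path)
    }
    counts <- as.integer(sub("^_", "", m))
    if (anyNA(counts) || any(counts < 0L)) {
      stop("negative or unparseable count suffix at line ",
           hdr_idx[which(is.na(counts) | counts < 0L)[1L]], " of ", path)
    }
    return(data.frame(sequence = seqs, count = counts,
                      stringsAsFactors = FALSE))
  }
  data.frame(sequence = seqs, count = rep.int(1L, length(seqs)),
             stringsAsFactors = FALSE)
}

normalize_alphabet <- function(x) toupper(chartr("Uu", "Tt", x))

#' Reverse complement (DNA alphabet)
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write collapsed reads as collapsed-FASTA
#'
#' Headers follow the \code{>id_count} convention: \code{>{prefix}{i}_{n}}.
#' Rows are written in decreasing count order, ties broken by sequence, so
#' output is deterministic.
#'
#' @param reads data.frame with columns \code{sequence} and \code{count}.
#' @param path output path.
#' @param prefix record id prefix.
#' @return \code{path}, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path, prefix = "s") {
  stopifnot(all(c("sequence", "count") %in% names(reads)))
  o <- order(-reads$count, reads$sequence)
  reads <- reads[o, , drop = FALSE]
  lines <- character(0)
  if (nrow(reads)) {
    lines <- as.vector(rbind(
      sprintf(">%s%d_%d", prefix, seq_len(nrow(reads)), reads$count),
      reads$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a plain FASTA file
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", nm), unname(seqs))), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path input FASTA.
#' @return named character vector (names are the header tokens before the
#'   first whitespace); U mapped to T, uppercased.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- normalize_alphabet(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a table as TSV
#'
#' Tab-separated, header line, no quoting or row names; numeric columns that
#' carry RPM values should be pre-formatted by the caller (the pipeline
#' writes RPM with 2 decimals).
#'
#' @param df data.frame of rows sharing one schema.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a TSV written by \code{write_table}
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Format RPM for TSV output: fixed 2 decimals.
format_rpm <- function(x) sprintf("%.2f", x)
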