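#' Match reads to a mature-miRNA reference
#'
#' Each read is compared ungapped and end-to-end against every reference
#' mature sequence of equal length and against every equal-length window of
#' longer references. A hit requires Hamming distance \code{<= m_max}; the
#' hit with the fewest mismatches wins, ties broken by lexicographically
#' smallest reference id.
#'
#' @param seqs character vector of unique read sequences (DNA alphabet).
#' @param reference named character vector of mature miRNA sequences
#'   (miRBase-style ids as names, e.g. \code{ssp-miR159a}); U is mapped to T.
#' @param m_max maximum Hamming mismatches.
#' @return data.frame \code{sequence}, \code{reference_id},
#'   \code{mismatches} with one row per matched read.
#' @export
match_reads <- function(seqs, reference, m_max = 3L) {
  stopifnot(length(reference) > 0L, !is.null(names(reference)))
  reference <- normalize_alphabet(reference)
  empty <- data.frame(sequence = character(), reference_id = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (!length(seqs)) return(empty)
  out <- vector("list", 0L)
  ref_len <- nchar(reference)
  for (L in sort(unique(nchar(seqs)))) {
    rs <- seqs[nchar(seqs) == L]
    # equal-length windows of every reference of length >= L
    idx <- which(ref_len >= L)
    if (!length(idx)) next
    wins <- lapply(idx, function(i) {
      n <- ref_len[i]
      data.frame(window = substring(reference[i], 1:(n - L + 1L),
                                    L:(n + 0L)),
                 reference_id = names(reference)[i],
                 stringsAsFactors = FALSE)
    })
    wins <- do.call(rbind, wins)
    wins <- wins[order(wins$reference_id), , drop = FALSE]
    d <- utils::adist(rs, wins$window,
                      costs = list(ins = 1000L, del = 1000L, sub = 1L))
    best <- apply(d, 1L, function(row) {
      m <- min(row)
      if (m > m_max) return(c(NA_integer_, NA_integer_))
      js <- which(row == m)
      # windows are sorted by reference_id, so the first minimal column is
      # the lexicographically smallest id
      c(js[1L], m)
    })
    hit <- !is.na(best[1L, ])
    if (!any(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      sequence = rs[hit],
      reference_id = wins$reference_id[best[1L, hit]],
      mismatches = as.integer(best[2L, hit]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# miR family from a miRBase-style id: the "miR<number>" token.
mirna_family <- function(id) {
  m <- regmatches(id, regexpr("(?i)mir-?[0-9]+", id, perl = TRUE))
  fam <- ifelse(lengths(regmatches(id, gregexpr("(?i)mir-?[0-9]+", id,
                                                perl = TRUE))) > 0L,
                paste0("miR", sub("(?i)mir-?", "", m, perl = TRUE)),
                id)
  fam
}

#' Profile conserved miRNAs across libraries
#'
#' Matches the unique filtered reads of all libraries to the mature-miRNA
#' reference, assigns family and star flags from the reference ids, labels
#' distinct matched sequences within each (family, star) group with Roman
#' numerals in lexicographic sequence order, and builds the electronic-
#' northern expression table.
#'
#' @param counts data.frame with a \code{sequence} column and one integer
#'   count column per library (see \code{\link{merge_libraries}}).
#' @param reference named character vector of mature miRNA sequences.
#' @param libraries data.frame with columns \code{id} and
#'   \code{total_filtered_reads}; ids must match the count columns.
#' @param config an \code{srna_config} list.
#' @return object of class \code{mirna_profile}: list with \code{hits}
#'   (sequence, reference_id, mismatches, family, is_star, variant_label),
#'   \code{expression} (the electronic northern), \code{libraries}.
#' @export
profile_mirnas <- function(counts, reference, libraries,
                           config = pipeline_config()) {
  stopifnot("sequence" %in% names(counts),
            all(libraries$id %in% names(counts)))
  hits <- match_reads(counts$sequence, reference, config$m_max_mirna)
  if (nrow(hits)) {
    hits$is_star <- grepl("\\*", hits$reference_id)
    hits$family <- mirna_family(hits$reference_id)
    grp <- paste0(hits$family, ifelse(hits$is_star, "*", ""))
    hits$variant_label <- NA_character_
    for (g in unique(grp)) {
      i <- which(grp == g)
      lev <- sort(unique(hits$sequence[i]))
      hits$variant_label[i] <-
        as.character(utils::as.roman(match(hits$sequence[i], lev)))
    }
    hits$mirna_id <- paste0(hits$family, ifelse(hits$is_star, "*", ""),
                            " ", hits$variant_label)
  } else {
    hits$is_star <- logical()
    hits$family <- character()
    hits$variant_label <- character()
    hits$mirna_id <- character()
  }
  expr <- build_expression_table(hits, counts, libraries)
  structure(list(hits = hits, expression = expr, libraries = libraries,
                 config = config),
            class = "mirna_profile")
}

#' @export
print.mirna_profile <- function(x, ...) {
  cat("miRNA profile:", nrow(x$hits), "matched unique sequences,",
      length(unique(x$hits$family)), "families,",
      sum(x$hits$is_star), "star sequences\n")
  cat("libraries:", paste(x$libraries$id, collapse = ", "), "\n")
  invisible(x)
}

#' Build the electronic-northern expression table
#'
#' One row per distinct matched read; raw counts per library and RPM
#' normalised against each library's total filtered reads (count * 1e6 /
#' total), rounded to 2 decimals. Rows are sorted by family then variant
#' label.
#'
#' @param hits data.frame of miRNA hits (needs \code{sequence}; identity
#'   columns \code{family}, \code{variant_label}, \code{mirna_id},
#'   \code{is_star} are carried through when present).
#' @param counts data.frame with \code{sequence} plus one count column per
#'   library.
#' @param libraries data.frame with \code{id}, \code{total_filtered_reads}.
#' @return data.frame with identity columns, \code{<lib>} raw counts and
#'   \code{rpm_<lib>} columns.
#' @export
build_expression_table <- function(hits, counts, libraries) {
  if (any(libraries$total_filtered_reads <= 0L)) {
    stop("library with total_filtered_reads = 0: ",
         paste(libraries$id[libraries$total_filtered_reads <= 0L],
               collapse = ", "))
  }
  id_cols <- intersect(c("mirna_id", "family", "variant_label", "is_star",
                         "reference_id", "mismatches", "sequence"),
                       names(hits))
  tab <- hits[!duplicated(hits$sequence), id_cols, drop = FALSE]
  m <- match(tab$sequence, counts$sequence)
  for (lib in libraries$id) {
    raw <- counts[[lib]][m]
    raw[is.na(raw)] <- 0L
    tab[[lib]] <- as.integer(raw)
    tot <- libraries$total_filtered_reads[libraries$id == lib]
    tab[[paste0("rpm_", lib)]] <- round(raw * 1e6 / tot, 2L)
  }
  if (all(c("family", "variant_label") %in% names(tab)) && nrow(tab)) {
    o <- order(tab$family,
               suppressWarnings(as.integer(utils::as.roman(tab$variant_label))))
    tab <- tab[o, , drop = FALSE]
  }
  tab$length <- nchar(tab$sequence)
  rownames(tab) <- NULL
  tab
}

#' Length and 5'-nucleotide composition of matched miRNAs
#'
#' Computed over unique matched sequences. Percentages sum to 100 within
#' rounding.
#'
#' @param hits data.frame with a \code{sequence} column.
#' @param l_min,l_max histogram support (nt).
#' @return list with \code{length_hist} (data.frame length, count) and
#'   \code{five_prime} (data.frame base, count, percent).
#' @export
composition_summary <- function(hits, l_min = 18L, l_max = 28L) {
  stopifnot(nrow(hits) >= 1L)
  u <- unique(hits$sequence)
  len <- factor(nchar(u), levels = l_min:l_max)
  lh <- data.frame(length = l_min:l_max,
                   count = as.integer(table(len)))
  fp <- factor(substr(u, 1L, 1L), levels = c("A", "C", "G", "T"))
  ct <- as.integer(table(fp))
  five <- data.frame(base = c("A", "C", "G", "U"),
                     count = ct,
                     percent = round(100 * ct / length(u), 1L))
  list(length_hist = lh, five_prime = five)
}

#' Venn region cardinalities of sequence sets
#'
#' @param sets named list (>= 2 elements) of character vectors.
#' @return data.frame \code{region} (set names joined with \code{&} for
#'   intersections-exclusive regions) and \code{count}; exact exclusive
#'   region cardinalities of the Venn decomposition.
#' @export
set_overlap <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_el <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_el %in% s, logical(length(all_el)))
  if (length(all_el) == 1L) memb <- matrix(memb, nrow = 1L,
                                           dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  region <- apply(combos, 1L, function(r) paste(names(sets)[as.logical(r)],
                                                collapse = "&"))
  count <- apply(combos, 1L, function(r) {
    if (!length(all_el)) return(0L)
    sum(apply(memb, 1L, function(m) all(m == as.logical(r))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Merge per-library collapsed reads into one count table
#'
#' @param read_list named list of collapsed-read data.frames (columns
#'   \code{sequence}, \code{count}); names are library ids.
#' @return data.frame with \code{sequence} and one integer column per
#'   library (0 where a sequence is absent).
#' @export
merge_libraries <- function(read_list) {
  stopifnot(length(read_list) >= 1L, !is.null(names(read_list)))
  seqs <- sort(unique(unlist(lapply(read_list, `[[`, "sequence"))))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (lib in names(read_list)) {
    m <- match(seqs, read_list[[lib]]$sequence)
    v <- read_list[[lib]]$count[m]
    v[is.na(v)] <- 0L
    out[[lib]] <- as.integer(v)
  }
  out
}
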