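#' Select 22-nt trigger miRNAs
#'
#' Secondary (trans-acting-style) siRNA production is triggered by 22-nt
#' miRNAs; this returns the distinct matched miRNA sequences of exactly
#' 22 nt.
#'
#' @param hits miRNA hit data.frame (needs a \code{sequence} column).
#' @param trigger_length trigger length in nt.
#' @return character vector of distinct 22-nt miRNA sequences (named by
#'   \code{mirna_id} when present).
#' @export
select_triggers <- function(hits, trigger_length = 22L) {
  sel <- !duplicated(hits$sequence) & nchar(hits$sequence) == trigger_length
  out <- hits$sequence[sel]
  if ("mirna_id" %in% names(hits)) names(out) <- hits$mirna_id[sel]
  out
}

# a_min-mer set of a string (one fixed k).
kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  unique(substring(x, 1:(n - k + 1L), k:n))
}

#' Scan a target transcript against the non-miRNA read pool
#'
#' A read hits iff a contiguous ungapped exact match of at least
#' \code{a_min} nt exists between the read and the transcript (sense) or its
#' reverse complement (antisense). Coordinates are reported on the
#' transcript, 1-based inclusive; antisense hits are printed high-to-low
#' (end < start). One maximal (longest, then leftmost) hit is reported per
#' read and strand.
#'
#' @param transcript transcript sequence (sense strand).
#' @param pool data.frame of non-miRNA reads (needs \code{sequence}); every
#'   previously identified miRNA sequence must already be excluded.
#' @param a_min minimum exact ungapped alignment length (nt).
#' @return data.frame \code{sequence}, \code{start}, \code{end},
#'   \code{strand} (\code{sense}/\code{antisense}).
#' @export
scan_target <- function(transcript, pool, a_min = 18L) {
  transcript <- normalize_alphabet(transcript)
  empty <- data.frame(sequence = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pool)) return(empty)
  tx_kmers <- kmer_set(transcript, a_min)
  rows <- list()
  find_hit <- function(query) {
    # longest, then leftmost, exact substring of query inside transcript
    n <- nchar(query)
    for (L in seq(n, a_min)) {
      best <- Inf; best_s <- NA_integer_
      for (s in seq_len(n - L + 1L)) {
        p <- regexpr(substr(query, s, s + L - 1L), transcript,
                     fixed = TRUE)
        if (p > 0L && p < best) { best <- p; best_s <- s }
      }
      if (is.finite(best)) return(c(best, best + L - 1L))
    }
    NULL
  }
  for (seq in unique(pool$sequence)) {
    if (nchar(seq) < a_min) next
    # sense strand
    if (any(kmer_set(seq, a_min) %in% tx_kmers)) {
      h <- find_hit(seq)
      if (!is.null(h)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seq, start = h[1L], end = h[2L], strand = "sense",
          stringsAsFactors = FALSE)
      }
    }
    # antisense: the reverse complement of the read matches the sense strand
    rc <- revcomp(seq)
    if (any(kmer_set(rc, a_min) %in% tx_kmers)) {
      h <- find_hit(rc)
      if (!is.null(h)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = seq, start = h[2L], end = h[1L], strand = "antisense",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge end-variant hits into siRNA candidates
#'
#' Hits on the same transcript and strand whose start and end coordinates
#' each differ by at most \code{end_slop} nt are grouped transitively; the
#' representative is the member with the maximal summed count across
#' libraries, ties broken by lexicographically smallest sequence.
#'
#' @param hits data.frame from \code{\link{scan_target}} (one transcript).
#' @param counts data.frame \code{sequence} plus per-library count columns.
#' @param lib_ids library id column names in \code{counts}.
#' @param end_slop maximum per-end coordinate difference within a group.
#' @return data.frame: one row per candidate with \code{sequence}
#'   (representative), \code{start}, \code{end}, \code{strand},
#'   \code{n_variants}, \code{variants} (comma-joined member sequences) and
#'   the representative's per-library counts.
#' @export
merge_variants <- function(hits, counts, lib_ids, end_slop = 2L) {
  if (!nrow(hits)) {
    out <- data.frame(sequence = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_variants = integer(), variants = character(),
                      stringsAsFactors = FALSE)
    for (lib in lib_ids) out[[lib]] <- integer()
    return(out)
  }
  lo <- pmin(hits$start, hits$end)
  hi <- pmax(hits$start, hits$end)
  n <- nrow(hits)
  # transitive grouping by union-find over pairs within slop on both ends
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (g in split(seq_len(n), hits$strand)) {
    for (a in seq_along(g)) {
      for (b in seq_len(a - 1L)) {
        i <- g[a]; j <- g[b]
        if (abs(lo[i] - lo[j]) <= end_slop && abs(hi[i] - hi[j]) <= end_slop) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  m <- match(hits$sequence, counts$sequence)
  summed <- rowSums(as.matrix(counts[m, lib_ids, drop = FALSE]))
  summed[is.na(summed)] <- 0
  rows <- lapply(unique(grp), function(g) {
    i <- which(grp == g)
    o <- i[order(-summed[i], hits$sequence[i])]
    rep_i <- o[1L]
    cnt <- counts[m[rep_i], lib_ids, drop = FALSE]
    cnt[is.na(cnt)] <- 0L
    cbind(data.frame(sequence = hits$sequence[rep_i],
                     start = hits$start[rep_i], end = hits$end[rep_i],
                     strand = hits$strand[rep_i],
                     n_variants = length(i),
                     variants = paste(sort(unique(hits$sequence[i])),
                                      collapse = ","),
                     stringsAsFactors = FALSE),
          cnt)
  })
  out <- do.call(rbind, rows)
  out <- out[order(pmin(out$start, out$end), out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-library abundance filter for siRNA candidates
#'
#' A candidate is present in a library iff its raw count there is strictly
#' greater than \code{c_min}; the core set is present in every library. The
#' per-library presence sets give the shared/exclusive partition.
#'
#' @param candidates data.frame with per-library count columns.
#' @param lib_ids library id column names.
#' @param c_min per-library count threshold (presence requires count >
#'   \code{c_min}).
#' @return \code{candidates} with added logical \code{present_<lib>} columns
#'   and \code{core}; the Venn decomposition of the presence sets in
#'   \code{attr(, "venn")}.
#' @export
filter_abundance <- function(candidates, lib_ids, c_min = 50L) {
  sets <- list()
  for (lib in lib_ids) {
    present <- candidates[[lib]] > c_min
    candidates[[paste0("present_", lib)]] <- present
    sets[[lib]] <- candidates$sequence[present]
  }
  pres <- as.matrix(candidates[, paste0("present_", lib_ids), drop = FALSE])
  candidates$core <- if (nrow(candidates)) rowSums(pres) == length(lib_ids)
                     else logical()
  attr(candidates, "venn") <- if (length(lib_ids) >= 2L) set_overlap(sets)
                              else NULL
  candidates
}

#' Cleavage-site concordance of a candidate with a predicted target site
#'
#' TRUE iff one end of the candidate's alignment lies within +/- 1 nt of the
#' site's cleavage position — the geometry expected when secondary siRNAs
#' are shed from the miRNA-guided cleavage point.
#'
#' @param start,end candidate alignment coordinates (antisense has
#'   end < start).
#' @param cleavage_position transcript coordinate of the cleavage site.
#' @param slop tolerance in nt.
#' @return logical vector.
#' @export
cleavage_concordance <- function(start, end, cleavage_position, slop = 1L) {
  abs(start - cleavage_position) <= slop | abs(end - cleavage_position) <= slop
}

#' Discover 22-nt-miRNA-triggered secondary siRNA candidates
#'
#' End-to-end scan: select the 22-nt triggers among the matched miRNAs,
#' take their predicted target sites, scan each target transcript against
#' the non-miRNA read pool, merge end variants, apply the per-library
#' abundance filter, and flag cleavage-site concordance and the 21-nt phase
#' register (reported, never filtered on). Candidate groups from distinct
#' transcripts with an identical representative sequence are reported
#' jointly (transcript ids joined with \code{/}).
#'
#' @param profile a \code{\link{profile_mirnas}} object.
#' @param sites target sites from \code{\link{predict_targets}} (any miRNAs;
#'   non-trigger rows are ignored).
#' @param transcripts named character vector of transcript sequences.
#' @param counts data.frame \code{sequence} plus per-library counts for the
#'   whole filtered pool (miRNA sequences are excluded here).
#' @param config an \code{srna_config} list.
#' @return data.frame of candidates: representative \code{sequence},
#'   \code{transcripts}, \code{coordinates} (start-end per transcript,
#'   \code{;}-joined), \code{trigger}, per-library counts and
#'   \code{rpm_<lib>}, \code{present_<lib>}, \code{core},
#'   \code{concordant}, \code{phase_offset}; presence-set Venn counts in
#'   \code{attr(, "venn")}.
#' @export
find_sirna_candidates <- function(profile, sites, transcripts, counts,
                                  config = pipeline_config()) {
  lib_ids <- profile$libraries$id
  triggers <- select_triggers(profile$hits)
  sites <- sites[sites$mirna %in% triggers, , drop = FALSE]
  pool <- counts[!(counts$sequence %in% profile$hits$sequence), ,
                 drop = FALSE]
  per_tx <- list()
  for (tx in unique(sites$transcript)) {
    hits <- scan_target(transcripts[[tx]], pool, config$a_min_scan)
    cand <- merge_variants(hits, pool, lib_ids)
    if (!nrow(cand)) next
    tx_sites <- sites[sites$transcript == tx, , drop = FALSE]
    conc <- rep(FALSE, nrow(cand))
    phase <- rep(NA_integer_, nrow(cand))
    for (k in seq_len(nrow(tx_sites))) {
      cp <- tx_sites$cleavage_position[k]
      conc <- conc | cleavage_concordance(cand$start, cand$end, cp)
      ph <- (pmin(cand$start, cand$end) - (cp + 1L)) %% 21L
      phase <- ifelse(is.na(phase), ph, pmin(phase, ph))
    }
    cand$transcript <- tx
    cand$trigger <- paste(sort(unique(
      if (!is.null(names(triggers)))
        names(triggers)[match(tx_sites$mirna, triggers)]
      else tx_sites$mirna_id)), collapse = "/")
    cand$concordant <- conc
    cand$phase_offset <- as.integer(phase)
    per_tx[[tx]] <- cand
  }
  if (!length(per_tx)) {
    out <- data.frame(sequence = character(), transcripts = character(),
                      coordinates = character(), trigger = character(),
                      concordant = logical(), phase_offset = integer(),
                      stringsAsFactors = FALSE)
    for (lib in lib_ids) out[[lib]] <- integer()
    return(filter_abundance(out, lib_ids, config$c_min_sirna))
  }
  all <- do.call(rbind, per_tx)
  # joint reporting of identical representative sequences across transcripts
  rows <- lapply(split(seq_len(nrow(all)), all$sequence), function(i) {
    first <- i[1L]
    cbind(data.frame(
      sequence = all$sequence[first],
      transcripts = paste(sort(unique(all$transcript[i])), collapse = "/"),
      coordinates = paste(sprintf("%d-%d", all$start[i], all$end[i]),
                          collapse = ";"),
      trigger = paste(sort(unique(unlist(
        strsplit(all$trigger[i], "/", fixed = TRUE)))), collapse = "/"),
      concordant = any(all$concordant[i]),
      phase_offset = suppressWarnings(min(all$phase_offset[i])),
      n_variants = max(all$n_variants[i]),
      stringsAsFactors = FALSE),
      all[first, lib_ids, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (lib in lib_ids) {
    tot <- profile$libraries$total_filtered_reads[
      profile$libraries$id == lib]
    out[[paste0("rpm_", lib)]] <- round(out[[lib]] * 1e6 / tot, 2L)
  }
  out <- filter_abundance(out, lib_ids, config$c_min_sirna)
  out[order(-rowSums(as.matrix(out[, lib_ids, drop = FALSE]))), ,
      drop = FALSE]
}
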