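# Nearest-neighbor stacking free energies (kcal/mol, 37 C) for RNA/RNA
# helices, stored in the DNA alphabet (U -> T). Keys are the miRNA-strand
# dinucleotide 5'->3' when both positions are Watson-Crick paired; the 10
# unique published parameters expand to all 16 keys by duplex symmetry.
.wc_stack <- c(
  AA = -0.93, TT = -0.93,
  AT = -1.10,
  TA = -1.33,
  CT = -2.08, AG = -2.08,
  CA = -2.11, TG = -2.11,
  GT = -2.24, AC = -2.24,
  GA = -2.35, TC = -2.35,
  CG = -2.36,
  GG = -3.26, CC = -3.26,
  GC = -3.42
)
# Simplified wobble treatment: a stack with exactly one G:U pair is assigned
# -1.3 kcal/mol, a tandem G:U stack -0.5. Each unpaired (MM) position adds a
# flat +1.0 penalty and voids its adjacent stacks. The acceptance rule only
# consumes the ratio of two energies computed by this same function.
.gu_stack_single <- -1.3
.gu_stack_double <- -0.5
.mm_penalty <- 1.0

# Pair state of miRNA base m against target base t (antiparallel pairing):
# WC for A:T/T:A/G:C/C:G, GU for G:T or T:G wobble, MM otherwise.
pair_state_of <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

# Weighted mismatch score of a pair-state vector: WC 0, GU 0.5, MM 1.
pair_weights <- function(states) {
  c(WC = 0, GU = 0.5, MM = 1)[states]
}

#' Align a miRNA against a transcript window as an ungapped duplex
#'
#' Position i of the miRNA (5' to 3') pairs with transcript position
#' \code{offset + length - i} (antiparallel, no gaps). Pair states are WC
#' for Watson-Crick pairs, GU for G:U wobbles (scored 0.5 mismatches), MM
#' otherwise (scored 1).
#'
#' @param mirna miRNA sequence (DNA alphabet, 5' to 3').
#' @param transcript transcript sequence (sense strand).
#' @param offset 1-based start of the binding window on the transcript.
#' @return object of class \code{duplex}: list with \code{mirna},
#'   \code{target_window}, \code{pair_states} (indexed from the miRNA 5'
#'   end), \code{mismatch_score_total}, \code{start}, \code{end}.
#' @export
align_duplex <- function(mirna, transcript, offset) {
  mirna <- normalize_alphabet(mirna)
  transcript <- normalize_alphabet(transcript)
  L <- nchar(mirna)
  if (offset < 1L || offset + L - 1L > nchar(transcript)) {
    stop("window [", offset, ", ", offset + L - 1L,
         "] out of transcript range")
  }
  window <- substr(transcript, offset, offset + L - 1L)
  m <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  t_of_i <- w[L:1L]  # miRNA position i pairs window position L - i + 1
  states <- pair_state_of(m, t_of_i)
  structure(list(mirna = mirna,
                 target_window = window,
                 pair_states = states,
                 mismatch_score_total = sum(pair_weights(states)),
                 start = as.integer(offset),
                 end = as.integer(offset + L - 1L)),
            class = "duplex")
}

#' @export
print.duplex <- function(x, ...) {
  cat("miRNA/target duplex, window ", x$start, "-", x$end,
      ", weighted mismatches ", x$mismatch_score_total, "\n", sep = "")
  cat(" 5'-", x$mirna, "-3' (miRNA)\n", sep = "")
  cat("    ", paste(c(WC = "|", GU = "o", MM = " ")[x$pair_states],
                    collapse = ""), "\n", sep = "")
  cat(" 3'-", paste(rev(strsplit(x$target_window, "")[[1L]]),
                    collapse = ""), "-5' (target)\n", sep = "")
  invisible(x)
}

#' Duplex free energy from the embedded nearest-neighbor table
#'
#' Sums tabulated stacking energies over adjacent paired positions: stacks
#' of two Watson-Crick pairs use the published RNA/RNA parameters, stacks
#' containing G:U wobbles use a simplified wobble value, a stack adjacent to
#' an unpaired (MM) position contributes 0, and each MM position adds a
#' fixed +1.0 kcal/mol destabilising penalty. The identical function scores
#' the perfect complement for the MFE ratio.
#'
#' @param duplex a \code{\link{align_duplex}} object.
#' @return free energy in kcal/mol (<= 0 for any stable duplex).
#' @export
duplex_mfe <- function(duplex) {
  states <- duplex$pair_states
  m <- strsplit(duplex$mirna, "", fixed = TRUE)[[1L]]
  L <- length(states)
  e <- .mm_penalty * sum(states == "MM")
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      s1 <- states[i]; s2 <- states[i + 1L]
      if (s1 == "MM" || s2 == "MM") next
      e <- e + if (s1 == "GU" && s2 == "GU") {
        .gu_stack_double
      } else if (s1 == "GU" || s2 == "GU") {
        .gu_stack_single
      } else {
        .wc_stack[[paste0(m[i], m[i + 1L])]]
      }
    }
  }
  e
}

#' MFE ratio of a duplex to the perfect complement
#'
#' \code{duplex_mfe(duplex) / duplex_mfe(perfect complement of the miRNA)},
#' clamped to [0, 1]: a duplex at or above 0 kcal/mol has ratio 0; the
#' perfect complement has ratio exactly 1.
#'
#' @param duplex a \code{\link{align_duplex}} object.
#' @return numeric in [0, 1].
#' @export
mfe_ratio <- function(duplex) {
  perfect <- duplex
  perfect$pair_states <- rep("WC", length(duplex$pair_states))
  e_perfect <- duplex_mfe(perfect)
  if (e_perfect >= 0) stop("degenerate miRNA: perfect complement MFE >= 0")
  e <- duplex_mfe(duplex)
  max(0, min(1, e / e_perfect))
}

#' Evaluate the plant target-prediction rules on a duplex
#'
#' Six rules, positions counted from the miRNA 5' end, G:U wobbles weighing
#' 0.5 mismatches in the numeric caps and occupying mismatch positions in
#' the adjacency rules:
#' \itemize{
#'   \item R1: total weighted mismatch score <= 4.0;
#'   \item R2: no run of more than 2 consecutive non-WC positions;
#'   \item R3: no two adjacent non-WC positions within positions 2--12;
#'   \item R4: positions 10 and 11 both WC;
#'   \item R5: weighted mismatch score over positions 1--12 <= 2.5;
#'   \item R6: MFE ratio >= the configured minimum (0.74).
#' }
#'
#' @param duplex a \code{\link{align_duplex}} object.
#' @param config an \code{srna_config} list (rule caps and MFE threshold).
#' @return named logical vector (R1..R6) with the overall verdict in
#'   \code{attr(, "accepted")} and the MFE ratio in \code{attr(, "mfe_ratio")}.
#' @export
check_rules <- function(duplex, config = pipeline_config()) {
  states <- duplex$pair_states
  w <- pair_weights(states)
  L <- length(states)
  non_wc <- states != "WC"
  r1 <- sum(w) <= config$rule_total_max
  runs <- rle(non_wc)
  r2 <- !any(runs$values & runs$lengths > config$rule_adjacent_max)
  idx_2_12 <- seq(2L, min(12L, L))
  r3 <- TRUE
  if (length(idx_2_12) >= 2L) {
    in_win <- non_wc[idx_2_12]
    r3 <- !any(in_win[-length(in_win)] & in_win[-1L])
  }
  r4 <- if (L >= 11L) !non_wc[10L] && !non_wc[11L] else FALSE
  r5 <- sum(w[seq_len(min(12L, L))]) <= config$rule_window_1_12_max
  ratio <- mfe_ratio(duplex)
  r6 <- ratio >= config$mfe_ratio_min
  out <- c(R1 = r1, R2 = r2, R3 = r3, R4 = r4, R5 = r5, R6 = r6)
  attr(out, "accepted") <- all(out)
  attr(out, "mfe_ratio") <- ratio
  out
}

# Vectorised weighted-mismatch prefilter: weighted score of the duplex at
# every window offset of one transcript, NA-free, without building duplex
# objects. Used by predict_targets; full rule evaluation runs only on
# offsets passing the R1 cap.
window_scores <- function(mirna, transcript) {
  L <- nchar(mirna)
  tc <- strsplit(transcript, "", fixed = TRUE)[[1L]]
  N <- length(tc)
  if (N < L) return(numeric())
  offsets <- seq_len(N - L + 1L)
  m <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  total <- numeric(length(offsets))
  for (i in seq_len(L)) {
    t_i <- tc[offsets + L - i]
    total <- total + pair_weights(pair_state_of(m[i], t_i))
  }
  total
}

#' Predict miRNA target sites on a transcript set
#'
#' Scores every window of every transcript as an ungapped antiparallel
#' duplex and returns the sites passing all six rules, sorted by transcript
#' id then start. The cleavage position is the transcript coordinate paired
#' to miRNA position 10 (the 5' side of the 10--11 bond) — standard slicer
#' geometry. All coordinates are 1-based inclusive on the transcript sense
#' strand.
#'
#' @param mirnas named character vector of miRNA sequences (ids as names).
#' @param transcripts named character vector of transcript sequences.
#' @param config an \code{srna_config} list.
#' @return data.frame \code{mirna_id}, \code{mirna}, \code{transcript},
#'   \code{start}, \code{end}, \code{mismatch_score}, \code{mfe_ratio},
#'   \code{cleavage_position}.
#' @export
predict_targets <- function(mirnas, transcripts, config = pipeline_config()) {
  stopifnot(length(transcripts) > 0L, !is.null(names(transcripts)))
  if (is.null(names(mirnas))) names(mirnas) <- paste0("mirna", seq_along(mirnas))
  mirnas <- normalize_alphabet(mirnas)
  transcripts <- normalize_alphabet(transcripts)
  rows <- list()
  for (mi in seq_along(mirnas)) {
    mirna <- mirnas[[mi]]
    L <- nchar(mirna)
    for (tx in sort(names(transcripts))) {
      scores <- window_scores(mirna, transcripts[[tx]])
      cand <- which(scores <= config$rule_total_max)
      for (offset in cand) {
        dup <- align_duplex(mirna, transcripts[[tx]], offset)
        rules <- check_rules(dup, config)
        if (!attr(rules, "accepted")) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = names(mirnas)[mi],
          mirna = mirna,
          transcript = tx,
          start = dup$start,
          end = dup$end,
          mismatch_score = dup$mismatch_score_total,
          mfe_ratio = attr(rules, "mfe_ratio"),
          cleavage_position = dup$start + L - 10L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), mirna = character(),
                      transcript = character(), start = integer(),
                      end = integer(), mismatch_score = numeric(),
                      mfe_ratio = numeric(), cleavage_position = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
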