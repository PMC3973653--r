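# Independent oracles used by the tests. These deliberately use different
# code paths from the package implementation (explicit loops, enumeration,
# dhyper) so they can act as cross-checks.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all 2x2
# tables with the observed margins.
oracle_fisher <- function(a, b, ta, tb) {
  k <- a + b                       # first-column margin
  x <- max(0L, k - tb):min(k, ta)  # feasible first-cell values
  p <- stats::dhyper(x, ta, tb, k)
  p_obs <- stats::dhyper(a, ta, tb, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Hamming distance between two equal-length strings, via explicit chars.
oracle_hamming <- function(x, y) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  stopifnot(length(cx) == length(cy))
  sum(cx != cy)
}

# Brute-force best miRNA hit: scan every equal-length window of every
# reference, track minimal distance, tie -> smallest reference id.
oracle_best_hit <- function(read, reference, m_max = 3L) {
  best_d <- Inf; best_id <- NULL
  L <- nchar(read)
  for (id in sort(names(reference))) {
    ref <- reference[[id]]
    n <- nchar(ref)
    if (n < L) next
    for (s in 1:(n - L + 1)) {
      d <- oracle_hamming(read, substr(ref, s, s + L - 1))
      if (d < best_d) { best_d <- d; best_id <- id }
    }
  }
  if (best_d > m_max) NULL else list(id = best_id, d = best_d)
}

# Independent rule evaluator over a pair-state vector (character, values
# "WC"/"GU"/"MM"), written with plain loops.
oracle_rules <- function(states, total_max = 4, adj_max = 2,
                         win_max = 2.5) {
  w <- ifelse(states == "WC", 0, ifelse(states == "GU", 0.5, 1))
  L <- length(states)
  r1 <- sum(w) <= total_max
  run <- 0L; worst <- 0L
  for (i in seq_len(L)) {
    run <- if (states[i] != "WC") run + 1L else 0L
    worst <- max(worst, run)
  }
  r2 <- worst <= adj_max
  r3 <- TRUE
  for (i in 2:min(11L, L - 1L)) {
    if (states[i] != "WC" && states[i + 1L] != "WC" && (i + 1L) <= 12L) {
      r3 <- FALSE
    }
  }
  r4 <- L >= 11 && states[10] == "WC" && states[11] == "WC"
  r5 <- sum(w[1:min(12L, L)]) <= win_max
  c(R1 = r1, R2 = r2, R3 = r3, R4 = r4, R5 = r5)
}

# Independent duplex energy: re-derive the stack table from the published
# 10 Watson-Crick parameters and re-walk the duplex.
oracle_energy <- function(mirna, states) {
  wc10 <- c(AA = -0.93, AT = -1.10, TA = -1.33, CT = -2.08, CA = -2.11,
            GT = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lookup <- function(d) {
    if (d %in% names(wc10)) return(wc10[[d]])
    # symmetry: E(5'XY3') == E(5'Y'X'3') with WC partners
    flip <- paste0(comp[[substr(d, 2, 2)]], comp[[substr(d, 1, 1)]])
    wc10[[flip]]
  }
  m <- strsplit(mirna, "")[[1]]
  e <- sum(states == "MM") * 1.0
  for (i in seq_len(length(m) - 1L)) {
    s1 <- states[i]; s2 <- states[i + 1L]
    if (s1 == "MM" || s2 == "MM") next
    e <- e + if (s1 == "GU" && s2 == "GU") -0.5
    else if (s1 == "GU" || s2 == "GU") -1.3
    else lookup(paste0(m[i], m[i + 1L]))
  }
  e
}

# Brute-force longest exact ungapped match between a read and a transcript
# (one strand): all substring pairs.
oracle_scan <- function(read, transcript, a_min = 18L) {
  n <- nchar(read)
  best <- NULL
  for (L in seq(n, a_min)) {
    for (s in 1:(n - L + 1)) {
      p <- regexpr(substr(read, s, s + L - 1), transcript, fixed = TRUE)
      if (p > 0 && (is.null(best) || L > best$len ||
                    (L == best$len && p < best$pos))) {
        if (is.null(best) || L > best$len) best <- list(pos = as.integer(p),
                                                        len = L)
        else best$pos <- min(best$pos, as.integer(p))
      }
    }
    if (!is.null(best)) return(c(best$pos, best$pos + best$len - 1L))
  }
  NULL
}

# Brute-force interval merging with a gap threshold (transitive), O(n^2).
oracle_merge_intervals <- function(start, end, gap) {
  n <- length(start)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (grp[i] != grp[j] &&
            max(start[i], start[j]) - min(end[i], end[j]) - 1L <= gap) {
          g <- min(grp[i], grp[j])
          grp[grp == grp[i] | grp == grp[j]] <- g
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(grp))
}

# Random pair-state vector generator for rule sweeps.
random_states <- function(L, p = c(WC = .6, GU = .2, MM = .2)) {
  sample(c("WC", "GU", "MM"), L, replace = TRUE, prob = p)
}

# Build a duplex object directly from a pair-state vector: synthesise a
# target window realising the states for the given miRNA.
duplex_from_states <- function(mirna, states) {
  # only positions where GU is possible (G or T) may carry GU
  m <- strsplit(mirna, "")[[1]]
  states[states == "GU" & !(m %in% c("G", "T"))] <- "MM"
  win <- canesrna:::window_for_states(mirna, states)
  dup <- align_duplex(mirna, paste0("AAAA", win, "AAAA"), 5L)
  list(dup = dup, states = states)
}

# A deterministic random miRNA-like sequence.
random_mirna <- function(L = 21L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
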