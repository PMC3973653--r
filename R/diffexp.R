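#' Fisher exact test on two library counts
#'
#' Two-sided exact test for the 2x2 table
#' \code{[[count_a, total_a - count_a], [count_b, total_b - count_b]]},
#' summing the probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's. This is the classical
#' per-sequence test for unreplicated count libraries. Vectorised over the
#' count arguments.
#'
#' @param count_a,count_b reads of the sequence in libraries A and B.
#' @param total_a,total_b total filtered reads of libraries A and B.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_count_test <- function(count_a, count_b, total_a, total_b) {
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(as.numeric(count_a), n)
  count_b <- rep_len(as.numeric(count_b), n)
  total_a <- rep_len(as.numeric(total_a), n)
  total_b <- rep_len(as.numeric(total_b), n)
  if (any(total_a <= 0) || any(total_b <= 0)) stop("library totals must be > 0")
  if (any(count_a < 0) || any(count_b < 0) ||
      any(count_a > total_a) || any(count_b > total_b)) {
    stop("counts must lie in [0, total] for their library")
  }
  vapply(seq_len(n), function(i) {
    stats::fisher.test(matrix(c(count_a[i], total_a[i] - count_a[i],
                                count_b[i], total_b[i] - count_b[i]),
                              nrow = 2L))$p.value
  }, numeric(1))
}

#' Direction and significance of a regulation call
#'
#' Direction compares RPM values: up if \code{rpm_b > rpm_a}, down if
#' \code{rpm_b < rpm_a}, unchanged if equal. "Regulated" requires a
#' significant adjusted p-value as well.
#'
#' @param rpm_a,rpm_b RPM in the reference and contrast library.
#' @param p_adj Bonferroni-adjusted p-value.
#' @param alpha significance level.
#' @return data.frame \code{direction} (\code{up}/\code{down}/
#'   \code{unchanged}), \code{significant}, \code{regulated}.
#' @export
call_regulation <- function(rpm_a, rpm_b, p_adj, alpha = 0.05) {
  stopifnot(all(rpm_a >= 0), all(rpm_b >= 0))
  direction <- ifelse(rpm_b > rpm_a, "up",
                      ifelse(rpm_b < rpm_a, "down", "unchanged"))
  significant <- p_adj < alpha
  data.frame(direction = direction, significant = significant,
             regulated = significant & direction != "unchanged",
             stringsAsFactors = FALSE)
}

#' Per-sequence differential expression between two libraries
#'
#' Fisher exact test per sequence with Bonferroni correction over the m
#' sequences tested in this library pair (per-contrast correction):
#' \code{p_adj = min(1, p_raw * m)}.
#'
#' @param expr expression table (from
#'   \code{\link{build_expression_table}}) with raw count and
#'   \code{rpm_<lib>} columns.
#' @param lib_a,lib_b library ids (column names in \code{expr}).
#' @param libraries data.frame with \code{id}, \code{total_filtered_reads}.
#' @param alpha significance level.
#' @return data.frame of regulation calls: identity columns, raw counts,
#'   \code{p_raw}, \code{p_adj}, \code{direction}, \code{significant}.
#' @export
test_differential_expression <- function(expr, lib_a, lib_b, libraries,
                                         alpha = 0.05) {
  stopifnot(all(c(lib_a, lib_b) %in% names(expr)),
            all(c(lib_a, lib_b) %in% libraries$id))
  tot_a <- libraries$total_filtered_reads[libraries$id == lib_a]
  tot_b <- libraries$total_filtered_reads[libraries$id == lib_b]
  m <- nrow(expr)
  p_raw <- if (m) fisher_count_test(expr[[lib_a]], expr[[lib_b]],
                                    tot_a, tot_b) else numeric()
  p_adj <- pmin(1, p_raw * m)
  calls <- call_regulation(expr[[paste0("rpm_", lib_a)]],
                           expr[[paste0("rpm_", lib_b)]], p_adj, alpha)
  id_cols <- intersect(c("mirna_id", "sequence"), names(expr))
  out <- cbind(expr[, id_cols, drop = FALSE],
               data.frame(library_a = lib_a, library_b = lib_b,
                          count_a = expr[[lib_a]], count_b = expr[[lib_b]],
                          p_raw = p_raw, p_adj = p_adj,
                          stringsAsFactors = FALSE),
               calls)
  rownames(out) <- NULL
  out
}

# Ratio direction from raw counts with a pseudocount substituted for zeros
# before RPM ratio formation (avoids division by zero; disclosed in output).
direction_of_ratio <- function(count_num, total_num, count_den, total_den,
                               pseudocount = 1L) {
  cn <- ifelse(count_num == 0, pseudocount, count_num)
  cd <- ifelse(count_den == 0, pseudocount, count_den)
  r <- (cn / total_num) / (cd / total_den)
  ifelse(r > 1, "up", ifelse(r < 1, "down", "unchanged"))
}

#' Agreement flag between two ratio directions
#'
#' @param dir_a,dir_b direction vectors (\code{up}/\code{down}/
#'   \code{unchanged}).
#' @return character vector of \code{"+"} (same direction) or \code{"-"}.
#' @export
comparison_flags <- function(dir_a, dir_b) {
  ifelse(dir_a == dir_b, "+", "-")
}

#' Classify pool-versus-individual concordance
#'
#' Given the per-miRNA comparison flags — comparison 1 contrasting the
#' genotype ratio in pools versus individual cultivars, comparison 2
#' contrasting the water-depletion response per genotype — assigns each
#' miRNA to one of four classes: concordant in \code{both}, in
#' \code{comp1_only}, in \code{comp2_only}, or \code{neither}.
#'
#' @param comp1,comp2 character vectors of \code{"+"}/\code{"-"} flags.
#' @param ids optional miRNA identifiers.
#' @return object of class \code{concordance}: data.frame \code{id},
#'   \code{comp1}, \code{comp2}, \code{class}, with the aggregate class
#'   counts in \code{attr(, "counts")} (both, comp1_only, comp2_only,
#'   neither, positive_any).
#' @export
classify_concordance <- function(comp1, comp2, ids = NULL) {
  stopifnot(length(comp1) == length(comp2),
            all(comp1 %in% c("+", "-")), all(comp2 %in% c("+", "-")))
  if (is.null(ids)) ids <- as.character(seq_along(comp1))
  cls <- ifelse(comp1 == "+" & comp2 == "+", "both",
                ifelse(comp1 == "+", "comp1_only",
                       ifelse(comp2 == "+", "comp2_only", "neither")))
  out <- data.frame(id = ids, comp1 = comp1, comp2 = comp2, class = cls,
                    stringsAsFactors = FALSE)
  counts <- c(both = sum(cls == "both"),
              comp1_only = sum(cls == "comp1_only"),
              comp2_only = sum(cls == "comp2_only"),
              neither = sum(cls == "neither"),
              positive_any = sum(cls != "neither"))
  attr(out, "counts") <- counts
  class(out) <- c("concordance", "data.frame")
  out
}

#' @export
print.concordance <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("concordance classes over", nrow(x), "miRNAs:\n")
  cat(sprintf("  both: %d  comp1_only: %d  comp2_only: %d  neither: %d\n",
              ct["both"], ct["comp1_only"], ct["comp2_only"], ct["neither"]))
  cat("  positive in >=1 comparison:", ct["positive_any"], "\n")
  invisible(x)
}

#' Pool-versus-individual concordance from an expression table
#'
#' Computes the two comparison flags directly from raw counts. Comparison 1
#' contrasts the genotype ratio under stress in pooled libraries
#' (T24h / S24h) with the same ratio in individual cultivars
#' (tolerant individual / sensitive individual). Comparison 2 contrasts, per
#' genotype, the individual cultivar against its pooled control with the
#' stressed pool against the same control ((ind_tol / T0h) vs (T24h / T0h);
#' (ind_sen / S0h) vs (S24h / S0h)); its flag is "+" when at least one
#' genotype agrees. Zero counts take a pseudocount before ratio formation.
#'
#' @param expr expression table with raw count columns for the six
#'   libraries.
#' @param libraries data.frame \code{id}, \code{total_filtered_reads}
#'   covering the six ids below.
#' @param pool_t0,pool_t24,pool_s0,pool_s24 pooled library ids (tolerant /
#'   sensitive, control / stressed).
#' @param ind_tol,ind_sen individual-cultivar library ids.
#' @param pseudocount raw-read pseudocount for zero counts.
#' @return a \code{\link{classify_concordance}} object with per-genotype
#'   comparison-2 flags in columns \code{comp2_tolerant},
#'   \code{comp2_sensitive}.
#' @export
concordance_from_expression <- function(expr, libraries,
                                        pool_t0 = "T0h", pool_t24 = "T24h",
                                        pool_s0 = "S0h", pool_s24 = "S24h",
                                        ind_tol = "IND_T", ind_sen = "IND_S",
                                        pseudocount = 1L) {
  libs <- c(pool_t0, pool_t24, pool_s0, pool_s24, ind_tol, ind_sen)
  missing <- setdiff(libs, intersect(names(expr), libraries$id))
  if (length(missing)) {
    stop("missing library column(s): ", paste(missing, collapse = ", "))
  }
  tot <- stats::setNames(libraries$total_filtered_reads, libraries$id)[libs]
  d <- function(num, den) {
    direction_of_ratio(expr[[num]], tot[[num]], expr[[den]], tot[[den]],
                       pseudocount)
  }
  comp1 <- comparison_flags(d(pool_t24, pool_s24), d(ind_tol, ind_sen))
  f_tol <- comparison_flags(d(ind_tol, pool_t0), d(pool_t24, pool_t0))
  f_sen <- comparison_flags(d(ind_sen, pool_s0), d(pool_s24, pool_s0))
  comp2 <- ifelse(f_tol == "+" | f_sen == "+", "+", "-")
  ids <- if ("mirna_id" %in% names(expr)) expr$mirna_id else expr$sequence
  out <- classify_concordance(comp1, comp2, ids)
  out$comp2_tolerant <- f_tol
  out$comp2_sensitive <- f_sen
  out
}
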