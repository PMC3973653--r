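#' Pipeline configuration
#'
#' Builds the configuration list shared by every stage of the small-RNA
#' pipeline. Defaults are the reference thresholds for conserved-miRNA
#' profiling in plants: an 18--28 nt read window, at least 3 distinct bases
#' per read, up to 3 mismatches against the mature-miRNA reference, a
#' minimum ungapped alignment of 18 nt for the secondary-siRNA scan, a
#' strict more-than-50-reads-per-library abundance filter for siRNA
#' candidates, a 0.05 significance level with Bonferroni control, and the
#' duplex rule caps (total weighted mismatches <= 4, no run of more than 2
#' adjacent mismatch positions, <= 2.5 weighted mismatches over miRNA
#' positions 1--12, duplex MFE >= 74% of the perfect-complement MFE).
#'
#' @param l_min,l_max read length window in nt (inclusive).
#' @param complexity_min_bases minimum number of distinct bases per read.
#' @param m_max_mirna maximum Hamming mismatches to a reference mature miRNA.
#' @param a_min_scan minimum ungapped exact alignment (nt) in the siRNA scan.
#' @param c_min_sirna per-library read-count threshold for siRNA candidates;
#'   presence requires strictly more than this many raw reads.
#' @param alpha significance level for the Fisher exact tests.
#' @param mfe_ratio_min minimum duplex-to-perfect-complement MFE ratio.
#' @param rule_total_max cap on the total weighted mismatch score (GU = 0.5).
#' @param rule_adjacent_max longest allowed run of consecutive non-Watson-
#'   Crick positions in the duplex.
#' @param rule_window_1_12_max cap on the weighted mismatch score over miRNA
#'   positions 1--12.
#' @param merge_gap maximum gap (nt) between read placements merged into one
#'   siRNA cluster.
#' @param adapter3 3' adapter sequence used for trimming.
#' @param min_adapter_overlap minimum adapter prefix overlap (nt) recognised
#'   at the 3' end of a read.
#' @param pseudocount raw-read pseudocount substituted for zero counts when
#'   forming expression ratios.
#' @param rng_seed integer seed propagated to every stochastic component.
#'
#' @return A named list of class \code{srna_config}.
#' @export
pipeline_config <- function(l_min = 18L,
                            l_max = 28L,
                            complexity_min_bases = 3L,
                            m_max_mirna = 3L,
                            a_min_scan = 18L,
                            c_min_sirna = 50L,
                            alpha = 0.05,
                            mfe_ratio_min = 0.74,
                            rule_total_max = 4.0,
                            rule_adjacent_max = 2L,
                            rule_window_1_12_max = 2.5,
                            merge_gap = 100L,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            min_adapter_overlap = 6L,
                            pseudocount = 1L,
                            rng_seed = 1L) {
  cfg <- list(
    l_min = as.integer(l_min),
    l_max = as.integer(l_max),
    complexity_min_bases = as.integer(complexity_min_bases),
    m_max_mirna = as.integer(m_max_mirna),
    a_min_scan = as.integer(a_min_scan),
    c_min_sirna = as.integer(c_min_sirna),
    alpha = alpha,
    mfe_ratio_min = mfe_ratio_min,
    rule_total_max = rule_total_max,
    rule_adjacent_max = as.integer(rule_adjacent_max),
    rule_window_1_12_max = rule_window_1_12_max,
    merge_gap = as.integer(merge_gap),
    adapter3 = toupper(chartr("Uu", "Tt", adapter3)),
    min_adapter_overlap = as.integer(min_adapter_overlap),
    pseudocount = as.integer(pseudocount),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "srna_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg an \code{srna_config} list.
#' @export
validate_config <- function(cfg) {
  stopifnot(
    cfg$l_min > 0L, cfg$l_max >= cfg$l_min,
    cfg$complexity_min_bases > 0L,
    cfg$m_max_mirna >= 0L,
    cfg$a_min_scan > 0L,
    cfg$c_min_sirna >= 0L,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$mfe_ratio_min > 0, cfg$mfe_ratio_min <= 1,
    cfg$rule_total_max > 0,
    cfg$rule_adjacent_max > 0L,
    cfg$rule_window_1_12_max > 0,
    cfg$merge_gap >= 0L,
    nchar(cfg$adapter3) >= cfg$min_adapter_overlap,
    cfg$pseudocount >= 0L
  )
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so that typos fail loudly. Keys absent from the
#' file keep their defaults.
#'
#' @param path path to a YAML file whose keys are arguments of
#'   \code{\link{pipeline_config}}.
#' @return An \code{srna_config} list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), c(allowed, "inputs", "libraries", "outdir"))
  if (length(extra)) {
    stop("unknown config key(s): /", paste(extra, collapse = ", /"))
  }
  cfg <- do.call(pipeline_config, raw[intersect(names(raw), allowed)])
  cfg$inputs <- raw$inputs
  cfg$libraries <- raw$libraries
  cfg$outdir <- raw$outdir
  cfg
}
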