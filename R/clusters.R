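#' Map non-miRNA reads onto repeat/EST references
#'
#' Exact full-length ungapped placements on either strand. A read with k
#' placements contributes weight 1/k to each (fractional multi-mapping, so
#' total read weight is conserved). Reads with no placement are returned in
#' the \code{unmapped} component; they form the unannotated-siRNA-cluster
#' pool.
#'
#' @param pool data.frame \code{sequence} plus per-library count columns.
#' @param references named character vector of reference sequences.
#' @param lib_ids library id column names in \code{pool}.
#' @return list with \code{placements} (data.frame \code{sequence},
#'   \code{reference}, \code{start}, \code{end}, \code{strand},
#'   \code{weight}) and \code{unmapped} (rows of \code{pool}).
#' @export
map_reads_to_references <- function(pool, references, lib_ids) {
  stopifnot(length(references) > 0L, !is.null(names(references)))
  references <- normalize_alphabet(references)
  empty <- data.frame(sequence = character(), reference = character(),
                      start = integer(), end = integer(),
                      strand = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(pool)) return(list(placements = empty, unmapped = pool))
  lens <- sort(unique(nchar(pool$sequence)))
  # window tables per read length, both strands, with transcript coordinates
  win <- list()
  for (L in lens) {
    for (ri in seq_along(references)) {
      ref <- references[[ri]]
      n <- nchar(ref)
      if (n < L) next
      starts <- 1:(n - L + 1L)
      w <- substring(ref, starts, starts + L - 1L)
      win[[length(win) + 1L]] <- data.frame(
        window = w, reference = names(references)[ri],
        start = starts, end = starts + L - 1L, strand = "sense",
        stringsAsFactors = FALSE)
      win[[length(win) + 1L]] <- data.frame(
        window = revcomp(w), reference = names(references)[ri],
        start = starts, end = starts + L - 1L, strand = "antisense",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(win)) return(list(placements = empty, unmapped = pool))
  win <- do.call(rbind, win)
  hit <- merge(data.frame(sequence = pool$sequence,
                          stringsAsFactors = FALSE),
               win, by.x = "sequence", by.y = "window")
  if (!nrow(hit)) return(list(placements = empty, unmapped = pool))
  k <- table(hit$sequence)
  hit$weight <- 1 / as.integer(k[hit$sequence])
  hit <- hit[order(hit$reference, hit$start, hit$sequence), , drop = FALSE]
  rownames(hit) <- NULL
  unmapped <- pool[!(pool$sequence %in% hit$sequence), , drop = FALSE]
  list(placements = hit, unmapped = unmapped)
}

#' Merge read placements into siRNA clusters
#'
#' Placements on the same reference whose intervals lie within
#' \code{merge_gap} nt of each other are merged transitively; the cluster
#' span is the union hull. Strand is ignored for clustering (siRNAs arise
#' from both strands of a double-stranded precursor).
#'
#' @param placements data.frame from \code{\link{map_reads_to_references}}.
#' @param merge_gap maximum gap (nt) bridged between placements.
#' @return data.frame \code{cluster_id}, \code{reference}, \code{start},
#'   \code{end}, \code{n_placements}; placements gain a matching
#'   \code{cluster_id} in \code{attr(, "assignment")}.
#' @export
build_clusters <- function(placements, merge_gap = 100L) {
  empty <- data.frame(cluster_id = character(), reference = character(),
                      start = integer(), end = integer(),
                      n_placements = integer(), stringsAsFactors = FALSE)
  if (!nrow(placements)) {
    attr(empty, "assignment") <- character()
    return(empty)
  }
  o <- order(placements$reference, placements$start, placements$end)
  p <- placements[o, , drop = FALSE]
  cluster_of <- integer(nrow(p))
  rows <- list()
  cid <- 0L
  for (ref in unique(p$reference)) {
    i <- which(p$reference == ref)
    cur_end <- -Inf
    for (j in i) {
      if (p$start[j] - cur_end - 1L > merge_gap) {
        cid <- cid + 1L
        rows[[cid]] <- list(reference = ref, start = p$start[j],
                            end = p$end[j], n = 0L)
        cur_end <- p$end[j]
      }
      rows[[cid]]$end <- max(rows[[cid]]$end, p$end[j])
      rows[[cid]]$n <- rows[[cid]]$n + 1L
      cur_end <- max(cur_end, p$end[j])
      cluster_of[j] <- cid
    }
  }
  out <- data.frame(
    cluster_id = sprintf("cl%04d", seq_len(cid)),
    reference = vapply(rows, `[[`, character(1), "reference"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    n_placements = vapply(rows, function(r) as.integer(r$n), integer(1)),
    stringsAsFactors = FALSE)
  assignment <- character(nrow(placements))
  assignment[o] <- out$cluster_id[cluster_of]
  attr(out, "assignment") <- assignment
  out
}

#' Annotate clusters and tabulate per-library category fractions
#'
#' Category priority: named repeat class from the annotation table, then TC
#' EST, then unannotated repeat, then unannotated-siRNA-cluster (reads with
#' no placement at all). Per-library fractions are read-weight fractions
#' over the whole pool (mapped weights plus unmapped counts) and sum to 1.
#' Length histograms are tabulated per category and library.
#'
#' @param mapping result of \code{\link{map_reads_to_references}}.
#' @param pool the pool data.frame given to the mapper.
#' @param annotation data.frame \code{reference}, \code{class} for repeat
#'   references; class \code{"unannotated"} marks unannotated repeats.
#' @param est_ids character vector of EST reference ids (TC EST category).
#' @param lib_ids library id column names.
#' @return list with \code{fractions} (category x library), \code{length_hist}
#'   (category, length, per-library weights), \code{categories} (per-
#'   placement category assignment).
#' @export
annotate_clusters <- function(mapping, pool, annotation, est_ids, lib_ids) {
  if (any(annotation$reference %in% est_ids)) {
    stop("annotation id collision: reference(s) listed both as repeat and ",
         "EST: ",
         paste(intersect(annotation$reference, est_ids), collapse = ", "))
  }
  category_of <- function(ref) {
    cls <- annotation$class[match(ref, annotation$reference)]
    ifelse(!is.na(cls) & cls != "unannotated", cls,
           ifelse(ref %in% est_ids, "TC EST",
                  ifelse(!is.na(cls), "unannotated repeat",
                         "unannotated-siRNA-cluster")))
  }
  pl <- mapping$placements
  cats <- sort(unique(c(category_of(unique(pl$reference)),
                        "unannotated-siRNA-cluster")))
  fractions <- matrix(0, nrow = length(cats), ncol = length(lib_ids),
                      dimnames = list(cats, lib_ids))
  lens <- sort(unique(nchar(pool$sequence)))
  hist_key <- expand.grid(category = cats, length = lens,
                          stringsAsFactors = FALSE)
  hist_w <- matrix(0, nrow = nrow(hist_key), ncol = length(lib_ids),
                   dimnames = list(NULL, lib_ids))
  add_weight <- function(cat, len, w_by_lib) {
    fractions[cat, ] <<- fractions[cat, ] + w_by_lib
    r <- which(hist_key$category == cat & hist_key$length == len)
    hist_w[r, ] <<- hist_w[r, ] + w_by_lib
  }
  if (nrow(pl)) {
    pl$category <- category_of(pl$reference)
    m <- match(pl$sequence, pool$sequence)
    for (j in seq_len(nrow(pl))) {
      w <- pl$weight[j] *
        as.numeric(pool[m[j], lib_ids, drop = TRUE])
      add_weight(pl$category[j], nchar(pl$sequence[j]), w)
    }
  }
  if (nrow(mapping$unmapped)) {
    for (j in seq_len(nrow(mapping$unmapped))) {
      w <- as.numeric(mapping$unmapped[j, lib_ids, drop = TRUE])
      add_weight("unannotated-siRNA-cluster",
                 nchar(mapping$unmapped$sequence[j]), w)
    }
  }
  totals <- colSums(fractions)
  frac <- sweep(fractions, 2L, ifelse(totals > 0, totals, 1), "/")
  list(fractions = as.data.frame(frac),
       length_hist = cbind(hist_key, as.data.frame(hist_w)),
       categories = if (nrow(pl)) pl else NULL)
}
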