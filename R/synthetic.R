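# Synthetic small-RNA study generator.
#
# Emulates the salient structure of pooled plant small-RNA libraries under a
# water-depletion design: four leaf libraries (tolerant/sensitive pools at
# 0 h and 24 h), read length peaks at 21/22/24 nt, a 5'-U bias, conserved
# miRNA families at library-specific abundances with planted fold changes,
# t/rRNA contaminants, repeat-derived siRNAs with a planted category mixture
# (including an LTR-gypsy 24-to-21 nt size shift in stressed tolerant
# plants), and a 22-nt miRNA whose target sheds cleavage-anchored secondary
# siRNAs present in every library. Same seed, same bytes.

rand_dna <- function(n, len, prob = NULL) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
}

# Build a target window for `mirna` whose duplex has the requested pair
# states ("WC"/"GU"/"MM" per miRNA position, 5'->3'). miRNA position i maps
# to window position L - i + 1.
window_for_states <- function(mirna, states) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  L <- length(m)
  stopifnot(length(states) == L)
  wc_partner <- c(A = "T", T = "A", G = "C", C = "G")
  gu_partner <- c(G = "T", T = "G")
  mm_choice <- list(A = "C", C = "A", G = "A", T = "C")  # never WC/GU
  w <- character(L)
  for (i in seq_len(L)) {
    b <- m[i]
    w[L - i + 1L] <- switch(states[i],
      WC = wc_partner[[b]],
      GU = {
        if (!b %in% names(gu_partner)) {
          stop("GU state impossible at position ", i, " (base ", b, ")")
        }
        gu_partner[[b]]
      },
      MM = mm_choice[[b]])
  }
  paste(w, collapse = "")
}

# Embed `insert` into `host` so that it occupies positions start..start+L-1.
embed_at <- function(host, insert, start) {
  L <- nchar(insert)
  stopifnot(start >= 1L, start + L - 1L <= nchar(host))
  paste0(substr(host, 1L, start - 1L), insert,
         substr(host, start + L, nchar(host)))
}

#' Define a synthetic small-RNA study
#'
#' Builds the full planted truth for a four-library leaf study: references
#' (mature miRNAs including a 22-nt trigger, t/rRNA contaminants, target and
#' decoy transcripts, classified repeats), the template read set with
#' per-library expected counts, planted target sites and decoys, the
#' cleavage-anchored ta-siRNA design, and the repeat-category mixture. All
#' randomness is drawn once here under \code{seed}; the same seed gives
#' byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param n_reads reads drawn per library (before fixed filter-fodder reads).
#' @param sampling \code{"multinomial"} draws reads from the expected
#'   proportions; \code{"exact"} emits each template exactly at its expected
#'   count (zero sampling noise).
#' @return object of class \code{srna_truth}; see the components in the
#'   source for the recorded truth tables.
#' @export
synthetic_truth <- function(seed = 1L, n_reads = 1e5L,
                            sampling = c("multinomial", "exact")) {
  sampling <- match.arg(sampling)
  stopifnot(n_reads >= 1000L)
  set.seed(seed)
  libs <- c("T0h", "T24h", "S0h", "S24h")

  ## ---- mature miRNA reference (conserved plant families; 22-nt trigger) --
  mirna_ref <- c(
    "ssp-miR156"   = "TGACAGAAGAGAGCGAGCAC",
    "ssp-miR159"   = "TTGGATTGAAGGGAGCTCTG",
    "ssp-miR164"   = "TGGAGAAGCAGGGCACGTGCT",
    "ssp-miR166"   = "TCTCGGACCAGGCTTCATTCC",
    "ssp-miR167"   = "TGAAGCTGCCAGCATGATCTGA",  # 22 nt trigger
    "ssp-miR168"   = "TCGCTTGGTGCAGATCGGGAC",
    "ssp-miR172"   = "AGAATCTTGATGATGCTGCAT",
    "ssp-miR397"   = "TTGAGTGCAGCGTTGATGAGC",
    "ssp-miR398"   = "TGTGTTCTCAGGTCGCCCCCG",
    "ssp-miR529"   = "AGAAGAGAGAGAGTACAGCCT",
    "ssp-miR1878"  = "ATTTGTAGTGTTCAGATTGAGTTT",
    "ssp-miR166*"  = "GAATGATGTCCGGTCCGAAGA"
  )
  trigger_id <- "ssp-miR167"
  trigger <- mirna_ref[[trigger_id]]

  ## ---- per-family expected read fractions (columns T0h T24h S0h S24h) ----
  # miR159 doubles in stressed tolerant pools; miR164 halves at 24 h in both
  # genotypes (the clean 2-fold design); miR397 splits by genotype.
  frac <- rbind(
    "ssp-miR156"  = c(.012, .012, .012, .012),
    "ssp-miR159"  = c(.018, .036, .018, .018),
    "ssp-miR164"  = c(.020, .010, .020, .010),
    "ssp-miR166"  = c(.010, .010, .010, .010),
    "ssp-miR167"  = c(.015, .020, .015, .018),
    "ssp-miR168"  = c(.008, .006, .008, .006),
    "ssp-miR172"  = c(.003, .003, .003, .003),
    "ssp-miR397"  = c(.004, .006, .004, .002),
    "ssp-miR398"  = c(.005, .005, .005, .005),
    "ssp-miR529"  = c(.002, .002, .002, .002),
    "ssp-miR1878" = c(.003, .003, .003, .003),
    "ssp-miR166*" = c(.002, .002, .002, .002)
  )
  colnames(frac) <- libs

  ## ---- contaminants (synthetic t/rRNA) ----------------------------------
  contaminants <- c(rRNA_1 = rand_dna(1L, 900L),
                    rRNA_2 = rand_dna(1L, 1200L),
                    tRNA_1 = rand_dna(1L, 150L))

  ## ---- transcripts: ta-siRNA source, planted sites, decoys, background --
  tx_len <- 800L
  transcripts <- c(
    TAS_TC900001 = rand_dna(1L, tx_len),
    TC800002     = rand_dna(1L, tx_len),
    TC800003     = rand_dna(1L, tx_len),
    TC800004     = rand_dna(1L, tx_len),
    TC800005     = rand_dna(1L, tx_len),
    TC800006     = rand_dna(1L, tx_len)
  )
  perfect <- function(m) rep("WC", nchar(m))
  site_tbl <- list()
  plant_site <- function(mirna_id, tx, start, states, kind, violated = NA) {
    mirna <- mirna_ref[[mirna_id]]
    win <- window_for_states(mirna, states)
    transcripts[[tx]] <<- embed_at(transcripts[[tx]], win, start)
    site_tbl[[length(site_tbl) + 1L]] <<- data.frame(
      mirna_id = mirna_id, mirna = mirna, transcript = tx,
      start = start, end = start + nchar(mirna) - 1L,
      cleavage_position = start + nchar(mirna) - 10L,
      kind = kind, violated_rule = violated, stringsAsFactors = FALSE)
  }
  # planted rule-passing sites
  plant_site(trigger_id, "TAS_TC900001", 301L, perfect(trigger), "planted")
  plant_site("ssp-miR159", "TC800002", 211L,
             perfect(mirna_ref[["ssp-miR159"]]), "planted")
  plant_site("ssp-miR398", "TC800003", 401L,
             perfect(mirna_ref[["ssp-miR398"]]), "planted")
  # decoys: each built to break a named rule
  st <- perfect(trigger); st[10L] <- "MM"
  plant_site(trigger_id, "TC800004", 251L, st, "decoy", "R4")
  st <- perfect(trigger); st[5:6] <- "MM"
  plant_site(trigger_id, "TC800005", 251L, st, "decoy", "R3")
  st <- perfect(trigger); st[14:16] <- "MM"
  plant_site(trigger_id, "TC800006", 251L, st, "decoy", "R2")
  sites <- do.call(rbind, site_tbl)

  ## ---- repeats with class labels ----------------------------------------
  repeats <- c(gypsy_1 = rand_dna(1L, 1200L), gypsy_2 = rand_dna(1L, 1000L),
               copia_1 = rand_dna(1L, 800L), dnaTn_1 = rand_dna(1L, 700L),
               mite_1 = rand_dna(1L, 400L), cen_1 = rand_dna(1L, 600L),
               unk_1 = rand_dna(1L, 800L))
  repeat_annotation <- data.frame(
    reference = names(repeats),
    class = c("retrotransposon/LTR-gypsy", "retrotransposon/LTR-gypsy",
              "retrotransposon", "transposon", "MITE",
              "centromere/telomere/ribosomal", "unannotated"),
    stringsAsFactors = FALSE)
  cluster_ests <- c(TC100001 = rand_dna(1L, 900L),
                    TC100002 = rand_dna(1L, 700L))
  est_ids <- names(cluster_ests)

  ## ---- template read table ----------------------------------------------
  tpl <- list()
  add <- function(sequence, class, subclass, counts) {
    tpl[[length(tpl) + 1L]] <<- data.frame(
      sequence = sequence, class = class, subclass = subclass,
      T0h = counts[1L], T24h = counts[2L], S0h = counts[3L],
      S24h = counts[4L], stringsAsFactors = FALSE)
  }
  # miRNA templates: the mature sequences themselves, plus one planted 1-
  # mismatch isoform of miR159 at a low flat abundance
  for (id in rownames(frac)) {
    add(mirna_ref[[id]], "mirna", id, round(frac[id, ] * n_reads))
  }
  iso <- mirna_ref[["ssp-miR159"]]
  substr(iso, 3L, 3L) <- "T"   # GG -> GT at position 3
  add(iso, "mirna", "ssp-miR159.iso", round(rep(.002, 4L) * n_reads))

  # contaminant templates: sense and antisense windows of the t/rRNA set
  n_cont <- 40L
  cont_src <- sample(names(contaminants), n_cont, replace = TRUE)
  cont_frac <- .08 / n_cont
  for (i in seq_len(n_cont)) {
    s <- contaminants[[cont_src[i]]]
    L <- sample(18:28, 1L)
    st <- sample.int(nchar(s) - L + 1L, 1L)
    w <- substr(s, st, st + L - 1L)
    if (i %% 2L == 0L) w <- revcomp(w)
    add(w, "contaminant", cont_src[i], round(rep(cont_frac, 4L) * n_reads))
  }

  # repeat-derived siRNA templates; per-category fractions of n_reads and a
  # 24->21 nt LTR-gypsy shift in the stressed libraries
  cat_frac <- c("retrotransposon/LTR-gypsy" = .16, "TC EST" = .12,
                "retrotransposon" = .032, "transposon" = .032,
                "MITE" = .024, "centromere/telomere/ribosomal" = .024,
                "unannotated" = .040)
  cat_refs <- list(
    "retrotransposon/LTR-gypsy" = c("gypsy_1", "gypsy_2"),
    "TC EST" = est_ids,
    "retrotransposon" = "copia_1", "transposon" = "dnaTn_1",
    "MITE" = "mite_1", "centromere/telomere/ribosomal" = "cen_1",
    "unannotated" = "unk_1")
  all_cluster_refs <- c(repeats, cluster_ests)
  n_win_per_len <- 12L
  for (cat in names(cat_frac)) {
    for (L in c(21L, 24L)) {
      # length weights: 24 nt dominant, flipped for LTR-gypsy under stress
      base_w <- if (L == 24L) .7 else .3
      shift_w <- if (L == 24L) .3 else .7
      w_lib <- if (cat == "retrotransposon/LTR-gypsy") {
        c(base_w, shift_w, base_w, shift_w)   # shift in T24h and S24h
      } else rep(base_w, 4L)
      per_win <- cat_frac[[cat]] * w_lib / n_win_per_len
      refs <- cat_refs[[cat]]
      ref_of <- refs[1L + (seq_len(n_win_per_len) - 1L) %% length(refs)]
      for (ref in unique(ref_of)) {
        k <- sum(ref_of == ref)
        s <- all_cluster_refs[[ref]]
        starts <- sample.int(nchar(s) - L + 1L, k)  # distinct starts
        for (i in seq_len(k)) {
          w <- substr(s, starts[i], starts[i] + L - 1L)
          if (i %% 2L == 0L) w <- revcomp(w)
          add(w, "repeat", cat, round(per_win * n_reads))
        }
      }
    }
  }

  # ta-siRNA candidates: the core candidate is a 21-mer whose 5' end sits
  # 1 nt 3' of the trigger's cleavage site, with two 1-2 nt end variants;
  # three further candidates are planted in exactly one library each
  cp <- sites$cleavage_position[sites$kind == "planted" &
                                  sites$mirna_id == trigger_id][1L]
  tas <- transcripts[["TAS_TC900001"]]
  core <- substr(tas, cp + 1L, cp + 21L)
  add(core, "tasi", "core", c(600L, 1400L, 500L, 1100L))
  add(substr(tas, cp, cp + 21L), "tasi", "core.var1",
      c(60L, 140L, 50L, 110L))
  add(substr(tas, cp + 2L, cp + 22L), "tasi", "core.var2",
      c(30L, 70L, 25L, 55L))
  add(substr(tas, 501L, 521L), "tasi", "only.T0h", c(120L, 0L, 0L, 0L))
  add(revcomp(substr(tas, 601L, 621L)), "tasi", "only.S24h",
      c(0L, 0L, 0L, 150L))
  add(substr(tas, 651L, 671L), "tasi", "only.S0h", c(0L, 0L, 90L, 0L))

  ## ---- background: clean negatives --------------------------------------
  # random 18-28-mers sharing no 18-mer with any reference and at Hamming
  # distance > 3 from every equal-length miRNA reference window
  ref_pool <- c(mirna_ref, contaminants, transcripts, repeats, cluster_ests)
  ref_kmers <- seq_windows(c(ref_pool, revcomp(ref_pool)), 18L, 18L)
  mir_windows <- seq_windows(c(mirna_ref, revcomp(mirna_ref)), 18L, 28L)
  n_bg <- 320L
  bg_lens <- sample(c(21L, 22L, 24L), n_bg, replace = TRUE,
                    prob = c(.40, .25, .35))
  bg <- character(n_bg)
  for (i in seq_len(n_bg)) {
    repeat {
      s <- rand_dna(1L, bg_lens[i])
      if (stats::runif(1L) < 0.6) substr(s, 1L, 1L) <- "T"   # 5'-U bias
      if (any(kmer_set(s, 18L) %in% ref_kmers)) next
      same_len <- mir_windows[nchar(mir_windows) == nchar(s)]
      if (length(same_len) &&
          min(utils::adist(s, same_len,
                           costs = list(ins = 99L, del = 99L,
                                        sub = 1L))) <= 3L) next
      break
    }
    bg[i] <- s
  }
  templates <- do.call(rbind, tpl)
  bg_total <- pmax(0, n_reads - colSums(templates[, libs]))
  bg_w <- stats::runif(n_bg, .5, 1.5)
  bg_w <- bg_w / sum(bg_w)
  for (i in seq_len(n_bg)) {
    add(bg[i], "background", "background", round(bg_w[i] * bg_total))
  }
  templates <- do.call(rbind, tpl)
  if (anyDuplicated(templates$sequence)) {
    stop("synthetic template collision; change the seed")
  }

  ## ---- expected cluster-category fractions (non-miRNA pool) --------------
  pool_rows <- templates$class %in% c("repeat", "tasi", "background")
  pool <- templates[pool_rows, , drop = FALSE]
  pool$category <- ifelse(pool$class == "repeat",
                          ifelse(pool$subclass == "unannotated",
                                 "unannotated repeat", pool$subclass),
                          "unannotated-siRNA-cluster")
  exp_frac <- sapply(libs, function(lib) {
    tapply(pool[[lib]], pool$category, sum) / sum(pool[[lib]])
  })

  structure(list(
    seed = as.integer(seed), n_reads = as.integer(n_reads),
    sampling = sampling,
    libraries = data.frame(id = libs, tissue = "leaf",
                           group = c("tolerant-pool", "tolerant-pool",
                                     "sensitive-pool", "sensitive-pool"),
                           timepoint = c("0h", "24h", "0h", "24h"),
                           stringsAsFactors = FALSE),
    mirna_ref = mirna_ref, trigger_id = trigger_id,
    contaminants = contaminants, transcripts = transcripts,
    repeats = repeats, repeat_annotation = repeat_annotation,
    cluster_ests = cluster_ests, est_ids = est_ids,
    sites = sites, templates = templates,
    core_tasi = core, core_cleavage = cp,
    expected_fractions = exp_frac,
    fodder = c(n_read = 200L, too_short = 150L, too_long = 150L,
               low_complexity = 100L)
  ), class = "srna_truth")
}

#' @export
print.srna_truth <- function(x, ...) {
  cat("synthetic small-RNA study: 4 leaf libraries x", x$n_reads,
      "reads (", x$sampling, "sampling ), seed", x$seed, "\n")
  cat(" ", nrow(x$templates), "read templates;",
      sum(x$sites$kind == "planted"), "planted target sites;",
      sum(x$sites$kind == "decoy"), "decoys\n")
  invisible(x)
}

#' Generate the synthetic library files
#'
#' Draws the four libraries from the truth's template table (multinomially,
#' or exactly at the expected counts), appends the 3' adapter to every
#' read, adds the fixed filter-fodder reads (N-containing, too short, too
#' long, low-complexity), and writes FASTQ files plus all reference FASTA /
#' annotation files and the realized truth tables.
#'
#' @param truth an \code{\link{synthetic_truth}} object.
#' @param dir output directory (created if needed).
#' @param config an \code{srna_config} (supplies the adapter).
#' @return list with \code{files} (named paths), \code{counts} (realized
#'   template x library read counts), \code{filter_truth} (expected
#'   FilterReport per library), \code{truth}.
#' @export
generate_libraries <- function(truth, dir = tempfile("synthlib"),
                               config = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  libs <- truth$libraries$id
  tpl <- truth$templates
  counts <- matrix(0L, nrow = nrow(tpl), ncol = length(libs),
                   dimnames = list(tpl$sequence, libs))
  for (li in seq_along(libs)) {
    expected <- tpl[[libs[li]]]
    if (truth$sampling == "exact") {
      counts[, li] <- as.integer(expected)
    } else {
      set.seed(truth$seed + 1000L * li)
      draw <- stats::rmultinom(1L, size = truth$n_reads,
                               prob = expected / sum(expected))
      counts[, li] <- as.integer(draw)
    }
  }
  adapter <- config$adapter3
  fodder <- function() {
    n_read <- paste0(substr(rand_dna(1L, 21L), 1L, 9L), "N",
                     substr(rand_dna(1L, 21L), 11L, 21L))
    c(rep(paste0(n_read, adapter), truth$fodder["n_read"]),
      rep(paste0(rand_dna(1L, 17L), adapter), truth$fodder["too_short"]),
      rep(paste0(rand_dna(1L, 29L), adapter), truth$fodder["too_long"]),
      rep(paste0(strrep("AC", 10L), adapter),
          truth$fodder["low_complexity"]))
  }
  files <- list()
  filter_truth <- list()
  for (li in seq_along(libs)) {
    lib <- libs[li]
    set.seed(truth$seed + 2000L * li)
    reads <- c(rep(paste0(tpl$sequence, adapter), counts[, li]), fodder())
    reads <- sample(reads)
    path <- file.path(dir, paste0(lib, ".fastq"))
    qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
    writeLines(as.vector(rbind(
      sprintf("@%s_%d", lib, seq_along(reads)), reads,
      rep("+", length(reads)), qual)), path)
    files[[lib]] <- path
    n_main <- sum(counts[, li])
    fo <- truth$fodder
    n_cont <- sum(counts[tpl$class == "contaminant", li])
    filter_truth[[lib]] <- data.frame(
      library = lib,
      input_reads = n_main + sum(fo),
      after_trim = n_main + sum(fo) - fo[["n_read"]],
      after_length = n_main + fo[["low_complexity"]],
      after_complexity = n_main,
      after_contaminant = n_main - n_cont,
      unique_sequences = sum(counts[tpl$class != "contaminant", li] > 0L),
      stringsAsFactors = FALSE)
  }
  files$mirna_ref <- write_fasta(truth$mirna_ref,
                                 file.path(dir, "mirna_mature.fasta"))
  files$contaminants <- write_fasta(truth$contaminants,
                                    file.path(dir, "contaminants.fasta"))
  files$transcripts <- write_fasta(truth$transcripts,
                                   file.path(dir, "transcripts.fasta"))
  files$repeats <- write_fasta(c(truth$repeats, truth$cluster_ests),
                               file.path(dir, "cluster_refs.fasta"))
  files$repeat_annotation <- write_table(truth$repeat_annotation,
                                         file.path(dir,
                                                   "repeat_annotation.tsv"))
  tt <- cbind(tpl[, c("sequence", "class", "subclass")],
              as.data.frame(counts))
  files$truth_counts <- write_table(tt, file.path(dir, "truth_counts.tsv"))
  files$truth_sites <- write_table(truth$sites,
                                   file.path(dir, "truth_sites.tsv"))
  list(files = files, counts = counts,
       filter_truth = do.call(rbind, filter_truth), truth = truth)
}
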