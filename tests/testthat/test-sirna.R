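test_that("only 22-nt sequences are selected as triggers", {
  hits <- data.frame(
    sequence = c(strrep("A", 20), strrep("C", 21), "TGAAGCTGCCAGCATGATCTGA",
                 strrep("G", 24)),
    mirna_id = paste0("m", 1:4), stringsAsFactors = FALSE)
  tr <- select_triggers(hits)
  expect_equal(unname(tr), "TGAAGCTGCCAGCATGATCTGA")
  expect_equal(names(tr), "m3")
  none <- select_triggers(hits[c(1, 2, 4), ])
  expect_equal(length(none), 0L)
})

test_that("scan_target reports sense and antisense hits per convention", {
  set.seed(10)
  tx <- random_mirna(400)
  sense_read <- substr(tx, 300, 320)             # 21 nt
  anti_read <- revcomp(substr(tx, 139, 159))     # 21 nt
  short_read <- substr(tx, 50, 66)               # 17 nt: below threshold
  pool <- data.frame(sequence = c(sense_read, anti_read, short_read),
                     stringsAsFactors = FALSE)
  hits <- scan_target(tx, pool, a_min = 18L)
  s <- hits[hits$sequence == sense_read, ]
  expect_equal(c(s$start, s$end), c(300L, 320L))
  expect_equal(s$strand, "sense")
  a <- hits[hits$sequence == anti_read, ]
  expect_equal(c(a$start, a$end), c(159L, 139L))  # high -> low
  expect_true(a$end < a$start)
  expect_false(short_read %in% hits$sequence)
})

test_that("scan_target equals the brute-force all-substrings oracle", {
  set.seed(20)
  tx <- random_mirna(500)
  # reads: exact windows, windows with mutated flanks, pure noise
  reads <- c(substr(tx, 101, 124),
             paste0("CC", substr(tx, 201, 219)),  # 18-nt core, fouled 5' end
             random_mirna(22),
             revcomp(substr(tx, 301, 321)))
  pool <- data.frame(sequence = unique(reads), stringsAsFactors = FALSE)
  hits <- scan_target(tx, pool, 18L)
  for (r in pool$sequence) {
    want_s <- oracle_scan(r, tx, 18L)
    got_s <- hits[hits$sequence == r & hits$strand == "sense", ]
    if (is.null(want_s)) {
      expect_equal(nrow(got_s), 0L)
    } else {
      expect_equal(c(got_s$start, got_s$end), want_s)
    }
    want_a <- oracle_scan(revcomp(r), tx, 18L)
    got_a <- hits[hits$sequence == r & hits$strand == "antisense", ]
    if (is.null(want_a)) {
      expect_equal(nrow(got_a), 0L)
    } else {
      expect_equal(c(got_a$end, got_a$start), want_a)
    }
  }
})

test_that("end variants within 2 nt group into one candidate", {
  hits <- data.frame(sequence = c("AAAACCCCGGGGTTTTACGTA",
                                  "AAACCCCGGGGTTTTACGTAC",
                                  "AAAACCCCGGGGTTTTACGTACG"),
                     start = c(139L, 140L, 139L),
                     end = c(157L, 157L, 159L),
                     strand = "sense", stringsAsFactors = FALSE)
  counts <- data.frame(sequence = hits$sequence,
                       L1 = c(100L, 10L, 5L), stringsAsFactors = FALSE)
  cand <- merge_variants(hits, counts, "L1")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$sequence, "AAAACCCCGGGGTTTTACGTA")  # max count wins
  expect_equal(cand$n_variants, 3L)

  # far-apart hits stay separate
  hits2 <- hits[c(1, 1), ]
  hits2$start <- c(139L, 170L); hits2$end <- c(157L, 190L)
  hits2$sequence <- c("AAAACCCCGGGGTTTTACGTA", "CCCCGGGGTTTTACGTAAAAA")
  counts2 <- data.frame(sequence = hits2$sequence, L1 = c(5L, 5L))
  expect_equal(nrow(merge_variants(hits2, counts2, "L1")), 2L)
})

test_that("representative ties break to the smallest sequence", {
  hits <- data.frame(sequence = c("TTTTCCCCGGGGAAAATTTTC", "AAAACCCCGGGGTTTTACGTA"),
                     start = c(10L, 11L), end = c(30L, 31L),
                     strand = "sense", stringsAsFactors = FALSE)
  counts <- data.frame(sequence = hits$sequence, L1 = c(50L, 50L))
  cand <- merge_variants(hits, counts, "L1")
  expect_equal(cand$sequence, "AAAACCCCGGGGTTTTACGTA")
})

test_that("the abundance filter is strictly greater-than per library", {
  cand <- data.frame(sequence = c("a", "b"),
                     L1 = c(51L, 50L), L2 = c(60L, 60L),
                     L3 = c(55L, 55L), L4 = c(70L, 70L),
                     stringsAsFactors = FALSE)
  out <- filter_abundance(cand, c("L1", "L2", "L3", "L4"), 50L)
  expect_true(out$core[out$sequence == "a"])
  expect_false(out$core[out$sequence == "b"])   # 50 is not > 50
  expect_false(out$present_L1[out$sequence == "b"])
})

test_that("cleavage concordance accepts ends within 1 nt of the site", {
  expect_true(cleavage_concordance(157L, 139L, 139L))   # end at the site
  expect_true(cleavage_concordance(140L, 160L, 139L))   # start 1 nt off
  expect_false(cleavage_concordance(294L, 311L, 139L))  # secondary locus
  expect_false(cleavage_concordance(169L, 189L, 139L))  # 30 nt downstream
})

test_that("identical siRNAs from two transcripts are reported jointly", {
  set.seed(30)
  shared <- random_mirna(21)
  tx1 <- paste0(random_mirna(120), shared, random_mirna(60))
  tx2 <- paste0(random_mirna(60), shared, random_mirna(120))
  trigger <- "TGAAGCTGCCAGCATGATCTGA"
  tx1 <- paste0(tx1, revcomp(trigger), random_mirna(20))
  tx2 <- paste0(tx2, revcomp(trigger), random_mirna(20))
  txs <- c(TCa = tx1, TCb = tx2)

  libs <- data.frame(id = c("L1", "L2"),
                     total_filtered_reads = c(10000, 10000))
  counts <- data.frame(sequence = c(trigger, shared),
                       L1 = c(100L, 200L), L2 = c(100L, 300L),
                       stringsAsFactors = FALSE)
  prof <- profile_mirnas(counts, c("xxx-miR167" = trigger), libs)
  sites <- predict_targets(stats::setNames(trigger, "miR167 I"), txs)
  expect_equal(sort(unique(sites$transcript)), c("TCa", "TCb"))
  cand <- find_sirna_candidates(prof, sites, txs, counts)
  row <- cand[cand$sequence == shared, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$transcripts, "TCa/TCb")
})

test_that("no candidate sequence carries a miRNA hit", {
  truth <- synthetic_truth(seed = 12, n_reads = 20000)
  gen <- generate_libraries(truth, dir = withr::local_tempdir())
  inputs <- list(libraries = unlist(gen$files[truth$libraries$id]),
                 mirna_ref = gen$files$mirna_ref,
                 contaminants = gen$files$contaminants,
                 transcripts = gen$files$transcripts,
                 repeats = gen$files$repeats,
                 repeat_annotation = gen$files$repeat_annotation,
                 est_ids = truth$est_ids)
  res <- run_pipeline(inputs, outdir = withr::local_tempdir(),
                      stages = c("preprocess", "profile", "diffexp",
                                 "targets", "sirna"))
  expect_gt(nrow(res$sirna), 0L)
  expect_false(any(res$sirna$sequence %in% res$profile$hits$sequence))
})
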