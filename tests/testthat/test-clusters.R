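test_that("fractional weights split across multi-mapped placements", {
  set.seed(40)
  core <- random_mirna(21)
  refs <- c(r1 = paste0(random_mirna(50), core, random_mirna(50)),
            r2 = paste0(random_mirna(80), core, random_mirna(20)),
            r3 = random_mirna(100))
  uniq <- substr(refs[["r3"]], 31, 51)
  pool <- data.frame(sequence = c(core, uniq, random_mirna(22)),
                     L1 = c(10L, 4L, 6L), stringsAsFactors = FALSE)
  mp <- map_reads_to_references(pool, refs, "L1")
  w_core <- mp$placements$weight[mp$placements$sequence == core]
  expect_equal(w_core, c(0.5, 0.5))
  expect_equal(mp$placements$weight[mp$placements$sequence == uniq], 1)
  expect_equal(nrow(mp$unmapped), 1L)
  # total read weight is conserved: each mapped read's placements sum to 1
  expect_equal(sum(mp$placements$weight), 2)
})

test_that("antisense placements are found on the reverse strand", {
  set.seed(41)
  ref <- c(r1 = random_mirna(120))
  read <- revcomp(substr(ref[["r1"]], 40, 60))
  pool <- data.frame(sequence = read, L1 = 5L, stringsAsFactors = FALSE)
  mp <- map_reads_to_references(pool, ref, "L1")
  expect_equal(mp$placements$strand, "antisense")
  expect_equal(mp$placements$start, 40L)
  expect_equal(mp$placements$end, 60L)
})

test_that("placements merge into clusters by the gap rule", {
  pl <- data.frame(sequence = c("a", "b"), reference = "r1",
                   start = c(1L, 60L), end = c(21L, 80L),
                   strand = "sense", weight = 1,
                   stringsAsFactors = FALSE)
  cl <- build_clusters(pl, merge_gap = 100L)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(1L, 80L))

  pl$start <- c(1L, 200L); pl$end <- c(21L, 220L)  # gap 178 > 100
  cl2 <- build_clusters(pl, merge_gap = 100L)
  expect_equal(nrow(cl2), 2L)
})

test_that("cluster counts equal a brute-force interval-merge oracle", {
  set.seed(50)
  for (i in 1:20) {
    n <- sample(3:25, 1)
    start <- sample(1000, n)
    end <- start + sample(18:28, n, replace = TRUE) - 1L
    gap <- sample(c(0L, 10L, 100L), 1)
    pl <- data.frame(sequence = paste0("s", seq_len(n)), reference = "r1",
                     start = start, end = end, strand = "sense",
                     weight = 1, stringsAsFactors = FALSE)
    expect_equal(nrow(build_clusters(pl, gap)),
                 oracle_merge_intervals(start, end, gap))
  }
})

test_that("annotation respects category priority and conserves weight", {
  set.seed(60)
  refs <- c(gyp = random_mirna(200), est = random_mirna(200),
            unk = random_mirna(200))
  annot <- data.frame(reference = c("gyp", "unk"),
                      class = c("retrotransposon/LTR-gypsy", "unannotated"),
                      stringsAsFactors = FALSE)
  pool <- data.frame(
    sequence = c(substr(refs[["gyp"]], 10, 30),
                 substr(refs[["est"]], 50, 70),
                 substr(refs[["unk"]], 100, 121),
                 random_mirna(24)),
    L1 = c(40L, 30L, 20L, 10L), stringsAsFactors = FALSE)
  mp <- map_reads_to_references(pool, refs, "L1")
  tab <- annotate_clusters(mp, pool, annot, est_ids = "est", "L1")
  fr <- tab$fractions
  expect_equal(fr["retrotransposon/LTR-gypsy", "L1"], 0.4)
  expect_equal(fr["TC EST", "L1"], 0.3)
  expect_equal(fr["unannotated repeat", "L1"], 0.2)
  expect_equal(fr["unannotated-siRNA-cluster", "L1"], 0.1)
  expect_equal(sum(fr$L1), 1)

  # an id listed both as repeat and EST is a configuration error
  expect_error(annotate_clusters(mp, pool, annot, est_ids = "gyp", "L1"),
               "collision")

  # empty library: all-zero fractions, no error
  pool$L2 <- 0L
  mp2 <- map_reads_to_references(pool, refs, c("L1", "L2"))
  tab2 <- annotate_clusters(mp2, pool, annot, est_ids = "est",
                            c("L1", "L2"))
  expect_equal(sum(tab2$fractions$L2), 0)
})

test_that("category fractions are invariant to reference file order", {
  truth <- synthetic_truth(seed = 13, n_reads = 20000)
  gen <- generate_libraries(truth, dir = withr::local_tempdir())
  refs <- c(truth$repeats, truth$cluster_ests)
  pool <- data.frame(sequence = rownames(gen$counts),
                     stringsAsFactors = FALSE)
  for (lib in truth$libraries$id) pool[[lib]] <- gen$counts[, lib]
  pool <- pool[!(pool$sequence %in% unname(truth$mirna_ref)), ]
  tab_a <- annotate_clusters(
    map_reads_to_references(pool, refs, truth$libraries$id),
    pool, truth$repeat_annotation, truth$est_ids, truth$libraries$id)
  tab_b <- annotate_clusters(
    map_reads_to_references(pool, rev(refs), truth$libraries$id),
    pool, truth$repeat_annotation, truth$est_ids, truth$libraries$id)
  expect_equal(tab_a$fractions, tab_b$fractions)
})

test_that("the planted LTR-gypsy 24-to-21 nt shift shows in the histograms", {
  truth <- synthetic_truth(seed = 14, n_reads = 50000)
  gen <- generate_libraries(truth, dir = withr::local_tempdir())
  refs <- c(truth$repeats, truth$cluster_ests)
  pool <- data.frame(sequence = rownames(gen$counts),
                     stringsAsFactors = FALSE)
  for (lib in truth$libraries$id) pool[[lib]] <- gen$counts[, lib]
  pool <- pool[!(pool$sequence %in% unname(truth$mirna_ref)), ]
  mp <- map_reads_to_references(pool, refs, truth$libraries$id)
  tab <- annotate_clusters(mp, pool, truth$repeat_annotation,
                           truth$est_ids, truth$libraries$id)
  h <- tab$length_hist
  gyp <- h[h$category == "retrotransposon/LTR-gypsy", ]
  w21 <- function(lib) gyp[[lib]][gyp$length == 21] /
    sum(gyp[[lib]][gyp$length %in% c(21, 24)])
  # control libraries are 24-nt dominated; stressed libraries flip to 21 nt
  expect_lt(w21("T0h"), 0.5)
  expect_gt(w21("T24h"), 0.5)
  expect_lt(w21("S0h"), 0.5)
  expect_gt(w21("S24h"), 0.5)
})
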