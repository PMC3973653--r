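ref <- c("osa-miR159a" = "TTGGATTGAAGGGAGCTCTG",
         "osa-miR164a" = "TGGAGAAGCAGGGCACGTGCT",
         "osa-miR167a" = "TGAAGCTGCCAGCATGATCTGA")

test_that("exact reads hit their reference with 0 mismatches", {
  hits <- match_reads("TTGGATTGAAGGGAGCTCTG", ref)
  expect_equal(hits$reference_id, "osa-miR159a")
  expect_equal(hits$mismatches, 0L)
})

test_that("reads beyond 3 mismatches from every window find no hit", {
  far <- "CCCCCCAACCCCACCCCACC"  # 20 nt, nothing like the references
  expect_equal(nrow(match_reads(far, ref)), 0L)
})

test_that("minimal-mismatch hit wins; ties break to the smallest id", {
  # 2 mismatches from miR159, >= 4 from the others
  r2 <- "TAGGATTGAAGGGAGCTCTA"
  hits <- match_reads(r2, ref, m_max = 3)
  expect_equal(hits$reference_id, "osa-miR159a")
  expect_equal(hits$mismatches, 2L)

  tie_ref <- c(bbb = "ACGTACGTACGTACGTACGT", aaa = "ACGTACGTACGTACGTACGT")
  tie <- match_reads("ACGTACGTACGTACGTACGA", tie_ref)
  expect_equal(tie$reference_id, "aaa")
})

test_that("match_reads agrees with a brute-force Hamming oracle", {
  set.seed(42)
  base <- ref[["osa-miR159a"]]
  reads <- vapply(1:40, function(i) {
    s <- base
    k <- sample(0:5, 1)
    pos <- sample(nchar(s), k)
    for (p in pos) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }, character(1))
  got <- match_reads(unique(reads), ref)
  for (r in unique(reads)) {
    want <- oracle_best_hit(r, ref)
    row <- got[got$sequence == r, ]
    if (is.null(want)) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(row$reference_id, want$id)
      expect_equal(row$mismatches, want$d)
    }
  }
})

test_that("reads match windows of longer references end-to-end", {
  long_ref <- c(hairpin1 = paste0("AAAA", ref[["osa-miR159a"]], "CCCC"))
  hits <- match_reads(ref[["osa-miR159a"]], long_ref)
  expect_equal(hits$reference_id, "hairpin1")
  expect_equal(hits$mismatches, 0L)
})

make_profile <- function(counts, totals) {
  libs <- data.frame(id = names(totals),
                     total_filtered_reads = unname(totals),
                     stringsAsFactors = FALSE)
  profile_mirnas(counts, ref, libs)
}

test_that("RPM normalisation is count * 1e6 / library total, 2 decimals", {
  counts <- data.frame(sequence = c("TTGGATTGAAGGGAGCTCTG",
                                    "TGGAGAAGCAGGGCACGTGCT"),
                       lib1 = c(250L, 0L), stringsAsFactors = FALSE)
  prof <- make_profile(counts, c(lib1 = 1e6))
  expr <- prof$expression
  expect_equal(expr$rpm_lib1[expr$sequence == "TTGGATTGAAGGGAGCTCTG"], 250)
  expect_equal(expr$rpm_lib1[expr$sequence == "TGGAGAAGCAGGGCACGTGCT"], 0)
  # zero library total is a configuration error
  expect_error(make_profile(counts, c(lib1 = 0)), "total_filtered_reads")
})

test_that("RPM is invariant under joint duplication of counts and totals", {
  counts <- data.frame(sequence = "TTGGATTGAAGGGAGCTCTG", lib1 = 123L,
                       stringsAsFactors = FALSE)
  a <- make_profile(counts, c(lib1 = 40000))$expression$rpm_lib1
  counts$lib1 <- 246L
  b <- make_profile(counts, c(lib1 = 80000))$expression$rpm_lib1
  expect_equal(a, b)
})

test_that("expression rows conserve per-library raw counts", {
  counts <- data.frame(sequence = c("TTGGATTGAAGGGAGCTCTG",
                                    "TGAAGCTGCCAGCATGATCTGA"),
                       lib1 = c(10L, 20L), lib2 = c(5L, 0L),
                       stringsAsFactors = FALSE)
  expr <- make_profile(counts, c(lib1 = 1000, lib2 = 1000))$expression
  m <- match(expr$sequence, counts$sequence)
  expect_equal(expr$lib1, counts$lib1[m])
  expect_equal(expr$lib2, counts$lib2[m])
})

test_that("variant labels are Roman numerals in lexicographic order", {
  fam_ref <- c("osa-miR159a" = "TTGGATTGAAGGGAGCTCTG",
               "osa-miR159b" = "GTTGGATTGAAGGGAGCTCTG")
  counts <- data.frame(sequence = c("TTGGATTGAAGGGAGCTCTG",
                                    "GTTGGATTGAAGGGAGCTCTG"),
                       lib1 = c(5L, 5L), stringsAsFactors = FALSE)
  libs <- data.frame(id = "lib1", total_filtered_reads = 1000)
  prof <- profile_mirnas(counts, fam_ref, libs)
  h <- prof$hits[order(prof$hits$sequence), ]
  expect_equal(h$variant_label, c("I", "II"))  # G... sorts before T...
  expect_equal(unique(h$family), "miR159")
})

test_that("composition summary counts unique sequences and sums to 100%", {
  hits <- data.frame(sequence = c("AACGTACGTACGTACGTACG",   # 20 nt, 5'A
                                  "TACGTACGTACGTACGTACGT",  # 21 nt, 5'U
                                  "TACGTACGTACGTACGTACGT"), # duplicate
                     stringsAsFactors = FALSE)
  cs <- composition_summary(hits)
  expect_equal(cs$length_hist$count[cs$length_hist$length == 20], 1L)
  expect_equal(cs$length_hist$count[cs$length_hist$length == 21], 1L)
  expect_equal(cs$five_prime$percent[cs$five_prime$base == "U"], 50)
  expect_equal(sum(cs$five_prime$count), 2L)
})

test_that("a planted 5'-U bias is recovered within the binomial 99% CI", {
  set.seed(99)
  p_u <- 0.6; n <- 500
  first <- ifelse(stats::runif(n) < p_u, "T",
                  sample(c("A", "C", "G"), n, replace = TRUE))
  seqs <- paste0(first, vapply(1:n, function(i) random_mirna(20),
                               character(1)))
  seqs <- unique(seqs)
  cs <- composition_summary(data.frame(sequence = seqs))
  phat <- cs$five_prime$count[cs$five_prime$base == "U"] / length(seqs)
  ci <- stats::qnorm(.995) * sqrt(p_u * (1 - p_u) / length(seqs))
  expect_lt(abs(phat - p_u), ci + 0.01)
})

test_that("set overlaps return exact Venn region cardinalities", {
  same <- set_overlap(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(same$count[same$region == "a&b"], 5L)
  expect_equal(same$count[same$region == "a"], 0L)

  disj <- set_overlap(list(a = letters[1:3], b = letters[4:7]))
  expect_equal(disj$count[disj$region == "a&b"], 0L)
  expect_equal(disj$count[disj$region == "a"], 3L)
  expect_equal(disj$count[disj$region == "b"], 4L)

  # planted intersection of 64 between sets of 88 and 273
  common <- paste0("c", 1:64)
  a <- c(common, paste0("a", 1:24))    # |A| = 88
  b <- c(common, paste0("b", 1:209))   # |B| = 273
  v <- set_overlap(list(leaf = a, root = b))
  expect_equal(v$count[v$region == "leaf&root"], 64L)
  expect_equal(v$count[v$region == "leaf"], 24L)
  expect_equal(v$count[v$region == "root"], 209L)
})
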