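ad3 <- "TGGAATTCTCGGGTGCCAAGG"
ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

mk_read <- function(seq, qual = strrep("I", nchar(seq)), id = "r1") {
  tibble::tibble(read_id = id, seq = seq, qual = qual)
}

test_that("cleaning rules fire in the documented order", {
  ins <- "ACGTGACGTGACGTGACGTGA"   # 21 nt
  good <- mk_read(paste0(ins, ad3))
  out <- clean_reads(good, ad3, ad5)
  expect_true(is.na(out$reason))
  expect_equal(out$insert, ins)

  # two bases at Q = 19 -> low quality, even though adapters are fine
  q <- strrep("I", nchar(good$seq)); substr(q, 3, 4) <- "44"
  expect_equal(clean_reads(mk_read(good$seq, q), ad3, ad5)$reason,
               "low_quality")
  # exactly one low-quality base is tolerated
  q1 <- strrep("I", nchar(good$seq)); substr(q1, 3, 3) <- "4"
  expect_true(is.na(clean_reads(mk_read(good$seq, q1), ad3, ad5)$reason))

  expect_equal(clean_reads(mk_read(sub("C", "N", good$seq)), ad3, ad5)$reason,
               "contains_n")
  expect_equal(clean_reads(mk_read(ins), ad3, ad5)$reason, "no_3p_adapter")
  expect_equal(clean_reads(mk_read(paste0(substr(ad5, 1, 8), ins, ad3)),
                           ad3, ad5)$reason, "has_5p_adapter")
  expect_equal(clean_reads(mk_read(ad3), ad3, ad5)$reason, "no_insert")
  expect_equal(clean_reads(mk_read(paste0(strrep("A", 20), ad3)),
                           ad3, ad5)$reason, "polya")
  expect_equal(clean_reads(mk_read(paste0("ACGTGACGTGACGTGAC", ad3)),
                           ad3, ad5)$reason, "too_short")   # 17 nt
  expect_equal(clean_reads(mk_read(paste0(strrep("ACGTG", 7), ad3)),
                           ad3, ad5)$reason, "too_long")    # 35 nt
})

test_that("polyA is judged on the insert: >= 80% A or terminal A run", {
  mostly_a <- paste0("AAAAAAAAGAAAAAAAAGA", ad3)       # 17/19 A
  expect_equal(clean_reads(mk_read(mostly_a), ad3, ad5)$reason, "polya")
  tail_run <- paste0("GCGTGCGTGC", strrep("A", 10), ad3)
  expect_equal(clean_reads(mk_read(tail_run), ad3, ad5)$reason, "polya")
  some_a <- paste0("AACGAACGAACGAACGAACG", ad3)        # 50% A, no run
  expect_true(is.na(clean_reads(mk_read(some_a), ad3, ad5)$reason))
})

test_that("cleaning an already-clean insert never shortens it further", {
  ins <- "GCGTACGTTAGCCATGCATGG"
  once <- clean_reads(mk_read(paste0(ins, ad3)), ad3, ad5)$insert
  again <- clean_reads(mk_read(paste0(once, ad3)), ad3, ad5)$insert
  expect_equal(again, once)
})

test_that("collapse merges identical sequences with per-library counts", {
  cl <- tibble::tibble(
    library_id = c("A", "A", "A", "B", "A", "B"),
    insert = c(rep("ACGTGACGTGACGTGACGTGA", 4),
               "ACGTGACGTGACGTGACGTGC", "ACGTGACGTGACGTGACGTGC"))
  tags <- collapse_tags(cl, c("A", "B"))
  expect_equal(nrow(tags), 2L)   # one-base difference keeps tags apart
  top <- tags[tags$seq == "ACGTGACGTGACGTGACGTGA", ]
  expect_equal(c(top$A, top$B), c(3L, 1L))
})

test_that("filter report conserves reads and ignores input order", {
  set.seed(42)
  ins <- replicate(30, random_dna(21))
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:60),
    seq = c(paste0(ins, ad3), replicate(20, random_dna(25)),
            rep(paste0(strrep("A", 20), ad3), 10)),
    qual = strrep("I", c(rep(42, 30), rep(25, 20), rep(41, 10))))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f1)
  write_fastq(reads[sample.int(60), ], f2)
  suppressMessages({
    p1 <- preprocess_libraries(c(L1 = f1), ad3, ad5)
    p2 <- preprocess_libraries(c(L1 = f2), ad3, ad5)
  })
  expect_equal(sum(p1$report$n), 60L)          # conservation, exactly
  expect_equal(dplyr::arrange(p1$report, reason),
               dplyr::arrange(p2$report, reason))
  expect_equal(p1$totals[["L1"]],
               p1$report$n[p1$report$reason == "clean"])
})

test_that("clean-tag FASTA headers carry the count string", {
  tags <- tibble::tibble(tag_id = "tag000001", seq = "ACGTGACGTGACGTGACGTGA",
                         A = 3L, B = 1L, C = 0L)
  f <- withr::local_tempfile(fileext = ".fa")
  write_clean_tags_fasta(tags, f)
  expect_equal(readLines(f)[1], ">tag000001|A:3;B:1")
})
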