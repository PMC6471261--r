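test_that("fold maximizes pair weight: frozen enumeration values", {
  # GGGGAAAACCCC: 4 GC pairs, score -12 (verified by exhaustive enumeration)
  f <- mejamir:::fold_nested_cpp("GGGGAAAACCCC", 3L)
  expect_equal(f$score, -12L)
  expect_equal(brute_fold_score("GGGGAAAACCCC"), -12)
  # perfect stem of 10 GC pairs around a 4-nt loop
  f2 <- mejamir:::fold_nested_cpp(paste0(strrep("G", 10), "AAAA",
                                         strrep("C", 10)), 3L)
  expect_equal(length(f2$i), 10L)
  expect_equal(f2$score, -30L)
})

test_that("fold equals brute-force enumeration on random short strings", {
  set.seed(7)
  for (rep in 1:40) {
    s <- random_dna(sample(8:14, 1))
    expect_equal(mejamir:::fold_nested_cpp(s, 3L)$score,
                 brute_fold_score(s), info = s)
  }
})

test_that("fold_window handles degenerate and out-of-range input", {
  expect_equal(fold_window(strrep("A", 50))$score, 0)
  expect_equal(nrow(fold_window(strrep("A", 50))$pairs), 0L)
  expect_error(fold_window("ACGT"), "40")
  expect_error(fold_window(strrep("A", 400)), "320")
})

ref_fixture <- function() {
  set.seed(20240915)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  mature <- tibble::tibble(
    id = c("MIR169-a", "MIR156-a", "MIR166-b"),
    seq = c("TTGAACTCTCTCCCTCATCGC", "TGACAGAAGAGAGTGAGCACA",
            "TCGGACCAGGCTTCATTCCCC"))
  ncrna <- tibble::tibble(id = "rRNA-1",
                          seq = paste0("GGCTAGCTAGGATCCGGATCCTTAACGCGT",
                                       mature$seq[3], "ACGGATGCGCGGCTAA"))
  arm <- "GCGTACGTTAGCCATGCATGG"
  contig <- paste0(random_dna(59), arm, "AATTGG", revcomp(arm),
                   random_dna(253))
  genes <- tibble::tibble(id = c("Unigene1", "Unigene2"),
                          seq = c(contig, random_dna(340)))
  write_fasta(mature, file.path(dir, "mature.fa"))
  write_fasta(ncrna, file.path(dir, "ncrna.fa"))
  write_fasta(genes, file.path(dir, "tx.fa"))
  list(refs = load_reference_set(file.path(dir, "mature.fa"),
                                 file.path(dir, "ncrna.fa"),
                                 file.path(dir, "tx.fa")),
       arm = arm, mature = mature)
}

test_that("classification follows the removal order and tolerances", {
  set.seed(11)
  fx <- ref_fixture()
  two_mm <- fx$mature$seq[1]
  substr(two_mm, 3, 3) <- "A"; substr(two_mm, 7, 7) <- "G"
  three_mm <- two_mm; substr(three_mm, 12, 12) <- "A"
  tags <- tibble::tibble(
    tag_id = sprintf("tag%06d", 1:5),
    seq = c(fx$mature$seq[1],          # exact known match
            fx$mature$seq[3],          # also an rRNA subsequence
            two_mm, three_mm,
            random_dna(24)),           # matches nothing
    L1 = c(5L, 4L, 3L, 2L, 1L))
  ann <- suppressMessages(annotate_tags(tags, fx$refs))$annotations
  expect_equal(ann$category,
               c("known_mirna", "other_ncrna", "known_mirna",
                 "unannotated", "unannotated"))
  expect_equal(ann$family[1], "MIR169")
  expect_equal(ann$mirna_id[3], "MIR169-a")
  # partition: every tag gets exactly one category
  expect_equal(sum(table(ann$category)), nrow(tags))
})

test_that("hairpin screen accepts a planted inverted repeat", {
  fx <- ref_fixture()
  contig <- fx$refs$transcriptome$seq[1]
  res <- screen_novel(fx$arm, contig, 60L)
  expect_true(res$accepted)
  expect_equal(res$star_seq, revcomp(fx$arm))
  expect_equal(res$arm, "5p")
  expect_gte(res$paired, 14)
  expect_lte(res$score, -18)
})

test_that("hairpin screen rejects unstructured and loop-straddling tags", {
  set.seed(5)
  fx <- ref_fixture()
  flat <- random_dna(340)
  res <- screen_novel(substr(flat, 100, 120), flat, 100L)
  expect_false(res$accepted)
  # tag centred on the loop pairs with both arms -> arm-rule violation
  contig <- fx$refs$transcriptome$seq[1]
  straddle <- substr(contig, 70, 90)   # spans arm end, loop, star start
  res2 <- screen_novel(straddle, contig, 70L)
  expect_false(res2$accepted)
  expect_equal(res2$reason, "arm")
  # contig too short for either window
  expect_equal(screen_novel(fx$arm, substr(contig, 55, 100), 6L)$reason,
               "no-window")
})

test_that("novel candidates emerge from the cascade with stable ids", {
  fx <- ref_fixture()
  tags <- tibble::tibble(tag_id = "tag000001", seq = fx$arm, L1 = 3L)
  out <- suppressMessages(annotate_tags(tags, fx$refs))
  expect_equal(out$annotations$category, "novel_candidate")
  expect_match(out$annotations$mirna_id, "^novel-m0001-5p$")
  expect_equal(nrow(out$hairpins), 1L)
})
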