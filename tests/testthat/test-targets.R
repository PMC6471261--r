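test_that("site alignment classifies pairs and scores wobbles as half", {
  mir <- "TTGACAGAAGAGAGTGAGCAC"
  aln <- align_site(mir, revcomp(mir))
  expect_true(all(aln$states == "wc"))
  expect_equal(aln$score, 0)

  # one G:U at miRNA position 5 (miRNA C->target G kept, make miRNA G face T)
  mir2 <- "AAAAGAAAAAAAAAAAAAAAA"
  win <- strsplit(revcomp(mir2), "")[[1]]
  win[nchar(mir2) - 5 + 1] <- "T"
  aln2 <- align_site(mir2, paste(win, collapse = ""))
  expect_equal(aln2$states[5], "gu")
  expect_equal(aln2$score, 0.5)

  win3 <- strsplit(revcomp(mir), "")[[1]]
  # miRNA bases at 3, 6, 14, 17, 20 are all non-T, so facing an A is a
  # full mismatch at each position
  for (i in c(3, 6, 14, 17, 20)) win3[nchar(mir) - i + 1] <- "A"
  aln3 <- align_site(mir, paste(win3, collapse = ""))
  expect_equal(aln3$score, 5)
  expect_error(align_site("ACGT", "ACGTA"), "length")
})

test_that("rule checks reproduce the worked verdicts", {
  mir <- strrep("G", 22)
  perfect <- fake_aln(mir, rep("wc", 22))
  v <- check_rules(perfect)
  expect_true(v$pass)
  expect_equal(v$ratio, 1)

  st <- rep("wc", 22); st[10] <- "mismatch"; st[14] <- "mismatch"
  expect_equal(check_rules(fake_aln(mir, st))$rule, "rule2")

  # G:U at 3,5,7,9,12 plus a mismatch at 20: total 3.5, core 2.5 -> pass
  st2 <- rep("wc", 22); st2[c(3, 5, 7, 9, 12)] <- "gu"; st2[20] <- "mismatch"
  v2 <- check_rules(fake_aln(mir, st2))
  expect_true(v2$pass)
  expect_equal(v2$score, 3.5)

  st3 <- rep("wc", 22); st3[18:20] <- "mismatch"
  expect_equal(check_rules(fake_aln(mir, st3))$rule, "rule1")

  # a G:U inside 10-11 violates the stringent core rule
  st4 <- rep("wc", 22); st4[11] <- "gu"
  expect_equal(check_rules(fake_aln(mir, st4))$rule, "rule2")
})

test_that("surrogate energies follow the additive model", {
  mir <- strrep("G", 22)
  expect_equal(perfect_energy(mir), -66)
  aln <- fake_aln(mir, rep("wc", 22))
  expect_equal(duplex_energy(aln), -66)
  st <- rep("wc", 22); st[5] <- "mismatch"
  expect_equal(duplex_energy(fake_aln(mir, st)), -62)  # +3 lost pair, +1 open
  expect_equal(check_rules(fake_aln(mir, st))$ratio, 62 / 66)
  # every single-position degradation makes the energy less negative
  set.seed(8)
  for (i in 1:20) {
    m <- random_dna(21)
    st0 <- sample(c("wc", "wc", "gu"), 21, replace = TRUE)
    e0 <- duplex_energy(fake_aln(m, st0))
    j <- sample(which(st0 != "mismatch"), 1)
    st1 <- st0
    st1[j] <- if (st0[j] == "wc") sample(c("gu", "mismatch"), 1) else "mismatch"
    expect_gt(duplex_energy(fake_aln(m, st1)), e0)
  }
})

test_that("rule verdicts agree with the literal evaluator", {
  set.seed(19)
  for (i in 1:2000) {
    L <- sample(18:24, 1)
    st <- sample(c("wc", "gu", "mismatch"), L, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
    mir <- random_dna(L)
    aln <- fake_aln(mir, st)
    got <- check_rules(aln)
    want <- literal_rules(st, duplex_energy(aln), perfect_energy(mir))
    expect_equal(ifelse(got$pass, "pass", got$rule), want,
                 info = paste(st, collapse = ","))
  }
})

test_that("perfect complements pass for every miRNA length 18-26", {
  set.seed(23)
  for (L in 18:26) {
    mir <- random_dna(L)
    aln <- align_site(mir, revcomp(mir))
    expect_true(check_rules(aln)$pass, info = mir)
  }
})

test_that("transcriptome scan recovers planted sites and picks best ones", {
  set.seed(37)
  mir <- "TGACAGAAGAGAGTGAGCACA"
  L <- nchar(mir)
  site <- revcomp(mir)
  gu_site <- strsplit(site, "")[[1]]
  i <- which(strsplit(mir, "")[[1]] %in% c("G", "T") &
               !(seq_len(L) %in% 10:11))[3]
  gu_site[L - i + 1] <- c(G = "T", T = "G")[substr(mir, i, i)]
  tx <- tibble::tibble(
    id = c("gene1", "gene2"),
    seq = c(paste0(random_dna(50), site, random_dna(50)),
            paste0(random_dna(20), paste(gu_site, collapse = ""),
                   random_dna(30), site, random_dna(20))))
  hits <- suppressMessages(
    scan_transcriptome(tibble::tibble(mirna_id = "mirX", seq = mir), tx))
  expect_equal(nrow(hits), 2L)
  g1 <- hits[hits$gene_id == "gene1", ]
  expect_equal(c(g1$site_start, g1$site_end), c(51L, 50L + L))
  expect_equal(g1$score, 0)
  # two sites in gene2 (scores 0.5 and 0): the score-0 site is reported
  expect_equal(hits$score[hits$gene_id == "gene2"], 0)
  # a shuffled transcript yields nothing for an unrelated 22-mer
  none <- suppressMessages(scan_transcriptome(
    tibble::tibble(mirna_id = "m", seq = random_dna(22)),
    tibble::tibble(id = "g", seq = random_dna(500))))
  expect_equal(nrow(none), 0L)
})

test_that("anti-correlation pairing applies both thresholds", {
  libs <- default_sample_sheet()$library_id
  z <- c(5, 9, 2, 7, 4, 8, 1, 6)
  mirna_tpm <- tibble::tibble(mirna_id = c("m1", "m2"))
  mrna <- tibble::tibble(gene_id = c("g1", "g2"))
  for (k in seq_along(libs)) {
    mirna_tpm[[libs[k]]] <- c(z[k], z[k])
    mrna[[libs[k]]] <- c(20 - z[k], z[k])
  }
  pairs <- tibble::tibble(mirna_id = c("m1", "m2"),
                          gene_id = c("g1", "g2"),
                          site_start = 1L, site_end = 21L, score = 0,
                          e_dup = -50, e_perf = -50, ratio = 1)
  out <- anti_correlate(pairs, mirna_tpm, mrna)
  expect_equal(out$r, c(-1, 1))
  expect_equal(out$anti_correlated, c(TRUE, FALSE))
})

test_that("r = -0.5 at n = 8 fails both anti-correlation conditions", {
  # frozen from the t-distribution tail: p = 0.2070 at r = -0.5, df = 6
  r <- -0.5
  t <- r * sqrt(6) / sqrt(1 - r^2)
  expect_equal(2 * pt(t, 6), 0.20703125, tolerance = 1e-6)
  libs <- default_sample_sheet()$library_id
  # build vectors with sample correlation exactly -0.5
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  xs <- (x - mean(x)) / sd(x)
  e <- c(1, -1, 1, -1, 1, -1, 1, -1)
  es <- resid(lm(e ~ xs)); es <- es / sd(es)
  y <- -0.5 * xs + sqrt(1 - 0.25) * es
  expect_equal(cor(x, y), -0.5, tolerance = 1e-12)
  mirna_tpm <- tibble::tibble(mirna_id = "m1")
  mrna <- tibble::tibble(gene_id = "g1")
  for (k in seq_along(libs)) {
    mirna_tpm[[libs[k]]] <- x[k]
    mrna[[libs[k]]] <- y[k] + 10
  }
  pairs <- tibble::tibble(mirna_id = "m1", gene_id = "g1",
                          site_start = 1L, site_end = 21L, score = 0,
                          e_dup = -50, e_perf = -50, ratio = 1)
  out <- anti_correlate(pairs, mirna_tpm, mrna)
  expect_false(out$anti_correlated)
  expect_equal(out$p_cor, 0.20703125, tolerance = 1e-6)
})

test_that("zero-variance expression drops the pair with a log message", {
  libs <- default_sample_sheet()$library_id
  mirna_tpm <- tibble::tibble(mirna_id = "m1")
  mrna <- tibble::tibble(gene_id = "g1")
  for (k in seq_along(libs)) {
    mirna_tpm[[libs[k]]] <- 5
    mrna[[libs[k]]] <- k
  }
  pairs <- tibble::tibble(mirna_id = "m1", gene_id = "g1",
                          site_start = 1L, site_end = 21L, score = 0,
                          e_dup = -50, e_perf = -50, ratio = 1)
  expect_message(out <- anti_correlate(pairs, mirna_tpm, mrna),
                 "zero variance")
  expect_equal(nrow(out), 0L)
})
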