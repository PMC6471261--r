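test_that("exact-test mass matches its closed forms", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_probability(5, 0, 1e6, 1e6), 2^-6)
  expect_error(ac_probability(-1, 0, 1, 1), ">= 0")
  expect_error(ac_probability(0, 0, 0, 1), "> 0")
})

test_that("masses sum to one over y for a range of x and library ratios", {
  for (ratio in list(c(1e6, 1e6), c(1e6, 2e6), c(3e6, 1e6))) {
    for (x in c(0, 1, 10, 50)) {
      s <- sum(ac_probability(x, 0:5000, ratio[1], ratio[2]))
      expect_equal(s, 1, tolerance = 1e-9)
    }
  }
})

test_that("p-values match the recurrence oracle and behave at the edges", {
  expect_equal(ac_pvalue(7, 7, 1e6, 1e6), 1)           # symmetric point
  expect_lt(ac_pvalue(0, 20, 1e6, 1e6), 1e-4)
  set.seed(31)
  for (i in 1:50) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    N1 <- sample(c(1e5, 1e6, 3e6), 1); N2 <- sample(c(1e5, 1e6, 2e6), 1)
    got <- ac_pvalue(x, y, N1, N2)
    want <- ac_oracle(x, y, N1, N2)
    expect_equal(got, want, tolerance = 1e-9, info = paste(x, y, N1, N2))
    expect_gt(got, 0); expect_lte(got, 1)
  }
})

test_that("swapping libraries changes the p-value by at most the point mass", {
  set.seed(12)
  for (i in 1:25) {
    x <- sample(0:80, 1); y <- sample(0:80, 1)
    N1 <- sample(c(1e6, 2e6), 1); N2 <- sample(c(1e6, 3e6), 1)
    a <- ac_pvalue(x, y, N1, N2)
    b <- ac_pvalue(y, x, N2, N1)
    bound <- 2 * max(ac_probability(x, y, N1, N2),
                     ac_probability(y, x, N2, N1))
    expect_lte(abs(a - b), bound + 1e-12)
  }
})

test_that("p-value is monotone in the departure from the expected ratio", {
  for (x in c(3, 25)) {
    # unimodal in y around the expected ratio (peak within a step of
    # x N2/N1; the exact argmax is where the two discrete tails cross)
    ys <- 0:120
    p <- ac_pvalue(rep(x, length(ys)), ys, 1e6, 2e6)
    peak <- which.max(p)
    expect_lte(abs(ys[peak] - 2 * x), 1)
    expect_true(all(diff(p[peak:length(p)]) <= 1e-12))
    expect_true(all(diff(p[1:peak]) >= -1e-12))
  }
})

toy_de_expr <- function(tpm_a, tpm_b, count_a = tpm_a, count_b = tpm_b,
                        total = 1e6) {
  ss <- default_sample_sheet()
  counts <- tibble::tibble(mirna_id = "m1", family = "F",
                           category = "known_mirna")
  tpm_tbl <- counts
  for (l in ss$library_id) {
    tp <- ss$timepoint[ss$library_id == l]
    counts[[l]] <- as.integer(if (tp == "CK") count_a else count_b)
    tpm_tbl[[l]] <- if (tp == "CK") tpm_a else tpm_b
  }
  list(counts = counts, tpm = tpm_tbl,
       totals = setNames(rep(total, 8), ss$library_id))
}

test_that("DEM calls apply fold-change and p-value thresholds jointly", {
  ex <- toy_de_expr(10, 40)
  de <- suppressMessages(call_dems(ex, c("CK", "T1")))
  expect_equal(de$log2fc, 2, tolerance = 1e-3)
  expect_equal(de$direction, "up")
  expect_true(de$significant)     # counts are large, p is tiny

  weak <- toy_de_expr(10, 15, count_a = 10000, count_b = 15000)
  de2 <- suppressMessages(call_dems(weak, c("CK", "T1")))
  expect_lt(de2$pvalue, 0.05)     # plenty of evidence ...
  expect_false(de2$significant)   # ... but |log2FC| < 1 blocks the call
  expect_error(suppressMessages(call_dems(ex, c("CK", "T9"))), "unknown")
})

test_that("up and down counts partition the significant set", {
  set.seed(101)
  ss <- default_sample_sheet()
  n <- 80
  counts <- tibble::tibble(mirna_id = sprintf("m%03d", 1:n),
                           family = "F", category = "known_mirna")
  tpm_tbl <- counts
  mu <- 200 * c(rep(1, 40), rep(4, 20), rep(0.25, 20))
  for (l in ss$library_id) {
    tp <- ss$timepoint[ss$library_id == l]
    m <- if (tp == "CK") rep(200, n) else mu
    counts[[l]] <- rpois(n, m)
    tpm_tbl[[l]] <- counts[[l]] * 5
  }
  ex <- list(counts = counts, tpm = tpm_tbl,
             totals = setNames(rep(2e5, 8), ss$library_id))
  de <- suppressMessages(call_all_dems(ex))
  g <- glance(de)
  expect_equal(g$n_up + g$n_down, g$n_significant)
  expect_equal(nrow(g), 6L)       # all six pairwise comparisons
})

test_that("type-I error is near nominal under the statistic's own model", {
  set.seed(77)
  n <- 4000
  mu <- 150
  x <- rpois(n, 2 * mu); y <- rpois(n, 2 * mu)   # replicate-summed nulls
  p <- ac_pvalue(x, y, 2e6, 2e6)
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(rate, 0.05 + 2 * se)
})
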