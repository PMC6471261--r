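#' Exact two-library count probability
#'
#' Probability of observing `y` tags in library 2 given `x` in library 1
#' under equal underlying rates, for library sizes `N1`, `N2`:
#' p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)).
#' Computed in log space via log-gamma; for fixed `x` the masses over
#' y = 0, 1, ... sum to 1.
#'
#' @param x,y Non-negative integer counts (`y` may be a vector).
#' @param N1,N2 Positive library totals.
#' @returns Probability mass(es).
#' @export
ac_probability <- function(x, y, N1, N2) {
  if (any(c(x, y) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(c(N1, N2) <= 0)) stop("library totals must be > 0", call. = FALSE)
  lr <- log(N2) - log(N1)
  exp(y * lr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(exp(lr)))
}

#' Exact-test p-value for a library pair
#'
#' Lower tail C = sum over y' <= y of p(y'|x), upper tail
#' D = sum over y' >= y of p(y'|x); the two-sided p-value is 2 min(C, D),
#' capped at 1. Both tails are summed directly (the upper tail out past
#' the distribution's bulk), which keeps extreme p-values accurate where
#' computing D as 1 - C would cancel catastrophically.
#'
#' @inheritParams ac_probability
#' @returns p-value in (0, 1]. Vectorized over `x`/`y` pairs.
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  stopifnot(length(x) == length(y))
  purrr::map2_dbl(x, y, function(xi, yi) {
    C <- sum(ac_probability(xi, 0:yi, N1, N2))
    r <- N2 / N1
    mode <- (xi + 1) * r         # bulk of p(.|x) sits near x N2/N1
    # the far tail decays geometrically with ratio r/(1+r); allow enough
    # terms that the truncated remainder is far below double precision
    upper <- ceiling(max(yi, mode) + 20 * sqrt(mode + yi + 1) +
                       60 * (1 + r) + 100)
    D <- sum(ac_probability(xi, yi:upper, N1, N2))
    min(1, 2 * min(C, D))
  })
}

#' Call differentially expressed miRNAs between two timepoints
#'
#' Fold change is computed on group-mean TPM with a pseudocount on both
#' sides; the p-value comes from the exact two-library statistic on
#' replicate-summed counts with summed library totals. A miRNA is
#' significant iff |log2 fold change| >= log2(`fold_change`) and
#' p < `de_p`.
#'
#' @param expr List from [expression_matrix()] (`counts`, `tpm`, `totals`).
#' @param comparison Length-2 character vector of timepoint labels,
#'   reference first, e.g. `c("CK", "T1")`.
#' @param sample_sheet Sample sheet mapping libraries to timepoints.
#' @param fold_change,de_p Significance thresholds.
#' @param pseudocount TPM pseudocount guarding against zeros.
#' @returns Tibble of class `mejamir_dem`: `mirna_id`, `comparison`,
#'   `mean_tpm_a`, `mean_tpm_b`, `log2fc` (B relative to A), `pvalue`,
#'   `direction`, `significant`.
#' @export
call_dems <- function(expr, comparison, sample_sheet = default_sample_sheet(),
                      fold_change = 2, de_p = 0.05, pseudocount = 0.01) {
  stopifnot(length(comparison) == 2)
  bad <- setdiff(comparison, sample_sheet$timepoint)
  if (length(bad)) stop("unknown group label: ", bad[1], call. = FALSE)
  libs_a <- sample_sheet$library_id[sample_sheet$timepoint == comparison[1]]
  libs_b <- sample_sheet$library_id[sample_sheet$timepoint == comparison[2]]

  cnt <- expr$counts
  x <- rowSums(as.matrix(cnt[libs_a]))
  y <- rowSums(as.matrix(cnt[libs_b]))
  N1 <- sum(expr$totals[libs_a])
  N2 <- sum(expr$totals[libs_b])
  mean_a <- rowMeans(as.matrix(expr$tpm[libs_a]))
  mean_b <- rowMeans(as.matrix(expr$tpm[libs_b]))
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  pval <- ac_pvalue(x, y, N1, N2)
  out <- tibble::tibble(
    mirna_id = cnt$mirna_id,
    comparison = paste0(comparison[1], "-VS-", comparison[2]),
    mean_tpm_a = mean_a, mean_tpm_b = mean_b,
    log2fc = log2fc, pvalue = pval,
    direction = ifelse(log2fc >= 0, "up", "down"),
    significant = abs(log2fc) >= log2(fold_change) & pval < de_p
  )
  log_stage("diffexpr", out$comparison[1] %||% "", ": ",
            sum(out$significant), "/", nrow(out), " significant")
  class(out) <- c("mejamir_dem", class(out))
  out
}

#' All six pairwise timepoint comparisons
#'
#' @inheritParams call_dems
#' @returns A single `mejamir_dem` tibble stacking CK-VS-T1 ... T2-VS-T3.
#' @export
call_all_dems <- function(expr, sample_sheet = default_sample_sheet(), ...) {
  tps <- TIMEPOINTS
  combos <- utils::combn(tps, 2, simplify = FALSE)
  out <- dplyr::bind_rows(lapply(combos, function(cc) {
    call_dems(expr, cc, sample_sheet = sample_sheet, ...)
  }))
  class(out) <- c("mejamir_dem", class(out))
  out
}

#' @export
tidy.mejamir_dem <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.mejamir_dem <- function(x, ...) {
  x |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_significant = sum(.data$significant),
      n_up = sum(.data$significant & .data$direction == "up"),
      n_down = sum(.data$significant & .data$direction == "down"),
      .groups = "drop")
}
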