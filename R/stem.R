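#' Enumerate short-time-series model profiles
#'
#' Candidate profiles over the four timepoints start at 0 and take integer
#' steps in \[-c, c\] between successive points, giving (2c+1)^3 candidates.
#' `k` representatives are chosen by greedy maximin Euclidean distance,
#' seeded with the flat profile; candidate order (and hence every
#' tie-break) is the nested enumeration order of the step triples.
#'
#' @param c Maximum absolute unit step between timepoints.
#' @param k Number of representative profiles.
#' @returns Tibble `profile_id` (0-based, selection order; flat = 0),
#'   `v1`-`v4` (profile values).
#' @export
enumerate_profiles <- function(c = 2L, k = 20L) {
  stopifnot(c >= 1, k >= 1, k <= (2 * c + 1)^3)
  steps <- expand.grid(d3 = -c:c, d2 = -c:c, d1 = -c:c)  # d1 varies slowest
  cand <- cbind(0, steps$d1, steps$d1 + steps$d2,
                steps$d1 + steps$d2 + steps$d3)
  flat <- which(rowSums(abs(cand)) == 0)[1]
  chosen <- flat
  dmin <- sqrt(rowSums(sweep(cand, 2, cand[flat, ])^2))
  while (length(chosen) < k) {
    nxt <- which.max(dmin)  # ties: first (enumeration order)
    chosen <- c(chosen, nxt)
    d <- sqrt(rowSums(sweep(cand, 2, cand[nxt, ])^2))
    dmin <- pmin(dmin, d)
  }
  sel <- cand[chosen, , drop = FALSE]
  tibble::tibble(profile_id = seq_along(chosen) - 1L,
                 v1 = sel[, 1], v2 = sel[, 2], v3 = sel[, 3], v4 = sel[, 4])
}

#' @rdname enumerate_profiles
#' @returns `candidate_profiles()`: all (2c+1)^3 candidate value vectors.
#' @export
candidate_profiles <- function(c = 2L) {
  steps <- expand.grid(d3 = -c:c, d2 = -c:c, d1 = -c:c)
  cbind(0, steps$d1, steps$d1 + steps$d2, steps$d1 + steps$d2 + steps$d3)
}

# Pearson correlation of each row of X against each profile row; rows or
# profiles with zero variance yield NA.
profile_correlation <- function(X, P) {
  Xc <- X - rowMeans(X)
  Pc <- P - rowMeans(P)
  xs <- sqrt(rowSums(Xc^2))
  ps <- sqrt(rowSums(Pc^2))
  R <- (Xc %*% t(Pc)) / outer(xs, ps)
  R[!is.finite(R)] <- NA
  R
}

assign_to_profiles <- function(V, profiles) {
  P <- as.matrix(profiles[c("v1", "v2", "v3", "v4")])
  R <- profile_correlation(V, P)
  flat_id <- profiles$profile_id[rowSums(abs(P)) == 0][1]
  best <- apply(R, 1, function(r) {
    if (all(is.na(r))) return(NA_integer_)
    which(r == max(r, na.rm = TRUE))[1]  # ties: smaller profile id
  })
  pid <- profiles$profile_id[best]
  pid[is.na(pid)] <- flat_id  # zero-variance genes: flat by convention
  corr <- R[cbind(seq_len(nrow(V)), ifelse(is.na(best), 1L, best))]
  corr[is.na(best)] <- NA_real_
  list(profile_id = pid, correlation = corr)
}

#' Assign miRNA temporal vectors to model profiles
#'
#' Expression is transformed to log2(TPM_t / TPM_CK) (pseudocount added),
#' so every standardized vector starts at 0, and each miRNA is assigned to
#' the profile with maximal Pearson correlation (ties to the smaller
#' profile id; zero-variance vectors go to the flat profile).
#'
#' @param tpm_by_timepoint Tibble: `mirna_id` plus columns CK, T1, T2, T3
#'   of (replicate-mean) TPM.
#' @param profiles From [enumerate_profiles()].
#' @param pseudocount TPM pseudocount.
#' @returns Tibble `mirna_id`, `v1`-`v4` (standardized vector),
#'   `profile_id`, `correlation`.
#' @export
stem_assign <- function(tpm_by_timepoint, profiles = enumerate_profiles(),
                        pseudocount = 0.01) {
  M <- as.matrix(tpm_by_timepoint[TIMEPOINTS])
  V <- log2(M + pseudocount) - log2(M[, 1] + pseudocount)
  a <- assign_to_profiles(V, profiles)
  tibble::tibble(mirna_id = tpm_by_timepoint$mirna_id,
                 v1 = V[, 1], v2 = V[, 2], v3 = V[, 3], v4 = V[, 4],
                 profile_id = a$profile_id, correlation = a$correlation)
}

#' Permutation significance of profile occupancy
#'
#' The null permutes each gene's four timepoint values independently and
#' re-assigns the re-referenced vector, estimating how many genes a
#' profile attracts by chance; p = P(permuted count >= observed) with the
#' +1 small-sample correction. Profiles with p <= `alpha` are flagged.
#'
#' @param assignments From [stem_assign()].
#' @param profiles From [enumerate_profiles()].
#' @param n_permutations Number of permutation rounds (>= 1).
#' @param seed RNG seed (local to this computation).
#' @param alpha Significance level for the flag.
#' @returns Tibble `profile_id`, `v1`-`v4`, `n_assigned`, `expected`,
#'   `p_value`, `significant`, sorted by p then id.
#' @export
profile_significance <- function(assignments, profiles = enumerate_profiles(),
                                 n_permutations = 1000L, seed = 1L,
                                 alpha = 0.02) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  V <- as.matrix(assignments[c("v1", "v2", "v3", "v4")])
  ng <- nrow(V)
  obs <- table(factor(assignments$profile_id, levels = profiles$profile_id))
  counts <- matrix(0L, n_permutations, nrow(profiles))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    for (b in seq_len(n_permutations)) {
      idx <- vapply(seq_len(ng), function(i) sample.int(4L), integer(4))
      Vp <- matrix(V[cbind(rep(seq_len(ng), each = 4), as.vector(idx))],
                   ncol = 4, byrow = TRUE)
      Vp <- Vp - Vp[, 1]
      a <- assign_to_profiles(Vp, profiles)
      counts[b, ] <- as.integer(table(factor(a$profile_id,
                                             levels = profiles$profile_id)))
    }
  })
  pv <- vapply(seq_along(obs), function(j) {
    (1 + sum(counts[, j] >= obs[j])) / (n_permutations + 1)
  }, numeric(1))
  out <- profiles |>
    dplyr::mutate(n_assigned = as.integer(obs),
                  expected = colMeans(counts),
                  p_value = pv,
                  significant = pv <= alpha) |>
    dplyr::arrange(.data$p_value, .data$profile_id)
  out
}

#' Full profile-clustering stage for differentially expressed miRNAs
#'
#' @param expr List from [expression_matrix()].
#' @param dems `mejamir_dem` tibble; miRNAs significant in any comparison
#'   are clustered.
#' @param sample_sheet Sample sheet.
#' @param n_permutations,seed,alpha See [profile_significance()].
#' @param c,k Profile enumeration parameters.
#' @returns List of class `mejamir_stem`: `profiles` (with significance),
#'   `assignments`.
#' @export
stem_profiles <- function(expr, dems, sample_sheet = default_sample_sheet(),
                          n_permutations = 1000L, seed = 1L, alpha = 0.02,
                          c = 2L, k = 20L) {
  dem_ids <- unique(dems$mirna_id[dems$significant])
  tp_means <- purrr::map(TIMEPOINTS, function(tp) {
    libs <- sample_sheet$library_id[sample_sheet$timepoint == tp]
    rowMeans(as.matrix(expr$tpm[libs]))
  })
  tbl <- tibble::tibble(mirna_id = expr$tpm$mirna_id) |>
    dplyr::bind_cols(setNames(tp_means, TIMEPOINTS)) |>
    dplyr::filter(.data$mirna_id %in% dem_ids)
  prof <- enumerate_profiles(c = c, k = k)
  assignments <- stem_assign(tbl, prof)
  sig <- profile_significance(assignments, prof,
                              n_permutations = n_permutations,
                              seed = seed, alpha = alpha)
  log_stage("stem", nrow(assignments), " DEMs clustered; ",
            sum(sig$significant), " significant profiles")
  structure(list(profiles = sig, assignments = assignments),
            class = "mejamir_stem")
}

#' @export
tidy.mejamir_stem <- function(x, ...) x$assignments

#' @export
glance.mejamir_stem <- function(x, ...) {
  tibble::tibble(n_clustered = nrow(x$assignments),
                 n_profiles = nrow(x$profiles),
                 n_significant = sum(x$profiles$significant))
}
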