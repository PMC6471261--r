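# Independent oracles used to freeze expected values. Each one deliberately
# takes a different computational path from the implementation it checks.

# Maximum pair weight over ALL nested structures (explicit recursion, no
# memoisation): exhaustive for short strings.
brute_fold_score <- function(seq, min_loop = 3) {
  ch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  pw <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
    0
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      w <- pw(ch[i], ch[k])
      if (w > 0) {
        cand <- w + (if (k > i + 1) rec(i + 1, k - 1) else 0) +
          (if (k < j) rec(k + 1, j) else 0)
        if (cand > best) best <- cand
      }
    }
    best
  }
  -rec(1, length(ch))
}

# Tail sums of the exact two-library statistic via the mass recurrence
# p(y|x) / p(y-1|x) = r (x+y) / (y (1+r)), seeded at
# p(0|x) = (1+r)^-(x+1) and accumulated in log space so that mid-range
# masses survive even when the seed would underflow; avoids the
# log-gamma route entirely.
ac_oracle <- function(x, y, N1, N2) {
  r <- N2 / N1
  upper <- ceiling(max(y, (x + 1) * r) + 20 * sqrt((x + 1) * r + y + 1) +
                     80 * (1 + r) + 200)
  yy <- seq_len(upper)
  lp <- cumsum(c(-(x + 1) * log1p(r),
                 log(r) + log(x + yy) - log(yy) - log1p(r)))
  C <- sum(exp(lp[1:(y + 1)]))
  D <- sum(exp(lp[(y + 1):(upper + 1)]))
  min(1, 2 * min(C, D))
}

# Hypergeometric upper tail summed directly (the implementation subtracts
# the lower tail from 1 instead).
hyper_oracle <- function(N, n, M, m) {
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# Literal re-evaluation of the four target-prediction rules, written as
# plain loops straight from the rule statements.
literal_rules <- function(states, e_dup, e_perf, mfe_ratio = 0.74,
                          max_mismatch = 4) {
  L <- length(states)
  w <- numeric(L)
  for (i in seq_len(L)) {
    w[i] <- switch(states[i], mismatch = 1, gu = 0.5, wc = 0)
  }
  score <- sum(w)
  # rule 1: total <= 4 and no more than two adjacent full mismatches
  run <- 0
  max_run <- 0
  for (i in seq_len(L)) {
    run <- if (states[i] == "mismatch") run + 1 else 0
    max_run <- max(max_run, run)
  }
  if (score > max_mismatch || max_run > 2) return("rule1")
  # rule 2: no adjacent non-WC pair with combined weight > 1 in 2-12;
  # positions 10-11 strictly Watson-Crick
  for (i in 2:min(11, L - 1)) {
    if (i + 1 <= 12 && w[i] + w[i + 1] > 1) return("rule2")
  }
  for (i in intersect(10:11, seq_len(L))) {
    if (states[i] != "wc") return("rule2")
  }
  # rule 3: at most 2.5 over positions 1-12
  if (sum(w[1:min(12, L)]) > 2.5) return("rule3")
  # rule 4: duplex energy at least 74% of the perfect-complement energy
  if (abs(e_dup) / abs(e_perf) < mfe_ratio) return("rule4")
  "pass"
}

# independent position-state classification for random duplex configs
classify_oracle <- function(mirna, window) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(mirna, "")[[1]]
  w <- strsplit(window, "")[[1]]
  L <- length(m)
  out <- character(L)
  for (i in seq_len(L)) {
    b <- w[L - i + 1]
    out[i] <- if (comp[[m[i]]] == b) "wc"
    else if ((m[i] == "G" && b == "T") || (m[i] == "T" && b == "G")) "gu"
    else "mismatch"
  }
  out
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a duplex_alignment built directly from a state vector (for rule tests
# that do not need a real window)
fake_aln <- function(mirna, states) {
  structure(list(mirna = mirna, window = NA_character_, states = states,
                 score = mismatch_score(states)),
            class = "duplex_alignment")
}

# small-but-complete synthesis configuration for fast end-to-end tests
small_synth_config <- function(seed = 1L, ...) {
  synth_config(seed = seed, depth = 4000, n_mirnas = 40, n_families = 12,
               n_novel = 4, n_ncrna = 6, n_ncrna_frags = 8,
               n_mrna_frags = 6, n_genes = 60, n_filler = 30,
               n_pass_perfect = 5, n_pass_gu = 5, n_fail_rule2 = 3,
               n_fail_rule1 = 3, n_anticorr = 6, n_pathways = 10,
               n_go_terms = 12, n_qpcr_assays = 5, ...)
}
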