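dna <- function(x) chartr("U", "T", toupper(x))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement (DNA alphabet)
#' @param x Character vector of sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(dna(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Align a miRNA against a same-length target window
#'
#' Ungapped antiparallel duplex: miRNA position i (1 = miRNA 5' end) pairs
#' with window position L - i + 1 on the mRNA sense strand. Each position
#' is Watson-Crick (`wc`), G:U wobble (`gu`) or `mismatch`; the mismatch
#' score is #mismatch + 0.5 #gu.
#'
#' @param mirna,window Equal-length sequences over A/C/G/T/U.
#' @returns List of class `duplex_alignment`: `mirna`, `window`, `states`
#'   (character vector along miRNA positions), `score`.
#' @export
align_site <- function(mirna, window) {
  mirna <- dna(mirna); window <- dna(window)
  if (nchar(mirna) != nchar(window)) {
    stop("miRNA and window lengths differ", call. = FALSE)
  }
  m <- strsplit(mirna, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])
  states <- ifelse(COMPLEMENT[m] == w, "wc",
                   ifelse((m == "G" & w == "T") | (m == "T" & w == "G"),
                          "gu", "mismatch"))
  structure(list(mirna = mirna, window = window, states = unname(states),
                 score = mismatch_score(states)),
            class = "duplex_alignment")
}

#' @rdname align_site
#' @param states Position-state vector (`wc`/`gu`/`mismatch`).
#' @export
mismatch_score <- function(states) {
  sum(states == "mismatch") + 0.5 * sum(states == "gu")
}

#' Surrogate duplex energies
#'
#' Additive per-position model: GC pair -3, AU pair -2, G:U pair -1,
#' mismatch 0 plus a +1 opening penalty per maximal mismatch run. This is
#' an explicit surrogate, not a nearest-neighbour thermodynamic model; the
#' criterion it feeds is the |E_dup| / |E_perf| ratio, for which only
#' monotone degradation matters. `energy_fn` hooks in [check_rules()] and
#' [scan_transcriptome()] allow an external folding engine instead.
#'
#' @param aln A `duplex_alignment`.
#' @returns `duplex_energy()`: E_dup (<= 0 for any site that can pass the
#'   rules); `perfect_energy()`: E_perf of the miRNA bound to its perfect
#'   complement.
#' @export
duplex_energy <- function(aln) {
  m <- strsplit(aln$mirna, "")[[1]]
  w <- ifelse(aln$states == "wc",
              ifelse(m %in% c("G", "C"), -3, -2),
              ifelse(aln$states == "gu", -1, 0))
  runs <- rle(aln$states == "mismatch")
  sum(w) + sum(runs$values)  # +1 per maximal mismatch run
}

#' @rdname duplex_energy
#' @param mirna miRNA sequence.
#' @export
perfect_energy <- function(mirna) {
  m <- strsplit(dna(mirna), "")[[1]]
  sum(ifelse(m %in% c("G", "C"), -3, -2))
}

#' Evaluate the plant target-prediction rules on a duplex
#'
#' Rules, in order, positions 1-based from the miRNA 5' end:
#' 1. at most `max_mismatch` total mismatch score (G:U = 0.5) and no run
#'    of more than two adjacent full mismatches;
#' 2. within positions 2-12, no two adjacent positions whose combined
#'    weight exceeds 1.0 (i.e. no adjacent pair involving a full mismatch
#'    and another non-Watson-Crick position; adjacent G:U + G:U is
#'    allowed), and positions 10-11 must both be Watson-Crick (a G:U there
#'    counts as a violation under the stringent reading);
#' 3. at most 2.5 mismatch score over positions 1-12;
#' 4. |E_dup| >= `mfe_ratio` x |E_perf|.
#' The first violated rule is reported.
#'
#' @param aln A `duplex_alignment` (or a bare state vector via `states`).
#' @param mfe_ratio Energy-ratio threshold.
#' @param max_mismatch Total mismatch-score cap.
#' @param energy_fn,perfect_fn Energy model hooks.
#' @returns List `pass` (logical), `rule` (first violated, NA when pass),
#'   `score`, `e_dup`, `e_perf`, `ratio`.
#' @export
check_rules <- function(aln, mfe_ratio = 0.74, max_mismatch = 4,
                        energy_fn = duplex_energy,
                        perfect_fn = perfect_energy) {
  st <- aln$states
  n <- length(st)
  score <- mismatch_score(st)
  e_dup <- energy_fn(aln)
  e_perf <- perfect_fn(aln$mirna)
  ratio <- abs(e_dup) / abs(e_perf)
  fail <- function(rule) list(pass = FALSE, rule = rule, score = score,
                              e_dup = e_dup, e_perf = e_perf, ratio = ratio)
  mm <- st == "mismatch"
  runs <- rle(mm)
  if (score > max_mismatch || any(runs$lengths[runs$values] > 2)) {
    return(fail("rule1"))
  }
  w <- ifelse(mm, 1, ifelse(st == "gu", 0.5, 0))
  core <- 2:min(12, n)
  adj <- head(core, -1)
  if (length(adj) && any(w[adj] + w[adj + 1] > 1.0)) return(fail("rule2"))
  p1011 <- intersect(10:11, seq_len(n))
  if (any(st[p1011] != "wc")) return(fail("rule2"))
  if (sum(w[seq_len(min(12, n))]) > 2.5) return(fail("rule3"))
  if (ratio < mfe_ratio) return(fail("rule4"))
  list(pass = TRUE, rule = NA_character_, score = score,
       e_dup = e_dup, e_perf = e_perf, ratio = ratio)
}

#' Scan a transcriptome for qualifying target sites
#'
#' Slides a window of the miRNA's length along the sense strand of every
#' transcript, keeps sites passing [check_rules()], and reports one site
#' per (miRNA, gene): lowest mismatch score, then lowest E_dup, then
#' leftmost. A fast compiled pre-scan discards windows whose mismatch
#' score already exceeds the rule-1 cap.
#'
#' @param mirnas Tibble `mirna_id`, `seq`.
#' @param transcriptome Tibble `id`, `seq` (e.g. from [read_fasta()]).
#' @inheritParams check_rules
#' @returns Tibble `mirna_id`, `gene_id`, `site_start`, `site_end`
#'   (1-based, closed), `score`, `e_dup`, `e_perf`, `ratio`.
#' @export
scan_transcriptome <- function(mirnas, transcriptome, mfe_ratio = 0.74,
                               max_mismatch = 4,
                               energy_fn = duplex_energy,
                               perfect_fn = perfect_energy) {
  res <- list()
  for (i in seq_len(nrow(mirnas))) {
    mir <- dna(mirnas$seq[i])
    L <- nchar(mir)
    for (g in seq_len(nrow(transcriptome))) {
      hits <- scan_duplex_cpp(mir, dna(transcriptome$seq[g]),
                              max_score = max_mismatch)
      if (nrow(hits) == 0) next
      best <- NULL
      for (h in seq_len(nrow(hits))) {
        win <- substr(transcriptome$seq[g], hits$start[h],
                      hits$start[h] + L - 1)
        aln <- align_site(mir, win)
        v <- check_rules(aln, mfe_ratio = mfe_ratio,
                         max_mismatch = max_mismatch,
                         energy_fn = energy_fn, perfect_fn = perfect_fn)
        if (!v$pass) next
        cand <- tibble::tibble(
          mirna_id = mirnas$mirna_id[i], gene_id = transcriptome$id[g],
          site_start = hits$start[h], site_end = hits$start[h] + L - 1L,
          score = v$score, e_dup = v$e_dup, e_perf = v$e_perf,
          ratio = v$ratio)
        if (is.null(best) || cand$score < best$score ||
            (cand$score == best$score && cand$e_dup < best$e_dup)) {
          best <- cand
        }
      }
      if (!is.null(best)) res[[length(res) + 1L]] <- best
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(mirna_id = character(), gene_id = character(),
                   site_start = integer(), site_end = integer(),
                   score = double(), e_dup = double(), e_perf = double(),
                   ratio = double())
  log_stage("targets", nrow(out), " (miRNA, gene) pairs pass the rules")
  out
}

#' Pair predicted targets with expression anti-correlation
#'
#' Pearson correlation of miRNA TPM against mRNA expression across the
#' 8 samples; the p-value uses t = r sqrt(n-2) / sqrt(1-r^2) with
#' n - 2 degrees of freedom, two-sided. A pair is `anti_correlated` iff
#' r < `cor_threshold` and p <= `cor_p`. Pairs with zero variance on
#' either side are dropped (logged).
#'
#' @param pairs Tibble from [scan_transcriptome()].
#' @param mirna_tpm Tibble `mirna_id` + 8 library columns.
#' @param mrna_expr Tibble `gene_id` + the same 8 library columns, same
#'   order.
#' @param cor_threshold,cor_p Anti-correlation thresholds.
#' @returns `pairs` plus `r`, `p_cor`, `anti_correlated`.
#' @export
anti_correlate <- function(pairs, mirna_tpm, mrna_expr,
                           cor_threshold = -0.50, cor_p = 0.05) {
  libs <- intersect(names(mirna_tpm), names(mrna_expr))
  libs <- setdiff(libs, c("mirna_id", "gene_id", "family", "category"))
  n <- length(libs)
  M <- as.matrix(mirna_tpm[libs])
  rownames(M) <- mirna_tpm$mirna_id
  G <- as.matrix(mrna_expr[libs])
  rownames(G) <- mrna_expr$gene_id
  keep <- pairs$mirna_id %in% rownames(M) & pairs$gene_id %in% rownames(G)
  pairs <- pairs[keep, ]
  x <- M[pairs$mirna_id, , drop = FALSE]
  y <- G[pairs$gene_id, , drop = FALSE]
  sx <- apply(x, 1, sd); sy <- apply(y, 1, sd)
  degenerate <- sx == 0 | sy == 0
  if (any(degenerate)) {
    log_stage("targets", sum(degenerate),
              " pairs dropped: zero variance in miRNA or mRNA vector")
    pairs <- pairs[!degenerate, ]; x <- x[!degenerate, , drop = FALSE]
    y <- y[!degenerate, , drop = FALSE]
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) cor(x[i, ], y[i, ]),
              numeric(1))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  dplyr::mutate(pairs, r = r, p_cor = p,
                anti_correlated = r < cor_threshold & p <= cor_p)
}
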