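TAG_CATEGORIES <- c("known_mirna", "other_ncrna", "mrna_fragment",
                    "repeat_excluded", "novel_candidate", "unannotated")

#' Load the reference set used for tag classification
#'
#' @param mature_fa FASTA of mature miRNA sequences; ids of the form
#'   `FAMILY-suffix` (e.g. `MIR169-a`), family = part before the first `-`.
#' @param ncrna_fa FASTA of other non-coding RNAs (rRNA/tRNA/sn(o)RNA).
#' @param transcriptome_fa FASTA of transcriptome contigs.
#' @returns List of tibbles `mature` (id, seq, family), `ncrna`,
#'   `transcriptome`.
#' @export
load_reference_set <- function(mature_fa, ncrna_fa, transcriptome_fa) {
  mature <- read_fasta(mature_fa)
  ncrna <- read_fasta(ncrna_fa)
  txome <- read_fasta(transcriptome_fa)
  if (nrow(mature) == 0 || nrow(ncrna) == 0 || nrow(txome) == 0) {
    stop("reference set must be non-empty", call. = FALSE)
  }
  len <- nchar(mature$seq)
  if (any(len < 18 | len > 26)) {
    stop("mature reference lengths must be in [18, 26] nt", call. = FALSE)
  }
  mature$family <- sub("-.*$", "", mature$id)
  list(mature = mature[order(mature$id), ], ncrna = ncrna,
       transcriptome = txome)
}

#' Fold a sequence window into its maximum-weight nested pairing
#'
#' Dynamic program over nested structures with pair weights GC = 3, AU = 2,
#' G:U = 1 and a minimum hairpin loop of 3 unpaired bases. The reported
#' score is the negative of the total pair weight (arbitrary units, <= 0).
#' Traceback is deterministic: the left end of an interval is paired
#' whenever pairing attains the optimum, to the outermost equal-scoring
#' partner.
#'
#' @param seq Nucleotide string, 40-320 nt.
#' @returns List with `score` and `pairs`, a tibble of 1-based paired
#'   positions `i < j` with their `weight` and pair `type`.
#' @export
fold_window <- function(seq) {
  n <- nchar(seq)
  if (n < 40 || n > 320) {
    stop("fold_window requires 40 <= length <= 320, got ", n, call. = FALSE)
  }
  res <- fold_nested_cpp(chartr("U", "T", toupper(seq)), 3L)
  pairs <- tibble::tibble(i = res$i, j = res$j, weight = res$weight,
                          type = c("GU", "AU", "GC")[res$weight])
  list(score = res$score, pairs = pairs[order(pairs$i), ])
}

#' Screen one transcriptome locus for a qualifying hairpin precursor
#'
#' Excises two candidate precursor windows around an exactly-mapped tag
#' (tag plus 150 nt downstream / upstream and 20 nt on the other side),
#' folds each, and evaluates the better-scoring one: the tag must sit
#' entirely on one arm (no self-pairing, all partners on one side), pair
#' with the opposite arm at >= `min_paired` bases, leave <= `max_bulged`
#' bases unpaired, and the window fold score must be <= `max_score`.
#'
#' @param tag_seq Tag sequence (mapped without mismatch).
#' @param contig_seq Contig sequence containing the tag.
#' @param start 1-based start of the tag on the contig.
#' @param min_paired,max_bulged,max_score Acceptance thresholds (defaults
#'   14 paired, 4 bulged, score <= -18).
#' @returns List: `accepted`, `reason` (NA when accepted) and, when
#'   accepted, `window_start`/`window_end` (1-based, closed), `arm`
#'   ("5p"/"3p"), `paired`, `score`, `star_seq`.
#' @export
screen_novel <- function(tag_seq, contig_seq, start,
                         min_paired = 14L, max_bulged = 4L,
                         max_score = -18) {
  L <- nchar(tag_seq)
  N <- nchar(contig_seq)
  windows <- list(c(start - 20L, start + L + 149L),
                  c(start - 150L, start + L + 19L))
  windows <- purrr::keep(windows, function(w) w[1] >= 1 && w[2] <= N)
  if (length(windows) == 0) {
    return(list(accepted = FALSE, reason = "no-window"))
  }
  folds <- purrr::map(windows, function(w) {
    f <- fold_window(substr(contig_seq, w[1], w[2]))
    c(f, list(w = w))
  })
  best <- folds[[which.min(purrr::map_dbl(folds, "score"))]]
  w <- best$w
  t1 <- start - w[1] + 1L            # tag position within the window
  t2 <- t1 + L - 1L
  pr <- best$pairs
  partner <- rep(NA_integer_, w[2] - w[1] + 1L)
  partner[pr$i] <- pr$j
  partner[pr$j] <- pr$i
  tagp <- partner[t1:t2]
  paired_in_tag <- !is.na(tagp) & tagp >= t1 & tagp <= t2
  outside <- tagp[!is.na(tagp) & !paired_in_tag]
  if (any(paired_in_tag) ||
      (length(outside) > 0 && !(all(outside < t1) || all(outside > t2)))) {
    return(list(accepted = FALSE, reason = "arm"))
  }
  if (length(outside) < min_paired) {
    return(list(accepted = FALSE, reason = "pairing"))
  }
  if (sum(is.na(tagp)) > max_bulged) {
    return(list(accepted = FALSE, reason = "bulge"))
  }
  if (best$score > max_score) {
    return(list(accepted = FALSE, reason = "score"))
  }
  star <- substr(substr(contig_seq, w[1], w[2]), min(outside), max(outside))
  list(accepted = TRUE, reason = NA_character_,
       window_start = w[1], window_end = w[2],
       arm = if (all(outside > t2)) "5p" else "3p",
       paired = length(outside), score = best$score, star_seq = star)
}

#' Classify clean tags
#'
#' Applies the removal cascade in the order used for small-RNA annotation:
#' other non-coding RNA first (exact substring of the ncRNA reference),
#' then transcriptome-mapped tags are screened -- tags hitting more than
#' `max_loci` distinct loci become `repeat_excluded`, mapped tags whose
#' loci fold into no qualifying hairpin become `mrna_fragment` -- then the
#' mature-miRNA search (<= 2 mismatches, no indels, ends within +/- 2 nt),
#' then surviving hairpin-positive tags become `novel_candidate`; the rest
#' are `unannotated`. Every tag receives exactly one category.
#'
#' @param tags Tibble from [collapse_tags()].
#' @param refs Reference set from [load_reference_set()].
#' @param max_mm,max_shift Mature-match tolerance.
#' @param max_loci Repeat threshold: tags mapping to more distinct
#'   transcriptome loci are excluded as repeats.
#' @param ... Passed on to [screen_novel()].
#' @returns List with `annotations` (tag_id, seq, category, hit_id,
#'   hit_start, family, mirna_id) and `hairpins` (accepted candidates).
#' @export
annotate_tags <- function(tags, refs, max_mm = 2L, max_shift = 2L,
                          max_loci = 10L, ...) {
  n <- nrow(tags)
  cat <- rep(NA_character_, n)
  hit_id <- rep(NA_character_, n)
  hit_start <- rep(NA_integer_, n)
  family <- rep(NA_character_, n)
  mirna_id <- rep(NA_character_, n)

  # 1. other ncRNA: exact substring of an ncRNA reference sequence
  nc <- map_exact_cpp(tags$seq, refs$ncrna$seq)
  if (nrow(nc)) {
    first <- nc[!duplicated(nc$tag_idx), ]
    cat[first$tag_idx] <- "other_ncrna"
    hit_id[first$tag_idx] <- refs$ncrna$id[first$contig_idx]
    hit_start[first$tag_idx] <- first$start
  }

  # 2. transcriptome mapping (sense strand, exact)
  tx <- map_exact_cpp(tags$seq, refs$transcriptome$seq)
  loci <- table(factor(tx$tag_idx, levels = seq_len(n)))
  rep_idx <- which(as.integer(loci) > max_loci & is.na(cat))
  cat[rep_idx] <- "repeat_excluded"

  # 3. hairpin screen for remaining mapped tags; first accepted locus wins
  hairpins <- list()
  mapped <- setdiff(unique(tx$tag_idx), which(!is.na(cat)))
  accepted <- logical(n)
  for (ti in mapped) {
    hits <- tx[tx$tag_idx == ti, , drop = FALSE]
    for (h in seq_len(nrow(hits))) {
      ci <- hits$contig_idx[h]
      res <- screen_novel(tags$seq[ti], refs$transcriptome$seq[ci],
                          hits$start[h], ...)
      if (isTRUE(res$accepted)) {
        accepted[ti] <- TRUE
        hit_id[ti] <- refs$transcriptome$id[ci]
        hit_start[ti] <- hits$start[h]
        hairpins[[length(hairpins) + 1L]] <- tibble::tibble(
          tag_id = tags$tag_id[ti], contig_id = refs$transcriptome$id[ci],
          window_start = res$window_start, window_end = res$window_end,
          arm = res$arm, paired = res$paired, score = res$score,
          star_seq = res$star_seq)
        break
      }
    }
    if (!accepted[ti]) {
      cat[ti] <- "mrna_fragment"
      hit_id[ti] <- refs$transcriptome$id[hits$contig_idx[1]]
      hit_start[ti] <- hits$start[1]
    }
  }

  # 4. known-miRNA search on the survivors
  open <- which(is.na(cat))
  if (length(open)) {
    mm <- match_mature_cpp(tags$seq[open], refs$mature$seq,
                           max_mm = max_mm, max_shift = max_shift)
    got <- which(mm$ref_idx > 0)
    idx <- open[got]
    cat[idx] <- "known_mirna"
    hit_id[idx] <- refs$mature$id[mm$ref_idx[got]]
    family[idx] <- refs$mature$family[mm$ref_idx[got]]
    mirna_id[idx] <- hit_id[idx]
  }

  # 5. hairpin-accepted survivors are novel candidates
  nov <- which(is.na(cat) & accepted)
  cat[nov] <- "novel_candidate"
  cat[is.na(cat)] <- "unannotated"

  hairpins <- if (length(hairpins)) dplyr::bind_rows(hairpins) else
    tibble::tibble(tag_id = character(), contig_id = character(),
                   window_start = integer(), window_end = integer(),
                   arm = character(), paired = integer(), score = double(),
                   star_seq = character())
  # stable novel ids in tag order
  if (length(nov)) {
    arms <- hairpins$arm[match(tags$tag_id[nov], hairpins$tag_id)]
    mirna_id[nov] <- sprintf("novel-m%04d-%s", seq_along(nov), arms)
    family[nov] <- NA_character_
  }

  ann <- tibble::tibble(tag_id = tags$tag_id, seq = tags$seq,
                        category = cat, hit_id = hit_id,
                        hit_start = hit_start, family = family,
                        mirna_id = mirna_id)
  log_stage("annotate", paste(names(table(cat)), table(cat),
                              sep = "=", collapse = ", "))
  list(annotations = ann, hairpins = hairpins)
}
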