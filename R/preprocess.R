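REJECT_REASONS <- c("low_quality", "contains_n", "no_3p_adapter",
                    "has_5p_adapter", "no_insert", "polya",
                    "too_short", "too_long")

#' Clean raw small-RNA reads
#'
#' Applies the read-cleaning cascade, in this fixed order: (1) reject reads
#' with more than one base of quality <= 20; (2) reject reads containing N;
#' (3) locate the 3' adapter (exact match of its leading 8-mer; first
#' occurrence) and reject reads without it; (4) reject reads carrying the
#' 5' adapter (leading 8-mer anywhere in the read); (5) reject reads with
#' an empty insert between adapters; (6) reject polyA inserts (>= 80% A or
#' a terminal run of >= 10 A); (7) reject inserts shorter than 18 nt or
#' longer than 30 nt. Rules apply to the insert, i.e. the bases 5' of the
#' located 3' adapter.
#'
#' @param reads Tibble from [read_fastq()].
#' @param adapter3,adapter5 Adapter sequences (>= 8 nt each).
#' @param min_len,max_len Retained insert length bounds (nt).
#' @param low_q Quality threshold: a base with score `<= low_q` counts as
#'   low-quality.
#' @param max_low_q Maximum tolerated number of low-quality bases.
#' @returns The input tibble plus columns `insert` (trimmed sequence, NA
#'   when rejected) and `reason` (rejection reason, NA when clean).
#' @export
clean_reads <- function(reads, adapter3, adapter5,
                        min_len = 18L, max_len = 30L,
                        low_q = 20L, max_low_q = 1L) {
  stopifnot(nchar(adapter3) >= 8, nchar(adapter5) >= 8)
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  set <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)

  # count of bases with Q <= low_q: Phred+33 chars '!' .. chr(33 + low_q)
  hi <- intToUtf8(33L + low_q)
  low_pat <- paste0("[^!-", hi, "]")
  n_low <- nchar(gsub(low_pat, "", reads$qual))
  set(n_low > max_low_q, "low_quality")
  set(grepl("N", reads$seq, fixed = TRUE), "contains_n")

  seed3 <- substr(adapter3, 1, 8)
  pos3 <- regexpr(seed3, reads$seq, fixed = TRUE)
  set(pos3 < 0, "no_3p_adapter")
  set(grepl(substr(adapter5, 1, 8), reads$seq, fixed = TRUE), "has_5p_adapter")

  insert <- ifelse(pos3 > 0, substr(reads$seq, 1, pos3 - 1), NA_character_)
  len <- ifelse(is.na(insert), 0L, nchar(insert))
  set(len == 0, "no_insert")
  n_a <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  polya <- !is.na(insert) & (n_a >= 0.8 * len | grepl("A{10,}$", insert))
  set(polya, "polya")
  set(len < min_len, "too_short")
  set(len > max_len, "too_long")

  dplyr::mutate(reads,
                insert = ifelse(is.na(reason), insert, NA_character_),
                reason = reason)
}

#' @rdname clean_reads
#' @param read A single-row tibble (or list) with `seq` and `qual`.
#' @returns `clean_read()`: a list with `status` ("clean"/"rejected"),
#'   `reason` and `insert`.
#' @export
clean_read <- function(read, adapter3, adapter5, ...) {
  df <- tibble::tibble(read_id = read$read_id %||% "r1",
                       seq = read$seq, qual = read$qual)
  out <- clean_reads(df, adapter3, adapter5, ...)
  list(status = if (is.na(out$reason)) "clean" else "rejected",
       reason = out$reason, insert = out$insert)
}

#' Collapse clean inserts to unique tags with per-library counts
#'
#' @param cleaned Long tibble with columns `library_id` and `insert`
#'   (already-clean inserts only).
#' @param library_ids Column order for the count columns; defaults to the
#'   libraries present.
#' @returns Tibble with `tag_id`, `seq` and one integer count column per
#'   library, ordered by decreasing total count (ties by sequence).
#' @export
collapse_tags <- function(cleaned, library_ids = NULL) {
  library_ids <- library_ids %||% unique(cleaned$library_id)
  wide <- cleaned |>
    dplyr::count(.data$library_id, seq = .data$insert) |>
    tidyr::pivot_wider(names_from = "library_id", values_from = "n",
                       values_fill = 0L)
  for (lib in setdiff(library_ids, names(wide))) wide[[lib]] <- 0L
  wide <- wide[c("seq", library_ids)]
  tot <- rowSums(as.matrix(wide[library_ids]))
  wide <- wide[order(-tot, wide$seq), ]
  dplyr::bind_cols(tibble::tibble(tag_id = sprintf("tag%06d", seq_len(nrow(wide)))),
                   wide)
}

#' Run the cleaning cascade over a set of FASTQ libraries
#'
#' @param fastq_paths Named character vector, one FASTQ path per
#'   `library_id`.
#' @inheritParams clean_reads
#' @returns List with `tags` (see [collapse_tags()]), `report` (long tibble
#'   `library_id`, `reason`, `n` including a `clean` row; reasons sum to the
#'   raw read count), and `totals` (named vector of clean-read counts per
#'   library, the TPM denominators).
#' @export
preprocess_libraries <- function(fastq_paths, adapter3, adapter5, ...) {
  stopifnot(!is.null(names(fastq_paths)))
  per_lib <- purrr::imap(fastq_paths, function(path, lib) {
    reads <- read_fastq(path)
    cl <- clean_reads(reads, adapter3, adapter5, ...)
    rep <- cl |>
      dplyr::count(reason = dplyr::coalesce(.data$reason, "clean")) |>
      dplyr::mutate(library_id = lib, .before = 1)
    log_stage("preprocess", lib, ": ", nrow(reads), " raw -> ",
              sum(is.na(cl$reason)), " clean")
    list(clean = tibble::tibble(library_id = lib,
                                insert = cl$insert[is.na(cl$reason)]),
         report = rep)
  })
  report <- dplyr::bind_rows(purrr::map(per_lib, "report")) |>
    tidyr::complete(.data$library_id,
                    reason = c(REJECT_REASONS, "clean"),
                    fill = list(n = 0L))
  cleaned <- dplyr::bind_rows(purrr::map(per_lib, "clean"))
  tags <- collapse_tags(cleaned, library_ids = names(fastq_paths))
  totals <- report |>
    dplyr::filter(.data$reason == "clean") |>
    dplyr::pull(.data$n, name = "library_id")
  list(tags = tags, report = report,
       totals = totals[names(fastq_paths)])
}

#' Write collapsed tags as FASTA with a count-string header
#'
#' Headers follow `tagN|libA:3;libB:1`, listing only libraries with a
#' positive count.
#' @param tags Tibble from [collapse_tags()].
#' @param path Output file.
#' @export
write_clean_tags_fasta <- function(tags, path) {
  libs <- setdiff(names(tags), c("tag_id", "seq"))
  counts <- as.matrix(tags[libs])
  hdr <- vapply(seq_len(nrow(tags)), function(i) {
    pos <- which(counts[i, ] > 0)
    paste0(tags$tag_id[i], "|",
           paste0(libs[pos], ":", counts[i, pos], collapse = ";"))
  }, character(1))
  write_fasta(tibble::tibble(id = hdr, seq = tags$seq), path)
}
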