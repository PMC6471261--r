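#' Tags-per-million normalization
#'
#' TPM = count / total clean tags x 10^6. The denominator is the library's
#' total clean-tag count over all categories, not the miRNA-mapped count.
#'
#' @param count Non-negative tag count(s).
#' @param total_clean_tags Positive library total(s).
#' @returns TPM value(s).
#' @export
tpm <- function(count, total_clean_tags) {
  if (any(total_clean_tags <= 0)) stop("total clean tags must be > 0",
                                       call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count / total_clean_tags * 1e6
}

#' Build the miRNA-by-library count and TPM matrices
#'
#' Rows are known and novel miRNAs; each tag sequence contributes to
#' exactly one row (its annotated miRNA id). Tags matching two mature
#' references equally are already resolved to the alphabetically first id
#' by the annotation stage.
#'
#' @param annotations Annotation tibble from [annotate_tags()].
#' @param tags Tag tibble from [collapse_tags()].
#' @param totals Named vector of per-library total clean-tag counts.
#' @returns List with `counts` and `tpm` tibbles (`mirna_id`, `family`,
#'   `category`, one column per library) and `totals`.
#' @export
expression_matrix <- function(annotations, tags, totals) {
  libs <- names(totals)
  mir <- annotations |>
    dplyr::filter(.data$category %in% c("known_mirna", "novel_candidate")) |>
    dplyr::select("tag_id", "mirna_id", "family", "category")
  counts <- mir |>
    dplyr::inner_join(tags, by = "tag_id") |>
    dplyr::group_by(.data$mirna_id, .data$family, .data$category) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(libs), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$mirna_id)
  bad <- purrr::map_lgl(libs, function(l) sum(counts[[l]]) > totals[[l]])
  if (any(bad)) stop("miRNA counts exceed library totals", call. = FALSE)
  tpm_tbl <- counts
  for (l in libs) tpm_tbl[[l]] <- tpm(counts[[l]], totals[[l]])
  list(counts = counts, tpm = tpm_tbl, totals = totals)
}

#' Family presence/abundance summary
#'
#' Families (known miRNAs only) ranked by summed count, descending; the
#' per-library presence flag is "+" exactly when the family has a positive
#' count in that library. Ties in total count break alphabetically.
#'
#' @param counts Count tibble from [expression_matrix()].
#' @param libs Library columns; default: everything beyond the id columns.
#' @returns Tibble `family`, `total_count`, per-library "+"/"-" flags.
#' @export
family_abundance <- function(counts,
                             libs = setdiff(names(counts),
                                            c("mirna_id", "family",
                                              "category"))) {
  fam <- counts |>
    dplyr::filter(!is.na(.data$family)) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(libs), sum),
                     .groups = "drop") |>
    dplyr::mutate(total_count = rowSums(dplyr::pick(dplyr::all_of(libs)))) |>
    dplyr::arrange(dplyr::desc(.data$total_count), .data$family)
  for (l in libs) fam[[l]] <- ifelse(fam[[l]] > 0, "+", "-")
  dplyr::select(fam, "family", "total_count", dplyr::all_of(libs))
}
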