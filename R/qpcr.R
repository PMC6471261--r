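#' Comparative-Ct relative expression
#'
#' For each treatment timepoint, ΔCt = mean Ct(target) - mean Ct(reference
#' assay, U6 by default) within the condition, ΔΔCt = ΔCt(treatment) -
#' ΔCt(control), and fold = 2^-ΔΔCt. The SD is computed on the
#' per-replicate ΔCt values of the treatment condition and expressed on
#' the fold scale as the 2^-(ΔΔCt±SD) range.
#'
#' @param ct Long Ct table: columns `timepoint`, `assay`, `replicate`,
#'   `ct` (one row per technical replicate; Ct in (0, 45)).
#' @param assay Target assay (miRNA id).
#' @param reference Reference assay, default "U6".
#' @param control Control timepoint, default "CK".
#' @returns Tibble `assay`, `timepoint`, `ddct`, `fold`, `sd_dct`,
#'   `fold_lo`, `fold_hi` (one row per non-control timepoint).
#' @export
ddct <- function(ct, assay, reference = "U6", control = "CK") {
  stopifnot(all(c("timepoint", "assay", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct >= 45)) stop("Ct values must lie in (0, 45)",
                                          call. = FALSE)
  if (!reference %in% ct$assay) stop("reference assay '", reference,
                                     "' missing from Ct table", call. = FALSE)
  if (!assay %in% ct$assay) stop("target assay '", assay,
                                 "' missing from Ct table", call. = FALSE)
  dct <- ct |>
    dplyr::filter(.data$assay %in% c(!!assay, reference)) |>
    tidyr::pivot_wider(id_cols = c("timepoint", "replicate"),
                       names_from = "assay", values_from = "ct") |>
    dplyr::mutate(dct = .data[[assay]] - .data[[reference]])
  per_tp <- dct |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(mean_dct = mean(.data$dct), sd_dct = sd(.data$dct),
                     .groups = "drop")
  ctrl <- per_tp$mean_dct[per_tp$timepoint == control]
  if (length(ctrl) != 1) stop("control timepoint '", control,
                              "' missing from Ct table", call. = FALSE)
  per_tp |>
    dplyr::filter(.data$timepoint != control) |>
    dplyr::transmute(assay = !!assay, timepoint = .data$timepoint,
                     ddct = .data$mean_dct - ctrl,
                     fold = 2^-.data$ddct,
                     sd_dct = .data$sd_dct,
                     fold_lo = 2^-(.data$ddct + .data$sd_dct),
                     fold_hi = 2^-(.data$ddct - .data$sd_dct))
}

#' Relative expression for every assay in a Ct table
#'
#' @inheritParams ddct
#' @returns Stacked [ddct()] results for all non-reference assays.
#' @export
qpcr_folds <- function(ct, reference = "U6", control = "CK") {
  assays <- setdiff(unique(ct$assay), reference)
  dplyr::bind_rows(lapply(assays, function(a) {
    ddct(ct, a, reference = reference, control = control)
  }))
}

#' Direction concordance between qPCR folds and pipeline fold changes
#'
#' The comparison is on direction only (fold > 1 vs log2FC > 0), because
#' the scaling that would make the two magnitudes commensurate is not
#' defined.
#'
#' @param folds Tibble from [qpcr_folds()].
#' @param dems `mejamir_dem` tibble with comparisons `CK-VS-<tp>`.
#' @returns List: `table` (per miRNA/timepoint match) and
#'   `fraction_concordant`.
#' @export
concordance <- function(folds, dems) {
  dd <- dems |>
    dplyr::filter(startsWith(.data$comparison, "CK-VS-")) |>
    dplyr::mutate(timepoint = sub("^CK-VS-", "", .data$comparison))
  tab <- folds |>
    dplyr::inner_join(dd, by = c(assay = "mirna_id", "timepoint")) |>
    dplyr::transmute(.data$assay, .data$timepoint, .data$fold,
                     .data$log2fc,
                     concordant = (.data$fold > 1) == (.data$log2fc > 0))
  if (nrow(tab) == 0) stop("no shared miRNA between qPCR and pipeline calls",
                           call. = FALSE)
  list(table = tab, fraction_concordant = mean(tab$concordant))
}

#' Read a Ct table from TSV
#'
#' Wide triplicate format: `sample`, `timepoint`, `assay`, `ct1`..`ct3`.
#' @param path TSV file.
#' @returns Long tibble `timepoint`, `assay`, `replicate`, `ct`.
#' @export
read_ct_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  x |>
    tidyr::pivot_longer(dplyr::starts_with("ct"), names_to = "replicate",
                        names_prefix = "ct", values_to = "ct") |>
    dplyr::mutate(replicate = as.integer(.data$replicate)) |>
    dplyr::select("timepoint", "assay", "replicate", "ct")
}
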