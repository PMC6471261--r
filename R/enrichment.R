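#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that at least `m` of the `n` selected genes are
#' annotated to a term, given `M` of the `N` universe genes are:
#' P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N, n), evaluated with
#' log-binomials.
#'
#' @param N Universe size (all annotated genes).
#' @param n Selected genes (e.g. DEM targets) in the universe.
#' @param M Genes annotated to the term.
#' @param m Selected genes annotated to the term.
#' @returns Upper-tail probability. Vectorized.
#' @export
hypergeom_p <- function(N, n, M, m) {
  args <- vctrs_recycle(N, n, M, m)
  purrr::pmap_dbl(args, function(N, n, M, m) {
    if (m > min(n, M) || M > N || n > N || m < 0) {
      stop("invalid hypergeometric input (need m <= min(n, M) <= N)",
           call. = FALSE)
    }
    if (m == 0) return(1)
    i <- 0:(m - 1)
    terms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
    max(0, min(1, 1 - sum(exp(terms))))
  })
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, len)
}

#' Term enrichment of a gene set
#'
#' One result per term with at least one selected gene. The universe N is
#' the annotated universe; selected genes lacking annotation are excluded
#' from n (and logged). Q-values are Benjamini-Hochberg over all tested
#' terms.
#'
#' @param genes Character vector of selected genes (e.g. DEM targets).
#' @param annotation Tibble from [read_annotation_tsv()] (`gene_id`,
#'   `term_id`, optional `name`, optional `namespace`).
#' @param p_cut Significance level applied to the raw P (the Q column is
#'   also reported).
#' @returns Tibble of class `mejamir_enrich`: `term_id`, `name`,
#'   `namespace`, `N`, `n`, `M`, `m`, `p_value`, `q_value`, `rich_factor`
#'   (m/M), `percentage` (100 m/n, half-even rounded to 2 decimals),
#'   `significant`; sorted by `p_value`.
#' @export
enrich <- function(genes, annotation, p_cut = 0.05) {
  if (nrow(annotation) == 0) stop("empty annotation table (N = 0)",
                                  call. = FALSE)
  if (!"namespace" %in% names(annotation)) annotation$namespace <- NA_character_
  universe <- unique(annotation$gene_id)
  N <- length(universe)
  sel <- unique(genes)
  dropped <- setdiff(sel, universe)
  if (length(dropped)) {
    log_stage("enrichment", length(dropped),
              " selected genes lack annotation; excluded from n")
  }
  sel <- intersect(sel, universe)
  n <- length(sel)
  out <- annotation |>
    dplyr::group_by(.data$term_id, .data$name, .data$namespace) |>
    dplyr::summarise(M = dplyr::n_distinct(.data$gene_id),
                     m = sum(unique(.data$gene_id) %in% sel),
                     .groups = "drop") |>
    dplyr::filter(.data$m >= 1) |>
    dplyr::mutate(N = N, n = n,
                  p_value = hypergeom_p(N, n, .data$M, .data$m),
                  q_value = p.adjust(.data$p_value, method = "BH"),
                  rich_factor = .data$m / .data$M,
                  percentage = round(100 * .data$m / n, 2),
                  significant = .data$p_value < p_cut) |>
    dplyr::select("term_id", "name", "namespace", "N", "n", "M", "m",
                  "p_value", "q_value", "rich_factor", "percentage",
                  "significant") |>
    dplyr::arrange(.data$p_value, .data$term_id)
  class(out) <- c("mejamir_enrich", class(out))
  out
}

#' Format an enrichment report cell
#'
#' `m (percentage%)` with the percentage = 100 m/n rounded half-even to
#' two decimals and trailing zeros trimmed (so 5.60 prints as "5.6" and
#' 12.00 as "12"); m = 0 renders as "0".
#'
#' @param m,n Counts.
#' @returns Character cell(s).
#' @export
report_cell <- function(m, n) {
  pct <- vapply(round(100 * m / n, 2), function(p) {
    s <- sprintf("%.2f", p)
    s <- sub("0+$", "", s)
    sub("\\.$", "", s)
  }, character(1))
  ifelse(m == 0, "0", paste0(m, " (", pct, "%)"))
}

#' Pathway-by-comparison report table
#'
#' One row per selected pathway, one column per comparison, cells
#' formatted by [report_cell()] from that comparison's (m, n).
#'
#' @param results Named list of `mejamir_enrich` tibbles, one per
#'   comparison (names become columns).
#' @param pathways Term ids (or names) selecting and ordering the rows.
#' @returns Tibble `pathway` + one character column per comparison.
#' @export
report_table <- function(results, pathways) {
  cols <- purrr::imap(results, function(res, cmp) {
    idx <- match(pathways, res$term_id)
    idx[is.na(idx)] <- match(pathways[is.na(idx)], res$name)
    m <- ifelse(is.na(idx), 0L, res$m[idx])
    n <- if (nrow(res)) res$n[1] else 1L
    report_cell(m, n)
  })
  dplyr::bind_cols(tibble::tibble(pathway = pathways), cols)
}

#' @export
tidy.mejamir_enrich <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mejamir_enrich <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x), N = x$N[1] %||% 0L, n = x$n[1] %||% 0L,
                 n_significant = sum(x$significant),
                 n_q_significant = sum(x$q_value < 0.05))
}
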