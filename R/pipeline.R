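with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes preprocess -> annotate -> quantify -> differential expression
#' -> profile clustering -> target prediction -> anti-correlation pairing
#' -> enrichment (-> qPCR when a Ct table is provided), writing every
#' stage's table under `out_dir` with stable filenames plus a
#' `manifest.json` of checksums and row counts. Stage failures propagate
#' with a stage-named error.
#'
#' @param inputs Named list: `fastq` (named paths per library),
#'   `mature_fa`, `ncrna_fa`, `transcriptome_fa`, `mrna_expr`,
#'   `pathway_annotation`, `go_annotation`, optional `ct_table`,
#'   `adapter3`, `adapter5` (e.g. from [simulate_bundle()]).
#' @param out_dir Output directory (created).
#' @param config A `mejamir_config`; its seed drives the permutation
#'   stage.
#' @returns Invisible list of all stage results (`tags`, `report`,
#'   `totals`, `annotations`, `hairpins`, `expr`, `dems`, `stem`,
#'   `targets`, `pairs`, `enrichment`, `qpcr`, `manifest`).
#' @export
run_pipeline <- function(inputs, out_dir, config = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ss <- config$sample_sheet
  out <- function(f) file.path(out_dir, f)

  pre <- with_stage("preprocess", {
    missing <- inputs$fastq[!file.exists(inputs$fastq)]
    if (length(missing)) stop("missing FASTQ: ", missing[1])
    preprocess_libraries(inputs$fastq, inputs$adapter3, inputs$adapter5)
  })
  write_clean_tags_fasta(pre$tags, out("clean_tags.fa"))
  write_tsv_quiet(pre$report, out("filter_report.tsv"))

  annot <- with_stage("annotate", {
    refs <- load_reference_set(inputs$mature_fa, inputs$ncrna_fa,
                               inputs$transcriptome_fa)
    c(annotate_tags(pre$tags, refs), list(refs = refs))
  })
  write_tsv_quiet(annot$annotations, out("annotations.tsv"))
  write_tsv_quiet(annot$hairpins, out("hairpins.tsv"))

  expr <- with_stage("quantify",
                     expression_matrix(annot$annotations, pre$tags,
                                       pre$totals))
  write_tsv_quiet(expr$counts, out("mirna_counts.tsv"))
  write_tsv_quiet(expr$tpm, out("mirna_tpm.tsv"))
  write_tsv_quiet(family_abundance(expr$counts), out("family_presence.tsv"))

  dems <- with_stage("diffexpr",
                     call_all_dems(expr, sample_sheet = ss,
                                   fold_change = config$fold_change,
                                   de_p = config$de_p))
  for (cmp in unique(dems$comparison)) {
    write_tsv_quiet(dems[dems$comparison == cmp, ],
                    out(paste0("dem_", gsub("-VS-", "_vs_", cmp), ".tsv")))
  }

  stem <- with_stage("stem",
                     stem_profiles(expr, dems, sample_sheet = ss,
                                   seed = config$seed,
                                   alpha = config$stem_p))
  write_tsv_quiet(stem$profiles, out("stem_profiles.tsv"))
  write_tsv_quiet(stem$assignments, out("stem_assignments.tsv"))

  targets <- with_stage("targets", {
    known <- annot$refs$mature |>
      dplyr::filter(.data$id %in% expr$counts$mirna_id) |>
      dplyr::transmute(mirna_id = .data$id, seq = .data$seq)
    novel <- annot$annotations |>
      dplyr::filter(.data$category == "novel_candidate") |>
      dplyr::transmute(mirna_id = .data$mirna_id, seq = .data$seq)
    scan_transcriptome(dplyr::bind_rows(known, novel),
                       annot$refs$transcriptome,
                       mfe_ratio = config$mfe_ratio,
                       max_mismatch = config$max_mismatch)
  })
  write_tsv_quiet(targets, out("targets.tsv"))

  pairs <- with_stage("targets", {
    mrna <- read_expression_tsv(inputs$mrna_expr, ss)
    anti_correlate(targets, expr$tpm, mrna,
                   cor_threshold = config$cor_threshold,
                   cor_p = config$cor_p)
  })
  write_tsv_quiet(pairs, out("pairs.tsv"))

  enrichment <- with_stage("enrichment", {
    for (f in c("pathway_annotation", "go_annotation")) {
      if (is.null(inputs[[f]]) || !file.exists(inputs[[f]])) {
        stop("missing annotation table: ", f)
      }
    }
    kegg_ann <- read_annotation_tsv(inputs$pathway_annotation)
    kegg_ann$namespace <- "KEGG"
    go_ann <- read_annotation_tsv(inputs$go_annotation)
    if (!"namespace" %in% names(go_ann)) go_ann$namespace <- "GO"
    res <- list()
    for (cmp in unique(dems$comparison)) {
      sig <- dems$mirna_id[dems$comparison == cmp & dems$significant]
      genes <- unique(targets$gene_id[targets$mirna_id %in% sig])
      both <- dplyr::bind_rows(
        if (length(genes)) enrich(genes, kegg_ann) else NULL,
        if (length(genes)) enrich(genes, go_ann) else NULL)
      res[[cmp]] <- both
      write_tsv_quiet(both, out(paste0("enrichment_",
                                       gsub("-VS-", "_vs_", cmp), ".tsv")))
    }
    res
  })

  qpcr <- NULL
  if (!is.null(inputs$ct_table) && file.exists(inputs$ct_table)) {
    qpcr <- with_stage("qpcr", {
      ct <- read_ct_tsv(inputs$ct_table)
      folds <- qpcr_folds(ct)
      shared <- intersect(folds$assay, dems$mirna_id)
      conc <- if (length(shared)) concordance(folds, dems) else NULL
      list(folds = folds, concordance = conc)
    })
    write_tsv_quiet(qpcr$folds, out("qpcr_folds.tsv"))
    if (!is.null(qpcr$concordance)) {
      write_tsv_quiet(qpcr$concordance$table, out("concordance.tsv"))
    }
  }

  manifest <- write_manifest(out_dir, config)
  invisible(list(tags = pre$tags, report = pre$report, totals = pre$totals,
                 annotations = annot$annotations, hairpins = annot$hairpins,
                 expr = expr, dems = dems, stem = stem, targets = targets,
                 pairs = pairs, enrichment = enrichment, qpcr = qpcr,
                 manifest = manifest, out_dir = out_dir))
}

#' Write the run manifest
#'
#' Records tool version, a configuration hash, and per-output-file md5
#' checksum and row count; re-running deterministic stages on identical
#' inputs reproduces identical checksums.
#'
#' @param out_dir Run directory containing the stage outputs.
#' @param config The run configuration.
#' @returns The manifest list, invisibly written to `manifest.json`.
#' @export
write_manifest <- function(out_dir, config = default_config()) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  paths <- file.path(out_dir, files)
  rows <- vapply(paths, function(p) length(readLines(p, warn = FALSE)),
                 integer(1))
  manifest <- list(
    tool = "mejamir",
    version = as.character(utils::packageVersion("mejamir")),
    config_hash = rlang::hash(unclass(config)),
    files = tibble::tibble(file = files,
                           md5 = unname(tools::md5sum(paths)),
                           lines = unname(rows)),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE)
  invisible(manifest)
}
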