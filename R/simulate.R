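#' Synthesis parameters for the truth-tracked generator
#'
#' Defaults mirror the study design the pipeline targets: 4 timepoints x
#' 2 replicates, ~10^5 clean reads per library, 500 mature miRNAs with a
#' planted 4-fold up/down/null class structure, hairpin precursors for
#' novel candidates, complementary target sites with controlled
#' rule-violating edits, anti-correlated mRNA partners at r_true = -0.9,
#' and pathway/GO tables with a few concentrated (enriched) terms. Count
#' noise is negative binomial with dispersion 0.1 -- deliberately harsher
#' than the Poisson-like sampling the exact test assumes.
#'
#' @param seed Master seed; byte-identical outputs for equal seeds.
#' @param depth Target clean reads per library.
#' @param n_mirnas,n_families Known mature miRNAs and family count.
#' @param n_novel Hairpin-backed novel miRNA candidates.
#' @param n_ncrna,n_ncrna_frags Other-ncRNA references and planted
#'   fragment tags.
#' @param n_mrna_frags Planted mRNA-degradation fragment tags.
#' @param n_genes,gene_len Transcriptome contigs.
#' @param frac_up,frac_down,fold Differential-expression class structure
#'   (multiplier `fold` at T1-T3 relative to CK). Classes are planted on
#'   the TPM (relative-abundance) scale, the scale the pipeline measures
#'   on; an uncharacterized filler fraction absorbs the mass difference so
#'   that library depth stays at `depth` for every timepoint.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param mirna_fraction Fraction of the clean depth carried by miRNAs at
#'   CK.
#' @param n_filler Unique uncharacterized filler tags.
#' @param base_sdlog Log-sd of the baseline abundance distribution.
#' @param n_pass_perfect,n_pass_gu,n_fail_rule2,n_fail_rule1 Planted
#'   target sites per intended verdict.
#' @param n_anticorr Planted anti-correlated miRNA-mRNA pairs.
#' @param r_true Planted correlation of those pairs.
#' @param n_pathways,n_go_terms,n_enriched Annotation structure.
#' @param n_qpcr_assays Assays in the synthetic Ct table.
#' @param contaminant_rates Named rates (per clean read) of injected
#'   contaminant classes.
#' @param adapter3,adapter5 Adapter sequences (3' default: Illumina
#'   small-RNA 3' adapter).
#' @returns A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, depth = 1e5, n_mirnas = 500L,
                         n_families = 100L, n_novel = 20L,
                         n_ncrna = 10L, n_ncrna_frags = 20L,
                         n_mrna_frags = 15L, n_genes = 300L,
                         gene_len = 400L,
                         frac_up = 0.1, frac_down = 0.1, fold = 4,
                         nb_dispersion = 0.1, mirna_fraction = 0.6,
                         n_filler = 150L, base_sdlog = 0.7,
                         n_pass_perfect = 20L, n_pass_gu = 20L,
                         n_fail_rule2 = 10L, n_fail_rule1 = 10L,
                         n_anticorr = 30L, r_true = -0.9,
                         n_pathways = 20L, n_go_terms = 30L,
                         n_enriched = 3L, n_qpcr_assays = 5L,
                         contaminant_rates = c(
                           low_quality = 0.02, contains_n = 0.01,
                           no_3p_adapter = 0.02, has_5p_adapter = 0.01,
                           no_insert = 0.005, polya = 0.01,
                           too_short = 0.01, too_long = 0.005),
                         adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                         adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC") {
  cfg <- as.list(environment())
  n_sites <- n_pass_perfect + n_pass_gu + n_fail_rule2 + n_fail_rule1
  if (n_sites + n_novel > n_genes) {
    stop("more planted sites + hairpins than genes", call. = FALSE)
  }
  if (n_anticorr > n_pass_perfect + n_pass_gu) {
    stop("more anti-correlated pairs than planted pass sites", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

random_seq <- function(n, len) {
  if (length(len) > 1) len <- sample(len, n, replace = TRUE)
  vapply(rep_len(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# insert sequences must survive the cleaning cascade untouched
clean_insert_seq <- function(n, len, cfg) {
  seed3 <- substr(cfg$adapter3, 1, 8)
  seed5 <- substr(cfg$adapter5, 1, 8)
  out <- character(0)
  while (length(out) < n) {
    cand <- random_seq(2 * (n - length(out)) + 4, len)
    n_a <- nchar(cand) - nchar(gsub("A", "", cand, fixed = TRUE))
    ok <- !grepl(seed3, cand, fixed = TRUE) &
      !grepl(seed5, cand, fixed = TRUE) &
      n_a < 0.8 * nchar(cand) & !grepl("A{10,}$", cand)
    out <- unique(c(out, cand[ok]))
  }
  out[seq_len(n)]
}

#' Generate a complete truth-tracked input bundle
#'
#' Writes 8 FASTQ libraries, the three reference FASTAs, the mRNA
#' expression matrix, pathway and GO annotation tables, a synthetic Ct
#' table, and `truth.json`, all derived from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created).
#' @returns List with `inputs` (file paths + adapters, ready for
#'   [run_pipeline()]), `truth` (planted-element tables) and `tables`
#'   (in-memory copies).
#' @export
simulate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  ss <- default_sample_sheet()
  libs <- ss$library_id

  ## --- references -----------------------------------------------------
  fam <- sprintf("MIR%03d", sample.int(900, cfg$n_families) + 99L)
  mature <- tibble::tibble(
    id = sprintf("%s-%s", sample(fam, cfg$n_mirnas, replace = TRUE),
                 rep_len(letters, cfg$n_mirnas)),
    seq = clean_insert_seq(cfg$n_mirnas, 21:22, cfg))
  mature$id <- make.unique(mature$id, sep = "")
  mature$family <- sub("-.*$", "", mature$id)

  ncrna <- tibble::tibble(
    id = paste0(rep(c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA"),
                    length.out = cfg$n_ncrna), "-", seq_len(cfg$n_ncrna)),
    seq = random_seq(cfg$n_ncrna, 120))
  frag_src <- sample.int(cfg$n_ncrna, cfg$n_ncrna_frags, replace = TRUE)
  frag_start <- sample.int(95, cfg$n_ncrna_frags, replace = TRUE)
  ncrna_frags <- substr(ncrna$seq[frag_src], frag_start, frag_start + 20L)

  genes <- tibble::tibble(id = sprintf("Unigene%06d", seq_len(cfg$n_genes)),
                          seq = random_seq(cfg$n_genes, cfg$gene_len))

  ## --- novel hairpins -------------------------------------------------
  novel_tags <- clean_insert_seq(cfg$n_novel, 21, cfg)
  hp_genes <- seq_len(cfg$n_novel)            # dedicated contigs
  hp_start <- 60L
  for (i in seq_len(cfg$n_novel)) {
    arm <- novel_tags[i]
    hp <- paste0(arm, random_seq(1, 6), revcomp(arm))
    g <- genes$seq[hp_genes[i]]
    genes$seq[hp_genes[i]] <- paste0(
      substr(g, 1, hp_start - 1), hp,
      substr(g, hp_start + nchar(hp), cfg$gene_len))
  }
  novel <- tibble::tibble(seq = novel_tags, contig = genes$id[hp_genes],
                          start = hp_start)

  ## --- expression classes and expected counts -------------------------
  n_up <- round(cfg$frac_up * cfg$n_mirnas)
  n_dn <- round(cfg$frac_down * cfg$n_mirnas)
  class <- sample(rep(c("up4x", "down4x", "null"),
                      c(n_up, n_dn, cfg$n_mirnas - n_up - n_dn)))
  base_mu <- cfg$depth * cfg$mirna_fraction / cfg$n_mirnas
  base <- stats::rlnorm(cfg$n_mirnas,
                        log(base_mu) - cfg$base_sdlog^2 / 2, cfg$base_sdlog)
  mult <- cbind(CK = 1,
                T1 = ifelse(class == "up4x", cfg$fold,
                            ifelse(class == "down4x", 1 / cfg$fold, 1)))
  mult <- cbind(mult, T2 = mult[, "T1"], T3 = mult[, "T1"])
  mirnas <- dplyr::bind_cols(mature, tibble::tibble(class = class,
                                                    base_count = base))

  draw_counts <- function(mu_by_tp) {
    # one NB draw per library; columns in sample-sheet order
    sapply(libs, function(l) {
      tp <- ss$timepoint[ss$library_id == l]
      stats::rnbinom(length(mu_by_tp[, tp]), mu = mu_by_tp[, tp],
                     size = 1 / cfg$nb_dispersion)
    })
  }
  mir_mu <- base * mult
  # non-miRNA classes carry fixed small fractions of the depth
  frag_mu <- matrix(0.03 * cfg$depth / cfg$n_ncrna_frags,
                    cfg$n_ncrna_frags, 4, dimnames = list(NULL, TIMEPOINTS))
  novel_mu <- matrix(0.015 * cfg$depth / cfg$n_novel, cfg$n_novel, 4,
                     dimnames = list(NULL, TIMEPOINTS))
  mfrag_mu <- matrix(0.012 * cfg$depth / cfg$n_mrna_frags,
                     cfg$n_mrna_frags, 4, dimnames = list(NULL, TIMEPOINTS))
  # uncharacterized filler keeps each library's expected depth near
  # `depth`, so planted TPM classes are exact on the relative scale;
  # sized from the configured (expected) masses so that generation is
  # depth-independent
  mean_mult <- c(CK = 1, T1 = NA, T2 = NA, T3 = NA)
  mean_mult[2:4] <- 1 + cfg$frac_up * (cfg$fold - 1) +
    cfg$frac_down * (1 / cfg$fold - 1)
  filler_mass <- cfg$depth *
    (1 - cfg$mirna_fraction * mean_mult - 0.03 - 0.015 - 0.012)
  if (any(filler_mass <= 0.05 * cfg$depth)) {
    stop("inconsistent config: planted miRNA mass exceeds library depth",
         call. = FALSE)
  }
  fw <- stats::rlnorm(cfg$n_filler, 0, 0.5)
  filler_mu <- outer(fw / sum(fw), filler_mass)
  colnames(filler_mu) <- TIMEPOINTS
  mir_counts <- draw_counts(mir_mu)
  frag_counts <- draw_counts(frag_mu)
  novel_counts <- draw_counts(novel_mu)

  ## --- target sites ---------------------------------------------------
  outcomes <- rep(c("pass_perfect", "pass_gu", "fail_rule2", "fail_rule1"),
                  c(cfg$n_pass_perfect, cfg$n_pass_gu, cfg$n_fail_rule2,
                    cfg$n_fail_rule1))
  n_sites <- length(outcomes)
  # prefer differentially expressed miRNAs so enrichment has signal
  dem_idx <- which(class != "null")
  site_mirna <- c(sample(dem_idx, min(length(dem_idx), round(0.75 * n_sites))),
                  sample(which(class == "null"),
                         n_sites - min(length(dem_idx),
                                       round(0.75 * n_sites))))
  site_gene <- cfg$n_novel + seq_len(n_sites)  # one site per dedicated gene
  site_start <- 150L
  sites <- tibble::tibble(mirna_id = mature$id[site_mirna],
                          mirna_seq = mature$seq[site_mirna],
                          gene_id = genes$id[site_gene],
                          start = site_start, outcome = outcomes)
  for (k in seq_len(n_sites)) {
    mir <- sites$mirna_seq[k]
    L <- nchar(mir)
    site <- strsplit(revcomp(mir), "")[[1]]
    mpos_to_w <- function(i) L - i + 1L
    mir_ch <- strsplit(mir, "")[[1]]
    if (outcomes[k] == "pass_gu") {
      # one G:U wobble at the first position in 3..8 where the miRNA has G/T
      i <- which(mir_ch %in% c("G", "T") & seq_len(L) >= 3 &
                   seq_len(L) <= 8)[1]
      if (is.na(i)) i <- which(mir_ch %in% c("G", "T"))[1]
      site[mpos_to_w(i)] <- ifelse(mir_ch[i] == "G", "T", "G")
    } else if (outcomes[k] == "fail_rule2") {
      # full mismatch at miRNA position 10
      site[mpos_to_w(10L)] <- setdiff(c("A", "C"),
                                      c(mir_ch[10], COMPLEMENT[mir_ch[10]]))[1]
    } else if (outcomes[k] == "fail_rule1") {
      # three adjacent full mismatches at positions 18-20
      for (i in 18:20) {
        repl <- setdiff(c("A", "C", "G", "T"),
                        c(COMPLEMENT[mir_ch[i]],
                          if (mir_ch[i] %in% c("G", "T"))
                            c(G = "T", T = "G")[mir_ch[i]]))
        site[mpos_to_w(i)] <- repl[1]
      }
    }
    g <- which(genes$id == sites$gene_id[k])
    genes$seq[g] <- paste0(substr(genes$seq[g], 1, site_start - 1),
                           paste(site, collapse = ""),
                           substr(genes$seq[g], site_start + L,
                                  cfg$gene_len))
  }
  # novel precursors expose a perfect-complement star site to their own arm
  precursor_sites <- tibble::tibble(
    mirna_id = sprintf("novel-arm-%02d", seq_len(cfg$n_novel)),
    mirna_seq = novel_tags, gene_id = novel$contig,
    start = NA_integer_, outcome = "pass_precursor")

  ## --- mRNA expression ------------------------------------------------
  pass_sites <- which(sites$outcome %in% c("pass_perfect", "pass_gu"))
  anti_idx <- sort(sample(pass_sites, cfg$n_anticorr))
  sigma <- sqrt(1 / cfg$r_true^2 - 1)
  mrna <- matrix(round(stats::rlnorm(cfg$n_genes * 8, log(800), 0.5)),
                 cfg$n_genes, 8, dimnames = list(genes$id, libs))
  for (k in anti_idx) {
    z <- mir_counts[site_mirna[k], ]
    zs <- if (sd(z) > 0) (z - mean(z)) / sd(z) else rnorm(8)
    y <- -zs + sigma * rnorm(8)
    mrna[sites$gene_id[k], ] <- round(pmax(0, 1000 + 250 * y))
  }
  anti <- sites[anti_idx, c("mirna_id", "gene_id")]
  anti$r_true <- cfg$r_true

  ## --- annotations ----------------------------------------------------
  dem_targets <- sites$gene_id[sites$outcome %in% c("pass_perfect", "pass_gu") &
                                 sites$mirna_id %in% mature$id[dem_idx]]
  path_ids <- sprintf("ko%05d", sample.int(99999, cfg$n_pathways))
  enriched_terms <- path_ids[seq_len(cfg$n_enriched)]
  ann <- tibble::tibble(
    gene_id = sample(genes$id, 3 * cfg$n_genes, replace = TRUE),
    term_id = sample(path_ids[-seq_len(cfg$n_enriched)], 3 * cfg$n_genes,
                     replace = TRUE))
  # concentrate DEM-target genes into the enriched terms
  conc <- tibble::tibble(
    gene_id = rep(dem_targets, length.out = 4 * length(enriched_terms)),
    term_id = rep(enriched_terms, each = 4))
  pathway_ann <- dplyr::distinct(dplyr::bind_rows(ann, conc)) |>
    dplyr::mutate(name = paste("Pathway", .data$term_id))
  go_ids <- sprintf("GO:%07d", sample.int(9999999, cfg$n_go_terms))
  go_ann <- tibble::tibble(
    gene_id = sample(genes$id, 2 * cfg$n_genes, replace = TRUE),
    term_id = sample(go_ids, 2 * cfg$n_genes, replace = TRUE)) |>
    dplyr::distinct() |>
    dplyr::mutate(name = paste("Term", .data$term_id),
                  namespace = sample(c("BP", "MF", "CC"), dplyr::n(),
                                     replace = TRUE))

  ## --- reads ----------------------------------------------------------
  qual_of <- function(seqs) strrep("I", nchar(seqs))
  fastq_paths <- setNames(file.path(dir, paste0(libs, ".fastq")), libs)
  all_tags <- c(mature$seq, novel_tags, ncrna_frags)
  all_counts <- rbind(mir_counts, novel_counts, frag_counts)
  # planted mRNA-degradation fragments from non-hairpin, non-site genes
  frag_genes <- sample((cfg$n_novel + n_sites + 1):cfg$n_genes,
                       cfg$n_mrna_frags)
  mrna_frags <- substr(genes$seq[frag_genes], 30, 50)
  filler_tags <- clean_insert_seq(cfg$n_filler, 20:24, cfg)
  all_tags <- c(all_tags, mrna_frags, filler_tags)
  all_counts <- rbind(all_counts, draw_counts(mfrag_mu),
                      draw_counts(filler_mu))
  for (l in libs) {
    clean <- rep(all_tags, all_counts[, l])
    reads <- paste0(clean, cfg$adapter3)
    quals <- qual_of(reads)
    n_c <- round(cfg$contaminant_rates * cfg$depth)
    mk <- function(n, len = 21) clean_insert_seq(n, len, cfg)
    contam <- list(
      low_quality = paste0(mk(n_c[["low_quality"]]), cfg$adapter3),
      contains_n = paste0(sub("^.", "N", mk(n_c[["contains_n"]])),
                          cfg$adapter3),
      no_3p_adapter = mk(n_c[["no_3p_adapter"]], 30),
      has_5p_adapter = paste0(substr(cfg$adapter5, 1, 8),
                              mk(n_c[["has_5p_adapter"]]), cfg$adapter3),
      no_insert = rep(cfg$adapter3, n_c[["no_insert"]]),
      polya = paste0(strrep("A", 22), cfg$adapter3),
      too_short = paste0(mk(n_c[["too_short"]], 15), cfg$adapter3),
      too_long = paste0(mk(n_c[["too_long"]], 35), cfg$adapter3))
    contam$polya <- rep(contam$polya[1], n_c[["polya"]])
    cseqs <- unlist(contam, use.names = FALSE)
    cquals <- qual_of(cseqs)
    # low-quality class: two bases at Q = 2
    nlq <- n_c[["low_quality"]]
    if (nlq > 0) {
      substr(cquals[seq_len(nlq)], 1, 2) <- "##"
    }
    seqs <- c(reads, cseqs)
    quals <- c(quals, cquals)
    ord <- sample.int(length(seqs))
    write_fastq(tibble::tibble(
      read_id = sprintf("%s_r%07d", l, seq_along(seqs)),
      seq = seqs[ord], qual = quals[ord]), fastq_paths[[l]])
  }

  ## --- qPCR Ct table --------------------------------------------------
  qpcr_idx <- c(sample(which(class == "up4x"), 2),
                sample(which(class == "down4x"), 2),
                sample(which(class == "null"),
                       cfg$n_qpcr_assays - 4))
  ct_rows <- list()
  for (tp in TIMEPOINTS) {
    ct_rows[[length(ct_rows) + 1]] <- tibble::tibble(
      sample = paste0(tp, "-q"), timepoint = tp, assay = "U6",
      ct1 = 20 + rnorm(1, 0, 0.05), ct2 = 20 + rnorm(1, 0, 0.05),
      ct3 = 20 + rnorm(1, 0, 0.05))
    for (i in qpcr_idx) {
      dct <- 3 - log2(mult[i, tp])
      ct_rows[[length(ct_rows) + 1]] <- tibble::tibble(
        sample = paste0(tp, "-q"), timepoint = tp, assay = mature$id[i],
        ct1 = 20 + dct + rnorm(1, 0, 0.05),
        ct2 = 20 + dct + rnorm(1, 0, 0.05),
        ct3 = 20 + dct + rnorm(1, 0, 0.05))
    }
  }
  ct_table <- dplyr::bind_rows(ct_rows)

  ## --- write bundle ---------------------------------------------------
  write_fasta(mature[c("id", "seq")], file.path(dir, "mature_ref.fa"))
  write_fasta(ncrna, file.path(dir, "ncrna_ref.fa"))
  write_fasta(genes, file.path(dir, "transcriptome.fa"))
  mrna_tbl <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mrna)),
                               tibble::as_tibble(mrna))
  write_tsv_quiet(mrna_tbl, file.path(dir, "mrna_expr.tsv"))
  write_tsv_quiet(pathway_ann, file.path(dir, "pathway_annotation.tsv"))
  write_tsv_quiet(go_ann, file.path(dir, "go_annotation.tsv"))
  write_tsv_quiet(ct_table, file.path(dir, "ct_table.tsv"))

  truth <- list(
    seed = cfg$seed,
    mirnas = dplyr::bind_cols(
      mirnas[c("id", "seq", "family", "class")],
      tibble::as_tibble(mir_mu / cfg$depth * 1e6) |>
        setNames(paste0("tpm_", TIMEPOINTS))),
    novel = novel,
    ncrna_frags = tibble::tibble(seq = ncrna_frags),
    mrna_frags = tibble::tibble(seq = mrna_frags,
                                gene_id = genes$id[frag_genes]),
    sites = dplyr::bind_rows(sites[c("mirna_id", "gene_id", "start",
                                     "outcome")],
                             precursor_sites[c("mirna_id", "gene_id",
                                               "start", "outcome")]),
    anticorr = anti,
    enriched_terms = enriched_terms,
    qpcr_assays = mature$id[qpcr_idx])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", digits = NA)

  inputs <- list(
    fastq = fastq_paths,
    mature_fa = file.path(dir, "mature_ref.fa"),
    ncrna_fa = file.path(dir, "ncrna_ref.fa"),
    transcriptome_fa = file.path(dir, "transcriptome.fa"),
    mrna_expr = file.path(dir, "mrna_expr.tsv"),
    pathway_annotation = file.path(dir, "pathway_annotation.tsv"),
    go_annotation = file.path(dir, "go_annotation.tsv"),
    ct_table = file.path(dir, "ct_table.tsv"),
    adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  list(inputs = inputs, truth = truth,
       tables = list(mature = mature, ncrna = ncrna, genes = genes,
                     mrna = mrna_tbl, pathway_ann = pathway_ann,
                     go_ann = go_ann, ct = ct_table))
}

#' Compare pipeline outputs against the planted truth
#'
#' @param results List returned by [run_pipeline()].
#' @param truth Truth list from [simulate_bundle()].
#' @returns Tibble `stage`, `metric`, `value`.
#' @export
truth_eval <- function(results, truth) {
  need <- c("annotations", "dems", "targets", "pairs", "enrichment")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing pipeline output for stage: ", miss[1],
                         call. = FALSE)
  ann <- results$annotations
  m <- list()
  add <- function(stage, metric, value) {
    m[[length(m) + 1]] <<- tibble::tibble(stage = stage, metric = metric,
                                          value = value)
  }

  known_seqs <- truth$mirnas$seq
  seen <- known_seqs %in% ann$seq
  lab <- ann$category[match(known_seqs, ann$seq)]
  add("annotate", "known_recall", mean(lab[seen] == "known_mirna"))
  nc_lab <- ann$category[match(truth$ncrna_frags$seq, ann$seq)]
  add("annotate", "ncrna_as_known", sum(nc_lab == "known_mirna", na.rm = TRUE))
  nov_lab <- ann$category[match(truth$novel$seq, ann$seq)]
  add("annotate", "novel_recall", mean(nov_lab == "novel_candidate",
                                       na.rm = TRUE))

  de <- results$dems[results$dems$comparison == "CK-VS-T1", ]
  cls <- truth$mirnas$class[match(de$mirna_id, truth$mirnas$id)]
  planted <- !is.na(cls) & cls != "null"
  add("diffexpr", "dem_recall", mean(de$significant[planted]))
  add("diffexpr", "dem_type1",
      mean(de$significant[!is.na(cls) & cls == "null"]))

  truth_pass <- truth$sites[grepl("^pass", truth$sites$outcome), ]
  got <- paste(results$targets$mirna_id, results$targets$gene_id)
  want <- paste(truth_pass$mirna_id, truth_pass$gene_id)
  # precursor self-sites carry synthetic ids; match them by gene instead
  prec <- truth_pass$outcome == "pass_precursor"
  want_gene_only <- truth_pass$gene_id[prec]
  planted_hit <- got %in% want |
    results$targets$gene_id %in% want_gene_only
  add("targets", "site_precision", mean(planted_hit))
  add("targets", "site_recall",
      mean(want[!prec] %in% got))
  fail_sites <- truth$sites[grepl("^fail", truth$sites$outcome), ]
  add("targets", "fail_sites_recovered",
      sum(paste(fail_sites$mirna_id, fail_sites$gene_id) %in% got))

  pr <- results$pairs
  key <- paste(pr$mirna_id, pr$gene_id)
  akey <- paste(truth$anticorr$mirna_id, truth$anticorr$gene_id)
  flagged <- pr$anti_correlated[match(akey, key)]
  add("targets", "anticorr_flagged", mean(flagged, na.rm = FALSE))

  enr <- results$enrichment[["CK-VS-T1"]]
  if (!is.null(enr)) {
    kegg <- enr[is.na(enr$namespace) | enr$namespace == "KEGG", ]
    hit <- truth$enriched_terms %in% kegg$term_id[kegg$p_value < 0.05]
    add("enrichment", "planted_terms_significant", mean(hit))
    null_terms <- setdiff(kegg$term_id, truth$enriched_terms)
    add("enrichment", "null_term_fpr",
        mean(kegg$p_value[kegg$term_id %in% null_terms] < 0.05))
  }
  dplyr::bind_rows(m)
}
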