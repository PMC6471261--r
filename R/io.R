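#' Read a FASTQ file into a tibble
#'
#' Parses 4-line FASTQ records with Phred+33 qualities. Qualities are kept
#' as the encoded string (see [phred_scores()] to decode); any character
#' implying a score above 60 is rejected as a likely Phred+64 file rather
#' than silently re-interpreted.
#'
#' @param path FASTQ file (plain text or gzip).
#' @returns Tibble with columns `read_id`, `seq`, `qual` (encoded string).
#'   Record order matches the file.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          qual = character()))
  }
  if (length(lines) %% 4 != 0) {
    stop("FASTQ parse error at line ", length(lines),
         ": truncated record (line count not a multiple of 4)", call. = FALSE)
  }
  idx <- seq(1, length(lines), by = 4)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1])
  plus <- lines[idx + 2]
  qual <- lines[idx + 3]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1]],
         ": header does not start with '@'", call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1]] + 2,
         ": separator line does not start with '+'", call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1]] + 3,
         ": quality length differs from sequence length", call. = FALSE)
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1]] + 1,
         ": sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  # Phred+33 scores live in '!'(0) .. ']'(60); anything above points at
  # a Phred+64 file, which is rejected explicitly rather than guessed at.
  bad <- which(grepl("[^\\x21-\\x5d]", qual, perl = TRUE))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1]] + 3,
         ": quality character outside Phred+33 range [0, 60]",
         " (Phred+64 input is not supported)", call. = FALSE)
  }
  tibble::tibble(read_id = sub("^@", "", hdr), seq = seqs, qual = qual)
}

#' Decode Phred+33 quality strings
#'
#' @param qual Character vector of encoded quality strings.
#' @returns List of integer vectors (one score per base).
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (nchar(q) == 0) return(integer())
    utf8ToInt(q) - 33L
  })
}

#' @rdname read_fastq
#' @param reads Tibble as returned by [read_fastq()].
#' @export
write_fastq <- function(reads, path) {
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read / write FASTA as a two-column tibble
#'
#' Uses Biostrings when installed; otherwise falls back to a plain-text
#' reader. Sequences are uppercased and U is mapped to T so that every
#' downstream comparison works on the DNA alphabet.
#'
#' @param path FASTA file.
#' @returns Tibble with columns `id` (first word of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- toupper(as.character(ss))
  } else {
    lines <- readLines(path)
    at <- grepl("^>", lines)
    if (!any(at)) stop("no FASTA records in ", path, call. = FALSE)
    grp <- cumsum(at)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[at]))
    seqs <- toupper(vapply(split(lines[!at], grp[!at]), paste0,
                           character(1), collapse = ""))
  }
  tibble::tibble(id = ids, seq = chartr("U", "T", unname(seqs)))
}

#' @rdname read_fasta
#' @param seqs Tibble with columns `id` and `seq`.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", seqs$id, "\n", seqs$seq), path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' @param path Tab-separated file: first column gene ids, remaining columns
#'   one per library.
#' @param sample_sheet Optional sample sheet; when given, columns are
#'   reordered to its `library_id` order and all must be present.
#' @returns Tibble, first column `gene_id`, then one numeric column per
#'   library.
#' @export
read_expression_tsv <- function(path, sample_sheet = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  if (anyDuplicated(x$gene_id)) {
    stop("duplicate gene id in ", path, ": ",
         x$gene_id[duplicated(x$gene_id)][1], call. = FALSE)
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path,
                              call. = FALSE)
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative expression value in ", path, call. = FALSE)
  }
  if (!is.null(sample_sheet)) {
    miss <- setdiff(sample_sheet$library_id, names(x))
    if (length(miss)) stop("expression table ", path, " lacks libraries: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    x <- x[c("gene_id", sample_sheet$library_id)]
  }
  x
}

#' Read a gene-to-term annotation table
#'
#' Two or three tab-separated columns: `gene_id`, `term_id` and an optional
#' `name`. Duplicate memberships collapse to a set; genes keep at least one
#' term by construction.
#'
#' @param path TSV file.
#' @returns Tibble with columns `gene_id`, `term_id`, `name` (NA when the
#'   file has no name column), one row per distinct membership.
#' @export
read_annotation_tsv <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (nrow(x) == 0) {
    return(tibble::tibble(gene_id = character(), term_id = character(),
                          name = character()))
  }
  # tolerate a header row
  if (identical(tolower(as.character(x[1, 1])), "gene_id")) x <- x[-1, ]
  if (ncol(x) < 2) stop("annotation table needs >= 2 columns", call. = FALSE)
  out <- tibble::tibble(
    gene_id = as.character(x[[1]]),
    term_id = as.character(x[[2]]),
    name = if (ncol(x) >= 3) as.character(x[[3]]) else NA_character_
  )
  if (any(is.na(out$gene_id) | out$gene_id == "")) {
    stop("blank gene id in ", path, call. = FALSE)
  }
  # one name per term; multiplicity of membership collapses to a set
  out |>
    dplyr::group_by(.data$term_id) |>
    dplyr::mutate(name = .data$name[which(!is.na(.data$name))[1] %||% 1L]) |>
    dplyr::ungroup() |>
    dplyr::distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
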