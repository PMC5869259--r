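#' Construct a validated count matrix
#'
#' The sequencing-level input: non-negative integer read counts per gene
#' and sample, with per-gene exon length (kb) and per-sample mapped-read
#' totals (millions) — the three quantities of the RPKM formula.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param exon_length_kb positive numeric vector, one entry per gene.
#' @param mapped_reads_millions positive numeric vector, one per sample.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, exon_length_kb, mapped_reads_millions) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  exon_length_kb <- exon_length_kb[gene_ids]
  mapped_reads_millions <- mapped_reads_millions[sample_ids]
  if (anyNA(exon_length_kb) || any(exon_length_kb <= 0)) {
    bad <- gene_ids[which(is.na(exon_length_kb) | exon_length_kb <= 0)[1L]]
    stop("exon_length_kb missing or non-positive for gene: ", bad)
  }
  if (anyNA(mapped_reads_millions) || any(mapped_reads_millions <= 0)) {
    bad <- sample_ids[which(is.na(mapped_reads_millions) |
                              mapped_reads_millions <= 0)[1L]]
    stop("mapped_reads_millions missing or non-positive for sample: ", bad)
  }
  structure(list(counts = counts, exon_length_kb = exon_length_kb,
                 mapped_reads_millions = mapped_reads_millions),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write / read the counts table
#'
#' Tab-delimited, UTF-8: `gene_id`, `exon_length_kb`, then one numeric
#' column per sample. Mapped-read totals travel in the design table.
#'
#' @param cm a [count_matrix()].
#' @param path file path.
#' @return `write_counts` returns `path` invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts),
                   exon_length_kb = unname(cm$exon_length_kb),
                   cm$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts
#' @param design the sample design data frame carrying
#'   `mapped_reads_millions` (see [read_design()]); required to rebuild
#'   the full [count_matrix()].
#' @export
read_counts <- function(path, design) {
  df <- read_tsv(path)
  for (col in c("gene_id", "exon_length_kb"))
    if (!col %in% names(df)) stop("counts file missing required column: ", col)
  sample_cols <- setdiff(names(df), c("gene_id", "exon_length_kb"))
  if (length(sample_cols) == 0L) stop("counts file has no sample columns")
  for (col in sample_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric count in column '", col, "', row ", bad[1L] + 1L,
           " of ", path)
    df[[col]] <- v
  }
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts,
               exon_length_kb = setNames(df$exon_length_kb, df$gene_id),
               mapped_reads_millions = setNames(design$mapped_reads_millions,
                                                design$sample_id))
}

#' Write / read the sample design table
#'
#' Tab-delimited with mandatory header: `sample_id`, `animal_id`,
#' `state` (pre/post), `tissue`, `library_id`, `mapped_reads_millions`.
#'
#' @param design data frame with the columns above.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- read_tsv(path)
  required <- c("sample_id", "animal_id", "state", "tissue", "library_id",
                "mapped_reads_millions")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("design file missing required column: ", missing[1L])
  validate_design(df)
  df
}

validate_design <- function(design) {
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         design$sample_id[duplicated(design$sample_id)][1L])
  if (!all(design$state %in% c("pre", "post")))
    stop("state must be 'pre' or 'post'")
  if (length(unique(design$state)) < 2L)
    stop("both states (pre, post) must be present")
  st <- tapply(design$state, design$animal_id, function(s) length(unique(s)))
  if (any(st > 1L))
    stop("animal mapped to more than one state: ", names(st)[st > 1L][1L])
  invisible(design)
}

#' Read a transcription-factor id list (one id per line)
#'
#' @param path file path.
#' @return character vector of unique, non-empty ids.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- readLines(path, encoding = "UTF-8")
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}
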