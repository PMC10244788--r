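#' Expression study container
#'
#' The universal input of the pipeline: a genes x samples numeric matrix
#' plus one metadata record per sample. Metadata must carry `sample_id`,
#' `age` (years; `NA` allowed for tumor/normal cohorts), `phenotype`, and
#' may carry `cohort`, `split`, `time`, `event`.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param samples Data frame of per-sample metadata aligned to the columns.
#' @return An `expression_study` object.
#' @export
expression_study <- function(matrix, samples) {
  stopifnot(is.matrix(matrix), is.data.frame(samples))
  if (ncol(matrix) != nrow(samples)) {
    stop("matrix has ", ncol(matrix), " columns but metadata has ",
         nrow(samples), " rows")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix must have gene rownames and sample colnames")
  }
  if (!all(c("sample_id", "phenotype") %in% names(samples))) {
    stop("metadata must contain sample_id and phenotype columns")
  }
  if (!identical(colnames(matrix), as.character(samples$sample_id))) {
    stop("matrix column names must equal metadata sample_id, in order")
  }
  structure(list(matrix = matrix, samples = samples),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  tab <- table(x$samples$phenotype)
  cat("  phenotypes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$matrix)

#' Subset an expression study by genes and/or samples
#'
#' @param study An `expression_study`.
#' @param genes Optional character vector of gene symbols to keep.
#' @param samples Optional logical/integer index or character sample ids.
#' @return A new `expression_study`.
#' @export
subset_study <- function(study, genes = NULL, samples = NULL) {
  mat <- study$matrix
  meta <- study$samples
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, colnames(mat))
    mat <- mat[, samples, drop = FALSE]
    meta <- meta[samples, , drop = FALSE]
    rownames(meta) <- NULL
  }
  expression_study(mat, meta)
}

#' Write / read an expression study as TSV
#'
#' The on-disk dialect is two files under `dir`: `matrix.tsv` (gene rows,
#' first column `gene`, then one column per sample) and `samples.tsv`
#' (the metadata records).
#'
#' @param study An `expression_study`.
#' @param dir Directory (created if absent).
#' @return `write_study` returns `dir` invisibly; `read_study` returns an
#'   `expression_study`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_df <- data.frame(gene = rownames(study$matrix), study$matrix,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mat_df, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  mat_df <- utils::read.delim(file.path(dir, "matrix.tsv"),
                              check.names = FALSE)
  meta <- utils::read.delim(file.path(dir, "samples.tsv"),
                            colClasses = c(sample_id = "character"))
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- mat_df$gene
  expression_study(mat, meta)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set format: one set per line, fields are
#' set name, description, then member gene symbols.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    sets[[fields[[1]]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path` invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
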