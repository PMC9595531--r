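#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV layout: header row of sample ids, first column gene ids. GCT 1.2:
#' `#1.2` line, a `n_genes n_samples` line, then a table whose first two
#' columns are NAME and Description.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; default guesses from the extension.
#' @param stage stage tag to attach (input files are TPM by convention).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"), stage = "tpm") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") return(read_gct(path, stage = stage))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = NULL, colClasses = NA, comment.char = "")
  gene_ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    bad <- which(nonnum)[1]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[bad]]))))[1]
    stop(sprintf("non-numeric cell in column '%s' near line %d of %s",
                 names(vals)[bad], row + 1L, path))
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  expression_matrix(m, stage)
}

read_gct <- function(path, stage = "tpm") {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^#1\\.2", lines[1]))
    stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("GCT dimension line malformed in ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2,
                           check.names = FALSE, comment.char = "")
  if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2])
    stop(sprintf("GCT header declares %d x %d but table is %d x %d",
                 dims[1], dims[2], nrow(tab), ncol(tab) - 2L))
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  expression_matrix(m, stage)
}

#' Write an expression matrix
#'
#' @param expr an [expression_matrix()] or plain named matrix.
#' @param path output path.
#' @param digits significant digits for serialization.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path, digits = 12) {
  write_matrix_tsv(unclass_matrix(expr), path, id_col = "gene_id", digits = digits)
}

#' @rdname write_expression_tsv
#' @export
write_expression_gct <- function(expr, path, digits = 12) {
  m <- unclass_matrix(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  header <- paste(c("NAME", "Description", colnames(m)), collapse = "\t")
  writeLines(header, con)
  body <- apply(signif(m, digits), 1, paste, collapse = "\t")
  writeLines(paste(rownames(m), "na", body, sep = "\t"), con)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "id", digits = 12) {
  df <- data.frame(rownames(m), signif(m, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Read a gene-set collection from GMT
#'
#' Each line: set name, description, member genes, tab-separated. The
#' description field is kept as an optional category label (a stand-in for
#' pathway-class annotations such as KEGG BRITE).
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `categories` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names_))
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  cats <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", character(1))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- names_
  names(cats) <- names_
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping empty gene sets: ", paste(names_[empty], collapse = ", "))
    sets <- sets[!empty]
    cats <- cats[!empty]
  }
  gene_set_collection(sets, cats)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors of gene ids.
#' @param categories optional named character vector of category labels.
#' @return a `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, categories = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  if (is.null(categories)) categories <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, categories = categories[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene set collection: %d sets, median size %d\n",
              length(x$sets), as.integer(stats::median(lengths(x$sets)))))
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param gsc a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$categories[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects columns `sample_id`, `batch`, `ischemic_time`, `sex`,
#' `age_bracket`, `hardy_code`.
#'
#' @param path TSV path.
#' @return a data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "batch", "ischemic_time", "sex", "age_bracket", "hardy_code")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (!all(meta$hardy_code %in% 0:4))
    stop("hardy_code values must be in 0..4")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  invisible(meta)
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-gene-per-line list file
#' @param path text file, one identifier per line; blank lines and `#`
#'   comments ignored.
#' @return character vector of unique ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname read_gene_list
#' @param genes character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
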