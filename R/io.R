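#' Read and write the pipeline's tabular formats
#'
#' Expression matrices travel as TSV with the row identifier in the first
#' column and sample ids in the header; sample designs as two-column TSV
#' (`sample`, `group` with groups `control` / `perturbed`); gene sets as GMT;
#' interaction networks as two-column edge-list TSV or three-column SIF.
#' Lines starting with `#` are treated as comments (provenance headers).
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path file path.
#' @param header optional character vector of comment lines to prepend
#'   (written as `# ...`).
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_expression_tsv <- function(expr, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyNA(m)) stop("expression matrix contains missing values")
  m
}

#' @rdname pipeline_io
#' @param design data frame with columns `sample`, `group`.
#' @export
write_design_tsv <- function(design, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("sample\tgroup", con)
  writeLines(paste(design$sample, design$group, sep = "\t"), con)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_design_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   colClasses = "character")
  if (!all(c("sample", "group") %in% names(df)))
    stop("design file must have columns 'sample' and 'group'")
  df
}

#' @rdname pipeline_io
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname pipeline_io
#' @param edges data frame with columns `from`, `to` (and optionally
#'   `confidence`).
#' @export
write_edge_tsv <- function(edges, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_edge_tsv <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             colClasses = "character")
}

#' @rdname pipeline_io
#' @param interaction SIF interaction type written in the middle column.
#' @export
write_sif <- function(edges, path, interaction = "interacts") {
  writeLines(paste(edges$from, interaction, edges$to, sep = "\t"), path)
  invisible(path)
}
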