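#' Read and write probes-x-samples expression matrices as TSV
#'
#' The on-disk layout is a header row of sample ids, a `probe_id` first
#' column, and tab-separated log2 values.
#'
#' @param path file path.
#' @return `read_expression_tsv`: numeric matrix with probe rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param matrix numeric matrix with probe rownames and sample colnames.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(probe_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Empty member fields are dropped.
#'
#' @param path file path.
#' @return named list of character vectors (class `"geneset_collection"`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  structure(sets, class = "geneset_collection")
}

#' @rdname read_gmt
#' @param collection named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write sample metadata / qPCR tables as TSV
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_metadata_tsv
#' @param df data.frame to write.
#' @export
write_metadata_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_metadata_tsv
#' @export
read_qpcr_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "ct", "tod")
  if (!all(need %in% names(df)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  df
}
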