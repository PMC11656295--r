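# Plain-text readers and writers for the formats the pipeline consumes:
# tab-delimited count matrices, two-column label and ID-conversion tables,
# and GMT gene set databases.

#' Read / write a tab-delimited count matrix
#'
#' First column holds gene IDs, the header row holds sample IDs.
#'
#' @param path file path.
#' @return integer matrix with gene IDs as rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  check_count_matrix(m)
}

#' @rdname read_counts
#' @param counts count matrix.
#' @export
write_counts <- function(counts, path) {
  check_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column sample label table
#'
#' Columns `sample` and `condition` (tab-delimited, with header).
#'
#' @param path file path.
#' @param origin label origin recorded on the returned object.
#' @return a [label_assignment()].
#' @export
read_labels <- function(path, origin = "true") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  label_assignment(df$sample, df$condition, origin = origin)
}

#' @rdname read_labels
#' @param labels a [label_assignment()].
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_assignment"))
  utils::write.table(
    data.frame(sample = labels$sample_ids,
               condition = as.character(labels$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene set database in GMT format
#'
#' One set per line: name, description, then the member gene IDs, all
#' tab-separated.
#'
#' @param path file path.
#' @param name database name attached to the returned object.
#' @return a [gene_set_db()].
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) {
    if (length(f) < 3) stop_gv("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(fields, `[[`, "", 1)
  gene_set_db(sets, name = name)
}

#' @rdname read_gmt
#' @param db a [gene_set_db()].
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(db, path, descriptions = NULL) {
  stopifnot(inherits(db, "gene_set_db"))
  desc <- descriptions %||% rep("na", length(db$sets))
  lines <- vapply(seq_along(db$sets), function(i) {
    paste(c(names(db$sets)[i], desc[i], db$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-column gene ID conversion table
#'
#' Columns `source` and `target` (tab-delimited, with header); each source
#' ID appears at most once, several sources may share a target.
#'
#' @param path file path.
#' @return data.frame of class `id_conversion_table`.
#' @export
read_id_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df))) {
    stop_gv("ID table needs columns 'source' and 'target'")
  }
  if (anyDuplicated(df$source) > 0) stop_gv("duplicated source IDs")
  class(df) <- c("id_conversion_table", "data.frame")
  df
}

#' @rdname read_id_table
#' @param table an `id_conversion_table`.
#' @export
write_id_table <- function(table, path) {
  utils::write.table(table[c("source", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a result table as tab-delimited text
#'
#' Works for `de_result`, `gsa_result` and any plain data.frame.
#'
#' @param x data.frame.
#' @param path file path.
#' @export
export_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
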