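#' Read a genes-by-samples expression table
#'
#' Delimited text with a header row of sample ids and gene ids in the
#' first column. Enforces rectangularity, unique gene and sample ids and
#' finite numeric values, naming the offending cell on failure.
#'
#' @param path Path to the table.
#' @param sep Field separator (default tab).
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           row.names = NULL, fill = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs gene ids plus >= 1 sample")
  genes <- tab[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ", genes[duplicated(genes)][1L])
  }
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1L])
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric cell at gene '", genes[bad[1L, 1L]], "', sample '",
         samples[bad[1L, 2L]], "': ", vals[bad[1L, , drop = FALSE]])
  }
  if (any(!is.finite(num))) stop("non-finite expression values")
  dimnames(num) <- list(genes, samples)
  num
}

#' Write an expression matrix as delimited text
#'
#' Counterpart of [read_expression_table()]; a write-then-read round trip
#' is the identity.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path, sep = "\t") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

de_timepoints <- c("3h_direct", "8h", "24h", "72h", "9d", "meta")

#' Read a differential-expression evidence table
#'
#' Delimited text with columns `gene_id`, `timepoint`, `direction`.
#' Timepoints come from the closed vocabulary
#' `3h_direct, 8h, 24h, 72h, 9d, meta`; direction is `up` or `down`.
#'
#' @param path Path to the table.
#' @param sep Field separator.
#' @return A data.frame of DE records, deduplicated per (gene, timepoint).
#' @export
read_de_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("DE table not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "timepoint", "direction") %in% names(tab)))
  validate_de_records(tab)
}

#' @rdname read_de_table
#' @param records DE record data.frame.
#' @export
write_de_table <- function(records, path, sep = "\t") {
  records <- validate_de_records(records)
  utils::write.table(records, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_de_records <- function(records) {
  bad <- setdiff(unique(records$timepoint), de_timepoints)
  if (length(bad) > 0L) {
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  }
  if (!all(records$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'")
  }
  records[!duplicated(records[, c("gene_id", "timepoint")]), , drop = FALSE]
}

#' Read or write a one-id-per-line gene list
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids[nzchar(ids)]
}

#' @rdname read_gene_list
#' @param ids Character vector of gene ids.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
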