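# Sample x taxon relative-abundance tables (percent per sample).

#' Relative-abundance table
#'
#' Validates and classes a sample x taxon matrix of relative abundances in
#' percent.  Rows are samples (metagenomes), columns taxa (e.g., microbial
#' classes).  Row sums may fall below 100 when rare taxa were dropped, but
#' may not exceed it beyond numerical tolerance.
#'
#' @param values numeric matrix (sample x taxon), percentages, all >= 0.
#' @param sample_ids,taxon_ids optional labels; default to existing dimnames
#'   or generated ones.
#' @param tol slack allowed above a row sum of 100.
#' @return a matrix of class `abundance_table`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values), tol = 1e-6) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop_("abundance values must be numeric with no missing entries")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop_("duplicate sample IDs")
  if (anyDuplicated(taxon_ids)) stop_("duplicate taxon IDs")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop_("negative abundance at sample '%s', taxon '%s'",
          sample_ids[neg[1L, 1L]], taxon_ids[neg[1L, 2L]])
  bad <- which(rowSums(values) > 100 + tol)
  if (length(bad))
    stop_("sample '%s' sums to %.4f%% (> 100%%)",
          sample_ids[bad[1L]], sum(values[bad[1L], ]))
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(values, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa (%%)\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L))
  invisible(x)
}

#' Read / write an abundance table
#'
#' CSV or TSV with sample IDs in the first column and taxon names in the
#' header; values are relative abundances in percent.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`; guessed from the extension by default.
#' @return [read_abundance_table()]: an [abundance_table()];
#'   [write_abundance_table()]: `path`, invisibly.
#' @export
read_abundance_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE))
      "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_("'%s': expected sample-ID column plus taxa", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop_("'%s': non-numeric abundance values", path)
  rownames(m) <- as.character(df[[1L]])
  abundance_table(m)
}

#' @rdname read_abundance_table
#' @param table an [abundance_table()].
#' @export
write_abundance_table <- function(table, path,
                                  dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE))
      "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a growth-parameter table
#'
#' CSV with header `taxon,r_max,mu,sigma`: per-taxon maximum growth-rate
#' scale (per day), mean ideal growth temperature and ideal-temperature
#' range (degC), as compiled from cultured representatives.
#'
#' @param path file path.
#' @return a [growth_params()] table.
#' @export
read_growth_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  as_growth_params(df)
}

#' @rdname read_growth_table
#' @param params a [growth_params()] table.
#' @export
write_growth_table <- function(params, path) {
  params <- as_growth_params(params)
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
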