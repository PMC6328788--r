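#' Column dialects for mutation tables
#'
#' A dialect maps the canonical record fields onto the column names of a
#' tab-separated export. Two dialects ship with the package:
#' \code{"cosmic"} for the COSMIC GenomeScreens mutant export (gene
#' symbols carrying a transcript suffix, e.g. \code{"TP53_ENST..."},
#' are truncated at the first underscore because scoring is per gene),
#' and \code{"canonical"} for files written by
#' \code{\link{writeMutationTable}}.
#'
#' @param name dialect name, \code{"cosmic"} or \code{"canonical"}.
#' @return named list with entries \code{sample_id}, \code{gene},
#'   \code{localization}, \code{description}, \code{mutation_id},
#'   \code{cds_length} (column names) and \code{strip_gene_suffix}.
#' @export
mutationDialect <- function(name = c("cosmic", "canonical")) {
  name <- match.arg(name)
  switch(name,
    cosmic = list(sample_id = "ID_sample",
                  gene = "Gene name",
                  localization = "Primary site",
                  description = "Mutation Description",
                  mutation_id = "Mutation ID",
                  cds_length = "Gene CDS length",
                  strip_gene_suffix = TRUE,
                  name = "cosmic"),
    canonical = list(sample_id = "sample_id",
                     gene = "gene",
                     localization = "localization",
                     description = "description",
                     mutation_id = "mutation_id",
                     cds_length = "cds_length",
                     strip_gene_suffix = FALSE,
                     name = "canonical"))
}

#' Read a somatic mutation table
#'
#' Parses a tab-separated mutation export into a
#' \linkS4class{MutationTable}. Gzip-compressed files are read
#' transparently. Rows missing the gene symbol or the sample identifier
#' are dropped and tallied in the provenance; an unreadable or
#' non-positive CDS length keeps the record with \code{cds_length = NA}.
#'
#' @param path path to a (optionally gzipped) TSV file with a header.
#' @param dialect a dialect list from \code{\link{mutationDialect}}, or
#'   a dialect name.
#' @return a \linkS4class{MutationTable}.
#' @export
readMutationTable <- function(path, dialect = mutationDialect("cosmic")) {
  if (is.character(dialect)) dialect <- mutationDialect(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(gzfile(path), check.names = FALSE,
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  mapped <- unlist(dialect[.MUT_COLS])
  missing_cols <- setdiff(mapped, colnames(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from header: ",
         paste(missing_cols, collapse = ", "))
  rec <- data.frame(sample_id = raw[[dialect$sample_id]],
                    gene = raw[[dialect$gene]],
                    localization = raw[[dialect$localization]],
                    description = raw[[dialect$description]],
                    mutation_id = raw[[dialect$mutation_id]],
                    cds_length = suppressWarnings(
                      as.integer(raw[[dialect$cds_length]])),
                    stringsAsFactors = FALSE)
  rec$cds_length[!is.na(rec$cds_length) & rec$cds_length <= 0] <- NA_integer_
  if (isTRUE(dialect$strip_gene_suffix))
    rec$gene <- sub("_.*$", "", rec$gene)
  keep <- nzchar(rec$sample_id) & nzchar(rec$gene)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " row(s) missing gene or sample dropped")
  new("MutationTable", records = rec[keep, , drop = FALSE],
      provenance = list(source = path, dialect = dialect$name,
                        rows_read = nrow(raw), rows_dropped = dropped))
}

#' Write a mutation table in the canonical dialect
#'
#' @param table a \linkS4class{MutationTable}.
#' @param path output path (\code{.gz} suffix gzips the file).
#' @return invisibly, \code{path}.
#' @export
writeMutationTable <- function(table, path) {
  stopifnot(is(table, "MutationTable"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(records(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene CDS lengths
#'
#' \code{readCdsLengths} reads a two-column TSV (gene symbol, CDS length
#' in nucleotides). \code{cdsLengthsFromTable} derives lengths from the
#' mutation records themselves, taking per gene the maximum length seen
#' across records so that conflicting per-transcript annotations resolve
#' deterministically; genes whose records never carry a length are
#' omitted.
#'
#' @param path TSV path with a header row and columns gene, length.
#' @param table a \linkS4class{MutationTable}.
#' @return named integer vector of CDS lengths (> 0), named by gene.
#' @export
readCdsLengths <- function(path) {
  df <- utils::read.delim(gzfile(path), check.names = FALSE, quote = "")
  if (ncol(df) < 2L) stop("CDS length table needs two columns")
  len <- suppressWarnings(as.integer(df[[2L]]))
  if (anyNA(len) || any(len <= 0))
    stop("all CDS lengths must be positive integers")
  if (anyDuplicated(df[[1L]])) stop("duplicate gene in CDS length table")
  setNames(len, as.character(df[[1L]]))
}

#' @rdname readCdsLengths
#' @export
cdsLengthsFromTable <- function(table) {
  stopifnot(is(table, "MutationTable"))
  rec <- records(table)
  rec <- rec[!is.na(rec$cds_length), c("gene", "cds_length")]
  if (!nrow(rec)) return(setNames(integer(0), character(0)))
  out <- vapply(split(rec$cds_length, rec$gene), max, integer(1))
  out[order(names(out))]
}
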