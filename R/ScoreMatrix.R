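#' Construct a ScoreMatrix
#'
#' @param scores numeric matrix, features in rows and samples in columns,
#'   both dimensions named.
#' @param localization character vector of primary-site labels, one per
#'   sample (recycled from names if named by sample).
#' @param featureKind \code{"MR"}, \code{"nMR"} or \code{"PI"}.
#' @return a \linkS4class{ScoreMatrix}.
#' @export
ScoreMatrix <- function(scores, localization, featureKind) {
  stopifnot(is.matrix(scores),
            nrow(scores) == 0L || !is.null(rownames(scores)),
            ncol(scores) == 0L || !is.null(colnames(scores)))
  if (is.null(dimnames(scores)))
    dimnames(scores) <- list(character(0), character(0))
  if (!is.null(names(localization)))
    localization <- localization[colnames(scores)]
  stopifnot(length(localization) == ncol(scores))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scores = scores),
    colData = S4Vectors::DataFrame(
      localization = as.character(localization),
      row.names = colnames(scores)))
  S4Vectors::metadata(se)$featureKind <- featureKind
  new("ScoreMatrix", se)
}

#' Read and write score matrices as TSV
#'
#' The on-disk layout is one row per sample: a \code{sample_id} column,
#' a \code{localization} column, then one numeric column per feature.
#' Values are written with 15 significant digits so a round trip is
#' lossless well beyond 1e-9.
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @param path TSV path.
#' @param featureKind the feature kind to stamp on the object read back.
#' @return \code{writeScoreMatrix} invisibly returns \code{path};
#'   \code{readScoreMatrix} returns a \linkS4class{ScoreMatrix}.
#' @export
writeScoreMatrix <- function(x, path) {
  stopifnot(is(x, "ScoreMatrix"))
  sc <- scores(x)
  df <- data.frame(sample_id = colnames(sc),
                   localization = unname(localizations(x)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  num <- as.data.frame(t(sc))
  colnames(num) <- rownames(sc)
  for (j in seq_along(num)) num[[j]] <- sprintf("%.15g", num[[j]])
  utils::write.table(cbind(df, num), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path, featureKind = c("PI", "nMR", "MR")) {
  featureKind <- match.arg(featureKind)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (!all(c("sample_id", "localization") %in% colnames(df)[1:2]))
    stop("first two columns must be sample_id and localization")
  feat <- colnames(df)[-(1:2)]
  m <- matrix(NA_real_, nrow = length(feat), ncol = nrow(df),
              dimnames = list(feat, df$sample_id))
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(df[[feat[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at sample '%s', feature '%s'",
                   df$sample_id[i], feat[j]))
    }
    m[j, ] <- v
  }
  ScoreMatrix(m, setNames(df$localization, df$sample_id), featureKind)
}
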