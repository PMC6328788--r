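#' @import methods
#' @importFrom stats cor rlnorm rpois runif rbinom sd prcomp setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
NULL

.MUT_COLS <- c("sample_id", "gene", "localization", "description",
               "mutation_id", "cds_length")

#' MutationTable: long-form somatic mutation records
#'
#' One row per mutation record with the canonical columns
#' \code{sample_id}, \code{gene}, \code{localization} (primary site),
#' \code{description} (mutation class label), \code{mutation_id} and
#' \code{cds_length} (coding-sequence length in nucleotides, \code{NA}
#' when unknown).
#'
#' @slot records data.frame with the canonical columns above.
#' @slot provenance list recording source path, dialect and row tallies.
#' @exportClass MutationTable
setClass("MutationTable",
         representation(records = "data.frame", provenance = "list"),
         prototype(records = data.frame(sample_id = character(),
                                        gene = character(),
                                        localization = character(),
                                        description = character(),
                                        mutation_id = character(),
                                        cds_length = integer(),
                                        stringsAsFactors = FALSE),
                   provenance = list()))

setValidity("MutationTable", function(object) {
  rec <- object@records
  if (!all(.MUT_COLS %in% colnames(rec)))
    return(paste("records must contain columns:",
                 paste(setdiff(.MUT_COLS, colnames(rec)), collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (anyNA(rec$sample_id) || any(!nzchar(rec$sample_id)))
    return("sample_id must be non-empty")
  if (anyNA(rec$gene) || any(!nzchar(rec$gene)))
    return("gene must be non-empty")
  len <- rec$cds_length
  if (any(!is.na(len) & len <= 0))
    return("cds_length must be > 0 where present")
  # one localization per sample is an input contract, not a preference
  loc <- unique(rec[, c("sample_id", "localization")])
  if (anyDuplicated(loc$sample_id))
    return("a sample maps to more than one localization")
  TRUE
})

#' PathwayCollection: named gene sets
#'
#' @slot pathways named list of character vectors (unique gene symbols).
#' @slot minSize integer; 0 until \code{\link{filterMinSize}} is applied.
#' @exportClass PathwayCollection
setClass("PathwayCollection",
         representation(pathways = "list", minSize = "integer"),
         prototype(pathways = list(), minSize = 0L))

setValidity("PathwayCollection", function(object) {
  pw <- object@pathways
  if (length(pw)) {
    if (is.null(names(pw)) || any(!nzchar(names(pw))))
      return("all pathways must be named")
    if (anyDuplicated(names(pw)))
      return("pathway names must be unique")
    if (!all(vapply(pw, is.character, logical(1))))
      return("pathway members must be character vectors")
    if (any(vapply(pw, anyDuplicated, integer(1)) > 0L))
      return("gene symbols within a pathway must be unique")
    if (object@minSize > 0L &&
        any(lengths(pw) < object@minSize))
      return("a retained pathway is smaller than minSize")
  }
  TRUE
})

#' Cohort: a filtered mutation table with its sample roster
#'
#' @slot table MutationTable restricted to the retained samples.
#' @slot samples character vector of retained sample identifiers.
#' @slot localization named character vector, localization per sample.
#' @exportClass Cohort
setClass("Cohort",
         representation(table = "MutationTable",
                        samples = "character",
                        localization = "character"))

setValidity("Cohort", function(object) {
  if (length(object@samples) != length(object@localization) ||
      !identical(object@samples, names(object@localization)))
    return("localization must be named by samples, in order")
  rec <- records(object@table)
  if (nrow(rec) && !all(rec$sample_id %in% object@samples))
    return("every record's sample must be on the sample roster")
  TRUE
})

#' ScoreMatrix: samples-by-features score container
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"scores"}
#' assay (features in rows, samples in columns, following the
#' Bioconductor convention), a \code{localization} column in
#' \code{colData}, and the feature kind (\code{"MR"}, \code{"nMR"} or
#' \code{"PI"}) in \code{metadata()$featureKind}.
#'
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", contains = "SummarizedExperiment")

setValidity("ScoreMatrix", function(object) {
  if (!"scores" %in% SummarizedExperiment::assayNames(object))
    return("must carry a 'scores' assay")
  if (!"localization" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain 'localization'")
  kind <- S4Vectors::metadata(object)$featureKind
  if (is.null(kind) || !kind %in% c("MR", "nMR", "PI"))
    return("metadata()$featureKind must be 'MR', 'nMR' or 'PI'")
  sc <- SummarizedExperiment::assay(object, "scores")
  if (length(sc) && (anyNA(sc) || any(!is.finite(sc)) || any(sc < 0)))
    return("scores must be finite and non-negative")
  TRUE
})

#' BiomarkerTable: per (feature, comparison) AUC records
#'
#' @slot records data.frame with columns \code{feature},
#'   \code{comparison} (\code{"ovr"} or \code{"pair"}), \code{group_a},
#'   \code{group_b}, \code{raw_auc}, \code{effective_auc},
#'   \code{direction} (\code{"high"}/\code{"low"}).
#' @slot threshold numeric AUC threshold the table was screened at.
#' @slot featureKind character, \code{"nMR"} or \code{"PI"}.
#' @exportClass BiomarkerTable
setClass("BiomarkerTable",
         representation(records = "data.frame", threshold = "numeric",
                        featureKind = "character"))

setValidity("BiomarkerTable", function(object) {
  rec <- object@records
  need <- c("feature", "comparison", "group_a", "group_b",
            "raw_auc", "effective_auc", "direction")
  if (!all(need %in% colnames(rec)))
    return(paste("records must contain columns:",
                 paste(setdiff(need, colnames(rec)), collapse = ", ")))
  if (nrow(rec)) {
    if (any(rec$raw_auc < 0 | rec$raw_auc > 1))
      return("raw_auc must lie in [0, 1]")
    eff <- pmax(rec$raw_auc, 1 - rec$raw_auc)
    if (max(abs(rec$effective_auc - eff)) > 1e-12)
      return("effective_auc must equal max(raw_auc, 1 - raw_auc)")
    dir_ok <- ifelse(rec$raw_auc >= 0.5, "high", "low")
    if (!identical(rec$direction, dir_ok))
      return("direction must be 'high' iff raw_auc >= 0.5")
    key <- paste(rec$feature, rec$comparison, rec$group_a, rec$group_b)
    if (anyDuplicated(key))
      return("one record per (feature, comparison)")
  }
  TRUE
})

#' PairCountMatrix: pairwise high-quality biomarker counts
#'
#' @slot counts symmetric integer matrix over localization labels with a
#'   zero diagonal.
#' @exportClass PairCountMatrix
setClass("PairCountMatrix", representation(counts = "matrix"))

setValidity("PairCountMatrix", function(object) {
  m <- object@counts
  if (!is.numeric(m) || nrow(m) != ncol(m))
    return("counts must be a square numeric matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("row and column names must match")
  if (!isSymmetric(unname(m))) return("counts must be symmetric")
  if (any(diag(m) != 0)) return("diagonal must be zero")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  TRUE
})

#' SimTruth: planted parameters of a synthetic cohort
#'
#' @slot config list, the realized simulation configuration.
#' @slot geneRates numeric matrix (genes x types) of per-sample Poisson
#'   rates after enrichment.
#' @slot planted data.frame of planted (type, pathway, fold) effects.
#' @slot seed integer seed the cohort was drawn with.
#' @exportClass SimTruth
setClass("SimTruth",
         representation(config = "list", geneRates = "matrix",
                        planted = "data.frame", seed = "integer"))
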