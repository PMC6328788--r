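#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))

#' @export
setGeneric("minSize", function(x) standardGeneric("minSize"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("localizations", function(x) standardGeneric("localizations"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' Accessors
#'
#' \code{records} returns the record data.frame of a
#' \linkS4class{MutationTable} or \linkS4class{BiomarkerTable};
#' \code{pathways} the named gene-set list of a
#' \linkS4class{PathwayCollection}; \code{sampleIds} and
#' \code{localizations} the sample roster of a \linkS4class{Cohort} or
#' \linkS4class{ScoreMatrix}; \code{scores} the numeric assay of a
#' \linkS4class{ScoreMatrix} (features x samples); \code{featureKind}
#' whether scores are \code{"nMR"} or \code{"PI"}; \code{pairCounts} the
#' symmetric count matrix of a \linkS4class{PairCountMatrix}.
#'
#' @param x the object.
#' @return see above.
#' @name accessors
#' @aliases records pathways minSize sampleIds localizations scores
#'   featureKind pairCounts
NULL

setMethod("records", "MutationTable", function(x) x@records)
setMethod("records", "BiomarkerTable", function(x) x@records)
setMethod("pathways", "PathwayCollection", function(x) x@pathways)
setMethod("minSize", "PathwayCollection", function(x) x@minSize)
setMethod("sampleIds", "Cohort", function(x) x@samples)
setMethod("localizations", "Cohort", function(x) x@localization)
setMethod("sampleIds", "ScoreMatrix", function(x) colnames(x))
setMethod("localizations", "ScoreMatrix", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$localization),
           colnames(x)))
setMethod("scores", "ScoreMatrix", function(x)
  SummarizedExperiment::assay(x, "scores"))
setMethod("featureKind", "ScoreMatrix", function(x)
  S4Vectors::metadata(x)$featureKind)
setMethod("featureKind", "BiomarkerTable", function(x) x@featureKind)
setMethod("pairCounts", "PairCountMatrix", function(x) x@counts)

setMethod("show", "MutationTable", function(object) {
  rec <- records(object)
  cat(sprintf("MutationTable: %d records, %d samples, %d genes\n",
              nrow(rec), length(unique(rec$sample_id)),
              length(unique(rec$gene))))
  if (!is.null(object@provenance$source))
    cat("  source:", object@provenance$source, "\n")
})

setMethod("show", "PathwayCollection", function(object) {
  pw <- pathways(object)
  cat(sprintf("PathwayCollection: %d gene sets", length(pw)))
  if (length(pw))
    cat(sprintf(" (sizes %d-%d)", min(lengths(pw)), max(lengths(pw))))
  if (object@minSize > 0L)
    cat(sprintf(", min size filter %d applied", object@minSize))
  cat("\n")
})

setMethod("show", "Cohort", function(object) {
  loc <- localizations(object)
  cat(sprintf("Cohort: %d samples, %d localizations, %d records\n",
              length(object@samples), length(unique(loc)),
              nrow(records(object@table))))
  tab <- sort(table(loc), decreasing = TRUE)
  for (nm in names(head(tab, 6)))
    cat(sprintf("  %s: %d samples\n", nm, tab[[nm]]))
  if (length(tab) > 6) cat("  ...\n")
})

setMethod("show", "BiomarkerTable", function(object) {
  rec <- records(object)
  cat(sprintf(
    "BiomarkerTable (%s): %d records, %d above threshold %.2f\n",
    object@featureKind, nrow(rec),
    sum(rec$effective_auc > object@threshold), object@threshold))
})

setMethod("show", "PairCountMatrix", function(object) {
  m <- pairCounts(object)
  cat(sprintf("PairCountMatrix: %d localizations, max pair count %d\n",
              nrow(m), if (length(m)) max(m) else 0L))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: seed %d, %d planted effect(s) over %d type(s)\n",
    object@seed, nrow(object@planted),
    length(unique(object@planted$type))))
})
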