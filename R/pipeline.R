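#' Run the full scoring and screening pipeline
#'
#' Orchestrates cohort construction, nMR/PI scoring, one-vs-rest and
#' pairwise biomarker screens at both the gene and pathway level,
#' universal- and informative-pathway selection, pair-count distance
#' clustering and PCA, writing every artifact plus a JSON manifest to
#' \code{outDir}. A stage failure is re-signalled with the stage name
#' and leaves a \code{FAILED} marker file next to any partial outputs.
#'
#' @param mutations path to a mutation TSV, or a
#'   \linkS4class{MutationTable}.
#' @param pathwayFile path to a GMT file, or a
#'   \linkS4class{PathwayCollection}.
#' @param outDir output directory (created if needed).
#' @param cdsLengths optional path to a gene/CDS-length TSV or a named
#'   vector; derived from the records when \code{NULL}.
#' @param dialect mutation-table dialect name (see
#'   \code{\link{mutationDialect}}).
#' @param minSamples,whitelist cohort filter (see
#'   \code{\link{filterCohort}}).
#' @param truncating restrict to truncating mutations after filtering.
#' @param dedupe collapse transcript-level duplicates first.
#' @param minSize pathway min-size filter (default 10).
#' @param threshold,aucCap,topFrac screening parameters (see
#'   \code{\link{oneVsRestScreen}}, \code{\link{universalPathways}}).
#' @param nComponents principal components reported.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(mutations, pathwayFile, outDir,
                        cdsLengths = NULL, dialect = "cosmic",
                        minSamples = 100, whitelist = NULL,
                        truncating = FALSE, dedupe = TRUE,
                        minSize = 10, threshold = 0.75, aucCap = 0.7,
                        topFrac = 0.10, nComponents = 2) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  fail_marker <- file.path(outDir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on_error <- function(e) {
    writeLines(paste(stage, conditionMessage(e)), fail_marker)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    stage <- "read"
    table <- if (is(mutations, "MutationTable")) mutations
             else readMutationTable(mutations, dialect)
    collection <- if (is(pathwayFile, "PathwayCollection")) pathwayFile
                  else readGmt(pathwayFile)
    lengths <- if (is.null(cdsLengths)) cdsLengthsFromTable(table)
               else if (is.character(cdsLengths)) readCdsLengths(cdsLengths)
               else cdsLengths

    stage <- "filter"
    if (dedupe) table <- dedupeMutations(table)
    cohort <- filterCohort(table, minSamples, whitelist)
    if (truncating) cohort <- restrictTruncating(cohort)
    collection <- filterMinSize(collection, minSize)

    stage <- "score"
    nmr <- sampleNmrMatrix(cohort, lengths)
    pi <- piMatrix(nmr, collection)
    writeScoreMatrix(nmr, file.path(outDir, "nmr.tsv"))
    writeScoreMatrix(pi, file.path(outDir, "pi.tsv"))

    stage <- "biomarkers"
    artifacts <- c("nmr.tsv", "pi.tsv")
    screens <- list(nmr = nmr, pi = pi)
    pair_counts <- list()
    for (kind in names(screens)) {
      ovr <- oneVsRestScreen(screens[[kind]], threshold)
      pr <- pairwiseScreen(screens[[kind]], threshold)
      pair_counts[[kind]] <- pr$counts
      f1 <- sprintf("biomarkers_ovr_%s.json", kind)
      f2 <- sprintf("biomarkers_pairwise_%s.json", kind)
      writeBiomarkerReport(ovr, file.path(outDir, f1))
      writeBiomarkerReport(pr$table, file.path(outDir, f2), pr$counts)
      artifacts <- c(artifacts, f1, f2)
      if (kind == "pi") {
        mean_pi <- rowMeans(scores(pi))
        up <- universalPathways(ovr, mean_pi, aucCap, topFrac)
        ri <- rankInformative(ovr, threshold)
        utils::write.table(up, file.path(outDir, "universal_pathways.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(ri, file.path(outDir, "informative_pathways.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        artifacts <- c(artifacts, "universal_pathways.tsv",
                       "informative_pathways.tsv")
      }
    }

    stage <- "structure"
    for (kind in names(pair_counts)) {
      f <- sprintf("tree_%s.nwk", kind)
      tree <- wardD2(biomarkerDistance(pair_counts[[kind]]))
      writeNewick(tree, file.path(outDir, f))
      artifacts <- c(artifacts, f)
    }
    pca <- pcaScores(pi, nComponents)
    pca_df <- data.frame(sample_id = rownames(pca$coordinates),
                         localization = unname(pca$localization),
                         pca$coordinates, check.names = FALSE)
    utils::write.table(pca_df, file.path(outDir, "pca_pi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "pca_pi.tsv")

    stage <- "manifest"
    manifest <- list(
      artifacts = artifacts,
      parameters = list(dialect = dialect, minSamples = minSamples,
                        truncating = truncating, dedupe = dedupe,
                        minSize = minSize, threshold = threshold,
                        aucCap = aucCap, topFrac = topFrac),
      cohort = list(nSamples = length(sampleIds(cohort)),
                    nLocalizations = length(unique(localizations(cohort))),
                    nRecords = nrow(records(cohort@table)),
                    nGenes = nrow(scores(nmr)),
                    nPathways = nrow(scores(pi))),
      varianceExplained = pca$varianceExplained,
      package_version = as.character(utils::packageVersion(
        "PathwayInstability")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = on_error)
}
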