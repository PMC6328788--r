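#' Per-gene mutation counts in a sample group
#'
#' Counts every retained mutation record of each gene across a group of
#' samples. Genes without any record in the group are absent from the
#' result and are treated as zero downstream.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param group character vector of sample ids, a subset of the cohort
#'   roster; defaults to all samples.
#' @return named integer vector of record counts by gene.
#' @export
geneCounts <- function(cohort, group = sampleIds(cohort)) {
  stopifnot(is(cohort, "Cohort"))
  if (!length(group)) stop("group must contain at least one sample")
  unknown <- setdiff(group, sampleIds(cohort))
  if (length(unknown))
    stop("sample(s) not in cohort: ", paste(head(unknown, 5),
                                            collapse = ", "))
  rec <- records(cohort@table)
  rec <- rec[rec$sample_id %in% group, , drop = FALSE]
  if (!nrow(rec)) return(setNames(integer(0), character(0)))
  cnt <- table(rec$gene)
  setNames(as.integer(cnt), names(cnt))
}

#' Mutation rate (MR) per gene
#'
#' MR of gene n in a sample group g is the total number of mutation
#' records of n across g divided by the number of samples in g.
#'
#' @param counts named integer vector from \code{\link{geneCounts}}.
#' @param nSamples number of samples in the group (>= 1).
#' @return named numeric vector of MR values.
#' @export
computeMR <- function(counts, nSamples) {
  if (length(nSamples) != 1L || is.na(nSamples) || nSamples <= 0)
    stop("nSamples must be a positive count")
  counts / nSamples
}

#' Normalized mutation rate (nMR) per gene
#'
#' nMR of gene n is 1000 * MR / L where L is the gene's coding-sequence
#' length in nucleotides. The factor 1000 expresses the rate per
#' kilobase of CDS, removing the bias by which longer genes accumulate
#' more mutations.
#'
#' @param mr named numeric vector of MR values.
#' @param lengths named integer vector of CDS lengths (see
#'   \code{\link{readCdsLengths}}).
#' @param missingLength \code{"strict"} (default) errors when a scored
#'   gene has no known length; \code{"drop"} excludes such genes with a
#'   message.
#' @return named numeric vector of nMR values.
#' @export
computeNMR <- function(mr, lengths, missingLength = c("strict", "drop")) {
  missingLength <- match.arg(missingLength)
  if (any(lengths <= 0, na.rm = TRUE)) stop("CDS lengths must be > 0")
  absent <- setdiff(names(mr), names(lengths))
  if (length(absent)) {
    if (missingLength == "strict")
      stop("no CDS length for gene(s): ",
           paste(head(absent, 10), collapse = ", "),
           if (length(absent) > 10) " ...")
    message(length(absent), " gene(s) without CDS length dropped")
    mr <- mr[!names(mr) %in% absent]
  }
  1000 * mr / as.numeric(lengths[names(mr)])
}

#' Per-sample nMR score matrix
#'
#' Scores each sample as a singleton group (so MR reduces to the raw
#' per-gene record count) over the gene universe observed in the
#' cohort; genes not mutated in a sample score zero.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param lengths named CDS length vector; when \code{NULL}, lengths are
#'   derived from the mutation records via
#'   \code{\link{cdsLengthsFromTable}}.
#' @param missingLength policy for genes without a length, as in
#'   \code{\link{computeNMR}}.
#' @return a \linkS4class{ScoreMatrix} with \code{featureKind = "nMR"},
#'   genes in rows and samples in columns.
#' @export
sampleNmrMatrix <- function(cohort, lengths = NULL,
                            missingLength = c("strict", "drop")) {
  stopifnot(is(cohort, "Cohort"))
  missingLength <- match.arg(missingLength)
  if (!length(sampleIds(cohort))) stop("empty cohort")
  if (is.null(lengths)) lengths <- cdsLengthsFromTable(cohort@table)
  rec <- records(cohort@table)
  universe <- sort(unique(rec$gene))
  absent <- setdiff(universe, names(lengths))
  if (length(absent)) {
    if (missingLength == "strict")
      stop("no CDS length for gene(s): ",
           paste(head(absent, 10), collapse = ", "),
           if (length(absent) > 10) " ...")
    message(length(absent), " gene(s) without CDS length dropped")
    universe <- setdiff(universe, absent)
    rec <- rec[rec$gene %in% universe, , drop = FALSE]
  }
  counts <- table(factor(rec$gene, levels = universe),
                  factor(rec$sample_id, levels = sampleIds(cohort)))
  m <- matrix(as.numeric(counts), nrow = length(universe),
              dimnames = list(universe, sampleIds(cohort)))
  m <- 1000 * m / as.numeric(lengths[universe])
  ScoreMatrix(m, localizations(cohort), "nMR")
}

#' Pathway instability (PI) score
#'
#' PI of pathway p is the sum of nMR over all genes belonging to p,
#' divided by the pathway's full member count N_p. Members without an
#' nMR value (never mutated) contribute zero; the denominator is always
#' N_p, not the number of mutated members. No weighting by molecular
#' role and no log transform is applied.
#'
#' @param nmr named numeric vector of per-gene nMR values.
#' @param collection a \linkS4class{PathwayCollection}, min-size
#'   filtered.
#' @return named numeric vector of PI scores, one per pathway, in
#'   lexicographic pathway order.
#' @export
computePI <- function(nmr, collection) {
  stopifnot(is(collection, "PathwayCollection"))
  pw <- pathways(collection)
  if (any(lengths(pw) == 0L)) stop("empty pathway in collection")
  pw <- pw[order(names(pw))]
  vapply(pw, function(genes)
    sum(nmr[match(genes, names(nmr))], na.rm = TRUE) / length(genes),
    numeric(1))
}

#' Samples-by-pathways PI matrix
#'
#' Applies \code{\link{computePI}} to every sample column of an nMR
#' score matrix. Pathway rows are in lexicographic name order.
#'
#' @param nmrMatrix a \linkS4class{ScoreMatrix} of kind \code{"nMR"}.
#' @param collection a min-size filtered \linkS4class{PathwayCollection}.
#' @return a \linkS4class{ScoreMatrix} with \code{featureKind = "PI"}.
#' @export
piMatrix <- function(nmrMatrix, collection) {
  stopifnot(is(nmrMatrix, "ScoreMatrix"),
            identical(featureKind(nmrMatrix), "nMR"),
            is(collection, "PathwayCollection"))
  pw <- pathways(collection)
  if (any(lengths(pw) == 0L)) stop("empty pathway in collection")
  pw <- pw[order(names(pw))]
  sc <- scores(nmrMatrix)
  m <- matrix(0, nrow = length(pw), ncol = ncol(sc),
              dimnames = list(names(pw), colnames(sc)))
  for (i in seq_along(pw)) {
    idx <- match(pw[[i]], rownames(sc))
    idx <- idx[!is.na(idx)]
    if (length(idx))
      m[i, ] <- colSums(sc[idx, , drop = FALSE]) / length(pw[[i]])
  }
  ScoreMatrix(m, localizations(nmrMatrix), "PI")
}
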