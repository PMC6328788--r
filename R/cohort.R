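.TRUNCATING_LABELS <- c("deletion-frameshift", "insertion-frameshift",
                        "complex-frameshift", "substitution-nonsense")

#' Collapse transcript-level duplicate records
#'
#' COSMIC-style exports carry one row per transcript annotation of the
#' same mutation event. Keeps at most one record per
#' (sample_id, mutation_id) pair; records lacking a mutation id are kept
#' as-is. The first occurrence wins, so with conflicting per-transcript
#' CDS lengths derive lengths via \code{\link{cdsLengthsFromTable}}
#' before deduplicating if the maximum is wanted.
#'
#' @param table a \linkS4class{MutationTable}.
#' @return the deduplicated \linkS4class{MutationTable}.
#' @export
dedupeMutations <- function(table) {
  stopifnot(is(table, "MutationTable"))
  rec <- records(table)
  has_id <- !is.na(rec$mutation_id) & nzchar(rec$mutation_id)
  key <- paste(rec$sample_id, rec$mutation_id, sep = "\r")
  keep <- !(has_id & duplicated(key))
  removed <- sum(!keep)
  if (removed > 0L)
    message(removed, " transcript-level duplicate record(s) collapsed")
  prov <- table@provenance
  prov$deduped <- removed
  new("MutationTable", records = rec[keep, , drop = FALSE],
      provenance = prov)
}

#' Build a cohort by localization size filtering
#'
#' Drops every record whose localization has fewer than
#' \code{minSamples} distinct samples (after an optional whitelist
#' restriction). The default of 100 samples per localization is the
#' usual floor for statistically stable per-type AUC screens.
#'
#' @param table a \linkS4class{MutationTable}.
#' @param minSamples minimum distinct samples per retained localization.
#' @param whitelist optional character vector of localization names to
#'   restrict to before size filtering.
#' @return a \linkS4class{Cohort}.
#' @export
filterCohort <- function(table, minSamples = 100, whitelist = NULL) {
  stopifnot(is(table, "MutationTable"), minSamples >= 1)
  rec <- records(table)
  if (!is.null(whitelist)) {
    absent <- setdiff(whitelist, rec$localization)
    if (length(absent))
      stop("whitelisted localization(s) absent: ",
           paste(absent, collapse = ", "))
    rec <- rec[rec$localization %in% whitelist, , drop = FALSE]
  }
  roster <- unique(rec[, c("sample_id", "localization")])
  n_by_loc <- table(roster$localization)
  keep_loc <- names(n_by_loc)[n_by_loc >= minSamples]
  if (!length(keep_loc))
    stop("no localization has >= ", minSamples, " samples")
  rec <- rec[rec$localization %in% keep_loc, , drop = FALSE]
  roster <- roster[roster$localization %in% keep_loc, , drop = FALSE]
  roster <- roster[order(roster$sample_id), , drop = FALSE]
  message(sprintf("retained %d localization(s), %d samples, %d records",
                  length(keep_loc), nrow(roster), nrow(rec)))
  new("Cohort",
      table = new("MutationTable", records = rec,
                  provenance = table@provenance),
      samples = roster$sample_id,
      localization = setNames(roster$localization, roster$sample_id))
}

#' Classify a mutation description as truncating
#'
#' True iff the description equals (case-insensitively, with whitespace
#' collapsed) one of the four loss-of-function labels used in COSMIC:
#' Deletion-Frameshift, Insertion-Frameshift, Complex-frameshift,
#' Substitution-Nonsense. Matching is exact-label, not substring.
#'
#' @param description character vector of mutation class labels.
#' @return logical vector.
#' @export
classifyTruncating <- function(description) {
  norm <- tolower(gsub("\\s+", " ", trimws(description)))
  norm %in% .TRUNCATING_LABELS
}

#' Restrict a cohort to truncating mutations
#'
#' Keeps only truncating records; samples left without any record are
#' dropped from the roster. The localization size filter is not
#' re-applied, so per-localization sample counts may fall below the
#' original floor.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @return the restricted \linkS4class{Cohort}.
#' @export
restrictTruncating <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  rec <- records(cohort@table)
  rec <- rec[classifyTruncating(rec$description), , drop = FALSE]
  keep <- cohort@samples %in% rec$sample_id
  new("Cohort",
      table = new("MutationTable", records = rec,
                  provenance = cohort@table@provenance),
      samples = cohort@samples[keep],
      localization = cohort@localization[keep])
}
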