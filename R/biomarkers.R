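#' Mann-Whitney AUC
#'
#' Area under the ROC curve of a score separating positives from
#' negatives, computed from rank statistics and equal to the normalized
#' count of positive-negative pairs ordered correctly, ties counting
#' one half: AUC = (number of (s+, s-) pairs with s+ > s- plus half the
#' tied pairs) / (n+ * n-).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, TRUE for the positive class.
#' @return the raw AUC in [0, 1].
#' @export
aucMannWhitney <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("both classes must be non-empty")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# Row-wise AUC of a features x samples block for one label split.
.aucRows <- function(sc, pos) {
  np <- sum(pos); nn <- sum(!pos)
  r <- t(apply(sc, 1L, rank))
  if (nrow(sc) == 1L) r <- matrix(r, nrow = 1L)
  (rowSums(r[, pos, drop = FALSE]) - np * (np + 1) / 2) / (np * nn)
}

.biomarkerRecords <- function(raw, feature, comparison, a, b) {
  data.frame(feature = feature, comparison = comparison,
             group_a = a, group_b = b, raw_auc = unname(raw),
             effective_auc = unname(pmax(raw, 1 - raw)),
             direction = unname(ifelse(raw >= 0.5, "high", "low")),
             stringsAsFactors = FALSE)
}

#' One-vs-rest biomarker screen
#'
#' For every (feature, localization) pair, the AUC of the feature's
#' scores separating that localization's samples (positives) from all
#' other samples pooled. Both the raw AUC and the two-sided effective
#' AUC max(AUC, 1 - AUC) are recorded, with a direction flag saying
#' whether the feature is elevated ("high") or depressed ("low") in the
#' positive class.
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @param threshold effective-AUC threshold stored on the table
#'   (default 0.75, the usual bar for a good-quality biomarker).
#' @return a \linkS4class{BiomarkerTable}.
#' @export
oneVsRestScreen <- function(x, threshold = 0.75) {
  stopifnot(is(x, "ScoreMatrix"))
  loc <- localizations(x)
  types <- sort(unique(loc))
  if (length(types) < 2L) stop("need at least two localizations")
  sizes <- table(loc)
  if (any(sizes < 2L))
    stop("localization(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  sc <- scores(x)
  out <- vector("list", length(types))
  for (k in seq_along(types)) {
    raw <- .aucRows(sc, loc == types[k])
    out[[k]] <- .biomarkerRecords(raw, rownames(sc), "ovr",
                                  types[k], "rest")
  }
  new("BiomarkerTable", records = do.call(rbind, out),
      threshold = threshold, featureKind = featureKind(x))
}

#' Pairwise biomarker screen
#'
#' For every unordered pair of localizations, the per-feature AUC
#' restricted to the two groups' samples (positives = the
#' lexicographically smaller label). Also tallies, per pair, the number
#' of features whose effective AUC strictly exceeds the threshold.
#'
#' @inheritParams oneVsRestScreen
#' @return a list with elements \code{table}
#'   (\linkS4class{BiomarkerTable}) and \code{counts}
#'   (\linkS4class{PairCountMatrix}).
#' @export
pairwiseScreen <- function(x, threshold = 0.75) {
  stopifnot(is(x, "ScoreMatrix"))
  loc <- localizations(x)
  types <- sort(unique(loc))
  if (length(types) < 2L) stop("need at least two localizations")
  sizes <- table(loc)
  if (any(sizes < 2L))
    stop("localization(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  sc <- scores(x)
  cnt <- matrix(0L, length(types), length(types),
                dimnames = list(types, types))
  out <- list()
  for (i in seq_len(length(types) - 1L)) {
    for (j in seq(i + 1L, length(types))) {
      sel <- loc %in% types[c(i, j)]
      raw <- .aucRows(sc[, sel, drop = FALSE],
                      loc[sel] == types[i])
      rec <- .biomarkerRecords(raw, rownames(sc), "pair",
                               types[i], types[j])
      cnt[i, j] <- cnt[j, i] <- sum(rec$effective_auc > threshold)
      out[[length(out) + 1L]] <- rec
    }
  }
  list(table = new("BiomarkerTable", records = do.call(rbind, out),
                   threshold = threshold, featureKind = featureKind(x)),
       counts = new("PairCountMatrix", counts = cnt))
}

#' Count high-quality biomarkers
#'
#' A record is high quality when its effective AUC strictly exceeds the
#' threshold.
#'
#' @param table a \linkS4class{BiomarkerTable}.
#' @param threshold defaults to the threshold stored on the table.
#' @return list with \code{total} (integer) and \code{by_comparison}
#'   (data.frame of per-comparison counts).
#' @export
countHighQuality <- function(table, threshold = NULL) {
  stopifnot(is(table, "BiomarkerTable"))
  if (is.null(threshold)) threshold <- table@threshold
  rec <- records(table)
  hq <- rec[rec$effective_auc > threshold, , drop = FALSE]
  if (!nrow(hq)) {
    by_comp <- data.frame(group_a = character(), group_b = character(),
                          n = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(n = hq$feature),
                            by = list(group_a = hq$group_a,
                                      group_b = hq$group_b), FUN = length)
    by_comp <- agg[order(agg$group_a, agg$group_b), , drop = FALSE]
    rownames(by_comp) <- NULL
  }
  list(total = nrow(hq), by_comparison = by_comp)
}

#' Universally mutated pathways
#'
#' Selects the pathways that discriminate no tumor type (effective AUC
#' below \code{aucCap} in every one-vs-rest comparison) yet carry a high
#' mutation load overall: the selection is intersected with the top
#' \code{floor(topFrac * P)} pathways by mean PI (P = number of scored
#' pathways), ties at the boundary broken by pathway name.
#'
#' @param ovrTable a one-vs-rest \linkS4class{BiomarkerTable} covering
#'   all pathways and localizations.
#' @param meanPI named numeric vector of cohort-average PI per pathway.
#' @param aucCap effective-AUC cap (default 0.7), strict "<".
#' @param topFrac fraction of pathways kept by mean PI (default 0.10).
#' @return data.frame with columns \code{pathway} and \code{mean_pi},
#'   sorted by mean PI descending.
#' @export
universalPathways <- function(ovrTable, meanPI, aucCap = 0.7,
                              topFrac = 0.10) {
  stopifnot(is(ovrTable, "BiomarkerTable"))
  if (topFrac <= 0 || topFrac > 1) stop("topFrac must be in (0, 1]")
  rec <- records(ovrTable)
  rec <- rec[rec$comparison == "ovr", , drop = FALSE]
  max_auc <- vapply(split(rec$effective_auc, rec$feature), max, numeric(1))
  below <- names(max_auc)[max_auc < aucCap]
  ord <- order(-meanPI, names(meanPI))
  top <- names(meanPI)[ord][seq_len(floor(topFrac * length(meanPI)))]
  sel <- intersect(top, below)
  sel <- sel[order(-meanPI[sel], sel)]
  data.frame(pathway = sel, mean_pi = unname(meanPI[sel]),
             stringsAsFactors = FALSE)
}

#' Most informative biomarker pathways
#'
#' Ranks features by the number of localizations in which they are a
#' high-quality one-vs-rest biomarker (effective AUC strictly above the
#' threshold); features that mark no localization are omitted.
#'
#' @param ovrTable a one-vs-rest \linkS4class{BiomarkerTable}.
#' @param threshold effective-AUC threshold (default 0.75).
#' @param topK number of rows returned (default 25).
#' @return data.frame with columns \code{feature} and \code{n_types},
#'   sorted by count descending then feature name.
#' @export
rankInformative <- function(ovrTable, threshold = 0.75, topK = 25) {
  stopifnot(is(ovrTable, "BiomarkerTable"))
  rec <- records(ovrTable)
  rec <- rec[rec$comparison == "ovr" & rec$effective_auc > threshold, ,
             drop = FALSE]
  if (!nrow(rec))
    return(data.frame(feature = character(), n_types = integer(),
                      stringsAsFactors = FALSE))
  cnt <- table(rec$feature)
  df <- data.frame(feature = names(cnt), n_types = as.integer(cnt),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_types, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  head(df, topK)
}

#' Write a biomarker report as JSON
#'
#' @param table a \linkS4class{BiomarkerTable}.
#' @param path output path.
#' @param counts optional \linkS4class{PairCountMatrix} from
#'   \code{\link{pairwiseScreen}}.
#' @return invisibly, \code{path}.
#' @export
writeBiomarkerReport <- function(table, path, counts = NULL) {
  stopifnot(is(table, "BiomarkerTable"))
  hq <- countHighQuality(table)
  report <- list(feature_kind = table@featureKind,
                 threshold = table@threshold,
                 n_records = nrow(records(table)),
                 n_high_quality = hq$total,
                 by_comparison = hq$by_comparison,
                 records = records(table))
  if (!is.null(counts))
    report$pair_counts <- as.data.frame(pairCounts(counts))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
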