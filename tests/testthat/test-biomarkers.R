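test_that("Mann-Whitney AUC matches hand-worked examples", {
  expect_equal(aucMannWhitney(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(aucMannWhitney(rep(2, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # pairs (0.1,0.35)+ (0.1,0.8)+ (0.4,0.35)- (0.4,0.8)+ -> 3/4
  expect_equal(aucMannWhitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(aucMannWhitney(1:3, c(1, 1, 1)), "non-empty")
})

test_that("AUC is invariant under monotone transforms and flips under label swap", {
  set.seed(31)
  for (i in 1:20) {
    s <- sample(0:5, 12, replace = TRUE) + ifelse(runif(12) < 0.5, 0, 0.25)
    l <- c(rep(TRUE, 5), rep(FALSE, 7))[sample(12)]
    a <- aucMannWhitney(s, l)
    expect_equal(aucMannWhitney(exp(2 * s), l), a, tolerance = 1e-12)
    expect_equal(aucMannWhitney(s, !l), 1 - a, tolerance = 1e-12)
    expect_equal(max(a, 1 - a), max(1 - a, a))
  }
})

test_that("one-vs-rest screen recovers a planted pathway and flags direction", {
  pl <- data.frame(type = "breast", pathway = "PW003", fold = 6)
  sim <- simulateCohort(simConfig(nTypes = 3, samplesPerType = 40,
                                  nGenes = 800, burden = 100,
                                  nPathways = 20, planted = pl, seed = 11))
  co <- toyCohort(sim$table)
  pm <- piMatrix(sampleNmrMatrix(co, sim$lengths),
                 filterMinSize(sim$pathways, 10))
  ovr <- oneVsRestScreen(pm)
  rec <- records(ovr)
  hit <- rec[rec$feature == "PW003" & rec$group_a == "breast", ]
  expect_gt(hit$effective_auc, 0.75)
  expect_equal(hit$direction, "high")

  # a constant feature is never a biomarker
  sc <- scores(pm)
  sc["PW001", ] <- 1
  flat <- oneVsRestScreen(ScoreMatrix(sc, localizations(pm), "PI"))
  frec <- records(flat)
  expect_equal(frec$effective_auc[frec$feature == "PW001"], rep(0.5, 3))

  # singleton localization is an error
  one <- ScoreMatrix(scores(pm)[, 1:41, drop = FALSE],
                     localizations(pm)[1:41], "PI")
  expect_error(oneVsRestScreen(one), "fewer than 2")
})

test_that("screen AUCs equal the scalar implementation per comparison", {
  rc <- randomCohort(seed = 13, n_samples = 10, n_genes = 10, n_types = 3)
  sm <- sampleNmrMatrix(rc$cohort, rc$lengths)
  loc <- localizations(sm)
  ovr <- records(oneVsRestScreen(sm))
  for (i in sample(nrow(ovr), 12)) {
    r <- ovr[i, ]
    expect_equal(r$raw_auc,
                 aucMannWhitney(scores(sm)[r$feature, ],
                                loc == r$group_a),
                 tolerance = 1e-12)
  }
  pw <- pairwiseScreen(sm)
  prec <- records(pw$table)
  for (i in sample(nrow(prec), 12)) {
    r <- prec[i, ]
    sel <- loc %in% c(r$group_a, r$group_b)
    expect_equal(r$raw_auc,
                 aucMannWhitney(scores(sm)[r$feature, sel],
                                loc[sel] == r$group_a),
                 tolerance = 1e-12)
  }
})

test_that("pairwise screen yields a symmetric zero-diagonal count matrix", {
  rc <- randomCohort(seed = 17, n_samples = 12, n_genes = 6, n_types = 3)
  sm <- sampleNmrMatrix(rc$cohort, rc$lengths)
  pw <- pairwiseScreen(sm)
  cnt <- pairCounts(pw$counts)
  expect_equal(nrow(records(pw$table)), 3 * nrow(scores(sm)))
  expect_true(isSymmetric(unname(cnt)))
  expect_equal(unname(diag(cnt)), rep(0L, 3))

  # with exactly two localizations the pair coincides with one-vs-rest
  rc2 <- randomCohort(seed = 19, n_samples = 10, n_genes = 6, n_types = 2)
  sm2 <- sampleNmrMatrix(rc2$cohort, rc2$lengths)
  pw2 <- pairwiseScreen(sm2)
  ovr2 <- records(oneVsRestScreen(sm2))
  prec <- records(pw2$table)
  m <- merge(prec, ovr2[ovr2$group_a == prec$group_a[1], ],
             by = "feature")
  expect_equal(m$effective_auc.x, m$effective_auc.y, tolerance = 1e-12)
})

test_that("high-quality counting uses a strict threshold", {
  rec <- data.frame(feature = c("f1", "f2", "f3"), comparison = "ovr",
                    group_a = "lung", group_b = "rest",
                    raw_auc = c(0.74, 0.75, 0.76),
                    effective_auc = c(0.74, 0.75, 0.76),
                    direction = "high", stringsAsFactors = FALSE)
  bt <- new("BiomarkerTable", records = rec, threshold = 0.75,
            featureKind = "PI")
  expect_equal(countHighQuality(bt)$total, 1L)
  expect_equal(countHighQuality(bt, 0.5)$total, 3L)
  empty <- new("BiomarkerTable", records = rec[0, ], threshold = 0.75,
               featureKind = "PI")
  expect_equal(countHighQuality(empty)$total, 0L)
})

test_that("BiomarkerTable validity pins effective AUC and direction", {
  rec <- data.frame(feature = "f", comparison = "ovr", group_a = "a",
                    group_b = "rest", raw_auc = 0.3,
                    effective_auc = 0.3, direction = "high",
                    stringsAsFactors = FALSE)
  expect_error(new("BiomarkerTable", records = rec, threshold = 0.75,
                   featureKind = "PI"), "effective_auc")
  rec$effective_auc <- 0.7
  expect_error(new("BiomarkerTable", records = rec, threshold = 0.75,
                   featureKind = "PI"), "direction")
  rec$direction <- "low"
  expect_s4_class(new("BiomarkerTable", records = rec, threshold = 0.75,
                      featureKind = "PI"), "BiomarkerTable")
})

.randomOvrTable <- function(seed, n_path = 10, types = c("t1", "t2", "t3")) {
  set.seed(seed)
  feats <- sprintf("p%02d", seq_len(n_path))
  rec <- expand.grid(feature = feats, group_a = types,
                     stringsAsFactors = FALSE)
  rec$comparison <- "ovr"
  rec$group_b <- "rest"
  rec$raw_auc <- runif(nrow(rec))
  rec$effective_auc <- pmax(rec$raw_auc, 1 - rec$raw_auc)
  rec$direction <- ifelse(rec$raw_auc >= 0.5, "high", "low")
  list(table = new("BiomarkerTable", records = rec, threshold = 0.75,
                   featureKind = "PI"),
       meanPI = setNames(rexp(n_path), feats))
}

test_that("universal-pathway selection intersects quiet pathways with top mean PI", {
  # a single pathway that is both quiet everywhere and highest by PI
  x <- .randomOvrTable(41)
  rec <- records(x$table)
  rec$raw_auc <- 0.8; rec$effective_auc <- 0.8; rec$direction <- "high"
  quiet <- rec$feature == "p05"
  rec$raw_auc[quiet] <- 0.6; rec$effective_auc[quiet] <- 0.6
  bt <- new("BiomarkerTable", records = rec, threshold = 0.75,
            featureKind = "PI")
  mp <- x$meanPI; mp["p05"] <- max(mp) + 1
  expect_equal(universalPathways(bt, mp, topFrac = 0.1)$pathway, "p05")

  # one AUC at 0.71 in one type excludes the pathway regardless of PI
  rec$effective_auc[quiet][1] <- 0.71
  rec$raw_auc[quiet][1] <- 0.71
  bt2 <- new("BiomarkerTable", records = rec, threshold = 0.75,
             featureKind = "PI")
  expect_equal(nrow(universalPathways(bt2, mp, topFrac = 0.1)), 0L)
  expect_error(universalPathways(bt, mp, topFrac = 0), "topFrac")
})

test_that("universal-pathway and informative rankings equal brute-force oracles", {
  for (seed in c(61, 62, 63)) {
    x <- .randomOvrTable(seed, n_path = 20)
    rec <- records(x$table)
    got <- universalPathways(x$table, x$meanPI, aucCap = 0.7,
                             topFrac = 0.25)
    # naive filter + sort
    quiet <- character(0)
    for (f in unique(rec$feature))
      if (all(rec$effective_auc[rec$feature == f] < 0.7))
        quiet <- c(quiet, f)
    top <- names(sort(x$meanPI, decreasing = TRUE))[1:floor(0.25 * 20)]
    want <- intersect(top, quiet)
    want <- want[order(-x$meanPI[want], want)]
    expect_equal(got$pathway, want)

    got_ri <- rankInformative(x$table, threshold = 0.6, topK = 50)
    cnt <- sapply(unique(rec$feature), function(f)
      sum(rec$effective_auc[rec$feature == f] > 0.6))
    cnt <- cnt[cnt > 0]
    want_ri <- data.frame(feature = names(cnt), n_types = as.integer(cnt))
    want_ri <- want_ri[order(-want_ri$n_types, want_ri$feature), ]
    rownames(want_ri) <- NULL
    expect_equal(got_ri, want_ri)
  }
  expect_equal(nrow(rankInformative(.randomOvrTable(64)$table,
                                    threshold = 1)), 0L)
})

test_that("biomarker reports serialize to JSON with summary counts", {
  x <- .randomOvrTable(71)
  path <- withr::local_tempfile(fileext = ".json")
  writeBiomarkerReport(x$table, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$feature_kind, "PI")
  expect_equal(rep$n_records, nrow(records(x$table)))
  expect_equal(rep$n_high_quality,
               sum(records(x$table)$effective_auc > 0.75))
})
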