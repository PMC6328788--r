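.SIM_SITES <- c("breast", "central nervous system", "cervix",
                "endometrium", "ovary", "prostate", "kidney",
                "urinary tract", "liver",
                "haematopoietic and lymphoid tissue", "stomach",
                "large intestine", "lung", "thyroid", "skin")

.TRUNC_OUT <- c("Deletion-Frameshift", "Insertion-Frameshift",
                "Complex-frameshift", "Substitution-Nonsense")

#' Synthetic cohort configuration
#'
#' Collects the parameters of the generative model used by
#' \code{\link{simulateCohort}}: per sample and gene, mutation counts
#' are Poisson with rate burden * L_gene / sum(L) times a planted
#' fold-enrichment when the gene belongs to an enriched pathway of the
#' sample's tumor type; each record is labeled truncating i.i.d. with
#' probability \code{truncatingFraction}.
#'
#' Defaults emulate a mid-sized pan-cancer exome cohort: 3 tumor
#' localizations of 200 samples, 5,000 genes with log-normal CDS
#' lengths (median 1.5 kb), about 390 somatic mutations per sample and
#' a 7 percent truncating fraction, with 50 partially overlapping
#' pathways of 10-50 genes.
#'
#' @param nTypes number of tumor localizations.
#' @param samplesPerType samples per localization.
#' @param nGenes size of the gene pool.
#' @param cdsMeanlog,cdsSdlog log-normal parameters of CDS length (nt).
#' @param burden expected mutations per sample, one value per type
#'   (recycled).
#' @param nPathways number of gene sets generated.
#' @param pathwaySizeRange inclusive range of set sizes.
#' @param overlapFraction fraction of each set drawn from a shared hub
#'   pool, so sets are non-disjoint as in real collections.
#' @param planted data.frame with columns \code{type} (localization
#'   name), \code{pathway} (set name) and \code{fold} (>= 1): genes of
#'   that set get their Poisson rate multiplied by \code{fold} in that
#'   type.
#' @param truncatingFraction probability a record is truncating.
#' @param seed integer seed; the cohort is a pure function of the
#'   configuration.
#' @return a named list (class \code{simConfig}).
#' @export
simConfig <- function(nTypes = 3, samplesPerType = 200, nGenes = 5000,
                      cdsMeanlog = log(1500), cdsSdlog = 0.6,
                      burden = 390, nPathways = 50,
                      pathwaySizeRange = c(10, 50),
                      overlapFraction = 0.2,
                      planted = NULL, truncatingFraction = 0.07,
                      seed = 1L) {
  stopifnot(nTypes >= 1, samplesPerType >= 1, nGenes >= 1,
            all(burden > 0), nPathways >= 1,
            pathwaySizeRange[1] >= 1,
            pathwaySizeRange[2] >= pathwaySizeRange[1],
            overlapFraction >= 0, overlapFraction <= 1,
            truncatingFraction >= 0, truncatingFraction <= 1)
  if (nTypes > length(.SIM_SITES))
    stop("at most ", length(.SIM_SITES), " localizations supported")
  if (pathwaySizeRange[2] > nGenes)
    stop("pathway sizes exceed the gene pool")
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("type", "pathway", "fold") %in% colnames(planted)),
              all(planted$fold >= 1))
  }
  structure(list(nTypes = as.integer(nTypes),
                 samplesPerType = as.integer(samplesPerType),
                 nGenes = as.integer(nGenes),
                 cdsMeanlog = cdsMeanlog, cdsSdlog = cdsSdlog,
                 burden = rep_len(burden, nTypes),
                 nPathways = as.integer(nPathways),
                 pathwaySizeRange = as.integer(pathwaySizeRange),
                 overlapFraction = overlapFraction,
                 planted = planted,
                 truncatingFraction = truncatingFraction,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Deterministic layout of a synthetic cohort
#'
#' Draws the seed-determined gene pool, CDS lengths and pathway
#' collection of a configuration without simulating any mutation
#' counts, so the collection can be inspected (e.g. to choose a
#' pathway to plant an effect in with \code{\link{plantablePathway}})
#' before the full cohort is generated. \code{\link{simulateCohort}}
#' reproduces exactly this layout for the same configuration, whatever
#' the planted effects, because effects alter Poisson rates only after
#' the layout is drawn.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{genes}, \code{lengths} (named integer
#'   vector) and \code{pathways} (a \linkS4class{PathwayCollection}).
#' @export
simLayout <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  ng <- config$nGenes
  genes <- sprintf("G%05d", seq_len(ng))
  L <- pmax(90L, as.integer(round(
    rlnorm(ng, config$cdsMeanlog, config$cdsSdlog))))
  names(L) <- genes

  hub <- sample(genes, max(2L, round(0.02 * ng)))
  sizes <- sample(seq(config$pathwaySizeRange[1],
                      config$pathwaySizeRange[2]),
                  config$nPathways, replace = TRUE)
  pw <- lapply(sizes, function(s) {
    n_hub <- min(length(hub), round(config$overlapFraction * s))
    sort(c(sample(hub, n_hub),
           sample(setdiff(genes, hub), s - n_hub)))
  })
  names(pw) <- sprintf("PW%03d", seq_len(config$nPathways))
  list(genes = genes, lengths = L,
       pathways = new("PathwayCollection", pathways = pw,
                      minSize = 0L))
}

#' Choose a pathway suitable for a spread-out planted effect
#'
#' A multiplicative fold-enrichment gives each member gene an absolute
#' rate increment proportional to its CDS length, so a very long member
#' can become an individually detectable gene-level marker rather than
#' a diffuse pathway-level signal. To plant an effect that is spread
#' over many small per-gene increments, this helper picks the largest
#' pathway whose members' CDS lengths all stay at or below
#' \code{maxGeneLength} (ties broken by name); if no pathway qualifies
#' it falls back to the pathway with the smallest maximal member
#' length.
#'
#' @param collection a \linkS4class{PathwayCollection}.
#' @param lengths named CDS length vector covering the members.
#' @param maxGeneLength per-gene CDS ceiling in nucleotides (default
#'   3000, roughly twice the median gene, keeping every member's
#'   baseline mutation rate individually weak).
#' @return the selected pathway name.
#' @export
plantablePathway <- function(collection, lengths, maxGeneLength = 3000) {
  stopifnot(is(collection, "PathwayCollection"))
  pw <- pathways(collection)
  maxL <- vapply(pw, function(g) max(as.numeric(lengths[g])), numeric(1))
  ok <- names(pw)[maxL <= maxGeneLength]
  if (length(ok)) {
    sizes <- vapply(pw[ok], length, integer(1))
    ok[order(-sizes, ok)][1L]
  } else {
    names(pw)[order(maxL, names(pw))][1L]
  }
}

#' Simulate a synthetic somatic-mutation cohort
#'
#' Draws a cohort from the length-proportional Poisson model described
#' in \code{\link{simConfig}} and returns it in the same shape real
#' data enters the pipeline: a \linkS4class{MutationTable} in the
#' canonical dialect, a \linkS4class{PathwayCollection}, a CDS length
#' vector, and the planted truth for recovery analysis. Identical
#' configurations yield identical cohorts.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{table}, \code{pathways},
#'   \code{lengths} and \code{truth} (a \linkS4class{SimTruth}).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  layout <- simLayout(config)   # seeds the RNG and draws the prefix
  ng <- config$nGenes
  genes <- layout$genes
  L <- layout$lengths
  pw <- pathways(layout$pathways)
  collection <- layout$pathways

  types <- .SIM_SITES[seq_len(config$nTypes)]
  base <- L / sum(as.numeric(L))
  rates <- matrix(0, ng, config$nTypes, dimnames = list(genes, types))
  for (t in seq_len(config$nTypes)) {
    enrich <- rep(1, ng)
    if (!is.null(config$planted)) {
      pl <- config$planted[config$planted$type == types[t], ,
                           drop = FALSE]
      for (r in seq_len(nrow(pl))) {
        if (is.null(pw[[pl$pathway[r]]]))
          stop("planted pathway not in the collection: ", pl$pathway[r])
        idx <- match(pw[[pl$pathway[r]]], genes)
        enrich[idx] <- pmax(enrich[idx], pl$fold[r])
      }
    }
    rates[, t] <- config$burden[t] * base * enrich
  }

  rec_list <- vector("list", config$nTypes)
  mut_counter <- 0L
  for (t in seq_len(config$nTypes)) {
    ns <- config$samplesPerType
    counts <- matrix(rpois(ng * ns, rates[, t]), nrow = ng)
    nz <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[nz]
    gene_idx <- rep(nz[, 1L], reps)
    samp_idx <- rep(nz[, 2L], reps)
    n_rec <- length(gene_idx)
    trunc <- runif(n_rec) < config$truncatingFraction
    desc <- rep("Substitution - Missense", n_rec)
    if (any(trunc))
      desc[trunc] <- sample(.TRUNC_OUT, sum(trunc), replace = TRUE)
    rec_list[[t]] <- data.frame(
      sample_id = sprintf("S%02d_%04d", t, samp_idx),
      gene = genes[gene_idx],
      localization = types[t],
      description = desc,
      mutation_id = sprintf("SIM%08d", mut_counter + seq_len(n_rec)),
      cds_length = unname(L[gene_idx]),
      stringsAsFactors = FALSE)
    mut_counter <- mut_counter + n_rec
  }
  rec <- do.call(rbind, rec_list)
  rec <- rec[order(rec$sample_id, rec$gene, rec$mutation_id), ,
             drop = FALSE]
  rownames(rec) <- NULL
  table <- new("MutationTable", records = rec,
               provenance = list(source = "simulateCohort",
                                 dialect = "canonical",
                                 seed = config$seed))
  planted <- if (is.null(config$planted))
    data.frame(type = character(), pathway = character(),
               fold = numeric(), stringsAsFactors = FALSE)
  else config$planted
  truth <- new("SimTruth", config = unclass(config), geneRates = rates,
               planted = planted, seed = config$seed)
  list(table = table, pathways = collection, lengths = L, truth = truth)
}

#' Planted-effect recovery summary
#'
#' Given the truth of a simulated cohort and a one-vs-rest biomarker
#' screen run on its PI matrix, reports the sensitivity (fraction of
#' planted (type, pathway) pairs whose effective AUC strictly exceeds
#' the threshold) and the false-call rate over all unplanted
#' (type, pathway) combinations.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param ovrTable a one-vs-rest \linkS4class{BiomarkerTable} computed
#'   on the cohort's PI \linkS4class{ScoreMatrix}.
#' @param threshold effective-AUC threshold (default 0.75).
#' @return list with \code{sensitivity} (NA when nothing was planted),
#'   \code{falseCallRate}, \code{planted} (data.frame with the attained
#'   AUCs) and the counts behind both rates.
#' @export
recoveryReport <- function(truth, ovrTable, threshold = 0.75) {
  stopifnot(is(truth, "SimTruth"), is(ovrTable, "BiomarkerTable"))
  rec <- records(ovrTable)
  rec <- rec[rec$comparison == "ovr", , drop = FALSE]
  key <- paste(rec$group_a, rec$feature)
  pl <- truth@planted
  planted_key <- paste(pl$type, pl$pathway)
  hit <- rec$effective_auc > threshold
  is_planted <- key %in% planted_key
  pl$effective_auc <- rec$effective_auc[match(planted_key, key)]
  list(sensitivity = if (nrow(pl)) mean(pl$effective_auc > threshold,
                                        na.rm = TRUE) else NA_real_,
       falseCallRate = mean(hit[!is_planted]),
       planted = pl,
       nPlanted = nrow(pl),
       nNull = sum(!is_planted))
}
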