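# Fixtures and independent oracles shared across test files.

# Small mutation table in the canonical dialect, built in code.
toyRecords <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2", "s2", "s3"),
    gene = c("A", "B", "A", "A", "C"),
    localization = c("lung", "lung", "skin", "skin", "skin"),
    description = c("Substitution - Missense", "Substitution-Nonsense",
                    "Deletion-Frameshift", "Substitution - Missense",
                    "Substitution - Missense"),
    mutation_id = sprintf("M%d", 1:5),
    cds_length = c(1000L, 500L, 1000L, 1000L, 2000L),
    stringsAsFactors = FALSE)
}

toyTable <- function() new("MutationTable", records = toyRecords(),
                           provenance = list(source = "toy"))

toyCohort <- function(table = toyTable()) {
  suppressMessages(filterCohort(table, minSamples = 1))
}

# Random cohort with per-sample localizations, for brute-force checks.
randomCohort <- function(seed, n_samples = 6, n_genes = 8,
                         n_types = 2, lambda = 2) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  L <- sample(300:3000, n_genes)
  names(L) <- genes
  sids <- sprintf("s%02d", seq_len(n_samples))
  loc <- paste0("type", rep_len(seq_len(n_types), n_samples))
  counts <- matrix(rpois(n_genes * n_samples, lambda), n_genes)
  gi <- rep(rep(seq_len(n_genes), n_samples), as.vector(counts))
  si <- rep(rep(seq_len(n_samples), each = n_genes), as.vector(counts))
  rec <- data.frame(sample_id = sids[si], gene = genes[gi],
                    localization = loc[si],
                    description = "Substitution - Missense",
                    mutation_id = sprintf("M%05d", seq_along(gi)),
                    cds_length = unname(L[gi]),
                    stringsAsFactors = FALSE)
  tab <- new("MutationTable", records = rec, provenance = list())
  list(cohort = toyCohort(tab), lengths = L, counts = counts,
       genes = genes, samples = sids)
}

# O(n+ * n-) pair-count AUC, ties counting one half.
aucPairOracle <- function(scores, labels) {
  sp <- scores[as.logical(labels)]
  sn <- scores[!as.logical(labels)]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Brute-force PI: explicit sum over pathway members / full member count.
piOracle <- function(nmr, sets) {
  vapply(sets, function(g) {
    s <- 0
    for (x in g) if (x %in% names(nmr)) s <- s + nmr[[x]]
    s / length(g)
  }, numeric(1))
}

# Naive Lance-Williams agglomeration returning merge heights and the
# cophenetic matrix, for comparison with wardD2().
wardOracle <- function(m) {
  n <- nrow(m)
  labs <- rownames(m)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  D <- m
  diag(D) <- Inf
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  heights <- numeric(0)
  while (sum(alive) > 1) {
    idx <- which(alive)
    bd <- Inf; bi <- bj <- NA
    for (a in idx) for (b in idx)
      if (a < b && D[a, b] < bd) { bd <- D[a, b]; bi <- a; bj <- b }
    heights <- c(heights, bd)
    for (x in members[[bi]]) for (y in members[[bj]])
      coph[x, y] <- coph[y, x] <- bd
    for (k in idx) if (k != bi && k != bj)
      D[bi, k] <- D[k, bi] <- sqrt(
        ((sizes[bi] + sizes[k]) * D[bi, k]^2 +
         (sizes[bj] + sizes[k]) * D[bj, k]^2 -
         sizes[k] * bd^2) / (sizes[bi] + sizes[bj] + sizes[k]))
    members[[bi]] <- c(members[[bi]], members[[bj]])
    sizes[bi] <- sizes[bi] + sizes[bj]
    alive[bj] <- FALSE
  }
  list(heights = heights, coph = coph)
}

randomDistMatrix <- function(seed, n = 8) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 1, 10)
  m <- m + t(m)
  dimnames(m) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  m
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))
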