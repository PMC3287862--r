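# Shared fixtures: all built in code, no files.

# genotype set with exact empirical MAFs: variant j gets
# round(2 n maf_j) minor alleles, assigned as heterozygotes (and
# homozygotes where the count exceeds n) from the first individual down.
geno_from_maf <- function(n, maf, gene = NULL, annotation = NULL) {
  m <- length(maf)
  dos <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    alleles <- round(2 * n * maf[j])
    full <- alleles %/% 2 * 0  # assign as carriers first
    k <- min(alleles, n)
    dos[seq_len(k), j] <- 1L
    extra <- alleles - k
    if (extra > 0) dos[seq_len(extra), j] <- 2L
  }
  gene <- gene %||% rep("G001", m)
  annotation <- annotation %||% rep("ns", m)
  colnames(dos) <- sprintf("%s_V%02d", gene, seq_len(m))
  genotype_set(dos, gene, annotation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated dataset shared by several evaluation tests
make_small_sim <- function(n = 250, n_genes = 15, R = 6,
                           n_causal = 3, h2 = 0.3, seed = 1) {
  g <- simulate_genotypes(n, n_genes, list(mean = 6), seed = seed)
  truth <- simulate_truth(g, h2 = list(Q2 = h2, Q4 = 0),
                          n_causal_genes = list(Q2 = n_causal, Q4 = 0),
                          seed = seed + 1000L)
  reps <- simulate_phenotypes(g, truth, traits = c("Q2", "Q4"), R = R,
                              seed = seed + 2000L)
  list(g = g, truth = truth, reps = reps)
}

# fabricate a list of fit_result objects whose gene-score features are
# selected in exactly `counts[j]` of R replicates; labels mark causal
# features (their variant sets intersect the returned truth)
fits_from_counts <- function(counts, R, labels) {
  stopifnot(length(counts) == length(labels), all(counts <= R))
  p <- length(counts)
  feat <- sprintf("F%02d", seq_len(p))
  info <- data.frame(name = feat, type = "gene_score", gene = feat,
                     annotation = "pooled", penalty_class = "penalized",
                     stringsAsFactors = FALSE)
  info$variants <- lapply(seq_len(p), function(j) paste0(feat[j], "_V1"))
  truth_trait <- list(
    variants = paste0(feat[labels == 1], "_V1"),
    genes = feat[labels == 1],
    effects = setNames(rep(1, sum(labels)), paste0(feat[labels == 1], "_V1"))
  )
  fits <- lapply(seq_len(R), function(r) {
    sel <- setNames(counts >= r, feat)  # feature j on in first counts[j] reps
    structure(list(selected = sel, info = info, link = "identity"),
              class = "fit_result")
  })
  list(fits = fits, truth_trait = truth_trait)
}

# brute-force pairwise concordance AUC (mid-rank ties) for the ROC oracle
concordance_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}
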