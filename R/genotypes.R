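#' Construct a genotype set
#'
#' A `genotype_set` holds a fixed dosage matrix (individuals x variants,
#' minor-allele counts in \{0, 1, 2\}) together with per-variant metadata:
#' the gene each variant belongs to, its functional annotation
#' (nonsynonymous `"ns"` or synonymous `"s"`), and its minor-allele
#' frequency computed from the dosages themselves.
#'
#' @param dosages integer matrix, individuals in rows (rownames are
#'   individual ids), variants in columns (colnames are variant ids).
#'   Values must be 0, 1 or 2 and count the minor allele.
#' @param gene character vector, gene symbol per variant.
#' @param annotation character vector, `"ns"` or `"s"` per variant.
#' @return An object of class `genotype_set` with elements `dosages`
#'   (integer matrix) and `variants` (data.frame with columns
#'   `variant_id`, `gene`, `annotation`, `maf`).
#' @export
genotype_set <- function(dosages, gene, annotation) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("V", seq_len(ncol(dosages)))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  stopifnot(
    length(gene) == ncol(dosages),
    length(annotation) == ncol(dosages),
    all(annotation %in% c("ns", "s")),
    all(dosages %in% 0:2)
  )
  maf <- colMeans(dosages) / 2
  if (any(maf > 0.5 + 1e-12))
    stop("dosages must count the minor allele (allele frequency > 0.5 found)")
  g <- structure(
    list(
      dosages = dosages,
      variants = data.frame(
        variant_id = colnames(dosages),
        gene = as.character(gene),
        annotation = as.character(annotation),
        maf = pmin(maf, 0.5),
        stringsAsFactors = FALSE
      )
    ),
    class = "genotype_set"
  )
  g
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf(
    "genotype_set: %d individuals x %d variants in %d genes (%d ns / %d s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$gene)),
    sum(x$variants$annotation == "ns"), sum(x$variants$annotation == "s")
  ))
  cat(sprintf("  MAF: median %.4f, %.0f%% rare at the 5%% threshold\n",
              stats::median(x$variants$maf),
              100 * mean(x$variants$maf <= 0.05)))
  invisible(x)
}

#' Check genotype-set invariants
#'
#' Verifies dosage coding, the stored-vs-recomputed MAF agreement, and
#' completeness of the gene and annotation assignments. Errors on the
#' first violation; returns the object invisibly when all hold.
#'
#' @param g a `genotype_set`.
#' @export
validate_genotype_set <- function(g) {
  stopifnot(inherits(g, "genotype_set"))
  if (!all(g$dosages %in% 0:2)) stop("dosages outside {0,1,2}")
  maf <- pmin(colMeans(g$dosages) / 2, 0.5)
  if (max(abs(maf - g$variants$maf)) > 1e-12)
    stop("stored MAF does not match MAF recomputed from dosages")
  if (anyNA(g$variants$gene) || any(g$variants$gene == ""))
    stop("every variant must map to a gene")
  if (!all(g$variants$annotation %in% c("ns", "s")))
    stop("every variant needs an ns/s annotation")
  invisible(g)
}

#' Specify a minor-allele-frequency spectrum
#'
#' The default spectrum is a mixture of a rare-skewed component (a Beta
#' distribution rescaled onto (0, `rare_max`\]) and a small uniform
#' common component on \[`common_min`, `common_max`\], reflecting the
#' rare-dominated site-frequency spectrum of exome data.
#'
#' @param rare_shape1,rare_shape2 Beta shape parameters of the rare
#'   component before rescaling to (0, `rare_max`].
#' @param rare_max upper MAF bound of the rare component.
#' @param common_fraction probability a variant is drawn from the common
#'   component.
#' @param common_min,common_max range of the uniform common component.
#' @return An object of class `maf_spectrum`.
#' @export
maf_spectrum <- function(rare_shape1 = 0.6, rare_shape2 = 3,
                         rare_max = 0.05, common_fraction = 0.1,
                         common_min = 0.05, common_max = 0.5) {
  stopifnot(rare_shape1 > 0, rare_shape2 > 0,
            rare_max > 0, rare_max <= 0.5,
            common_fraction >= 0, common_fraction <= 1,
            common_min >= 0, common_max <= 0.5, common_min <= common_max)
  structure(
    list(rare_shape1 = rare_shape1, rare_shape2 = rare_shape2,
         rare_max = rare_max, common_fraction = common_fraction,
         common_min = common_min, common_max = common_max),
    class = "maf_spectrum"
  )
}

#' Theoretical mean MAF of a spectrum
#'
#' @param spec a `maf_spectrum`.
#' @return the expectation of a MAF drawn from `spec`.
#' @export
mean_maf <- function(spec) {
  stopifnot(inherits(spec, "maf_spectrum"))
  rare_mean <- spec$rare_max * spec$rare_shape1 /
    (spec$rare_shape1 + spec$rare_shape2)
  common_mean <- (spec$common_min + spec$common_max) / 2
  (1 - spec$common_fraction) * rare_mean +
    spec$common_fraction * common_mean
}

draw_maf <- function(spec, m) {
  if (is.numeric(spec)) return(rep_len(spec, m))
  if (!inherits(spec, "maf_spectrum"))
    stop("maf_spectrum must be a maf_spectrum object or a numeric vector")
  common <- runif(m) < spec$common_fraction
  maf <- spec$rare_max * rbeta(m, spec$rare_shape1, spec$rare_shape2)
  maf[common] <- runif(sum(common), spec$common_min, spec$common_max)
  maf
}

#' Simulate a mini-exome style genotype set
#'
#' Draws population allele frequencies from `maf_spectrum` and samples
#' genotypes under Hardy-Weinberg equilibrium (dosage ~ Binomial(2, p)
#' independently per individual and variant). Dosages are re-oriented to
#' count the sample minor allele, so the stored MAF always equals the
#' empirical frequency and never exceeds 0.5.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_genes number of genes.
#' @param variants_per_gene either a single count used for every gene, or
#'   a list `list(mean = m)` for Poisson-distributed gene sizes
#'   (truncated at 1 so every gene has at least one variant).
#' @param maf_spectrum a [maf_spectrum()] object, or a numeric vector of
#'   fixed allele frequencies recycled across variants.
#' @param nonsyn_fraction probability a variant is annotated
#'   nonsynonymous.
#' @param seed integer seed; the same seed reproduces the same set.
#' @return a [genotype_set()].
#' @export
simulate_genotypes <- function(n_individuals, n_genes,
                               variants_per_gene = list(mean = 8),
                               maf_spectrum = rarelasso::maf_spectrum(),
                               nonsyn_fraction = 0.5, seed = NULL) {
  stopifnot(n_individuals >= 2, n_genes >= 1,
            nonsyn_fraction >= 0, nonsyn_fraction <= 1)
  with_seed(seed, {
    if (is.numeric(variants_per_gene) && length(variants_per_gene) %in%
        c(1L, n_genes)) {
      sizes <- rep_len(as.integer(variants_per_gene), n_genes)
    } else if (is.list(variants_per_gene) &&
               !is.null(variants_per_gene$mean)) {
      sizes <- pmax(1L, stats::rpois(n_genes, variants_per_gene$mean))
    } else {
      stop("variants_per_gene must be a count or list(mean = m)")
    }
    if (any(sizes < 1L)) stop("every gene needs at least one variant")
    genes <- sprintf("G%03d", seq_len(n_genes))
    gene_of <- rep(genes, sizes)
    m <- sum(sizes)
    vid <- unlist(lapply(seq_len(n_genes), function(l) {
      sprintf("%s_V%02d", genes[l], seq_len(sizes[l]))
    }), use.names = FALSE)
    p <- draw_maf(maf_spectrum, m)
    if (any(p < 0 | p > 0.5)) stop("allele frequencies must lie in [0, 0.5]")
    dos <- matrix(rbinom(n_individuals * m, 2L, rep(p, each = n_individuals)),
                  nrow = n_individuals, ncol = m,
                  dimnames = list(sprintf("ind%04d", seq_len(n_individuals)),
                                  vid))
    # re-orient columns where the sampled allele ended up major
    flip <- colMeans(dos) / 2 > 0.5
    if (any(flip)) dos[, flip] <- 2L - dos[, flip]
    anno <- ifelse(runif(m) < nonsyn_fraction, "ns", "s")
    genotype_set(dos, gene_of, anno)
  })
}
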