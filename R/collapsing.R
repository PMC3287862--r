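#' Collapsing configuration
#'
#' @param method collapsing method: `"PROP"` (carrier-proportion coding),
#'   `"DAS"` (data-adaptive sum with orientation flips), or `"WS"`
#'   (frequency-weighted sum pooling rare and common variants).
#' @param rare_maf_threshold MAF at or below which a variant is rare
#'   (boundary inclusive on the rare side). Default 0.05; set 0.01 for
#'   the stricter convention.
#' @param das_alpha0 significance level below which a negative marginal
#'   slope triggers an orientation flip in DAS.
#' @param ws_frequency_source group in which WS allele frequencies are
#'   estimated: `"unaffected_only"` (used automatically for the binary
#'   disease trait) or `"all_samples"` (quantitative traits).
#' @param split_by_annotation collapse nonsynonymous and synonymous
#'   variants into separate per-gene scores, enabling differential
#'   penalties downstream.
#' @return a `collapse_config` object.
#' @export
collapse_config <- function(method = c("PROP", "DAS", "WS"),
                            rare_maf_threshold = 0.05,
                            das_alpha0 = 0.1,
                            ws_frequency_source = c("auto", "all_samples",
                                                    "unaffected_only"),
                            split_by_annotation = FALSE) {
  method <- match.arg(method)
  ws_frequency_source <- match.arg(ws_frequency_source)
  stopifnot(rare_maf_threshold > 0, rare_maf_threshold <= 0.5,
            das_alpha0 >= 0, das_alpha0 < 1)
  structure(list(method = method,
                 rare_maf_threshold = rare_maf_threshold,
                 das_alpha0 = das_alpha0,
                 ws_frequency_source = ws_frequency_source,
                 split_by_annotation = split_by_annotation),
            class = "collapse_config")
}

#' Partition variants into rare and common by MAF
#'
#' A variant is rare iff its MAF is less than or equal to `threshold`;
#' all others are common. The partition is exhaustive and disjoint.
#'
#' @param g a [genotype_set()].
#' @param threshold rare/common MAF boundary (inclusive on the rare side).
#' @return list with character vectors `rare` and `common` of variant ids.
#' @export
classify_variants <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "genotype_set"))
  rare <- g$variants$maf <= threshold
  list(rare = g$variants$variant_id[rare],
       common = g$variants$variant_id[!rare])
}

#' Proportion (carrier-proportion) collapsing score
#'
#' For each individual, the fraction of the gene's rare sites at which
#' they carry at least one minor allele (an indicator per site, not an
#' allele count), so the score lies in \[0, 1\].
#'
#' @param g a [genotype_set()].
#' @param gene gene symbol.
#' @param rare_set character vector of rare variant ids (the gene's rare
#'   sites are its intersection with this set).
#' @return numeric score per individual.
#' @export
collapse_prop <- function(g, gene, rare_set) {
  sites <- intersect(g$variants$variant_id[g$variants$gene == gene], rare_set)
  if (length(sites) == 0L)
    stop("gene ", gene, " has no rare variants; skip it upstream")
  rowMeans(g$dosages[, sites, drop = FALSE] >= 1L)
}

# Marginal single-variant slope and p-value, matching the trait's link.
# Identity link: closed-form simple regression t-test. Logit: one glm per
# variant. Monomorphic dosage columns return NA (no flip possible).
marginal_scan <- function(dos, y, link) {
  m <- ncol(dos)
  slope <- pval <- rep(NA_real_, m)
  if (link == "identity") {
    n <- length(y)
    xc <- sweep(dos, 2, colMeans(dos))
    yc <- y - mean(y)
    sxx <- colSums(xc^2)
    ok <- sxx > 0
    b <- colSums(xc * yc)[ok] / sxx[ok]
    res_ss <- sum(yc^2) - b^2 * sxx[ok]
    se <- sqrt(pmax(res_ss, 0) / (n - 2) / sxx[ok])
    tt <- ifelse(se > 0, b / se, 0)
    slope[ok] <- b
    pval[ok] <- 2 * pt(-abs(tt), df = n - 2)
  } else {
    for (j in seq_len(m)) {
      x <- dos[, j]
      if (var(x) == 0) next
      fit <- suppressWarnings(
        glm.fit(cbind(1, x), y, family = binomial()))
      cf <- fit$coefficients[2]
      # Wald p from the fisher information at the fit
      w <- fit$weights
      X <- cbind(1, x)
      I <- crossprod(X * sqrt(w))
      vc <- tryCatch(solve(I), error = function(e) NULL)
      if (is.null(vc) || vc[2, 2] <= 0) next
      z <- cf / sqrt(vc[2, 2])
      slope[j] <- cf
      pval[j] <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(slope = slope, pval = pval)
}

#' Data-adaptive sum collapsing score
#'
#' Fits the marginal single-variant regression of the trait on each rare
#' site's dosage (same link as the trait). A site whose marginal slope is
#' negative with p-value below `alpha0` has its dosage recoded to
#' `2 - dosage`; the score is the sum of the (possibly recoded) dosages.
#' Orientation decisions are data-dependent and must be re-estimated for
#' every phenotype replicate.
#'
#' @inheritParams collapse_prop
#' @param y trait vector aligned to the individuals of `g`.
#' @param alpha0 flip significance level; `alpha0 = 0` never flips.
#' @param link `"identity"` or `"logit"`.
#' @return numeric score per individual, with attribute `"flipped"`
#'   naming the recoded variants.
#' @export
collapse_das <- function(g, y, gene, rare_set, alpha0 = 0.1,
                         link = "identity") {
  sites <- intersect(g$variants$variant_id[g$variants$gene == gene], rare_set)
  if (length(sites) == 0L)
    stop("gene ", gene, " has no rare variants; skip it upstream")
  dos <- g$dosages[, sites, drop = FALSE]
  flip <- rep(FALSE, length(sites))
  if (alpha0 > 0) {
    sc <- marginal_scan(dos, y, link)
    flip <- !is.na(sc$slope) & sc$slope < 0 & sc$pval < alpha0
  }
  dos2 <- dos
  if (any(flip)) dos2[, flip] <- 2L - dos2[, flip]
  out <- rowSums(dos2)
  attr(out, "flipped") <- sites[flip]
  out
}

#' Weighted-sum collapsing score
#'
#' Pools all of a gene's variants (rare and common) into
#' `sum_j dosage_ij / w_j` with `w_j = sqrt(n * q_j * (1 - q_j))`, where
#' `q_j = (m_j + 1) / (2 n_u + 2)` is a smoothed minor-allele frequency
#' estimated in the frequency-source group (`n_u` individuals with
#' minor-allele count `m_j`), and `n` is the total sample size. For the
#' binary disease trait the frequency source is the unaffected group;
#' quantitative traits use all individuals.
#'
#' @inheritParams collapse_das
#' @param frequency_source `"all_samples"` or `"unaffected_only"`.
#' @return numeric score per individual.
#' @export
collapse_ws <- function(g, y, gene,
                        frequency_source = c("all_samples",
                                             "unaffected_only")) {
  frequency_source <- match.arg(frequency_source)
  sites <- g$variants$variant_id[g$variants$gene == gene]
  if (length(sites) == 0L) stop("gene ", gene, " has no variants")
  dos <- g$dosages[, sites, drop = FALSE]
  if (frequency_source == "unaffected_only") {
    grp <- which(y == 0)
    if (length(grp) == 0L) stop("frequency-source group (unaffected) is empty")
  } else {
    grp <- seq_len(nrow(dos))
  }
  n_u <- length(grp)
  n <- nrow(dos)
  m_j <- colSums(dos[grp, , drop = FALSE])
  q <- (m_j + 1) / (2 * n_u + 2)
  w <- sqrt(n * q * (1 - q))
  as.numeric(dos %*% (1 / w))
}

#' Build the collapsed design matrix for the multimarker regression
#'
#' Columns are, in order: covariates (Age, Sex, Smoke, population dummy
#' columns; never penalized), individual common-variant dosages (omitted
#' under WS, which pools common and rare variants into the gene term),
#' and one collapsed score per gene — or two per gene when
#' `split_by_annotation` is set, collapsing nonsynonymous and synonymous
#' variants separately so they can receive different penalties. Genes
#' with no variants in a stratum contribute no column for it.
#'
#' @param g a [genotype_set()].
#' @param covariates data.frame with `individual_id`, `Age`, `Sex`,
#'   `Smoke`, `population`, rows aligned to `g`.
#' @param config a [collapse_config()].
#' @param y trait vector; required by DAS (orientation) and by WS for the
#'   disease trait (unaffected frequency source).
#' @param link `"identity"` or `"logit"`; decides DAS marginal link and
#'   the WS frequency-source default under `"auto"`.
#' @return object of class `collapsed_design`: list with the numeric
#'   matrix `X` and a data.frame `info` (columns `name`, `type`, `gene`,
#'   `annotation`, `penalty_class`, and a list-column `variants` giving
#'   each genetic column's underlying variant ids).
#' @export
build_design <- function(g, covariates, config, y = NULL,
                         link = c("identity", "logit")) {
  stopifnot(inherits(g, "genotype_set"), inherits(config, "collapse_config"))
  link <- match.arg(link)
  n <- nrow(g$dosages)
  if (nrow(covariates) != n)
    stop("covariate rows do not align with genotype individuals")
  if (!is.null(covariates$individual_id) &&
      !identical(as.character(covariates$individual_id),
                 rownames(g$dosages)))
    stop("individual ids of covariates and genotypes do not match")
  if (config$method %in% c("DAS") && is.null(y))
    stop("DAS needs the trait vector y to orient variants")

  part <- classify_variants(g, config$rare_maf_threshold)
  vtab <- g$variants

  cols <- list(); info <- list()
  add <- function(values, name, type, gene = NA_character_,
                  annotation = NA_character_, penalty_class, variants = NULL) {
    cols[[length(cols) + 1L]] <<- values
    info[[length(info) + 1L]] <<- list(name = name, type = type, gene = gene,
                                       annotation = annotation,
                                       penalty_class = penalty_class,
                                       variants = variants %||% character(0))
  }

  for (nm in c("Age", "Sex", "Smoke"))
    add(as.numeric(covariates[[nm]]), nm, "covariate",
        penalty_class = "unpenalized")
  pop <- factor(covariates$population)
  if (nlevels(pop) > 1) {
    for (lev in levels(pop)[-1])
      add(as.numeric(pop == lev), paste0("population", lev), "covariate",
          penalty_class = "unpenalized")
  }

  if (config$method != "WS") {
    for (v in part$common)
      add(as.numeric(g$dosages[, v]), v, "common_variant",
          gene = vtab$gene[vtab$variant_id == v],
          penalty_class = "penalized", variants = v)
  }

  freq_src <- config$ws_frequency_source
  if (freq_src == "auto")
    freq_src <- if (link == "logit") "unaffected_only" else "all_samples"

  gene_score <- function(gene, sites, anno_class) {
    score <- switch(config$method,
      PROP = collapse_prop(g, gene, sites),
      DAS = collapse_das(g, y, gene, sites, alpha0 = config$das_alpha0,
                         link = link),
      WS = {
        sub <- subset_genotype_set(g, sites)
        collapse_ws(sub, y, gene, frequency_source = freq_src)
      })
    pclass <- if (!config$split_by_annotation) "penalized"
              else if (anno_class == "ns") "penalized_ns" else "penalized_s"
    nm <- if (config$split_by_annotation) paste0(gene, "_", anno_class)
          else gene
    add(as.numeric(score), nm, "gene_score", gene = gene,
        annotation = if (config$split_by_annotation) anno_class else "pooled",
        penalty_class = pclass, variants = sites)
  }

  genes <- unique(vtab$gene)
  for (gene in genes) {
    gv <- vtab[vtab$gene == gene, , drop = FALSE]
    # WS pools rare and common; PROP/DAS use rare sites only
    pool <- if (config$method == "WS") gv$variant_id
            else intersect(gv$variant_id, part$rare)
    if (!config$split_by_annotation) {
      if (length(pool) == 0L) {
        warning("gene ", gene, " has no rare variants; no score column")
        next
      }
      gene_score(gene, pool, "pooled")
    } else {
      for (anno_class in c("ns", "s")) {
        sites <- intersect(pool, gv$variant_id[gv$annotation == anno_class])
        if (length(sites) == 0L) next
        gene_score(gene, sites, anno_class)
      }
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- vapply(info, `[[`, "", "name")
  rownames(X) <- rownames(g$dosages)
  info_df <- data.frame(
    name = vapply(info, `[[`, "", "name"),
    type = vapply(info, `[[`, "", "type"),
    gene = vapply(info, `[[`, "", "gene"),
    annotation = vapply(info, `[[`, "", "annotation"),
    penalty_class = vapply(info, `[[`, "", "penalty_class"),
    stringsAsFactors = FALSE
  )
  info_df$variants <- lapply(info, `[[`, "variants")
  structure(list(X = X, info = info_df, method = config$method,
                 config = config),
            class = "collapsed_design")
}

# restrict a genotype_set to a subset of variants (order preserved
# as given)
subset_genotype_set <- function(g, variant_ids) {
  idx <- match(variant_ids, g$variants$variant_id)
  if (anyNA(idx)) stop("unknown variant id(s)")
  genotype_set(g$dosages[, idx, drop = FALSE],
               g$variants$gene[idx], g$variants$annotation[idx])
}

#' @export
print.collapsed_design <- function(x, ...) {
  tab <- table(x$info$type)
  cat(sprintf("collapsed_design (%s): %d x %d [%s]\n", x$method,
              nrow(x$X), ncol(x$X),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
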