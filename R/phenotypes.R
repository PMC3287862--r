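#' Draw a causal truth set over a genotype set
#'
#' Selects causal genes and, within each causal gene, causal variants for
#' each trait. All causal variants are nonsynonymous, mirroring the
#' simulation design the package emulates. Per-variant raw effects are
#' proportional to `1 / sqrt(2 p (1 - p))` (rarer alleles get larger
#' per-allele effects, so each causal variant contributes comparable
#' trait variance), then rescaled jointly so the realized genetic
#' variance of the causal score equals `h2` on this genotype matrix.
#'
#' @param g a [genotype_set()].
#' @param h2 named list of target genetic variance fractions per trait;
#'   traits with `h2 = 0` (or omitted, like Q4) receive no causal
#'   variants.
#' @param n_causal_genes named list of causal gene counts per trait.
#' @param causal_variant_prob probability each nonsynonymous variant in a
#'   causal gene is causal (at least one is forced).
#' @param seed integer seed.
#' @return object of class `truth_set`: a list with one element per
#'   trait, each holding `variants`, `genes` and a named `effects`
#'   vector (trait units per minor allele).
#' @export
simulate_truth <- function(g,
                           h2 = list(Q1 = 0.3, Q2 = 0.3, disease = 0.15),
                           n_causal_genes = list(Q1 = 5, Q2 = 5,
                                                 disease = 5),
                           causal_variant_prob = 0.5, seed = NULL) {
  stopifnot(inherits(g, "genotype_set"))
  with_seed(seed, {
    v <- g$variants
    eligible <- v$variant_id[v$annotation == "ns" & v$maf > 0]
    genes_with_ns <- unique(v$gene[v$variant_id %in% eligible])
    out <- list()
    for (trait in names(n_causal_genes)) {
      k <- n_causal_genes[[trait]]
      if (k == 0 || is.null(h2[[trait]]) || h2[[trait]] <= 0) {
        out[[trait]] <- list(variants = character(0), genes = character(0),
                             effects = setNames(numeric(0), character(0)))
        next
      }
      if (k > length(genes_with_ns))
        stop("not enough genes with nonsynonymous variants for trait ", trait)
      cg <- sample(genes_with_ns, k)
      cv <- unlist(lapply(cg, function(gene) {
        cand <- v$variant_id[v$gene == gene &
                               v$variant_id %in% eligible]
        pick <- cand[runif(length(cand)) < causal_variant_prob]
        if (length(pick) == 0L) pick <- sample(cand, 1L)
        pick
      }), use.names = FALSE)
      p <- v$maf[match(cv, v$variant_id)]
      beta <- 1 / sqrt(2 * pmax(p, 1e-3) * (1 - pmax(p, 1e-3)))
      score <- as.numeric(g$dosages[, cv, drop = FALSE] %*% beta)
      s <- var(score)
      if (s <= 0) stop("degenerate causal score for trait ", trait)
      beta <- beta * sqrt(h2[[trait]] / s)
      out[[trait]] <- list(variants = cv, genes = sort(unique(cg)),
                           effects = setNames(beta, cv))
    }
    structure(out, class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  for (trait in names(x)) {
    cat(sprintf("%s: %d causal variants in %d genes\n", trait,
                length(x[[trait]]$variants), length(x[[trait]]$genes)))
  }
  invisible(x)
}

default_variance_model <- function() {
  list(
    Q1 = list(cov_frac = 0.2, cov = c(Age = 1, Smoke = 1)),
    Q2 = list(cov_frac = 0, cov = numeric(0)),
    Q4 = list(cov_frac = 0.35, cov = c(Age = 1, Sex = 0.5, Smoke = 1)),
    disease = list(liability_weights = c(Q1 = 0.5, Q2 = 0.5, Q4 = 0.3),
                   noise_var = 0.3)
  )
}

simulate_covariates <- function(n, seed = NULL) {
  with_seed(seed, {
    data.frame(
      individual_id = sprintf("ind%04d", seq_len(n)),
      Age = pmin(pmax(round(rnorm(n, 45, 12)), 18), 90),
      Sex = rbinom(n, 1L, 0.5),
      Smoke = rbinom(n, 1L, 0.25),
      population = sample(c("pop1", "pop2", "pop3"), n, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate multi-replicate phenotypes over fixed genotypes
#'
#' Genotypes and covariates are fixed; only the phenotype noise is
#' redrawn in each of the `R` replicates, mimicking a workshop-style
#' design where many phenotype simulations share one genotype matrix.
#' Trait models:
#' \describe{
#'   \item{Q1}{covariates (Age, Smoke) + causal-variant effects + noise.}
#'   \item{Q2}{causal-variant effects + noise only.}
#'   \item{Q4}{covariates (Age, Sex, Smoke) + noise; no genetic term.}
#'   \item{disease}{indicator that a latent liability, a weighted sum of
#'     Q1, Q2 and Q4 plus disease-specific causal-variant effects and
#'     noise, exceeds the (1 - prevalence) quantile of its replicate.}
#' }
#' Covariate components are rescaled so they explain `cov_frac` of unit
#' total trait variance; the genetic score contributes the `h2` encoded
#' in the truth-set effects; residual noise fills the remainder.
#'
#' @param g a [genotype_set()].
#' @param truth a `truth_set` from [simulate_truth()].
#' @param traits character vector of traits to simulate (any of Q1, Q2,
#'   Q4, disease; disease forces the three quantitative traits to be
#'   computed internally).
#' @param R number of phenotype replicates.
#' @param prevalence disease prevalence in (0, 1).
#' @param variance_model list controlling covariate variance fractions
#'   and liability weights; see `rarelasso:::default_variance_model`.
#' @param covariates optional covariate data.frame (columns
#'   `individual_id`, `Age`, `Sex`, `Smoke`, `population`); generated if
#'   omitted.
#' @param seed integer seed covering covariate generation and all
#'   replicate noise.
#' @return object of class `replicate_set`: list with `covariates`,
#'   `traits` (named list of n x R matrices), and `R`.
#' @export
simulate_phenotypes <- function(g, truth,
                                traits = c("Q1", "Q2", "Q4", "disease"),
                                R = 200, prevalence = 0.3,
                                variance_model = default_variance_model(),
                                covariates = NULL, seed = NULL) {
  stopifnot(inherits(g, "genotype_set"), R >= 1)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1")
  unknown <- setdiff(traits, c("Q1", "Q2", "Q4", "disease"))
  if (length(unknown)) stop("unknown trait(s): ", paste(unknown, collapse = ", "))
  n <- nrow(g$dosages)
  with_seed(seed, {
    if (is.null(covariates)) covariates <- simulate_covariates(n)
    stopifnot(nrow(covariates) == n)

    gscore <- function(trait) {
      tr <- truth[[trait]]
      if (is.null(tr) || length(tr$variants) == 0L) return(rep(0, n))
      as.numeric(g$dosages[, tr$variants, drop = FALSE] %*% tr$effects)
    }
    cov_part <- function(trait) {
      vm <- variance_model[[trait]]
      if (is.null(vm) || vm$cov_frac <= 0 || length(vm$cov) == 0L)
        return(rep(0, n))
      raw <- rep(0, n)
      for (nm in names(vm$cov))
        raw <- raw + vm$cov[[nm]] * as.numeric(scale(covariates[[nm]]))
      s <- var(raw)
      if (s <= 0) return(rep(0, n))
      raw * sqrt(vm$cov_frac / s)
    }

    quant <- function(trait) {
      gpart <- gscore(trait)
      cpart <- cov_part(trait)
      noise_var <- max(1 - var(gpart) - var(cpart), 0.05)
      fixed <- gpart + cpart
      vapply(seq_len(R), function(r) fixed + rnorm(n, 0, sqrt(noise_var)),
             numeric(n))
    }

    need_quant <- "disease" %in% traits
    q1 <- if ("Q1" %in% traits || need_quant) quant("Q1")
    q2 <- if ("Q2" %in% traits || need_quant) quant("Q2")
    q4 <- if ("Q4" %in% traits || need_quant) quant("Q4")

    out <- list()
    if ("Q1" %in% traits) out$Q1 <- q1
    if ("Q2" %in% traits) out$Q2 <- q2
    if ("Q4" %in% traits) out$Q4 <- q4
    if ("disease" %in% traits) {
      w <- variance_model$disease$liability_weights
      gd <- gscore("disease")
      nv <- variance_model$disease$noise_var
      liab <- w[["Q1"]] * q1 + w[["Q2"]] * q2 + w[["Q4"]] * q4 +
        gd + matrix(rnorm(n * R, 0, sqrt(nv)), n, R)
      out$disease <- vapply(seq_len(R), function(r) {
        thr <- quantile(liab[, r], 1 - prevalence, names = FALSE)
        as.numeric(liab[, r] > thr)
      }, numeric(n))
    }
    out <- lapply(out, function(m) {
      dimnames(m) <- list(covariates$individual_id,
                          paste0("rep", seq_len(R)))
      m
    })
    structure(list(covariates = covariates, traits = out, R = R),
              class = "replicate_set")
  })
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set: %d individuals, R = %d replicates, traits: %s\n",
              nrow(x$covariates), x$R,
              paste(names(x$traits), collapse = ", ")))
  invisible(x)
}
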