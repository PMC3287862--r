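test_that("rare/common classification is inclusive on the rare side", {
  n <- 1000
  g <- geno_from_maf(n, c(0.001, 0.04, 0.05, 0.051, 0.2),
                     gene = rep("G001", 5))
  expect_equal(g$variants$maf, c(0.001, 0.04, 0.05, 0.051, 0.2))
  part <- classify_variants(g, 0.05)
  expect_setequal(part$rare, g$variants$variant_id[1:3])   # 0.05 is rare
  expect_setequal(part$common, g$variants$variant_id[4:5])
  # MAF 0.5 is common at the default threshold
  g5 <- geno_from_maf(10, 0.5)
  expect_equal(classify_variants(g5, 0.05)$common,
               g5$variants$variant_id)
})

test_that("PROP is the carrier proportion over rare sites", {
  # 5 rare sites; individual 1 carries minor alleles at two of them
  dos <- matrix(0L, 4, 5,
                dimnames = list(NULL, paste0("G001_V0", 1:5)))
  dos[1, 1] <- 1L; dos[1, 2] <- 2L
  dos[2, 3] <- 1L
  g <- genotype_set(dos, rep("G001", 5), rep("ns", 5))
  rare <- g$variants$variant_id
  s <- collapse_prop(g, "G001", rare)
  expect_equal(unname(s), c(2 / 5, 1 / 5, 0, 0))

  # homozygote at the single rare site scores 1.0: indicator, not count
  g1 <- genotype_set(matrix(c(2L, 0L), 2, 1), "G001", "ns")
  expect_equal(unname(collapse_prop(g1, "G001",
                                    g1$variants$variant_id)), c(1, 0))
  expect_error(collapse_prop(g1, "G001", character(0)), "no rare variants")
})

test_that("DAS flips significantly protective variants and alpha0 = 0 never flips", {
  set.seed(10)
  n <- 500
  x <- rbinom(n, 2, 0.2)
  x2 <- rbinom(n, 2, 0.1)
  dos <- cbind(G001_V01 = x, G001_V02 = x2)
  g <- genotype_set(dos, c("G001", "G001"), c("ns", "ns"))
  y <- -1 * x + 0.05 * x2 + rnorm(n)
  s <- collapse_das(g, y, "G001", colnames(dos), alpha0 = 0.1)
  expect_identical(attr(s, "flipped"), "G001_V01")
  expect_equal(as.vector(s), as.vector((2 - x) + x2))
  # oracle: the flipped site now has a positive marginal slope
  expect_gt(coef(lm(y ~ I(2 - x)))[2], 0)

  s0 <- collapse_das(g, y, "G001", colnames(dos), alpha0 = 0)
  expect_equal(as.vector(s0), as.vector(x + x2))
  expect_length(attr(s0, "flipped"), 0)
})

test_that("WS weights match the stated frequency arithmetic", {
  # 100 individuals, 50 unaffected; one minor allele among the unaffected
  n <- 100
  dos <- matrix(0L, n, 1, dimnames = list(NULL, "G001_V01"))
  dos[1, 1] <- 1L              # individual 1 is unaffected (y = 0)
  dos[60, 1] <- 1L             # an affected carrier too
  y <- rep(c(0, 1), each = 50)
  g <- genotype_set(dos, "G001", "ns")
  s <- collapse_ws(g, y, "G001", frequency_source = "unaffected_only")
  q <- (1 + 1) / (2 * 50 + 2)
  w <- sqrt(n * q * (1 - q))
  expect_equal(q, 2 / 102)
  expect_equal(unname(s[1]), 1 / w)
  expect_equal(unname(s[1]), 0.72127, tolerance = 1e-4)
  expect_equal(unname(s[5]), 0)
  # identical dosage rows score identically
  expect_equal(s[1], s[60], ignore_attr = TRUE)
  expect_error(collapse_ws(g, rep(1, n), "G001",
                           frequency_source = "unaffected_only"),
               "empty")
})

test_that("WS with equal allele counts is proportional to the plain dosage sum", {
  set.seed(2)
  dos <- matrix(rbinom(200 * 4, 1, 0.1), 200, 4)
  # force equal column sums
  target <- 20
  for (j in 1:4) {
    dos[, j] <- 0L
    dos[seq_len(target) + (j - 1) * 5, j] <- 1L
  }
  g <- genotype_set(dos, rep("G001", 4), rep("ns", 4))
  s <- collapse_ws(g, NULL, "G001", frequency_source = "all_samples")
  expect_equal(cor(s, rowSums(dos)), 1, tolerance = 1e-12)
})

test_that("collapsers are invariant to variant order within a gene", {
  set.seed(3)
  dos <- matrix(rbinom(100 * 6, 2, 0.05), 100, 6,
                dimnames = list(NULL, paste0("G001_V0", 1:6)))
  g <- genotype_set(dos, rep("G001", 6), rep("ns", 6))
  perm <- c(4, 2, 6, 1, 5, 3)
  gp <- genotype_set(dos[, perm], rep("G001", 6), rep("ns", 6))
  rare <- g$variants$variant_id
  y <- rnorm(100)
  expect_equal(collapse_prop(g, "G001", rare),
               collapse_prop(gp, "G001", rare))
  expect_equal(unname(collapse_das(g, y, "G001", rare)),
               unname(collapse_das(gp, y, "G001", rare)))
  expect_equal(collapse_ws(g, y, "G001"), collapse_ws(gp, y, "G001"))
})

test_that("design columns follow the documented accounting", {
  set.seed(4)
  n <- 120
  # 2 genes x 4 rare variants (both annotation classes present) + 3
  # common variants
  maf <- c(rep(0.02, 8), rep(0.2, 3))
  gene <- c(rep(c("G001", "G002"), each = 4), "G001", "G001", "G002")
  anno <- c(rep(c("ns", "ns", "s", "s"), 2), "ns", "s", "ns")
  g <- geno_from_maf(n, maf, gene = gene, annotation = anno)
  cov <- simulate_phenotypes(g, structure(list(), class = "truth_set"),
                             traits = "Q4", R = 1, seed = 1)$covariates
  cov$individual_id <- rownames(g$dosages)
  n_cov <- 3 + (length(unique(cov$population)) - 1)

  d <- build_design(g, cov, collapse_config("PROP"))
  expect_equal(ncol(d$X), n_cov + 3 + 2)
  expect_equal(sum(d$info$type == "common_variant"), 3)
  expect_true(all(d$info$penalty_class[d$info$type == "covariate"] ==
                    "unpenalized"))

  ds <- build_design(g, cov, collapse_config("PROP",
                                             split_by_annotation = TRUE))
  expect_equal(ncol(ds$X), n_cov + 3 + 4)
  expect_setequal(unique(ds$info$penalty_class[ds$info$type == "gene_score"]),
                  c("penalized_ns", "penalized_s"))

  # WS pools common variants into the gene term: no common columns
  y <- rnorm(n)
  dw <- build_design(g, cov, collapse_config("WS"), y = y)
  expect_equal(sum(dw$info$type == "common_variant"), 0)
  # PROP scores lie in [0, 1]
  gs <- d$X[, d$info$type == "gene_score", drop = FALSE]
  expect_true(all(gs >= 0 & gs <= 1))
})

test_that("pooled PROP score is the site-count weighted mean of the stratum scores", {
  set.seed(5)
  n <- 150
  maf <- rep(0.03, 7)
  anno <- c("ns", "ns", "ns", "s", "s", "s", "s")
  g <- geno_from_maf(n, maf, gene = rep("G001", 7), annotation = anno)
  rare <- g$variants$variant_id
  pooled <- collapse_prop(g, "G001", rare)
  s_ns <- collapse_prop(g, "G001", rare[anno == "ns"])
  s_s <- collapse_prop(g, "G001", rare[anno == "s"])
  expect_equal(pooled, (3 * s_ns + 4 * s_s) / 7)
  expect_true(all(pmin(s_ns, s_s) <= pooled & pooled <= pmax(s_ns, s_s)))
})
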