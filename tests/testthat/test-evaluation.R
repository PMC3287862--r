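test_that("consistency score matches hand-computed values and its invariances", {
  # identical selections in every replicate: perfectly consistent
  s <- matrix(1, 5, 3)
  expect_equal(consistency_score(s), 0)

  # R = 4, one feature selected in exactly 2 replicates: 2 * 2 / 4 = 1
  s1 <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(consistency_score(s1), 1)

  # adding a feature selected in all R replicates changes nothing
  s2 <- cbind(s1, 1)
  expect_equal(consistency_score(s2), consistency_score(s1))

  # invariant to feature and replicate order
  set.seed(1)
  s3 <- matrix(rbinom(40, 1, 0.4), 8, 5)
  s3[, 1] <- 1  # make sure F is non-empty
  expect_equal(consistency_score(s3),
               consistency_score(s3[sample(8), sample(5)]))

  # normalized variant divides by |F|
  nf <- sum(colSums(s3) > 0)
  expect_equal(consistency_score(s3, "per_feature"),
               consistency_score(s3) / nf)

  expect_error(consistency_score(matrix(0, 4, 2)), "empty feature set")
  expect_error(consistency_score(matrix(1, 1, 2)), "2 replicates")
})

test_that("ranking AUC equals brute-force pairwise concordance, with ties", {
  cases <- list(
    list(counts = c(10, 8, 5, 3, 2, 1), labels = c(1, 1, 0, 0, 0, 0),
         R = 10),
    list(counts = c(10, 5, 5, 3, 2, 1), labels = c(1, 0, 1, 0, 0, 0),
         R = 10),
    list(counts = c(7, 7, 7, 0, 2, 9, 4, 4), labels = c(1, 0, 1, 0, 0, 1,
                                                        1, 0), R = 9)
  )
  for (cs in cases) {
    fx <- fits_from_counts(cs$counts, cs$R, cs$labels)
    rr <- rank_and_roc(fx$fits, fx$truth_trait)
    expect_equal(unname(rr$counts), cs$counts)
    expect_equal(rr$auc, concordance_auc(cs$counts, cs$labels))
    # ROC is a monotone step curve in the threshold
    expect_true(all(diff(rr$roc$sensitivity) <= 0))
    expect_true(all(diff(rr$roc$specificity) >= 0))
  }

  # perfect separation gives AUC 1; counts independent of truth give 1/2
  fx <- fits_from_counts(c(10, 10, 0, 0), 10, c(1, 1, 0, 0))
  expect_equal(rank_and_roc(fx$fits, fx$truth_trait)$auc, 1)
  fx2 <- fits_from_counts(c(4, 4, 4, 4), 10, c(1, 0, 1, 0))
  expect_equal(rank_and_roc(fx2$fits, fx2$truth_trait)$auc, 0.5)

  # ties in top_features break lexicographically
  fx3 <- fits_from_counts(c(3, 5, 3), 6, c(1, 0, 0))
  tf <- rank_and_roc(fx3$fits, fx3$truth_trait)$top_features
  expect_equal(tf$feature, c("F02", "F01", "F03"))

  empty_truth <- list(variants = character(0), genes = character(0))
  expect_error(rank_and_roc(fx3$fits, empty_truth), "truth")
})

test_that("prediction improvement is exactly zero when genetics never enter", {
  sim <- make_small_sim(n = 120, n_genes = 6, R = 3, seed = 13)
  cfg <- collapse_config("PROP")
  d <- build_design(sim$g, sim$reps$covariates, cfg)
  fits <- lapply(1:3, function(r) {
    f <- fit_lasso(d, sim$reps$traits$Q2[, r], "identity",
                   penalty_spec(lambda = 1e4))
    f$replicate <- r
    f
  })
  genetic <- fits[[1]]$info$type != "covariate"
  expect_true(all(vapply(fits,
                         function(f) all(f$coefficients[genetic] == 0),
                         logical(1))))
  impr <- cross_replicate_prediction(fits, sim$reps, "Q2")
  expect_identical(as.numeric(impr), 0)
})

test_that("improvement is positive for a genetic trait in a strong-signal toy", {
  sim <- make_small_sim(n = 250, n_genes = 10, R = 4, n_causal = 3,
                        h2 = 0.4, seed = 17)
  cfg <- collapse_config("PROP")
  fits <- fit_all_replicates(sim$g, sim$reps, "Q2", cfg, seed = 3,
                             nlambda = 20, k = 3)
  expect_gt(cross_replicate_prediction(fits, sim$reps, "Q2"), 0)
  # a fit list not matching the replicate count is rejected
  expect_error(cross_replicate_prediction(fits[1:2], sim$reps, "Q2"),
               "one fit per replicate")
})

test_that("compare_methods assembles one row per method and trait, deterministically", {
  sim <- make_small_sim(n = 150, n_genes = 8, R = 4, seed = 23)
  rep1 <- compare_methods(sim$g, sim$reps, sim$truth, methods = "PROP",
                          traits = c("Q2", "Q4"), seed = 2, nlambda = 12,
                          k = 3)
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(nrow(rep1$summary), 2)
  expect_equal(rep1$summary$method, c("PROP", "PROP"))
  rep2 <- compare_methods(sim$g, sim$reps, sim$truth, methods = "PROP",
                          traits = c("Q2", "Q4"), seed = 2, nlambda = 12,
                          k = 3)
  expect_identical(rep1$summary, rep2$summary)
  auc_q2 <- rep1$summary$auc[rep1$summary$trait == "Q2"]
  expect_true(auc_q2 >= 0 && auc_q2 <= 1)
  # Q4 has no causal truth set, so no ROC is defined for it
  expect_true(is.na(rep1$summary$auc[rep1$summary$trait == "Q4"]))
})
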