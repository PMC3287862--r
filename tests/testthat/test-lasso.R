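make_design_matrix <- function(n = 60, p = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- c(1.2, -0.8, 0.5, rep(0, p - 3))
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y)
}

test_that("the unpenalized limit equals OLS and a dominant penalty zeroes everything", {
  d <- make_design_matrix()
  f0 <- lasso_fit(d$X, d$y, "identity", lambda = 0)
  ols <- lm(d$y ~ d$X)
  expect_equal(unname(f0$coefficients), unname(coef(ols))[-1],
               tolerance = 1e-6)
  expect_equal(f0$intercept, unname(coef(ols))[1], tolerance = 1e-6)

  fbig <- lasso_fit(d$X, d$y, "identity", lambda = 1e4)
  expect_true(all(fbig$coefficients == 0))   # exact zeros, no epsilon
  expect_equal(fbig$intercept, mean(d$y), tolerance = 1e-8)
})

test_that("solutions satisfy the subgradient (KKT) conditions for both links", {
  for (seed in 1:6) {
    inst <- random_instance(seed, n = 60, p = 6, link = "identity")
    f <- lasso_fit(inst$X, inst$y, "identity", inst$lam,
                   standardize = FALSE, tol = 1e-9)
    expect_lt(lasso_kkt(inst$X, inst$y, "identity", inst$lam,
                        f$coefficients, f$intercept), 1e-6)
    expect_identical(unname(f$selected), unname(f$coefficients != 0))
  }
  for (seed in 7:10) {
    inst <- random_instance(seed, n = 60, p = 4, link = "logit")
    f <- lasso_fit(inst$X, inst$y, "logit", inst$lam,
                   standardize = FALSE, tol = 1e-9)
    expect_lt(lasso_kkt(inst$X, inst$y, "logit", inst$lam,
                        f$coefficients, f$intercept), 1e-5)
  }
})

test_that("per-feature factors are equivalent to rescaling the columns", {
  d <- make_design_matrix(n = 80, p = 5, seed = 3)
  fac <- c(0.5, 2, 1, 3, 0.8)
  lam <- 0.2
  f1 <- lasso_fit(d$X, d$y, "identity", lambda = lam * fac,
                  standardize = FALSE, tol = 1e-9)
  X2 <- sweep(d$X, 2, fac, "/")
  f2 <- lasso_fit(X2, d$y, "identity", lambda = lam,
                  standardize = FALSE, tol = 1e-9)
  expect_equal(unname(f1$coefficients),
               unname(f2$coefficients / fac), tolerance = 1e-6)
})

test_that("selection is monotone along a decreasing penalty grid", {
  d <- make_design_matrix(n = 70, p = 10, seed = 4)
  grid <- exp(seq(log(0.8), log(0.001), length.out = 25))
  k <- vapply(grid, function(l) {
    sum(lasso_fit(d$X, d$y, "identity", l)$selected)
  }, numeric(1))
  expect_true(all(diff(k) >= 0))  # non-increasing in lambda (grid descends)
})

test_that("the solver reproduces glmnet with penalty factors on both links", {
  skip_if_not_installed("glmnet")
  set.seed(42)
  n <- 80; p <- 10
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("x", 1:p)
  beta <- c(1.5, -1, 0.5, rep(0, p - 3))
  y <- drop(X %*% beta) + rnorm(n)
  pf <- c(0, 0, rep(1, p - 2))
  lam <- 0.15
  f1 <- lasso_fit(X, y, "identity", lambda = lam * pf, tol = 1e-9)
  g1 <- glmnet::glmnet(X, y, lambda = lam * sum(pf) / p,
                       penalty.factor = pf, thresh = 1e-14)
  expect_equal(unname(f1$coefficients), as.numeric(coef(g1))[-1],
               tolerance = 1e-6)
  yb <- rbinom(n, 1, plogis(drop(X %*% beta * 0.8)))
  f2 <- lasso_fit(X, yb, "logit", lambda = lam * pf, tol = 1e-9)
  g2 <- glmnet::glmnet(X, yb, family = "binomial",
                       lambda = lam * sum(pf) / p, penalty.factor = pf,
                       thresh = 1e-14)
  expect_equal(unname(f2$coefficients), as.numeric(coef(g2))[-1],
               tolerance = 1e-5)
})

test_that("logit fits match a dense-grid reference optimum on a symmetric toy", {
  set.seed(6)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  pr <- plogis(1.2 * x1 - 0.6 * x2)
  y <- rbinom(n, 1, pr)
  # symmetrize so the optimal intercept is exactly 0
  X <- rbind(cbind(x1, x2), cbind(-x1, -x2))
  colnames(X) <- c("x1", "x2")
  yy <- c(y, 1 - y)
  lam <- c(0.05, 0.05)
  f <- lasso_fit(X, yy, "logit", lam, standardize = FALSE, tol = 1e-9)
  grid <- seq(-2, 2, by = 0.01)
  objs <- outer(grid, grid, Vectorize(function(b1, b2) {
    penalized_objective(X, yy, "logit", lam, c(b1, b2), 0)
  }))
  expect_lt(abs(f$intercept), 1e-6)
  obj_fit <- penalized_objective(X, yy, "logit", lam, f$coefficients,
                                 f$intercept)
  expect_lt(obj_fit, min(objs) + 1e-3)
  expect_gt(obj_fit, min(objs) - 1e-3)
})

test_that("input contracts are enforced", {
  d <- make_design_matrix()
  expect_error(lasso_fit(d$X, c(d$y[-1], NA), "identity", 0.1), "finite")
  expect_error(lasso_fit(d$X, d$y, "logit", 0.1), "binary")
  expect_error(lasso_fit(d$X, d$y, "identity", -0.1), "non-negative")
})

sim_split_design <- function(seed = 11, n = 200, n_genes = 10) {
  g <- simulate_genotypes(n, n_genes, 6, seed = seed)
  truth <- simulate_truth(g, h2 = list(Q2 = 0.4), causal_variant_prob = 0.8,
                          n_causal_genes = list(Q2 = 3), seed = seed + 1)
  reps <- simulate_phenotypes(g, truth, traits = "Q2", R = 1,
                              seed = seed + 2)
  cfg <- collapse_config("PROP", split_by_annotation = TRUE)
  design <- build_design(g, reps$covariates, cfg)
  list(design = design, y = reps$traits$Q2[, 1], g = g, truth = truth)
}

test_that("differential fitting degenerates to the single-penalty fit", {
  s <- sim_split_design()
  lam <- 0.05
  fd <- fit_differential(s$design, s$y, "identity",
                         grid_ns = lam, grid_s = lam, k = 3, seed = 1)
  fs <- fit_lasso(s$design, s$y, "identity", penalty_spec(lambda = lam))
  expect_equal(fd$coefficients, fs$coefficients, tolerance = 1e-10)
  expect_identical(fd$selected, fs$selected)
})

test_that("a dominant synonymous penalty zeroes every synonymous term", {
  s <- sim_split_design()
  fd <- fit_differential(s$design, s$y, "identity",
                         grid_ns = c(0.2, 0.05), grid_s = 1e4,
                         k = 3, seed = 1)
  is_s <- s$design$info$penalty_class == "penalized_s"
  expect_true(any(is_s))
  expect_true(all(fd$coefficients[is_s] == 0))
  expect_error(fit_differential(s$design, s$y, "identity",
                                grid_ns = 0.1, grid_s = 0.1, k = 1),
               "k_folds")
})

test_that("replicate fitting is deterministic and honors R = 1", {
  sim <- make_small_sim(n = 150, n_genes = 8, R = 3, seed = 77)
  cfg <- collapse_config("PROP")
  fits1 <- fit_all_replicates(sim$g, sim$reps, "Q2", cfg, seed = 5,
                              nlambda = 15, k = 3)
  fits2 <- fit_all_replicates(sim$g, sim$reps, "Q2", cfg, seed = 5,
                              nlambda = 15, k = 3)
  expect_identical(selection_matrix(fits1), selection_matrix(fits2))
  expect_identical(vapply(fits1, function(f) f$replicate, integer(1)), 1:3)

  one <- structure(list(covariates = sim$reps$covariates,
                        traits = list(Q2 = sim$reps$traits$Q2[, 1,
                                                              drop = FALSE]),
                        R = 1L), class = "replicate_set")
  f1 <- fit_all_replicates(sim$g, one, "Q2", cfg, seed = 5,
                           nlambda = 15, k = 3)
  expect_length(f1, 1)
  d <- build_design(sim$g, sim$reps$covariates, cfg)
  direct <- cv_lasso(d, sim$reps$traits$Q2[, 1], "identity",
                     nlambda = 15, k = 3, seed = 6)  # seed + r = 5 + 1
  expect_equal(f1[[1]]$coefficients, direct$coefficients)
})
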