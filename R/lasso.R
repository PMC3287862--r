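# L1-penalized GLM fitting with per-feature penalties.
#
# The solver minimizes
#   identity link:  (1/(2n)) ||y - b0 - X beta||^2 + sum_j lambda_j |beta_j|
#   logit link:    -(1/n) loglik(beta) + sum_j lambda_j |beta_j|
# by cyclical coordinate descent (soft-thresholding, so inactive
# coefficients are exact zeros), with an IRLS outer loop for the logit
# link. Covariates carry lambda_j = 0 and are never shrunk.

std_stats <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  s[s < 1e-12] <- 1
  list(mu = mu, s = s)
}

# Gaussian problems use covariance updates (each coordinate step is
# O(p) given C = Xc'Xc/n and q = Xc'yc/n); with centered columns the
# intercept is analytically mean(y).
gaussian_ctx <- function(Xc, y) {
  n <- nrow(Xc)
  ybar <- mean(y)
  list(C = crossprod(Xc) / n, q = drop(crossprod(Xc, y - ybar)) / n,
       ybar = ybar)
}

solve_gaussian <- function(ctx, lam, beta, tol = 1e-7, maxit = 100000L) {
  res <- cd_cov(ctx$C, ctx$q, lam, beta, tol, maxit)
  res$b0 <- ctx$ybar
  res$outer_converged <- res$converged
  res
}

solve_penalized_std <- function(Xs, y, link, lam, beta, b0,
                                tol = 1e-7, maxit = 100000L) {
  if (link == "identity") {
    return(solve_gaussian(gaussian_ctx(Xs, y), lam, beta, tol, maxit))
  }
  # logit: IRLS with coordinate descent on the working response
  outer_converged <- FALSE
  res <- list(beta = beta, b0 = b0, iter = 0L, converged = TRUE)
  for (it in seq_len(100L)) {
    eta <- drop(Xs %*% res$beta) + res$b0
    eta <- pmin(pmax(eta, -30), 30)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-5)
    z <- eta + (y - p) / w
    old <- c(res$b0, res$beta)
    res <- cd_wls(Xs, z, w, lam, res$beta, res$b0, TRUE, tol, maxit)
    if (max(abs(c(res$b0, res$beta) - old)) < 1e-8) {
      outer_converged <- TRUE
      break
    }
  }
  res$outer_converged <- outer_converged
  res
}

#' Fit an L1-penalized GLM with per-feature penalty levels
#'
#' Low-level fitting routine taking a plain numeric matrix and a vector
#' of per-feature penalties (0 = unpenalized). With
#' `standardize = TRUE` (the default used by the pipeline) columns are
#' centered and scaled to unit variance before penalization and the
#' coefficients are mapped back to the original scale; with
#' `standardize = FALSE` the penalty applies to the raw-scale
#' coefficients, which is the convention used by [penalized_objective()]
#' and [lasso_kkt()].
#'
#' @param X numeric matrix (n x p).
#' @param y response; binary 0/1 for `link = "logit"`.
#' @param link `"identity"` or `"logit"`.
#' @param lambda per-feature penalty vector (recycled if length 1).
#' @param standardize standardize columns internally before penalizing.
#' @param tol coordinate-descent convergence tolerance (max coefficient
#'   change per cycle).
#' @param maxit maximum coordinate-descent cycles.
#' @param init optional warm start: list with `beta` (on the fitting
#'   scale) and `b0`.
#' @return list with `coefficients` (original scale, named), `intercept`,
#'   `selected` (exact-nonzero indicator), `fitted` (response scale),
#'   `converged`, and the fitting-scale `beta_std`/`b0_std` for warm
#'   starts.
#' @export
lasso_fit <- function(X, y, link = c("identity", "logit"), lambda,
                      standardize = TRUE, tol = 1e-7, maxit = 100000L,
                      init = NULL) {
  link <- match.arg(link)
  X <- as.matrix(X)
  if (!all(is.finite(y))) stop("y contains non-finite values")
  if (nrow(X) != length(y)) stop("X and y are not aligned")
  if (link == "logit" && !all(y %in% c(0, 1)))
    stop("logit link requires a binary 0/1 response")
  p <- ncol(X)
  lam <- rep_len(lambda, p)
  if (any(lam < 0)) stop("penalties must be non-negative")

  st <- if (standardize) std_stats(X)
        else list(mu = colMeans(X), s = rep(1, p))
  if (link == "identity") {
    # always center for the covariance-update solver; centering only
    # reparameterizes the intercept and leaves the penalty untouched
    Xf <- sweep(sweep(X, 2, st$mu), 2, st$s, "/")
  } else {
    if (standardize) {
      Xf <- sweep(sweep(X, 2, st$mu), 2, st$s, "/")
    } else {
      Xf <- X
      st <- list(mu = rep(0, p), s = rep(1, p))
    }
  }
  beta0 <- init$beta %||% rep(0, p)
  b00 <- init$b0 %||% (if (link == "logit") qlogis(pmin(pmax(mean(y), 1e-3),
                                                        1 - 1e-3))
                       else mean(y))
  res <- solve_penalized_std(Xf, y, link, lam, beta0, b00, tol, maxit)
  if (!res$converged || !isTRUE(res$outer_converged))
    warning("coordinate descent did not fully converge; ",
            "returning the current (regularized) iterate")
  beta_std <- res$beta
  beta <- beta_std / st$s
  b0 <- res$b0 - sum(beta_std * st$mu / st$s)
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta) + b0
  list(coefficients = beta, intercept = b0,
       selected = beta != 0,
       fitted = if (link == "logit") plogis(eta) else eta,
       link = link, lambda = lam,
       converged = res$converged && isTRUE(res$outer_converged),
       iter = res$iter,
       beta_std = beta_std, b0_std = res$b0)
}

#' Penalized objective value
#'
#' Smooth loss plus L1 penalty on the scale of the supplied matrix:
#' `(1/(2n)) RSS` for the identity link, `-(1/n) log-likelihood` for the
#' logit link, plus `sum_j lambda_j |beta_j|`.
#'
#' @inheritParams lasso_fit
#' @param beta coefficient vector; @param b0 intercept.
#' @export
penalized_objective <- function(X, y, link, lambda, beta, b0) {
  n <- length(y)
  eta <- drop(as.matrix(X) %*% beta) + b0
  smooth <- if (link == "identity") sum((y - eta)^2) / (2 * n)
            else sum(log1p(exp(eta)) - y * eta) / n
  smooth + sum(rep_len(lambda, length(beta)) * abs(beta))
}

#' Subgradient (KKT) violation of a penalized fit
#'
#' For the objective of [penalized_objective()], returns the largest
#' violation over: intercept gradient; `|grad_j| - lambda_j` for zero
#' coefficients (should be <= 0); `|grad_j + lambda_j * sign(beta_j)|`
#' for active ones (should be 0). A correct solution gives a value near
#' machine precision relative to the convergence tolerance.
#'
#' @inheritParams penalized_objective
#' @export
lasso_kkt <- function(X, y, link, lambda, beta, b0) {
  X <- as.matrix(X)
  n <- length(y)
  lam <- rep_len(lambda, length(beta))
  eta <- drop(X %*% beta) + b0
  r <- if (link == "identity") y - eta else y - plogis(eta)
  grad <- -drop(crossprod(X, r)) / n
  g0 <- -sum(r) / n
  active <- beta != 0
  viol <- abs(g0)
  if (any(!active))
    viol <- max(viol, max(abs(grad[!active]) - lam[!active], 0))
  if (any(active))
    viol <- max(viol, max(abs(grad[active] + lam[active] * sign(beta[active]))))
  viol
}

#' Penalty specification for the multimarker model
#'
#' Maps the design's penalty classes to penalty levels: covariates are
#' always unpenalized (factor 0); plain genetic features get `lambda`;
#' under an annotation split, nonsynonymous and synonymous collapsed
#' terms get `lambda_ns` and `lambda_s`.
#'
#' @param lambda penalty for ordinary penalized features.
#' @param lambda_ns,lambda_s penalties for nonsynonymous / synonymous
#'   collapsed terms (default to `lambda`).
#' @param factors optional named per-feature multipliers.
#' @export
penalty_spec <- function(lambda = 0, lambda_ns = NULL, lambda_s = NULL,
                         factors = NULL) {
  lambda_ns <- lambda_ns %||% lambda
  lambda_s <- lambda_s %||% lambda
  stopifnot(lambda >= 0, lambda_ns >= 0, lambda_s >= 0)
  structure(list(lambda = lambda, lambda_ns = lambda_ns,
                 lambda_s = lambda_s, factors = factors),
            class = "penalty_spec")
}

# per-feature penalty vector from a design's penalty classes
lambda_vector <- function(info, penalties) {
  lam <- numeric(nrow(info))
  lam[info$penalty_class == "penalized"] <- penalties$lambda
  lam[info$penalty_class == "penalized_ns"] <- penalties$lambda_ns
  lam[info$penalty_class == "penalized_s"] <- penalties$lambda_s
  if (!is.null(penalties$factors)) {
    idx <- match(names(penalties$factors), info$name)
    if (anyNA(idx)) stop("unknown feature in penalty factors")
    lam[idx] <- lam[idx] * penalties$factors
  }
  lam
}

as_fit_result <- function(fit, design, penalties, cv_error = NA_real_,
                          replicate = NA_integer_) {
  structure(list(coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 selected = fit$selected,
                 fitted = fit$fitted,
                 link = fit$link,
                 chosen_penalties = penalties,
                 cv_error = cv_error,
                 converged = fit$converged,
                 info = design$info,
                 replicate = replicate),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  pen <- x$info$penalty_class != "unpenalized"
  cat(sprintf("fit_result (%s link): %d/%d penalized features selected\n",
              x$link, sum(x$selected & pen), sum(pen)))
  if (!is.na(x$cv_error)) cat(sprintf("  cv error %.5f\n", x$cv_error))
  invisible(x)
}

#' Fit the collapsed multimarker model at fixed penalties
#'
#' @param design a [build_design()] result.
#' @param y trait vector.
#' @param link `"identity"` (quantitative) or `"logit"` (disease).
#' @param penalties a [penalty_spec()].
#' @param ... passed to [lasso_fit()] (`standardize`, `tol`, ...).
#' @return a `fit_result`.
#' @export
fit_lasso <- function(design, y, link = c("identity", "logit"),
                      penalties, ...) {
  link <- match.arg(link)
  stopifnot(inherits(design, "collapsed_design"),
            inherits(penalties, "penalty_spec"))
  lam <- lambda_vector(design$info, penalties)
  fit <- lasso_fit(design$X, y, link, lam, ...)
  as_fit_result(fit, design, penalties)
}

# largest penalty for which all penalized coefficients are zero, given
# the unpenalized covariates are fit freely
lambda_max_for <- function(Xs, y, link, penalized) {
  n <- length(y)
  if (any(!penalized)) {
    Xu <- cbind(1, Xs[, !penalized, drop = FALSE])
    fit0 <- if (link == "identity") stats::lm.fit(Xu, y)
            else suppressWarnings(glm.fit(Xu, y, family = binomial()))
    r <- if (link == "identity") fit0$residuals
         else y - fit0$fitted.values
  } else {
    r <- if (link == "identity") y - mean(y) else y - mean(y)
  }
  max(abs(crossprod(Xs[, penalized, drop = FALSE], r)) / n) * 1.000001
}

make_lambda_grid <- function(lmax, nlambda, lambda_min_ratio) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# standardize once and fit a whole penalty sequence with warm starts,
# returning original-scale coefficients per step; the workhorse behind
# cv_lasso and fit_differential
std_path <- function(X, y, link, lam_list, tol = 1e-7, maxit = 100000L) {
  st <- std_stats(X)
  Xs <- sweep(sweep(X, 2, st$mu), 2, st$s, "/")
  p <- ncol(X)
  beta <- rep(0, p)
  b0 <- if (link == "logit") qlogis(pmin(pmax(mean(y), 1e-3), 1 - 1e-3))
        else mean(y)
  ctx <- if (link == "identity") gaussian_ctx(Xs, y)
  lapply(lam_list, function(lam) {
    res <- if (link == "identity")
      solve_gaussian(ctx, lam, beta, tol, maxit)
    else
      solve_penalized_std(Xs, y, link, lam, beta, b0, tol, maxit)
    beta <<- res$beta
    b0 <<- res$b0
    bo <- res$beta / st$s
    list(coefficients = bo,
         intercept = res$b0 - sum(res$beta * st$mu / st$s),
         beta_std = res$beta, b0_std = res$b0,
         converged = res$converged && isTRUE(res$outer_converged))
  })
}

cv_measure <- function(y, pred, link) {
  if (link == "identity") return(mean((y - pred)^2))
  p <- pmin(pmax(pred, 1e-8), 1 - 1e-8)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

make_folds <- function(n, k, seed = NULL) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Single-penalty fit with the penalty chosen by cross-validation
#'
#' Computes a decreasing log-spaced penalty grid from the smallest value
#' that zeroes every penalized coefficient, runs k-fold cross-validation
#' within the replicate (squared error for the identity link, deviance
#' for the logit link), and refits on the full data at the
#' error-minimizing penalty.
#'
#' @inheritParams fit_lasso
#' @param nlambda grid length.
#' @param lambda_min_ratio smallest grid value relative to the largest.
#' @param k number of folds (>= 2).
#' @param seed seed for the fold assignment.
#' @param foldid optional explicit fold assignment (overrides `seed`).
#' @return a `fit_result` carrying the chosen penalty and its cv error;
#'   attribute `"cv_path"` holds the per-lambda mean cv error.
#' @export
cv_lasso <- function(design, y, link = c("identity", "logit"),
                     nlambda = 50, lambda_min_ratio = 0.001, k = 5,
                     seed = NULL, foldid = NULL) {
  link <- match.arg(link)
  stopifnot(inherits(design, "collapsed_design"))
  if (k < 2) stop("k_folds must be at least 2")
  X <- design$X
  n <- nrow(X)
  penalized <- design$info$penalty_class != "unpenalized"
  st <- std_stats(X)
  Xs <- sweep(sweep(X, 2, st$mu), 2, st$s, "/")
  lmax <- lambda_max_for(Xs, y, link, penalized)
  grid <- make_lambda_grid(lmax, nlambda, lambda_min_ratio)
  foldid <- foldid %||% make_folds(n, k, seed)

  lam_list <- lapply(grid, function(l) ifelse(penalized, l, 0))
  err <- matrix(NA_real_, nlambda, k)
  for (fold in seq_len(k)) {
    tr <- foldid != fold
    path <- std_path(X[tr, , drop = FALSE], y[tr], link, lam_list)
    Xval <- X[!tr, , drop = FALSE]
    for (li in seq_along(grid)) {
      eta <- drop(Xval %*% path[[li]]$coefficients) + path[[li]]$intercept
      pred <- if (link == "logit") plogis(eta) else eta
      err[li, fold] <- cv_measure(y[!tr], pred, link)
    }
  }
  mean_err <- rowMeans(err)
  best <- which.min(mean_err)
  # warm-started path on the full data down to the chosen lambda
  full <- std_path(X, y, link, lam_list[seq_len(best)])
  fit <- full[[best]]
  names(fit$coefficients) <- colnames(X)
  eta <- drop(X %*% fit$coefficients) + fit$intercept
  fit$fitted <- if (link == "logit") plogis(eta) else eta
  fit$selected <- fit$coefficients != 0
  fit$link <- link
  res <- as_fit_result(fit, design, penalty_spec(lambda = grid[best]),
                       cv_error = mean_err[best])
  attr(res, "cv_path") <- data.frame(lambda = grid, cv_error = mean_err)
  res
}

#' Differential-penalty fit over a 2-D penalty grid
#'
#' For an annotation-split design, searches a grid of
#' (lambda_ns, lambda_s) pairs by k-fold cross-validation within the
#' replicate and refits at the error-minimizing pair. Common-variant
#' columns are penalized at `min(lambda_ns, lambda_s)` (configurable),
#' since the differential penalty indexes only the annotation classes.
#'
#' @inheritParams cv_lasso
#' @param grid_ns,grid_s explicit penalty grids; by default `nlambda`
#'   log-spaced values per class descending from the smallest penalty
#'   that zeroes every penalized coefficient.
#' @param nlambda per-class grid length when grids are not supplied.
#' @param common_penalty rule for common-variant columns: `"min"`,
#'   `"lambda_ns"` or `"lambda_s"`.
#' @return a `fit_result`; attribute `"cv_grid"` holds the full
#'   cross-validation error matrix (rows = grid_ns, cols = grid_s).
#' @export
fit_differential <- function(design, y, link = c("identity", "logit"),
                             grid_ns = NULL, grid_s = NULL, nlambda = 10,
                             lambda_min_ratio = 0.01, k = 5, seed = NULL,
                             foldid = NULL,
                             common_penalty = c("min", "lambda_ns",
                                                "lambda_s")) {
  link <- match.arg(link)
  common_penalty <- match.arg(common_penalty)
  stopifnot(inherits(design, "collapsed_design"))
  if (k < 2) stop("k_folds must be at least 2")
  cls <- design$info$penalty_class
  is_ns <- cls == "penalized_ns"
  is_s <- cls == "penalized_s"
  is_cm <- cls == "penalized"
  if (!any(is_ns) && !any(is_s))
    stop("fit_differential needs a design built with split_by_annotation")
  X <- design$X
  n <- nrow(X)
  penalized <- cls != "unpenalized"
  st <- std_stats(X)
  Xs <- sweep(sweep(X, 2, st$mu), 2, st$s, "/")
  if (is.null(grid_ns)) {
    lmax <- lambda_max_for(Xs, y, link, penalized)
    grid_ns <- make_lambda_grid(lmax, nlambda, lambda_min_ratio)
  }
  if (is.null(grid_s)) {
    lmax <- lambda_max_for(Xs, y, link, penalized)
    grid_s <- make_lambda_grid(lmax, nlambda, lambda_min_ratio)
  }
  if (!length(grid_ns) || !length(grid_s)) stop("empty penalty grid")
  foldid <- foldid %||% make_folds(n, k, seed)
  k_used <- length(unique(foldid))

  lam_for <- function(lns, ls) {
    lcm <- switch(common_penalty, min = min(lns, ls),
                  lambda_ns = lns, lambda_s = ls)
    lam <- numeric(length(cls))
    lam[is_ns] <- lns; lam[is_s] <- ls; lam[is_cm] <- lcm
    lam
  }

  cvm <- matrix(0, length(grid_ns), length(grid_s))
  p <- ncol(X)
  for (fold in sort(unique(foldid))) {
    tr <- foldid != fold
    sttr <- std_stats(X[tr, , drop = FALSE])
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, sttr$mu), 2, sttr$s, "/")
    ytr <- y[tr]
    Xval <- X[!tr, , drop = FALSE]
    yval <- y[!tr]
    b0_start <- if (link == "logit")
      qlogis(pmin(pmax(mean(ytr), 1e-3), 1 - 1e-3)) else mean(ytr)
    ctx <- if (link == "identity") gaussian_ctx(Xtr, ytr)
    col_init <- rep(list(list(beta = rep(0, p), b0 = b0_start)),
                    length(grid_s))  # warm starts down grid_ns
    for (ai in seq_along(grid_ns)) {
      for (si in seq_along(grid_s)) {
        res <- if (link == "identity")
          solve_gaussian(ctx, lam_for(grid_ns[ai], grid_s[si]),
                         col_init[[si]]$beta)
        else
          solve_penalized_std(Xtr, ytr, link,
                              lam_for(grid_ns[ai], grid_s[si]),
                              col_init[[si]]$beta,
                              col_init[[si]]$b0)
        col_init[[si]] <- list(beta = res$beta, b0 = res$b0)
        beta_orig <- res$beta / sttr$s
        b0_orig <- res$b0 - sum(res$beta * sttr$mu / sttr$s)
        eta <- drop(Xval %*% beta_orig) + b0_orig
        pred <- if (link == "logit") plogis(eta) else eta
        cvm[ai, si] <- cvm[ai, si] + cv_measure(yval, pred, link) / k_used
      }
    }
  }
  best <- arrayInd(which.min(cvm), dim(cvm))
  lns <- grid_ns[best[1]]; ls <- grid_s[best[2]]
  fit <- lasso_fit(X, y, link, lam_for(lns, ls))
  pen <- penalty_spec(lambda = switch(common_penalty, min = min(lns, ls),
                                      lambda_ns = lns, lambda_s = ls),
                      lambda_ns = lns, lambda_s = ls)
  res <- as_fit_result(fit, design, pen, cv_error = min(cvm))
  attr(res, "cv_grid") <- cvm
  res
}

#' Fit the model to every phenotype replicate
#'
#' Runs the collapsing + penalized-fit pipeline once per replicate.
#' DAS orientation and (for the disease trait) WS weights depend on the
#' phenotype, so those designs are rebuilt per replicate; PROP designs
#' are built once. The penalty is chosen within each replicate by
#' cross-validation — single-penalty ([cv_lasso()]) or differential
#' ([fit_differential()]).
#'
#' @param g a [genotype_set()].
#' @param reps a `replicate_set`.
#' @param trait trait name present in `reps$traits`.
#' @param config a [collapse_config()].
#' @param protocol `"cv"` (single penalty) or `"differential"`.
#' @param seed base seed; replicate r uses `seed + r` for its folds.
#' @param ... passed to [cv_lasso()] / [fit_differential()].
#' @return list of `fit_result`, one per replicate.
#' @export
fit_all_replicates <- function(g, reps, trait, config,
                               protocol = c("cv", "differential"),
                               seed = 1L, ...) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(reps, "replicate_set"))
  if (!trait %in% names(reps$traits))
    stop("trait ", trait, " not present in the replicate set")
  if (protocol == "differential" && !config$split_by_annotation)
    stop("differential protocol needs split_by_annotation = TRUE")
  link <- if (trait == "disease") "logit" else "identity"
  Y <- reps$traits[[trait]]
  R <- ncol(Y)
  design_fixed <- if (config$method == "PROP")
    build_design(g, reps$covariates, config, y = NULL, link = link)
  lapply(seq_len(R), function(r) {
    y <- Y[, r]
    tryCatch({
      design <- design_fixed %||%
        build_design(g, reps$covariates, config, y = y, link = link)
      fit <- if (protocol == "cv")
        cv_lasso(design, y, link, seed = seed + r, ...)
      else
        fit_differential(design, y, link, seed = seed + r, ...)
      fit$replicate <- r
      fit
    }, error = function(e) {
      stop("replicate ", r, " (", trait, ", ", config$method, "): ",
           conditionMessage(e), call. = FALSE)
    })
  })
}
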