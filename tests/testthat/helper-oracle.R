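# Independent brute-force oracles for the penalized solver. These never
# call the coordinate-descent code path.

# Global minimum of (1/(2n))||y - b0 - X beta||^2 + sum lam_j |beta_j|
# by enumeration of sign patterns over the penalized features: for each
# pattern the restricted problem is an unconstrained quadratic in the
# free coefficients solved in closed form; sign-consistent stationary
# points include the true minimizer, so the minimum objective over
# consistent patterns is the global optimum. Feasible for p <= ~6.
oracle_gaussian <- function(X, y, lam) {
  n <- nrow(X); p <- ncol(X)
  pen <- which(lam > 0)
  unpen <- setdiff(seq_len(p), pen)
  best <- Inf
  patterns <- expand.grid(rep(list(c(-1, 0, 1)), length(pen)))
  for (r in seq_len(nrow(patterns))) {
    s <- as.numeric(patterns[r, ])
    nz <- pen[s != 0]
    free <- c(unpen, nz)
    A <- cbind(1, X[, free, drop = FALSE])
    shift <- c(0, rep(0, length(unpen)), lam[nz] * s[s != 0])
    # stationarity: (1/n) A'(A theta - y) + shift = 0
    theta <- tryCatch(
      solve(crossprod(A) / n, crossprod(A, y) / n - shift),
      error = function(e) NULL)
    if (is.null(theta)) next
    beta <- numeric(p)
    if (length(free))
      beta[free] <- theta[-1]
    if (any(sign(beta[nz]) != s[s != 0])) next  # sign-inconsistent
    obj <- penalized_objective(X, y, "identity", lam, beta, theta[1])
    if (obj < best) best <- obj
  }
  best
}

# Global minimum for the logit link: the closed orthants of the
# penalized coordinates cover the whole space and |beta_j| is linear on
# each, so minimizing the smooth objective + linear penalty over every
# orthant (box-constrained BFGS) and taking the smallest value yields
# the global optimum. Feasible for p <= ~4 penalized features.
oracle_logit <- function(X, y, lam) {
  n <- nrow(X); p <- ncol(X)
  pen <- which(lam > 0)
  obj_fn <- function(theta, s) {
    b0 <- theta[1]; beta <- theta[-1]
    eta <- drop(X %*% beta) + b0
    sum(log1p(exp(eta)) - y * eta) / n + sum(lam[pen] * s * beta[pen])
  }
  grad_fn <- function(theta, s) {
    b0 <- theta[1]; beta <- theta[-1]
    eta <- drop(X %*% beta) + b0
    r <- plogis(eta) - y
    g <- c(sum(r), drop(crossprod(X, r))) / n
    g[1 + pen] <- g[1 + pen] + lam[pen] * s
    g
  }
  best <- Inf
  orthants <- expand.grid(rep(list(c(-1, 1)), length(pen)))
  for (r in seq_len(nrow(orthants))) {
    s <- as.numeric(orthants[r, ])
    lower <- rep(-Inf, p + 1); upper <- rep(Inf, p + 1)
    lower[1 + pen[s > 0]] <- 0
    upper[1 + pen[s < 0]] <- 0
    init <- rep(0, p + 1)
    opt <- stats::optim(init, obj_fn, grad_fn, s = s, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500, factr = 1e3))
    if (opt$value < best) best <- opt$value
  }
  best
}

random_instance <- function(seed, n = 50, p = 5, link = "identity") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- rnorm(p) * rbinom(p, 1, 0.6)
  eta <- drop(X %*% beta) * 0.8
  y <- if (link == "identity") eta + rnorm(n)
       else rbinom(n, 1, plogis(eta))
  # mixed per-feature penalties incl. at least one unpenalized column
  lam <- runif(p, 0.02, 0.4)
  lam[sample(p, 1)] <- 0
  list(X = X, y = y, lam = lam)
}
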