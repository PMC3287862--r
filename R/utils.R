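# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. A NULL seed leaves the RNG
# alone so callers can opt out of determinism.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted half. Used both for
#' predicted disease probabilities and for replicate selection counts.
#'
#' @param score numeric scores, higher = more positive.
#' @param label binary 0/1 truth labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, label) {
  stopifnot(length(score) == length(label), all(label %in% c(0, 1)))
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
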