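#' Replicate-by-feature selection matrix
#'
#' Binary matrix with one row per replicate and one column per feature
#' that received a nonzero coefficient in at least one replicate.
#' Covariates are excluded by default: they are unpenalized, so their
#' coefficients are nonzero in every replicate and carry no selection
#' information (they would contribute zero to the consistency score in
#' any case).
#'
#' @param fits list of `fit_result` objects sharing one feature space.
#' @param include_covariates keep covariate columns too.
#' @return binary matrix (R x |F|) with feature names as colnames.
#' @export
selection_matrix <- function(fits, include_covariates = FALSE) {
  stopifnot(length(fits) >= 1)
  info <- fits[[1]]$info
  keep <- if (include_covariates) rep(TRUE, nrow(info))
          else info$type != "covariate"
  s <- do.call(rbind, lapply(fits, function(f) {
    stopifnot(identical(names(f$selected), info$name))
    as.integer(f$selected[keep])
  }))
  colnames(s) <- info$name[keep]
  s[, colSums(s) > 0, drop = FALSE]
}

#' Cross-replicate selection consistency score
#'
#' Measures the instability of feature selection across replicates. With
#' `n_j` the number of replicates selecting feature `j`, the default
#' scorer is `C = sum_{j in F} n_j (R - n_j) / R`, summed over the set
#' `F` of features selected in at least one replicate. A feature
#' selected in every replicate (or none) contributes 0, so C = 0 means
#' perfectly reproducible selection and lower values mean more
#' consistent methods. `normalize = "per_feature"` divides by `|F|`.
#'
#' @param sel a binary selection matrix (rows = replicates), e.g. from
#'   [selection_matrix()].
#' @param normalize `"none"` (the default instability sum) or
#'   `"per_feature"`.
#' @return non-negative scalar.
#' @export
consistency_score <- function(sel, normalize = c("none", "per_feature")) {
  normalize <- match.arg(normalize)
  sel <- as.matrix(sel)
  if (!all(sel %in% c(0, 1))) stop("selection matrix must be binary")
  R <- nrow(sel)
  if (R < 2) stop("consistency needs at least 2 replicates")
  nj <- colSums(sel)
  nj <- nj[nj > 0]
  if (length(nj) == 0L) stop("empty feature set F: nothing was ever selected")
  C <- sum(nj * (R - nj) / R)
  if (normalize == "per_feature") C <- C / length(nj)
  C
}

#' Cross-replicate prediction improvement from genetic features
#'
#' Each replicate's fitted model predicts the trait in every other
#' replicate (genotypes and covariates are fixed, so a model's
#' predictions are a single per-individual vector). For quantitative
#' traits the improvement is mean baseline MSE minus mean full-model
#' MSE; for disease it is mean full-model AUC minus mean baseline AUC.
#' Positive values mean the genetic features helped. The baseline is a
#' covariates-only GLM refit per replicate.
#'
#' @param fits list of `fit_result` (one per replicate, in order).
#' @param reps the `replicate_set` the fits came from.
#' @param trait trait name.
#' @return scalar improvement; attribute `"detail"` carries the mean
#'   full and baseline error/AUC.
#' @export
cross_replicate_prediction <- function(fits, reps, trait) {
  stopifnot(inherits(reps, "replicate_set"),
            trait %in% names(reps$traits))
  Y <- reps$traits[[trait]]
  R <- ncol(Y)
  if (length(fits) != R) stop("need one fit per replicate")
  link <- fits[[1]]$link
  if ((trait == "disease") != (link == "logit"))
    stop("trait/link mismatch between fits and trait")

  # baseline design: covariates only (incl. population dummies), refit
  # per replicate
  cv <- reps$covariates
  pop <- factor(cv$population)
  Xcov <- cbind(Age = cv$Age, Sex = cv$Sex, Smoke = cv$Smoke,
                if (nlevels(pop) > 1)
                  sapply(levels(pop)[-1],
                         function(l) as.numeric(pop == l)))
  full_pred <- vapply(fits, function(f) f$fitted, numeric(nrow(Y)))

  # the baseline uses the same solver, tolerance and cold start as the
  # full fits, so a full fit that never activates a genetic column gives
  # bit-identical predictions and an improvement of exactly zero
  base_pred <- vapply(seq_len(R), function(r) {
    suppressWarnings(
      lasso_fit(Xcov, Y[, r], link, lambda = 0)$fitted)
  }, numeric(nrow(Y)))

  score_one <- function(pred_r, r) {
    others <- setdiff(seq_len(R), r)
    vals <- vapply(others, function(k) {
      if (link == "identity") mean((Y[, k] - pred_r)^2)
      else auc_rank(pred_r, Y[, k])
    }, numeric(1))
    mean(vals)
  }
  full <- vapply(seq_len(R), function(r) score_one(full_pred[, r], r),
                 numeric(1))
  base <- vapply(seq_len(R), function(r) score_one(base_pred[, r], r),
                 numeric(1))
  improvement <- if (link == "identity") mean(base) - mean(full)
                 else mean(full) - mean(base)
  attr(improvement, "detail") <- c(full = mean(full), baseline = mean(base))
  improvement
}

# truth labels for the genetic feature universe of a fit list: a column
# is positive iff its underlying variant set contains a causal variant
# (for split designs only the stratum holding the causal variants is
# positive; since causal variants are nonsynonymous, synonymous columns
# of causal genes count negative).
feature_truth_labels <- function(info, truth_trait) {
  genetic <- info$type != "covariate"
  vapply(which(genetic), function(j) {
    as.integer(length(intersect(info$variants[[j]],
                                truth_trait$variants)) > 0)
  }, integer(1))
}

#' Rank features by replicate selection counts and trace a truth-set ROC
#'
#' Features (collapsed gene scores and individual common variants) are
#' ranked by the number of replicates in which they received a nonzero
#' coefficient. For each count threshold `t` in `0..R+1`, features with
#' count >= t are declared positive and compared with the causal truth
#' set; sensitivity and specificity over the full genetic feature
#' universe trace the ROC, and the AUC is the area under it (trapezoid
#' rule, equal to rank concordance with ties at half).
#'
#' @param fits list of `fit_result` sharing one feature space.
#' @param truth_trait one trait's entry of a `truth_set` (with
#'   `variants`).
#' @param n_top how many top features to report.
#' @return list with `counts` (named replicate counts over all genetic
#'   features), `labels`, `roc` (data.frame threshold/sensitivity/
#'   specificity), `auc`, and `top_features` (feature, count, ties
#'   broken lexicographically).
#' @export
rank_and_roc <- function(fits, truth_trait, n_top = 10) {
  stopifnot(length(fits) >= 1)
  info <- fits[[1]]$info
  genetic <- info$type != "covariate"
  R <- length(fits)
  counts <- rowSums(vapply(fits, function(f) {
    stopifnot(identical(names(f$selected), info$name))
    as.numeric(f$selected[genetic])
  }, numeric(sum(genetic))))
  names(counts) <- info$name[genetic]
  labels <- feature_truth_labels(info, truth_trait)
  if (sum(labels) == 0L)
    stop("truth set contains no causal feature in this design")
  if (sum(labels == 0L) == 0L)
    stop("every feature is causal; specificity undefined")

  roc <- do.call(rbind, lapply(0:(R + 1), function(t) {
    pos <- counts >= t
    data.frame(threshold = t,
               sensitivity = sum(pos & labels == 1) / sum(labels == 1),
               specificity = sum(!pos & labels == 0) / sum(labels == 0))
  }))
  ord <- order(1 - roc$specificity, roc$sensitivity)
  fpr <- (1 - roc$specificity)[ord]
  tpr <- roc$sensitivity[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  top <- data.frame(feature = names(counts), count = counts,
                    row.names = NULL, stringsAsFactors = FALSE)
  top <- top[order(-top$count, top$feature), , drop = FALSE]
  list(counts = counts, labels = labels, roc = roc, auc = auc,
       top_features = utils::head(top, n_top))
}

#' Run the full pipeline for several collapsing methods and traits
#'
#' For each method x trait combination: build the collapsed design, fit
#' the penalized model to every replicate with the penalty chosen by
#' within-replicate cross-validation, then score selection consistency,
#' cross-replicate prediction improvement over a covariates-only
#' baseline, and the truth-set ROC/AUC from replicate selection counts.
#'
#' @param g a [genotype_set()].
#' @param reps a `replicate_set`.
#' @param truth a `truth_set`.
#' @param methods subset of `c("PROP", "DAS", "WS")`.
#' @param traits subset of the traits in `reps`.
#' @param rare_maf_threshold rare/common MAF boundary.
#' @param split_by_annotation collapse ns/s separately and use the
#'   differential-penalty protocol.
#' @param seed base seed for all cross-validation folds.
#' @param n_top top features to report per method x trait.
#' @param ... passed to [fit_all_replicates()] (e.g. `nlambda`, `k`).
#' @return object of class `evaluation_report`: list with data.frame
#'   `summary` (method, trait, consistency, improvement, auc) and nested
#'   `detail[[method]][[trait]]` holding the roc table, top features and
#'   fits' selection counts.
#' @export
compare_methods <- function(g, reps, truth,
                            methods = c("PROP", "DAS", "WS"),
                            traits = names(reps$traits),
                            rare_maf_threshold = 0.05,
                            split_by_annotation = FALSE,
                            seed = 1L, n_top = 10, ...) {
  methods <- match.arg(methods, c("PROP", "DAS", "WS"), several.ok = TRUE)
  stopifnot(all(traits %in% names(reps$traits)))
  rows <- list(); detail <- list()
  for (m in methods) {
    detail[[m]] <- list()
    for (tr in traits) {
      cfg <- collapse_config(method = m,
                             rare_maf_threshold = rare_maf_threshold,
                             split_by_annotation = split_by_annotation)
      fits <- fit_all_replicates(
        g, reps, tr, cfg,
        protocol = if (split_by_annotation) "differential" else "cv",
        seed = seed, ...)
      sel <- selection_matrix(fits)
      cons <- consistency_score(sel)
      impr <- cross_replicate_prediction(fits, reps, tr)
      # traits without causal variants (Q4-style) have no ROC to draw
      has_truth <- !is.null(truth[[tr]]) && length(truth[[tr]]$variants) > 0
      rr <- if (has_truth) rank_and_roc(fits, truth[[tr]], n_top = n_top)
            else list(roc = NULL, auc = NA_real_, counts = NULL,
                      top_features = NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, trait = tr, consistency = cons,
        improvement = as.numeric(impr), auc = rr$auc,
        stringsAsFactors = FALSE)
      detail[[m]][[tr]] <- list(roc = rr$roc, auc = rr$auc,
                                top_features = rr$top_features,
                                counts = rr$counts,
                                improvement_detail = attr(impr, "detail"),
                                consistency = cons)
    }
  }
  structure(list(summary = do.call(rbind, rows), detail = detail,
                 R = reps$R, methods = methods, traits = traits),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report over R = %d replicates\n", x$R))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
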