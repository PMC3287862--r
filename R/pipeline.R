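#' Pipeline run configuration
#'
#' Either `data_dir` points at a dataset directory written by
#' [write_dataset()], or `simulate` holds arguments for an in-memory
#' simulation (`n_individuals`, `n_genes`, `R`, ...). All randomness in
#' a run flows from the single `seed`.
#'
#' @param data_dir dataset directory, or `NULL` to simulate.
#' @param simulate named list of simulation settings used when
#'   `data_dir` is `NULL`: `n_individuals`, `n_genes`,
#'   `variants_per_gene`, `R`, `h2`, `n_causal_genes`, `prevalence`.
#' @param methods collapsing methods to run.
#' @param traits traits to analyse.
#' @param rare_maf_threshold rare/common MAF boundary.
#' @param split_by_annotation use the annotation split and differential
#'   penalties.
#' @param nlambda,k cross-validation settings.
#' @param seed master seed.
#' @param out_dir directory for report files.
#' @return a `run_config` object.
#' @export
run_config <- function(data_dir = NULL, simulate = list(),
                       methods = c("PROP", "DAS", "WS"),
                       traits = c("Q1", "Q2", "Q4", "disease"),
                       rare_maf_threshold = 0.05,
                       split_by_annotation = FALSE,
                       nlambda = 50, k = 5, seed = 1L,
                       out_dir = NULL) {
  methods <- match.arg(methods, c("PROP", "DAS", "WS"), several.ok = TRUE)
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stop("data_dir does not exist: ", data_dir)
  structure(list(data_dir = data_dir, simulate = simulate,
                 methods = methods, traits = traits,
                 rare_maf_threshold = rare_maf_threshold,
                 split_by_annotation = split_by_annotation,
                 nlambda = nlambda, k = k, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Run the whole analysis pipeline from a configuration
#'
#' Loads (or simulates) the dataset, runs
#' classify / collapse / fit-per-replicate / evaluate for every
#' configured method and trait, and, when `out_dir` is set, writes the
#' summary and per-method ROC and top-feature tables plus a JSON run
#' manifest carrying the seed and a hash of the configuration.
#'
#' @param config a [run_config()], or the path of a yaml file holding
#'   its fields.
#' @return the [compare_methods()] `evaluation_report` (invisibly when
#'   files are written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$data_dir)) {
    ds <- read_dataset(config$data_dir)
    g <- ds$g; reps <- ds$reps; truth <- ds$truth
  } else {
    sim <- config$simulate
    g <- simulate_genotypes(sim$n_individuals %||% 500,
                            sim$n_genes %||% 50,
                            sim$variants_per_gene %||% list(mean = 8),
                            seed = config$seed)
    truth <- simulate_truth(g, h2 = sim$h2 %||%
                              list(Q1 = 0.3, Q2 = 0.3, disease = 0.15),
                            n_causal_genes = sim$n_causal_genes %||%
                              list(Q1 = 5, Q2 = 5, disease = 5),
                            seed = config$seed + 1L)
    reps <- simulate_phenotypes(g, truth, traits = config$traits,
                                R = sim$R %||% 50,
                                prevalence = sim$prevalence %||% 0.3,
                                seed = config$seed + 2L)
  }
  missing_tr <- setdiff(config$traits, names(reps$traits))
  if (length(missing_tr))
    stop("configured trait(s) absent from the data: ",
         paste(missing_tr, collapse = ", "))
  report <- compare_methods(
    g, reps, truth, methods = config$methods, traits = config$traits,
    rare_maf_threshold = config$rare_maf_threshold,
    split_by_annotation = config$split_by_annotation,
    seed = config$seed, nlambda = config$nlambda, k = config$k)
  if (is.null(config$out_dir)) return(report)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  wt <- function(x, name) {
    write.table(x, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(report$summary, "summary.tsv")
  tops <- list()
  for (m in names(report$detail)) {
    for (tr in names(report$detail[[m]])) {
      d <- report$detail[[m]][[tr]]
      if (is.null(d$roc)) next  # trait without a causal truth set
      wt(d$roc, sprintf("roc_%s_%s.tsv", m, tr))
      tf <- d$top_features
      tf$method <- m; tf$trait <- tr
      tops[[length(tops) + 1L]] <- tf
    }
  }
  wt(do.call(rbind, tops), "top_features.tsv")
  jsonlite::write_json(
    list(package = "rarelasso",
         version = as.character(packageVersion("rarelasso")),
         seed = config$seed, config_hash = hash,
         config = unclass(config)),
    file.path(config$out_dir, "run_manifest.json"),
    auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(report)
}
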