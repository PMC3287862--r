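# Readers and writers for the external formats: VCF genotypes with
# GENE/ANNO INFO tags, delimited covariate / phenotype / truth tables,
# and a yaml manifest tying a dataset directory together.

#' Write a genotype set as VCF
#'
#' Minimal VCF 4.2 with one biallelic record per variant, the minor
#' allele as ALT (so a round trip reproduces the dosages exactly unless
#' MAF is exactly 0.5), and INFO tags `GENE=<symbol>;ANNO=<ns|s>`.
#'
#' @param g a [genotype_set()].
#' @param path output file path.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_set"))
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  gt <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rarelasso",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=ANNO,Number=1,Type=String,Description=\"ns|s annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(g$dosages)), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", j, g$variants$variant_id[j], "A", "T", ".", "PASS",
            sprintf("GENE=%s;ANNO=%s", g$variants$gene[j],
                    g$variants$annotation[j]),
            "GT", gt[g$dosages[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# allele-count dosage from GT strings for one ALT allele code;
# returns NA for missing. Accepts phased and unphased separators.
gt_to_count <- function(gt, allele_code) {
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(al) {
    if (length(al) == 0L || anyNA(al) || any(al == "."))
      return(NA_integer_)
    if (!all(grepl("^[0-9]+$", al))) stop("malformed GT field")
    sum(al == as.character(allele_code))
  }, integer(1))
}

#' Read genotypes from VCF or a delimited matrix
#'
#' VCF records are read with the `vcfR` package; multi-allelic sites are
#' split into one biallelic record per ALT allele. Dosages are
#' re-oriented so they count the minor allele as determined from the
#' sample itself (a site whose ALT is the major allele has its counts
#' flipped). Missing genotypes are imputed to the per-variant mean
#' dosage rounded to the nearest integer, with a message reporting the
#' count; a variant with more than 10% missingness triggers a warning.
#' Gene and annotation come from the `GENE`/`ANNO` INFO tags (VCF) or
#' from a sidecar metadata table (matrix format: columns `variant_id`,
#' `gene`, `annotation`).
#'
#' @param path genotype file (VCF or a tab-delimited individuals x
#'   variants matrix with a header of variant ids and individual ids in
#'   the first column).
#' @param format `"vcf"` or `"matrix"`.
#' @param metadata path to the variant metadata table (required for
#'   `"matrix"`).
#' @return a [genotype_set()].
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (format == "matrix") {
    if (is.null(metadata)) stop("matrix format needs a metadata table")
    mat <- read.delim(path, row.names = 1, check.names = FALSE)
    meta <- read.delim(metadata, stringsAsFactors = FALSE)
    need <- c("variant_id", "gene", "annotation")
    if (!all(need %in% names(meta)))
      stop("metadata must have columns variant_id, gene, annotation")
    idx <- match(colnames(mat), meta$variant_id)
    if (anyNA(idx)) stop("metadata missing for some variants")
    dos <- as.matrix(mat)
    flip <- colMeans(dos) / 2 > 0.5
    dos[, flip] <- 2L - dos[, flip]
    return(genotype_set(dos, meta$gene[idx], meta$annotation[idx]))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gtmat <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gtmat)
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^.*?", key, "="), "", m)
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gene <- info_field(fix[i, "INFO"], "GENE")
    anno <- info_field(fix[i, "INFO"], "ANNO")
    if (is.na(gene) || is.na(anno))
      stop("VCF record ", i, " lacks GENE/ANNO INFO tags")
    for (a in seq_along(alts)) {
      cnt <- tryCatch(gt_to_count(gtmat[i, ], a),
                      error = function(e)
                        stop("malformed GT at record ", i))
      id <- fix[i, "ID"]
      if (length(alts) > 1) id <- paste0(id, "_alt", a)
      rows[[length(rows) + 1L]] <- list(id = id, gene = gene, anno = anno,
                                        dos = cnt)
    }
  }
  dos <- vapply(rows, `[[`, integer(length(samples)), "dos")
  rownames(dos) <- samples
  colnames(dos) <- vapply(rows, `[[`, "", "id")
  miss <- colSums(is.na(dos))
  if (any(miss > 0)) {
    frac <- miss / nrow(dos)
    if (any(frac > 0.1))
      warning(sum(frac > 0.1), " variant(s) exceed 10% missing genotypes")
    for (j in which(miss > 0)) {
      dos[is.na(dos[, j]), j] <- as.integer(round(mean(dos[, j],
                                                       na.rm = TRUE)))
    }
    message("imputed ", sum(miss), " missing genotype(s) to the ",
            "rounded per-variant mean dosage")
  }
  flip <- colMeans(dos) / 2 > 0.5
  if (any(flip)) dos[, flip] <- 2L - dos[, flip]
  genotype_set(dos, vapply(rows, `[[`, "", "gene"),
               vapply(rows, `[[`, "", "anno"))
}

#' Write a complete simulated dataset to a directory
#'
#' Emits `genotypes.vcf`, `covariates.tsv`, `phenotypes.tsv` (one column
#' per trait.replicate), `truth.tsv` and a `manifest.yaml` listing the
#' files and dimensions. The dataset round-trips losslessly through
#' [read_dataset()].
#'
#' @param g a [genotype_set()]; must contain at least one gene.
#' @param reps a `replicate_set`.
#' @param truth a `truth_set`.
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest for provenance.
#' @return invisible named vector of file paths (the manifest).
#' @export
write_dataset <- function(g, reps, truth, out_dir, seed = NA) {
  stopifnot(inherits(g, "genotype_set"), inherits(reps, "replicate_set"))
  if (length(unique(g$variants$gene)) == 0L || ncol(g$dosages) == 0L)
    stop("genotype set has no variants/genes to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(out_dir, "genotypes.vcf"),
             covariates = file.path(out_dir, "covariates.tsv"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             manifest = file.path(out_dir, "manifest.yaml"))
  write_vcf(g, paths[["genotypes"]])
  write.table(reps$covariates, paths[["covariates"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  ph <- do.call(cbind, lapply(names(reps$traits), function(tr) {
    m <- reps$traits[[tr]]
    colnames(m) <- paste0(tr, ".", seq_len(ncol(m)))
    m
  }))
  ph <- data.frame(individual_id = reps$covariates$individual_id, ph,
                   check.names = FALSE)
  write.table(ph, paths[["phenotypes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tt <- do.call(rbind, lapply(names(truth), function(tr) {
    t1 <- truth[[tr]]
    if (length(t1$variants) == 0L) return(NULL)
    data.frame(trait = tr, variant_id = t1$variants,
               gene = g$variants$gene[match(t1$variants,
                                            g$variants$variant_id)],
               effect = as.numeric(t1$effects[t1$variants]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tt))
    tt <- data.frame(trait = character(0), variant_id = character(0),
                     gene = character(0), effect = numeric(0))
  write.table(tt, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(
    package = "rarelasso",
    version = as.character(packageVersion("rarelasso")),
    seed = seed,
    n_individuals = nrow(g$dosages),
    n_variants = ncol(g$dosages),
    n_genes = length(unique(g$variants$gene)),
    R = reps$R,
    traits = names(reps$traits),
    files = as.list(setNames(basename(paths), names(paths)))[
      names(paths) != "manifest"]
  )
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing a `manifest.yaml`.
#' @return list with elements `g` ([genotype_set()]), `reps`
#'   (`replicate_set`), `truth` (`truth_set`) and `manifest`.
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  g <- read_genotypes(file.path(dir, manifest$files$genotypes),
                      format = "vcf")
  cov <- read.delim(file.path(dir, manifest$files$covariates),
                    stringsAsFactors = FALSE)
  if (anyNA(cov)) stop("missing covariate values are not allowed")
  ph <- read.delim(file.path(dir, manifest$files$phenotypes),
                   check.names = FALSE)
  traits <- list()
  for (tr in manifest$traits) {
    cols <- grep(paste0("^", tr, "\\."), names(ph), value = TRUE)
    m <- as.matrix(ph[, cols, drop = FALSE])
    dimnames(m) <- list(ph$individual_id,
                        paste0("rep", seq_along(cols)))
    traits[[tr]] <- m
  }
  reps <- structure(list(covariates = cov, traits = traits,
                         R = manifest$R),
                    class = "replicate_set")
  tt <- read.delim(file.path(dir, manifest$files$truth),
                   stringsAsFactors = FALSE)
  truth <- lapply(split(tt, factor(tt$trait, levels = manifest$traits)),
                  function(d) {
    list(variants = d$variant_id, genes = sort(unique(d$gene)),
         effects = setNames(d$effect, d$variant_id))
  })
  truth <- structure(truth, class = "truth_set")
  list(g = g, reps = reps, truth = truth, manifest = manifest)
}
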