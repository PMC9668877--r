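#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of gene vectors, with a `description`
#'   attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    structure(f[-(1:2)], description = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

write_matrix_tsv <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write a simulated study bundle to disk
#'
#' Writes the beta matrix (TSV), phenotype table (CSV), probe annotation
#' (TSV), gene sets (GMT), cell-type reference (TSV), smoking effect table
#' (TSV) and ground truth (JSON) under `outdir`. Numeric matrices
#' round-trip exactly through the 17-significant-digit text encoding.
#'
#' @param sim result of [simulate_cohort()] or [simulate_methylome()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a named vector of file paths.
#' @export
write_fixture_bundle <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 17, scipen = 10)
  on.exit(options(old))
  paths <- c(
    beta = file.path(outdir, "beta.tsv"),
    phenotypes = file.path(outdir, "phenotypes.csv"),
    annotation = file.path(outdir, "annotation.tsv"),
    gene_sets = file.path(outdir, "gene_sets.gmt"),
    cell_reference = file.path(outdir, "cell_reference.tsv"),
    smoking_effects = file.path(outdir, "smoking_effects.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_matrix_tsv(sim$beta, paths[["beta"]])
  utils::write.csv(sim$phenotypes, paths[["phenotypes"]], row.names = FALSE)
  utils::write.table(sim$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$gene_sets)) {
    write_gmt(sim$gene_sets, paths[["gene_sets"]])
  }
  write_matrix_tsv(sim$cell_reference, paths[["cell_reference"]],
                   id_col = "cell_type")
  utils::write.table(sim$smoking_effects, paths[["smoking_effects"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth_json <- list(
    labels = as.list(truth$labels),
    planted_mediation = truth$planted_mediation,
    covariate_effect_sds = lapply(truth$covariate_effects, stats::sd)
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a study bundle written by [write_fixture_bundle()]
#'
#' @param dir bundle directory.
#' @return list with `beta`, `phenotypes`, `annotation`, `gene_sets`,
#'   `cell_reference`, `smoking_effects`, `truth`.
#' @export
read_fixture_bundle <- function(dir) {
  pheno <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                           stringsAsFactors = FALSE)
  for (cv in c("income", "education", "employment")) {
    lv <- switch(cv, income = income_levels, education = education_levels,
                 employment = employment_levels)
    if (cv %in% names(pheno)) pheno[[cv]] <- factor(pheno[[cv]], levels = lv)
  }
  gmt <- file.path(dir, "gene_sets.gmt")
  list(
    beta = read_matrix_tsv(file.path(dir, "beta.tsv")),
    phenotypes = pheno,
    annotation = utils::read.delim(file.path(dir, "annotation.tsv"),
                                   stringsAsFactors = FALSE),
    gene_sets = if (file.exists(gmt)) read_gmt(gmt),
    cell_reference = read_matrix_tsv(file.path(dir, "cell_reference.tsv")),
    smoking_effects = utils::read.delim(file.path(dir, "smoking_effects.tsv"),
                                        stringsAsFactors = FALSE),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
}
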