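#' Probe-wise exposure association scan
#'
#' For every probe, fits `residual M ~ CTQ + income + education + TEI +
#' employment` and returns the p-value of the exposure-of-interest term.
#' All four exposures sit in the model; the one of interest is tested, the
#' others act as covariates. Probes with nominal `p < alpha` are flagged as
#' the enrichment input set. The identical design across probes allows a
#' single QR decomposition, so the scan is vectorized over probes.
#'
#' @param resid probes x samples residualized M-value matrix.
#' @param pheno aligned phenotype table.
#' @param exposure one of `"ctq"`, `"tei"`, `"income_low"`,
#'   `"education_low"`.
#' @param alpha nominal flagging threshold.
#' @return data.frame with columns `probe_id`, `beta`, `t`, `p`, `flagged`.
#' @export
probewise_ewas <- function(resid, pheno, exposure = "ctq", alpha = 0.05) {
  stopifnot(ncol(resid) == nrow(pheno))
  exposure <- match.arg(exposure, names(exposure_terms))
  pheno <- standardize_continuous(relevel_exposures(pheno))
  x <- stats::model.matrix(~ income + education + ctq_z + tei_z + employment,
                           data = pheno)
  term <- exposure_terms[[exposure]]
  if (!term %in% colnames(x)) stop("term not in design: ", term, call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  qx <- qr(x)
  if (qx$rank < k) stop("rank-deficient exposure design", call. = FALSE)
  y <- t(resid)                          # samples x probes
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  sigma2 <- colSums(res^2) / (n - k)
  xtx_inv_jj <- solve(crossprod(x))[term, term]
  beta <- coef[term, ]
  se <- sqrt(sigma2 * xtx_inv_jj)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  data.frame(probe_id = rownames(resid), beta = unname(beta), t = unname(tval),
             p = unname(p), flagged = unname(p < alpha),
             stringsAsFactors = FALSE)
}

#' Aggregate probe p-values to gene p-values
#'
#' Sidak-corrected minimum probe p-value:
#' `p_gene = 1 - (1 - min_i p_i)^k` for the `k` probes annotated to the
#' gene. The correction counteracts the advantage genes with many probes
#' would otherwise enjoy. Aggregation is monotone: lowering any probe p
#' never raises its gene's p.
#'
#' @param probe_ps named numeric vector of probe p-values.
#' @param annotation data.frame with `probe_id` and `gene` columns; probes
#'   with an empty gene are dropped.
#' @return named numeric vector of gene p-values.
#' @export
probes_to_gene_p <- function(probe_ps, annotation) {
  ann <- annotation[match(names(probe_ps), annotation$probe_id), ]
  keep <- !is.na(ann$gene) & ann$gene != ""
  if (!any(keep)) stop("no probe maps to a gene", call. = FALSE)
  gene <- ann$gene[keep]
  p <- probe_ps[keep]
  minp <- tapply(p, gene, min)
  k <- tapply(p, gene, length)
  out <- 1 - (1 - minp)^k
  stats::setNames(as.numeric(out), names(minp))
}

#' Gene-set over-representation test
#'
#' Hypergeometric tail test of the overlap between the significant genes
#' (`gene p < alpha`) and each set, with the measured-gene universe as
#' background. Sets are filtered to `[min_size, max_size]` genes *after*
#' intersection with the universe, dropping both under-powered and
#' uninformative high-level sets. P-values are Benjamini-Hochberg adjusted
#' over the tested sets.
#'
#' @param gene_ps named numeric vector of gene p-values (the universe).
#' @param sets named list of gene-identifier vectors (e.g. [read_gmt()]).
#' @param min_size,max_size post-intersection set-size bounds.
#' @param alpha gene-level significance threshold.
#' @return data.frame sorted by p: `set`, `size`, `overlap`, `p`, `q`,
#'   `driver_genes` (comma-separated significant members).
#' @export
gene_set_test <- function(gene_ps, sets, min_size = 25, max_size = 1000,
                          alpha = 0.05) {
  universe <- names(gene_ps)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  sig <- universe[gene_ps < alpha]
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    sz <- length(members)
    if (sz < min_size || sz > max_size) return(NULL)
    hit <- intersect(members, sig)
    p <- stats::phyper(length(hit) - 1, length(sig),
                       length(universe) - length(sig), sz,
                       lower.tail = FALSE)
    data.frame(set = nm, size = sz, overlap = length(hit), p = p,
               driver_genes = paste(hit, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    stop("no gene set within the size bounds after intersection", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), c("set", "size", "overlap", "p", "q", "driver_genes")]
  rownames(out) <- NULL
  out
}
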