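#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))` after clipping beta into
#' `[epsilon, 1 - epsilon]`. The base-2 logit variance-stabilizes
#' methylation fractions for linear modelling.
#'
#' @param beta numeric matrix (probes x samples) of values in `[0, 1]`.
#' @param epsilon clipping bound in `(0, 0.5)`; keeps M finite at the
#'   boundaries without distorting interior values.
#' @return M-value matrix with the same dimnames.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(is.numeric(beta), epsilon > 0, epsilon < 0.5)
  if (anyNA(beta)) stop("beta matrix contains missing values", call. = FALSE)
  if (any(beta < 0 | beta > 1)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Probe filtering cascade
#'
#' Removes sex-chromosome probes, `rs`-prefixed SNP probes and probes
#' flagged cross-reactive, then keeps only probes whose blood-brain
#' correlation p-value is below `bloodbrain_alpha` (restricting analysis to
#' loci with surrogate potential for CNS tissue). Input probe order is
#' preserved; the cascade is idempotent.
#'
#' @param matrix probes x samples matrix with probe ids as rownames.
#' @param annotation data.frame with columns `probe_id`, `chrom`,
#'   `cross_reactive`, `bloodbrain_p`.
#' @param bloodbrain_alpha blood-brain correlation significance cutoff.
#' @return filtered matrix (possibly zero rows, with a warning).
#' @export
filter_probes <- function(matrix, annotation, bloodbrain_alpha = 0.05) {
  ids <- rownames(matrix)
  if (is.null(ids)) stop("matrix must carry probe ids as rownames", call. = FALSE)
  miss <- setdiff(ids, annotation$probe_id)
  if (length(miss)) {
    stop("probes missing from annotation: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5),
         call. = FALSE)
  }
  ann <- annotation[match(ids, annotation$probe_id), ]
  keep <- !(ann$chrom %in% c("chrX", "chrY", "X", "Y")) &
    !startsWith(ids, "rs") &
    ann$cross_reactive == 0 &
    ann$bloodbrain_p < bloodbrain_alpha
  if (!any(keep)) warning("no probes survive filtering")
  matrix[keep, , drop = FALSE]
}

#' Reference-based leukocyte deconvolution
#'
#' Estimates the leukocyte composition of each sample by projecting its
#' beta profile onto reference cell-type methylation profiles under
#' nonnegativity and sum-to-at-most-one constraints (constrained
#' least-squares projection in the style of reference-based blood
#' deconvolution).
#'
#' @param beta probes x samples beta matrix.
#' @param reference cell-types x probes matrix of mean reference betas.
#' @param min_shared minimum number of shared probes required.
#' @return samples x cell-types matrix of estimated fractions.
#' @export
estimate_cell_proportions <- function(beta, reference, min_shared = 50) {
  shared <- intersect(rownames(beta), colnames(reference))
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " probes shared with reference (need >= ",
         min_shared, ")", call. = FALSE)
  }
  a <- t(reference[, shared, drop = FALSE])      # probes x cells
  if (qr(a)$rank < ncol(a)) {
    stop("reference profiles are rank deficient", call. = FALSE)
  }
  b <- beta[shared, , drop = FALSE]
  est <- vapply(seq_len(ncol(b)), function(j) {
    w <- pracma::lsqnonneg(a, b[, j])$x
    if (sum(w) > 1 + 1e-9) {
      # re-solve with a heavy penalty row pulling the sum onto the simplex
      lam <- 1e4 * sqrt(nrow(a))
      w <- pracma::lsqnonneg(rbind(a, lam), c(b[, j], lam))$x
    }
    w
  }, numeric(ncol(a)))
  out <- t(est)
  dimnames(out) <- list(colnames(b), colnames(a))
  out
}

#' Polyepigenetic smoking score
#'
#' Linear score `sum_i effect_i * beta_i` over the supplied signature
#' probes (typically the top hits of a smoking epigenome-wide association
#' study), computed on the beta scale. Signature probes absent from the
#' matrix are dropped with a message.
#'
#' @param beta probes x samples beta matrix.
#' @param effect_table data.frame with columns `probe_id`, `effect`.
#' @return named numeric vector, one score per sample.
#' @export
smoking_score <- function(beta, effect_table) {
  stopifnot(all(c("probe_id", "effect") %in% names(effect_table)))
  present <- effect_table$probe_id %in% rownames(beta)
  if (!any(present)) {
    stop("no signature probes present in the beta matrix", call. = FALSE)
  }
  if (any(!present)) {
    message(sum(!present), " signature probe(s) missing; using ",
            sum(present), " of ", length(present))
  }
  tab <- effect_table[present, ]
  drop(crossprod(beta[tab$probe_id, , drop = FALSE], tab$effect))
}

#' Residualize M-values against covariates
#'
#' Per probe, ordinary least squares of the M-value on the covariate design
#' (with intercept); the returned matrix holds residuals, which are
#' mean-zero and orthogonal to every design column. These residualized
#' M-values are the input to network construction.
#'
#' @param m probes x samples M-value matrix.
#' @param design samples x covariates numeric matrix or data.frame
#'   (intercept added automatically).
#' @return probes x samples residual matrix.
#' @export
residualize <- function(m, design) {
  design <- as.matrix(design)
  stopifnot(ncol(m) == nrow(design))
  x <- cbind(`(Intercept)` = 1, design)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("collinear design columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(design) <= ncol(x) + 2) {
    stop("too few samples for the covariate design", call. = FALSE)
  }
  res <- t(qr.resid(qx, t(m)))
  dimnames(res) <- dimnames(m)
  res
}

#' Quantile normalization across samples
#'
#' Maps each sample's empirical distribution onto the across-sample mean
#' order statistics so that all column distributions coincide. Delegates to
#' the standard limma implementation.
#'
#' @param beta probes x samples matrix.
#' @return normalized matrix; a single-sample input is returned unchanged
#'   with a warning.
#' @export
quantile_normalize <- function(beta) {
  if (ncol(beta) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(beta)
  }
  out <- limma::normalizeQuantiles(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' Assemble the probe-residualization covariate design
#'
#' Standard design for removing non-exposure effects from M-values: age,
#' five leukocyte fractions (granulocytes excluded as the complement),
#' genomic-ancestry dimensions, and the smoking score.
#'
#' @param pheno phenotype data.frame (needs `age` and `ancestry_*` columns).
#' @param cells samples x cell-types fraction matrix.
#' @param smoking per-sample smoking score.
#' @return samples x covariates numeric matrix.
#' @export
covariate_design <- function(pheno, cells, smoking) {
  keep <- setdiff(colnames(cells), "granulocytes")
  anc <- as.matrix(pheno[, grep("^ancestry_", names(pheno)), drop = FALSE])
  cbind(age = pheno$age, cells[, keep, drop = FALSE], anc, smoking = smoking)
}
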