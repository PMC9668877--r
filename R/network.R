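#' Weighted co-methylation adjacency
#'
#' Unsigned adjacency `a_ij = |cor(probe_i, probe_j)|^power` (or signed,
#' `((1 + r)/2)^power`) across samples. The diagonal is set to 0 so that
#' connectivity sums exclude self-adjacency.
#'
#' @param resid probes x samples residualized M-value matrix.
#' @param power soft-threshold exponent (>= 1).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return symmetric probes x probes matrix with zero diagonal.
#' @export
adjacency_matrix <- function(resid, power, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  stopifnot(power >= 1, ncol(resid) >= 3)
  sds <- apply(resid, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance probe(s): ",
         paste(utils::head(rownames(resid)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(t(resid))
  a <- if (type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Connectivity `k_i = sum_j a_ij` is binned into `n_bins` equal-width bins
#' (equal-count binning would make the bin frequencies constant by
#' construction); the fit regresses `log10(bin frequency)` on
#' `log10(mean k)` over non-empty bins. Returned R-squared values follow the signed convention
#' (multiplied by the negated sign of the slope, truncated below at zero),
#' so anti-scale-free networks score 0; the degrees-of-freedom-adjusted
#' version is reported alongside.
#'
#' @param adj adjacency matrix (zero diagonal).
#' @param n_bins number of connectivity bins.
#' @return list with `r_squared`, `adj_r_squared`, `slope`,
#'   `mean_connectivity`.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  k <- rowSums(adj)
  if (length(k) < 20) stop("need >= 20 probes for a scale-free fit", call. = FALSE)
  if (stats::sd(k) == 0) {
    warning("all connectivities identical; scale-free fit undefined")
    return(list(r_squared = 0, adj_r_squared = 0, slope = NA_real_,
                mean_connectivity = mean(k)))
  }
  bins <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tabulate(bins, nbins = nlevels(bins)) / length(k)
  kmean <- tapply(k, bins, mean)
  ok <- freq > 0 & is.finite(kmean) & kmean > 0
  if (sum(ok) < 3) {
    warning("too few populated bins; scale-free fit undefined")
    return(list(r_squared = 0, adj_r_squared = 0, slope = NA_real_,
                mean_connectivity = mean(k)))
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
  sm <- summary(fit)
  slope <- stats::coef(fit)[2]
  sgn <- -sign(slope)
  list(
    r_squared = max(0, sgn * sm$r.squared),
    adj_r_squared = max(0, sgn * sm$adj.r.squared),
    slope = unname(slope),
    mean_connectivity = mean(k)
  )
}

#' Soft-threshold selection scan
#'
#' Evaluates the scale-free fit across candidate powers and picks the
#' lowest power whose fit exceeds `r2_min`. If no power passes, the argmax
#' power is returned with `warning_flag = TRUE`.
#'
#' @param resid probes x samples residualized M-value matrix.
#' @param powers ascending candidate powers.
#' @param r2_min fit threshold.
#' @param statistic which fit statistic drives selection: the signed
#'   R-squared or its degrees-of-freedom-adjusted variant.
#' @param type network type passed to [adjacency_matrix()].
#' @return list of class `soft_threshold_scan`: `scan` (data.frame with
#'   power, r_squared, adj_r_squared, slope, mean_connectivity),
#'   `chosen_power`, `warning_flag`.
#' @export
pick_soft_threshold <- function(resid, powers = 1:20, r2_min = 0.90,
                                statistic = c("r_squared", "adj_r_squared"),
                                type = "unsigned") {
  statistic <- match.arg(statistic)
  stopifnot(length(powers) > 0, !is.unsorted(powers))
  rows <- lapply(powers, function(p) {
    f <- scale_free_fit(adjacency_matrix(resid, p, type))
    data.frame(power = p, r_squared = f$r_squared,
               adj_r_squared = f$adj_r_squared, slope = f$slope,
               mean_connectivity = f$mean_connectivity)
  })
  scan <- do.call(rbind, rows)
  pass <- which(scan[[statistic]] > r2_min)
  if (length(pass)) {
    chosen <- scan$power[pass[1]]
    flag <- FALSE
  } else {
    chosen <- scan$power[which.max(scan[[statistic]])]
    flag <- TRUE
    warning("no candidate power reached the scale-free fit threshold; ",
            "using argmax power ", chosen)
  }
  structure(list(scan = scan, chosen_power = chosen, warning_flag = flag,
                 r2_min = r2_min, statistic = statistic),
            class = "soft_threshold_scan")
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`; the returned dissimilarity is `1 - TOM` with a
#' zero diagonal. Shared-neighbour structure makes module membership more
#' robust than raw adjacency.
#'
#' @param adj symmetric adjacency with zero diagonal and entries in `[0,1]`.
#' @return symmetric dissimilarity matrix with entries in `[0,1]`.
#' @export
tom_dissimilarity <- function(adj) {
  if (any(adj < 0 | adj > 1)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  k <- rowSums(adj)
  l <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  d <- 1 - tom
  d[d < 0] <- 0            # guard tiny negative rounding
  dimnames(d) <- dimnames(adj)
  d
}

# color aliases for module reporting, in a stable order
module_color_alias <- function(n) {
  pool <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue",
            "saddlebrown", "steelblue", "paleturquoise", "violet",
            "darkolivegreen", "darkmagenta", "maroon", "lightcoral",
            "indianred4", "antiquewhite4", "coral1")
  if (n <= length(pool)) pool[seq_len(n)] else
    c(pool, paste0("module", seq.int(length(pool) + 1, n)))[seq_len(n)]
}

#' Cluster probes into co-methylation modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity, cut at
#' a fixed height (`cut_height` as a fraction of the maximum merge height).
#' Clusters smaller than `min_size` are relabelled 0 (unassigned);
#' surviving modules are renumbered 1..K by decreasing size and given color
#' aliases for reporting.
#'
#' @param diss probes x probes dissimilarity matrix.
#' @param min_size minimum module size (>= 2).
#' @param cut_height tree-cut height as a fraction of the maximum merge
#'   height.
#' @return list with `labels` (named integer vector, 0 = unassigned),
#'   `colors` (named character), `sizes`, `dendrogram` (hclust object).
#' @export
cluster_modules <- function(diss, min_size = 10, cut_height = 0.995) {
  if (min_size < 2) stop("min_size must be >= 2", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  h <- cut_height * max(hc$height)
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)])]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  names(labels) <- rownames(diss)
  k <- max(labels)
  colors <- c("unassigned", module_color_alias(k))[labels + 1]
  names(colors) <- names(labels)
  list(labels = labels, colors = colors,
       sizes = if (k) table(labels[labels > 0]) else table(integer()),
       dendrogram = hc)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member probes across samples: the per-sample score
#' summarizing the module's co-methylation profile. The sign is fixed so
#' the eigengene correlates positively with the module's mean probe
#' profile, and scores are standardized to unit SD. The fraction of member
#' variance explained by the first component is recorded.
#'
#' @param resid probes x samples residualized M-value matrix.
#' @param labels named integer vector of module labels (0 = unassigned).
#' @return list of class `module_set`: `eigengenes` (samples x modules
#'   matrix, columns `ME1..MEK`), `variance_explained`, `labels`, `colors`.
#' @export
module_eigengenes <- function(resid, labels) {
  stopifnot(!is.null(names(labels)))
  labels <- labels[rownames(resid)]
  mods <- sort(unique(labels[labels > 0]))
  n <- ncol(resid)
  eig <- matrix(NA_real_, nrow = n, ncol = length(mods),
                dimnames = list(colnames(resid), paste0("ME", mods)))
  varexp <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    member <- resid[labels == mods[i], , drop = FALSE]
    if (nrow(member) < 2) stop("module ", mods[i], " has < 2 probes", call. = FALSE)
    sds <- apply(member, 1, stats::sd)
    if (any(sds == 0)) {
      stop("constant probe in module ", mods[i], ": ",
           rownames(member)[which(sds == 0)[1]], call. = FALSE)
    }
    z <- t(scale(t(member)))               # probes standardized across samples
    sv <- svd(t(z), nu = 1, nv = 0)        # samples x probes
    scores <- sv$u[, 1] * sv$d[1]
    align <- colMeans(z)
    if (stats::sd(align) < 1e-10) align <- z[1, ]  # balanced anticorrelated pair
    if (stats::cor(scores, align) < 0) scores <- -scores
    eig[, i] <- scores / stats::sd(scores)
    varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = eig, variance_explained = varexp,
                 labels = labels,
                 colors = c("unassigned", module_color_alias(max(c(0, mods))))[labels + 1]),
            class = "module_set")
}
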