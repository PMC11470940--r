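# Weir-Cockerham Fst, genotype PCA, windowed local PCA with MDS
# partitioning.

geno_attrs <- function(geno) {
  list(ploidy = attr(geno, "ploidy"), pops = attr(geno, "pops"),
       chrom = attr(geno, "chrom"), pos = attr(geno, "pos"))
}

# Collapse tetraploid dosages 0..4 onto diploid calls 0/1/2 by half-up
# rounding of dosage/2 (0->0, 1,2->1, 3,4->2).
diploidize <- function(geno, ploidy) {
  if (ploidy == 2L) return(geno)
  floor(geno / 2 + 0.5)
}

#' Weir-Cockerham weighted Fst between two populations
#'
#' Per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) following
#' Weir & Cockerham (1984), with observed heterozygosity taken from the
#' genotype calls; the weighted estimate is sum(a) / sum(a + b + c) across
#' loci.  Tetraploid dosages are diploidized by default (0..4 -> 0/1/2),
#' reflecting the diploid model behind the estimator; a frequency-based
#' Hudson estimator is available as the ploidy-agnostic alternative.
#'
#' @param geno A `genotype_matrix` (see [sim_genotypes_bn()]).
#' @param pop_a,pop_b Population labels; default the first two labels.
#' @param method `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @return An `fst_result`: `weighted_fst`, `per_locus` (a, b, c, fst,
#'   chrom, pos), `n_excluded` (loci with undefined components), labels.
#' @examples
#' g <- sim_genotypes_bn(2, 20, 500, fst = 0.2, seed = 1)
#' weighted_fst(g$geno)$weighted_fst
#' @export
weighted_fst <- function(geno, pop_a = NULL, pop_b = NULL,
                         method = c("wc", "hudson")) {
  method <- match.arg(method)
  at <- geno_attrs(geno)
  pops <- at$pops
  labs <- unique(pops)
  if (is.null(pop_a)) pop_a <- labs[1L]
  if (is.null(pop_b)) pop_b <- labs[2L]
  if (!all(c(pop_a, pop_b) %in% labs)) {
    stop("population labels not found in genotype matrix", call. = FALSE)
  }
  rows_a <- which(pops == pop_a)
  rows_b <- which(pops == pop_b)
  if (length(rows_a) < 2L || length(rows_b) < 2L) {
    stop("need at least 2 samples per population", call. = FALSE)
  }
  g <- unclass(geno)[c(rows_a, rows_b), , drop = FALSE]
  grp <- rep(c(1L, 2L), c(length(rows_a), length(rows_b)))

  if (method == "hudson") {
    ploidy <- at$ploidy
    cnt <- function(rows) {
      n_al <- colSums(!is.na(g[rows, , drop = FALSE])) * ploidy
      x <- colSums(g[rows, , drop = FALSE], na.rm = TRUE)
      list(p = x / n_al, n = n_al)
    }
    A <- cnt(which(grp == 1L)); B <- cnt(which(grp == 2L))
    num <- (A$p - B$p)^2 -
      A$p * (1 - A$p) / (A$n - 1) - B$p * (1 - B$p) / (B$n - 1)
    den <- A$p * (1 - B$p) + B$p * (1 - A$p)
    ok <- is.finite(num) & is.finite(den) & den > 0
    per_locus <- data.frame(chrom = at$chrom, pos = at$pos,
                            a = NA_real_, b = NA_real_, c = NA_real_,
                            fst = ifelse(ok, num / den, NA_real_))
    wfst <- sum(num[ok]) / sum(den[ok])
    return(structure(list(weighted_fst = wfst, per_locus = per_locus,
                          n_excluded = sum(!ok), pop_a = pop_a,
                          pop_b = pop_b, method = method),
                     class = "fst_result"))
  }

  gd <- diploidize(g, at$ploidy)
  comp <- wc84_components(gd, grp)
  ok <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c) &
    (comp$a + comp$b + comp$c) != 0
  per_locus <- data.frame(chrom = at$chrom, pos = at$pos,
                          a = comp$a, b = comp$b, c = comp$c,
                          fst = ifelse(ok, comp$a /
                                         (comp$a + comp$b + comp$c),
                                       NA_real_))
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!any(ok) || denom == 0) {
    warning("weighted Fst undefined: all loci monomorphic or excluded")
    wfst <- NA_real_
  } else {
    wfst <- sum(comp$a[ok]) / denom
  }
  structure(list(weighted_fst = wfst, per_locus = per_locus,
                 n_excluded = sum(!ok), pop_a = pop_a, pop_b = pop_b,
                 method = method),
            class = "fst_result")
}

# Vectorized WC84 variance components for diploid calls (0/1/2) across r
# groups.  `grp` is an integer group index per row of `gd`.
wc84_components <- function(gd, grp) {
  groups <- sort(unique(grp))
  r <- length(groups)
  per_group <- function(f) {
    do.call(rbind, lapply(groups, function(k)
      f(gd[grp == k, , drop = FALSE])))
  }
  n_i <- per_group(function(m) colSums(!is.na(m)))
  p_i <- per_group(function(m) colMeans(m, na.rm = TRUE) / 2)
  h_i <- per_group(function(m) colMeans(m == 1L, na.rm = TRUE))
  n_tot <- colSums(n_i)
  n_bar <- n_tot / r
  n_c <- (n_tot - colSums(n_i^2) / n_tot) / (r - 1)
  p_bar <- colSums(n_i * p_i) / n_tot
  s2 <- colSums(n_i * (p_i - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / n_tot
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_comp <- h_bar / 2
  list(a = a, b = b, c = c_comp)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weighted Fst (%s) %s vs %s: %s  [%d loci excluded]\n",
              x$method, x$pop_a, x$pop_b,
              if (is.na(x$weighted_fst)) "undefined"
              else sprintf("%.4f", x$weighted_fst),
              x$n_excluded))
  invisible(x)
}

#' Loci exceeding an Fst threshold
#'
#' @param result An `fst_result`.
#' @param threshold Per-locus Fst threshold (default 0.8).
#' @return Data frame of loci with per-locus Fst above the threshold.
#' @export
high_fst_loci <- function(result, threshold = 0.8) {
  pl <- result$per_locus
  pl[!is.na(pl$fst) & pl$fst > threshold, , drop = FALSE]
}

#' Principal component analysis of genotype dosages
#'
#' Loci with more than 20% missing dosages are dropped; remaining missing
#' values are mean-imputed per locus; zero-variance loci are removed; the
#' column-centered (optionally frequency-standardized) matrix is
#' decomposed by SVD.
#'
#' @param geno A `genotype_matrix`.
#' @param n_components Number of components returned (default 10, capped
#'   by the matrix rank).
#' @param standardize Divide each locus by sqrt(p(1-p))? Default FALSE.
#' @return A `genotype_pca`: `coords` (samples x components),
#'   `var_explained`, `sdev`, `pops`.
#' @examples
#' g <- sim_genotypes_bn(3, 10, 300, fst = 0.3, seed = 1)
#' pca <- genotype_pca(g$geno)
#' head(pca$var_explained)
#' @export
genotype_pca <- function(geno, n_components = 10L, standardize = FALSE) {
  at <- geno_attrs(geno)
  g <- unclass(geno)
  if (nrow(g) < 2L) stop("need at least 2 samples", call. = FALSE)
  miss <- colMeans(is.na(g))
  g <- g[, miss <= 0.2, drop = FALSE]
  for (j in which(colSums(is.na(g)) > 0L)) {
    g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
  }
  v <- apply(g, 2L, var)
  g <- g[, v > 0, drop = FALSE]
  if (standardize) {
    p <- colMeans(g) / at$ploidy
    g <- sweep(g, 2L, sqrt(p * (1 - p)), "/")
  }
  pc <- prcomp(g, center = TRUE, scale. = FALSE)
  k <- min(n_components, length(pc$sdev))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                 var_explained = ve[seq_len(k)],
                 sdev = pc$sdev[seq_len(k)],
                 pops = at$pops),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("Genotype PCA: ", nrow(x$coords), " samples, ", ncol(x$coords),
      " components\n  variance explained: ",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, 5L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Windowed local PCA with MDS partitioning
#'
#' Splits loci into windows (genomic bp span by default, or a fixed SNP
#' count), summarizes each window by the rank-k eigenstructure of its
#' centered sample-covariance (eigenvalues normalized to unit total),
#' measures window dissimilarity by the Frobenius norm between rank-k
#' approximations, embeds windows by classical (Torgerson) MDS, and flags
#' outlier windows farther than 3 median-absolute-deviations above the
#' median distance to the medoid window, grouped into at most 3 clusters
#' labelled LS1..LS3 by decreasing size.
#'
#' @param geno A `genotype_matrix` with locus coordinates.
#' @param window Window size: bp span (default 3000) or SNP count when
#'   `window_type = "snp"`.
#' @param window_type `"bp"` or `"snp"`.
#' @param k Rank of the per-window eigen-summary (default 2).
#' @param n_axes MDS axes returned (default 2).
#' @return A `local_pca_partition`: `windows` (coordinates, n_loci,
#'   labels), `dist` (window distance matrix), `mds` (window coordinates),
#'   `n_skipped` (windows with fewer than k+1 polymorphic loci).
#' @examples
#' g <- sim_genotypes_bn(2, 15, 600, fst = 0.2, seed = 1)
#' lp <- local_pca_partition(g$geno, window = 50, window_type = "snp")
#' table(lp$windows$label)
#' @export
local_pca_partition <- function(geno, window = 3000L,
                                window_type = c("bp", "snp"),
                                k = 2L, n_axes = 2L) {
  window_type <- match.arg(window_type)
  at <- geno_attrs(geno)
  g <- unclass(geno)
  n_loci <- ncol(g)
  if (window_type == "bp") {
    bin <- floor((at$pos - 1L) / window)
    keys <- paste(at$chrom, bin)
    idx_list <- split(seq_len(n_loci), factor(keys, levels = unique(keys)))
  } else {
    bin <- floor((seq_len(n_loci) - 1L) / window)
    idx_list <- split(seq_len(n_loci), bin)
  }
  summaries <- list()
  meta <- list()
  n_skipped <- 0L
  for (w in seq_along(idx_list)) {
    idx <- idx_list[[w]]
    X <- g[, idx, drop = FALSE]
    for (j in which(colSums(is.na(X)) > 0L)) {
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    }
    poly <- apply(X, 2L, var) > 0
    X <- X[, poly, drop = FALSE]
    if (ncol(X) < k + 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    Xc <- scale(X, center = TRUE, scale = FALSE)
    C <- tcrossprod(Xc) / (ncol(Xc) - 1L)
    eig <- eigen(C, symmetric = TRUE)
    vals <- pmax(eig$values[seq_len(k)], 0)
    if (sum(vals) <= 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    vals <- vals / sum(vals)
    U <- eig$vectors[, seq_len(k), drop = FALSE]
    A <- U %*% (vals * t(U))
    summaries[[length(summaries) + 1L]] <- A
    meta[[length(meta) + 1L]] <- data.frame(
      chrom = at$chrom[idx[1L]],
      start = min(at$pos[idx]), end = max(at$pos[idx]),
      n_loci = length(idx)
    )
  }
  nw <- length(summaries)
  if (nw < 3L) {
    stop("fewer than 3 usable windows; reduce `window` or supply more loci",
         call. = FALSE)
  }
  D <- matrix(0, nw, nw)
  for (i in seq_len(nw - 1L)) {
    for (j in (i + 1L):nw) {
      d <- sqrt(sum((summaries[[i]] - summaries[[j]])^2))
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  mds <- cmdscale(D, k = n_axes)
  medoid <- which.min(rowSums(D))
  d_med <- D[, medoid]
  thr <- median(d_med) + 3 * mad(d_med)
  out_idx <- which(d_med > thr)
  labels <- rep("none", nw)
  if (length(out_idx)) {
    if (length(out_idx) == 1L) {
      labels[out_idx] <- "LS1"
    } else {
      sub <- as.dist(D[out_idx, out_idx, drop = FALSE])
      tree <- hclust(sub, method = "average")
      # outlier windows closer to each other than the outlier threshold
      # belong to one landscape; cap at 3 clusters
      cl <- cutree(tree, h = thr)
      if (length(unique(cl)) > 3L) cl <- cutree(tree, k = 3L)
      sizes <- sort(table(cl), decreasing = TRUE)
      relabel <- setNames(paste0("LS", seq_along(sizes)), names(sizes))
      labels[out_idx] <- relabel[as.character(cl)]
    }
  }
  windows <- do.call(rbind, meta)
  windows$label <- labels
  structure(list(windows = windows, dist = D, mds = mds,
                 n_skipped = n_skipped, medoid = medoid,
                 threshold = thr),
            class = "local_pca_partition")
}

#' @export
print.local_pca_partition <- function(x, ...) {
  cat("Local PCA partition: ", nrow(x$windows), " windows (",
      x$n_skipped, " skipped), outliers: ",
      sum(x$windows$label != "none"), "\n", sep = "")
  tl <- table(x$windows$label)
  cat("  ", paste(names(tl), tl, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
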