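# Allele-balance ploidy inference: histogram modes and fixed-mean Gaussian
# mixture model selection over ploidy hypotheses.

#' Extract allele-balance evidence from a VCF
#'
#' Retains heterozygous biallelic SNPs passing quality and depth windows and
#' records per-site reference/alternate allele depths from the `AD` FORMAT
#' field.  Calls are filtered to `min_qual` (default Q20) and to a depth
#' window guarding against collapsed repeats.
#'
#' @param vcf Path to a VCF v4.2 with per-sample `AD`, a `vcfR` object, or
#'   an `allele_depth_table` (then only the filters are applied).
#' @param sample Sample name; defaults to the first sample.
#' @param min_qual Minimum site QUAL (default 20).
#' @param min_depth Minimum total depth (default 20).
#' @param max_depth Maximum total depth; default 3x the median depth.
#' @return An `allele_depth_table` with columns chrom, pos, ref_depth,
#'   alt_depth, qual and a `fraction` column (unfolded alt fraction).
#' @examples
#' sim <- sim_allele_depths(2, 200, 60, seed = 1)
#' f <- tempfile(fileext = ".vcf")
#' write_allele_depth_vcf(sim$table, f)
#' nrow(extract_allele_balance(f))
#' @export
extract_allele_balance <- function(vcf, sample = NULL, min_qual = 20,
                                   min_depth = 20, max_depth = NULL) {
  if (is.character(vcf) && length(vcf) == 1L) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  if (inherits(vcf, "vcfR")) {
    fmt <- vcf@gt[, 1L]
    if (!any(grepl("AD", fmt))) {
      stop("VCF lacks the AD (allelic depths) FORMAT field", call. = FALSE)
    }
    biall <- vcfR::is.biallelic(vcf)
    ad <- vcfR::extract.gt(vcf, element = "AD")
    if (is.null(sample)) sample <- colnames(ad)[1L]
    if (!sample %in% colnames(ad)) {
      stop("sample not present in VCF: ", sample, call. = FALSE)
    }
    parts <- strsplit(ad[, sample], ",", fixed = TRUE)
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    alt <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    tab <- data.frame(
      chrom = vcf@fix[, "CHROM"],
      pos = as.integer(vcf@fix[, "POS"]),
      ref_depth = ref, alt_depth = alt,
      qual = suppressWarnings(as.numeric(vcf@fix[, "QUAL"]))
    )
    tab <- tab[biall & !is.na(ref) & !is.na(alt), , drop = FALSE]
  } else if (is.data.frame(vcf)) {
    tab <- as.data.frame(vcf)
  } else {
    stop("`vcf` must be a path, a vcfR object or an allele-depth table",
         call. = FALSE)
  }
  depth <- tab$ref_depth + tab$alt_depth
  if (is.null(max_depth)) max_depth <- 3 * median(depth)
  keep <- !is.na(tab$qual) & tab$qual >= min_qual &
    depth >= min_depth & depth <= max_depth &
    tab$ref_depth >= 1L & tab$alt_depth >= 1L
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("no heterozygous biallelic sites pass the quality/depth filters",
         call. = FALSE)
  }
  tab$fraction <- tab$alt_depth / (tab$ref_depth + tab$alt_depth)
  rownames(tab) <- NULL
  class(tab) <- c("allele_depth_table", "data.frame")
  tab
}

allele_fractions <- function(table) {
  if (!is.null(table$fraction)) return(table$fraction)
  table$alt_depth / (table$ref_depth + table$alt_depth)
}

#' Allele-balance histogram and its modes
#'
#' Bins (optionally folded) allele fractions, smooths counts with a 3-bin
#' moving average, and reports modes: local maxima with height at least 10%
#' of the tallest bin, merged when closer than 0.05.  An autotetraploid
#' shows folded modes near 0.25 and 0.5; a diploid a single mode near 0.5.
#'
#' @param table An `allele_depth_table`.
#' @param bin_width Histogram bin width in `(0, 0.25]`; default 0.02.
#' @param fold Fold fractions to the minor allele (`min(f, 1-f)`)?
#'   Default TRUE (display convention).
#' @return A list of class `ab_histogram` with `modes` (ascending bin
#'   centers of detected modes) and `histogram` (mid, count, smoothed).
#' @examples
#' sim <- sim_allele_depths(4, 20000, 60, seed = 1)
#' histogram_modes(sim$table)$modes
#' @export
histogram_modes <- function(table, bin_width = 0.02, fold = TRUE) {
  if (bin_width <= 0 || bin_width > 0.25) {
    stop("`bin_width` must lie in (0, 0.25]", call. = FALSE)
  }
  f <- allele_fractions(table)
  if (length(f) < 1000L) {
    warning("fewer than 1000 sites; histogram modes may be unstable")
  }
  if (fold) {
    # minor-allele fraction computed from the depths directly so the
    # histogram is exactly invariant under ref/alt swap (1 - alt/(ref+alt)
    # and ref/(ref+alt) differ by one ulp on the binary scale)
    f <- if (!is.null(table$ref_depth)) {
      pmin(table$ref_depth, table$alt_depth) /
        (table$ref_depth + table$alt_depth)
    } else {
      pmin(f, 1 - f)
    }
  }
  upper <- if (fold) 0.5 else 1
  breaks <- seq(0, upper, by = bin_width)
  if (breaks[length(breaks)] < upper) breaks <- c(breaks, upper)
  cut_idx <- findInterval(f, breaks, rightmost.closed = TRUE)
  cut_idx <- pmin(pmax(cut_idx, 1L), length(breaks) - 1L)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1L)
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  n <- length(counts)
  sm <- counts
  if (n >= 3L) {
    sm <- c((counts[1L] + counts[2L]) / 2,
            (counts[1:(n - 2L)] + counts[2:(n - 1L)] + counts[3:n]) / 3,
            (counts[n - 1L] + counts[n]) / 2)
  }
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < n) sm[i + 1L] else -Inf
    sm[i] >= left && sm[i] >= right && sm[i] > 0
  }, logical(1))
  cand <- which(is_max & sm >= 0.1 * max(sm))
  # merge modes closer than 0.05, keeping the taller
  modes <- numeric(0)
  if (length(cand)) {
    ord <- cand[order(-sm[cand])]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(mids[i] - mids[kept]) >= 0.05)) {
        kept <- c(kept, i)
      }
    }
    modes <- sort(mids[kept])
  }
  structure(list(modes = modes,
                 histogram = data.frame(mid = mids, count = counts,
                                        smoothed = sm)),
            class = "ab_histogram")
}

#' @export
print.ab_histogram <- function(x, ...) {
  cat("Allele-balance histogram: ", sum(x$histogram$count), " sites, ",
      length(x$modes), " mode(s) at ",
      paste(format(x$modes, digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Shared 1-D Gaussian mixture EM.  With fixed_means, only weights and the
# shared variance are updated (the nQuire convention); otherwise means are
# free.  Returns logL, weights, means, sd and a convergence flag.
gaussian_mixture_em <- function(x, means, fixed_means = TRUE,
                                max_iter = 200L, tol = 1e-6,
                                var_floor = 1e-4) {
  n <- length(x)
  kk <- length(means)
  w <- rep(1 / kk, kk)
  s2 <- max(var(x), var_floor)
  mu <- means
  prev_ll <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(kk),
                   function(j) w[j] * dnorm(x, mu[j], sqrt(s2)),
                   numeric(n))
    row_tot <- rowSums(dens)
    row_tot[row_tot < 1e-300] <- 1e-300
    ll <- sum(log(row_tot))
    resp <- dens / row_tot
    nk <- colSums(resp)
    w <- nk / n
    if (!fixed_means) {
      mu <- ifelse(nk > 0, colSums(resp * x) / nk, mu)
    }
    s2 <- max(sum(resp * (outer(x, mu, "-"))^2) / n, var_floor)
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol) {
      converged <- TRUE
      prev_ll <- ll
      break
    }
    prev_ll <- ll
  }
  list(logL = prev_ll, weights = w, means = mu, sd = sqrt(s2),
       converged = converged, iterations = iter)
}

#' Classify ploidy from allele-balance distributions
#'
#' For each ploidy hypothesis P, fits a Gaussian mixture with means fixed at
#' i/P (i = 1..P-1), shared variance and free weights to the unfolded alt
#' fractions, and compares its log-likelihood with a free 3-component
#' mixture.  The called hypothesis minimizes `logL_free - logL_fixed` plus
#' (by default) a BIC-style penalty of `(P - 2)/2 * log(n)` for the extra
#' free mixture weights of higher hypotheses: without it, a near-zero-weight
#' component parked at 1/4 can absorb a handful of binomial tail sites of a
#' genuine diploid and tip the raw likelihood toward tetraploidy.  Ties
#' break toward the smaller ploidy (parsimony).
#'
#' @param table An `allele_depth_table`.
#' @param hypotheses Ploidies to test; default `c(2, 3, 4)`.
#' @param penalty `"bic"` (default) penalizes each extra free mixture
#'   weight by `log(n)/2`; `"none"` compares raw delta log-likelihoods.
#' @param max_iter,tol EM controls (defaults 200 iterations, 1e-6 on logL).
#' @return A `ploidy_call` with per-hypothesis log-likelihoods, delta-logL,
#'   the free-model log-likelihood, detected folded modes and
#'   `called_ploidy`.
#' @examples
#' sim <- sim_allele_depths(4, 5000, 60, seed = 7)
#' classify_ploidy(sim$table)$called_ploidy
#' @export
classify_ploidy <- function(table, hypotheses = c(2L, 3L, 4L),
                            penalty = c("bic", "none"),
                            max_iter = 200L, tol = 1e-6) {
  penalty <- match.arg(penalty)
  x <- allele_fractions(table)
  if (any(x <= 0 | x >= 1)) {
    stop("unfolded fractions must lie strictly inside (0, 1)", call. = FALSE)
  }
  free <- gaussian_mixture_em(x, means = quantile(x, c(0.25, 0.5, 0.75),
                                                  names = FALSE),
                              fixed_means = FALSE,
                              max_iter = max_iter, tol = tol)
  fits <- lapply(hypotheses, function(P) {
    gaussian_mixture_em(x, means = seq_len(P - 1L) / P, fixed_means = TRUE,
                        max_iter = max_iter, tol = tol)
  })
  logl_fixed <- vapply(fits, `[[`, 0, "logL")
  delta <- free$logL - logl_fixed
  score <- delta
  if (penalty == "bic") {
    score <- delta + (hypotheses - 2) / 2 * log(length(x))
  }
  hyp_order <- order(hypotheses)  # ensure parsimony tie-break
  best <- hyp_order[which.min(score[hyp_order])]
  hist <- histogram_modes(table, fold = TRUE)
  structure(list(
    called_ploidy = as.integer(hypotheses[best]),
    hypotheses = as.integer(hypotheses),
    logL_fixed = setNames(logl_fixed, paste0("ploidy", hypotheses)),
    logL_free = free$logL,
    delta_logL = setNames(delta, paste0("ploidy", hypotheses)),
    detected_modes = hist$modes,
    histogram = hist$histogram,
    fits = fits,
    unconverged = !all(vapply(fits, `[[`, TRUE, "converged")) ||
      !free$converged
  ), class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("Ploidy call: ", x$called_ploidy,
      if (x$unconverged) "  [EM unconverged]" else "", "\n", sep = "")
  cat("  delta logL (free - fixed):\n")
  for (i in seq_along(x$hypotheses)) {
    cat(sprintf("    ploidy %d: %.2f%s\n", x$hypotheses[i], x$delta_logL[i],
                if (x$hypotheses[i] == x$called_ploidy) "  <- called" else ""))
  }
  cat("  folded histogram modes: ",
      paste(format(x$detected_modes, digits = 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Two-dimensional depth-by-fraction histogram
#'
#' Counts sites over a (total depth x folded minor-allele fraction) grid.
#' Marginalizing over depth reproduces the 1-D allele-balance histogram.
#'
#' @param table An `allele_depth_table`.
#' @param depth_bins Depth bin edges; default 12 equal bins over the
#'   observed depth range.
#' @param fraction_bins Folded-fraction bin edges; default width 0.02 over
#'   `[0, 0.5]`.
#' @return A matrix (depth bins x fraction bins) with `depth_mids` /
#'   `fraction_mids` attributes.
#' @export
coverage_fraction_hist2d <- function(table, depth_bins = NULL,
                                     fraction_bins = NULL) {
  if (nrow(table) == 0L) stop("empty allele-depth table", call. = FALSE)
  depth <- table$ref_depth + table$alt_depth
  f <- pmin(table$ref_depth, table$alt_depth) / depth
  if (is.null(depth_bins)) {
    depth_bins <- seq(min(depth), max(depth), length.out = 13L)
    depth_bins[length(depth_bins)] <- depth_bins[length(depth_bins)] + 1e-9
  }
  if (is.null(fraction_bins)) fraction_bins <- seq(0, 0.5, by = 0.02)
  if (length(depth_bins) < 2L || length(fraction_bins) < 2L) {
    stop("bin grids need at least two edges", call. = FALSE)
  }
  di <- findInterval(depth, depth_bins, rightmost.closed = TRUE)
  fi <- findInterval(f, fraction_bins, rightmost.closed = TRUE)
  ok <- di >= 1L & di < length(depth_bins) &
    fi >= 1L & fi < length(fraction_bins)
  h <- matrix(0L, length(depth_bins) - 1L, length(fraction_bins) - 1L)
  for (i in which(ok)) h[di[i], fi[i]] <- h[di[i], fi[i]] + 1L
  attr(h, "depth_mids") <-
    (depth_bins[-length(depth_bins)] + depth_bins[-1L]) / 2
  attr(h, "fraction_mids") <-
    (fraction_bins[-length(fraction_bins)] + fraction_bins[-1L]) / 2
  h
}
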