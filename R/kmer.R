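# K-mer spectrum genome profiling: haploid size, unique/repeat partition and
# heterozygosity from a depth histogram.

new_kmer_spectrum <- function(rows, k) {
  stopifnot(is.data.frame(rows), all(c("depth", "count") %in% names(rows)))
  structure(list(k = as.integer(k), rows = rows), class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("K-mer spectrum (k = ", x$k, "): ", nrow(x$rows), " depth bins, mass ",
      format(sum(as.numeric(x$rows$depth) * x$rows$count), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Parse a two-column k-mer depth histogram
#'
#' Reads jellyfish-style `.histo` text: whitespace-separated depth and
#' distinct-k-mer count per line.  Depths must be positive integers without
#' duplicates; out-of-order rows are re-sorted with a warning.
#'
#' @param path Histogram file path.
#' @param k K-mer size used to build the histogram (or taken from a
#'   `#k=NN` header comment if present).
#' @return A `kmer_spectrum` object.
#' @examples
#' f <- tempfile(fileext = ".histo")
#' writeLines(c("1 100", "30 1000"), f)
#' parse_histo(f, k = 19)
#' @export
parse_histo <- function(path, k = NULL) {
  lines <- readLines(path)
  header_k <- grep("^#\\s*k\\s*=", lines, value = TRUE)
  if (is.null(k) && length(header_k)) {
    k <- as.integer(sub(".*=\\s*", "", header_k[1L]))
  }
  if (is.null(k)) stop("`k` must be supplied (or a '#k=' header present)",
                       call. = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty histogram file: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 2L || anyNA(suppressWarnings(as.numeric(p))) ||
        any(as.numeric(p) != floor(as.numeric(p)))) {
      stop(sprintf("non-integer or malformed fields at line %d of %s",
                   i, path), call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  rows <- data.frame(depth = as.integer(m[, 1L]), count = m[, 2L])
  if (anyDuplicated(rows$depth)) {
    dup <- rows$depth[duplicated(rows$depth)][1L]
    stop(sprintf("duplicate depth %d at line %d of %s",
                 dup, which(rows$depth == dup)[2L], path), call. = FALSE)
  }
  if (is.unsorted(rows$depth)) {
    warning("depths out of order; re-sorting")
    rows <- rows[order(rows$depth), , drop = FALSE]
    rownames(rows) <- NULL
  }
  if (sum(as.numeric(rows$depth) * rows$count) <= 0) {
    stop("histogram has zero total k-mer mass", call. = FALSE)
  }
  new_kmer_spectrum(rows, k)
}

# Dense count vector over depths 1..max, 3-bin moving-average smoothed.
smooth_counts <- function(rows) {
  dense <- numeric(max(rows$depth))
  dense[rows$depth] <- rows$count
  n <- length(dense)
  if (n < 3L) return(dense)
  sm <- dense
  sm[2:(n - 1L)] <- (dense[1:(n - 2L)] + dense[2:(n - 1L)] + dense[3:n]) / 3
  sm[1L] <- (dense[1L] + dense[2L]) / 2
  sm[n] <- (dense[n - 1L] + dense[n]) / 2
  sm
}

#' Fit a genome profile to a k-mer spectrum
#'
#' A deliberately simple peak-based model of the GenomeScope geometry.  The
#' error cutoff is the first local minimum (valley) of the 3-bin smoothed
#' counts; the homozygous peak is the dominant mode above the cutoff, with a
#' heterozygous peak, if present, near half that depth.  Haploid genome size
#' is total above-cutoff mass divided by the homozygous peak depth.  K-mers
#' deeper than 1.5x the homozygous peak are treated as repetitive and their
#' mass defines the repeat partition.  Heterozygosity is recovered from the
#' fraction of haplotype-specific distinct k-mers f via
#' h = 1 - (1 - f)^(1/k).
#'
#' @param spectrum A `kmer_spectrum`.
#' @param ploidy_hint Relabels peaks only (homozygous peak assumed at
#'   `ploidy_hint x haploid depth`); default 2.
#' @return A `genome_profile` list: `genome_size_bp`, `unique_bp`,
#'   `repeat_bp`, `repeat_fraction`, `heterozygosity_fraction`,
#'   `het_peak_depth`, `hom_peak_depth`, `error_depth_cutoff`.
#' @examples
#' sp <- sim_kmer_spectrum(50000, 0, 0, k = 19, mean_depth = 60, seed = 1)
#' fit_spectrum(sp$spectrum)
#' @export
fit_spectrum <- function(spectrum, ploidy_hint = 2L) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  rows <- spectrum$rows
  sm <- smooth_counts(rows)
  n <- length(sm)
  # error cutoff: first depth at which the smoothed counts start rising
  # (valley after the error slope, or the leading flat before the main peak)
  cutoff <- 0L
  for (d in seq_len(n - 1L)) {
    if (sm[d + 1L] > sm[d]) { cutoff <- d; break }
  }
  above <- which(seq_len(n) > cutoff & sm > 0)
  if (!length(above)) {
    stop("insufficient coverage: no k-mer mode above the error cutoff",
         call. = FALSE)
  }
  # dominant mode above the cutoff; ties toward lower depth
  hom_peak <- above[which.max(sm[above])]
  # a heterozygous peak would be a local maximum near hom_peak / 2
  het_lo <- max(cutoff + 1L, floor(hom_peak * 0.35))
  het_hi <- ceiling(hom_peak * 0.65)
  het_peak <- NA_integer_
  if (het_hi > het_lo + 1L) {
    cand <- (het_lo + 1L):(min(het_hi, n - 1L))
    cand <- cand[cand > 1L]
    is_max <- sm[cand] >= sm[cand - 1L] & sm[cand] >= sm[cand + 1L] &
      sm[cand] > 0.05 * sm[hom_peak]
    if (any(is_max)) {
      cc <- cand[is_max]
      het_peak <- cc[which.max(sm[cc])]
    }
  }
  # In a het-dominated spectrum the global mode is the haplotype-specific
  # peak and the homozygous peak sits at twice its depth.  A repeat-heavy
  # spectrum shows the same (d, 2d) geometry with the roles reversed, so
  # the half-depth ambiguity is resolved by asking whether the het
  # interpretation implies a biologically plausible heterozygosity
  # (<= 0.055): the distinct-k-mer balance of a repeat peak does not.
  dbl <- round(hom_peak * 2)
  if (dbl <= n - 1L && dbl >= 3L) {
    win <- max(3L, round(0.15 * dbl))
    reg <- max(cutoff + 1L, dbl - win):min(n - 1L, dbl + win)
    if (length(reg)) {
      loc <- reg[sm[reg] >= sm[reg - 1L] & sm[reg] >= sm[reg + 1L]]
      if (length(loc) && max(sm[loc]) > 0.2 * sm[hom_peak]) {
        cand_hom <- loc[which.max(sm[loc])]
        c_low <- sum(rows$count[rows$depth > cutoff &
                                  rows$depth <= 0.75 * cand_hom])
        c_high <- sum(rows$count[rows$depth > 0.75 * cand_hom &
                                   rows$depth <= 1.5 * cand_hom])
        if (c_low > 0 && c_high > 0) {
          f_imp <- (c_low / 2) / (c_low / 2 + c_high)
          h_imp <- 1 - (1 - f_imp)^(1 / spectrum$k)
          if (h_imp <= 0.055) {
            het_peak <- hom_peak
            hom_peak <- cand_hom
          }
        }
      }
    }
  }

  dd <- rows$depth
  cc <- rows$count
  sel <- dd > cutoff
  mass_above <- sum(as.numeric(dd[sel]) * cc[sel])
  genome_size <- mass_above / hom_peak
  rep_sel <- dd > 1.5 * hom_peak
  repeat_bp <- sum(as.numeric(dd[rep_sel]) * cc[rep_sel]) / hom_peak
  unique_bp <- genome_size - repeat_bp

  heterozygosity <- 0
  if (!is.na(het_peak)) {
    # distinct k-mers near each peak: everything below 0.75x hom depth is
    # attributed to the haplotype-specific (het) component
    het_sel <- dd > cutoff & dd <= 0.75 * hom_peak
    hom_sel <- dd > 0.75 * hom_peak & dd <= 1.5 * hom_peak
    c_het <- sum(cc[het_sel])
    c_hom <- sum(cc[hom_sel])
    if (c_het > 0 && c_hom + c_het > 0) {
      f <- (c_het / 2) / (c_het / 2 + c_hom)
      heterozygosity <- 1 - (1 - f)^(1 / spectrum$k)
    }
  }

  structure(list(
    genome_size_bp = genome_size,
    unique_bp = unique_bp,
    repeat_bp = repeat_bp,
    repeat_fraction = repeat_bp / genome_size,
    heterozygosity_fraction = heterozygosity,
    het_peak_depth = het_peak,
    hom_peak_depth = hom_peak,
    error_depth_cutoff = cutoff,
    ploidy_hint = as.integer(ploidy_hint),
    k = spectrum$k
  ), class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat("Genome profile (k = ", x$k, ")\n", sep = "")
  cat(sprintf("  Genome size (bp)   : %s\n",
              format(round(x$genome_size_bp), big.mark = ",")))
  cat(sprintf("  Unique genome (bp) : %s\n",
              format(round(x$unique_bp), big.mark = ",")))
  cat(sprintf("  Repeat genome (bp) : %s\n",
              format(round(x$repeat_bp), big.mark = ",")))
  cat(sprintf("  Repeat fraction (%%): %.1f\n", 100 * x$repeat_fraction))
  cat(sprintf("  Heterozygosity (%%) : %.2f\n",
              100 * x$heterozygosity_fraction))
  cat(sprintf("  Peaks: hom depth %d%s; error cutoff %d\n",
              x$hom_peak_depth,
              if (is.na(x$het_peak_depth)) ""
              else sprintf(", het depth %d", x$het_peak_depth),
              x$error_depth_cutoff))
  invisible(x)
}

#' Summarize a genome profile as a one-row report table
#'
#' Columns follow the conventional k-mer survey report: genome size, unique
#' and repeat partitions, repeat fraction (%), heterozygosity (%).
#'
#' @param object A `genome_profile`.
#' @param ... Unused.
#' @return A one-row data.frame.
#' @export
summary.genome_profile <- function(object, ...) {
  data.frame(
    genome_size_bp = round(object$genome_size_bp),
    unique_bp = round(object$unique_bp),
    repeat_bp = round(object$repeat_bp),
    repeat_fraction_pct = round(100 * object$repeat_fraction, 1),
    heterozygosity_pct = round(100 * object$heterozygosity_fraction, 2)
  )
}
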