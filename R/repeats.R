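# Tandem-repeat monomer / HOR detection, windowed identity heatmaps and
# telomere tract measurement.

#' Detect tandem-repeat monomer and higher-order structure
#'
#' Scores each candidate period p by the mean per-base identity between the
#' sequence and itself shifted by p.  The monomer is the smallest period
#' whose score is a local maximum within 2% of the global maximum (with
#' parabolic sub-bp refinement); higher-order repeats (HORs) are
#' near-multiples of the monomer whose score exceeds the monomer score —
#' the signature of alternating divergent monomer variants, as in
#' centromeric satellite.
#'
#' @param seq A single DNA sequence (character).
#' @param min_period,max_period Period search bounds in bp (defaults 50 and
#'   1000, covering typical plant centromere monomers and their HORs).
#' @param max_scan_bp At most this many central bases are used for scoring
#'   (keeps long arrays cheap without changing the estimate).
#' @return A `tandem_array_report`: `monomer_length_bp` (NA when no period
#'   scores >= 0.6), `hor_lengths_bp`, `array_span`, `mean_identity`,
#'   `periodicity` (score profile).
#' @examples
#' arr <- sim_repeat_sequences("tandem", random_monomer(158, seed = 5), 400,
#'                             divergence = 0.02, flank_bp = 500, seed = 1)
#' detect_tandem_structure(arr$seq)$monomer_length_bp
#' @export
detect_tandem_structure <- function(seq, min_period = 50L,
                                    max_period = 1000L,
                                    max_scan_bp = 100000L) {
  seq <- unname(seq[1L])
  n <- nchar(seq)
  if (n < 3L * max_period) {
    stop("sequence shorter than 3x `max_period`", call. = FALSE)
  }
  if (n > max_scan_bp) {
    off <- (n - max_scan_bp) %/% 2L
    seq_use <- substr(seq, off + 1L, off + max_scan_bp)
  } else {
    seq_use <- seq
  }
  x <- strsplit(seq_use, "", fixed = TRUE)[[1L]]
  m <- length(x)
  periods <- min_period:max_period
  score <- vapply(periods, function(p) {
    mean(x[1:(m - p)] == x[(p + 1):m])
  }, 0)
  names(score) <- periods
  profile <- data.frame(period = periods, score = score, row.names = NULL)
  if (max(score) < 0.6) {
    return(structure(list(monomer_length_bp = NA_real_,
                          hor_lengths_bp = numeric(0),
                          array_span = c(NA_integer_, NA_integer_),
                          mean_identity = NA_real_, periodicity = profile),
                     class = "tandem_array_report"))
  }
  ns <- length(score)
  local_max <- which(score >= c(-Inf, score[-ns]) &
                       score >= c(score[-1L], -Inf))
  top <- max(score)
  cands <- local_max[score[local_max] >= 0.98 * top]
  mono_idx <- min(cands)
  refine <- function(idx) {
    if (idx <= 1L || idx >= ns) return(periods[idx])
    y <- score[(idx - 1L):(idx + 1L)]
    denom <- y[1L] - 2 * y[2L] + y[3L]
    if (abs(denom) < 1e-12) return(periods[idx])
    periods[idx] + 0.5 * (y[1L] - y[3L]) / denom
  }
  monomer <- refine(mono_idx)
  mono_p <- periods[mono_idx]
  mono_score <- score[mono_idx]

  hors <- numeric(0)
  q <- 2L
  while (q * mono_p <= max_period) {
    center <- q * mono_p
    win <- max(2L, round(0.02 * center))
    reg <- which(abs(periods - center) <= win)
    reg_max <- intersect(reg, local_max)
    if (length(reg_max)) {
      best <- reg_max[which.max(score[reg_max])]
      if (score[best] > mono_score + 0.005) {
        hors <- c(hors, refine(best))
      }
    }
    q <- q + 1L
  }

  # array span: contiguous region of high identity at the monomer lag
  lag <- mono_p
  hit <- x[1:(m - lag)] == x[(lag + 1):m]
  w <- min(2L * lag, length(hit))
  cs <- cumsum(hit)
  roll <- (cs[w:length(hit)] - c(0, cs[seq_len(length(hit) - w)])) / w
  inside <- which(roll >= 0.6)
  span <- if (length(inside)) {
    c(min(inside), max(inside) + w + lag - 1L)
  } else c(NA_integer_, NA_integer_)
  if (n > max_scan_bp && !anyNA(span)) {
    span <- span + (n - max_scan_bp) %/% 2L
  }

  structure(list(monomer_length_bp = monomer,
                 hor_lengths_bp = hors,
                 array_span = span,
                 mean_identity = unname(mono_score),
                 periodicity = profile),
            class = "tandem_array_report")
}

#' @export
print.tandem_array_report <- function(x, ...) {
  if (is.na(x$monomer_length_bp)) {
    cat("No tandem structure detected (max periodicity score < 0.6)\n")
  } else {
    cat(sprintf("Tandem array: monomer %.1f bp (identity %.3f)",
                x$monomer_length_bp, x$mean_identity))
    if (length(x$hor_lengths_bp)) {
      cat(", HORs at", paste(round(x$hor_lengths_bp), collapse = ", "), "bp")
    }
    cat(sprintf("; span %d-%d\n", x$array_span[1L], x$array_span[2L]))
  }
  invisible(x)
}

#' A random monomer sequence (convenience for simulations)
#'
#' @param length_bp Monomer length.
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
random_monomer <- function(length_bp, seed = 1L) {
  with_seed(seed, random_dna(length_bp))
}

#' Windowed pairwise identity heatmap of a sequence
#'
#' Tiles the sequence into non-overlapping windows and estimates the
#' per-base identity between every pair of windows from k-mer set Jaccard
#' similarity via the Mash distance transform
#' d = -(1/k) log(2J / (1 + J)); identity = 1 - d.
#'
#' @param seq A single DNA sequence.
#' @param window_bp Window size (>= 10k bases); default 5000.
#' @param k Sketch k-mer size; default 15.
#' @return Symmetric identity matrix with unit diagonal; window start
#'   coordinates as dimnames.
#' @export
identity_heatmap <- function(seq, window_bp = 5000L, k = 15L) {
  seq <- unname(seq[1L])
  if (window_bp < 10L * k) stop("`window_bp` must be >= 10k", call. = FALSE)
  n <- nchar(seq)
  n_win <- n %/% window_bp
  if (n_win < 2L) {
    stop("sequence shorter than two windows", call. = FALSE)
  }
  starts <- (seq_len(n_win) - 1L) * window_bp + 1L
  sets <- lapply(starts, function(s) {
    unique(seq_kmers(substr(seq, s, s + window_bp - 1L), k))
  })
  idm <- matrix(1, n_win, n_win,
                dimnames = list(starts, starts))
  for (i in seq_len(n_win - 1L)) {
    for (j in (i + 1L):n_win) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(sets[[i]]) + length(sets[[j]]) - inter
      jac <- if (uni > 0) inter / uni else 0
      ident <- if (jac <= 0) 0 else {
        max(0, min(1, 1 + log(2 * jac / (1 + jac)) / k))
      }
      idm[i, j] <- ident
      idm[j, i] <- ident
    }
  }
  idm
}

#' Measure terminal telomere tracts
#'
#' From each end of each sequence, extends through consecutive copies of
#' the telomere motif (any circular permutation of the motif or of its
#' reverse complement), allowing up to `max_mismatch_per_copy` mismatches
#' per copy and terminating after two consecutive failing copies.  Reports
#' the maximal terminal tract per end and box-plot summary statistics over
#' sequences with a non-zero tract.
#'
#' @param seqs Named character vector of sequences.
#' @param motif Telomere motif; default the plant-type 7-mer `AAACCCT`
#'   (its 6-mer variant `AAACCT` can be passed explicitly).
#' @param max_mismatch_per_copy Mismatches tolerated per motif copy
#'   (default 1).
#' @return A `telomere_measure`: `per_end` data.frame (seq, end,
#'   tract_length_bp, copies, mismatch_fraction) and `summary`
#'   (median, q25, q75, min, max, n over per-sequence maxima).
#' @examples
#' tel <- sim_repeat_sequences("telomere", "AAACCCT", 700, 0, 500, seed = 1)
#' measure_telomeres(tel$seq)$per_end
#' @export
measure_telomeres <- function(seqs, motif = "AAACCCT",
                              max_mismatch_per_copy = 1L) {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) {
    stop("motif must contain only A, C, G, T", call. = FALSE)
  }
  if (nchar(motif) < 6L) stop("motif length must be >= 6", call. = FALSE)
  m <- nchar(motif)
  rots <- function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1L]]
    vapply(seq_along(x), function(i) {
      paste(c(x[i:length(x)], if (i > 1L) x[1:(i - 1L)]), collapse = "")
    }, "")
  }
  variants <- unique(c(rots(motif), rots(revcomp(motif))))
  var_chars <- lapply(variants, function(v) strsplit(v, "", fixed = TRUE)[[1L]])

  measure_end <- function(chars, end) {
    n <- length(chars)
    best <- c(tract = 0, copies = 0, mism = 0)
    max_copies <- n %/% m
    if (max_copies == 0L) return(best)
    for (vc in var_chars) {
      copies_ok <- 0L
      total_mism <- 0L
      run_mism <- 0L
      fails <- 0L
      i <- 1L
      while (i <= max_copies && fails < 2L) {
        idx <- if (end == "3prime") {
          (n - i * m + 1L):(n - (i - 1L) * m)
        } else {
          ((i - 1L) * m + 1L):(i * m)
        }
        mism <- sum(chars[idx] != vc)
        if (mism <= max_mismatch_per_copy) {
          fails <- 0L
          copies_ok <- i
          run_mism <- run_mism + mism
        } else {
          fails <- fails + 1L
        }
        i <- i + 1L
      }
      if (copies_ok > best["copies"]) {
        best <- c(tract = copies_ok * m, copies = copies_ok,
                  mism = run_mism)
      }
    }
    best
  }

  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- list()
  for (nm in names(seqs)) {
    chars <- strsplit(toupper(seqs[[nm]]), "", fixed = TRUE)[[1L]]
    for (end in c("5prime", "3prime")) {
      r <- measure_end(chars, end)
      rows[[length(rows) + 1L]] <- data.frame(
        seq = nm, end = end,
        tract_length_bp = unname(r["tract"]),
        copies = unname(r["copies"]),
        mismatch_fraction = if (r["tract"] > 0)
          unname(r["mism"] / r["tract"]) else NA_real_
      )
    }
  }
  per_end <- do.call(rbind, rows)
  per_seq <- tapply(per_end$tract_length_bp, per_end$seq, max)
  tr <- per_seq[per_seq > 0]
  summ <- if (length(tr)) {
    data.frame(n = length(tr), min = min(tr),
               q25 = unname(quantile(tr, 0.25)),
               median = median(tr),
               q75 = unname(quantile(tr, 0.75)), max = max(tr))
  } else {
    data.frame(n = 0L, min = NA_real_, q25 = NA_real_, median = NA_real_,
               q75 = NA_real_, max = NA_real_)
  }
  structure(list(per_end = per_end, summary = summ, motif = motif),
            class = "telomere_measure")
}

#' @export
print.telomere_measure <- function(x, ...) {
  cat("Telomere tracts (motif ", x$motif, "): ", x$summary$n,
      " sequence(s) with a tract", sep = "")
  if (x$summary$n > 0) {
    cat(sprintf("; median %d bp, max %d bp", round(x$summary$median),
                round(x$summary$max)))
  }
  cat("\n")
  invisible(x)
}
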