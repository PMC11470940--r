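# Solo vs intact LTR classification, solo:intact ratios, insertion-age
# dating and TE class summaries.

#' Classify solo LTRs with the six-filter rule set
#'
#' A homology-method LTR candidate is accepted as a solo LTR only if all of
#' the following hold, checked in order with the first failure recorded:
#' \enumerate{
#'   \item length >= 100 bp;
#'   \item identity to the reference LTR >= 0.8;
#'   \item alignment score >= 300;
#'   \item the four nearest flanking LTR-RT annotations (two upstream, two
#'     downstream on the same chromosome) do not share one element ID among
#'     themselves;
#'   \item distance >= 5000 bp to the nearest adjacent annotation
#'     (solo-LTR candidate, intact LTR or internal sequence);
#'   \item length <= the 95th percentile of intact-element LTR lengths.
#' }
#'
#' @param annotation A `te_annotation_set` (see [sim_te_gff()] /
#'   [read_te_gff()]).
#' @return A `solo_ltr_report`: per-candidate verdicts (`rule` = `"pass"`
#'   or the first violated filter), per-chromosome solo/intact counts, and
#'   the 95th-percentile length bound used.
#' @examples
#' sim <- sim_te_gff(4, 5, 6, 1e6, seed = 1)
#' report <- classify_solo_ltrs(sim$annotation)
#' table(report$verdicts$rule)
#' @export
classify_solo_ltrs <- function(annotation) {
  stopifnot(is.data.frame(annotation))
  ann <- annotation[order(annotation$chrom, annotation$start), , drop = FALSE]
  cand_idx <- which(ann$role == "candidate" |
                      (!is.na(ann$method) & ann$method == "homology"))
  cand_idx <- unique(cand_idx)
  intact_lens <- ann$ltr_len[ann$role == "intact" & !is.na(ann$ltr_len)]
  pct_skipped <- length(intact_lens) == 0L
  if (pct_skipped) {
    warning("no intact LTRs present; the length-percentile rule is skipped")
    len_bound <- Inf
  } else {
    len_bound <- quantile(intact_lens, 0.95, names = FALSE)
  }

  verdict <- character(length(cand_idx))
  for (j in seq_along(cand_idx)) {
    i <- cand_idx[j]
    len <- ann$end[i] - ann$start[i] + 1L
    same_chr <- which(ann$chrom == ann$chrom[i])
    others <- setdiff(same_chr, i)
    rule <- "pass"
    if (len < 100L) {
      rule <- "length"
    } else if (is.na(ann$identity[i]) || ann$identity[i] < 0.8) {
      rule <- "identity"
    } else if (is.na(ann$score[i]) || ann$score[i] < 300) {
      rule <- "score"
    } else {
      up <- others[ann$end[others] < ann$start[i]]
      dn <- others[ann$start[others] > ann$end[i]]
      up <- up[order(ann$end[up], decreasing = TRUE)]
      dn <- dn[order(ann$start[dn])]
      flank <- c(head(up, 2L), head(dn, 2L))
      ids <- ann$ltr_rt_id[flank]
      ids <- ids[!is.na(ids)]
      if (length(ids) && anyDuplicated(ids)) {
        rule <- "shared_id_adjacency"
      } else {
        overlaps <- others[ann$start[others] <= ann$end[i] &
                             ann$end[others] >= ann$start[i]]
        gaps <- c(ann$start[i] - ann$end[others[ann$end[others] < ann$start[i]]],
                  ann$start[others[ann$start[others] > ann$end[i]]] - ann$end[i],
                  if (length(overlaps)) 0)
        min_gap <- if (length(gaps)) min(gaps) else Inf
        if (min_gap < 5000) {
          rule <- "distance"
        } else if (len > len_bound) {
          rule <- "length_percentile"
        }
      }
    }
    verdict[j] <- rule
  }

  verdicts <- data.frame(
    ltr_rt_id = ann$ltr_rt_id[cand_idx],
    chrom = ann$chrom[cand_idx],
    start = ann$start[cand_idx],
    end = ann$end[cand_idx],
    rule = verdict,
    solo = verdict == "pass",
    stringsAsFactors = FALSE
  )
  chroms <- sort(unique(ann$chrom))
  counts <- data.frame(
    chrom = chroms,
    n_solo = vapply(chroms, function(ch)
      sum(verdicts$solo & verdicts$chrom == ch), 0L),
    n_intact = vapply(chroms, function(ch)
      sum(ann$role == "intact" & ann$chrom == ch), 0L),
    row.names = NULL
  )
  structure(list(verdicts = verdicts, counts = counts,
                 length_bound_95 = len_bound,
                 percentile_rule_skipped = pct_skipped),
            class = "solo_ltr_report")
}

#' @export
print.solo_ltr_report <- function(x, ...) {
  cat("Solo-LTR report: ", sum(x$verdicts$solo), " solo / ",
      nrow(x$verdicts), " candidates; ", sum(x$counts$n_intact),
      " intact elements\n", sep = "")
  rej <- table(x$verdicts$rule[!x$verdicts$solo])
  if (length(rej)) {
    cat("  rejections:",
        paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
  }
  if (x$percentile_rule_skipped) {
    cat("  [length-percentile rule skipped: no intact LTRs]\n")
  }
  invisible(x)
}

#' Solo-to-intact LTR ratio
#'
#' High solo:intact ratios indicate aggressive purging of LTR
#' retrotransposons by intra-element recombination.
#'
#' @param report A `solo_ltr_report`.
#' @param by `"chromosome"` or `"genome"`.
#' @return Data frame with n_solo, n_intact, ratio and an `undefined` flag
#'   for zero-intact groups.
#' @export
solo_intact_ratio <- function(report, by = c("genome", "chromosome")) {
  by <- match.arg(by)
  tab <- if (by == "chromosome") report$counts else {
    data.frame(chrom = "genome",
               n_solo = sum(report$counts$n_solo),
               n_intact = sum(report$counts$n_intact))
  }
  tab$undefined <- tab$n_intact == 0L
  tab$ratio <- ifelse(tab$undefined, NA_real_, tab$n_solo / tab$n_intact)
  tab
}

#' LTR insertion age from the divergence of its two terminal repeats
#'
#' The two LTRs of a retrotransposon are identical at insertion; their
#' p-distance, Jukes-Cantor corrected (d = -3/4 ln(1 - 4/3 p)) and divided
#' by twice the substitution rate, gives the insertion age.
#'
#' @param ltr5_seq,ltr3_seq Aligned 5' and 3' LTR sequences (equal length;
#'   gap characters `-` allowed and excluded column-wise).
#' @param rate Substitution rate per site per year; default 4.72e-9.
#' @param correction `"JC"` (default) or `"raw"` (uncorrected p-distance).
#' @return An `insertion_age` list: `p_distance`, `divergence` (corrected),
#'   `age_years`, `rate`.
#' @examples
#' a <- strrep("ACGT", 250)
#' ltr_insertion_age(a, a)$age_years
#' @export
ltr_insertion_age <- function(ltr5_seq, ltr3_seq, rate = 4.72e-9,
                              correction = c("JC", "raw")) {
  correction <- match.arg(correction)
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  a <- strsplit(toupper(ltr5_seq), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(ltr3_seq), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("LTR sequences must be aligned to equal length", call. = FALSE)
  }
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("alignment has no ungapped columns", call. = FALSE)
  p <- mean(a[keep] != b[keep])
  if (correction == "JC") {
    if (p >= 0.75) {
      stop("saturated divergence: p >= 0.75, Jukes-Cantor correction undefined",
           call. = FALSE)
    }
    d <- -0.75 * log(1 - 4 / 3 * p)
  } else {
    d <- p
  }
  structure(list(p_distance = p, divergence = d,
                 age_years = d / (2 * rate), rate = rate,
                 correction = correction),
            class = "insertion_age")
}

#' @export
print.insertion_age <- function(x, ...) {
  cat(sprintf("LTR insertion age: %.3g years (p = %.4g, d = %.4g, rate = %g/site/yr, %s)\n",
              x$age_years, x$p_distance, x$divergence, x$rate, x$correction))
  invisible(x)
}

#' Per-class TE summary
#'
#' Counts records and genome coverage per TE superfamily, merging
#' overlapping intervals within a class before measuring covered bp.
#'
#' @param annotation A `te_annotation_set`.
#' @param genome_length_bp Genome length for percentages.
#' @return Data frame: te_class, n_records, bp_covered, pct_genome, plus a
#'   `total` row.
#' @export
te_summary <- function(annotation, genome_length_bp) {
  if (genome_length_bp <= 0) {
    stop("`genome_length_bp` must be positive", call. = FALSE)
  }
  over <- which(annotation$end > genome_length_bp)
  if (length(over)) {
    stop(sprintf("record %d (%s:%d-%d) extends beyond the genome length",
                 over[1L], annotation$chrom[over[1L]],
                 annotation$start[over[1L]], annotation$end[over[1L]]),
         call. = FALSE)
  }
  merged_bp <- function(df) {
    total <- 0
    for (ch in unique(df$chrom)) {
      d <- df[df$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      cur_s <- d$start[1L]; cur_e <- d$end[1L]
      for (i in seq_len(nrow(d))[-1L]) {
        if (d$start[i] <= cur_e + 1L) {
          cur_e <- max(cur_e, d$end[i])
        } else {
          total <- total + (cur_e - cur_s + 1L)
          cur_s <- d$start[i]; cur_e <- d$end[i]
        }
      }
      total <- total + (cur_e - cur_s + 1L)
    }
    total
  }
  classes <- sort(unique(annotation$te_class))
  out <- do.call(rbind, lapply(classes, function(cl) {
    d <- annotation[annotation$te_class == cl, , drop = FALSE]
    bp <- merged_bp(d)
    data.frame(te_class = cl, n_records = nrow(d), bp_covered = bp,
               pct_genome = 100 * bp / genome_length_bp)
  }))
  total_bp <- merged_bp(annotation)
  rbind(out, data.frame(te_class = "total", n_records = nrow(annotation),
                        bp_covered = total_bp,
                        pct_genome = 100 * total_bp / genome_length_bp))
}

#' Export accepted solo LTRs as BED (0-based half-open)
#'
#' @param report A `solo_ltr_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solo_bed <- function(report, path) {
  v <- report$verdicts[report$verdicts$solo, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", v$chrom, v$start - 1L, v$end,
                     v$ltr_rt_id), path)
  invisible(path)
}
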