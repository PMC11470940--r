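# Nei-Gojobori (1986) synonymous distances, Ks peak detection and
# rate-based dating of whole-genome multiplication events.

.ng86_cache <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.ng86_cache$code)) {
    .ng86_cache$code <- Biostrings::GENETIC_CODE
  }
  .ng86_cache$code
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Synonymous site count of one codon: per position, the fraction of
# non-stop single-base changes that are synonymous (changes to stop codons
# are excluded from the site denominator).
ng86_syn_sites <- function(codon) {
  if (is.null(.ng86_cache$sites)) .ng86_cache$sites <- list()
  hit <- .ng86_cache$sites[[codon]]
  if (!is.null(hit)) return(hit)
  code <- codon_table()
  aa <- code[[codon]]
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(DNA_BASES, chars[pos])
    syn <- 0L
    valid <- 0L
    for (b in alts) {
      mut <- chars
      mut[pos] <- b
      mut_codon <- paste(mut, collapse = "")
      mut_aa <- code[[mut_codon]]
      if (mut_aa == "*") next
      valid <- valid + 1L
      if (mut_aa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  .ng86_cache$sites[[codon]] <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons: all orders of the differing positions are enumerated, pathways
# through stop codons are excluded (unless all are blocked), and counts are
# averaged over the remaining pathways.
ng86_diffs <- function(codon_a, codon_b) {
  key <- paste0(codon_a, codon_b)
  if (is.null(.ng86_cache$diffs)) .ng86_cache$diffs <- list()
  hit <- .ng86_cache$diffs[[key]]
  if (!is.null(hit)) return(hit)
  code <- codon_table()
  a <- strsplit(codon_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(codon_b, "", fixed = TRUE)[[1L]]
  pos <- which(a != b)
  if (!length(pos)) {
    out <- c(sd = 0, nd = 0)
  } else {
    perms <- if (length(pos) == 1L) list(pos) else {
      # all orderings of the differing positions
      perm_list <- list()
      gen <- function(prefix, rest) {
        if (!length(rest)) {
          perm_list[[length(perm_list) + 1L]] <<- prefix
        } else {
          for (i in seq_along(rest)) {
            gen(c(prefix, rest[i]), rest[-i])
          }
        }
      }
      gen(integer(0), pos)
      perm_list
    }
    tally <- function(order_pos, allow_stop) {
      cur <- a
      sd <- 0L; nd <- 0L
      for (p in order_pos) {
        nxt <- cur
        nxt[p] <- b[p]
        aa_cur <- code[[paste(cur, collapse = "")]]
        aa_nxt <- code[[paste(nxt, collapse = "")]]
        if (!allow_stop && (aa_nxt == "*" || aa_cur == "*")) return(NULL)
        if (aa_cur == aa_nxt) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, tally, allow_stop = FALSE))
    if (!length(res)) res <- lapply(perms, tally, allow_stop = TRUE)
    mat <- do.call(rbind, res)
    out <- colMeans(mat)
  }
  .ng86_cache$diffs[[key]] <- out
  out
}

#' Synonymous distance between two codon-aligned coding sequences
#'
#' Nei-Gojobori (1986): synonymous site counts are averaged over the two
#' sequences (mutations to stop codons excluded from the site counts),
#' differences at multi-hit codons are averaged over all mutational
#' pathways, and the proportion of synonymous differences pS = Sd/S is
#' Jukes-Cantor corrected to Ks = -3/4 ln(1 - 4/3 pS).
#'
#' @param cds_a,cds_b Codon-aligned CDS strings of equal length, divisible
#'   by 3, with gap columns removed and no internal stop codons.
#' @param gene_a,gene_b Optional identifiers carried through to the output.
#' @return A `ks_record` list: `S`, `Sd`, `pS`, `Ks`, `N`, `Nd`,
#'   `saturated` (TRUE with infinite Ks when pS >= 0.75).
#' @examples
#' compute_ks(strrep("GGG", 10), paste0(strrep("GGG", 9), "GGA"))$Ks
#' @export
compute_ks <- function(cds_a, cds_b, gene_a = "a", gene_b = "b") {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (length(ca) != length(cb)) {
    stop("sequences must be codon-aligned to equal length", call. = FALSE)
  }
  code <- codon_table()
  if (any(code[ca] == "*") || any(code[cb] == "*")) {
    stop("internal stop codon in input CDS", call. = FALSE)
  }
  s_a <- sum(vapply(ca, ng86_syn_sites, 0))
  s_b <- sum(vapply(cb, ng86_syn_sites, 0))
  S <- (s_a + s_b) / 2
  n_sites_total <- 3 * length(ca)
  N <- n_sites_total - S
  sd_total <- 0
  nd_total <- 0
  for (i in seq_along(ca)) {
    if (ca[i] != cb[i]) {
      d <- ng86_diffs(ca[i], cb[i])
      sd_total <- sd_total + d[["sd"]]
      nd_total <- nd_total + d[["nd"]]
    }
  }
  pS <- if (S > 0) sd_total / S else 0
  saturated <- pS >= 0.75
  Ks <- if (saturated) Inf else -0.75 * log(1 - 4 / 3 * pS)
  structure(list(gene_a = gene_a, gene_b = gene_b, S = S, Sd = sd_total,
                 pS = pS, Ks = Ks, N = N, Nd = nd_total,
                 saturated = saturated),
            class = "ks_record")
}

#' @export
print.ks_record <- function(x, ...) {
  cat(sprintf("Ks(%s, %s): %s  (S = %.2f, Sd = %.2f, pS = %.4f%s)\n",
              x$gene_a, x$gene_b,
              if (x$saturated) "saturated" else sprintf("%.4f", x$Ks),
              x$S, x$Sd, x$pS,
              if (x$saturated) ", pS >= 0.75" else ""))
  invisible(x)
}

#' Detect peaks in a Ks distribution
#'
#' Gaussian kernel density over (0, `range[2]`]; peaks are local maxima
#' with density at least 10% of the global maximum, returned ascending with
#' the mixture weight of values assigned to each peak by proximity.
#'
#' @param ks_values Numeric Ks values; non-finite (saturated) values are
#'   dropped.
#' @param bandwidth Kernel bandwidth; default `stats::bw.nrd0`.
#' @param range Interval considered; default `c(0, 3)`.
#' @return Data frame: ks_mode, density, weight (ascending in ks_mode).
#' @examples
#' ks_peaks(c(rnorm(300, 0.1, 0.03), rnorm(300, 0.8, 0.1)))
#' @export
ks_peaks <- function(ks_values, bandwidth = NULL, range = c(0, 3)) {
  x <- ks_values[is.finite(ks_values) & ks_values > range[1L] &
                   ks_values <= range[2L]]
  if (!length(x)) {
    stop("no finite Ks values in range (all saturated or empty input)",
         call. = FALSE)
  }
  if (length(x) < 50L) {
    warning("fewer than 50 finite Ks values; peaks may be unstable")
  }
  dens <- if (is.null(bandwidth)) {
    density(x, from = range[1L], to = range[2L], n = 1024L)
  } else {
    density(x, bw = bandwidth, from = range[1L], to = range[2L], n = 1024L)
  }
  y <- dens$y
  n <- length(y)
  is_max <- y >= c(-Inf, y[-n]) & y >= c(y[-1L], -Inf) &
    y >= 0.1 * max(y)
  idx <- which(is_max)
  # collapse plateaus
  if (length(idx) > 1L) {
    idx <- idx[c(TRUE, diff(idx) > 1L)]
  }
  # merge micro-modes closer than twice the kernel bandwidth (taller wins)
  if (length(idx) > 1L) {
    min_sep <- max(2 * dens$bw, 0.05)
    keep <- integer(0)
    for (i in idx[order(-y[idx])]) {
      if (!length(keep) || all(abs(dens$x[i] - dens$x[keep]) >= min_sep)) {
        keep <- c(keep, i)
      }
    }
    idx <- sort(keep)
  }
  modes <- dens$x[idx]
  assign_peak <- vapply(x, function(v) which.min(abs(v - modes)), 0L)
  weight <- tabulate(assign_peak, nbins = length(modes)) / length(x)
  out <- data.frame(ks_mode = modes, density = y[idx], weight = weight)
  out[order(out$ks_mode), , drop = FALSE]
}

#' Convert a synonymous distance to an absolute time
#'
#' T = Ks / (2 r) with r the synonymous substitution rate per site per
#' year; the default rate is 6.56e-9.
#'
#' @param ks Synonymous distance(s), >= 0.
#' @param rate Substitution rate per site per year, > 0.
#' @return Time(s) in years.
#' @examples
#' ks_to_time(0.3936)  # ~3.0e7 years
#' @export
ks_to_time <- function(ks, rate = 6.56e-9) {
  if (any(ks < 0)) stop("`ks` must be non-negative", call. = FALSE)
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  ks / (2 * rate)
}

#' Codon-aware global alignment of two CDS (convenience)
#'
#' Translates both sequences, aligns the proteins globally (match 1,
#' mismatch -1, gap open/extend -2), back-threads the alignment onto
#' codons, and removes gap columns, producing input suitable for
#' [compute_ks()].
#'
#' @param cds_a,cds_b Unaligned CDS strings (length divisible by 3, no
#'   internal stops).
#' @return List with aligned, gap-free `a` and `b` CDS strings.
#' @export
align_codons <- function(cds_a, cds_b) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  code <- codon_table()
  aa_a <- paste(code[ca], collapse = "")
  aa_b <- paste(code[cb], collapse = "")
  alpha <- Biostrings::AA_ALPHABET
  sub_mat <- matrix(-1, length(alpha), length(alpha),
                    dimnames = list(alpha, alpha))
  diag(sub_mat) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    type = "global",
    substitutionMatrix = sub_mat, gapOpening = 2, gapExtension = 2
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  for (i in seq_along(pa)) {
    if (pa[i] != "-") ia <- ia + 1L
    if (ps[i] != "-") ib <- ib + 1L
    if (pa[i] != "-" && ps[i] != "-") {
      keep_a <- c(keep_a, ca[ia])
      keep_b <- c(keep_b, cb[ib])
    }
  }
  list(a = paste(keep_a, collapse = ""), b = paste(keep_b, collapse = ""))
}
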