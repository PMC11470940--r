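# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: literal formula transcriptions and brute-force
# enumerations frozen against the implementations they check.

# Weir & Cockerham (1984) variance components, written as a plain per-locus
# loop straight from the published formulas (diploid calls 0/1/2).
wc84_oracle <- function(gd, grp) {
  groups <- sort(unique(grp))
  r <- length(groups)
  n_loci <- ncol(gd)
  a <- b <- cc <- numeric(n_loci)
  for (l in seq_len(n_loci)) {
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_along(groups)) {
      gk <- gd[grp == groups[k], l]
      gk <- gk[!is.na(gk)]
      n_i[k] <- length(gk)
      p_i[k] <- sum(gk) / (2 * length(gk))
      h_i[k] <- mean(gk == 1)
    }
    n_tot <- sum(n_i)
    n_bar <- n_tot / r
    n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
    p_bar <- sum(n_i * p_i) / n_tot
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / n_tot
    a[l] <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) /
         (n_bar - 1))
    b[l] <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc[l] <- h_bar / 2
  }
  list(a = a, b = b, c = cc)
}

# Exhaustive synteny chaining: enumerates every collinear chain (both
# orientations) by depth-first search, then applies the same greedy
# best-first extraction and tie-break policy as the chainer.  Feasible for
# <= ~15 anchors.
enumerate_best_chain <- function(a, max_gap) {
  n <- nrow(a)
  q <- a$query_ord
  t <- a$target_ord
  best <- NULL
  lex_precedes <- function(qx, tx, qy, ty) {
    m <- min(length(qx), length(qy))
    for (i in seq_len(m)) {
      if (qx[i] != qy[i]) return(qx[i] < qy[i])
      if (tx[i] != ty[i]) return(tx[i] < ty[i])
    }
    length(qx) < length(qy)
  }
  consider <- function(chain_idx, orientation) {
    cand <- list(idx = chain_idx, len = length(chain_idx),
                 ori = orientation)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    better <- FALSE
    if (cand$len > best$len) {
      better <- TRUE
    } else if (cand$len == best$len) {
      if (lex_precedes(q[cand$idx], t[cand$idx], q[best$idx], t[best$idx])) {
        better <- TRUE
      } else if (!lex_precedes(q[best$idx], t[best$idx],
                               q[cand$idx], t[cand$idx]) &&
                 cand$ori == "+" && best$ori == "-") {
        better <- TRUE  # identical chains: forward orientation preferred
      }
    }
    if (better) best <<- cand
  }
  extend <- function(chain_idx, orientation) {
    consider(chain_idx, orientation)
    last <- chain_idx[length(chain_idx)]
    for (i in seq_len(n)) {
      gq <- q[i] - q[last]
      if (gq <= 0 || gq > max_gap) next
      gt <- if (orientation == "+") t[i] - t[last] else t[last] - t[i]
      if (gt <= 0 || gt > max_gap) next
      extend(c(chain_idx, i), orientation)
    }
  }
  for (ori in c("+", "-")) {
    for (s in seq_len(n)) extend(s, ori)
  }
  best
}

oracle_chain_blocks <- function(anchors, min_anchors, max_gap) {
  blocks <- list()
  pairs <- unique(anchors[, c("query_chrom", "target_chrom")])
  for (p in seq_len(nrow(pairs))) {
    a <- anchors[anchors$query_chrom == pairs$query_chrom[p] &
                   anchors$target_chrom == pairs$target_chrom[p], ,
                 drop = FALSE]
    rownames(a) <- NULL
    repeat {
      if (nrow(a) < min_anchors) break
      best <- enumerate_best_chain(a, max_gap)
      if (is.null(best) || best$len < min_anchors) break
      blk <- a[best$idx, , drop = FALSE]
      blk <- blk[order(blk$query_ord), , drop = FALSE]
      rownames(blk) <- NULL
      blocks[[length(blocks) + 1L]] <- list(
        query_chrom = pairs$query_chrom[p],
        target_chrom = pairs$target_chrom[p],
        orientation = best$ori,
        anchors = blk
      )
      a <- a[-best$idx, , drop = FALSE]
      rownames(a) <- NULL
    }
  }
  blocks
}

# Shift-identity score used as the autocorrelation oracle for tandem
# arrays (independent of detect_tandem_structure's scan machinery).
shift_identity <- function(seq, p) {
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(x[1:(length(x) - p)] == x[(p + 1):length(x)])
}

# Per-base identity between two equal-length ungapped sequences.
direct_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(x == y)
}

random_anchor_instance <- function(n, seed) {
  set.seed(seed)
  a <- data.frame(
    query_chrom = "q1",
    query_ord = sample.int(30L, n, replace = TRUE),
    target_chrom = "t1",
    target_ord = sample.int(30L, n, replace = TRUE),
    score = 100
  )
  a <- a[!duplicated(a[, c("query_ord", "target_ord")]), , drop = FALSE]
  rownames(a) <- NULL
  class(a) <- c("anchor_set", "data.frame")
  attr(a, "query_gene_count") <- 30L
  a
}

block_signature <- function(blocks) {
  lapply(blocks, function(b) {
    list(q = b$query_chrom, t = b$target_chrom, ori = b$orientation,
         anchors = paste(b$anchors$query_ord, b$anchors$target_ord,
                         sep = ":", collapse = ","))
  })
}
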