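# Collinear anchor chaining into synteny blocks; syntenic depth and
# gene-retention profiles.

# Longest collinear chain among anchors of one chromosome pair, one
# orientation.  Anchors must be a data.frame with query_ord / target_ord.
# Exact dynamic program over the collinearity DAG: successor j of i needs
# q_j > q_i, t_j > t_i (or < for orientation "-"), both gaps <= max_gap.
# Among maximum-length chains the lexicographically smallest sequence of
# (query_ord, target_ord) pairs is returned, reconstructed greedily from a
# start-anchored DP (the first anchor dominates the lexicographic order,
# so picking the smallest valid anchor at each step is exact).
best_chain <- function(a, orientation, max_gap) {
  n <- nrow(a)
  q <- a$query_ord
  t <- a$target_ord
  succ_ok <- function(i, j) {
    gq <- q[j] - q[i]
    if (gq <= 0L || gq > max_gap) return(FALSE)
    gt <- if (orientation == "+") t[j] - t[i] else t[i] - t[j]
    gt > 0L && gt <= max_gap
  }
  ord_desc <- order(-q, -t)
  dp <- rep(1L, n)
  for (i in ord_desc) {
    for (j in seq_len(n)) {
      if (succ_ok(i, j) && dp[j] + 1L > dp[i]) dp[i] <- dp[j] + 1L
    }
  }
  L <- max(dp)
  pick_min <- function(idx) idx[order(q[idx], t[idx])[1L]]
  cur <- pick_min(which(dp == L))
  chain <- cur
  remaining <- L - 1L
  while (remaining > 0L) {
    succ <- which(vapply(seq_len(n), function(j)
      succ_ok(cur, j) && dp[j] == remaining, logical(1)))
    cur <- pick_min(succ)
    chain <- c(chain, cur)
    remaining <- remaining - 1L
  }
  list(rows = chain, length = L, orientation = orientation)
}

# Lexicographic comparison of two chains over (query_ord, target_ord)
# pairs; returns TRUE when chain `x` precedes chain `y`.
chain_precedes <- function(qx, tx, qy, ty) {
  m <- min(length(qx), length(qy))
  for (i in seq_len(m)) {
    if (qx[i] != qy[i]) return(qx[i] < qy[i])
    if (tx[i] != ty[i]) return(tx[i] < ty[i])
  }
  length(qx) < length(qy)
}

#' Chain collinear anchors into synteny blocks
#'
#' Per chromosome pair, anchors collinear in both genomes (both
#' orientations tried) are chained by dynamic programming with a gene-rank
#' gap limit; chain score is the anchor count.  Blocks are extracted
#' greedily best-score first (ties resolved to the lexicographically
#' smallest chain of (query, target) ranks — so the earlier query position
#' wins — then to the forward orientation), each anchor joining at most one
#' block; chains shorter than `min_anchors` are discarded.
#'
#' @param anchors An `anchor_set` (see [sim_anchor_sets()] /
#'   [read_anchors_tsv()]).
#' @param min_anchors Minimum anchors per block (default 4).
#' @param max_gap_genes Maximum rank gap between consecutive anchors in
#'   either genome (default 20).
#' @return A `synteny_blocks` list of blocks (query_chrom, target_chrom,
#'   orientation, anchors data.frame) with attribute `query_gene_count`.
#' @examples
#' sim <- sim_anchor_sets(60, c(1, 0, 0, 0, 0), 0, seed = 1)
#' length(chain_anchors(sim$anchors))
#' @export
chain_anchors <- function(anchors, min_anchors = 4L, max_gap_genes = 20L) {
  stopifnot(is.data.frame(anchors))
  key <- paste(anchors$query_chrom, anchors$query_ord,
               anchors$target_chrom, anchors$target_ord)
  if (anyDuplicated(key)) {
    warning("duplicate identical anchors collapsed")
    anchors <- anchors[!duplicated(key), , drop = FALSE]
  }
  blocks <- list()
  pairs <- unique(anchors[, c("query_chrom", "target_chrom")])
  for (p in seq_len(nrow(pairs))) {
    sel <- anchors$query_chrom == pairs$query_chrom[p] &
      anchors$target_chrom == pairs$target_chrom[p]
    a <- anchors[sel, , drop = FALSE]
    rownames(a) <- NULL
    repeat {
      if (nrow(a) < min_anchors) break
      cand <- list(best_chain(a, "+", max_gap_genes),
                   best_chain(a, "-", max_gap_genes))
      lens <- vapply(cand, `[[`, 0L, "length")
      pick <- if (lens[1L] != lens[2L]) {
        which.max(lens)
      } else if (chain_precedes(a$query_ord[cand[[2L]]$rows],
                                a$target_ord[cand[[2L]]$rows],
                                a$query_ord[cand[[1L]]$rows],
                                a$target_ord[cand[[1L]]$rows])) {
        2L  # the "-" chain strictly precedes lexicographically
      } else 1L
      ch <- cand[[pick]]
      if (ch$length < min_anchors) break
      blk_anchors <- a[ch$rows, , drop = FALSE]
      blk_anchors <- blk_anchors[order(blk_anchors$query_ord), , drop = FALSE]
      rownames(blk_anchors) <- NULL
      blocks[[length(blocks) + 1L]] <- list(
        query_chrom = pairs$query_chrom[p],
        target_chrom = pairs$target_chrom[p],
        orientation = ch$orientation,
        n_anchors = ch$length,
        anchors = blk_anchors
      )
      a <- a[-ch$rows, , drop = FALSE]
      rownames(a) <- NULL
    }
  }
  structure(blocks,
            query_gene_count = attr(anchors, "query_gene_count"),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("Synteny blocks: ", length(x), " block(s), ",
      sum(vapply(x, `[[`, 0L, "n_anchors")), " anchors\n", sep = "")
  for (i in seq_along(head(x, 10L))) {
    b <- x[[i]]
    cat(sprintf("  %s ~ %s (%s): %d anchors, query %d-%d\n",
                b$query_chrom, b$target_chrom, b$orientation, b$n_anchors,
                min(b$anchors$query_ord), max(b$anchors$query_ord)))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Syntenic depth and gene copy-retention profile
#'
#' Per query gene, depth is the number of synteny blocks containing an
#' anchor for that gene.  The headline syntenic-depth ratio is the modal
#' non-zero depth (reported as "d:1"), and the retention profile gives the
#' fraction of query genes found in 1..5 copies, with the depth-0
#' (fully fractionated / unanchored) share reported alongside.
#'
#' @param blocks A `synteny_blocks` object.
#' @param query_gene_count Number of query genes; defaults to the
#'   attribute carried by the anchor set.
#' @return A `retention_profile` list: `depth` (per-gene integer vector),
#'   `ratio` ("d:1" string), `modal_depth`, `retention` (named fractions
#'   for depths 0..5) and `depth_gt5` fraction.
#' @examples
#' sim <- sim_anchor_sets(200, c(0, 0, 0, 1, 0), 0, seed = 1)
#' depth_and_retention(chain_anchors(sim$anchors))$ratio
#' @export
depth_and_retention <- function(blocks, query_gene_count = NULL) {
  if (is.null(query_gene_count)) {
    query_gene_count <- attr(blocks, "query_gene_count")
  }
  if (is.null(query_gene_count)) {
    query_gene_count <- max(vapply(blocks, function(b)
      max(b$anchors$query_ord), 0L))
  }
  depth <- integer(query_gene_count)
  for (b in blocks) {
    g <- unique(b$anchors$query_ord)
    depth[g] <- depth[g] + 1L
  }
  modal_depth <- if (any(depth > 0L)) {
    tab <- tabulate(depth[depth > 0L])
    which.max(tab)
  } else NA_integer_
  retention <- vapply(0:5, function(d) mean(depth == d), 0)
  names(retention) <- paste0("depth", 0:5)
  structure(list(
    depth = depth,
    modal_depth = modal_depth,
    ratio = if (is.na(modal_depth)) NA_character_
            else paste0(modal_depth, ":1"),
    retention = retention,
    depth_gt5 = mean(depth > 5L),
    query_gene_count = as.integer(query_gene_count)
  ), class = "retention_profile")
}

#' @export
print.retention_profile <- function(x, ...) {
  cat("Syntenic depth ratio: ", x$ratio, "\n", sep = "")
  cat("  retention (fraction of genes at depth 0..5):\n  ")
  cat(paste(sprintf("%d: %.1f%%", 0:5, 100 * x$retention), collapse = "  "),
      "\n")
  if (x$depth_gt5 > 0) {
    cat(sprintf("  depth > 5: %.1f%%\n", 100 * x$depth_gt5))
  }
  invisible(x)
}
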