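# Simulators for TE annotations and synteny anchor sets.

SOLO_RULES <- c("length", "identity", "score", "shared_id_adjacency",
                "distance", "length_percentile")

TE_CLASSES <- c("Copia", "Gypsy", "Mutator", "CACTA")

#' Simulate a TE annotation with planted solo/intact/decoy labels
#'
#' Emits an EDTA-dialect annotation containing intact LTR retrotransposons
#' (structural records), true solo-LTR candidates (homology records passing
#' every filter), and decoy candidates each of which violates exactly one of
#' the six solo-LTR filters: minimum length 100 bp, minimum identity 0.8,
#' minimum alignment score 300, no shared element ID among the four nearest
#' flanking LTR-RT annotations, minimum 5000 bp distance to the nearest
#' adjacent annotation, and length within the 95th percentile of intact-LTR
#' lengths.  The violated rule of every decoy is recorded in the truth
#' object, making the classifier's confusion matrix fully determined.
#'
#' @param n_intact Number of intact LTR retrotransposons.
#' @param n_solo Number of true solo-LTR candidates.
#' @param n_decoys Number of decoys; rules are assigned by cycling through
#'   the six filters in order.
#' @param chrom_length_bp Chromosome length; must accommodate all records
#'   with >= 5000 bp spacing.
#' @param seed Integer seed.
#' @return List with `annotation` (a `te_annotation_set` data.frame) and
#'   `truth` (per-candidate labels: `"solo"` or the violated rule name).
#' @examples
#' sim <- sim_te_gff(n_intact = 4, n_solo = 5, n_decoys = 6,
#'                   chrom_length_bp = 1e6, seed = 1)
#' table(sim$truth$planted_params$labels)
#' @export
sim_te_gff <- function(n_intact, n_solo, n_decoys, chrom_length_bp,
                       seed = 1L) {
  if (n_decoys > 0L && n_intact < 2L) {
    stop("need >= 2 intact elements to define the length percentile for decoys",
         call. = FALSE)
  }
  with_seed(seed, {
    gap <- 6000L
    rules <- if (n_decoys > 0L) {
      rep(SOLO_RULES, length.out = n_decoys)
    } else character(0)

    rec <- list()
    cand_label <- character(0)
    cand_id <- character(0)
    pos <- 1L
    te_counter <- 0L

    add <- function(len, type, method, identity, score, ltr_rt_id, role,
                    ltr_len = NA_real_, offset = gap) {
      len <- as.integer(len)
      start <- as.integer(pos + offset)
      rec[[length(rec) + 1L]] <<- data.frame(
        chrom = "chr1", start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L), type = type,
        te_class = sample(TE_CLASSES, 1L), method = method,
        identity = identity, score = score, ltr_rt_id = ltr_rt_id,
        role = role, ltr_len = ltr_len, stringsAsFactors = FALSE
      )
      pos <<- start + len - 1L
    }
    new_id <- function() {
      te_counter <<- te_counter + 1L
      sprintf("TE_%08d", te_counter)
    }
    add_intact <- function() {
      add(round(runif(1, 5000, 9000)), "LTR_retrotransposon", "structural",
          NA_real_, NA_real_, new_id(), "intact",
          ltr_len = round(runif(1, 480, 520)))
    }
    add_solo <- function(label, len = round(runif(1, 150, 450)),
                         identity = runif(1, 0.85, 0.99),
                         score = round(runif(1, 400, 2000)),
                         offset = gap) {
      id <- new_id()
      add(len, "long_terminal_repeat", "homology", identity, score, id,
          "candidate", offset = offset)
      cand_label <<- c(cand_label, label)
      cand_id <<- c(cand_id, id)
    }

    # interleave intacts and solos with clean spacing
    for (i in seq_len(max(n_intact, 1L))) {
      if (i <= n_intact) add_intact()
      if (i <= n_solo) add_solo("solo")
    }
    if (n_solo > n_intact) {
      for (i in seq_len(n_solo - n_intact)) add_solo("solo")
    }

    for (rule in rules) {
      switch(rule,
        length = add_solo(rule, len = 60L),
        identity = add_solo(rule, identity = runif(1, 0.4, 0.7)),
        score = add_solo(rule, score = round(runif(1, 50, 250))),
        length_percentile = add_solo(rule, len = 1200L),
        distance = add_solo(rule, offset = 4000L),
        shared_id_adjacency = {
          # a split element: two structural LTRs sharing one ID, the decoy
          # candidate centred between them, 5500 bp from each
          shared <- new_id()
          add(500L, "long_terminal_repeat", "structural", NA_real_,
              NA_real_, shared, "ltr")
          add_solo(rule, offset = 5500L)
          add(500L, "long_terminal_repeat", "structural", NA_real_,
              NA_real_, shared, "ltr", offset = 5500L)
        }
      )
    }

    annotation <- do.call(rbind, rec)
    if (max(annotation$end) > chrom_length_bp) {
      stop(sprintf(
        "cannot place %d records with >= 5000 bp spacing on %d bp (need %d bp)",
        nrow(annotation), chrom_length_bp, max(annotation$end)),
        call. = FALSE)
    }
    rownames(annotation) <- NULL
    class(annotation) <- c("te_annotation_set", "data.frame")
    truth <- new_sim_truth(
      "sim_te_gff", seed,
      list(n_intact = n_intact, n_solo = n_solo, n_decoys = n_decoys,
           labels = setNames(cand_label, cand_id))
    )
    list(annotation = annotation, truth = truth)
  })
}

#' Write a TE annotation set as GFF3 (EDTA TEanno dialect)
#'
#' Coordinates are 1-based inclusive; homology records carry
#' `Method=homology` and `Identity=` attributes with the alignment score in
#' the score column, matching the EDTA TEanno convention.
#'
#' @param annotation A `te_annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_gff <- function(annotation, path) {
  attrs <- sprintf(
    "ID=%s;Name=%s;Classification=LTR/%s;Method=%s%s%s",
    paste0(annotation$ltr_rt_id, "_", seq_len(nrow(annotation))),
    annotation$ltr_rt_id, annotation$te_class, annotation$method,
    ifelse(is.na(annotation$identity), "",
           sprintf(";Identity=%.4f", annotation$identity)),
    ifelse(is.na(annotation$ltr_len), "",
           sprintf(";ltr_length=%d", as.integer(annotation$ltr_len)))
  )
  lines <- sprintf("%s\tbaokit\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   annotation$chrom, annotation$type,
                   annotation$start, annotation$end,
                   ifelse(is.na(annotation$score), ".",
                          as.character(annotation$score)),
                   annotation$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a TE annotation set from an EDTA-dialect GFF3
#'
#' @param path GFF3 path.
#' @return A `te_annotation_set` data.frame.
#' @export
read_te_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) {
    stop(sprintf("malformed GFF3 line %d: expected 9 fields", bad[1L]),
         call. = FALSE)
  }
  f <- do.call(rbind, f)
  get_attr <- function(attr, key) {
    vapply(regmatches(attr, gregexpr(paste0("(^|;)", key, "=[^;]*"), attr)),
           function(x) if (length(x) && nzchar(x[1L]))
             sub(paste0(".*", key, "="), "", x[1L]) else NA_character_,
           "", USE.NAMES = FALSE)
  }
  attr_col <- f[, 9L]
  classification <- get_attr(attr_col, "Classification")
  annotation <- data.frame(
    chrom = f[, 1L],
    start = as.integer(f[, 4L]),
    end = as.integer(f[, 5L]),
    strand = f[, 7L],
    type = f[, 3L],
    te_class = sub("^LTR/", "", ifelse(is.na(classification), "other",
                                       classification)),
    method = get_attr(attr_col, "Method"),
    identity = suppressWarnings(as.numeric(get_attr(attr_col, "Identity"))),
    score = suppressWarnings(as.numeric(ifelse(f[, 6L] == ".", NA, f[, 6L]))),
    ltr_rt_id = get_attr(attr_col, "Name"),
    role = ifelse(f[, 3L] == "LTR_retrotransposon", "intact",
                  ifelse(get_attr(attr_col, "Method") == "homology",
                         "candidate", "ltr")),
    ltr_len = suppressWarnings(as.numeric(get_attr(attr_col, "ltr_length"))),
    stringsAsFactors = FALSE
  )
  class(annotation) <- c("te_annotation_set", "data.frame")
  annotation
}

#' Simulate a collinear anchor set with planted gene copy numbers
#'
#' Models post-polyploidy fractionation: every query gene is assigned a copy
#' number from `copy_number_probs` (over 1..5 copies) and placed, in query
#' order, on that many of five parallel target chromosomes, producing
#' collinear runs.  A `shuffle_rate` fraction of anchors is transposed at
#' random as noise.  Genes may also be dropped entirely (copy number 0) via
#' the optional `p_lost` parameter.
#'
#' @param n_genes Number of query genes (ordinals 1..n_genes).
#' @param copy_number_probs Probability vector over copy numbers 1..5
#'   (length 5, sums to 1 after adding `p_lost` handling).
#' @param shuffle_rate Fraction of anchors transposed as noise.
#' @param p_lost Probability a gene is lost entirely (depth 0).
#' @param seed Integer seed.
#' @return List with `anchors` (an `anchor_set` data.frame: query_chrom,
#'   query_ord, target_chrom, target_ord, score; attribute
#'   `query_gene_count`) and `truth` (per-gene copy numbers).
#' @examples
#' sim <- sim_anchor_sets(100, copy_number_probs = c(0, 0, 0, 1, 0),
#'                        shuffle_rate = 0, seed = 1)
#' table(sim$truth$planted_params$copy_number)
#' @export
sim_anchor_sets <- function(n_genes, copy_number_probs, shuffle_rate = 0,
                            p_lost = 0, seed = 1L) {
  if (length(copy_number_probs) != 5L ||
      abs(sum(copy_number_probs) - 1) > 1e-8) {
    stop("`copy_number_probs` must be a length-5 probability vector over copy numbers 1..5",
         call. = FALSE)
  }
  stopifnot_fraction(shuffle_rate, "shuffle_rate", 0, 1)
  stopifnot_fraction(p_lost, "p_lost", 0, 1)
  with_seed(seed, {
    copy_n <- sample(1:5, n_genes, replace = TRUE, prob = copy_number_probs)
    if (p_lost > 0) copy_n[runif(n_genes) < p_lost] <- 0L
    # choose, per gene, which target chromosomes carry a copy
    membership <- matrix(FALSE, n_genes, 5L)
    for (g in seq_len(n_genes)) {
      if (copy_n[g] > 0L) {
        membership[g, sample.int(5L, copy_n[g])] <- TRUE
      }
    }
    anchor_list <- list()
    for (t in 1:5) {
      genes <- which(membership[, t])
      if (!length(genes)) next
      anchor_list[[t]] <- data.frame(
        query_chrom = "q1", query_ord = genes,
        target_chrom = paste0("t", t),
        target_ord = seq_along(genes),
        score = round(runif(length(genes), 100, 500)),
        stringsAsFactors = FALSE
      )
    }
    anchors <- do.call(rbind, anchor_list)
    shuffled <- logical(nrow(anchors))
    if (shuffle_rate > 0 && nrow(anchors) >= 2L) {
      n_sh <- round(shuffle_rate * nrow(anchors))
      if (n_sh >= 2L) {
        idx <- sample.int(nrow(anchors), n_sh)
        perm <- sample(idx)
        anchors$target_ord[idx] <- anchors$target_ord[perm]
        anchors$target_chrom[idx] <- anchors$target_chrom[perm]
        shuffled[idx] <- TRUE
      }
    }
    rownames(anchors) <- NULL
    attr(anchors, "query_gene_count") <- n_genes
    class(anchors) <- c("anchor_set", "data.frame")
    truth <- new_sim_truth(
      "sim_anchor_sets", seed,
      list(copy_number = copy_n, shuffle_rate = shuffle_rate,
           shuffled = shuffled, membership = membership)
    )
    list(anchors = anchors, truth = truth)
  })
}

#' Write an anchor set as TSV
#'
#' Columns: geneA geneB score chromA posA chromB posB (gene names derived
#' from ordinals).
#'
#' @param anchors An `anchor_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchors_tsv <- function(anchors, path) {
  out <- data.frame(
    geneA = sprintf("q%05d", anchors$query_ord),
    geneB = sprintf("%s_g%05d", anchors$target_chrom, anchors$target_ord),
    score = anchors$score,
    chromA = anchors$query_chrom, posA = anchors$query_ord,
    chromB = anchors$target_chrom, posB = anchors$target_ord
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an anchor set from TSV
#'
#' @param path TSV with columns geneA geneB score chromA posA chromB posB.
#' @param query_gene_count Total number of query genes (for depth-0
#'   accounting); defaults to the maximum query ordinal seen.
#' @return An `anchor_set`.
#' @export
read_anchors_tsv <- function(path, query_gene_count = NULL) {
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  anchors <- data.frame(
    query_chrom = x$chromA, query_ord = as.integer(x$posA),
    target_chrom = x$chromB, target_ord = as.integer(x$posB),
    score = x$score, stringsAsFactors = FALSE
  )
  attr(anchors, "query_gene_count") <-
    if (is.null(query_gene_count)) max(anchors$query_ord)
    else as.integer(query_gene_count)
  class(anchors) <- c("anchor_set", "data.frame")
  anchors
}
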