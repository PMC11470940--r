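# Solo-LTR classification, ratios, insertion ages, TE summaries.

# minimal hand-built annotation: two intact elements and one candidate
# whose properties are controlled per test
tiny_annotation <- function(cand_start, cand_len = 300L, identity = 0.9,
                            score = 800) {
  ann <- data.frame(
    chrom = "chr1",
    start = c(10000L, 40000L, cand_start),
    end = c(17000L, 47000L, cand_start + cand_len - 1L),
    strand = "+",
    type = c("LTR_retrotransposon", "LTR_retrotransposon",
             "long_terminal_repeat"),
    te_class = "Copia",
    method = c("structural", "structural", "homology"),
    identity = c(NA, NA, identity),
    score = c(NA, NA, score),
    ltr_rt_id = c("TE_1", "TE_2", "TE_3"),
    role = c("intact", "intact", "candidate"),
    ltr_len = c(500, 500, NA),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("te_annotation_set", "data.frame")
  ann
}

test_that("each printed filter rejects for its own reason", {
  rule_of <- function(ann) classify_solo_ltrs(ann)$verdicts$rule[1]
  # 90 bp candidate: below the 100 bp minimum
  expect_identical(rule_of(tiny_annotation(25000L, cand_len = 90L)),
                   "length")
  # 4 kb from an intact element: below the 5000 bp minimum distance
  expect_identical(rule_of(tiny_annotation(21000L)), "distance")
  # identity below 0.8
  expect_identical(rule_of(tiny_annotation(25000L, identity = 0.5)),
                   "identity")
  # score below 300
  expect_identical(rule_of(tiny_annotation(25000L, score = 100)), "score")
  # longer than the 95th percentile of intact LTR lengths (500 bp here)
  expect_identical(rule_of(tiny_annotation(25000L, cand_len = 900L)),
                   "length_percentile")
  # and a clean candidate passes
  expect_identical(rule_of(tiny_annotation(25000L)), "pass")
})

test_that("planted decoys are rejected with matching rule labels", {
  sim <- sim_te_gff(n_intact = 4, n_solo = 6, n_decoys = 6,
                    chrom_length_bp = 1e6, seed = 1)
  report <- classify_solo_ltrs(sim$annotation)
  truth <- sim$truth$planted_params$labels
  got <- setNames(report$verdicts$rule, report$verdicts$ltr_rt_id)
  expect_identical(unname(got[names(truth)]),
                   unname(ifelse(truth == "solo", "pass", truth)))
  # precision = recall = 1 by construction
  expect_identical(sum(report$verdicts$solo), sum(truth == "solo"))
})

test_that("the pass/fail verdict is invariant to filter order", {
  # evaluate all six rules independently and compare the conjunction with
  # the classifier's verdict across several seeds
  for (seed in 1:3) {
    sim <- sim_te_gff(3, 4, 6, 1e6, seed = seed)
    ann <- sim$annotation
    report <- classify_solo_ltrs(ann)
    intact_lens <- ann$ltr_len[ann$role == "intact" & !is.na(ann$ltr_len)]
    bound <- quantile(intact_lens, 0.95, names = FALSE)
    for (j in seq_len(nrow(report$verdicts))) {
      v <- report$verdicts[j, ]
      i <- which(ann$start == v$start & ann$end == v$end &
                   ann$role == "candidate")[1]
      len <- ann$end[i] - ann$start[i] + 1L
      others <- setdiff(seq_len(nrow(ann)), i)
      up <- others[ann$end[others] < ann$start[i]]
      dn <- others[ann$start[others] > ann$end[i]]
      up <- up[order(ann$end[up], decreasing = TRUE)]
      dn <- dn[order(ann$start[dn])]
      ids <- ann$ltr_rt_id[c(head(up, 2), head(dn, 2))]
      gaps <- c(ann$start[i] - ann$end[up], ann$start[dn] - ann$end[i])
      ok <- len >= 100 &&
        (!is.na(ann$identity[i]) && ann$identity[i] >= 0.8) &&
        (!is.na(ann$score[i]) && ann$score[i] >= 300) &&
        !anyDuplicated(ids) &&
        min(gaps) >= 5000 &&
        len <= bound
      expect_identical(v$solo, ok)
    }
  }
})

test_that("missing intact LTRs skip the percentile rule with a warning", {
  ann <- tiny_annotation(25000L)
  ann <- ann[ann$role != "intact", , drop = FALSE]
  expect_warning(r <- classify_solo_ltrs(ann), "percentile")
  expect_true(r$percentile_rule_skipped)
})

test_that("solo:intact ratios handle zero denominators explicitly", {
  rep8 <- list(counts = data.frame(chrom = c("chr1", "chr2"),
                                   n_solo = c(8L, 3L),
                                   n_intact = c(2L, 0L)))
  class(rep8) <- "solo_ltr_report"
  tab <- solo_intact_ratio(rep8, by = "chromosome")
  expect_equal(tab$ratio[1], 4.0)
  expect_true(tab$undefined[2])
  expect_true(is.na(tab$ratio[2]))
  genome <- solo_intact_ratio(rep8, by = "genome")
  expect_equal(genome$ratio, 11 / 2)
  zero <- list(counts = data.frame(chrom = "chr1", n_solo = 0L,
                                   n_intact = 5L))
  class(zero) <- "solo_ltr_report"
  expect_equal(solo_intact_ratio(zero)$ratio, 0)
})

test_that("insertion ages follow the Jukes-Cantor clock arithmetic", {
  a <- strrep("ACGT", 250)
  expect_equal(ltr_insertion_age(a, a)$age_years, 0)
  # p = 0.01: d = 0.010067, age ~ 1.066e6 years at 4.72e-9/site/year
  x <- strsplit(a, "")[[1]]
  y <- x
  y[seq(1, 1000, by = 100)] <- "G"  # positions 1, 101, ... are all "A"
  age <- ltr_insertion_age(paste(x, collapse = ""), paste(y, collapse = ""))
  expect_equal(age$p_distance, 0.01)
  d_exact <- -0.75 * log(1 - 4 / 3 * 0.01)  # 0.0100671
  expect_equal(age$divergence, d_exact, tolerance = 1e-12)
  expect_equal(age$divergence, 0.010067, tolerance = 1e-4)
  expect_equal(age$age_years, d_exact / (2 * 4.72e-9), tolerance = 1e-12)
  expect_equal(age$age_years, 1.066e6, tolerance = 1e-3)
  # uncorrected mode: p = 0.00944 -> exactly 1.0 Myr at the default rate
  long <- rep("A", 100000L)
  mut <- long
  mut[seq_len(944L)] <- "G"
  raw <- ltr_insertion_age(paste(long, collapse = ""),
                           paste(mut, collapse = ""), correction = "raw")
  expect_equal(raw$p_distance, 0.00944)
  expect_equal(raw$age_years, 1e6)
  # saturation: JC undefined at p >= 0.75
  w <- chartr("ACGT", "CAGA", x)
  expect_error(ltr_insertion_age(paste(x, collapse = ""),
                                 paste(w, collapse = ""),
                                 rate = 4.72e-9),
               "saturated")
})

test_that("age is strictly increasing in p over the defined range", {
  n <- 1000L
  base <- strrep("A", n)
  ages <- vapply(seq(0, 0.74, by = 0.02), function(p) {
    k <- round(p * n)
    mut <- paste(c(rep("C", k), rep("A", n - k)), collapse = "")
    ltr_insertion_age(base, mut)$age_years
  }, 0)
  expect_true(all(diff(ages) > 0))
})

test_that("TE class summary merges overlaps and bounds percentages", {
  ann <- data.frame(
    chrom = "chr1", start = c(1L, 50L, 500L), end = c(100L, 150L, 1500L),
    strand = "+", type = "x", te_class = c("Mutator", "Mutator", "Copia"),
    method = "structural", identity = NA, score = NA,
    ltr_rt_id = c("a", "b", "c"), role = "intact", ltr_len = NA
  )
  class(ann) <- c("te_annotation_set", "data.frame")
  tab <- te_summary(ann, genome_length_bp = 10000)
  expect_equal(tab$bp_covered[tab$te_class == "Mutator"], 150)
  expect_equal(tab$pct_genome[tab$te_class == "Copia"], 10.01)
  expect_lte(tab$pct_genome[tab$te_class == "total"], 100)
  expect_error(te_summary(ann, genome_length_bp = 1000), "beyond")
})
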