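#' Simulate per-site allele depths under a known ploidy
#'
#' Generates read depths at heterozygous biallelic sites the way a
#' short-read variant caller would report them for an organism of the given
#' ploidy.  Total depth per site is Poisson(`mean_depth`); the alternate
#' allele dosage is drawn from `dosage_weights` over `1..ploidy-1`; alternate
#' read counts are Binomial(depth, p) with p = dosage/ploidy perturbed by a
#' symmetric sequencing error rate.  The allele-balance distribution of such
#' a table is the raw material for ploidy inference: diploids place all mass
#' near 1/2, autotetraploids near 1/4, 1/2 and 3/4.
#'
#' @param ploidy Integer ploidy, one of 2, 3 or 4.
#' @param n_sites Number of heterozygous sites to simulate.
#' @param mean_depth Mean total read depth per site (> 0).
#' @param error_rate Per-read base error rate (< 0.05).
#' @param dosage_weights Probability vector over alternate-allele dosages
#'   `1..ploidy-1`; defaults to uniform.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A list with `table` (data.frame of class `allele_depth_table`
#'   with columns chrom, pos, ref_depth, alt_depth, qual) and `truth`
#'   (a `sim_truth` carrying ploidy and the per-site dosage).
#' @examples
#' sim <- sim_allele_depths(ploidy = 4, n_sites = 500, mean_depth = 60,
#'                          seed = 1)
#' head(sim$table)
#' @export
sim_allele_depths <- function(ploidy, n_sites, mean_depth,
                              error_rate = 0.001,
                              dosage_weights = NULL, seed = 1L) {
  if (!ploidy %in% c(2L, 3L, 4L)) {
    stop("`ploidy` must be one of 2, 3, 4", call. = FALSE)
  }
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)
  stopifnot_fraction(error_rate, "error_rate", 0, 0.05 - 1e-12)
  dosages <- seq_len(ploidy - 1L)
  if (is.null(dosage_weights)) {
    dosage_weights <- rep(1 / length(dosages), length(dosages))
  }
  if (length(dosage_weights) != length(dosages) ||
      abs(sum(dosage_weights) - 1) > 1e-8) {
    stop("`dosage_weights` must sum to 1 over dosages 1..ploidy-1",
         call. = FALSE)
  }
  with_seed(seed, {
    dosage <- sample(dosages, n_sites, replace = TRUE, prob = dosage_weights)
    depth <- rpois(n_sites, mean_depth)
    p <- dosage / ploidy
    p_obs <- p * (1 - error_rate) + (1 - p) * error_rate
    alt <- rbinom(n_sites, depth, p_obs)
    ref <- depth - alt
    tab <- data.frame(
      chrom = "chr1",
      pos = sort(sample.int(n_sites * 100L, n_sites)),
      ref_depth = ref,
      alt_depth = alt,
      qual = round(runif(n_sites, 30, 90), 1)
    )
    keep <- tab$ref_depth >= 1L & tab$alt_depth >= 1L
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("allele_depth_table", "data.frame")
    truth <- new_sim_truth(
      "sim_allele_depths", seed,
      list(ploidy = ploidy, n_sites = n_sites, mean_depth = mean_depth,
           error_rate = error_rate, dosage_weights = dosage_weights,
           dosage = dosage[keep])
    )
    list(table = tab, truth = truth)
  })
}

#' Write an allele-depth table as a minimal VCF v4.2
#'
#' Emits one heterozygous biallelic SNP record per site with a single sample
#' carrying `GT` and `AD` (ref,alt allele depths), the format
#' [extract_allele_balance()] consumes.
#'
#' @param table An `allele_depth_table` (see [sim_allele_depths()]).
#' @param path Output file path.
#' @param sample Sample name for the single genotype column.
#' @return `path`, invisibly.
#' @export
write_allele_depth_vcf <- function(table, path, sample = "SIM") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- sprintf("%s\t%d\t.\tA\tG\t%.1f\tPASS\t.\tGT:AD\t0/1:%d,%d",
                  table$chrom, table$pos, table$qual,
                  table$ref_depth, table$alt_depth)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate genotype dosages under the Balding-Nichols model
#'
#' Population allele frequencies are Beta-distributed around an ancestral
#' frequency p with shape parameters p(1-F)/F and (1-p)(1-F)/F, so the
#' model's F parameter equals the expected Fst between populations —
#' a closed-form recovery target for the Weir-Cockerham estimator.
#' Individual dosages are Binomial(ploidy, population frequency).
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Samples per population.
#' @param n_loci Number of biallelic loci.
#' @param fst Differentiation parameter F, strictly inside (0, 1).
#' @param ploidy Sample ploidy, 2 or 4.
#' @param maf_floor Ancestral frequencies are uniform on
#'   `[maf_floor, 1 - maf_floor]`.
#' @param seed Integer seed.
#' @return A list with `geno` (a `genotype_matrix`: integer samples x loci
#'   dosage matrix with attributes `ploidy`, `pops`, `chrom`, `pos`) and
#'   `truth` (per-population allele frequencies and F).
#' @examples
#' g <- sim_genotypes_bn(2, 10, 200, fst = 0.2, seed = 1)
#' dim(g$geno)
#' @export
sim_genotypes_bn <- function(n_pops, n_per_pop, n_loci, fst,
                             ploidy = 2L, maf_floor = 0.05, seed = 1L) {
  if (!is.numeric(fst) || fst <= 0 || fst >= 1) {
    stop("`fst` must lie strictly inside (0, 1); the Beta model degenerates at 0 and 1",
         call. = FALSE)
  }
  if (!ploidy %in% c(2L, 4L)) stop("`ploidy` must be 2 or 4", call. = FALSE)
  stopifnot_fraction(maf_floor, "maf_floor", 0, 0.5)
  with_seed(seed, {
    p_anc <- runif(n_loci, maf_floor, 1 - maf_floor)
    shape_scale <- (1 - fst) / fst
    n_samples <- n_pops * n_per_pop
    pop <- rep(paste0("pop", seq_len(n_pops)), each = n_per_pop)
    p_pop <- matrix(0, n_pops, n_loci)
    for (k in seq_len(n_pops)) {
      p_pop[k, ] <- rbeta(n_loci, p_anc * shape_scale,
                          (1 - p_anc) * shape_scale)
    }
    geno <- matrix(0L, n_samples, n_loci)
    for (k in seq_len(n_pops)) {
      rows <- which(pop == paste0("pop", k))
      geno[rows, ] <- matrix(
        rbinom(length(rows) * n_loci, ploidy,
               rep(p_pop[k, ], each = length(rows))),
        nrow = length(rows)
      )
    }
    dimnames(geno) <- list(paste0(pop, "_", sequence(rep(n_per_pop, n_pops))),
                           paste0("locus", seq_len(n_loci)))
    geno <- new_genotype_matrix(geno, ploidy = ploidy, pops = pop,
                                chrom = rep("chr1", n_loci),
                                pos = seq_len(n_loci) * 100L)
    truth <- new_sim_truth(
      "sim_genotypes_bn", seed,
      list(fst = fst, ploidy = ploidy, n_pops = n_pops,
           n_per_pop = n_per_pop, n_loci = n_loci,
           ancestral_freq = p_anc, pop_freq = p_pop)
    )
    list(geno = geno, truth = truth)
  })
}

#' Construct a genotype matrix
#'
#' Wraps a samples x loci dosage matrix with the metadata the
#' population-structure analyses need: sample ploidy, population labels
#' and locus coordinates.
#'
#' @param geno Integer matrix of alternate-allele dosages (0..ploidy;
#'   NA allowed).
#' @param ploidy Sample ploidy (2 or 4).
#' @param pops Population label per sample (row).
#' @param chrom,pos Locus coordinates (per column); default a single
#'   chromosome with 100 bp spacing.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, ploidy = 2L, pops = NULL,
                            chrom = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  if (!ploidy %in% c(2L, 4L)) stop("`ploidy` must be 2 or 4", call. = FALSE)
  if (any(geno > ploidy, na.rm = TRUE) || any(geno < 0, na.rm = TRUE)) {
    stop("dosages must lie in 0..ploidy", call. = FALSE)
  }
  if (is.null(pops)) pops <- rep("pop1", nrow(geno))
  if (length(pops) != nrow(geno)) {
    stop("`pops` must have one label per sample", call. = FALSE)
  }
  if (is.null(chrom)) chrom <- rep("chr1", ncol(geno))
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 100L
  new_genotype_matrix(geno, ploidy, pops, chrom, pos)
}

new_genotype_matrix <- function(geno, ploidy, pops, chrom, pos) {
  structure(geno, ploidy = as.integer(ploidy), pops = pops,
            chrom = chrom, pos = as.integer(pos),
            class = c("genotype_matrix", class(geno)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x), " samples x ", ncol(x), " loci, ploidy ",
      attr(x, "ploidy"), ", ", length(unique(attr(x, "pops"))),
      " population(s)\n", sep = "")
  invisible(x)
}
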