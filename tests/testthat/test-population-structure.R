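# Weir-Cockerham Fst, PCA, local PCA partitioning.

test_that("WC84 components equal the brute-force oracle to 1e-12", {
  for (trial in 1:100) {
    set.seed(2000 + trial)
    r <- sample(2:3, 1)
    n_per <- sample(4:10, r, replace = TRUE)
    n_loci <- 20L
    pops <- rep(paste0("pop", seq_len(r)), n_per)
    g <- matrix(rbinom(sum(n_per) * n_loci, 2,
                       rep(runif(n_loci, 0.1, 0.9), each = sum(n_per))),
                nrow = sum(n_per))
    geno <- genotype_matrix(g, ploidy = 2, pops = pops)
    res <- weighted_fst(geno, "pop1", "pop2")
    sel <- pops %in% c("pop1", "pop2")
    oracle <- wc84_oracle(g[sel, , drop = FALSE],
                          as.integer(factor(pops[sel])))
    expect_equal(res$per_locus$a, oracle$a, tolerance = 1e-12)
    expect_equal(res$per_locus$b, oracle$b, tolerance = 1e-12)
    expect_equal(res$per_locus$c, oracle$c, tolerance = 1e-12)
  }
})

test_that("an exact-HWE two-deme configuration gives the closed-form Fst", {
  # 25 diploids per deme at p = 0.8 vs 0.2 with exact HWE counts:
  # per-locus a = 0.176667, b = 0.003333, c = 0.16, Fst = 0.519608
  # (frozen from the hand-applied 1984 component formulas)
  deme <- function(p) c(rep(2L, round(25 * p^2)),
                        rep(1L, round(25 * 2 * p * (1 - p))),
                        rep(0L, round(25 * (1 - p)^2)))
  g <- matrix(c(deme(0.8), deme(0.2)), ncol = 1)
  geno <- genotype_matrix(g, ploidy = 2,
                          pops = rep(c("pop1", "pop2"), each = 25))
  res <- weighted_fst(geno)
  a_exact <- 0.18 - 0.08 / 24
  b_exact <- 25 / 24 * 0.0032
  expect_equal(res$per_locus$a, a_exact, tolerance = 1e-12)
  expect_equal(res$per_locus$b, b_exact, tolerance = 1e-12)
  expect_equal(res$per_locus$c, 0.16, tolerance = 1e-12)
  expect_equal(res$weighted_fst, a_exact / (a_exact + b_exact + 0.16),
               tolerance = 1e-12)
  expect_equal(res$weighted_fst, 0.5196, tolerance = 1e-4)
})

test_that("null differentiation estimates are near zero", {
  set.seed(7)
  p <- runif(1000, 0.2, 0.8)
  g <- matrix(rbinom(50 * 1000, 2, rep(p, each = 50)), nrow = 50)
  geno <- genotype_matrix(g, ploidy = 2,
                          pops = rep(c("pop1", "pop2"), each = 25))
  expect_lt(abs(weighted_fst(geno)$weighted_fst), 0.02)
})

test_that("Balding-Nichols differentiation is recovered", {
  g <- sim_genotypes_bn(2, 30, 2000, fst = 0.2, seed = 1)
  expect_lt(abs(weighted_fst(g$geno)$weighted_fst - 0.2), 0.05)
  # tetraploid input through the diploidized route stays close
  g4 <- sim_genotypes_bn(2, 30, 2000, fst = 0.2, ploidy = 4, seed = 2)
  expect_lt(abs(weighted_fst(g4$geno)$weighted_fst - 0.2), 0.05)
  # the Hudson frequency-based alternative agrees
  expect_lt(abs(weighted_fst(g$geno, method = "hudson")$weighted_fst - 0.2),
            0.05)
})

test_that("monomorphic-only input is flagged undefined", {
  g <- matrix(2L, nrow = 10, ncol = 5)
  geno <- genotype_matrix(g, ploidy = 2,
                          pops = rep(c("pop1", "pop2"), each = 5))
  expect_warning(res <- weighted_fst(geno), "undefined")
  expect_true(is.na(res$weighted_fst))
})

test_that("high-Fst scans return exactly the planted outlier loci", {
  set.seed(5)
  p <- runif(200, 0.3, 0.7)
  g <- matrix(rbinom(20 * 200, 2, rep(p, each = 20)), nrow = 20)
  g[1:10, 42] <- 2L   # fixed difference at locus 42
  g[11:20, 42] <- 0L
  geno <- genotype_matrix(g, ploidy = 2,
                          pops = rep(c("pop1", "pop2"), each = 10))
  res <- weighted_fst(geno)
  hits <- high_fst_loci(res, threshold = 0.8)
  expect_identical(hits$pos, 42L * 100L)
  # at threshold 0 every locus with positive differentiation is returned
  expect_identical(nrow(high_fst_loci(res, threshold = 0)),
                   sum(!is.na(res$per_locus$fst) & res$per_locus$fst > 0))
  expect_identical(nrow(high_fst_loci(res, threshold = -Inf)),
                   sum(!is.na(res$per_locus$fst)))
})

test_that("PCA separates planted structure and conserves variance", {
  # two groups of identical rows: PC1 carries all variance
  g <- rbind(matrix(0L, 5, 50), matrix(2L, 5, 50))
  geno <- genotype_matrix(g, ploidy = 2,
                          pops = rep(c("a", "b"), each = 5))
  pca <- genotype_pca(geno, n_components = 3)
  expect_gt(pca$var_explained[1], 0.999)
  expect_true(all(sign(pca$coords[1:5, 1]) != sign(pca$coords[6:10, 1])))
  # three Balding-Nichols populations: k-means on PC1-2 recovers labels
  g3 <- sim_genotypes_bn(3, 10, 1000, fst = 0.3, seed = 3)
  p3 <- genotype_pca(g3$geno)
  km <- kmeans(p3$coords[, 1:2], 3, nstart = 25)
  tab <- table(km$cluster, attr(g3$geno, "pops"))
  expect_gte(sum(apply(tab, 1, max)) / 30, 0.95)
  expect_lte(sum(p3$var_explained), 1 + 1e-8)
})

test_that("PCA is invariant to locus order", {
  g <- sim_genotypes_bn(2, 10, 300, fst = 0.2, seed = 4)
  perm <- sample(300)
  gp <- unclass(g$geno)[, perm]
  geno_p <- genotype_matrix(gp, ploidy = 2, pops = attr(g$geno, "pops"))
  c1 <- genotype_pca(g$geno)$coords[, 1]
  c2 <- genotype_pca(geno_p)$coords[, 1]
  expect_equal(abs(cor(c1, c2)), 1, tolerance = 1e-9)
})

test_that("identical windows are at distance zero in local PCA", {
  set.seed(6)
  block <- matrix(rbinom(20 * 40, 2, 0.4), nrow = 20)
  g <- cbind(block, block, block)
  geno <- genotype_matrix(g, ploidy = 2,
                          pops = rep("pop1", 20))
  lp <- suppressWarnings(
    local_pca_partition(geno, window = 40, window_type = "snp"))
  expect_equal(lp$dist[1, 2], 0, tolerance = 1e-12)
  expect_identical(lp$dist, t(lp$dist))
  expect_true(all(diag(lp$dist) == 0))
})

test_that("a planted aberrant window block is flagged as one outlier cluster", {
  set.seed(8)
  n <- 30
  base_p <- runif(600, 0.2, 0.8)
  g <- matrix(rbinom(n * 600, 2, rep(base_p, each = n)), nrow = n)
  # windows 11-12 (SNPs 501-600): two artificial sample groups with fixed
  # differences -> a strong, distinctive covariance structure
  g[1:15, 501:600] <- 0L
  g[16:30, 501:600] <- 2L
  jig <- matrix(rbinom(n * 100, 2, 0.02), nrow = n)  # slight noise
  g[, 501:600] <- pmin(pmax(g[, 501:600] + jig - 1L, 0L), 2L)
  geno <- genotype_matrix(g, ploidy = 2, pops = rep("pop1", n))
  lp <- local_pca_partition(geno, window = 50, window_type = "snp")
  lab <- lp$windows$label
  expect_true(all(lab[11:12] != "none"))
  expect_identical(length(unique(lab[11:12])), 1L)
  expect_identical(ncol(lp$mds), 2L)
})

test_that("MDS preserves distances for a low-dimensional window layout", {
  # alternating copies of two genotype blocks: the windows occupy two
  # points, so two MDS axes must reproduce the distances almost exactly
  set.seed(9)
  A <- matrix(rbinom(20 * 40, 2, 0.3), nrow = 20)
  B <- matrix(rbinom(20 * 40, 2, 0.7), nrow = 20)
  g <- cbind(A, B, A, B, A, B)
  geno <- genotype_matrix(g, ploidy = 2, pops = rep("p", 20))
  lp <- local_pca_partition(geno, window = 40, window_type = "snp")
  mds_d <- as.matrix(dist(lp$mds))
  off <- upper.tri(lp$dist)
  expect_gt(cor(mds_d[off], lp$dist[off]), 0.99)
})

test_that("windows with too few polymorphic loci are skipped and counted", {
  g <- cbind(matrix(1L, 10, 5),
             matrix(rbinom(10 * 100, 2, 0.5), nrow = 10))
  geno <- genotype_matrix(g, ploidy = 2, pops = rep("p", 10))
  lp <- local_pca_partition(geno, window = 5, window_type = "snp")
  expect_gte(lp$n_skipped, 1L)
})
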