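# Generators: determinism, planted truth, format validity.

test_that("every generator is byte-reproducible under a fixed seed", {
  expect_identical(sim_allele_depths(4, 2000, 60, seed = 11),
                   sim_allele_depths(4, 2000, 60, seed = 11))
  expect_identical(sim_kmer_spectrum(5000, 0.01, 0.1, 19, 60, seed = 11),
                   sim_kmer_spectrum(5000, 0.01, 0.1, 19, 60, seed = 11))
  expect_identical(sim_repeat_sequences("tandem", random_monomer(20), 50,
                                        0.02, 100, seed = 11),
                   sim_repeat_sequences("tandem", random_monomer(20), 50,
                                        0.02, 100, seed = 11))
  expect_identical(sim_paralog_cds(2, 0.2, 200, seed = 11),
                   sim_paralog_cds(2, 0.2, 200, seed = 11))
  expect_identical(sim_genotypes_bn(2, 5, 100, 0.2, seed = 11),
                   sim_genotypes_bn(2, 5, 100, 0.2, seed = 11))
  expect_identical(sim_anchor_sets(50, c(0.5, 0.5, 0, 0, 0), 0.1, seed = 11),
                   sim_anchor_sets(50, c(0.5, 0.5, 0, 0, 0), 0.1, seed = 11))
  # GFF3 text identity, not just in-memory identity
  s1 <- sim_te_gff(3, 3, 6, 1e6, seed = 11)
  s2 <- sim_te_gff(3, 3, 6, 1e6, seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  write_te_gff(s1$annotation, f1); write_te_gff(s2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generator calls do not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(sim_allele_depths(2, 100, 30, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("allele-depth simulation reproduces the binomial dosage law", {
  # diploid, no error: expected alt fraction 1/2 at every site
  s2 <- sim_allele_depths(2, 5000, 60, error_rate = 0, seed = 3)
  f <- s2$table$alt_depth / (s2$table$ref_depth + s2$table$alt_depth)
  expect_lt(abs(mean(f) - 0.5), 0.005)
  # tetraploid: per-dosage-class mean alt fraction within 0.01 of dosage/4
  s4 <- sim_allele_depths(4, 50000, 60, error_rate = 0, seed = 1)
  f4 <- s4$table$alt_depth / (s4$table$ref_depth + s4$table$alt_depth)
  dosage <- s4$truth$planted_params$dosage
  for (d in 1:3) {
    expect_lt(abs(mean(f4[dosage == d]) - d / 4), 0.01)
  }
  expect_error(sim_allele_depths(5, 100, 30), "2, 3, 4")
})

test_that("k-mer spectrum plants heterozygosity and repeat content as built", {
  # homozygous: single non-error peak at mean_depth
  s0 <- sim_kmer_spectrum(50000, 0, 0, 19, 60, seed = 2)
  rows <- s0$spectrum$rows
  expect_lt(abs(rows$depth[which.max(rows$count)] - 60), 3)
  # haplotype-specific distinct k-mer fraction close to 1 - (1-h)^k
  sh <- sim_kmer_spectrum(2e5, 0.016, 0, 19, 60, seed = 3)
  expected <- 1 - (1 - 0.016)^19
  got <- sh$truth$planted_params$hap_specific_fraction
  expect_lt(abs(got - expected) / expected, 0.10)
  # repeat fraction realized as k-mer mass above 1.5x the homozygous peak
  sr <- sim_kmer_spectrum(3e5, 0, 0.3, 19, 60, seed = 4)
  r <- sr$spectrum$rows
  mass <- as.numeric(r$depth) * r$count
  frac <- sum(mass[r$depth > 90]) / sum(mass)
  expect_lt(abs(frac - 0.3) / 0.3, 0.15)
  expect_error(sim_kmer_spectrum(100, 0, 0, 19, 60), "10 \\* k")
})

test_that("repeat-sequence simulation: array arithmetic, telomere tracts, HOR period", {
  mono <- random_monomer(158, seed = 5)
  arr <- sim_repeat_sequences("tandem", mono, 500, divergence = 0.02,
                              flank_bp = 250, seed = 1)
  expect_identical(nchar(unname(arr$seq)), 500L * 158L + 2L * 250L)
  expect_equal(arr$truth$planted_params$array_end -
                 arr$truth$planted_params$array_start + 1L, 500L * 158L)
  tel <- sim_repeat_sequences("telomere", "AAACCCT", 700, 0, 300, seed = 1)
  expect_identical(substr(unname(tel$seq), 301, 1000), strrep("AAACCCT", 100))
  # an AB higher-order pattern leaves its signature in the autocorrelation
  hor <- sim_repeat_sequences("tandem", mono, 120, divergence = 0,
                              flank_bp = 0, hor_pattern = "AB", seed = 2)
  s1 <- shift_identity(unname(hor$seq), 158L)
  s2 <- shift_identity(unname(hor$seq), 316L)
  expect_gt(s2, s1)
  expect_gt(s2, 0.99)
  expect_error(sim_repeat_sequences("circular", mono, 10), "mode")
})

test_that("paralog CDS pairs carry the planted synonymous distance", {
  p0 <- sim_paralog_cds(1, 0, 200, seed = 1)
  expect_identical(p0$pairs[[1]]$a, p0$pairs[[1]]$b)
  p <- sim_paralog_cds(3, c(0.1, 0.3, 0.8), 400, seed = 2)
  code <- Biostrings::GENETIC_CODE
  for (i in 1:3) {
    b <- p$pairs[[i]]$b
    codons <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    expect_false(any(code[codons] == "*"))  # never introduces stops
    expect_lt(abs(p$truth$planted_params$ks_values[i] -
                    p$truth$planted_params$ks_targets[i]), 0.01)
  }
  # a steep target at few codons is honestly unreachable
  expect_error(sim_paralog_cds(1, 2, 100, seed = 1), "unreachable")
})

test_that("Balding-Nichols genotypes respect ploidy bounds and degenerate cases", {
  g4 <- sim_genotypes_bn(2, 8, 300, fst = 0.3, ploidy = 4, seed = 1)
  expect_true(all(g4$geno >= 0 & g4$geno <= 4))
  g1 <- sim_genotypes_bn(1, 10, 100, fst = 0.2, seed = 2)
  expect_identical(length(unique(attr(g1$geno, "pops"))), 1L)
  expect_error(sim_genotypes_bn(2, 5, 100, fst = 0), "strictly inside")
  expect_error(sim_genotypes_bn(2, 5, 100, fst = 1), "strictly inside")
})

test_that("anchor sets realize planted copy-number layouts", {
  one <- sim_anchor_sets(50, c(1, 0, 0, 0, 0), 0, seed = 1)
  expect_identical(nrow(one$anchors), 50L)
  expect_identical(sort(unique(one$anchors$query_ord)), 1:50)
  # a 1:1 map: within each target chromosome anchors are collinear
  for (t in unique(one$anchors$target_chrom)) {
    a <- one$anchors[one$anchors$target_chrom == t, ]
    expect_identical(a$target_ord[order(a$query_ord)], sort(a$target_ord))
  }
  four <- sim_anchor_sets(40, c(0, 0, 0, 1, 0), 0, seed = 2)
  per_gene <- table(four$anchors$query_ord)
  expect_true(all(per_gene == 4L))
  expect_error(sim_anchor_sets(10, c(0.5, 0.5), 0), "length-5")
})

test_that("emitted formats are parsed cleanly by the package's own readers", {
  # VCF round trip preserves depths
  sv <- sim_allele_depths(4, 1500, 60, seed = 5)
  fv <- tempfile(fileext = ".vcf")
  write_allele_depth_vcf(sv$table, fv)
  tab <- extract_allele_balance(fv, min_qual = 0, min_depth = 0)
  expect_identical(nrow(tab), nrow(sv$table))
  expect_identical(tab$alt_depth, sv$table$alt_depth)
  # GFF3 round trip preserves the classifier-relevant fields
  sg <- sim_te_gff(3, 4, 6, 1e6, seed = 6)
  fg <- tempfile(fileext = ".gff3")
  write_te_gff(sg$annotation, fg)
  back <- read_te_gff(fg)
  expect_identical(back$start, sg$annotation$start)
  expect_identical(back$role, sg$annotation$role)
  expect_equal(back$identity, round(sg$annotation$identity, 4))
  # FASTA round trip
  ff <- tempfile(fileext = ".fa")
  write_fasta(c(a = "ACGTACGTAC"), ff)
  expect_identical(read_fasta(ff), c(a = "ACGTACGTAC"))
  # anchors TSV round trip
  sa <- sim_anchor_sets(30, c(0.5, 0.5, 0, 0, 0), 0, seed = 7)
  fa <- tempfile(fileext = ".tsv")
  write_anchors_tsv(sa$anchors, fa)
  back_a <- read_anchors_tsv(fa, query_gene_count = 30)
  expect_identical(back_a$query_ord, sa$anchors$query_ord)
  expect_identical(back_a$target_ord, sa$anchors$target_ord)
})

test_that("truth sidecars round-trip through JSON", {
  sim <- sim_allele_depths(4, 200, 60, seed = 8)
  f <- tempfile(fileext = ".truth.json")
  write_truth_json(sim$truth, f)
  back <- read_truth_json(f)
  expect_identical(back$generator_name, "sim_allele_depths")
  expect_identical(back$seed, 8L)
  expect_equal(back$planted_params$dosage,
               sim$truth$planted_params$dosage)
})
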