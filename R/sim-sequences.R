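#' Simulate a k-mer depth spectrum with planted genome properties
#'
#' Builds a pair of haplotype sequences of the requested length at the
#' requested heterozygosity, with a tandem-duplicated segment realizing the
#' requested repeat fraction, counts k-mers exactly across both haplotypes,
#' and draws an observed sequencing depth for each distinct k-mer from a
#' Poisson law at copy_number x `mean_depth`.  Copy number is in
#' haploid-equivalent units (occurrences across both haplotypes divided by
#' two), so homozygous single-copy k-mers peak at `mean_depth` and
#' haplotype-specific k-mers at `mean_depth / 2` — the classic GenomeScope
#' two-peak geometry.
#'
#' @param genome_length_bp Haploid genome length (>= 10 * k).
#' @param heterozygosity Per-base heterozygosity in `[0, 0.05]`.
#' @param repeat_fraction Fraction of the genome made of a duplicated
#'   segment, in `[0, 1)`.
#' @param k Odd k-mer size in `[15, 31]`.
#' @param mean_depth Sequencing depth of homozygous single-copy k-mers.
#' @param seed Integer seed.
#' @return List with `spectrum` (a `kmer_spectrum`, see [parse_histo()])
#'   and `truth`.
#' @examples
#' sp <- sim_kmer_spectrum(50000, heterozygosity = 0.01, repeat_fraction = 0,
#'                         k = 19, mean_depth = 60, seed = 1)
#' head(sp$spectrum$rows)
#' @export
sim_kmer_spectrum <- function(genome_length_bp, heterozygosity = 0,
                              repeat_fraction = 0, k = 19L,
                              mean_depth = 60, seed = 1L) {
  stopifnot_fraction(heterozygosity, "heterozygosity", 0, 0.05)
  stopifnot_fraction(repeat_fraction, "repeat_fraction", 0, 1 - 1e-9)
  if (k %% 2L != 1L || k < 15L || k > 31L) {
    stop("`k` must be odd and within [15, 31]", call. = FALSE)
  }
  if (genome_length_bp < 10L * k) {
    stop("`genome_length_bp` must be at least 10 * k", call. = FALSE)
  }
  with_seed(seed, {
    rep_seg_len <- round(genome_length_bp * repeat_fraction / 2)
    uniq_len <- genome_length_bp - 2L * rep_seg_len
    uniq <- random_dna(uniq_len)
    rep_seg <- if (rep_seg_len > 0) random_dna(rep_seg_len) else ""
    hap1 <- paste0(uniq, rep_seg, rep_seg)
    hap2 <- mutate_seq(hap1, heterozygosity)
    k1 <- seq_kmers(hap1, k)
    k2 <- seq_kmers(hap2, k)
    km <- sort(c(k1, k2), method = "radix")
    r <- rle(km)
    copy <- r$lengths / 2
    u1 <- unique(k1)
    hap_specific_fraction <- mean(!(u1 %in% k2))
    depth <- rpois(length(copy), copy * mean_depth)
    depth <- depth[depth > 0L]
    counts <- tabulate(depth)
    rows <- data.frame(depth = which(counts > 0L),
                       count = counts[counts > 0L])
    spectrum <- new_kmer_spectrum(rows, k = k)
    truth <- new_sim_truth(
      "sim_kmer_spectrum", seed,
      list(genome_length_bp = genome_length_bp,
           heterozygosity_fraction = heterozygosity,
           repeat_fraction = repeat_fraction, k = k, mean_depth = mean_depth,
           n_distinct_kmers = length(copy),
           hap_specific_fraction = hap_specific_fraction)
    )
    list(spectrum = spectrum, truth = truth)
  })
}

#' Simulate tandem-repeat arrays or telomere-bearing sequences
#'
#' `mode = "tandem"` concatenates mutated copies of a monomer between random
#' flanks, optionally with a higher-order pattern of alternating divergent
#' monomer variants (e.g. `hor_pattern = "AB"` plants a higher-order repeat
#' at twice the monomer length).  `mode = "telomere"` places a terminal
#' motif tract of the requested length at the 3' end of a random sequence.
#'
#' @param mode `"tandem"` or `"telomere"`.
#' @param monomer_or_motif Monomer (tandem) or telomere motif (telomere)
#'   sequence; length >= 6.
#' @param copies_or_tract Number of monomer copies (tandem) or tract length
#'   in bp (telomere).
#' @param divergence Per-base substitution rate applied to each copy,
#'   `<= 0.1`.
#' @param flank_bp Length of random flanking sequence on each side
#'   (tandem) or preceding the tract (telomere).
#' @param hor_pattern Optional higher-order pattern such as `"AB"`; each
#'   distinct letter becomes a monomer variant.
#' @param hor_divergence Substitution rate separating higher-order variant
#'   monomers from the base monomer.
#' @param seed Integer seed.
#' @return List with `seq` (named character, one sequence) and `truth`
#'   (monomer length, copies, array/tract coordinates, HOR period if any).
#' @examples
#' tel <- sim_repeat_sequences("telomere", "AAACCCT", 700, divergence = 0,
#'                             flank_bp = 2000, seed = 1)
#' nchar(tel$seq)
#' @export
sim_repeat_sequences <- function(mode, monomer_or_motif, copies_or_tract,
                                 divergence = 0, flank_bp = 1000L,
                                 hor_pattern = NULL, hor_divergence = 0.015,
                                 seed = 1L) {
  if (!mode %in% c("tandem", "telomere")) {
    stop("unknown `mode`: must be \"tandem\" or \"telomere\"", call. = FALSE)
  }
  stopifnot_fraction(divergence, "divergence", 0, 0.1)
  monomer_or_motif <- toupper(monomer_or_motif)
  if (nchar(monomer_or_motif) < 6L) {
    stop("monomer/motif length must be >= 6", call. = FALSE)
  }
  if (grepl("[^ACGT]", monomer_or_motif)) {
    stop("monomer/motif must contain only A, C, G, T", call. = FALSE)
  }
  flank_bp <- as.integer(flank_bp)
  copies_or_tract <- as.integer(copies_or_tract)
  with_seed(seed, {
    if (mode == "tandem") {
      mono_len <- nchar(monomer_or_motif)
      letters_seq <- if (is.null(hor_pattern)) "A" else {
        strsplit(hor_pattern, "", fixed = TRUE)[[1L]]
      }
      uniq_letters <- unique(letters_seq)
      variants <- setNames(vector("character", length(uniq_letters)),
                           uniq_letters)
      variants[[1L]] <- monomer_or_motif
      if (length(uniq_letters) > 1L) {
        for (l in uniq_letters[-1L]) {
          variants[[l]] <- mutate_seq(monomer_or_motif, hor_divergence)
        }
      }
      template <- rep(letters_seq, length.out = copies_or_tract)
      copies <- vapply(template,
                       function(l) mutate_seq(variants[[l]], divergence), "")
      array <- paste(copies, collapse = "")
      left <- if (flank_bp > 0) random_dna(flank_bp) else ""
      right <- if (flank_bp > 0) random_dna(flank_bp) else ""
      seq <- paste0(left, array, right)
      truth <- new_sim_truth(
        "sim_repeat_sequences", seed,
        list(mode = "tandem", monomer_length_bp = mono_len,
             copies = copies_or_tract, divergence = divergence,
             array_start = flank_bp + 1L,
             array_end = flank_bp + nchar(array),
             hor_period_bp = if (length(uniq_letters) > 1L)
               length(letters_seq) * mono_len else NA_integer_)
      )
    } else {
      motif <- monomer_or_motif
      n_copies <- ceiling(copies_or_tract / nchar(motif))
      tract <- substr(strrep(motif, n_copies), 1L, copies_or_tract)
      tract <- mutate_seq(tract, divergence)
      seq <- paste0(random_dna(flank_bp), tract)
      truth <- new_sim_truth(
        "sim_repeat_sequences", seed,
        list(mode = "telomere", motif = motif,
             tract_length_bp = copies_or_tract, divergence = divergence,
             tract_end = "3prime")
      )
    }
    list(seq = c(sim = seq), truth = truth)
  })
}

# Fourfold-degenerate codon families with exactly one NG86 synonymous site
# per codon: any third-position change is synonymous, no first- or
# second-position change is, and no single change reaches a stop codon.
# (CTN and CGN are excluded: their first positions admit synonymous
# Leu/Arg changes, which would inflate S beyond one site per codon.)
FOURFOLD_PREFIXES <- c("GG", "GC", "CC", "AC", "GT", "TC")

#' Simulate paralogous CDS pairs at planted synonymous distances
#'
#' Each pair starts as a random coding sequence built from
#' fourfold-degenerate codon families and accumulates only synonymous
#' third-position substitutions until its Nei-Gojobori Ks is within 0.01 of
#' the target.  Because every codon carries exactly one synonymous site, a
#' target proportion of synonymous differences pS maps directly onto a
#' number of mutated codons, and [compute_ks()] recovers the planted value
#' exactly up to the 1/`n_codons` granularity.
#'
#' @param n_pairs Number of CDS pairs.
#' @param ks_targets Vector of target Ks values, recycled to `n_pairs`;
#'   each in `[0, 2]`.
#' @param n_codons Codons per sequence (>= 100).
#' @param seed Integer seed.
#' @return List with `pairs` (list of `list(a =, b =)` CDS strings) and
#'   `truth` (realized Ks per pair).
#' @examples
#' p <- sim_paralog_cds(2, ks_targets = 0.3, n_codons = 300, seed = 1)
#' compute_ks(p$pairs[[1]]$a, p$pairs[[1]]$b)$Ks
#' @export
sim_paralog_cds <- function(n_pairs, ks_targets, n_codons = 500L, seed = 1L) {
  if (n_codons < 100L) stop("`n_codons` must be >= 100", call. = FALSE)
  if (any(ks_targets < 0 | ks_targets > 2)) {
    stop("`ks_targets` must lie in [0, 2]", call. = FALSE)
  }
  ks_targets <- rep_len(ks_targets, n_pairs)
  with_seed(seed, {
    pairs <- vector("list", n_pairs)
    realized <- numeric(n_pairs)
    for (i in seq_len(n_pairs)) {
      prefixes <- sample(FOURFOLD_PREFIXES, n_codons, replace = TRUE)
      third <- sample(DNA_BASES, n_codons, replace = TRUE)
      a_codons <- paste0(prefixes, third)
      target <- ks_targets[i]
      p_target <- 0.75 * (1 - exp(-4 / 3 * target))
      m <- round(p_target * n_codons)
      ks_real <- if (m == 0L) 0 else -0.75 * log(1 - 4 / 3 * (m / n_codons))
      if (abs(ks_real - target) > 0.01) {
        stop(sprintf(
          "ks target %.3f unreachable at %d codons (nearest realizable %.4f); increase n_codons",
          target, n_codons, ks_real), call. = FALSE)
      }
      b_codons <- a_codons
      if (m > 0L) {
        idx <- sample.int(n_codons, m)
        new_third <- vapply(third[idx],
                            function(b) sample(setdiff(DNA_BASES, b), 1L), "")
        b_codons[idx] <- paste0(prefixes[idx], new_third)
      }
      pairs[[i]] <- list(a = paste(a_codons, collapse = ""),
                         b = paste(b_codons, collapse = ""))
      realized[i] <- ks_real
    }
    truth <- new_sim_truth(
      "sim_paralog_cds", seed,
      list(ks_targets = ks_targets, ks_values = realized,
           n_codons = n_codons)
    )
    list(pairs = pairs, truth = truth)
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
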