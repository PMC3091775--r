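# Alignment engines: exact-copy recovery, strand symmetry, oracle equality
# against brute-force dynamic programming, spliced self-recovery.

# back-translate a protein deterministically (one codon per residue)
.codon_for <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- vapply(unique(gc), function(aa) names(gc)[gc == aa][1], "")
    }
    tab
  }
})

back_translate <- function(protein) {
  tab <- .codon_for()
  paste(tab[strsplit(protein, "")[[1]]], collapse = "")
}

rand_protein <- function(n) {
  paste(sample(setdiff(rownames(retroforge:::get_blosum62())[1:20], "*"),
               n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

test_that("translated search finds an exactly planted ORF on both strands", {
  set.seed(5)
  prot <- rand_protein(60)
  orf <- back_translate(prot)
  left <- rand_dna(500)
  genome <- Biostrings::DNAStringSet(paste0(left, orf, rand_dna(400)))
  names(genome) <- "chr1"
  h <- translated_search(prot, genome, min_score = 60, protein_id = "p")
  top <- h[which.max(h$score), ]
  expect_equal(top$start, 500)
  expect_equal(top$end, 500 + nchar(orf))
  expect_equal(top$strand, "+")
  expect_equal(top$identity, 100)
  # reverse strand: same interval, strand flipped, score unchanged
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- "chr1"
  h2 <- translated_search(prot, rc, min_score = 60, protein_id = "p")
  top2 <- h2[which.max(h2$score), ]
  expect_equal(top2$strand, "-")
  expect_equal(top2$score, top$score)
  L <- Biostrings::width(genome)[1]
  expect_equal(top2$start, L - top$end)
  expect_equal(top2$end, L - top$start)
})

test_that("translated search input contracts", {
  expect_error(translated_search("MKT", rand_dna(100)), "at least 20")
  expect_error(translated_search(paste0(rand_protein(30), "1"),
                                 rand_dna(100)), "non-amino-acid")
  empty <- translated_search(rand_protein(30),
                             Biostrings::DNAStringSet(character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("top translated-search score equals the exhaustive DP oracle", {
  set.seed(23)
  submat <- retroforge:::get_blosum62()
  for (rep in 1:3) {
    prot <- rand_protein(50)
    genome_chr <- rand_dna(3000)
    genome <- Biostrings::DNAStringSet(genome_chr); names(genome) <- "chr1"
    h <- translated_search(prot, genome, min_score = 20, protein_id = "p")
    impl_best <- max(h$score)
    # oracle: full local DP of the protein against each of the six frames
    frames <- retroforge::prepare_genome_frames(genome)
    oracle_best <- max(vapply(frames$frames, function(fr)
      oracle_local_score(prot, fr$aa, submat), numeric(1)))
    expect_equal(impl_best, oracle_best)
  }
})

test_that("raising min_score never adds hits (nested result sets)", {
  set.seed(71)
  prot <- rand_protein(60)
  genome <- Biostrings::DNAStringSet(paste0(
    rand_dna(300), back_translate(prot), rand_dna(3000)))
  names(genome) <- "chr1"
  lo <- translated_search(prot, genome, min_score = 20, protein_id = "p")
  hi <- translated_search(prot, genome, min_score = 100, protein_id = "p")
  expect_true(all(paste(hi$start, hi$end, hi$strand, hi$frame) %in%
                    paste(lo$start, lo$end, lo$strand, lo$frame)))
  expect_true(all(hi$score >= 100))
})

test_that("decoy calibration yields a workable threshold", {
  set.seed(3)
  genome <- Biostrings::DNAStringSet(rand_dna(30000)); names(genome) <- "chr1"
  prot <- rand_protein(80)
  s_strict <- calibrate_min_score(prot, genome, n_decoys = 8,
                                  target_hits_per_mb = 1e-3)
  s_loose <- calibrate_min_score(prot, genome, n_decoys = 8,
                                 target_hits_per_mb = 1)
  expect_gt(s_strict, s_loose) # rarer hits need higher scores
  # a planted true copy scores far above the calibrated threshold
  planted <- Biostrings::DNAStringSet(paste0(rand_dna(200),
                                             back_translate(prot),
                                             rand_dna(200)))
  names(planted) <- "chr1"
  h <- translated_search(prot, planted, min_score = 30, protein_id = "p")
  expect_gt(max(h$score), s_strict)
})

test_that("spliced alignment recovers annotated parent structure", {
  sim <- shared_sim()
  ann <- sim$annotation
  contig <- as.character(sim$genome[[1]])
  for (gid in c("gene001", "gene002")) {
    g <- ann[ann$type == "gene" & ann$gene_id == gid, ]
    region <- substr(contig, g$start + 1, g$end)
    if (g$strand == "-") region <- retroforge:::.revcomp(region)
    st <- spliced_align(as.character(sim$proteome[[gid]]), region)
    exp_introns <- sum(ann$type == "exon" & ann$gene_id == gid) - 1
    expect_true(st$accepted)
    expect_equal(nrow(st$introns), exp_introns)
    expect_true(all(st$introns$donor == "GT"))
    expect_true(all(st$introns$acceptor == "AG"))
    # intron coordinates match the annotation's inter-exon gaps
    ex <- ann[ann$type == "exon" & ann$gene_id == gid, ]
    widths <- sort(ex$start)[-1] - sort(ex$end)[-nrow(ex)]
    expect_setequal(st$introns$length, widths)
  }
})

test_that("spliced alignment of a parent protein to its retrocopy is intronless", {
  sim <- shared_sim()
  contig <- as.character(sim$genome[[1]])
  truth <- sim$truth[sim$truth$class == "intact", ]
  for (r in seq_len(nrow(truth))) {
    seqr <- substr(contig, truth$start[r] + 1, truth$end[r])
    if (truth$strand[r] == "-") seqr <- retroforge:::.revcomp(seqr)
    st <- spliced_align(as.character(sim$proteome[[truth$parent_id[r]]]), seqr)
    expect_true(st$accepted)
    expect_equal(nrow(st$introns), 0)
  }
})

test_that("tiny spliced instance equals the exhaustive placement oracle", {
  set.seed(13)
  for (rep in 1:2) {
    prot <- rand_protein(20)
    cds <- back_translate(prot)
    intron <- paste0("GT", rand_dna(46), "AG") # 50 bp canonical intron
    dna <- paste0(rand_dna(15), substr(cds, 1, 30), intron,
                  substr(cds, 31, 60), rand_dna(15))
    impl <- spliced_align(prot, dna, min_intron_bp = 40, filtration_score = 10)
    oracle <- oracle_single_intron_score(prot, dna, min_intron = 40,
                                         intron_open = 50, donor_bonus = 5,
                                         acceptor_bonus = 5)
    expect_equal(impl$score, oracle)
    expect_equal(nrow(impl$introns), 1)
    expect_equal(impl$introns$length, 50)
  }
})

test_that("spliced alignment rejects undersized regions and weak structures", {
  r <- spliced_align("MKTAYIAKQRQISFVKSHFSRQ", "ACGT")
  expect_false(r$accepted)
  set.seed(2)
  weak <- spliced_align(rand_protein(30), rand_dna(90),
                        filtration_score = 200)
  expect_false(weak$accepted)
})

test_that("nucleotide search: unique and duplicated placements, oracle identity", {
  set.seed(9)
  core <- rand_dna(150)
  genome <- Biostrings::DNAStringSet(paste0(rand_dna(300), core, rand_dna(300)))
  names(genome) <- "chr1"
  h <- nucleotide_search(core, genome, min_len = 100, est_id = "e1")
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 100)
  expect_equal(h$start, 300)
  expect_equal(h$end, 450)
  # exact duplication: two equal-identity placements
  genome2 <- Biostrings::DNAStringSet(paste0(rand_dna(200), core,
                                             rand_dna(200), core, rand_dna(100)))
  names(genome2) <- "chr1"
  h2 <- nucleotide_search(core, genome2, min_len = 100, est_id = "e1")
  expect_equal(nrow(h2), 2)
  expect_equal(h2$identity, c(100, 100))
  # identity of the best placement equals the DP oracle's best score path
  mut <- retroforge::mutate_k2p(core, 0.02)$seq
  genome3 <- Biostrings::DNAStringSet(paste0(rand_dna(100), mut, rand_dna(100)))
  names(genome3) <- "chr1"
  h3 <- nucleotide_search(core, genome3, min_len = 100, est_id = "e1")
  oracle <- oracle_local_score(core, as.character(genome3[[1]]),
                               oracle_nt_submat(), open = 5, ext = 3)
  expect_equal(max(h3$score), oracle)
  expect_error(nucleotide_search(rand_dna(50), genome, min_len = 100),
               "below min_len")
})

test_that("codon-aware CDS alignment: identity, codon gaps, oracle equality", {
  set.seed(4)
  prot <- rand_protein(40)
  a <- back_translate(prot)
  al <- align_cds_pair(a, a)
  expect_equal(al$identity, 100)
  expect_equal(al$n_gap_codons, 0)
  # one deleted codon produces a single 3-nt gap at a codon boundary
  b <- paste0(substr(a, 1, 30), substr(a, 34, nchar(a)))
  al2 <- align_cds_pair(a, b)
  expect_equal(al2$n_gap_codons, 1)
  gap_pos <- as.integer(regexpr("---", al2$aligned_b))
  expect_gt(gap_pos, 0)
  expect_equal((gap_pos - 1) %% 3, 0)
  # in the gap-free limit the score equals an unconstrained nucleotide NW
  x <- rand_dna(60); y <- retroforge::mutate_k2p(x, 0.05)$seq
  al3 <- align_cds_pair(x, y)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  expect_equal(al3$score, sum(ifelse(xs == ys, 1, -1)))
  expect_error(align_cds_pair("ACGTA", "ACGTAA"), "codons")
})

test_that("EST placement map is deterministic and respects strand", {
  set.seed(77)
  core <- rand_dna(200)
  genome <- Biostrings::DNAStringSet(paste0(rand_dna(150), core, rand_dna(150)))
  names(genome) <- "chr1"
  rc <- retroforge:::.revcomp(core)
  h <- nucleotide_search(rc, genome, min_len = 100, est_id = "e")
  expect_equal(h$strand, "-")
  expect_equal(h$start, 150)
  expect_equal(h$end, 350)
})
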