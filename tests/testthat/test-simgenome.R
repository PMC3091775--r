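# Synthetic-genome generator: determinism, planted-feature bookkeeping,
# disablement planting, EST sampling statistics, annotation validity.

test_that("configuration invariants are enforced", {
  expect_s3_class(small_config(), "sim_config")
  expect_error(sim_config(retro_divergence = 0.8), "0.75")
  expect_error(sim_config(intron_length = c(60, 200)), "70")
  expect_error(sim_config(n_retro_intact = -1), ">= 0")
  expect_error(sim_config(est_length = c(50, 200)), "100")
  expect_error(sim_config(est_error_rate = 1.2), "est_error_rate")
})

test_that("identical configurations give byte-identical output", {
  cfg <- sim_config(genome_length = 50000, n_parent_genes = 3,
                    n_retro_intact = 1, n_retro_pseudo = 1,
                    n_retro_chimeric = 1, n_single_exon_decoys = 1,
                    n_decoy_retro = 0, seed = 42)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  ra <- sample_ests(a); rb <- sample_ests(b)
  expect_identical(as.character(ra$ests), as.character(rb$ests))
  # a different seed changes the genome
  cfg2 <- sim_config(genome_length = 50000, n_parent_genes = 3,
                     n_retro_intact = 1, n_retro_pseudo = 1,
                     n_retro_chimeric = 1, n_single_exon_decoys = 1,
                     n_decoy_retro = 0, seed = 43)
  expect_false(identical(as.character(generate_genome(cfg2)$genome),
                         as.character(a$genome)))
})

test_that("planted features are bookkept with the closed label vocabulary", {
  sim <- shared_sim()
  cfg <- sim$config
  expect_equal(nrow(sim$truth),
               cfg$n_retro_intact + cfg$n_retro_pseudo + cfg$n_retro_chimeric)
  expect_equal(sum(sim$truth$class == "intact"), cfg$n_retro_intact)
  expect_equal(sum(sim$truth$class %in% c("frameshift", "premature_stop")),
               cfg$n_retro_pseudo)
  expect_equal(sum(grepl("^chimeric_", sim$truth$class)), cfg$n_retro_chimeric)
  expect_true(all(sim$truth$class %in%
                    c("intact", "frameshift", "premature_stop", "chimeric_N",
                      "chimeric_C", "chimeric_both", "chimeric_UTR")))
  # every planted interval lies within the genome
  L <- Biostrings::width(sim$genome)[1]
  expect_true(all(sim$truth$start >= 0 & sim$truth$end <= L))
  expect_true(all(sim$truth$end > sim$truth$start))
})

test_that("zero divergence gives exact parent CDS copies", {
  cfg <- sim_config(genome_length = 60000, n_parent_genes = 3,
                    n_retro_intact = 2, n_retro_pseudo = 0,
                    n_retro_chimeric = 0, n_single_exon_decoys = 0,
                    n_decoy_retro = 0, retro_divergence = 0, seed = 11)
  sim <- generate_genome(cfg)
  contig <- as.character(sim$genome[[1]])
  for (r in seq_len(nrow(sim$truth))) {
    body <- substr(contig, sim$truth$start[r] + 1, sim$truth$end[r])
    if (sim$truth$strand[r] == "-") body <- retroforge:::.revcomp(body)
    expect_identical(body, unname(sim$cds[sim$truth$parent_id[r]]))
    expect_equal(sim$truth$divergence[r], 0)
  }
})

test_that("planted copies diverge by the configured amount", {
  sim <- shared_sim()
  contig <- as.character(sim$genome[[1]])
  plain <- sim$truth[!grepl("chimeric", sim$truth$class), ]
  for (r in seq_len(nrow(plain))) {
    expect_equal(plain$divergence[r], sim$config$retro_divergence,
                 tolerance = 0.2)
    if (plain$class[r] != "intact") next
    body <- substr(contig, plain$start[r] + 1, plain$end[r])
    if (plain$strand[r] == "-") body <- retroforge:::.revcomp(body)
    parent <- unname(sim$cds[plain$parent_id[r]])
    # identity within 3 points of 1 - divergence
    bs <- strsplit(body, "")[[1]]; ps <- strsplit(parent, "")[[1]]
    expect_equal(length(bs), length(ps))
    expect_equal(mean(bs == ps), 1 - plain$divergence[r], tolerance = 0.03)
  }
})

test_that("parent genes have >= 2 GT-AG introns and clean ORFs", {
  sim <- shared_sim()
  contig <- as.character(sim$genome[[1]])
  validate_annotation(sim$annotation)
  for (gid in grep("^gene", names(sim$cds), value = TRUE)) {
    ex <- sim$annotation[sim$annotation$gene_id == gid &
                           sim$annotation$type == "exon", ]
    expect_gte(nrow(ex), 2)
    ex <- ex[order(ex$start), ]
    # introns between consecutive exons are canonical on the coding strand
    for (k in seq_len(nrow(ex) - 1)) {
      intron <- substr(contig, ex$end[k] + 1, ex$start[k + 1])
      if (ex$strand[1] == "-") intron <- retroforge:::.revcomp(intron)
      expect_identical(substr(intron, 1, 2), "GT")
      expect_identical(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
      expect_gt(nchar(intron), 70)
    }
    cds <- sim$cds[[gid]]
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_identical(substr(cds, 1, 3), "ATG")
  }
})

test_that("sizing errors name the deficit", {
  expect_error(generate_genome(sim_config(genome_length = 20000,
                                          n_parent_genes = 20, seed = 1)),
               "more bp")
})

test_that("disablement planting follows the definitions", {
  set.seed(123)
  cds <- retroforge:::.rand_cds(80)
  for (i in 1:10) {
    fs <- plant_disablement(cds, "frameshift")
    expect_true((nchar(fs$seq) - nchar(cds)) %% 3 != 0)
    expect_equal(fs$record$kind, "frameshift")
    ps <- plant_disablement(cds, "premature_stop")
    expect_equal(nchar(ps$seq), nchar(cds))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(ps$seq)))
    body <- substr(aa, 1, nchar(aa) - 1)
    expect_true(grepl("\\*", body))
    # planted before 80% of the CDS
    expect_lt(ps$record$position, 0.8 * nchar(cds))
  }
  expect_error(plant_disablement(substr(cds, 1, 57), "frameshift"), "short")
  # same RNG state reproduces the same mutation
  set.seed(9); a <- plant_disablement(cds, "frameshift")
  set.seed(9); b <- plant_disablement(cds, "frameshift")
  expect_identical(a, b)
})

test_that("EST sampling respects rates, lengths and the error model", {
  sim <- shared_sim()
  reads <- shared_reads()
  expect_true(all(Biostrings::width(reads$ests) >= 100))
  expect_equal(nrow(reads$est_truth), length(reads$ests))
  # error-free configuration: every EST is an exact substring of its source
  cfg0 <- sim_config(genome_length = 60000, n_parent_genes = 4,
                     n_retro_intact = 1, n_retro_pseudo = 0,
                     n_retro_chimeric = 0, n_single_exon_decoys = 0,
                     n_decoy_retro = 0, est_error_rate = 0, seed = 21)
  sim0 <- generate_genome(cfg0)
  reads0 <- sample_ests(sim0)
  for (i in seq_along(reads0$ests)) {
    src <- sim0$transcripts[[reads0$est_truth$source_id[i]]]
    est <- as.character(reads0$ests[[i]])
    if (reads0$est_truth$orientation[i] == "-") est <- retroforge:::.revcomp(est)
    expect_true(grepl(est, src, fixed = TRUE))
  }
  # zero rate: no ESTs at all
  cfg_none <- sim_config(genome_length = 60000, n_parent_genes = 4,
                         n_retro_intact = 1, n_retro_pseudo = 0,
                         n_retro_chimeric = 0, n_single_exon_decoys = 0,
                         n_decoy_retro = 0, est_per_transcript = 0, seed = 21)
  reads_none <- sample_ests(generate_genome(cfg_none))
  expect_equal(length(reads_none$ests), 0)
})

test_that("observed EST error fraction is within 3 binomial SDs of the rate", {
  cfg <- sim_config(genome_length = 80000, n_parent_genes = 6,
                    n_retro_intact = 0, n_retro_pseudo = 0,
                    n_retro_chimeric = 0, n_single_exon_decoys = 0,
                    n_decoy_retro = 0, est_per_transcript = 25,
                    est_error_rate = 0.01, seed = 33)
  sim <- generate_genome(cfg)
  reads <- sample_ests(sim)
  total_bases <- sum(Biostrings::width(reads$ests))
  expect_gt(total_bases, 10000)
  # recount errors directly against the sources
  n_err <- 0
  for (i in seq_along(reads$ests)) {
    tr <- reads$est_truth[i, ]
    src <- substr(sim$transcripts[[tr$source_id]], tr$src_start + 1, tr$src_end)
    est <- as.character(reads$ests[[i]])
    if (tr$orientation == "-") est <- retroforge:::.revcomp(est)
    n_err <- n_err + sum(strsplit(est, "")[[1]] != strsplit(src, "")[[1]])
  }
  p_hat <- n_err / total_bases
  sd3 <- 3 * sqrt(0.01 * 0.99 / total_bases)
  expect_lt(abs(p_hat - 0.01), sd3 + 1e-9)
})

test_that("GFF3 round trip preserves coordinates and strands", {
  sim <- shared_sim()
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$annotation, path)
  back <- read_gff3(path)
  key <- function(x) paste(x$seqid, x$type, x$start, x$end, x$strand)
  expect_setequal(key(back), key(sim$annotation))
  unlink(path)
})

test_that("write_simulation emits the documented file set", {
  cfg <- sim_config(genome_length = 50000, n_parent_genes = 3,
                    n_retro_intact = 1, n_retro_pseudo = 0,
                    n_retro_chimeric = 0, n_single_exon_decoys = 0,
                    n_decoy_retro = 0, seed = 2)
  sim <- generate_genome(cfg)
  out <- tempfile()
  paths <- write_simulation(sim, out, reads = sample_ests(sim))
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths["genome"])
  expect_equal(unname(Biostrings::width(fa)), cfg$genome_length)
  truth <- utils::read.delim(paths["truth"])
  expect_equal(nrow(truth), nrow(sim$truth))
  unlink(out, recursive = TRUE)
})
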