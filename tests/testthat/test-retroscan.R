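# Pipeline stages: merge boundary behavior, candidate filters, parent
# assignment rules, intron-loss confirmation boundaries, duplicate demotion,
# disablement classification, end-to-end recovery on the shared fixture.

mk_hits <- function(starts, ends, q_starts, q_ends, strand = "+",
                    identity = 90, protein_length = 200) {
  tibble::tibble(
    protein_id = "p1", seqid = "chr1",
    start = as.integer(starts), end = as.integer(ends), strand = strand,
    frame = 0L, score = 100, identity = identity,
    q_start = as.integer(q_starts), q_end = as.integer(q_ends),
    n_aligned = as.integer(q_ends - q_starts + 1L),
    protein_length = as.integer(protein_length))
}

test_that("merge gap boundary: 39 bp merges, 40 bp does not", {
  h39 <- mk_hits(c(1000, 1239), c(1200, 1500), c(1, 70), c(60, 160))
  m39 <- merge_hits(h39, merge_gap_bp = 40)
  expect_equal(nrow(m39), 1) # gap = 1239 - 1200 = 39 < 40
  expect_equal(m39$start, 1000)
  expect_equal(m39$end, 1500)
  h40 <- mk_hits(c(1000, 1240), c(1200, 1500), c(1, 70), c(60, 160))
  expect_equal(nrow(merge_hits(h40, merge_gap_bp = 40)), 2)
})

test_that("merging is idempotent, order-invariant and strand-separating", {
  h <- mk_hits(c(1000, 1220, 5000), c(1200, 1400, 5300),
               c(1, 70, 1), c(60, 130, 100))
  m1 <- merge_hits(h, 40)
  m2 <- merge_hits(h[c(3, 1, 2), ], 40)
  expect_equal(m1, m2)
  expect_equal(nrow(m1), 2)
  # a single hit passes through unchanged
  single <- merge_hits(h[1, ], 40)
  expect_equal(single$start, 1000)
  expect_equal(single$n_hits, 1)
  # opposite strands never merge
  hs <- dplyr::bind_rows(mk_hits(1000, 1200, 1, 60),
                         mk_hits(1210, 1400, 61, 120, strand = "-"))
  expect_equal(nrow(merge_hits(hs, 40)), 2)
  # mixed proteins are an input error
  bad <- h; bad$protein_id[1] <- "p2"
  expect_error(merge_hits(bad), "single protein")
})

test_that("merged identity and coverage pool the member hits", {
  h <- mk_hits(c(1000, 1239), c(1200, 1500), c(1, 61), c(60, 160))
  h$identity <- c(100, 70)
  m <- merge_hits(h, 40)
  expect_equal(m$n_aligned, 160) # union of 1-60 and 61-160
  expect_equal(m$coverage, 160 / 200)
  expect_equal(m$identity,
               (100 * 60 + 70 * 100) / 160)
})

test_that("candidate filters apply the published thresholds strictly", {
  base <- merge_hits(mk_hits(1000, 1600, 1, 150), 40)
  cfg <- pipeline_config()
  at <- function(identity = 80, coverage = 0.8, n_aligned = 150L) {
    x <- base
    x$identity <- identity; x$coverage <- coverage
    x$n_aligned <- as.integer(n_aligned)
    x
  }
  expect_equal(nrow(filter_candidates(at(identity = 49), cfg)), 0)
  expect_equal(nrow(filter_candidates(at(identity = 50), cfg)), 0) # strict >
  expect_equal(nrow(filter_candidates(at(identity = 51), cfg)), 1)
  expect_equal(nrow(filter_candidates(at(coverage = 0.69), cfg)), 0)
  expect_equal(nrow(filter_candidates(at(coverage = 0.71), cfg)), 1)
  expect_equal(nrow(filter_candidates(at(n_aligned = 49), cfg)), 0)
  expect_equal(nrow(filter_candidates(at(n_aligned = 50), cfg)), 1) # at least
})

test_that("intron-loss confirmation boundary: > 70 bp confirms, 70 does not", {
  mk_struct <- function(intron_lengths, q_boundaries, q_range = c(1, 200),
                        score = 500) {
    structure(list(
      score = score, accepted = TRUE, reason = NA_character_,
      exons = tibble::tibble(dna_start = 0, dna_end = 600,
                             q_start = q_range[1], q_end = q_range[2]),
      introns = tibble::tibble(
        dna_start = 0, dna_end = intron_lengths,
        length = intron_lengths,
        donor = rep("GT", length(intron_lengths)),
        acceptor = rep("AG", length(intron_lengths)),
        q_boundary = q_boundaries)
    ), class = "spliced_structure")
  }
  no_introns <- mk_struct(numeric(0), integer(0))
  retro_flat <- no_introns
  parent71 <- mk_struct(71, 100)
  parent70 <- mk_struct(70, 100)
  expect_true(confirm_intron_loss(parent71, retro_flat))
  expect_false(confirm_intron_loss(parent70, retro_flat))
  # candidate spanning only one parental exon cannot confirm
  narrow <- mk_struct(numeric(0), integer(0))
  narrow$exons$q_start <- 1; narrow$exons$q_end <- 90
  expect_false(confirm_intron_loss(parent71, narrow))
  # parental structure without introns is rejected outright
  expect_false(confirm_intron_loss(no_introns, retro_flat))
  expect_match(attr(confirm_intron_loss(no_introns, retro_flat), "reason"),
               "no introns")
  # an intron retained at the same protein position blocks confirmation
  retro_same <- mk_struct(80, 100)
  expect_false(confirm_intron_loss(parent71, retro_same))
})

test_that("retro-derived duplicates are demoted, ties stay primary", {
  set.seed(15)
  parent <- retroforge:::.rand_cds(120)
  old_retro <- mutate_k2p(parent, 0.15)$seq   # old, diverged copy
  dup <- mutate_k2p(old_retro, 0.01)$seq      # near-identical copy of the copy
  genome <- Biostrings::DNAStringSet(paste0(
    strrep("A", 100), old_retro, strrep("C", 100), dup, strrep("G", 100)))
  names(genome) <- "chr1"
  calls <- tibble::tibble(
    call_id = c("rc1", "rc2"), parent_id = "gene1", seqid = "chr1",
    start = c(100L, 100L + 360L + 100L),
    end = c(100L + 360L, 100L + 360L + 100L + 360L),
    strand = "+")
  out <- exclude_retro_derived(calls, genome, list(gene1 = parent))
  # the two copies match each other better than the parent CDS: demoted
  expect_equal(out$primary, c(FALSE, FALSE))
  # a unique retrocopy stays primary
  solo <- exclude_retro_derived(calls[1, ], genome, list(gene1 = parent))
  expect_true(solo$primary)
  # two independent copies of the same parent stay primary: each matches the
  # parent better than it matches the other copy
  indep1 <- mutate_k2p(parent, 0.1)$seq
  indep2 <- mutate_k2p(parent, 0.1)$seq
  genome2 <- Biostrings::DNAStringSet(paste0(
    strrep("A", 100), indep1, strrep("C", 100), indep2, strrep("G", 100)))
  names(genome2) <- "chr1"
  out2 <- exclude_retro_derived(calls, genome2, list(gene1 = parent))
  expect_equal(out2$primary, c(TRUE, TRUE))
})

test_that("disablement classification detects planted lesions", {
  set.seed(44)
  parent <- retroforge:::.rand_cds(150)
  # clean diverged copy stays intact
  clean <- mutate_k2p(parent, 0.05, avoid_stop_frame = TRUE)$seq
  r <- classify_disablements(parent, clean)
  expect_equal(r$classification, "intact")
  expect_equal(nrow(r$disablements), 0)
  # 1-nt deletion mid-CDS is a frameshift
  p <- 220
  fs_seq <- paste0(substr(clean, 1, p), substr(clean, p + 2, nchar(clean)))
  r_fs <- classify_disablements(parent, fs_seq)
  expect_equal(r_fs$classification, "pseudogene")
  expect_true("frameshift" %in% r_fs$disablements$kind)
  # in-frame TGA at half the CDS is a premature stop
  j <- 75
  ps_seq <- paste0(substr(clean, 1, 3 * (j - 1)), "TGA",
                   substr(clean, 3 * j + 1, nchar(clean)))
  r_ps <- classify_disablements(parent, ps_seq)
  expect_equal(r_ps$classification, "pseudogene")
  expect_true("premature_stop" %in% r_ps$disablements$kind)
  # the projected codon pair supports Ka/Ks computation
  kk <- kaks_lpb(r$codon_pair$parent, r$codon_pair$candidate,
                 drop_stops = TRUE)
  expect_gte(kk$ks, 0)
})

test_that("pipeline recovers planted retrocopies with correct parents", {
  sim <- shared_sim()
  res <- shared_result()
  ev <- evaluate_calls(res, sim$truth)
  expect_gte(ev$sensitivity, 0.9)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$classification_agreement, 1)
  # stage monotonicity: the funnel never grows
  sc <- res$stage_counts
  funnel <- sc$n[sc$stage %in% c("merged_candidates", "filtered",
                                 "distinct_loci", "parent_assigned",
                                 "intron_loss_confirmed")]
  expect_true(all(diff(funnel) <= 0))
  # no call overlaps its own parent locus
  genes <- sim$annotation[sim$annotation$type == "gene", ]
  for (i in seq_len(nrow(res$calls))) {
    g <- genes[genes$gene_id == res$calls$parent_id[i], ]
    expect_true(res$calls$end[i] <= g$start || res$calls$start[i] >= g$end)
  }
  # intragenic flags match the planted geometry
  m <- ev$matches[ev$matches$matched, ]
  flags <- merge(m, sim$truth[, c("retro_id", "intragenic")], by = "retro_id")
  called <- res$calls[match(flags$call_id, res$calls$call_id), ]
  plain <- !grepl("chimeric", flags$class)
  expect_equal(called$intragenic[plain], flags$intragenic[plain])
})

test_that("a genome with no plantings yields no calls", {
  cfg <- sim_config(genome_length = 60000, n_parent_genes = 4,
                    n_retro_intact = 0, n_retro_pseudo = 0,
                    n_retro_chimeric = 0, n_single_exon_decoys = 1,
                    n_decoy_retro = 0, seed = 13)
  res <- run_pipeline(generate_genome(cfg))
  expect_equal(nrow(res$calls), 0)
  expect_equal(glance(res)$n_calls, 0)
})

test_that("result tidiers and plots expose the calls", {
  res <- shared_result()
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("call_id", "parent_id", "classification", "primary",
                    "ks") %in% names(td)))
  g <- glance(res)
  expect_equal(g$n_calls, nrow(res$calls))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("pipeline_config rejects inconsistent thresholds", {
  expect_error(pipeline_config(confirm_span_bp = 30), "exceed")
  expect_error(pipeline_config(min_identity_pct = -1), "positive")
})
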