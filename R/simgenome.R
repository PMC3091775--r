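# Synthetic genomes with planted retrocopies and machine-readable ground
# truth: multi-exon parent genes with canonical GT-AG phase-0 introns,
# intron-less retrocopies (intact / disabled / chimeric) with poly(A) tracts
# and target-site duplications, EST/mRNA read sets, and ortholog CDS pairs
# for rate calibration. Coordinates are 0-based half-open throughout;
# conversion to 1-based happens only at the GFF3 boundary.

.STOPS <- c("TAA", "TAG", "TGA")

.rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rand_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c(.STOPS, "ATG"))
  body <- sample(sense, n_codons - 2, replace = TRUE)
  paste(c("ATG", body, sample(.STOPS, 1)), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.sample_range <- function(rng, n = 1) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-genome generator and validates it.
#' Defaults describe the standard recovery experiment: a 2 Mb genome with 60
#' multi-exon parent genes and 40 planted retrocopies (20 intact, 12
#' disabled, 8 chimeric) at 10% nucleotide divergence.
#'
#' @param genome_length total genome size in bp.
#' @param n_parent_genes number of multi-exon parent genes.
#' @param exons_per_gene length-2 range of exon counts per gene.
#' @param exon_length_codons length-2 range of codons per exon.
#' @param intron_length length-2 range of intron lengths (min must exceed
#'   70 bp so that planted parents satisfy the intron-loss confirmation rule).
#' @param n_retro_intact,n_retro_pseudo,n_retro_chimeric planted retrocopy
#'   counts by class.
#' @param n_single_exon_decoys single-exon (olfactory-like) decoy genes.
#' @param n_decoy_retro planted copies of a decoy gene (negative controls:
#'   the parent-assignment rule must reject them).
#' @param retro_divergence fraction of retrocopy sites substituted relative
#'   to the parent CDS, in `[0, 0.75)`.
#' @param ts_tv_ratio transition/transversion ratio of the mutation model.
#' @param polya_length,tsd_length length-2 ranges (bp) of the poly(A) tract
#'   and target-site duplication flanking each insertion.
#' @param intragenic_frac fraction of plain retrocopies planted inside host
#'   gene introns (never exons).
#' @param retro_transcribed_frac fraction of plain retrocopies that emit
#'   ESTs.
#' @param est_per_transcript mean EST count per transcribed sequence
#'   (Poisson).
#' @param est_length length-2 range of EST lengths (bp, min >= 100).
#' @param est_error_rate per-base EST substitution error rate.
#' @param mrna_fraction fraction of transcribed sources that also emit one
#'   full-length mRNA.
#' @param seed integer seed; identical configurations give byte-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 2e6,
                       n_parent_genes = 60,
                       exons_per_gene = c(3, 7),
                       exon_length_codons = c(30, 80),
                       intron_length = c(75, 400),
                       n_retro_intact = 20,
                       n_retro_pseudo = 12,
                       n_retro_chimeric = 8,
                       n_single_exon_decoys = 2,
                       n_decoy_retro = 1,
                       retro_divergence = 0.10,
                       ts_tv_ratio = 2,
                       polya_length = c(15, 30),
                       tsd_length = c(5, 15),
                       intragenic_frac = 0.35,
                       retro_transcribed_frac = 0.6,
                       est_per_transcript = 4,
                       est_length = c(150, 500),
                       est_error_rate = 0.005,
                       mrna_fraction = 0.3,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_parent_genes, cfg$n_retro_intact, cfg$n_retro_pseudo,
              cfg$n_retro_chimeric, cfg$n_single_exon_decoys, cfg$n_decoy_retro)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (cfg$retro_divergence < 0 || cfg$retro_divergence >= 0.75) {
    stop("retro_divergence must lie in [0, 0.75)", call. = FALSE)
  }
  if (cfg$intron_length[1] <= 70) {
    stop("minimum intron length must exceed 70 bp", call. = FALSE)
  }
  if (cfg$est_error_rate < 0 || cfg$est_error_rate >= 1) {
    stop("est_error_rate must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$ts_tv_ratio <= 0) stop("ts_tv_ratio must be positive", call. = FALSE)
  if (cfg$est_length[1] < 100) stop("minimum EST length must be >= 100", call. = FALSE)
  for (f in c("exons_per_gene", "exon_length_codons", "intron_length",
              "polya_length", "tsd_length", "est_length")) {
    r <- cfg[[f]]
    if (length(r) != 2 || r[1] > r[2]) stop(f, " must be a valid range", call. = FALSE)
  }
  if (cfg$n_decoy_retro > 0 && cfg$n_single_exon_decoys == 0) {
    stop("decoy retrocopies need at least one single-exon decoy gene", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Kimura two-parameter site substitution
#'
#' Substitutes `round(divergence * length)` distinct sites, each a transition
#' with probability `kappa / (kappa + 1)`, else a random transversion. With
#' `avoid_stop_frame = TRUE` any internal in-frame codon turned into a stop
#' is reverted, so intact copies keep an open reading frame.
#'
#' @param seq nucleotide string.
#' @param divergence target fraction of substituted sites.
#' @param kappa transition/transversion ratio.
#' @param avoid_stop_frame revert mutations creating internal in-frame stops
#'   (sequence read as codons from position 1).
#' @return list: `seq` (mutated), `divergence` (realized fraction).
#' @export
mutate_k2p <- function(seq, divergence, kappa = 2, avoid_stop_frame = FALSE) {
  x <- strsplit(toupper(as.character(seq)), "")[[1]]
  orig <- x
  L <- length(x)
  n_mut <- round(divergence * L)
  if (n_mut > 0) {
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    sites <- sample.int(L, n_mut)
    for (p in sites) {
      if (runif(1) < kappa / (kappa + 1)) {
        x[p] <- ts_map[[x[p]]]
      } else {
        x[p] <- sample(setdiff(c("A", "C", "G", "T"),
                               c(x[p], ts_map[[x[p]]])), 1)
      }
    }
    if (avoid_stop_frame && L >= 6) {
      n_cod <- L %/% 3
      for (j in seq_len(n_cod - 1)) {
        idx <- (3 * j - 2):(3 * j)
        if (paste(x[idx], collapse = "") %in% .STOPS) x[idx] <- orig[idx]
      }
    }
  }
  list(seq = paste(x, collapse = ""), divergence = mean(x != orig))
}

#' Plant a disabling mutation in a CDS copy
#'
#' `frameshift`: a 1- or 2-bp indel strictly inside the CDS (length not
#' divisible by 3). `premature_stop`: an in-frame stop codon before 80% of
#' the CDS length.
#'
#' @param cds_copy nucleotide string, length >= 60.
#' @param kind `"frameshift"` or `"premature_stop"`.
#' @return list: `seq` (mutated), `record` (tibble with `kind`, `position`
#'   0-based).
#' @export
plant_disablement <- function(cds_copy, kind = c("frameshift", "premature_stop")) {
  kind <- match.arg(kind)
  x <- toupper(as.character(cds_copy))
  L <- nchar(x)
  if (L < 60) stop("CDS too short to disable (", L, " < 60 nt)", call. = FALSE)
  if (kind == "frameshift") {
    p <- sample(seq(ceiling(0.2 * L), floor(0.7 * L)), 1)
    ilen <- sample(1:2, 1)
    if (runif(1) < 0.5) {
      seq <- paste0(substr(x, 1, p), substr(x, p + ilen + 1, L))      # deletion
    } else {
      seq <- paste0(substr(x, 1, p), .rand_nt(ilen), substr(x, p + 1, L)) # insertion
    }
    rec <- tibble(kind = "frameshift", position = p)
  } else {
    n_cod <- L %/% 3
    lo <- max(2, ceiling(0.15 * n_cod))
    hi <- max(lo, floor(0.8 * n_cod) - 1)
    j <- sample(seq(lo, hi), 1)
    stop_codon <- sample(.STOPS, 1)
    seq <- paste0(substr(x, 1, 3 * (j - 1)), stop_codon, substr(x, 3 * j + 1, L))
    rec <- tibble(kind = "premature_stop", position = 3L * (j - 1L))
  }
  list(seq = seq, record = rec)
}

# ---- gene construction -----------------------------------------------------

.flip_iv <- function(start, end, L) c(L - end, L - start)

# Build one gene element in + orientation, optionally flipped to minus.
# `insert`: list(seq, intron_index) planted mid-intron (host-gene case).
.make_gene <- function(gene_id, exon_codons, intron_lengths, strand = "+",
                       insert = NULL) {
  cds <- .rand_cds(sum(exon_codons))
  ends <- cumsum(exon_codons) * 3
  starts <- c(0, ends[-length(ends)])
  exon_seqs <- substring(cds, starts + 1, ends)
  intron_seqs <- vapply(intron_lengths, function(l) {
    paste0("GT", .rand_nt(l - 4), "AG")
  }, "")
  insert_iv <- NULL
  if (!is.null(insert)) {
    k <- insert$intron_index
    half <- nchar(intron_seqs[k]) %/% 2
    intron_seqs[k] <- paste0(substr(intron_seqs[k], 1, half), insert$seq,
                             substr(intron_seqs[k], half + 1,
                                    nchar(intron_seqs[k])))
  }
  pieces <- character(0)
  feats <- list()
  off <- 0L
  for (i in seq_along(exon_seqs)) {
    w <- nchar(exon_seqs[i])
    feats[[length(feats) + 1]] <- tibble(type = c("exon", "CDS"),
                                         start = off, end = off + w,
                                         exon_number = i)
    pieces <- c(pieces, exon_seqs[i])
    off <- off + w
    if (i <= length(intron_seqs)) {
      if (!is.null(insert) && insert$intron_index == i) {
        half <- (nchar(intron_seqs[i]) - nchar(insert$seq)) %/% 2
        insert_iv <- c(off + half, off + half + nchar(insert$seq))
      }
      pieces <- c(pieces, intron_seqs[i])
      off <- off + nchar(intron_seqs[i])
    }
  }
  seq <- paste(pieces, collapse = "")
  L <- nchar(seq)
  ft <- bind_rows(feats)
  if (strand == "-") {
    seq <- .revcomp(seq)
    new_start <- L - ft$end
    ft$end <- L - ft$start
    ft$start <- new_start
    if (!is.null(insert_iv)) insert_iv <- .flip_iv(insert_iv[1], insert_iv[2], L)
  }
  ft <- bind_rows(
    tibble(type = c("gene", "mRNA"), start = 0L, end = L, exon_number = NA_integer_),
    ft)
  ft$strand <- strand
  ft$gene_id <- gene_id
  ft$transcript_id <- paste0(gene_id, ".t1")
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, nchar(cds) - 3))))
  list(seq = seq, features = ft, cds = cds, protein = protein,
       insert_iv = insert_iv, length = L, gene_id = gene_id)
}

# cassette around a retro body: TSD + [body (+ polyA)] + TSD, optionally
# reverse-complemented body+polyA for minus-strand insertions
.make_cassette <- function(body, strand, polya_rng, tsd_rng) {
  tsd <- .rand_nt(.sample_range(tsd_rng))
  polya <- strrep("A", .sample_range(polya_rng))
  core <- paste0(body, polya)
  if (strand == "-") core <- .revcomp(core)
  b_off <- if (strand == "+") 0L else nchar(polya)
  list(seq = paste0(tsd, core, tsd),
       body_iv = c(nchar(tsd) + b_off, nchar(tsd) + b_off + nchar(body)))
}

# ---- chimera complex builders (all transcripts on + strand) ----------------

# Returns an element: seq, features (partner gene + chimeric transcript),
# truth row fields for the planted retro.
.make_chimera <- function(idx, category, new_splice_site, parent, divergence,
                          kappa, polya_rng, tsd_rng) {
  chim_id <- sprintf("chim%02d", idx)
  partner_id <- sprintf("partner%02d", idx)
  body_src <- substr(parent$cds, 1, nchar(parent$cds) - 3) # drop terminal stop
  mut <- mutate_k2p(body_src, divergence, kappa, avoid_stop_frame = TRUE)
  R <- mut$seq
  rlen <- nchar(R)
  r_codons <- rlen %/% 3
  spacer <- paste0("GT", .rand_nt(max(100, 150 - 4)), "AG")

  feats <- list()
  add_feat <- function(type, start, end, gid, tid, exon_number = NA_integer_) {
    feats[[length(feats) + 1]] <<- tibble(
      type = type, start = as.integer(start), end = as.integer(end),
      exon_number = exon_number, strand = "+", gene_id = gid,
      transcript_id = tid)
  }
  chim_tid <- paste0(chim_id, ".t1")

  if (category %in% c("chimeric_C", "chimeric_N")) {
    shared_codons <- max(30, ceiling(0.55 * r_codons))
    other_codons <- 40
    if (category == "chimeric_C") {
      partner <- .make_gene(partner_id, c(shared_codons, other_codons),
                            .sample_range(c(80, 200)), "+")
      seq <- paste0(R, spacer, partner$seq)
      p_off <- rlen + nchar(spacer)
      shared <- partner$features %>%
        filter(.data$type == "exon", .data$exon_number == 1)
      sh_iv <- c(p_off + shared$start, p_off + shared$end)
      if (new_splice_site) {
        ex1_end <- 3 * floor(0.6 * r_codons)
        add_feat("exon", 0, ex1_end, chim_id, chim_tid, 1L)
        add_feat("CDS", 0, ex1_end, chim_id, chim_tid, 1L)
      } else {
        add_feat("exon", 0, rlen, chim_id, chim_tid, 1L)
        add_feat("CDS", 0, rlen, chim_id, chim_tid, 1L)
      }
      add_feat("exon", sh_iv[1], sh_iv[2], chim_id, chim_tid, 2L)
      add_feat("CDS", sh_iv[1], sh_iv[2], chim_id, chim_tid, 2L)
      body_iv <- c(0L, rlen)
    } else { # chimeric_N: partner left, shared = partner's last exon, then R
      partner <- .make_gene(partner_id, c(other_codons, shared_codons),
                            .sample_range(c(80, 200)), "+")
      seq <- paste0(partner$seq, spacer, R)
      r_off <- partner$length + nchar(spacer)
      shared <- partner$features %>%
        filter(.data$type == "exon", .data$exon_number == 2)
      add_feat("exon", shared$start, shared$end, chim_id, chim_tid, 1L)
      add_feat("CDS", shared$start, shared$end, chim_id, chim_tid, 1L)
      if (new_splice_site) {
        ex2_start <- r_off + 3 * floor(0.4 * r_codons)
        add_feat("exon", ex2_start, r_off + rlen, chim_id, chim_tid, 2L)
        add_feat("CDS", ex2_start, r_off + rlen, chim_id, chim_tid, 2L)
      } else {
        add_feat("exon", r_off, r_off + rlen, chim_id, chim_tid, 2L)
        add_feat("CDS", r_off, r_off + rlen, chim_id, chim_tid, 2L)
      }
      body_iv <- c(r_off, r_off + rlen)
    }
    feats[[length(feats) + 1]] <- partner$features %>%
      mutate(start = .data$start + if (category == "chimeric_C") p_off else 0L,
             end = .data$end + if (category == "chimeric_C") p_off else 0L)
    mode_truth <- "fusion"
  } else if (category == "chimeric_both") {
    e_codons <- max(25, ceiling(0.3 * r_codons))
    cassette <- .make_cassette(R, "+", polya_rng, tsd_rng)
    partner <- .make_gene(partner_id, c(e_codons, e_codons),
                          max(300, rlen + 250),
                          "+", insert = list(seq = cassette$seq, intron_index = 1))
    seq <- partner$seq
    body_iv <- c(partner$insert_iv[1] + cassette$body_iv[1],
                 partner$insert_iv[1] + cassette$body_iv[2])
    pex <- partner$features %>% filter(.data$type == "exon")
    add_feat("exon", pex$start[1], pex$end[1], chim_id, chim_tid, 1L)
    add_feat("CDS", pex$start[1], pex$end[1], chim_id, chim_tid, 1L)
    add_feat("exon", body_iv[1], body_iv[2], chim_id, chim_tid, 2L)
    add_feat("CDS", body_iv[1], body_iv[2], chim_id, chim_tid, 2L)
    add_feat("exon", pex$start[2], pex$end[2], chim_id, chim_tid, 3L)
    add_feat("CDS", pex$start[2], pex$end[2], chim_id, chim_tid, 3L)
    feats[[length(feats) + 1]] <- partner$features
    mode_truth <- "fusion"
  } else { # chimeric_UTR: recruited UTRs around the retro, single exon
    u5 <- .rand_nt(max(60, ceiling(0.25 * rlen)))
    u3 <- .rand_nt(max(60, ceiling(0.20 * rlen)))
    seq <- paste0(u5, R, u3)
    body_iv <- c(nchar(u5), nchar(u5) + rlen)
    cds_start <- nchar(u5) + 3 * floor(0.4 * r_codons)
    add_feat("exon", 0, nchar(seq), chim_id, chim_tid, 1L)
    add_feat("CDS", cds_start, nchar(u5) + rlen, chim_id, chim_tid, 1L)
    partner <- NULL
    mode_truth <- "de_novo"
  }
  ft <- bind_rows(feats)
  exons <- ft %>% filter(.data$transcript_id == chim_tid, .data$type == "exon")
  ft <- bind_rows(
    tibble(type = c("gene", "mRNA"),
           start = min(exons$start), end = max(exons$end),
           exon_number = NA_integer_, strand = "+", gene_id = chim_id,
           transcript_id = chim_tid),
    ft)
  # spliced transcript sequence (+ strand, exons left to right)
  exons <- exons %>% arrange(.data$start)
  spliced <- paste(substring(seq, exons$start + 1, exons$end), collapse = "")
  list(seq = seq, features = ft, body_iv = body_iv,
       truth = tibble(
         retro_id = chim_id, parent_id = parent$gene_id, strand = "+",
         class = category, divergence = mut$divergence,
         transcript_id = chim_tid, new_splice_site = new_splice_site,
         mode = mode_truth, transcribed = TRUE,
         disablement_kind = NA_character_, disablement_pos = NA_integer_),
       transcript = spliced,
       partner = partner)
}

# ---- top-level generator ---------------------------------------------------

#' Generate a synthetic genome with planted retrocopies
#'
#' Builds a genome (single contig), its gene annotation, a proteome, planted
#' retrocopies of three classes with poly(A)/TSD hallmarks, single-exon decoy
#' genes with a planted decoy copy, and ground truth for every planting.
#' Same configuration (including seed) gives byte-identical output.
#'
#' @param config a [sim_config()].
#' @return A `sim_genome` list: `genome` ([Biostrings::DNAStringSet]),
#'   `annotation` (feature tibble, 0-based half-open), `proteome`
#'   ([Biostrings::AAStringSet], parent/partner/decoy proteins), `cds` (named
#'   character, spliced CDS per annotated gene), `transcripts` (named
#'   character: transcribed sequences for EST sampling), `truth` (planted
#'   retrocopy tibble), `decoy_truth` (planted negative controls), `config`.
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .generate_genome_impl(config))
}

#' @rdname generate_genome
#' @export
simulate_genome <- generate_genome

.generate_genome_impl <- function(cfg) {
  elements <- list() # each: list(seq, features, truth, decoy, transcripts)
  kappa <- cfg$ts_tv_ratio

  # parent genes (half minus strand); intragenic retros are planted into
  # host introns at construction time
  n_plain <- cfg$n_retro_intact + cfg$n_retro_pseudo
  plain_class <- c(rep("intact", cfg$n_retro_intact),
                   rep(c("frameshift", "premature_stop"),
                       length.out = cfg$n_retro_pseudo))
  if (n_plain > 0) plain_class <- sample(plain_class)
  n_intragenic <- round(cfg$intragenic_frac * n_plain)
  intragenic <- rep(FALSE, n_plain)
  if (n_intragenic > 0) intragenic[sample.int(n_plain, n_intragenic)] <- TRUE

  gene_ids <- sprintf("gene%03d", seq_len(cfg$n_parent_genes))
  gene_specs <- lapply(gene_ids, function(gid) {
    n_ex <- .sample_range(cfg$exons_per_gene)
    list(id = gid,
         exon_codons = .sample_range(cfg$exon_length_codons, n_ex),
         introns = .sample_range(cfg$intron_length, n_ex - 1),
         strand = sample(c("+", "-"), 1))
  })

  # assign plain retros to parents; build retro cassettes first so host genes
  # can receive intragenic ones
  if (cfg$n_parent_genes == 0 && n_plain + cfg$n_retro_chimeric > 0) {
    stop("cannot plant retrocopies without parent genes", call. = FALSE)
  }
  plain <- list()
  host_inserts <- stats::setNames(vector("list", cfg$n_parent_genes), gene_ids)
  if (n_plain > 0) {
    parents_of <- sample(cfg$n_parent_genes, n_plain, replace = TRUE)
    for (i in seq_len(n_plain)) {
      plain[[i]] <- list(parent_idx = parents_of[i], class = plain_class[i],
                         strand = sample(c("+", "-"), 1),
                         intragenic = intragenic[i],
                         transcribed = runif(1) < cfg$retro_transcribed_frac)
    }
  }

  # parent CDS must exist before retro bodies: build gene elements now,
  # but intragenic cassettes need the mutated body, which needs the parent
  # CDS. Two passes: draw CDS first, then assemble gene sequences.
  genes_cds <- lapply(gene_specs, function(sp) .rand_cds(sum(sp$exon_codons)))

  retro_rows <- list()
  for (i in seq_along(plain)) {
    p <- plain[[i]]
    rid <- sprintf("retro%03d", i)
    parent_cds <- genes_cds[[p$parent_idx]]
    mut <- mutate_k2p(parent_cds, cfg$retro_divergence, kappa,
                      avoid_stop_frame = TRUE)
    body <- mut$seq
    dis_kind <- NA_character_; dis_pos <- NA_integer_
    if (p$class != "intact") {
      d <- plant_disablement(body, p$class)
      body <- d$seq
      dis_kind <- d$record$kind; dis_pos <- as.integer(d$record$position)
    }
    cassette <- .make_cassette(body, p$strand, cfg$polya_length, cfg$tsd_length)
    retro_rows[[i]] <- list(
      retro_id = rid, parent_id = gene_ids[p$parent_idx], strand = p$strand,
      class = p$class, divergence = mut$divergence, body = body,
      cassette = cassette, intragenic = p$intragenic,
      transcribed = p$transcribed,
      disablement_kind = dis_kind, disablement_pos = dis_pos)
  }
  # park intragenic cassettes inside random host genes (not their own parent,
  # so the call never overlaps its parent locus)
  for (i in seq_along(retro_rows)) {
    if (!plain[[i]]$intragenic) next
    hosts <- setdiff(seq_len(cfg$n_parent_genes), plain[[i]]$parent_idx)
    if (length(hosts) == 0) { retro_rows[[i]]$intragenic <- FALSE; next }
    h <- if (length(hosts) == 1) hosts else sample(hosts, 1)
    hid <- gene_ids[h]
    if (!is.null(host_inserts[[hid]])) { # one insert per host
      retro_rows[[i]]$intragenic <- FALSE
      next
    }
    host_inserts[[hid]] <- list(retro_i = i)
  }

  # gene elements (with any intragenic cassette planted into intron 1)
  truth_iv <- list()  # retro_id -> c(element_idx, rel_start, rel_end, strand)
  for (g in seq_along(gene_specs)) {
    sp <- gene_specs[[g]]
    ins <- host_inserts[[sp$id]]
    insert <- NULL
    if (!is.null(ins)) {
      insert <- list(seq = retro_rows[[ins$retro_i]]$cassette$seq,
                     intron_index = sample(length(sp$introns), 1))
    }
    el2 <- .rebuild_gene_with_cds(sp, genes_cds[[g]], insert)
    elements[[length(elements) + 1]] <- list(
      kind = "gene", seq = el2$seq, features = el2$features,
      cds = el2$cds, protein = el2$protein, gene_id = sp$id)
    if (!is.null(ins)) {
      ri <- ins$retro_i
      rr <- retro_rows[[ri]]
      civ <- el2$insert_iv
      flip <- sp$strand == "-"
      b <- rr$cassette$body_iv
      clen <- nchar(rr$cassette$seq)
      if (flip) {
        biv <- c(civ[1] + (clen - b[2]), civ[1] + (clen - b[1]))
        bstrand <- if (rr$strand == "+") "-" else "+"
      } else {
        biv <- c(civ[1] + b[1], civ[1] + b[2])
        bstrand <- rr$strand
      }
      truth_iv[[rr$retro_id]] <- list(element = length(elements),
                                      rel = biv, strand = bstrand)
      retro_rows[[ri]]$strand <- bstrand
    }
  }

  # intergenic plain retro elements
  for (i in seq_along(retro_rows)) {
    rr <- retro_rows[[i]]
    if (!is.null(truth_iv[[rr$retro_id]])) next
    elements[[length(elements) + 1]] <- list(
      kind = "retro", seq = rr$cassette$seq, features = NULL)
    truth_iv[[rr$retro_id]] <- list(
      element = length(elements),
      rel = rr$cassette$body_iv, strand = rr$strand)
  }

  # decoy single-exon genes + planted decoy copies (negative controls)
  decoy_ids <- sprintf("decoy%02d", seq_len(cfg$n_single_exon_decoys))
  decoys <- list()
  for (d in seq_along(decoy_ids)) {
    el <- .make_gene(decoy_ids[d], 150, integer(0), sample(c("+", "-"), 1))
    elements[[length(elements) + 1]] <- list(
      kind = "gene", seq = el$seq, features = el$features, cds = el$cds,
      protein = el$protein, gene_id = decoy_ids[d])
    decoys[[d]] <- el
  }
  decoy_iv <- list()
  for (d in seq_len(cfg$n_decoy_retro)) {
    src <- decoys[[1 + (d - 1) %% length(decoys)]]
    mut <- mutate_k2p(src$cds, cfg$retro_divergence, kappa,
                      avoid_stop_frame = TRUE)
    cassette <- .make_cassette(mut$seq, "+", cfg$polya_length, cfg$tsd_length)
    elements[[length(elements) + 1]] <- list(kind = "decoy_retro",
                                             seq = cassette$seq, features = NULL)
    decoy_iv[[sprintf("decoyretro%02d", d)]] <- list(
      element = length(elements), rel = cassette$body_iv, strand = "+",
      source = src$gene_id)
  }

  # chimera complexes
  chim_categories <- rep(c("chimeric_C", "chimeric_N", "chimeric_both",
                           "chimeric_UTR"), length.out = cfg$n_retro_chimeric)
  chim_truth <- list()
  nss_counter <- c(chimeric_C = 0L, chimeric_N = 0L)
  for (ci in seq_len(cfg$n_retro_chimeric)) {
    cat_i <- chim_categories[ci]
    pidx <- sample(cfg$n_parent_genes, 1)
    parent <- list(gene_id = gene_ids[pidx], cds = genes_cds[[pidx]])
    nss <- FALSE
    if (cat_i %in% c("chimeric_C", "chimeric_N")) {
      nss_counter[cat_i] <- nss_counter[cat_i] + 1L
      nss <- nss_counter[cat_i] %% 2L == 0L
    }
    ch <- .make_chimera(ci, cat_i, nss, parent, cfg$retro_divergence, kappa,
                        cfg$polya_length, cfg$tsd_length)
    elements[[length(elements) + 1]] <- list(
      kind = "chimera", seq = ch$seq, features = ch$features,
      transcript = ch$transcript, transcript_id = ch$truth$transcript_id,
      partner = ch$partner)
    truth_iv[[ch$truth$retro_id]] <- list(element = length(elements),
                                          rel = ch$body_iv, strand = "+")
    chim_truth[[ci]] <- ch$truth
  }

  # ---- assemble the contig --------------------------------------------------
  n_el <- length(elements)
  el_len <- vapply(elements, function(e) nchar(e$seq), integer(1))
  min_gap <- 150L
  deficit <- sum(el_len) + (n_el + 1L) * min_gap - cfg$genome_length
  if (deficit > 0) {
    stop("genome_length too small: need at least ", deficit,
         " more bp to host the requested features", call. = FALSE)
  }
  order_idx <- sample(n_el)
  spare <- cfg$genome_length - sum(el_len) - (n_el + 1L) * min_gap
  cuts <- sort(runif(n_el))
  gap_extra <- floor(diff(c(0, cuts, 1)) * spare)
  gaps <- min_gap + gap_extra
  gaps[length(gaps)] <- gaps[length(gaps)] +
    (cfg$genome_length - sum(el_len) - sum(gaps))

  pieces <- character(2 * n_el + 1)
  offsets <- integer(n_el) # genomic offset of each element (original index)
  pos <- 0L
  pieces[1] <- .rand_nt(gaps[1]); pos <- pos + gaps[1]
  for (k in seq_len(n_el)) {
    i <- order_idx[k]
    offsets[i] <- pos
    pieces[2 * k] <- elements[[i]]$seq
    pos <- pos + el_len[i]
    pieces[2 * k + 1] <- .rand_nt(gaps[k + 1])
    pos <- pos + gaps[k + 1]
  }
  contig <- paste(pieces, collapse = "")
  stopifnot(nchar(contig) == cfg$genome_length)
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "chr1"

  # ---- absolute annotation, proteome, truth --------------------------------
  feats <- list()
  proteome <- character(0)
  cds_by_gene <- character(0)
  transcripts <- character(0)
  for (i in seq_len(n_el)) {
    e <- elements[[i]]
    if (!is.null(e$features)) {
      feats[[length(feats) + 1]] <- e$features %>%
        mutate(start = .data$start + offsets[i], end = .data$end + offsets[i],
               seqid = "chr1")
    }
    if (identical(e$kind, "gene")) {
      proteome[e$gene_id] <- e$protein
      cds_by_gene[e$gene_id] <- e$cds
      transcripts[paste0(e$gene_id, ".t1")] <- e$cds
    }
    if (identical(e$kind, "chimera")) {
      transcripts[e$transcript_id] <- e$transcript
      if (!is.null(e$partner)) {
        proteome[e$partner$gene_id] <- e$partner$protein
        cds_by_gene[e$partner$gene_id] <- e$partner$cds
        transcripts[paste0(e$partner$gene_id, ".t1")] <- e$partner$cds
      }
    }
  }
  annotation <- bind_rows(feats) %>%
    select("seqid", "type", "start", "end", "strand", "gene_id",
           "transcript_id", "exon_number") %>%
    arrange(.data$start, .data$end)

  truth_plain <- lapply(retro_rows, function(rr) {
    tibble(retro_id = rr$retro_id, parent_id = rr$parent_id,
           strand = rr$strand, class = rr$class, divergence = rr$divergence,
           transcript_id = NA_character_, new_splice_site = FALSE,
           mode = NA_character_, transcribed = rr$transcribed,
           disablement_kind = rr$disablement_kind,
           disablement_pos = rr$disablement_pos)
  })
  truth <- bind_rows(c(truth_plain, chim_truth))
  if (nrow(truth) > 0) {
    iv <- t(vapply(truth$retro_id, function(id) {
      ti <- truth_iv[[id]]
      c(offsets[ti$element] + ti$rel[1], offsets[ti$element] + ti$rel[2])
    }, numeric(2)))
    truth$seqid <- "chr1"
    truth$start <- as.integer(iv[, 1])
    truth$end <- as.integer(iv[, 2])
    truth$strand <- vapply(truth$retro_id, function(id) truth_iv[[id]]$strand, "")
    gene_spans <- annotation %>% filter(.data$type == "gene")
    truth$intragenic <- vapply(seq_len(nrow(truth)), function(r) {
      own <- truth$transcript_id[r]
      sp <- gene_spans
      if (!is.na(own)) sp <- sp %>% filter(.data$transcript_id != own)
      any(sp$start <= truth$start[r] & sp$end >= truth$end[r])
    }, logical(1))
  }
  decoy_truth <- bind_rows(lapply(names(decoy_iv), function(id) {
    di <- decoy_iv[[id]]
    tibble(decoy_id = id, source_gene = di$source, seqid = "chr1",
           start = as.integer(offsets[di$element] + di$rel[1]),
           end = as.integer(offsets[di$element] + di$rel[2]),
           strand = di$strand)
  }))

  # transcribed plain retros emit their body as a transcript
  if (nrow(truth) > 0) {
    for (r in seq_len(nrow(truth))) {
      if (!truth$transcribed[r] || !is.na(truth$transcript_id[r])) next
      seq <- substr(contig, truth$start[r] + 1, truth$end[r])
      if (truth$strand[r] == "-") seq <- .revcomp(seq)
      transcripts[truth$retro_id[r]] <- seq
    }
  }

  structure(list(
    genome = genome,
    annotation = annotation,
    proteome = Biostrings::AAStringSet(proteome),
    cds = cds_by_gene,
    transcripts = transcripts,
    truth = truth,
    decoy_truth = decoy_truth,
    config = cfg
  ), class = "sim_genome")
}

# rebuild a gene element from a pre-drawn CDS (keeps .make_gene's layout code
# in one place for everything except the codon draw)
.rebuild_gene_with_cds <- function(sp, cds, insert = NULL) {
  ends <- cumsum(sp$exon_codons) * 3
  starts <- c(0, ends[-length(ends)])
  exon_seqs <- substring(cds, starts + 1, ends)
  intron_seqs <- vapply(sp$introns, function(l) paste0("GT", .rand_nt(l - 4), "AG"), "")
  insert_iv <- NULL
  pieces <- character(0); feats <- list(); off <- 0L
  for (i in seq_along(exon_seqs)) {
    w <- nchar(exon_seqs[i])
    feats[[length(feats) + 1]] <- tibble(type = c("exon", "CDS"),
                                         start = off, end = off + w,
                                         exon_number = i)
    pieces <- c(pieces, exon_seqs[i]); off <- off + w
    if (i <= length(intron_seqs)) {
      iseq <- intron_seqs[i]
      if (!is.null(insert) && insert$intron_index == i) {
        half <- nchar(iseq) %/% 2
        iseq <- paste0(substr(iseq, 1, half), insert$seq,
                       substr(iseq, half + 1, nchar(iseq)))
        insert_iv <- c(off + half, off + half + nchar(insert$seq))
      }
      pieces <- c(pieces, iseq); off <- off + nchar(iseq)
    }
  }
  seq <- paste(pieces, collapse = "")
  L <- nchar(seq)
  ft <- bind_rows(feats)
  if (sp$strand == "-") {
    seq <- .revcomp(seq)
    new_start <- L - ft$end; ft$end <- L - ft$start; ft$start <- new_start
    if (!is.null(insert_iv)) insert_iv <- .flip_iv(insert_iv[1], insert_iv[2], L)
  }
  ft <- bind_rows(
    tibble(type = c("gene", "mRNA"), start = 0L, end = L,
           exon_number = NA_integer_), ft)
  ft$strand <- sp$strand; ft$gene_id <- sp$id
  ft$transcript_id <- paste0(sp$id, ".t1")
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, nchar(cds) - 3))))
  list(seq = seq, features = ft, cds = cds, protein = protein,
       insert_iv = insert_iv, length = L)
}

#' Sample ESTs (and mRNAs) from a synthetic genome's transcripts
#'
#' Each transcribed sequence emits Poisson(`est_per_transcript`) ESTs:
#' contiguous subsequences of at least 100 bp with per-base substitution
#' errors at `est_error_rate`, in random orientation. A `mrna_fraction`
#' subset of sources also emits one full-length mRNA.
#'
#' @param sim a [generate_genome()] result.
#' @param config optional override of `sim$config`.
#' @return list: `ests`, `mrnas` ([Biostrings::DNAStringSet]) and
#'   `est_truth`, `mrna_truth` (source map tibbles).
#' @export
sample_ests <- function(sim, config = NULL) {
  stopifnot(inherits(sim, "sim_genome"))
  cfg <- config %||% sim$config
  withr::with_seed(cfg$seed + 104729L, {
    srcs <- sim$transcripts
    est_seqs <- character(0); est_rows <- list()
    mrna_seqs <- character(0); mrna_rows <- list()
    k <- 0L
    for (sid in names(srcs)) {
      tseq <- srcs[[sid]]
      tlen <- nchar(tseq)
      if (tlen < 100) next
      n <- stats::rpois(1, cfg$est_per_transcript)
      for (j in seq_len(n)) {
        k <- k + 1L
        len <- min(tlen, .sample_range(cfg$est_length))
        s0 <- sample.int(tlen - len + 1L, 1) - 1L
        read <- substr(tseq, s0 + 1, s0 + len)
        nerr <- stats::rbinom(1, len, cfg$est_error_rate)
        if (nerr > 0) {
          x <- strsplit(read, "")[[1]]
          at <- sample.int(len, nerr)
          x[at] <- vapply(x[at], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
          read <- paste(x, collapse = "")
        }
        ori <- sample(c("+", "-"), 1)
        if (ori == "-") read <- .revcomp(read)
        id <- sprintf("est%05d", k)
        est_seqs[id] <- read
        est_rows[[k]] <- tibble(est_id = id, source_id = sid,
                                src_start = s0, src_end = s0 + len,
                                orientation = ori, n_errors = nerr)
      }
      if (stats::runif(1) < cfg$mrna_fraction) {
        id <- sprintf("mrna_%s", sid)
        mrna_seqs[id] <- tseq
        mrna_rows[[length(mrna_rows) + 1]] <- tibble(
          mrna_id = id, source_id = sid, src_start = 0L, src_end = tlen)
      }
    }
    list(
      ests = Biostrings::DNAStringSet(est_seqs),
      mrnas = Biostrings::DNAStringSet(mrna_seqs),
      est_truth = bind_rows(est_rows),
      mrna_truth = bind_rows(mrna_rows)
    )
  })
}

#' Simulate ortholog CDS pairs at a target synonymous divergence
#'
#' Pairs of coding sequences whose synonymous sites have diverged by
#' Ks = 2 r T under a Kimura two-parameter process (transitions at 2- and
#' 4-fold degenerate third positions, transversions at 4-fold sites only);
#' nonsynonymous sites are held fixed. Codons with irregular degeneracy
#' (Leu/Arg first-position exchanges, Ile ATA) are avoided so the planted
#' divergence is exactly the quantity the LPB estimator targets.
#'
#' @param n number of pairs.
#' @param r synonymous substitution rate per silent site per year.
#' @param t_years divergence time in years.
#' @param len_codons codons per sequence.
#' @param ts_tv_ratio transition/transversion ratio of the planted process.
#' @param seed optional seed for reproducibility.
#' @param saturation_bound refuse divergences at or beyond this value
#'   (default 0.75; raise explicitly for recovery experiments at high Ks,
#'   where the K2P inversion is still defined).
#' @return Tibble: `pair_id`, `cds_a`, `cds_b`, `true_ks`.
#' @export
make_ortholog_pairs <- function(n = 38, r = 4.13e-9, t_years = 5e7,
                                len_codons = 300, ts_tv_ratio = 2,
                                seed = NULL, saturation_bound = 0.75) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (r <= 0 || t_years < 0) stop("r must be > 0 and t_years >= 0", call. = FALSE)
  d <- 2 * r * t_years
  if (d >= saturation_bound) {
    stop("2*r*T = ", signif(d, 3), " is at or beyond saturation (",
         saturation_bound, ")", call. = FALSE)
  }
  run <- function() {
    deg <- codon_degeneracy_table()
    regular <- rownames(deg)[!is.na(deg[, 1]) & deg[, 1] == 0 & deg[, 2] == 0 &
                               deg[, 3] %in% c(2L, 4L)]
    # keep only codons whose 2-fold third position is transition-synonymous
    gc <- Biostrings::GENETIC_CODE
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    ok2 <- vapply(regular, function(cd) {
      if (deg[cd, 3] == 4L) return(TRUE)
      alt <- cd
      substr(alt, 3, 3) <- ts_map[[substr(cd, 3, 3)]]
      gc[[alt]] == gc[[cd]]
    }, logical(1))
    regular <- regular[ok2]
    # per-site transition/transversion divergences and the K2P-inverted
    # substitution probabilities that realize them in expectation
    kap <- ts_tv_ratio
    a <- d * kap / (kap + 1); b <- d / (kap + 1)
    qv <- (1 - exp(-2 * b)) / 2
    pv <- (1 - exp(-2 * a - b) - qv) / 2
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      codons <- sample(regular, len_codons, replace = TRUE)
      cds_a <- paste(codons, collapse = "")
      xb <- codons
      for (j in seq_along(xb)) {
        cls <- deg[xb[j], 3]
        third <- substr(xb[j], 3, 3)
        u <- runif(1)
        if (u < pv) {
          substr(xb[j], 3, 3) <- ts_map[[third]]
        } else if (cls == 4L && u < pv + qv) {
          substr(xb[j], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"),
                                                c(third, ts_map[[third]])), 1)
        }
      }
      rows[[i]] <- tibble(pair_id = sprintf("orth%03d", i),
                          cds_a = cds_a, cds_b = paste(xb, collapse = ""),
                          true_ks = d)
    }
    bind_rows(rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
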