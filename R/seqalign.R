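# Alignment engines: six-frame translated protein-vs-genome search, spliced
# GT-AG protein-to-genome alignment, nucleotide EST placement, codon-aware
# CDS alignment. Window-level pairwise alignment is delegated to
# Biostrings::pairwiseAlignment; seeding, frame bookkeeping and coordinate
# mapping live here; the spliced three-state DP is compiled code.

.blosum62_flat <- function() {
  if (is.null(.rf_cache$blosum_flat)) {
    bl <- get_blosum62()
    m <- matrix(-4L, 26, 26, dimnames = list(LETTERS, LETTERS))
    common <- intersect(rownames(bl), LETTERS)
    m[common, common] <- bl[common, common]
    .rf_cache$blosum_flat <- as.integer(t(m)) # row-major for C++ (p * 26 + aa)
  }
  .rf_cache$blosum_flat
}

#' @keywords internal
get_blosum62 <- function() {
  if (is.null(.rf_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .rf_cache$blosum62 <- e$BLOSUM62
  }
  .rf_cache$blosum62
}

.code64 <- function() {
  if (is.null(.rf_cache$code64)) {
    nts <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
    # index = 16a + 4b + c requires first base outermost
    codons <- paste0(rep(nts, each = 16), rep(rep(nts, each = 4), 4), rep(nts, 16))
    .rf_cache$code64 <- paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  .rf_cache$code64
}

.as_dnaset <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) {
    out <- Biostrings::DNAStringSet(genome)
    names(out) <- "chr1"
    return(out)
  }
  out <- Biostrings::DNAStringSet(unlist(genome))
  if (is.null(names(out))) names(out) <- paste0("chr", seq_along(out))
  out
}

.empty_hits <- function() {
  tibble(protein_id = character(), seqid = character(),
         start = integer(), end = integer(), strand = character(),
         frame = integer(), score = numeric(), identity = numeric(),
         q_start = integer(), q_end = integer(), n_aligned = integer(),
         protein_length = integer())
}

#' Precompute six-frame translations of a genome
#'
#' Shared by repeated [translated_search()] calls (one translation pass,
#' many proteins).
#'
#' @param genome a [Biostrings::DNAStringSet] (or DNAString).
#' @return An opaque list used by `translated_search(frames = )`.
#' @export
prepare_genome_frames <- function(genome) {
  genome <- .as_dnaset(genome)
  frames <- list()
  for (ci in seq_along(genome)) {
    contig <- genome[[ci]]
    L <- length(contig)
    rc <- Biostrings::reverseComplement(contig)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contig else rc
      for (f in 0:2) {
        len <- ((L - f) %/% 3) * 3
        aa <- if (len >= 3) {
          as.character(suppressWarnings(
            Biostrings::translate(Biostrings::subseq(s, f + 1, f + len),
                                  if.fuzzy.codon = "X")))
        } else ""
        frames[[length(frames) + 1]] <- list(
          seqid = names(genome)[ci], contig_length = L,
          strand = strand, frame = f, aa = aa)
      }
    }
  }
  structure(list(frames = frames, genome = genome), class = "genome_frames")
}

# recursively collect local alignments with score >= min_score inside one
# subject window, splitting the subject at each accepted alignment
.iter_local <- function(pattern, subject_chr, min_score, submat, gap_open,
                        gap_ext, offset = 0L, depth = 0L, max_hits = 25L) {
  if (nchar(subject_chr) < 3 || depth > max_hits) return(list())
  pa <- Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject_chr,
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_ext, type = "local")
  sc <- Biostrings::score(pa)
  if (sc < min_score) return(list())
  srange <- pa@subject@range
  prange <- pa@pattern@range
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  hit <- list(
    score = sc,
    s_start = offset + BiocGenerics::start(srange),    # 1-based in window frame
    s_end = offset + BiocGenerics::end(srange),
    q_start = BiocGenerics::start(prange),
    q_end = BiocGenerics::end(prange),
    n_match = nm, n_aligned = nm + nmm)
  left <- substr(subject_chr, 1L, BiocGenerics::start(srange) - 1L)
  right_from <- BiocGenerics::end(srange) + 1L
  right <- if (right_from <= nchar(subject_chr))
    substr(subject_chr, right_from, nchar(subject_chr)) else ""
  c(list(hit),
    .iter_local(pattern, left, min_score, submat, gap_open, gap_ext,
                offset, depth + 1L, max_hits),
    .iter_local(pattern, right, min_score, submat, gap_open, gap_ext,
                offset + right_from - 1L, depth + 1L, max_hits))
}

#' Translated six-frame local search of a protein against a genome
#'
#' A TblastN-style scan: the genome is translated in all six reading frames
#' and the protein is aligned locally (BLOSUM62, affine gaps, open 11 /
#' extend 1) within each frame. Frameshifted copies therefore surface as
#' adjacent hits in different frames, to be joined later by [merge_hits()].
#' Genomes at or below `exact_max_bp` are scanned exhaustively (full local DP
#' per frame); larger genomes are scanned by exact amino-acid k-mer seeding
#' followed by windowed alignment.
#'
#' @param protein amino-acid sequence (character or [Biostrings::AAString]),
#'   length >= 20.
#' @param genome [Biostrings::DNAStringSet] (ignored if `frames` given).
#' @param min_score minimum local alignment score to report.
#' @param protein_id id recorded in the output.
#' @param frames optional [prepare_genome_frames()] result.
#' @param exact_max_bp exhaustive-scan size cutoff.
#' @param seed_k amino-acid seed length (seeded regime).
#' @param pad_aa window padding, in residues, around seed clusters.
#' @param min_seeds minimum seed k-mers per window (seeded regime).
#' @param max_hits_per_window cap on alignments reported per window (0 =
#'   best hit only).
#' @return Tibble of hits: genomic `start`/`end` (0-based half-open),
#'   `strand`, `frame`, `score`, `identity` (percent, matches over aligned
#'   columns excluding gaps), query coordinates and `protein_length`.
#' @export
translated_search <- function(protein, genome = NULL, min_score = 50,
                              protein_id = "query", frames = NULL,
                              exact_max_bp = 100000L, seed_k = 5L,
                              pad_aa = 80L, min_seeds = 3L,
                              max_hits_per_window = 25L) {
  prot <- toupper(as.character(protein))
  if (nchar(prot) < 20) stop("protein must be at least 20 aa", call. = FALSE)
  if (grepl("[^A-Z*]", prot)) stop("non-amino-acid characters in protein", call. = FALSE)
  if (is.null(frames)) {
    genome <- .as_dnaset(genome)
    if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
      return(.empty_hits())
    }
    frames <- prepare_genome_frames(genome)
  }
  qlen <- nchar(prot)
  submat <- get_blosum62()
  pat <- Biostrings::AAString(prot)
  rows <- list()
  for (fr in frames$frames) {
    if (nchar(fr$aa) < 5) next
    exact <- fr$contig_length <= exact_max_bp
    windows <- if (exact) {
      IRanges::IRanges(1L, nchar(fr$aa))
    } else {
      pos <- .seed_positions_cpp(fr$aa, prot, seed_k)
      if (length(pos) == 0) next
      seed_ir <- IRanges::IRanges(pos + 1L, pos + seed_k)
      ir <- IRanges::reduce(seed_ir, min.gapwidth = 150L)
      # isolated random seeds are noise: demand a minimum seed count per
      # cluster (true homologous regions carry dozens of intact k-mers)
      nseed <- IRanges::countOverlaps(ir, seed_ir)
      ir <- ir[nseed >= min_seeds]
      if (length(ir) == 0) next
      ir <- IRanges::restrict(ir + pad_aa, 1L, nchar(fr$aa))
      IRanges::reduce(ir)
    }
    for (w in seq_along(windows)) {
      ws <- BiocGenerics::start(windows)[w]
      we <- BiocGenerics::end(windows)[w]
      hits <- .iter_local(pat, substr(fr$aa, ws, we), min_score, submat,
                          11, 1, offset = ws - 1L,
                          max_hits = max_hits_per_window)
      for (h in hits) {
        # aa coords in this frame -> nt coords on the frame's strand
        nt_lo <- fr$frame + 3L * (h$s_start - 1L)   # 0-based
        nt_hi <- fr$frame + 3L * h$s_end
        if (fr$strand == "+") {
          g_start <- nt_lo; g_end <- nt_hi
        } else {
          g_start <- fr$contig_length - nt_hi
          g_end <- fr$contig_length - nt_lo
        }
        rows[[length(rows) + 1]] <- tibble(
          protein_id = protein_id, seqid = fr$seqid,
          start = as.integer(g_start), end = as.integer(g_end),
          strand = fr$strand, frame = fr$frame,
          score = h$score,
          identity = 100 * h$n_match / h$n_aligned,
          q_start = h$q_start, q_end = h$q_end,
          n_aligned = as.integer(h$n_aligned),
          protein_length = as.integer(qlen))
      }
    }
  }
  if (length(rows) == 0) return(.empty_hits())
  bind_rows(rows) %>% arrange(.data$seqid, .data$start) %>%
    distinct(.data$seqid, .data$start, .data$end, .data$strand, .data$frame,
             .keep_all = TRUE)
}

#' Calibrate a translated-search score threshold from shuffled decoys
#'
#' Estimates the score whose expected number of random hits per megabase is
#' at most `target_hits_per_mb`, by aligning shuffled (composition-preserving)
#' decoy proteins against the genome and fitting a Gumbel law to the decoy
#' maxima by moments.
#'
#' @param protein template protein (its shuffles are the decoys).
#' @param genome [Biostrings::DNAStringSet].
#' @param n_decoys number of shuffles.
#' @param target_hits_per_mb tolerated random-hit rate per Mb.
#' @param sample_bp at most this much genome is scanned per decoy.
#' @return Suggested `min_score` (numeric scalar).
#' @export
calibrate_min_score <- function(protein, genome, n_decoys = 20,
                                target_hits_per_mb = 1e-3,
                                sample_bp = 100000L) {
  genome <- .as_dnaset(genome)
  w <- min(Biostrings::width(genome)[1], sample_bp)
  region <- Biostrings::DNAStringSet(Biostrings::subseq(genome[[1]], 1, w))
  names(region) <- "decoy_region"
  frames <- prepare_genome_frames(region)
  prot <- toupper(as.character(protein))
  maxima <- vapply(seq_len(n_decoys), function(i) {
    decoy <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    h <- translated_search(decoy, frames = frames, min_score = 10,
                           protein_id = "decoy", exact_max_bp = w + 1L,
                           max_hits_per_window = 0L)
    if (nrow(h) == 0) 10 else max(h$score)
  }, numeric(1))
  mu_hat <- mean(maxima); sd_hat <- max(stats::sd(maxima), 1e-6)
  beta <- pi / (sd_hat * sqrt(6))
  mu <- mu_hat - 0.57722 / beta
  # hits/Mb exceeding s ~ (1e6 / w) * exp(-beta (s - mu))
  mu + log((1e6 / w) / target_hits_per_mb) / beta
}

#' Spliced protein-to-genome alignment (GT-AG intron model)
#'
#' A GeneWise-style three-state local dynamic program: codon matches scored
#' with BLOSUM62, codon-level gaps, and intron states with a fixed opening
#' penalty, a GT donor / AG acceptor bonus (non-canonical introns allowed at
#' full penalty) and a minimum intron length. Frameshift moves (2- or 4-nt
#' pseudo-codons) let alignments continue through single-base indels of
#' decayed copies. Structures scoring below `filtration_score` are rejected.
#'
#' @param protein amino-acid sequence.
#' @param region genomic DNA (character or [Biostrings::DNAString]); supply
#'   the reverse complement for minus-strand loci.
#' @param min_intron_bp minimum intron length.
#' @param filtration_score minimum structure score.
#' @param intron_open,donor_bonus,acceptor_bonus,gap_codon,fs_pen,stop_score
#'   scoring knobs (BLOSUM62 units).
#' @return A `spliced_structure` list: `score`, `accepted`, `exons` (tibble,
#'   0-based half-open `dna_start`/`dna_end` plus query residue range),
#'   `introns` (tibble with coordinates, `length`, `donor`, `acceptor`
#'   dinucleotides recorded verbatim, and `q_boundary`, the last aligned
#'   residue of the upstream exon).
#' @export
spliced_align <- function(protein, region, min_intron_bp = 40,
                          filtration_score = 35, intron_open = 50,
                          donor_bonus = 5, acceptor_bonus = 5,
                          gap_codon = 12, fs_pen = 15, stop_score = -8) {
  prot <- toupper(as.character(protein))
  dna <- toupper(as.character(region))
  if (nchar(dna) < 3 * 5) {
    return(structure(list(score = 0, accepted = FALSE,
                          reason = "region shorter than protein needs",
                          exons = NULL, introns = NULL),
                     class = "spliced_structure"))
  }
  res <- .spliced_align_cpp(prot, dna, .blosum62_flat(), .code64(),
                            as.integer(min_intron_bp), as.integer(intron_open),
                            as.integer(donor_bonus), as.integer(acceptor_bonus),
                            as.integer(gap_codon), as.integer(fs_pen),
                            as.integer(stop_score))
  ex <- res$exons
  exons <- tibble(dna_start = ex[, 1], dna_end = ex[, 2],
                  q_start = ex[, 3], q_end = ex[, 4])
  inm <- res$introns
  introns <- tibble(
    dna_start = inm[, 1], dna_end = inm[, 2],
    length = inm[, 2] - inm[, 1],
    donor = substr(rep(dna, nrow(inm)), inm[, 1] + 1, inm[, 1] + 2),
    acceptor = substr(rep(dna, nrow(inm)), inm[, 2] - 1, inm[, 2]))
  if (nrow(introns) > 0 && nrow(exons) > 1) {
    introns$q_boundary <- exons$q_end[seq_len(nrow(introns))]
  } else if (nrow(introns) > 0) {
    introns$q_boundary <- NA_integer_
  } else {
    introns$q_boundary <- integer(0)
  }
  structure(list(score = res$score, accepted = res$score >= filtration_score,
                 reason = if (res$score >= filtration_score) NA_character_
                          else "below filtration score",
                 exons = exons, introns = introns),
            class = "spliced_structure")
}

#' @export
print.spliced_structure <- function(x, ...) {
  cat("Spliced alignment: score ", x$score,
      if (x$accepted) " (accepted)" else paste0(" (rejected: ", x$reason, ")"),
      "\n", sep = "")
  if (!is.null(x$exons) && nrow(x$exons) > 0) {
    cat("  ", nrow(x$exons), " exon block(s), ", nrow(x$introns),
        " intron(s)\n", sep = "")
  }
  invisible(x)
}

.empty_placements <- function() {
  tibble(est_id = character(), seqid = character(), start = integer(),
         end = integer(), strand = character(), aligned_len = integer(),
         identity = numeric(), score = numeric(), est_length = integer(),
         blocks = list())
}

# chain collinear local blocks (non-overlapping in read coordinates, genomic
# gap below max_intron) into spliced placements, BLAT-style
.chain_blocks <- function(hits, max_intron = 5000L, q_slop = 10L) {
  if (length(hits) == 0) return(list())
  ord <- order(vapply(hits, function(h) h$s_start, numeric(1)))
  hits <- hits[ord]
  chains <- list()
  for (h in hits) {
    placed <- FALSE
    for (k in seq_along(chains)) {
      last <- chains[[k]][[length(chains[[k]])]]
      if (h$s_start >= last$s_end &&
          h$s_start - last$s_end <= max_intron &&
          h$q_start >= last$q_end - q_slop) {
        chains[[k]][[length(chains[[k]]) + 1]] <- h
        placed <- TRUE
        break
      }
    }
    if (!placed) chains[[length(chains) + 1]] <- list(h)
  }
  chains
}

.nt_submat <- function(match = 1, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = TRUE)
}

# local nucleotide alignments of one EST against one window of one strand
.nt_window_hits <- function(est_chr, window_chr, min_score, offset,
                            gap_open = 5, gap_ext = 3) {
  .iter_local(Biostrings::DNAString(est_chr), window_chr, min_score,
              .nt_submat(), gap_open, gap_ext, offset = offset)
}

#' Nucleotide placement of an EST/mRNA on a genome
#'
#' BLAT-style placement: local nucleotide alignments of the read (both
#' orientations) against the genome; every placement with nucleotide identity
#' at or above `min_identity` and aligned length at least
#' `min_aligned_frac * length(est)` is returned, best first. Genomes at or
#' below `exact_max_bp` are scanned exhaustively; larger ones via exact
#' 16-mer seeding.
#'
#' @param est read sequence (character or [Biostrings::DNAString]).
#' @param genome [Biostrings::DNAStringSet].
#' @param min_len minimum read length (shorter input errors).
#' @param min_identity minimum percent identity of reported placements.
#' @param est_id id recorded in the output.
#' @param min_aligned_frac minimum aligned fraction of the read.
#' @param exact_max_bp exhaustive-scan size cutoff.
#' @return Tibble of placements sorted by identity then score: 0-based
#'   half-open genomic coordinates, `strand`, `aligned_len` (columns excluding
#'   gaps), percent `identity`.
#' @export
nucleotide_search <- function(est, genome, min_len = 100, min_identity = 90,
                              est_id = "est", min_aligned_frac = 0.5,
                              exact_max_bp = 100000L) {
  est_chr <- toupper(as.character(est))
  if (nchar(est_chr) < min_len) {
    stop("EST length ", nchar(est_chr), " is below min_len ", min_len,
         call. = FALSE)
  }
  ests <- Biostrings::DNAStringSet(est_chr)
  names(ests) <- est_id
  map_ests(ests, genome, min_identity = min_identity,
           min_aligned_frac = min_aligned_frac, exact_max_bp = exact_max_bp)
}

#' Place many ESTs/mRNAs on a genome in one pass
#'
#' Vectorized engine behind [nucleotide_search()]: one exact-seed scan
#' (16-mers, both strands) over the genome for the whole read set, then
#' windowed local alignment per seed cluster.
#'
#' @param ests named [Biostrings::DNAStringSet].
#' @inheritParams nucleotide_search
#' @param seed_width,seed_stride seed k-mer width and sampling stride.
#' @return Tibble of placements (see [nucleotide_search()]).
#' @export
map_ests <- function(ests, genome, min_identity = 90, min_aligned_frac = 0.5,
                     exact_max_bp = 100000L, seed_width = 16L,
                     seed_stride = 8L) {
  genome <- .as_dnaset(genome)
  if (length(ests) == 0) return(.empty_placements())
  if (is.null(names(ests))) names(ests) <- paste0("est", seq_along(ests))
  small <- all(Biostrings::width(genome) <= exact_max_bp)
  est_chrs <- as.character(ests)
  rc_chrs <- as.character(Biostrings::reverseComplement(ests))

  # one pooled exact-seed dictionary over all reads and both orientations
  seed_tbl <- NULL
  if (!small) {
    seed_rows <- list()
    for (ei in seq_along(ests)) {
      elen <- nchar(est_chrs[ei])
      starts <- unique(c(seq(1L, max(1L, elen - seed_width + 1L), seed_stride),
                         max(1L, elen - seed_width + 1L)))
      for (strand in c("+", "-")) {
        q <- if (strand == "+") est_chrs[ei] else rc_chrs[ei]
        seeds <- substring(q, starts, starts + seed_width - 1L)
        keep <- nchar(seeds) == seed_width & !grepl("[^ACGT]", seeds)
        if (!any(keep)) next
        seed_rows[[length(seed_rows) + 1]] <- tibble(
          est_i = ei, strand = strand, seed = unique(seeds[keep]))
      }
    }
    seed_tbl <- bind_rows(seed_rows)
  }

  rows <- list()
  for (ci in seq_along(genome)) {
    contig <- genome[[ci]]
    L <- length(contig)
    contig_chr <- as.character(contig)
    seqid <- names(genome)[ci]
    # windows per (est, strand)
    win_list <- list()
    if (small) {
      for (ei in seq_along(ests)) for (strand in c("+", "-")) {
        win_list[[paste(ei, strand)]] <- IRanges::IRanges(1L, L)
      }
    } else if (nrow(seed_tbl) > 0) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_tbl$seed))
      m <- Biostrings::matchPDict(pd, contig)
      starts_by_seed <- BiocGenerics::start(m)
      for (key in split(seq_len(nrow(seed_tbl)),
                        paste(seed_tbl$est_i, seed_tbl$strand))) {
        pos <- unlist(starts_by_seed[key], use.names = FALSE)
        if (length(pos) == 0) next
        ei <- seed_tbl$est_i[key[1]]
        elen <- nchar(est_chrs[ei])
        ir <- IRanges::reduce(IRanges::IRanges(pos, pos + seed_width - 1L),
                              min.gapwidth = elen)
        ir <- IRanges::reduce(IRanges::restrict(ir + elen, 1L, L))
        win_list[[paste(ei, seed_tbl$strand[key[1]])]] <- ir
      }
    }
    for (key in names(win_list)) {
      parts <- strsplit(key, " ")[[1]]
      ei <- as.integer(parts[1]); strand <- parts[2]
      q <- if (strand == "+") est_chrs[ei] else rc_chrs[ei]
      elen <- nchar(q)
      windows <- win_list[[key]]
      min_score <- max(25, floor(0.15 * elen))
      for (w in seq_along(windows)) {
        ws <- BiocGenerics::start(windows)[w]
        we <- BiocGenerics::end(windows)[w]
        hits <- .nt_window_hits(q, substr(contig_chr, ws, we), min_score,
                                offset = ws - 1L)
        for (chain in .chain_blocks(hits)) {
          n_match <- sum(vapply(chain, function(h) h$n_match, numeric(1)))
          n_aligned <- sum(vapply(chain, function(h) h$n_aligned, numeric(1)))
          ident <- 100 * n_match / n_aligned
          if (ident < min_identity) next
          if (n_aligned < min_aligned_frac * elen) next
          blocks <- tibble(
            start = vapply(chain, function(h) h$s_start - 1L, integer(1)),
            end = vapply(chain, function(h) h$s_end, integer(1)),
            q_start = vapply(chain, function(h) h$q_start, integer(1)),
            q_end = vapply(chain, function(h) h$q_end, integer(1)))
          rows[[length(rows) + 1]] <- tibble(
            est_id = names(ests)[ei], seqid = seqid,
            start = min(blocks$start), end = max(blocks$end),
            strand = strand, aligned_len = as.integer(n_aligned),
            identity = ident,
            score = sum(vapply(chain, function(h) h$score, numeric(1))),
            est_length = as.integer(elen),
            blocks = list(blocks))
        }
      }
    }
  }
  if (length(rows) == 0) return(.empty_placements())
  bind_rows(rows) %>%
    distinct(.data$est_id, .data$seqid, .data$start, .data$end, .data$strand,
             .keep_all = TRUE) %>%
    arrange(.data$est_id, dplyr::desc(.data$identity), dplyr::desc(.data$score))
}

#' Codon-aware global alignment of two coding sequences
#'
#' Global alignment with gaps constrained to codon boundaries; a terminal
#' stop codon is trimmed from either sequence first. Column score is the sum
#' of per-nucleotide match/mismatch scores over the codon.
#'
#' @param cds_a,cds_b coding sequences, length a multiple of 3 after trimming
#'   any terminal stop codon.
#' @param match,mismatch,gap_codon per-nucleotide match/mismatch scores and
#'   per-codon gap penalty.
#' @return A `cds_alignment` list: `aligned_a`, `aligned_b` (gapped, equal
#'   length), `score`, percent `identity` over gap-free columns, and
#'   `n_gap_codons`.
#' @export
align_cds_pair <- function(cds_a, cds_b, match = 1, mismatch = -1,
                           gap_codon = 7) {
  trim <- function(x) {
    x <- toupper(as.character(x))
    if (nchar(x) %% 3 != 0) {
      stop("CDS length ", nchar(x), " is not reducible to codons", call. = FALSE)
    }
    if (nchar(x) >= 3) {
      last <- substr(x, nchar(x) - 2, nchar(x))
      if (last %in% c("TAA", "TAG", "TGA")) x <- substr(x, 1, nchar(x) - 3)
    }
    x
  }
  a <- trim(cds_a); b <- trim(cds_b)
  res <- .codon_nw_cpp(a, b, as.integer(match), as.integer(mismatch),
                       as.integer(gap_codon))
  ca <- strsplit(res$aligned_a, "")[[1]]
  cb <- strsplit(res$aligned_b, "")[[1]]
  ungapped <- ca != "-" & cb != "-"
  structure(list(
    aligned_a = res$aligned_a, aligned_b = res$aligned_b,
    score = res$score,
    identity = if (any(ungapped)) 100 * mean(ca[ungapped] == cb[ungapped]) else NA_real_,
    n_gap_codons = (sum(ca == "-") + sum(cb == "-")) / 3
  ), class = "cds_alignment")
}

#' @export
print.cds_alignment <- function(x, ...) {
  cat("Codon-aware CDS alignment: score ", x$score, ", identity ",
      round(x$identity, 2), "%, ", x$n_gap_codons, " gap codon(s)\n", sep = "")
  invisible(x)
}
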