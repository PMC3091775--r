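# The retrocopy calling pipeline: translated search -> hit merging ->
# candidate filters -> parent assignment -> dual spliced-alignment intron-loss
# confirmation -> retro-derived duplicate demotion -> disablement
# classification (+ Ka/Ks per call).

#' Pipeline thresholds
#'
#' Houses every numeric threshold of the retrocopy calling pipeline. The
#' defaults are the published rule set: merge gap < 40 bp, amino-acid
#' identity > 50%, query overlap > 70% and at least 50 aa, minimum intron
#' 40 bp, intron-loss confirmation span > 70 bp, spliced-structure filtration
#' score 35, parents need >= 2 coding exons and >= 50% coverage/identity.
#'
#' @param merge_gap_bp,min_identity_pct,min_overlap_frac,min_overlap_aa
#'   candidate merging/filtering thresholds.
#' @param min_intron_bp,confirm_span_bp,filtration_score spliced-alignment
#'   thresholds; `confirm_span_bp` must exceed `merge_gap_bp` (an intron
#'   larger than the merge gap cannot be a merging artifact).
#' @param parent_min_coding_exons,parent_min_cov_frac,parent_min_identity_pct
#'   parent assignment thresholds.
#' @param min_score translated-search raw score threshold.
#' @param pad_bp padding around candidate loci for spliced alignment.
#' @param boundary_tol_aa tolerance (residues) when matching intron positions
#'   between the parent and candidate structures.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(merge_gap_bp = 40, min_identity_pct = 50,
                            min_overlap_frac = 0.70, min_overlap_aa = 50,
                            min_intron_bp = 40, confirm_span_bp = 70,
                            filtration_score = 35,
                            parent_min_coding_exons = 2,
                            parent_min_cov_frac = 0.50,
                            parent_min_identity_pct = 50,
                            min_score = 50, pad_bp = 150,
                            boundary_tol_aa = 3) {
  cfg <- as.list(environment())
  if (any(unlist(cfg) <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (cfg$confirm_span_bp <= cfg$merge_gap_bp) {
    stop("confirm_span_bp must exceed merge_gap_bp", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Merge nearby translated-search hits into candidates
#'
#' Hits from the same protein on the same strand whose genomic gap is
#' strictly smaller than `merge_gap_bp` are unioned transitively (nearby
#' matches too close to be separated by an intron). Identity is re-averaged
#' over aligned columns; query coverage is the union of the hits' query
#' ranges.
#'
#' @param hits [translated_search()] tibble for one protein.
#' @param merge_gap_bp maximum gap (exclusive).
#' @return Candidate tibble: interval, summed `score`, pooled `identity`,
#'   `n_aligned` (union of query residues), `coverage`, `n_hits`.
#' @export
merge_hits <- function(hits, merge_gap_bp = 40) {
  if (nrow(hits) == 0) {
    return(tibble(protein_id = character(), seqid = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = numeric(), identity = numeric(),
                  n_aligned = integer(), coverage = numeric(),
                  q_start = integer(), q_end = integer(), n_hits = integer(),
                  protein_length = integer()))
  }
  if (length(unique(hits$protein_id)) > 1) {
    stop("merge_hits expects hits from a single protein", call. = FALSE)
  }
  out <- list()
  for (grp in split(hits, paste(hits$seqid, hits$strand))) {
    g <- grp %>% arrange(.data$start, .data$end)
    cluster <- integer(nrow(g))
    cid <- 1L; cur_end <- g$end[1]; cluster[1] <- 1L
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] - cur_end < merge_gap_bp) {
        cluster[i] <- cid
        cur_end <- max(cur_end, g$end[i])
      } else {
        cid <- cid + 1L
        cluster[i] <- cid
        cur_end <- g$end[i]
      }
    }
    for (cl in split(g, cluster)) {
      qu <- IRanges::reduce(IRanges::IRanges(cl$q_start, cl$q_end))
      n_aligned <- sum(IRanges::width(qu))
      out[[length(out) + 1]] <- tibble(
        protein_id = cl$protein_id[1], seqid = cl$seqid[1],
        start = min(cl$start), end = max(cl$end), strand = cl$strand[1],
        score = sum(cl$score),
        identity = sum(cl$identity * cl$n_aligned) / sum(cl$n_aligned),
        n_aligned = as.integer(n_aligned),
        coverage = n_aligned / cl$protein_length[1],
        q_start = min(cl$q_start), q_end = max(cl$q_end),
        n_hits = nrow(cl),
        protein_length = cl$protein_length[1])
    }
  }
  bind_rows(out) %>% arrange(.data$seqid, .data$start)
}

#' Filter merged candidates on identity, coverage and aligned length
#'
#' Keeps candidates with amino-acid identity strictly above
#' `min_identity_pct`, query coverage strictly above `min_overlap_frac` of
#' the protein length, and at least `min_overlap_aa` aligned residues.
#'
#' @param candidates [merge_hits()] output.
#' @param config [pipeline_config()].
#' @export
filter_candidates <- function(candidates, config = pipeline_config()) {
  candidates %>%
    filter(.data$identity > config$min_identity_pct,
           .data$coverage > config$min_overlap_frac,
           .data$n_aligned >= config$min_overlap_aa)
}

# keep the best-scoring candidate per overlapping genomic locus
.dedupe_loci <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  out <- list()
  for (grp in split(candidates, candidates$seqid)) {
    ir <- IRanges::IRanges(grp$start + 1L, grp$end)
    red <- IRanges::reduce(ir)
    cl <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    grp$cluster <- cl
    out[[length(out) + 1]] <- grp %>%
      group_by(.data$cluster) %>%
      arrange(dplyr::desc(.data$score), .data$protein_id, .by_group = TRUE) %>%
      slice(1) %>% ungroup() %>% select(-"cluster")
  }
  bind_rows(out)
}

#' Extract the spliced CDS of an annotated gene
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param annotation feature tibble.
#' @param gene_id gene to extract.
#' @return Sense-strand spliced CDS (character).
#' @export
extract_cds <- function(genome, annotation, gene_id) {
  cds <- annotation %>%
    filter(.data$gene_id == .env$gene_id, .data$type == "CDS") %>%
    arrange(.data$start)
  if (nrow(cds) == 0) stop("no CDS features for ", gene_id, call. = FALSE)
  contig <- as.character(genome[[cds$seqid[1]]])
  seqs <- substring(contig, cds$start + 1, cds$end)
  spliced <- paste(seqs, collapse = "")
  if (cds$strand[1] == "-") spliced <- .revcomp(spliced)
  spliced
}

#' Assign a parental gene to each candidate
#'
#' The best-scoring proteome match among hits overlapping the candidate
#' whose own annotated locus does not overlap the candidate interval. A
#' candidate whose best such match is a single-coding-exon gene is rejected
#' (intronless genes cannot donate a retrocopy), as is one whose best match
#' covers less than `parent_min_cov_frac` of the protein or falls below
#' `parent_min_identity_pct` identity. Ties break by identity, then
#' coverage, then protein id.
#'
#' @param candidates filtered candidate tibble.
#' @param hits_all genome-wide [translated_search()] hits for every protein.
#' @param annotation feature tibble (gene spans + CDS exon counts).
#' @param config [pipeline_config()].
#' @return list: `assigned` (candidates + `parent_id`, `parent_identity`,
#'   `parent_coverage`), `dropped` (tibble with `reason`).
#' @export
assign_parent <- function(candidates, hits_all, annotation,
                          config = pipeline_config()) {
  gene_spans <- annotation %>% filter(.data$type == "gene")
  cds_exons <- annotation %>% filter(.data$type == "CDS") %>%
    dplyr::count(.data$gene_id, name = "n_coding_exons")
  assigned <- list(); dropped <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    ov <- hits_all %>%
      filter(.data$seqid == cand$seqid,
             .data$start < cand$end, .data$end > cand$start)
    if (nrow(ov) == 0) {
      dropped[[length(dropped) + 1]] <- cand %>% mutate(reason = "no_overlapping_hits")
      next
    }
    ranked <- ov %>%
      group_by(.data$protein_id) %>%
      summarise(score = sum(.data$score),
                identity = sum(.data$identity * .data$n_aligned) / sum(.data$n_aligned),
                coverage = sum(IRanges::width(IRanges::reduce(
                  IRanges::IRanges(.data$q_start, .data$q_end)))) /
                  .data$protein_length[1],
                .groups = "drop") %>%
      arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
              dplyr::desc(.data$coverage), .data$protein_id)
    best <- NULL
    for (j in seq_len(nrow(ranked))) {
      locus <- gene_spans %>% filter(.data$gene_id == ranked$protein_id[j])
      overlaps_own <- nrow(locus) > 0 &&
        any(locus$seqid == cand$seqid & locus$start < cand$end &
              locus$end > cand$start)
      if (!overlaps_own) { best <- ranked[j, ]; break }
    }
    if (is.null(best)) {
      dropped[[length(dropped) + 1]] <- cand %>% mutate(reason = "only_self_match")
      next
    }
    nex <- cds_exons$n_coding_exons[match(best$protein_id, cds_exons$gene_id)]
    if (is.na(nex)) nex <- 0L
    if (nex < config$parent_min_coding_exons) {
      dropped[[length(dropped) + 1]] <- cand %>% mutate(reason = "parent_single_exon")
      next
    }
    if (best$coverage < config$parent_min_cov_frac ||
        best$identity < config$parent_min_identity_pct) {
      dropped[[length(dropped) + 1]] <- cand %>% mutate(reason = "parent_below_thresholds")
      next
    }
    assigned[[length(assigned) + 1]] <- cand %>%
      mutate(parent_id = best$protein_id, parent_identity = best$identity,
             parent_coverage = best$coverage)
  }
  list(assigned = bind_rows(assigned), dropped = bind_rows(dropped))
}

#' Confirm intron loss from a dual spliced alignment
#'
#' A candidate is a confirmed retrocopy when the parent's spliced structure
#' contains an intron longer than `confirm_span_bp` whose position (in
#' protein coordinates) is covered on both sides by the candidate's
#' alignment, and no intron occurs at that position in the candidate's
#' structure.
#'
#' @param parent_structure [spliced_align()] of the parent protein on its
#'   own locus.
#' @param retro_structure [spliced_align()] of the parent protein on the
#'   candidate locus.
#' @param confirm_span_bp minimum parental intron length (exclusive).
#' @param margin_aa residues required on each side of the intron position.
#' @param boundary_tol_aa positional tolerance when matching intron
#'   positions between structures.
#' @return logical; attribute `"reason"` explains rejections.
#' @export
confirm_intron_loss <- function(parent_structure, retro_structure,
                                confirm_span_bp = 70, margin_aa = 2,
                                boundary_tol_aa = 3) {
  fail <- function(reason) structure(FALSE, reason = reason)
  if (!isTRUE(parent_structure$accepted)) return(fail("parent structure rejected"))
  if (!isTRUE(retro_structure$accepted)) return(fail("candidate structure rejected"))
  pint <- parent_structure$introns
  if (is.null(pint) || nrow(pint) == 0) {
    return(fail("parent has no introns: loss cannot be demonstrated"))
  }
  rex <- retro_structure$exons
  q_min <- min(rex$q_start); q_max <- max(rex$q_end)
  rint <- retro_structure$introns
  for (k in seq_len(nrow(pint))) {
    if (pint$length[k] <= confirm_span_bp) next
    p <- pint$q_boundary[k]
    if (is.na(p)) next
    if (q_min > p - margin_aa || q_max < p + margin_aa + 1) next
    lost <- nrow(rint) == 0 ||
      all(abs(rint$q_boundary - p) > boundary_tol_aa)
    if (lost) return(structure(TRUE, reason = NA_character_))
  }
  fail("no qualifying parental intron is lost within the aligned span")
}

.pair_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = .nt_submat(1, -1), gapOpening = 5, gapExtension = 2,
    type = "overlap")
  nm <- Biostrings::nmatch(pa); nmm <- Biostrings::nmismatch(pa)
  if (nm + nmm == 0) 0 else 100 * nm / (nm + nmm)
}

#' Demote retrocopies that derive from other retrocopies
#'
#' Within each parent's call set, a call whose nucleotide identity to
#' another call's locus exceeds its identity to the parent's spliced CDS is
#' demoted (`primary = FALSE`); ties favor primary. Demoted calls stay in
#' the output.
#'
#' @param calls call tibble (needs `call_id`, `parent_id`, coordinates).
#' @param genome [Biostrings::DNAStringSet].
#' @param parent_cds named character of parent spliced CDS.
#' @return `calls` with a `primary` logical column.
#' @export
exclude_retro_derived <- function(calls, genome, parent_cds) {
  if (nrow(calls) == 0) return(calls %>% mutate(primary = logical(0)))
  contigs <- lapply(stats::setNames(names(genome), names(genome)),
                    function(s) as.character(genome[[s]]))
  seq_of <- function(r) {
    s <- substr(contigs[[calls$seqid[r]]], calls$start[r] + 1, calls$end[r])
    if (calls$strand[r] == "-") s <- .revcomp(s)
    s
  }
  primary <- rep(TRUE, nrow(calls))
  for (pid in unique(calls$parent_id)) {
    idx <- which(calls$parent_id == pid)
    if (length(idx) < 2) next
    seqs <- vapply(idx, seq_of, "")
    ref <- parent_cds[[pid]]
    id_parent <- vapply(seqs, function(s) .pair_identity(s, ref), numeric(1))
    for (a in seq_along(idx)) {
      best_other <- max(vapply(seq_along(idx)[-a], function(b)
        .pair_identity(seqs[a], seqs[b]), numeric(1)))
      if (best_other > id_parent[a]) primary[idx[a]] <- FALSE
    }
  }
  calls$primary <- primary
  calls
}

# anchor a candidate sequence on the parent CDS frame; returns projected
# codon-aligned strings plus indel records
.anchor_to_parent <- function(parent_cds, cand_seq) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(parent_cds), Biostrings::DNAString(cand_seq),
    substitutionMatrix = .nt_submat(2, -2), gapOpening = 12, gapExtension = 4,
    type = "global-local")
  P <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  S <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  L <- sum(P != "-")
  # indel runs
  runs <- rle(ifelse(P == "-", "ins", ifelse(S == "-", "del", "m")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ppos <- cumsum(P != "-") # parent coordinate at each column
  indels <- list()
  for (k in seq_along(runs$values)) {
    if (runs$values[k] == "m") next
    pos <- if (starts[k] == 1) 0L else ppos[starts[k] - 1]
    indels[[length(indels) + 1]] <- tibble(
      kind = runs$values[k], length = runs$lengths[k], position = as.integer(pos))
  }
  s_proj <- S[P != "-"]
  list(parent_len = L, s_proj = s_proj, indels = bind_rows(indels))
}

#' Classify a call as intact or pseudogene from its disabling mutations
#'
#' A frameshift is an aligned indel of length not divisible by three,
#' strictly inside the CDS; a premature stop is an in-frame stop codon
#' upstream of the final aligned codon (the candidate is projected onto the
#' parent's codon frame first). Any disablement makes the call a pseudogene.
#'
#' @param parent_cds parent spliced CDS (sense strand, includes terminal
#'   stop).
#' @param cand_seq candidate locus sequence, oriented like the parent
#'   protein.
#' @return list: `classification` (`"intact"`/`"pseudogene"`),
#'   `disablements` (tibble of `kind`, `position`), `codon_pair` (projected
#'   codon-aligned parent/candidate strings for Ka/Ks).
#' @export
classify_disablements <- function(parent_cds, cand_seq) {
  anc <- .anchor_to_parent(parent_cds, cand_seq)
  L <- anc$parent_len
  dis <- list()
  if (nrow(anc$indels) > 0) {
    fs <- anc$indels %>%
      filter(.data$length %% 3 != 0, .data$position >= 3,
             .data$position <= L - 3)
    if (nrow(fs) > 0) {
      dis[[length(dis) + 1]] <- fs %>%
        mutate(kind = "frameshift") %>% select("kind", "position")
    }
  }
  n_cod <- L %/% 3
  s <- anc$s_proj
  par_codons <- character(n_cod); cand_codons <- character(n_cod)
  pc <- split_codons(substr(parent_cds, 1, 3 * n_cod))
  for (j in seq_len(n_cod)) {
    cj <- paste(s[(3 * j - 2):(3 * j)], collapse = "")
    cand_codons[j] <- cj
    par_codons[j] <- pc[j]
    if (j < n_cod && grepl("^[ACGT]{3}$", cj) &&
        cj %in% c("TAA", "TAG", "TGA")) {
      dis[[length(dis) + 1]] <- tibble(kind = "premature_stop",
                                       position = 3L * (j - 1L))
    }
  }
  keep <- grepl("^[ACGT]{3}$", cand_codons) & grepl("^[ACGT]{3}$", par_codons)
  disablements <- bind_rows(dis)
  if (nrow(disablements) == 0) {
    disablements <- tibble(kind = character(), position = integer())
  }
  list(
    classification = if (nrow(disablements) > 0) "pseudogene" else "intact",
    disablements = disablements,
    codon_pair = list(parent = paste(par_codons[keep], collapse = ""),
                      candidate = paste(cand_codons[keep], collapse = ""))
  )
}

#' Run the full retrocopy discovery pipeline
#'
#' Executes translated search, hit merging, candidate filtering, parent
#' assignment, dual spliced-alignment intron-loss confirmation, demotion of
#' retro-derived duplicates, disablement classification and per-call LPB
#' Ka/Ks. A failure on one candidate drops only that candidate (logged).
#'
#' @param genome [Biostrings::DNAStringSet] (or a `sim_genome`, from which
#'   proteome and annotation default too).
#' @param proteome [Biostrings::AAStringSet] of annotated proteins, named by
#'   gene id.
#' @param annotation feature tibble.
#' @param config [pipeline_config()].
#' @param verbose print stage progress.
#' @return A `retroscan_result`: `calls` tibble (interval, strand,
#'   `parent_id`, `classification`, `disablements` list-column, `primary`,
#'   `intragenic`, `ka`/`ks`/`ka_ks`), `dropped` log, `stage_counts`,
#'   `config`.
#' @export
run_pipeline <- function(genome, proteome = NULL, annotation = NULL,
                         config = pipeline_config(), verbose = FALSE) {
  if (inherits(genome, "sim_genome")) {
    sim <- genome
    genome <- sim$genome
    proteome <- proteome %||% sim$proteome
    annotation <- annotation %||% sim$annotation
  }
  genome <- .as_dnaset(genome)
  say <- function(...) if (verbose) message(...)
  stage <- list()

  say("translating genome (6 frames)")
  frames <- prepare_genome_frames(genome)
  say("translated search: ", length(proteome), " proteins")
  hits_all <- bind_rows(lapply(names(proteome), function(pid) {
    translated_search(as.character(proteome[[pid]]), frames = frames,
                      min_score = config$min_score, protein_id = pid)
  }))
  stage$hits <- nrow(hits_all)

  candidates <- bind_rows(lapply(split(hits_all, hits_all$protein_id),
                                 merge_hits, merge_gap_bp = config$merge_gap_bp))
  stage$merged_candidates <- nrow(candidates)
  filtered <- filter_candidates(candidates, config)
  stage$filtered <- nrow(filtered)
  deduped <- .dedupe_loci(filtered)
  stage$distinct_loci <- nrow(deduped)

  say("parent assignment")
  pa <- assign_parent(deduped, hits_all, annotation, config)
  assigned <- pa$assigned
  dropped <- pa$dropped
  stage$parent_assigned <- nrow(assigned)

  say("intron-loss confirmation: ", nrow(assigned), " candidates")
  gene_spans <- annotation %>% filter(.data$type == "gene")
  contig_chr <- lapply(stats::setNames(names(genome), names(genome)),
                       function(s) as.character(genome[[s]]))
  parent_struct_cache <- list()
  parent_structure_of <- function(pid) {
    if (!is.null(parent_struct_cache[[pid]])) return(parent_struct_cache[[pid]])
    locus <- gene_spans %>% filter(.data$gene_id == pid) %>% slice(1)
    region <- substr(contig_chr[[locus$seqid]], locus$start + 1, locus$end)
    if (locus$strand == "-") region <- .revcomp(region)
    st <- spliced_align(as.character(proteome[[pid]]), region,
                        min_intron_bp = config$min_intron_bp,
                        filtration_score = config$filtration_score)
    parent_struct_cache[[pid]] <<- st
    st
  }
  confirmed <- list()
  for (i in seq_len(nrow(assigned))) {
    cand <- assigned[i, ]
    res <- tryCatch({
      pstr <- parent_structure_of(cand$parent_id)
      rs <- max(0L, cand$start - config$pad_bp)
      re <- min(nchar(contig_chr[[cand$seqid]]), cand$end + config$pad_bp)
      region <- substr(contig_chr[[cand$seqid]], rs + 1, re)
      if (cand$strand == "-") region <- .revcomp(region)
      rstr <- spliced_align(as.character(proteome[[cand$parent_id]]), region,
                            min_intron_bp = config$min_intron_bp,
                            filtration_score = config$filtration_score)
      ok <- confirm_intron_loss(pstr, rstr,
                                confirm_span_bp = config$confirm_span_bp,
                                boundary_tol_aa = config$boundary_tol_aa)
      list(ok = isTRUE(ok), reason = attr(ok, "reason"))
    }, error = function(e) list(ok = FALSE, reason = conditionMessage(e)))
    if (res$ok) {
      confirmed[[length(confirmed) + 1]] <- cand
    } else {
      dropped <- bind_rows(dropped, cand %>% mutate(reason = res$reason))
    }
  }
  calls <- bind_rows(confirmed)
  stage$intron_loss_confirmed <- nrow(calls)

  if (nrow(calls) > 0) {
    calls$call_id <- sprintf("rc%03d", seq_len(nrow(calls)))
    say("duplicate demotion, classification, Ka/Ks")
    parent_cds <- lapply(stats::setNames(unique(calls$parent_id),
                                         unique(calls$parent_id)),
                         function(pid) extract_cds(genome, annotation, pid))
    calls <- exclude_retro_derived(calls, genome, parent_cds)

    cls <- vector("list", nrow(calls))
    for (i in seq_len(nrow(calls))) {
      cand_seq <- substr(contig_chr[[calls$seqid[i]]], calls$start[i] + 1,
                         calls$end[i])
      if (calls$strand[i] == "-") cand_seq <- .revcomp(cand_seq)
      cls[[i]] <- tryCatch({
        cd <- classify_disablements(parent_cds[[calls$parent_id[i]]], cand_seq)
        kk <- tryCatch(
          kaks_lpb(cd$codon_pair$parent, cd$codon_pair$candidate,
                   drop_stops = TRUE),
          error = function(e) tibble(ka = NA_real_, ks = NA_real_,
                                     ka_ks = NA_real_))
        list(classification = cd$classification,
             disablements = cd$disablements,
             ka = kk$ka, ks = kk$ks, ka_ks = kk$ka_ks)
      }, error = function(e) list(classification = NA_character_,
                                  disablements = tibble(), ka = NA_real_,
                                  ks = NA_real_, ka_ks = NA_real_))
    }
    calls$classification <- vapply(cls, function(x) x$classification, "")
    calls$disablements <- lapply(cls, function(x) x$disablements)
    calls$n_frameshift <- vapply(cls, function(x)
      sum(x$disablements$kind == "frameshift"), numeric(1))
    calls$n_premature_stop <- vapply(cls, function(x)
      sum(x$disablements$kind == "premature_stop"), numeric(1))
    calls$ka <- vapply(cls, function(x) x$ka, numeric(1))
    calls$ks <- vapply(cls, function(x) x$ks, numeric(1))
    calls$ka_ks <- vapply(cls, function(x) x$ka_ks, numeric(1))
    calls$intragenic <- vapply(seq_len(nrow(calls)), function(i) {
      any(gene_spans$seqid == calls$seqid[i] &
            gene_spans$start <= calls$start[i] &
            gene_spans$end >= calls$end[i])
    }, logical(1))
  }
  stage$calls <- nrow(calls)
  stage$primary <- if (nrow(calls) > 0) sum(calls$primary) else 0L

  stage_names <- names(stage)
  stage_n <- as.integer(unlist(stage, use.names = FALSE))
  structure(list(
    calls = calls, dropped = dropped,
    stage_counts = tibble(stage = stage_names, n = stage_n),
    config = config
  ), class = "retroscan_result")
}

#' @export
print.retroscan_result <- function(x, ...) {
  cat("Retrocopy scan: ", nrow(x$calls), " call(s)\n", sep = "")
  print(x$stage_counts)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object a `retroscan_result`.
#' @param ... unused.
#' @method tidy retroscan_result
#' @export
tidy.retroscan_result <- function(x, ...) {
  as_tibble(x$calls)
}

#' @rdname run_pipeline
#' @method glance retroscan_result
#' @export
glance.retroscan_result <- function(x, ...) {
  calls <- x$calls
  tibble(
    n_calls = nrow(calls),
    n_primary = if (nrow(calls)) sum(calls$primary) else 0L,
    n_intact = if (nrow(calls)) sum(calls$classification == "intact", na.rm = TRUE) else 0L,
    n_pseudogene = if (nrow(calls)) sum(calls$classification == "pseudogene", na.rm = TRUE) else 0L,
    n_intragenic = if (nrow(calls)) sum(calls$intragenic) else 0L,
    median_ks = if (nrow(calls)) median(calls$ks, na.rm = TRUE) else NA_real_
  )
}

#' @rdname run_pipeline
#' @method autoplot retroscan_result
#' @export
autoplot.retroscan_result <- function(object, ...) {
  sc <- object$stage_counts %>%
    mutate(stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "records", y = NULL,
                  title = "Pipeline stage funnel") +
    ggplot2::theme_minimal()
}

#' Score pipeline calls against planted ground truth
#'
#' Matches primary calls to planted retrocopies (same parent, >= 50%
#' overlap of the planted interval) and reports sensitivity, false discovery
#' rate, disablement-classification agreement.
#'
#' @param result [run_pipeline()] output.
#' @param truth `sim$truth` tibble.
#' @return list: `sensitivity`, `fdr`, `n_truth`, `n_matched`,
#'   `n_false`, `classification_agreement`, `matches` tibble.
#' @export
evaluate_calls <- function(result, truth) {
  calls <- result$calls %>% filter(.data$primary)
  matches <- list()
  used_calls <- character(0)
  for (r in seq_len(nrow(truth))) {
    t <- truth[r, ]
    ov <- calls %>%
      filter(.data$seqid == t$seqid, .data$parent_id == t$parent_id,
             pmin(.data$end, t$end) - pmax(.data$start, t$start) >=
               0.5 * (t$end - t$start))
    matched <- nrow(ov) > 0
    cls_ok <- NA
    if (matched) {
      call <- ov[1, ]
      used_calls <- c(used_calls, call$call_id)
      expected <- switch(t$class,
                         intact = "intact",
                         frameshift = , premature_stop = "pseudogene",
                         "intact") # chimeric bodies carry intact frames
      cls_ok <- identical(call$classification, expected)
      if (cls_ok && t$class %in% c("frameshift", "premature_stop")) {
        kinds <- call$disablements[[1]]$kind
        cls_ok <- t$class %in% kinds
      }
    }
    matches[[r]] <- tibble(retro_id = t$retro_id, class = t$class,
                           matched = matched,
                           call_id = if (matched) ov$call_id[1] else NA_character_,
                           classification_ok = cls_ok)
  }
  m <- bind_rows(matches)
  n_false <- sum(!calls$call_id %in% m$call_id)
  list(
    sensitivity = if (nrow(truth)) mean(m$matched) else NA_real_,
    fdr = if (nrow(calls)) n_false / nrow(calls) else 0,
    n_truth = nrow(truth), n_matched = sum(m$matched), n_false = n_false,
    classification_agreement = mean(m$classification_ok[m$matched]),
    matches = m
  )
}
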