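# EST placement disambiguation and transcription evidence: the strict
# best-hit/uniqueness filter, per-call EST/mRNA counts, chimeric-transcript
# confirmation, flanking transcriptional activity and distance to the
# closest gene.

#' Disambiguate EST placements (best-hit / uniqueness filter)
#'
#' Per EST: retain the best placement plus any placement whose identity
#' falls less than `best_gap_pct` points below it and is at least
#' `genome_min_identity`. An EST is accepted only when exactly one retained
#' location remains, its aligned length strictly exceeds `min_len`, and its
#' identity strictly exceeds `placement_min_identity`.
#'
#' @param raw placement tibble from [map_ests()] / [nucleotide_search()]
#'   (per EST, best first).
#' @param min_len minimum aligned length (exclusive bound).
#' @param genome_min_identity retention floor for near-best placements (%).
#' @param placement_min_identity acceptance floor for the unique placement
#'   (%, exclusive bound).
#' @param best_gap_pct identity gap (percentage points, exclusive) defining
#'   "near-best".
#' @return All retained placements with `accepted` (logical) and `reason`
#'   columns; downstream analyses use `filter(accepted)`.
#' @export
place_ests <- function(raw, min_len = 100, genome_min_identity = 96,
                       placement_min_identity = 97, best_gap_pct = 0.5) {
  if (nrow(raw) == 0) {
    return(raw %>% mutate(accepted = logical(0), reason = character(0)))
  }
  raw %>%
    group_by(.data$est_id) %>%
    mutate(best_identity = max(.data$identity)) %>%
    filter(.data$identity > .data$best_identity - best_gap_pct,
           .data$identity >= genome_min_identity |
             .data$identity == .data$best_identity) %>%
    mutate(n_retained = sum(.data$identity >= genome_min_identity),
           unique_loc = .data$n_retained == 1 &
             .data$identity >= genome_min_identity) %>%
    ungroup() %>%
    mutate(
      accepted = .data$unique_loc & .data$aligned_len > min_len &
        .data$identity > placement_min_identity,
      reason = dplyr::case_when(
        .data$accepted ~ NA_character_,
        !.data$unique_loc & .data$n_retained > 1 ~ "multiple_locations",
        !.data$unique_loc ~ "below_genome_identity",
        .data$aligned_len <= min_len ~ "aligned_length",
        TRUE ~ "below_placement_identity"
      )
    ) %>%
    select(-"best_identity", -"n_retained", -"unique_loc")
}

#' Attach EST/mRNA evidence to retrocopy calls
#'
#' Counts accepted placements overlapping each call interval by at least
#' 1 bp.
#'
#' @param calls call tibble.
#' @param placements accepted EST placements (`filter(accepted)` applied
#'   internally if the column is present).
#' @param mrna_placements optional accepted mRNA placements.
#' @return Tibble: `call_id`, `n_est`, `n_mrna`, `transcribed`.
#' @export
attach_evidence <- function(calls, placements, mrna_placements = NULL) {
  take <- function(p) {
    if (!is.null(p) && "accepted" %in% names(p)) p <- p %>% filter(.data$accepted)
    p
  }
  placements <- take(placements)
  mrna_placements <- take(mrna_placements)
  count_over <- function(p, call) {
    if (is.null(p) || nrow(p) == 0) return(0L)
    sum(p$seqid == call$seqid & p$start < call$end & p$end > call$start)
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    tibble(call_id = call$call_id,
           n_est = count_over(placements, call),
           n_mrna = count_over(mrna_placements, call))
  })
  bind_rows(rows) %>% mutate(transcribed = .data$n_est > 0 | .data$n_mrna > 0)
}

#' Confirm a chimeric transcript with a junction-spanning EST
#'
#' TRUE when one single accepted EST overlaps at least one retro-derived
#' exon and at least one non-retro-derived exon of the chimeric transcript.
#'
#' @param placements accepted EST placements.
#' @param chimera one row of a chimera tibble (`call_id`, `transcript_id`).
#' @param calls retrocopy call tibble.
#' @param annotation feature tibble.
#' @return logical.
#' @export
confirm_chimeric_transcript <- function(placements, chimera, calls,
                                        annotation) {
  if ("accepted" %in% names(placements)) {
    placements <- placements %>% filter(.data$accepted)
  }
  call <- calls %>% filter(.data$call_id == chimera$call_id) %>% slice(1)
  ex <- annotation %>%
    filter(.data$transcript_id == chimera$transcript_id,
           .data$type == "exon")
  if (nrow(ex) == 0 || nrow(placements) == 0) return(FALSE)
  retro_ex <- pmin(ex$end, call$end) - pmax(ex$start, call$start) >= 1
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    if (p$seqid != ex$seqid[1]) next
    # use aligned blocks when available (spliced placements), else the span
    iv <- if ("blocks" %in% names(placements) && !is.null(p$blocks[[1]])) {
      p$blocks[[1]]
    } else {
      tibble(start = p$start, end = p$end)
    }
    hits_exon <- vapply(seq_len(nrow(ex)), function(k)
      any(iv$start < ex$end[k] & iv$end > ex$start[k]), logical(1))
    if (any(hits_exon & retro_ex) && any(hits_exon & !retro_ex)) return(TRUE)
  }
  FALSE
}

#' Transcriptional activity flanking a call
#'
#' Counts accepted placements overlapping the two flanking windows
#' `[start - window, start - exclusion)` and `(end + exclusion, end +
#' window]`, clipped at contig ends; placements within the exclusion zone
#' are ignored.
#'
#' @param calls call tibble.
#' @param placements accepted placements.
#' @param exclusion inner exclusion distance (bp).
#' @param window outer window distance (bp).
#' @param contig_lengths named integer vector (for clipping); optional.
#' @return Tibble: `call_id`, `flank_est_count`.
#' @export
flanking_activity <- function(calls, placements, exclusion = 2000,
                              window = 40000, contig_lengths = NULL) {
  if ("accepted" %in% names(placements)) {
    placements <- placements %>% filter(.data$accepted)
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    clen <- if (!is.null(contig_lengths)) contig_lengths[[call$seqid]] else Inf
    lw <- c(max(0, call$start - window), max(0, call$start - exclusion))
    rw <- c(min(clen, call$end + exclusion), min(clen, call$end + window))
    p <- placements %>% filter(.data$seqid == call$seqid)
    in_left <- p$start < lw[2] & p$end > lw[1]
    in_right <- p$start < rw[2] & p$end > rw[1]
    tibble(call_id = call$call_id,
           flank_est_count = sum(in_left | in_right))
  })
  bind_rows(rows)
}

#' Distance from each call to the closest non-overlapping transcript
#'
#' Minimum gap (bp, strand-ignored) between the call interval and any
#' transcript span; transcripts overlapping the call are removed first. NA
#' when no non-overlapping transcript exists.
#'
#' @param calls call tibble.
#' @param annotation feature tibble (mRNA spans used).
#' @return Tibble: `call_id`, `distance_to_closest_gene`.
#' @export
distance_to_closest_gene <- function(calls, annotation) {
  tx <- annotation %>% filter(.data$type == "mRNA")
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    t <- tx %>% filter(.data$seqid == call$seqid)
    overlapping <- t$start < call$end & t$end > call$start
    t <- t[!overlapping, ]
    d <- if (nrow(t) == 0) NA_integer_ else {
      as.integer(min(ifelse(t$start >= call$end, t$start - call$end,
                            call$start - t$end)))
    }
    tibble(call_id = call$call_id, distance_to_closest_gene = d)
  })
  bind_rows(rows)
}

#' Group comparisons of transcription evidence
#'
#' Mann-Whitney U on flanking EST counts between transcribed and silent
#' calls, and Fisher's exact test on EST presence/absence by classification
#' (intact vs pseudogene). Degenerate groups are reported as not computable.
#'
#' @param evidence tibble with `classification`, `n_est`,
#'   `flank_est_count`, `transcribed`.
#' @return Tibble of test results (`comparison`, `method`, `p_value`,
#'   `statistic`, `computable`).
#' @export
compare_groups <- function(evidence) {
  out <- list()
  x <- evidence$flank_est_count[evidence$transcribed]
  y <- evidence$flank_est_count[!evidence$transcribed]
  if (length(x) > 0 && length(y) > 0) {
    mw <- mann_whitney_u(x, y)
    out[[1]] <- tibble(comparison = "flank_activity_transcribed_vs_silent",
                       method = mw$method, statistic = mw$u,
                       p_value = mw$p_value, computable = TRUE)
  } else {
    out[[1]] <- tibble(comparison = "flank_activity_transcribed_vs_silent",
                       method = "mann_whitney_u", statistic = NA_real_,
                       p_value = NA_real_, computable = FALSE)
  }
  tab <- table(factor(evidence$classification,
                      levels = c("intact", "pseudogene")),
               factor(evidence$n_est > 0, levels = c(TRUE, FALSE)))
  if (all(rowSums(tab) > 0)) {
    fe <- fisher_exact(matrix(as.numeric(tab), 2))
    out[[2]] <- tibble(comparison = "est_support_intact_vs_pseudogene",
                       method = fe$method, statistic = fe$odds_ratio,
                       p_value = fe$p_value, computable = TRUE)
  } else {
    out[[2]] <- tibble(comparison = "est_support_intact_vs_pseudogene",
                       method = "fisher_exact", statistic = NA_real_,
                       p_value = NA_real_, computable = FALSE)
  }
  bind_rows(out)
}
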