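# Chimerical retrogene identification and structural classification:
# transcripts that overlap a retrocopy but are mostly novel sequence, split
# into N-/C-/both-terminal peptide additions or UTR conversion, fusion vs
# de novo mode, and new-splice-site detection.

# transcript-coordinate machinery: exons of one transcript in transcript
# order, with cumulative spliced offsets
.tx_exons <- function(annotation, tid) {
  ex <- annotation %>%
    filter(.data$transcript_id == tid, .data$type == "exon") %>%
    arrange(.data$start)
  if (nrow(ex) == 0) return(ex)
  if (ex$strand[1] == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  ex$width <- ex$end - ex$start
  ex$tx_start <- cumsum(c(0, ex$width[-nrow(ex)]))
  ex
}

# map a genomic interval to transcript coordinates (list of tx intervals)
.to_tx <- function(ex, g_start, g_end) {
  out <- list()
  for (i in seq_len(nrow(ex))) {
    lo <- max(g_start, ex$start[i]); hi <- min(g_end, ex$end[i])
    if (hi <= lo) next
    if (ex$strand[i] == "+") {
      t0 <- ex$tx_start[i] + (lo - ex$start[i])
      out[[length(out) + 1]] <- c(t0, t0 + (hi - lo))
    } else {
      t0 <- ex$tx_start[i] + (ex$end[i] - hi)
      out[[length(out) + 1]] <- c(t0, t0 + (hi - lo))
    }
  }
  out
}

#' Find chimeric-transcript candidates for retrocopy calls
#'
#' A transcript is a chimera candidate when its exons overlap the retrocopy
#' interval, the retrocopy covers strictly less than `max_retro_frac` of the
#' transcript's spliced length (guaranteeing at least 20% novel sequence),
#' and the transcript does not arise from the call's parental locus.
#'
#' @param calls retrocopy call tibble (`call_id`, `parent_id`, coordinates).
#' @param annotation feature tibble with transcript exon structures.
#' @param max_retro_frac retro-derived fraction bound (exclusive).
#' @return Tibble: `call_id`, `transcript_id`, `retro_fraction`,
#'   `spliced_length`.
#' @export
find_chimeras <- function(calls, annotation, max_retro_frac = 0.80) {
  out <- list()
  gene_spans <- annotation %>% filter(.data$type == "gene")
  tids <- annotation %>% filter(.data$type == "exon") %>%
    distinct(.data$transcript_id, .data$gene_id, .data$seqid)
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    parent_span <- gene_spans %>% filter(.data$gene_id == call$parent_id)
    for (j in seq_len(nrow(tids))) {
      if (tids$seqid[j] != call$seqid) next
      ex <- .tx_exons(annotation, tids$transcript_id[j])
      ov <- sum(pmax(0, pmin(ex$end, call$end) - pmax(ex$start, call$start)))
      if (ov < 1) next
      spliced <- sum(ex$width)
      frac <- ov / spliced
      if (frac >= max_retro_frac) next
      tx_lo <- min(ex$start); tx_hi <- max(ex$end)
      from_parent <- nrow(parent_span) > 0 &&
        any(parent_span$seqid == tids$seqid[j] &
              parent_span$start < tx_hi & parent_span$end > tx_lo)
      if (from_parent) next
      out[[length(out) + 1]] <- tibble(
        call_id = call$call_id, transcript_id = tids$transcript_id[j],
        retro_fraction = frac, spliced_length = spliced)
    }
  }
  bind_rows(out)
}

#' Classify chimera structure (N/C/both peptide additions, UTR conversion)
#'
#' Novel (non-retro-derived) coding sequence upstream of the retro segment
#' only gives `N_add`; downstream only gives `C_add`; both sides `both_add`;
#' a retro-derived region inside the 5'UTR with no novel CDS gives
#' `UTR_conversion`. Segments shorter than `min_novel_nt` are ignored
#' (alignment-end jitter).
#'
#' @param chimeras [find_chimeras()] tibble.
#' @param calls retrocopy call tibble.
#' @param annotation feature tibble (exon + CDS per transcript).
#' @param min_novel_nt minimum novel segment length counted.
#' @return `chimeras` with a `category` column (NA when the transcript has
#'   no CDS).
#' @export
classify_chimera <- function(chimeras, calls, annotation, min_novel_nt = 30) {
  category <- character(nrow(chimeras))
  for (i in seq_len(nrow(chimeras))) {
    tid <- chimeras$transcript_id[i]
    call <- calls %>% filter(.data$call_id == chimeras$call_id[i]) %>% slice(1)
    ex <- .tx_exons(annotation, tid)
    cds <- annotation %>%
      filter(.data$transcript_id == tid, .data$type == "CDS")
    if (nrow(cds) == 0) { category[i] <- NA_character_; next }
    retro_tx <- .to_tx(ex, call$start, call$end)
    cds_tx <- unlist(lapply(seq_len(nrow(cds)), function(k)
      .to_tx(ex, cds$start[k], cds$end[k])), recursive = FALSE)
    r_lo <- min(vapply(retro_tx, `[`, numeric(1), 1))
    r_hi <- max(vapply(retro_tx, `[`, numeric(1), 2))
    c_lo <- min(vapply(cds_tx, `[`, numeric(1), 1))
    c_hi <- max(vapply(cds_tx, `[`, numeric(1), 2))
    up <- max(0, min(r_lo, c_hi) - c_lo)
    down <- max(0, c_hi - max(r_hi, c_lo))
    has_up <- up >= min_novel_nt
    has_down <- down >= min_novel_nt
    if (has_up && has_down) {
      category[i] <- "both_add"
    } else if (has_up) {
      category[i] <- "N_add"
    } else if (has_down) {
      category[i] <- "C_add"
    } else {
      utr5 <- max(0, min(r_hi, c_lo) - r_lo) # retro-derived 5'UTR sequence
      category[i] <- if (utr5 >= min_novel_nt) "UTR_conversion" else NA_character_
    }
  }
  chimeras$category <- category
  chimeras
}

#' Classify chimera mode: fusion with a neighbor vs de novo
#'
#' `fusion` when the chimeric transcript shares exonic sequence with a
#' different, pre-existing gene; `de_novo` otherwise (recruited UTRs forming
#' a single-exon gene, or the retrocopy spanning the full new CDS).
#'
#' @inheritParams classify_chimera
#' @return `chimeras` with a `mode` column.
#' @export
classify_mode <- function(chimeras, calls, annotation) {
  exons <- annotation %>% filter(.data$type == "exon")
  mode <- character(nrow(chimeras))
  for (i in seq_len(nrow(chimeras))) {
    tid <- chimeras$transcript_id[i]
    ex <- exons %>% filter(.data$transcript_id == tid)
    own_gene <- ex$gene_id[1]
    others <- exons %>%
      filter(.data$gene_id != own_gene, .data$seqid == ex$seqid[1])
    shared <- FALSE
    for (k in seq_len(nrow(ex))) {
      if (any(pmin(others$end, ex$end[k]) - pmax(others$start, ex$start[k]) >= 1)) {
        shared <- TRUE; break
      }
    }
    mode[i] <- if (shared) "fusion" else "de_novo"
  }
  chimeras$mode <- mode
  chimeras
}

#' Flag chimeras whose retro segment crosses an exon-intron boundary
#'
#' TRUE when the retro-derived segment extends at least 1 bp on each side of
#' an internal exon boundary of the chimeric transcript (a new splice site
#' inside retro-derived sequence).
#'
#' @inheritParams classify_chimera
#' @return `chimeras` with a `new_splice_site` column.
#' @export
detect_new_splice_site <- function(chimeras, calls, annotation) {
  flag <- logical(nrow(chimeras))
  for (i in seq_len(nrow(chimeras))) {
    call <- calls %>% filter(.data$call_id == chimeras$call_id[i]) %>% slice(1)
    ex <- annotation %>%
      filter(.data$transcript_id == chimeras$transcript_id[i],
             .data$type == "exon") %>%
      arrange(.data$start)
    if (nrow(ex) < 1) next
    tx_lo <- min(ex$start); tx_hi <- max(ex$end)
    boundaries <- setdiff(c(ex$start, ex$end), c(tx_lo, tx_hi))
    flag[i] <- any(call$start <= boundaries - 1 & call$end >= boundaries + 1)
  }
  chimeras$new_splice_site <- flag
  chimeras
}

#' Full chimera call set for a pipeline result
#'
#' Convenience wrapper: find candidates, classify category, mode and new
#' splice sites, and assert the retro-fraction invariant.
#'
#' @param result a [run_pipeline()] `retroscan_result` (primary calls used).
#' @param annotation feature tibble.
#' @param max_retro_frac retro-derived fraction bound.
#' @return Chimera tibble with `category`, `mode`, `new_splice_site`.
#' @export
call_chimeras <- function(result, annotation, max_retro_frac = 0.80) {
  calls <- result$calls %>% filter(.data$primary)
  ch <- find_chimeras(calls, annotation, max_retro_frac)
  if (nrow(ch) == 0) return(ch)
  ch <- classify_chimera(ch, calls, annotation)
  ch <- classify_mode(ch, calls, annotation)
  ch <- detect_new_splice_site(ch, calls, annotation)
  stopifnot(all(ch$retro_fraction < max_retro_frac))
  ch
}
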