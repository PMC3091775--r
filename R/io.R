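# FASTA / GFF3 / TSV boundaries. Internally everything is 0-based half-open;
# rtracklayer handles the 1-based inclusive GFF3 convention.

#' Write an annotation tibble as GFF3
#'
#' @param annotation feature tibble (`seqid`, `type`, `start`, `end`,
#'   `strand`, `gene_id`, `transcript_id`; 0-based half-open).
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  # CDS phase: cumulative coding length along each transcript, 5' to 3'
  annotation$phase <- NA_integer_
  is_cds <- annotation$type == "CDS"
  for (tid in unique(annotation$transcript_id[is_cds])) {
    idx <- which(is_cds & annotation$transcript_id == tid)
    idx <- idx[order(annotation$start[idx])]
    if (annotation$strand[idx[1]] == "-") idx <- rev(idx)
    lens <- annotation$end[idx] - annotation$start[idx]
    annotation$phase[idx] <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqid,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- annotation$type
  S4Vectors::mcols(gr)$ID <- paste0(annotation$type, ":",
                                    annotation$gene_id, ":",
                                    seq_len(nrow(annotation)))
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id
  S4Vectors::mcols(gr)$transcript_id <- annotation$transcript_id
  S4Vectors::mcols(gr)$phase <- annotation$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into the internal annotation tibble
#'
#' @param path GFF3 file.
#' @return Feature tibble with 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = if ("gene_id" %in% colnames(md)) as.character(md$gene_id) else NA_character_,
    transcript_id = if ("transcript_id" %in% colnames(md))
      as.character(md$transcript_id) else NA_character_
  )
}

#' Validate an annotation tibble
#'
#' Checks that exon/CDS intervals lie within their gene span, that every
#' transcript's features share one strand, and that intervals are non-empty.
#'
#' @param annotation feature tibble.
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_annotation <- function(annotation) {
  stopifnot(all(c("seqid", "type", "start", "end", "strand", "gene_id") %in%
                  names(annotation)))
  if (any(annotation$end <= annotation$start)) {
    stop("empty or inverted feature interval", call. = FALSE)
  }
  genes <- annotation %>% filter(.data$type == "gene")
  feats <- annotation %>% filter(.data$type %in% c("exon", "CDS", "mRNA"))
  for (g in seq_len(nrow(genes))) {
    f <- feats %>% filter(.data$gene_id == genes$gene_id[g])
    if (nrow(f) == 0) next
    if (any(f$start < genes$start[g]) || any(f$end > genes$end[g])) {
      stop("feature outside gene span for ", genes$gene_id[g], call. = FALSE)
    }
    if (any(f$strand != genes$strand[g])) {
      stop("strand mismatch within ", genes$gene_id[g], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a simulation to disk (FASTA + GFF3 + truth TSV)
#'
#' @param sim [generate_genome()] result.
#' @param outdir output directory (created if missing).
#' @param reads optional [sample_ests()] result to write alongside.
#' @return Named character vector of written paths.
#' @export
write_simulation <- function(sim, outdir, reads = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    proteome = file.path(outdir, "proteome.fa"),
    annotation = file.path(outdir, "annotation.gff3"),
    truth = file.path(outdir, "truth.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  Biostrings::writeXStringSet(sim$proteome, paths["proteome"])
  write_gff3(sim$annotation, paths["annotation"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(reads)) {
    paths["ests"] <- file.path(outdir, "ests.fa")
    Biostrings::writeXStringSet(reads$ests, paths["ests"])
    if (length(reads$mrnas) > 0) {
      paths["mrnas"] <- file.path(outdir, "mrnas.fa")
      Biostrings::writeXStringSet(reads$mrnas, paths["mrnas"])
    }
  }
  paths
}
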