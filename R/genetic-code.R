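# Codon degeneracy classification under the standard genetic code.
#
# A codon position is 4-fold degenerate when every substitution at it is
# synonymous, 0-fold when none is, and 2-fold otherwise (3-fold sites, i.e.
# Ile, are treated as 2-fold, the usual LWL/LPB convention).

.rf_cache <- new.env(parent = emptyenv())

#' Per-position degeneracy classes for all sense codons
#'
#' Computed once from the standard genetic code and cached. Returns a 64 x 3
#' integer matrix (rownames = codons) with entries in \{0, 2, 4\}; stop codons
#' get NA rows.
#'
#' @return integer matrix, 64 codons x 3 positions.
#' @keywords internal
codon_degeneracy_table <- function() {
  if (!is.null(.rf_cache$degeneracy)) return(.rf_cache$degeneracy)
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  codons <- names(gc)
  deg <- matrix(NA_integer_, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- gc[[cd]]
    if (aa == "*") next
    for (pos in 1:3) {
      alts <- setdiff(nts, substr(cd, pos, pos))
      syn <- 0L
      for (nt in alts) {
        alt <- cd
        substr(alt, pos, pos) <- nt
        if (gc[[alt]] == aa) syn <- syn + 1L
      }
      deg[cd, pos] <- if (syn == 0L) 0L else if (syn == 3L) 4L else 2L
    }
  }
  .rf_cache$degeneracy <- deg
  deg
}

#' @keywords internal
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' @keywords internal
is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

# split an nt string into codon triplets
#' @keywords internal
split_codons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0) {
    stop("sequence length ", nchar(x), " is not a multiple of 3", call. = FALSE)
  }
  if (nchar(x) == 0) return(character(0))
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}
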