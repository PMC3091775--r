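# LPB (Li 1993 / Pamilo-Bianchi 1993) Ka/Ks estimation, synonymous-rate
# calibration from ortholog pairs, retrocopy ages and origination rates.

#' Count degenerate sites and differences for an aligned codon pair
#'
#' Classifies every ungapped codon position of a codon-aligned pair as 0-, 2-
#' or 4-fold degenerate (3-fold treated as 2-fold) and tallies transition and
#' transversion differences per class. Site classes are taken from each
#' sequence's own codon and averaged over the two sequences, as in the
#' LWL/LPB family of estimators; a differing position whose class disagrees
#' between the two codons contributes 0.5 to each class.
#'
#' Codon columns containing an alignment gap (`-`) or an ambiguity code are
#' excluded. An internal stop codon is an error unless `drop_stops = TRUE`,
#' in which case the offending codon column is excluded (needed when scoring
#' processed pseudogenes, whose reading frames contain stops by definition).
#'
#' @param cds_a,cds_b aligned, equal-length coding sequences (character or
#'   [Biostrings::DNAString]); length a multiple of 3; gaps as `-`.
#' @param drop_stops drop codon columns where either sequence has a stop
#'   codon instead of erroring.
#' @return A one-row tibble with site counts `l0`, `l2`, `l4` (averaged over
#'   the two sequences), transition counts `ts0`, `ts2`, `ts4`, transversion
#'   counts `tv0`, `tv2`, `tv4`, and `n_codons` (ungapped codon columns used).
#' @export
count_sites <- function(cds_a, cds_b, drop_stops = FALSE) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (length(ca) != length(cb)) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  aa_a <- translate_codons(ca); aa_b <- translate_codons(cb)
  stop_hit <- which(aa_a == "*" | aa_b == "*")
  # a terminal stop is tolerated silently
  stop_hit <- stop_hit[stop_hit < length(ca)]
  if (length(stop_hit) > 0 && !drop_stops) {
    stop("internal stop codon at codon ", stop_hit[1], call. = FALSE)
  }
  term_stop <- length(ca) > 0 && (aa_a[length(ca)] == "*" || aa_b[length(ca)] == "*")
  drop <- unique(c(stop_hit, if (term_stop) length(ca)))
  if (length(drop) > 0) { ca <- ca[-drop]; cb <- cb[-drop] }

  zero <- c(`0` = 0, `2` = 0, `4` = 0)
  l <- zero; ts <- zero; tv <- zero
  if (length(ca) > 0) {
    deg <- codon_degeneracy_table()
    for (pos in 1:3) {
      cls_a <- as.character(deg[ca, pos])
      cls_b <- as.character(deg[cb, pos])
      for (k in names(l)) {
        l[k] <- l[k] + sum(cls_a == k) / 2 + sum(cls_b == k) / 2
      }
      na <- substr(ca, pos, pos); nb <- substr(cb, pos, pos)
      diff <- na != nb
      if (!any(diff)) next
      w_ts <- diff & is_transition(na, nb)
      w_tv <- diff & !is_transition(na, nb)
      for (k in names(l)) {
        ts[k] <- ts[k] + sum(w_ts & cls_a == k) / 2 + sum(w_ts & cls_b == k) / 2
        tv[k] <- tv[k] + sum(w_tv & cls_a == k) / 2 + sum(w_tv & cls_b == k) / 2
      }
    }
  }
  tibble(
    l0 = l[["0"]], l2 = l[["2"]], l4 = l[["4"]],
    ts0 = ts[["0"]], ts2 = ts[["2"]], ts4 = ts[["4"]],
    tv0 = tv[["0"]], tv2 = tv[["2"]], tv4 = tv[["4"]],
    n_codons = length(ca)
  )
}

# K2P per-class distances from proportions P (transitions) and Q
# (transversions): A = 1/2 ln(1/(1-2P-Q)) - 1/4 ln(1/(1-2Q)), B = 1/2 ln(1/(1-2Q))
.k2p_class <- function(p, q, class) {
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0) {
    stop("substitution saturation at ", class, "-fold sites (P=",
         signif(p, 4), ", Q=", signif(q, 4), ")", call. = FALSE)
  }
  c(a = 0.5 * log(1 / w1) - 0.25 * log(1 / w2), b = 0.5 * log(1 / w2))
}

#' LPB Ka/Ks for an aligned codon pair
#'
#' The Li (1993) / Pamilo-Bianchi (1993) estimator: sites are split into 0-,
#' 2- and 4-fold degenerate classes, Kimura two-parameter transitional (A_i)
#' and transversional (B_i) distances are computed per class, and
#' \deqn{Ks = (L_2 A_2 + L_4 A_4)/(L_2 + L_4) + B_4}
#' \deqn{Ka = A_0 + (L_0 B_0 + L_2 B_2)/(L_0 + L_2)}
#'
#' @inheritParams count_sites
#' @return One-row tibble: `ka`, `ks`, `ka_ks` (NA when `ks` is 0), the site
#'   counts `l0`,`l2`,`l4`, per-class proportions `p0`,`p2`,`p4`,
#'   `q0`,`q2`,`q4`, distances `a0`,`a2`,`a4`, `b0`,`b2`,`b4`, and `n_codons`.
#' @examples
#' a <- strrep("GGG", 10)
#' b <- paste0(strrep("GGG", 9), "GGA")
#' kaks_lpb(a, b)  # all change at 4-fold sites: ka = 0
#' @export
kaks_lpb <- function(cds_a, cds_b, drop_stops = FALSE) {
  cs <- count_sites(cds_a, cds_b, drop_stops = drop_stops)
  l <- c(cs$l0, cs$l2, cs$l4)
  ts <- c(cs$ts0, cs$ts2, cs$ts4)
  tv <- c(cs$tv0, cs$tv2, cs$tv4)
  p <- ifelse(l > 0, ts / l, 0)
  q <- ifelse(l > 0, tv / l, 0)
  ab <- mapply(.k2p_class, p, q, c(0, 2, 4))
  a <- ab["a", ]; b <- ab["b", ]
  ks <- if (l[2] + l[3] > 0) (l[2] * a[2] + l[3] * a[3]) / (l[2] + l[3]) + b[3] else NA_real_
  ka <- if (l[1] + l[2] > 0) a[1] + (l[1] * b[1] + l[2] * b[2]) / (l[1] + l[2]) else NA_real_
  tibble(
    ka = ka, ks = ks,
    ka_ks = ifelse(!is.na(ks) & ks > 0, ka / ks, NA_real_),
    l0 = l[1], l2 = l[2], l4 = l[3],
    p0 = p[1], p2 = p[2], p4 = p[3],
    q0 = q[1], q2 = q[2], q4 = q[3],
    a0 = a[1], a2 = a[2], a4 = a[3],
    b0 = b[1], b2 = b[2], b4 = b[3],
    n_codons = cs$n_codons
  )
}

#' Calibrate the synonymous substitution rate from ortholog Ks values
#'
#' Given per-pair synonymous divergences between orthologs of two species
#' that split `t_years` ago, estimates the lineage synonymous rate
#' r = mean(Ks) / (2 T) in substitutions per silent site per year.
#'
#' @param ortholog_ks numeric vector of ortholog Ks values (NAs = saturated
#'   pairs; excluded with a warning).
#' @param t_years divergence time in years.
#' @param stat `"mean"` (default) or `"median"`.
#' @return A `rate_calibration` object (see [tidy.rate_calibration()]).
#' @export
calibrate_rate <- function(ortholog_ks, t_years, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(ortholog_ks) == 0) stop("no ortholog Ks values", call. = FALSE)
  if (t_years <= 0) stop("t_years must be positive", call. = FALSE)
  bad <- is.na(ortholog_ks)
  if (any(bad)) {
    warning(sum(bad), " saturated/NA Ks value(s) excluded from calibration")
    ortholog_ks <- ortholog_ks[!bad]
    if (length(ortholog_ks) == 0) stop("no usable Ks values", call. = FALSE)
  }
  center <- if (stat == "mean") mean(ortholog_ks) else median(ortholog_ks)
  structure(
    list(r = center / (2 * t_years), t_years = t_years,
         ortholog_ks = ortholog_ks, n_pairs = length(ortholog_ks), stat = stat),
    class = "rate_calibration"
  )
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat("Synonymous-rate calibration (", x$n_pairs, " ortholog pairs, ",
      x$stat, " Ks = ", signif(get(x$stat)(x$ortholog_ks), 4), ")\n",
      "  divergence time T = ", format(x$t_years, big.mark = ","), " years\n",
      "  r = ", signif(x$r, 4), " substitutions per silent site per year\n",
      sep = "")
  invisible(x)
}

#' @rdname calibrate_rate
#' @param x a `rate_calibration` object.
#' @param ... unused.
#' @method tidy rate_calibration
#' @export
tidy.rate_calibration <- function(x, ...) {
  tibble(ks = x$ortholog_ks)
}

#' @rdname calibrate_rate
#' @method glance rate_calibration
#' @export
glance.rate_calibration <- function(x, ...) {
  tibble(r = x$r, t_years = x$t_years, n_pairs = x$n_pairs,
         mean_ks = mean(x$ortholog_ks), median_ks = median(x$ortholog_ks))
}

#' Age of a duplicate from its synonymous divergence
#'
#' Inverts the molecular-clock identity Ks = 2 r T: `T = Ks / (2 r)` years.
#'
#' @param ks synonymous substitutions per site (vectorized).
#' @param r synonymous rate in substitutions per silent site per year,
#'   or a [calibrate_rate()] object.
#' @return ages in years.
#' @export
estimate_age <- function(ks, r) {
  if (inherits(r, "rate_calibration")) r <- r$r
  if (r <= 0) stop("rate r must be positive", call. = FALSE)
  if (any(ks < 0, na.rm = TRUE)) stop("negative Ks", call. = FALSE)
  ks / (2 * r)
}

#' Expected Ks accumulated over a time window
#'
#' The forward clock identity Ks = 2 r T; e.g. the Ks cutoff corresponding
#' to an age window of T years at rate r.
#'
#' @inheritParams estimate_age
#' @param t_years time in years.
#' @export
ks_for_age <- function(r, t_years) {
  if (inherits(r, "rate_calibration")) r <- r$r
  2 * r * t_years
}

#' Origination rate of new genes within an age window
#'
#' Counts ages at or below `window_years` and expresses the rate per million
#' years, optionally with the ratio to a reference lineage's rate.
#'
#' @param ages numeric vector of ages in years (NAs dropped).
#' @param window_years age window in years (> 0).
#' @param reference_rate optional reference rate (genes per My) to take a
#'   ratio against.
#' @return One-row tibble: `n_within`, `window_my`, `rate_per_my`,
#'   `ratio_to_reference` (NA when no reference given).
#' @export
origination_rate <- function(ages, window_years, reference_rate = NULL) {
  if (window_years <= 0) stop("window_years must be positive", call. = FALSE)
  ages <- ages[!is.na(ages)]
  n <- sum(ages <= window_years)
  window_my <- window_years / 1e6
  rate <- n / window_my
  tibble(
    n_within = n, window_my = window_my, rate_per_my = rate,
    ratio_to_reference = if (is.null(reference_rate)) NA_real_ else rate / reference_rate
  )
}

#' Histogram of Ks values with an upper cutoff
#'
#' Bins Ks values over `[0, max_ks]`; values above `max_ks` (or NA) are
#' excluded and reported via the `n_excluded` attribute.
#'
#' @param ks_values numeric vector.
#' @param max_ks upper limit (values > max_ks excluded).
#' @param bin_width bin width (> 0).
#' @return Tibble of class `ks_histogram` with `bin_start`, `bin_end`,
#'   `count`; attributes `n_excluded`, `n_total`.
#' @export
ks_histogram <- function(ks_values, max_ks = 1.5, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  n_total <- length(ks_values)
  keep <- !is.na(ks_values) & ks_values >= 0 & ks_values <= max_ks
  x <- ks_values[keep]
  breaks <- seq(0, max_ks, by = bin_width)
  if (breaks[length(breaks)] < max_ks) breaks <- c(breaks, max_ks)
  # left-closed bins; the last bin also closed on the right
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  out <- tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = counts
  )
  attr(out, "n_excluded") <- n_total - length(x)
  attr(out, "n_total") <- n_total
  class(out) <- c("ks_histogram", class(out))
  out
}

#' @rdname ks_histogram
#' @param object a `ks_histogram`.
#' @param ... unused.
#' @method autoplot ks_histogram
#' @export
autoplot.ks_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = min(object$bin_end - object$bin_start) * 0.95,
                      fill = "steelblue") +
    ggplot2::labs(x = "Ks", y = "pairs") +
    ggplot2::theme_minimal()
}
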