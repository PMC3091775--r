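# Independent brute-force oracles used by the DERIVED-value tests. These are
# deliberately naive implementations (full dynamic programming, exhaustive
# enumeration) kept separate from the package's own code paths.

# affine-gap local alignment score (Smith-Waterman), gap of length L costs
# open + L * ext -- the same convention as Biostrings::pairwiseAlignment.
# Column-sweep formulation so the inner loop is vectorized over the pattern.
oracle_local_score <- function(pattern, subject, submat, open = 11, ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  keep <- s %in% colnames(submat)
  m <- length(p); n <- length(s)
  NEG <- -1e9
  Mprev <- rep(0, m + 1)
  Ixprev <- rep(NEG, m + 1)
  Iyprev <- rep(NEG, m + 1)
  best <- 0
  for (j in 1:n) {
    sc <- if (keep[j]) submat[p, s[j]] else rep(-4, m)
    diag_src <- pmax(Mprev[1:m], Ixprev[1:m], Iyprev[1:m])
    Mcur <- c(0, pmax(0, diag_src + sc))
    Iycur <- c(NEG, pmax(Mprev[2:(m + 1)] - open - ext,
                         Iyprev[2:(m + 1)] - ext))
    # Ix (gap consuming pattern) runs down the current column: sequential
    Ixcur <- rep(NEG, m + 1)
    for (i in 2:(m + 1)) {
      Ixcur[i] <- max(Mcur[i - 1] - open - ext, Ixcur[i - 1] - ext)
    }
    best <- max(best, max(Mcur))
    Mprev <- Mcur; Ixprev <- Ixcur; Iyprev <- Iycur
  }
  best
}

oracle_nt_submat <- function(match = 1, mismatch = -3) {
  nts <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(nts, nts))
  diag(m) <- match
  m
}

# exhaustive two-sided Fisher p: sum of hypergeometric probabilities of all
# tables with the observed margins that are no more probable than observed
# (relative tolerance for floating-point ties)
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + rel_tol)])
}

# exact two-sided Mann-Whitney p by complete enumeration of group labelings
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_stat <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_stat)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force best gap-free spliced alignment score with zero or one intron.
# Exact for alignments made of two codon-diagonal runs joined by one intron
# (length >= min_intron) between codons: A[e, r] = best run ending at dna
# position e with protein residue r; B[s, r] = best run starting at s with
# residue r; answer = max over donor/acceptor pairs of A + B + penalty.
oracle_single_intron_score <- function(protein, dna, min_intron, intron_open,
                                       donor_bonus, acceptor_bonus,
                                       stop_score = -8) {
  bl <- retroforge:::get_blosum62()
  code <- Biostrings::GENETIC_CODE
  p <- strsplit(protein, "")[[1]]
  m <- length(p)
  n <- nchar(dna)
  nm <- union(rownames(bl), c("*", "X"))
  bl2 <- matrix(-4, length(nm), length(nm), dimnames = list(nm, nm))
  bl2[rownames(bl), colnames(bl)] <- bl
  bl2[, "*"] <- stop_score
  aa_at <- function(s) { # codon starting at 1-based s
    aa <- unname(code[substr(dna, s, s + 2)])
    if (is.na(aa)) "X" else aa
  }
  NEG <- -1e9
  A <- matrix(NEG, n, m) # runs ending at dna pos e (codon = e-2..e)
  for (e in 3:n) {
    sc <- bl2[p, aa_at(e - 2)]
    A[e, 1] <- sc[1] # residue 1 can only start fresh
    if (m >= 2) {
      A[e, 2:m] <- if (e >= 6) {
        pmax(A[e - 3, 1:(m - 1)], 0) + sc[2:m] # continue or start fresh
      } else sc[2:m]
    }
  }
  B <- matrix(NEG, n, m) # runs starting at dna pos s (codon = s..s+2)
  for (s_pos in (n - 2):1) {
    sc <- bl2[p, aa_at(s_pos)]
    B[s_pos, m] <- sc[m]
    if (s_pos + 3 <= n - 2 && m >= 2) {
      B[s_pos, 1:(m - 1)] <- pmax(B[s_pos + 3, 2:m], 0) + sc[1:(m - 1)]
    } else if (m >= 2) {
      B[s_pos, 1:(m - 1)] <- sc[1:(m - 1)]
    }
  }
  best <- max(0, A[is.finite(A)]) # no-intron case
  donor <- vapply(1:n, function(k)
    if (k + 1 <= n && substr(dna, k, k + 1) == "GT") donor_bonus else 0,
    numeric(1))
  acceptor <- vapply(1:n, function(k)
    if (k - 1 >= 1 && substr(dna, k - 1, k) == "AG") acceptor_bonus else 0,
    numeric(1))
  if (m >= 2) {
    for (e in 3:(n - min_intron - 3)) {
      amax <- A[e, 1:(m - 1)]
      if (all(amax < 0)) next
      for (s_pos in (e + min_intron + 1):(n - 2)) {
        pen <- -intron_open + donor[e + 1] + acceptor[s_pos - 1]
        cand <- max(amax + B[s_pos, 2:m])
        if (cand + pen > best) best <- cand + pen
      }
    }
  }
  best
}
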