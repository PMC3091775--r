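---
title: "Methods: retrocopy discovery, chimera classification and Ka/Ks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrocopy discovery, chimera classification and Ka/Ks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroforge)
```

## The model

A retrocopy is the genomic reinsertion of a reverse-transcribed mRNA: a
single contiguous copy of the parent's spliced CDS, lacking the parent's
introns, possibly flanked by a poly(A) remnant and target-site
duplications. The discovery problem is therefore: find genomic loci with
strong protein-level similarity to an annotated multi-exon gene, at a
different location, in which at least one substantial parental intron is
demonstrably absent. Downstream questions — is the copy disabled
(pseudogene), has it recruited flanking coding sequence or UTRs (chimera),
is it transcribed, how old is it — each get a dedicated module.

## Discovery pipeline and its thresholds

`run_pipeline()` chains translated search → hit merging → candidate
filters → parent assignment → dual spliced alignment → duplicate demotion
→ disablement classification. The numeric rule set lives in
`pipeline_config()`:

* **merge gap, 40 bp** — translated-search hits from one protein on one
  strand merge when their genomic gap is strictly under 40 bp. Gaps this
  small cannot be real introns, so merged blocks represent one candidate
  locus; frameshifted copies surface as adjacent hits in different reading
  frames and are re-united here.
* **identity > 50%, coverage > 70%, ≥ 50 aa** — a merged candidate is kept
  only with majority amino-acid identity over most of the query protein.
  Coverage is measured against the protein (query) length, consistent with
  the companion "at least 50 amino acids" bound.
* **parent assignment** — the best-scoring protein among hits overlapping
  the candidate whose own annotated locus does *not* overlap it. If that
  best match is a single-coding-exon gene the candidate is rejected
  outright: intronless genes (e.g. olfactory receptors) cannot donate an
  intron-lost copy, and keeping the rule strict avoids chains of
  retro-derived "parents". The match must also cover ≥ 50% of the protein
  at ≥ 50% identity. Ties break deterministically (identity, then
  coverage, then lexicographic id).
* **intron-loss confirmation, 70 bp** — the parent protein is splice-aligned
  to its own locus (yielding every intron position and length) and to the
  candidate locus. The candidate is confirmed when some parental intron
  longer than 70 bp falls, in protein coordinates, strictly inside the
  candidate's aligned span and no intron occurs there in the candidate's
  structure. 70 bp exceeds both the merge gap (40 bp) — so a "lost intron"
  cannot be a merging artifact — and the size of spurious micro-introns.
  The rule is applied per intron: one qualifying lost intron confirms the
  call (the quoted confirmation sentence speaks of a single inter-exon
  distance).
* **duplicate demotion** — within a parent's call set, a call whose
  nucleotide identity to another call exceeds its identity to the parent's
  spliced CDS is flagged `primary = FALSE` (a copy of a copy); ties stay
  primary. Only same-parent pairs are compared: a retrocopy of a retrocopy
  necessarily matches the same parent.

## Alignment engines

Window-level pairwise alignment is `Biostrings::pairwiseAlignment`
(BLOSUM62, affine gaps open 11 / extend 1 for protein; match +1 /
mismatch −3, open 5 / extend 3 for nucleotide). What the package adds is
the search strategy and the spliced model:

* `translated_search()` scans all six reading frames. Genomes up to
  100 kb are scanned exhaustively (full local DP per frame — the regime in
  which the test suite checks exact score equality against a brute-force
  Smith–Waterman oracle). Larger genomes are scanned by exact amino-acid
  5-mer seeding: seed clusters (gap ≤ 150 aa) with at least 3 seeds become
  alignment windows, padded by 80 residues. A true homologous region of
  even 50 aa at the default 10% nucleotide divergence carries ~15 intact
  5-mers, so the 3-seed floor costs no sensitivity while suppressing the
  thousands of isolated random 5-mer matches a 2 Mb genome produces.
  Raising `min_score` never adds hits; percent identity is matches over
  aligned columns excluding gaps.
* `spliced_align()` is a three-state local dynamic program in compiled
  code: codon matches (BLOSUM62), codon-level gaps (12), an intron state
  with a fixed opening penalty (50) discounted by +5 for a GT donor and +5
  for an AG acceptor, a minimum intron length (40 bp), and frameshift
  moves (2- or 4-nt pseudo-codons, penalty 15) so alignments continue
  through the single-base indels of decayed copies. Intron penalties are
  deliberately stiff: a canonical intron costs a net 40, far below the
  ~5/residue gained across a true exon but above what chance 7–8 residue
  matches can pay, so random sequence does not chain spurious "exons".
  Structures scoring below the filtration score (default 35) are
  rejected. Introns are modelled between codons only (phase 0); the
  simulator plants phase-0 introns, and every downstream contract (intron
  positions, lengths, loss) is phase-agnostic. `calibrate_min_score()`
  estimates a translated-search threshold from shuffled decoys by a
  moment-fit Gumbel tail.
* `nucleotide_search()` / `map_ests()` place ESTs BLAT-style: one pooled
  exact 16-mer dictionary over all reads and both orientations, one scan,
  then windowed local alignment. Collinear blocks (non-overlapping in read
  coordinates, genomic gap ≤ 5 kb) are chained into spliced placements, so
  a junction-spanning EST of a chimeric transcript is one placement with
  two blocks — which is what the chimera-confirmation rule needs.
* `align_cds_pair()` does global codon-unit alignment (gaps only at codon
  boundaries) for clean CDS pairs; inside the pipeline, candidate loci are
  instead anchored on the parent CDS by a pattern-global alignment and
  projected codon-by-codon, which tolerates the frameshifts and stops of
  pseudogenes.

## Disablement classification

From the anchored alignment: an indel whose length is not divisible by 3,
strictly inside the CDS (not within the terminal codons), is a frameshift;
a projected in-frame stop codon upstream of the final aligned codon is a
premature stop. Either makes the call a pseudogene. Because the global
anchor re-synchronises the frame after an indel, a single planted deletion
yields exactly one frameshift record rather than a cascade of phantom
stops.

## Chimera rules

A transcript is a chimera candidate when its exons overlap a retrocopy
call, the retro-derived fraction of its spliced length is strictly below
0.80, and the transcript does not arise from the call's parental locus.
The 80% bound is read against the transcript's spliced length — this
guarantees at least 20% novel sequence — and the parental-locus exclusion
implements the requirement that the transcript overlap both the retrogene
and something that is not the parental gene. Classification is geometric,
in transcript coordinates: novel CDS strictly upstream of the retro
segment → `N_add`; downstream → `C_add`; both → `both_add`; no novel CDS
but retro-derived sequence inside the 5'UTR → `UTR_conversion`. Novel
segments shorter than 30 nt are ignored because call boundaries come from
local alignments and can jitter by a few codons; planted novel segments
are ≥ 75 nt, so the guard costs nothing. Mode is `fusion` when the
transcript shares exonic sequence with a different gene and `de_novo`
otherwise (recruited-UTR single-exon genes, or a retrocopy spanning the
full new CDS). A new splice site is flagged when the retro segment extends
at least 1 bp on each side of an internal exon boundary.

## EST evidence

`place_ests()` applies the disambiguation rules literally: per EST the
best placement is retained together with placements within 0.5 identity
points of it that also reach 96% identity; the EST is accepted only when
exactly one retained location remains and that placement exceeds 100 bp
aligned and 97% identity. All bounds are strict, so an EST aligned over
exactly 100 bp, or at exactly 97%, is rejected, and a second hit exactly
0.5 points below the best does not block uniqueness. Flanking activity
counts accepted placements in the 2–40 kb flanks on both sides; the 2 kb
exclusion is measured from the call's outermost coordinates. Group
comparisons delegate to `fisher_exact()`, `chi_square_2x2()` (Pearson, no
continuity correction — an option restores Yates) and `mann_whitney_u()`
(exact enumeration when `n1*n2 <= 400` and tie-free, otherwise the normal
approximation with tie correction), which are thin tidy wrappers over the
corresponding base-R tests; the test suite checks them against independent
hypergeometric and permutation enumerations.

## LPB Ka/Ks and the molecular clock

`count_sites()` classifies each codon position as 0-, 2- or 4-fold
degenerate under the standard code (3-fold Ile sites count as 2-fold),
taking the class from each sequence's own codon and averaging — the
LWL/LPB convention, which also handles the Arg/Leu first-position
irregularities. Differences are tallied per class as transitions or
transversions position-by-position (no multi-hit pathway weighting; at the
divergences this package targets the difference from pathway-averaged
variants is small, and the test suite cross-checks against an independent
LWL-family implementation at moderate divergence with a loose tolerance).
Per class, Kimura's two-parameter distances are
`A = ½ln(1/(1−2P−Q)) − ¼ln(1/(1−2Q))` and `B = ½ln(1/(1−2Q))`, and

```
Ks = (L2·A2 + L4·A4) / (L2 + L4) + B4
Ka = A0 + (L0·B0 + L2·B2) / (L0 + L2)
```

Saturation (`1−2P−Q ≤ 0` or `1−2Q ≤ 0`) raises an error rather than
returning NaN; the pipeline converts it to a missing Ks for that call.
Internal stops are an error unless explicitly dropped (`drop_stops`),
which the pipeline does for pseudogenes. The clock is the usual
`Ks = 2rT`: `calibrate_rate()` estimates `r` as the mean ortholog Ks over
`2T` (median by option; the mean is the default because the calibration
is a point estimate of a lineage average), `estimate_age()` inverts it,
and `origination_rate()` turns an age vector and window into genes per
million years plus a ratio to a reference lineage. A Ka/Ks of a call is
reported but no per-gene significance against a 0.5 bound is claimed —
the underlying test is not specified well enough to reproduce, so the
package reports counts below 0.5 and leaves inference to the user.

## The synthetic genome

`generate_genome()` builds a single contig from i.i.d. uniform background
(no compositional claims are tested, so simplicity wins) carrying:

* parent genes — 3–7 exons of 30–80 codons, introns 75–400 bp with
  canonical GT-AG ends (all introns exceed the 70 bp confirmation bound by
  construction), an in-frame ATG…stop CDS, half on the minus strand;
* planted retrocopies — intron-less copies of a parent CDS substituted at
  `retro_divergence` under K2P (ts/tv 2.0), with substitutions that would
  create internal in-frame stops reverted so intact copies keep an open
  frame; poly(A) 15–30 bp and target-site duplications 5–15 bp (the
  hallmark features are described qualitatively in the literature without
  canonical lengths; these ranges are typical of recent insertions);
  pseudogene copies get a planted 1–2 bp frameshift or an in-frame stop
  before 80% of the CDS; about a third insert into a host gene's intron
  (never an exon, keeping the host intact);
* chimera complexes — partner genes share an exon with the chimeric
  transcript (N/C/both layouts; the `both` layout plants the retro inside
  the partner's intron), and the UTR-conversion layout recruits novel
  5'/3' UTRs around a retro whose 5' part is annotated as UTR; every
  second N/C chimera declares its exon boundary inside the retro segment
  to plant a new splice site;
* single-exon decoy genes plus a planted decoy copy — negative controls
  that the parent-assignment rule must reject;
* EST/mRNA sets — per transcribed sequence, Poisson counts of ≥ 100 bp
  substrings with per-base substitution errors, random orientation.

The generator's defaults are the package's standard recovery experiment —
2 Mb, 60 parents, 20/12/8 planted intact/pseudogene/chimeric copies at 10%
divergence — which the acceptance script runs end to end. Divergence is
realized as an exact fraction of substituted sites, so the planted
identity matches `1 − divergence` up to the stop-reversion correction.
`make_ortholog_pairs()` plants synonymous divergence only: codons with
irregular degeneracy are avoided, transitions are applied at 2- and 4-fold
third positions and transversions at 4-fold sites, with per-site
probabilities obtained by inverting the K2P distance so the expected
estimated Ks equals `2rT`. Its domain is bounded at 2rT < 0.75 by default
(`saturation_bound` lifts it for recovery experiments at higher true Ks,
where the inversion is still defined).

Everything is deterministic given the seed: identical configurations give
byte-identical FASTA/GFF3/truth output.

### What the simulation does not emulate

Real genomes have repeat landscapes, paralogous gene families, biased
composition, alternative transcripts, non-phase-0 introns and sequencing
chimeras; the simulator has none of these. Passing the recovery suite
therefore demonstrates that the rule set is implemented faithfully and
recovers planted truth under the stated conditions — not that the
thresholds are optimal for a real genome, where paralogy and repeats are
the dominant error sources.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open everywhere inside the package and become
1-based inclusive only in GFF3. Empty alignments return zero counts;
zero-margin contingency tables return p = 1 (Fisher) or an error
(chi-square, whose expected counts are undefined); saturated Ks values are
excluded from calibration with a warning. A stage failure on one candidate
drops only that candidate, with the reason logged in the result's
`dropped` table. Problem sizes in the tests are chosen to keep the default
suite fast: the oracle-equality checks run in the exhaustive regime
(≤ 300 bp genomes for acceptance, up to 3 kb in module tests), the shared
fixture is a 150 kb genome with 9 plantings, and the full-scale run is the
2 Mb default, executed once.

## Known limitations

* The spliced aligner models phase-0 introns and a fixed intron cost; it
  is a functional stand-in for an HMM gene-structure aligner, not a
  re-implementation of one.
* Retrocopies of retrocopies are demoted, not re-parented; primaries only.
* LPB difference counting is per-position; at high divergence (Ks well
  above 1) pathway-averaged estimators diverge from it and saturation
  errors become common.
* EST placement assumes substitution-only errors; indel-rich reads would
  fragment placements.
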