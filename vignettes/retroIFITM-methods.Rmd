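---
title: "Methods: retrogene hallmark detection and IFITM family classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrogene hallmark detection and IFITM family classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroIFITM)
```

## The biological model

Primate genomes carry the IFITM family in two arrangements. The
*canonical cluster* sits on one chromosome between conserved anchor genes
(*PGGHG*, *B4GALNT4*, *CTSD*) and contains the single-copy *IFITM5* and
*IFITM10* plus a variable set of immunity-related (IR-)IFITMs. Additional
IFITM copies are *retro(pseudo)genes*: when a LINE-1 reverse transcriptase
binds a polyadenylated IFITM mRNA, target-site primed reverse
transcription (TPRT) integrates a spliced, intronless cDNA at a new
genomic position, duplicating the target-site k-mer on both flanks and
retaining the transcript's poly-A signal (`AATAAA`) and a genomically
encoded poly-A tail. These scars decay with time, so a crisp hallmark set
marks a recent copy; premature stop codons mark the transition from
retrogene to retropseudogene. This package turns those observations into
deterministic, parameterized detectors, with a simulator that embodies
the same generative model so every detector can be validated against
known truth.

## Coordinate and orientation conventions

Internally all loci are 0-based, half-open; files on disk (loci tables,
reports) are 1-based inclusive, matching genome-browser convention.
`extract_window()` is strand-normalizing: on the minus strand all three
window parts are reverse-complemented and swapped, so "upstream" always
means 5′ of the coding sequence and every downstream offset (signal,
tail, TSD) reads in coding orientation regardless of the genomic strand.

## The hallmark detectors and their parameters

**Poly-A signal.** First exact `AATAAA` in the ≤ 400 bp downstream
window (0-based offset). The `ATTAAA` variant is accepted only behind an
explicit flag, since the canonical hexamer is the diagnostic motif.

**Poly-A tail start** (`min_run = 12`, `purity = 0.8`,
`max_gap_to_signal = 50`). The tail start is the first position `p`
carrying an A whose following `min_run` bases are at least `purity` A,
within `max_gap_to_signal` bases of the signal end (anywhere in the
window when no signal was found). The run length of 12 reflects the
substantial poly-A stretch the L1 machinery requires; it is long enough
that random genomic windows rarely qualify (which keeps downstream TSD
calls specific), yet with 80% purity a 10-bp tail flanked by its TSD
still qualifies and a point-mutated tail is tolerated.

**Target-site duplications** (`min_len = 6`, `max_len = 25`,
`max_mismatch_per_10bp = 1`, `search_after_tail = 10`,
`upstream_search = 120`). The detector mirrors TPRT geometry rather than
performing an unconstrained repeat search: the downstream copy must begin
within `search_after_tail` bases of the end of the poly-A run (the TSD is
directly adjacent to the tail; the slack absorbs tail-end estimation
error on mutated copies), and the upstream copy must end within
`upstream_search` bases of the canonical start codon, bounding the
plausible 5′ UTR length. Candidate repeats must match at both ends, and
the mismatch allowance is one per *complete* 10 bp — a 6-mer with a free
mismatch is statistically indistinguishable from background in a
200 × 400 bp window, so short repeats must be exact. Ranking is
tail-adjacency first, then fewest mismatches, then length, then
proximity of the upstream copy to the insertion junction. The poly-A run
end is computed robustly: isolated non-A bases inside the tail are
skipped while the next 8 bases remain A-dominated, so a point mutation
does not truncate the run, while the scan still stops exactly where the
TSD begins. These constraints are what make the detector's operating
point achievable at all: an unconstrained longest-first search over the
full window would call a "TSD" on essentially every window, true or not,
because exact random 6-mers occur with near certainty in that much
sequence. All thresholds are exposed as arguments and recorded in run
manifests.

**Intron loss.** The spliced parent mRNA is fitted into the window
(global in the mRNA, local in the window) and every annotated exon–exon
junction inspected: "yes" needs ≥ 20 aligned bases with ≤ 2 gaps around
each junction, a ≥ 50 bp genomic insertion within ±10 bp of a junction
gives "no", and poor coverage gives "unknown" (mirroring the one
ambiguous case a manual analysis cannot adjudicate either). The fit uses
a mild gap extension (−0.5) deliberately: with ordinary extension
penalties a several-hundred-bp intron scores better "mismatched through"
than as one long gap, and the junction signal — which is the gap
structure, not the substitution score — would be destroyed.

**CDS integrity.** Frame-0 translation from the canonical ATG; the first
stop before codon `expected_aa_len + 1` (parent CDS length when a parent
is assigned, the copy's own final codon otherwise) is premature;
`full_cds` requires no premature stop and a terminal stop codon.

**Verdict.** With at least 3 of the 4 structural hallmarks (intron loss,
signal, tail, TSD): *retrogene* if the CDS is complete, otherwise
*retropseudogene*; fewer hallmarks give *indeterminate* — a locus is
never called a retropseudogene merely for having a broken frame.

**Parent assignment.** The whole window is fitted against each candidate
mRNA; identity over the CDS-aligned region picks the parent (ties
broken lexicographically; margin = distance to the runner-up). UTR
identities are reported when ≥ 30 bases align, and ≥ 95% in both UTRs
sets the recency flag, since UTRs decay fastest after insertion.

## Chimera scanning

For query *q* and parents *A*, *B*, per-position match profiles (projected
onto ungapped query coordinates through global alignment) give
`M(b) = matches(A on [0,b)) + matches(B on [b,L))`, maximized over `b`
and over both parent orders; `score_gain` is the improvement over the
best single parent and must reach `min_gain = 5` matches. Within a run
of columns where the parents agree the breakpoint is unidentifiable, so
the reported breakpoint is the **midpoint of the maximizing plateau**:
the leftmost maximizer would be biased left by half the typical
informative-column spacing, which at realistic parent divergence is
several residues. `X` (the frameshift marker in translated queries)
never counts as a match. Breakpoint resolution is set by the informative
column density: with parents that each diverged ~15% from their common
ancestor the inferred breakpoint is usually within a few columns of
truth, while at 15% *pairwise* divergence the uninformative plateaus are
wide enough that no estimator can do much better than ±7 columns — a
fundamental identifiability limit, not an implementation one.

## Group profiles and conservation

Group profiles are PWMs (additive pseudocount 0.5) over user-designated
N- and C-terminal column blocks of a member alignment — the CD225 core
is nearly invariant across groups and deliberately excluded — plus
ungapped member length ranges per block, since the groups differ in
terminal length as well as sequence. Classification aligns a query to
each profile consensus, sums log PWM probabilities over the block
columns (gaps and unknown residues score at the pseudocount floor), and
flags length compatibility separately. Ties break by lexicographic group
label and are flagged ambiguous. A column is "fully conserved" only if
gap-free and identical in every row (the strictest reading); logo
probabilities exclude gaps from the denominator, and information content
`log2(A) + Σ p log2 p` carries no small-sample correction.

## Distance trees and bootstrap

Column filtering keeps sites with ≥ 95% unambiguous residues (ambiguity
characters count as gaps; the comparison is `>=`). Distances use
pairwise deletion with p, Poisson (`−ln(1−p)`, protein) or JC69
(`−3/4 ln(1−4p/3)`, DNA) corrections; saturated pairs are capped
(default 5) and flagged rather than erroring, so a single diverged pair
cannot abort a run. Neighbor joining is delegated to `ape::nj`
(negative branch estimates clamped to 0 and flagged); bootstrap
resamples filtered columns with replacement under a caller-supplied
seed, and supports are the percentage of replicates containing each
reference bipartition, stored as integer node labels. Likelihood tree
search and Γ rate heterogeneity are intentionally out of scope: the
distance/NJ/bootstrap machinery here is the reproducible surrogate, and
ML software can consume the same filtered alignments externally.

## What the simulator emulates — and what it does not

`simulate_retrogenome()` embodies the generative hypothesis the
detectors target: a cluster contig (anchors, IFITM5/10, and IR-family
genes that are true paralogs at `paralog_divergence = 0.05`, with
preserved reading frames and poly-A signals), plus a background contig
receiving TPRT-style insertions — spliced mRNA + tail (10–50 bp),
duplicated target k-mer (6–20 bp), optional 5′ truncation, planted
nonsense codons, and per-site copy mutations. Retro-insertions land on a
separate contig because that is where real retrogenes land (other
chromosomes); on a single short contig the canonical/scattered
distinction would be vacuous at any realistic anchor distance.

Two classes of generative constraints keep ground truth well-defined.
The signal-to-tail spacer carries no A, so "the tail start" is a single
position; and insertion sites are resampled until the planted TSD is
unambiguous — it must not start with A (it would fuse with the tail),
the 8 following bases must not be A-dominated (the tail scan must stop
at it), the k-mer must be unique in the upstream window, and chance
single-base extensions on either side are excluded. These are checked by
direct string inspection, never by running the detectors. Without them,
"exact TSD recovery" is an ill-posed target: a random window of this
size contains competing short repeats with non-negligible probability.

Deliberate simplifications: copy mutations hit the inserted mRNA and
tail but not the TSD copies; insertions never nest; integration sites
are uniform (no L1 `TTAAAA` nick preference); evolution along trees is
substitution-only (no indels), with per-branch event counts Poisson in
rate × length × sites, which for DNA is exactly the JC69 chain. Passing
tests therefore demonstrate correctness of the detectors under the TPRT
model, not robustness to assembly gaps, nested repeats, segmental
duplications or A-rich isochores in real genomes.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the scales the methods
are meant for: 200 simulated insertions on a 2 Mb background for
hallmark recovery (exact at mutation rate 0; overlap-based TSD recall at
1%), 100 shuffled-flank negative windows, 100 chimera replicates
(breakpoints uniform in [30, 100] of 130-residue proteins), 50
eight-taxon trees with 2 kb alignments for topology recovery, 200
bootstrap replicates for seed-exactness, and 300 held-out draws across
six simulated groups for classification. Alignment scores are exact
integers (or halves, with the −0.5 extension) and compared exactly; PWM
column sums and logo probabilities are checked to 1e-9; Newick
round-trips preserve branch lengths to 1e-9. Exhaustive-enumeration
oracles back the aligner (all monotone alignments for sequences ≤ 6 nt)
and the breakpoint sums (all columns, both orientations); plain column
scans back the conservation and coverage filters.

## Known limitations

Intron-loss calls need an annotated, correct parent exon structure; a
wrong parent gives "unknown" more often than a wrong answer, but the
call is only as good as the annotation. The TSD detector's upstream
bound (120 bp) assumes 5′ UTRs of at most that length — unusually long
UTRs require widening `upstream_search`, at a cost in specificity.
Terminal-block columns for group profiles are user-supplied; the package
does not infer domain boundaries. Single-IR-member species are flagged,
not adjudicated: a lone cluster member may reflect an assembly gap
rather than biology.
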