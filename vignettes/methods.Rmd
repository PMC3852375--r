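---
title: "Dating X/Y degeneration with strataclock: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating X/Y degeneration with strataclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataclock)
```

## The problem

When recombination between a young X and Y chromosome stops, the two
copies of every region in the non-recombining block begin to diverge
like a duplicated locus. Three clocks can be read off a pair of X- and
Y-derived sequences:

1. **The recombination-stop time.** Synonymous sites of an X/Y gene
   pair accumulate substitutions neutrally, so the synonymous
   divergence `Ks` dates the stop: `T = Ks / (2r)`, the factor 2
   because both lineages accumulate changes at rate `r`.
2. **Retroelement insertion times.** An LTR retrotransposon inserts
   with two *identical* long terminal repeats; their subsequent
   divergence `k` dates the insertion by the same formula.
3. **Noncoding block divergence.** Homologous noncoding blocks that
   survive between the X and Y carry a TN93 divergence that should be
   consistent with the gene-pair stop time if they stopped recombining
   together.

`strataclock` implements the detection steps (self-homology search for
direct repeats, reciprocal search for X-Y blocks), the distance
estimators (TN93, Nei-Gojobori), the clock conversion, a two-point
Kosambi linkage mapper for placing X-linked markers, and — centrally
for validation — a generative simulator of the whole assumed process.

## Models and estimators

**TN93 distance.** For a gap- and ambiguity-free pair of aligned
sequences (pairwise deletion), the closed-form Tamura-Nei (1993)
estimator is computed from the proportions of purine transitions
(`A<->G`), pyrimidine transitions (`C<->T`), and transversions, with
base frequencies pooled over both sequences. When the two transition
classes are equal and composition is uniform the estimate coincides
with the Kimura two-parameter form, a property the test suite checks
exactly; the implementation is also cross-checked against
`ape::dist.dna(model = "TN93")`. Saturation (a non-positive logarithm
argument) is an error, not an `NA`, so downstream dating cannot
silently use an undefined distance.

**Synonymous/nonsynonymous distances.** "Synonymous divergence" here
is Nei-Gojobori (1986) pathway counting: fractional synonymous site
counts per codon position, differences averaged over all
minimal-change pathways between two codons, and a Jukes-Cantor
correction `d = -(3/4) log(1 - 4p/3)`. Two conventions deserve note,
both configurable nowhere because they define the method as
implemented: mutations to stop codons are excluded from pathways *and*
from site denominators (a position with one viable alternative that is
synonymous counts as a full synonymous site), and codon columns
containing gaps or `N` are deleted codon-wise. The method is the
reproducible baseline among the family of counting estimators; where a
report needs to flag the choice, the `method` field of every
`distance_estimate` records it.

**Standard errors.** SEs are column (or codon-column) bootstrap, 1000
replicates by default, seeded for exact reproducibility. Replicates
that hit saturation are dropped; more than 5% failures is an error.
The bootstrap is validated against the analytic Jukes-Cantor SE
`sqrt(p(1-p)/n) / (1 - 4p/3)` on simulated pairs.

**Dating.** `T = k / (2r)` with `r = 1.8e-8` substitutions per
(synonymous) site per year by default — the Brassicaceae-derived rate
conventionally applied to *Silene*. SEs propagate linearly
(`se_T = se_k / 2r`). Reports round ages to two significant figures
(the field's convention for MYA tables) but always carry the
full-precision value alongside; rounding `k` first and converting
afterwards does not generally round-trip, which is why both are kept.

## Detection steps and their numerical choices

**Global alignment** is an affine-gap Needleman-Wunsch with a gap of
length `L` costing `gap_open + (L-1) * gap_extend`; defaults are the
EMBOSS-Needle-style configuration (match +5 / mismatch -4, gap 30,
extension 0, end gaps free). With free end gaps the optimum may be a
*staggered* overlap in which the leading gap run sits in one sequence
and the trailing run in the other; this is the standard ends-free
semantics and is what the brute-force enumeration oracle in the test
suite produces. Traceback prefers diagonal over gap-in-`b` over
gap-in-`a` on ties, making output deterministic. The DP is quadratic
in memory and refuses pairs beyond ~30 million cells; the pipeline
only aligns LTR pairs and homology blocks (a few kb), never whole
regions.

**Local search** is a seed-and-extend scan: exact 11-mer seeds,
ungapped X-drop extension (X = 20), scores +2/-3, and E-values
`E = K m n exp(-lambda S)` from Karlin-Altschul statistics. `lambda`
solves `sum p_i p_j exp(lambda s_ij) = 1` by bisection; `K` uses the
lattice series approximation, which reproduces the published ungapped
BLASTN constants (for +2/-3: lambda 0.634, K 0.41) to three figures.
These are ungapped statistics used as approximations for thresholding;
the thresholds in this workflow (1e-10 for self-hits, 1e-50 for X-Y
blocks) are coarse filters with orders of magnitude of headroom, so
the approximation is immaterial to which hits survive.

**Repeat classification.** Self-hits (off-diagonal, deduplicated) are
classified simple repeats (overlapping intervals or an autocorrelation
period of at most 10 bp at 80% agreement), LTR candidates (direct,
ordered, non-overlapping, at least 100 bp), or other repeats. Because
the score-maximum trim of an X-drop extension can over- or undershoot
a repeat boundary by chance runs, direct self-hits are re-trimmed at
the maximum of a cumulative log-likelihood ratio (match
`log((1-p)/q)`, mismatch `log(p/(1-q))`, `p` the hit's divergence,
`q` the background match probability) — the maximum-likelihood
changepoint for the boundary. Boundary errors beyond ~5 bp then
require genuine mismatch clusters at the boundary, which no estimator
can resolve.

**Element calling.** LTR candidates become elements under inferred
structural constraints: minimum LTR length 100 bp, minimum LTR-LTR
identity 0.85, maximum span 30 kb, left/right length ratio within
[0.8, 1.25]. Published element tables show LTRs of 169-1670 bp,
identities 93-99% and spans up to ~21.6 kb, so these defaults are
permissive relative to the regime of interest; all are arguments.
Overlapping candidate pairings that are not proper nestings are
resolved greedily by descending identity, then descending LTR length;
losers are retained in an `unresolved` attribute rather than dropped
silently. Nesting is containment of one element's span in another's
internal region — reported element *spans* therefore include nested
inserts, while published "length" columns for nested hosts subtract
them; report tables carry the span and leave net lengths to the
reader, since net length is not well defined once elements overlap
arbitrary other insertions.

**X-Y homologous blocks.** Ungapped HSPs fragment wherever an indel
falls, and homologous noncoding blocks are riddled with small indels,
so collinear HSPs on nearby diagonals (junction gaps up to 200 bp on
both sequences) are chained into gapped blocks — the desk-scale
analogue of a gapped BLASTN hit. The chain score is the sum of member
scores minus affine junction penalties, the E-value follows from that
score, identity counts matches over the gapped block length, and the
three thresholds (500 bp, 1e-50, 80%) apply to the chained block. The
block's TN93 divergence uses the concatenated ungapped member columns,
which is exactly the column set pairwise deletion would retain from
the gapped alignment.

**Coverage** is reported two ways: the plain sum of per-side block
lengths (overlapping blocks counted twice) and the merged union
(counted once). The summed statistic is primary because published
coverage figures follow that convention — with the published block
tables, only the summed lengths reproduce the quoted X and Y coverage
percentages, the Y side containing one overlapping pair whose union
is ~8.9% rather than 10.6%.

**Linkage.** Testcross coding (presence/absence of the male-parent
allele) with pairwise-deleted missing data, exhaustive order search up
to 8 markers minimizing summed adjacent Kosambi distances
(`cM = 25 log((1+2rf)/(1-2rf))`), canonicalized by endpoint name.
Only marker order is generally testable on real data of this design;
distances are validated on simulated testcrosses.

## The simulator: what it emulates and what it does not

`simulate_xy_pair()` generates an ancestral region (default 100 kb,
composition 30/20/20/30 — the AT-rich noncoding composition typical of
the system), duplicates it at `t_stop` (default 3.4 MY), and evolves
each lineage independently to the present:

* **Substitutions** via exact TN93 transition matrices
  `P(t) = exp(Qt)` per inter-event epoch (no generation
  discretization), rate `r = 1.8e-8`/site/yr, transition/transversion
  multipliers `kappa1 = kappa2 = 2` (a typical plant nuclear bias;
  the source workflow does not pin one down).
* **Element insertions** at scheduled times (default six, split
  between lineages, ages 0.083-1.6 MY — the published insertion-age
  range): two identical LTR copies flanking an internal region, all
  drawn from the background composition, inserted as a block and then
  evolving with the rest of the lineage. Nesting arises naturally when
  an insertion point falls inside an earlier element's internal
  region.
* **Indels** as a Poisson process (default 2e-9 events/site/yr, about
  a tenth of the substitution rate, a realistic plant noncoding
  figure) with geometric lengths (mean 5 bp). Indels are rejected
  inside LTR copies, so planted boundary-recovery problems stay
  well-posed; this is the one deliberate departure from uniformity and
  is configurable.
* **Ground truth**: every element's intervals in final coordinates,
  every indel, and an ancestral-to-final coordinate lift per lineage,
  emitted as GFF3 + JSON next to the FASTA.

`simulate_coding_pair()` evolves a stop-free codon sequence along both
lineages with every single-nucleotide change at a position with `v`
viable (non-stop) alternatives occurring at rate `r/v` (times `omega`
if nonsynonymous). This makes "rate `r` per synonymous site" mean
precisely what the Nei-Gojobori estimator measures — the site
denominators of process and estimator coincide — so `E[Ks] = 2 r
t_stop` and the headline recovery (`Ks ~ 0.12`, `T ~ 3.4` MY at the
reference conditions) is an estimator check, not a calibration.

Features of real data deliberately *not* modeled: selection,
within-lineage recombination and gene conversion (which the source
analysis raises as a possible depressor of coding divergence —
simulating it would require guessing a magnitude the data do not
give), solo-LTR formation by intra-element recombination, target-site
duplications, population-level coalescent variance, and the deep
repeat landscape that makes real noncoding homology decay much faster
than substitutions and simple indels alone would predict. Passing
recovery tests therefore demonstrate that the estimators invert the
assumed process correctly — not that the assumed process is a complete
account of *Silene* sex-chromosome evolution.

## Problem sizes used in the validation suite

Parameter-recovery tests run at sizes chosen to make Monte-Carlo error
small relative to the effects tested while keeping the suite quick to
run as a routine check: 100 replicate coding pairs of 500 codons for
the Ks/stop-time recovery; 100 replicate 10-kb regions with two
planted elements each (LTR 300 bp, internal 2 kb, ages uniform on
0.1-1.6 MY) for boundary and age recovery; 100 replicate 10-kb
neutral evolutions for the substitution-process closed form; 100
simulated testcrosses of 500 progeny for marker-order recovery. The
acceptance script (`scripts/acceptance.R`) re-runs the coding
recovery from scratch at exactly these conditions.

## Known limitations

* Local-search E-values are ungapped approximations applied to (for
  chained blocks) gapped scores; they are filters, not p-values.
* The global aligner's quadratic memory bounds it to a few kb per
  pair; intron and LTR alignments fit comfortably, whole BACs do not
  (and are never aligned globally by the pipeline).
* Boundary recovery degrades gracefully with element age: beyond ~2 MY
  of LTR divergence the changepoint ambiguity grows with `p`.
* The simulator's indel process never splits LTRs by default; real
  elements lose LTR ends. Detection sensitivity to truncated elements
  is untested by design.
* `syn_nonsyn_distance` implements equal-weight pathway counting; the
  transition/transversion-weighted ("modified") variants would give
  slightly different `Ks` on strongly biased data.
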