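---
title: "Error-correction alignment of spectrum and proteoform mass graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-correction alignment of spectrum and proteoform mass graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgalign)
```

## The model and its assumptions

A protein with variable modifications is encoded as a *proteoform mass graph*
(PMG): bond nodes $x_0,\dots,x_n$ where each position carries a black edge
with the unmodified residue mass and a parallel red edge per applicable
modification rule, all as scaled integers $\lfloor m \cdot 274.335215\rfloor$
(one unit $\approx$ 3.65 mDa; the scale maps residue masses close to
integers). A deconvoluted spectrum is a *spectrum mass graph* (SMG): nodes
$y_0,\dots,y_m$ at the discretized prefix masses, $y_0 = 0$.

An *error-correction alignment* is a sequence of triples $(x_{j_q}, y_{i_q},
k_{i_q})$ with strictly increasing node and peak indices such that

$$ (m_{i_q} + k_{i_q}) - (m_{i_{q-1}} + k_{i_{q-1}}) \in d(j_{q-1}, j_q), $$

where $d(s,j)$ is the set of distinct sub-path masses between $x_s$ and
$x_j$ and $k_i \in [-\delta_i^-, +\delta_i^+]$ is an integer correction
bounded by the peak's tolerance. Because the constraint binds *corrected*
masses exactly, the observed error between **any** pair of matched peaks is
at most $|k_i| + |k_j| \le 2\delta_{\max}$ — the property that distinguishes
this model from local edge-tolerance alignment, where same-signed errors
accumulate linearly with alignment length. The dynamic program maximizes the
number of triples over table cells $T(i, j, k)$; both endpoints are free, so
the reported optimum is the maximum over all cells (a single matched triple
scores 1).

Assumptions worth stating: peaks are already deconvoluted, charge-reduced
prefix masses (no isotope envelopes, no fixed modifications); the precursor
mass in the spectrum header is already adjusted so that complementary peaks
are `precursor − m`; and modifications are *variable* (red edges never
replace black ones).

## Tolerances, pruning and overlap deletion

Two tolerance models are provided. The fixed model assigns $\delta_i = 27$
scaled units ($\approx 0.1$ Da) to every peak. The peak-dependent model adds
a ppm term, $\delta_i = 27 + \mathrm{round}(\mathrm{ppm}\cdot m_i/10^6)$
with ppm = 15 by default; a complementary peak inherits the uncertainty of
the precursor as well, $\delta_i = 27 + \mathrm{round}(\mathrm{ppm}\cdot(m_i
+ M)/10^6)$. The ppm coefficient is a parameter because the constant is the
conventional second component of mass tolerances; satellite peaks
($m \pm 1.00235$ Da, generated for peaks above 5000 Da to absorb one-Dalton
deconvolution errors) inherit the tolerance class of the peak that spawned
them, since they are surrogates for the same measurement.

Each peak's candidate corrected positions form the interval $[m_i -
\delta_i^-, m_i + \delta_i^+]$. Preprocessing enforces three things:

1. **Domain clipping.** Corrected masses must be positive; lower bounds are
   clipped so position 0 belongs to $y_0$ alone ($y_0$'s correction is
   pinned to zero — its mass is exact by construction).
2. **Dominated-peak pruning.** A peak whose interval is contained in a
   neighbour's offers nothing the neighbour does not; containment of
   consecutive peaks is iterated to a fixpoint (which subsumes chains), and
   mutual containment (identical intervals) keeps the later peak — a
   deterministic tie-break.
3. **Overlap deletion.** Remaining consecutive overlaps are split at the
   midpoint $\lfloor (m_i + m_{i+1})/2 \rfloor$ (overlapped integers go to
   the nearer peak, ties to the earlier one), shrinking $\delta_i^+$ and
   $\delta_{i+1}^-$ so the union of covered integer positions is preserved
   exactly, each position once. Any split rule preserving the union yields
   the same optimum: when the smallest (modified or unmodified) residue edge
   mass exceeds $4\delta_{\max}$, a corrected position reachable through one
   peak of an overlapping pair is reachable through the other with the same
   table value. The aligner *checks* this precondition on the raw tolerances
   and refuses to run when it fails (with the standard residue table and
   $\delta = 27$: $15642 > 108$, so it always holds in practice; a
   deliberately absurd $\delta_{\max} = 5000$ trips the gate).

After deletion the per-peak ranges are pairwise disjoint, so the DP core
(C++, via Rcpp — the same place this field's packages put their alignment
kernels) indexes cells by (node, corrected position) and examines each
candidate position exactly once; transitions for a fixed (node, sub-path
mass) pair reduce to a single two-pointer sweep over the sorted position
array. One caveat of the per-pair width test used in the test-suite: an
overlap always shrinks the widths of the two peaks involved, but the global
$q = \max_i(\delta_i^- + \delta_i^+)$ only shrinks if *every* maximal-width
peak was involved in an overlap.

## Alignment modes and tie-breaking

*Global* mode leaves both endpoints free, which also covers peptide-level
(local) searches: a peptide's $y_0$ may match any interior node, so the
free-endpoint optimum *is* the best local alignment. *Diagonal* mode takes a
start node/peak pair (in practice supplied by an upstream candidate filter,
which is out of scope here) and extends forward only, keeping every matched
pair within a band around the unmodified-residue diagonal:
$|(m_i - m_{i_0}) - (B_j - B_{j_0})| \le \mathrm{band}$ with $B$ the
black-edge prefix mass. The default band, $2\delta_{\max}$ plus the largest
single-edge mass, cannot cut an optimal modification-free stretch.

Sub-path enumeration is capped at 10 residues per alignment step and 2
modified residues per step (both configurable); the caps bound the universe
size $L$ that drives the running time, and alignment steps longer than 10
residues carry little evidence anyway. Equal-scoring optima are resolved
toward the lexicographically smallest (peak, node, k) — determinism for
testing; the choice carries no scientific meaning. Transitions require
strictly increasing node indices, consistent with sub-paths needing
$s < j$.

## Numerical choices and degenerate inputs

All arithmetic is on scaled integers (stored in doubles in R, `int` in the
C++ core; a range check guards the conversion). Duplicate scaled masses
merge into one SMG node, keeping the earliest provenance
(original < complementary < satellite). An empty spectrum leaves only
$y_0$ and yields score 1; a zero tolerance demands exact matches.
`verify_alignment()` re-checks every emitted alignment against first
principles (monotone indices, corrections in range, every consecutive
corrected difference a member of the recomputed $d(s,j)$) and names the
first violated step.

Two independent oracles guard the core on small instances: an exhaustive
recursive enumerator over full symmetric ranges (`brute_force_align`,
guarded to $n, m \le 10$) and a pure-R full-range DP without overlap
deletion (`dp_score_full_ranges`). The test suite checks both against the
reduced-range C++ path on hundreds of seeded random instances, which is the
operational content of the overlap-deletion soundness claim.

## What the simulator emulates — and what it does not

`simulate_spectrum()` generates data in the representation the aligner
consumes: scaled prefix masses of a modified proteoform. It chooses
modification sites without replacement, keeps a coverage fraction (default
0.8) of the internal prefixes, perturbs each kept peak by a uniform integer
error in $[-\varepsilon, +\varepsilon]$ (default $\varepsilon = 27$, equal
to the default alignment tolerance so instances are recoverable), reports
each fragment from the N or C terminus (default half each; C-terminal
fragments are written as precursor − prefix so complementary-peak
preprocessing reconstructs prefix coordinates), adds uniform noise peaks
(default 5), and always emits the whole-proteoform mass, since the precursor
is always known in top-down MS.

Peaks are written mid-bin — a peak with true scaled prefix $P$ and error $k$
is stored in Da as $(P + k + 0.5)/274.335215$ — so discretization recovers
$P + k$ exactly and the recorded ground truth is exact. Real deconvoluted
masses are *not* mid-bin: a continuous mass accumulates floor-rounding drift
of up to one unit per residue against the PMG's per-residue floors, which
the tolerance absorbs over short spans but which the simulator deliberately
does not emulate. The simulator also models no fragment-ion physics: no
charge states, ion types, intensities, or isotope errors beyond the
±1.00235 Da satellite mechanism. Passing recovery benchmarks therefore
demonstrates the alignment machinery, not robustness to instrument
artefacts.

The bundled rule sets are community-standard UNIMOD masses: Oxidation (M),
Deamidation (N/Q), Phosphorylation (S/T/Y) and Carbamidomethylation (C) as
shifts, and the K→C / T→A / V→G sequence variants as replacements.

## Study conditions and problem sizes

The packaged benchmarks run at desk scale, chosen once: a 50-protein
database of random 30–60-mers; 20 whole-protein spectra with five
modifications each; 20 peptide spectra with three modifications and lengths
drawn from $[23, \min(154, \text{protein length})]$ (all within 23–154);
coverage 0.8, $\varepsilon = 27$, five noise peaks. Ranking is by alignment
size, ties by smaller AME, then database order. Under these conditions the
true protein is top-ranked in 100% of both searches and the worst observed
MME over 50 pairs is 54 — exactly the $2\delta$ bound (coverage and noise
levels of the peak lists are exercised parameters, not measured facts, and
are stated here so they can be varied).

## Known limitations

* The DP table is dense over (nodes × candidate positions); very long
  proteins with peak-dependent tolerances are memory-hungry (the same
  scaling the complexity bound $O(nmq + L)$ predicts).
* No statistical significance (E-values/FDR) is attached to scores; the
  benchmark ranks by raw alignment size.
* Diagonal mode needs externally supplied start positions; the package does
  not implement the candidate-filtering step that would produce them.
* The spectrum text format is deliberately minimal; there is no msalign or
  mzML reader.
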