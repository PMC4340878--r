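---
title: "Methods: from ChIP enrichment to regulon logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ChIP enrichment to regulon logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscope)
```

`regulonscope` reconstructs the regulon of a bacterial transcription factor
from ChIP enrichment data and classifies the regulatory logic that connects
the factor to its targets under stress. This vignette explains each stage's
model and assumptions, the parameters that matter, and the design choices
made where the procedure was genuinely open. It is written around the
package's motivating system — the IclR-family regulator NdgR of
*Streptomyces coelicolor*, which sits downstream of the thiol-stress sigma
factor and controls branched-chain amino acid and cysteine/sulfur
assimilation genes through a 15-bp imperfect palindromic binding site — but
every stage is generic.

## Coordinate frame and formats

All internal coordinates are 1-based inclusive, so values printed in a
published peak table can be used verbatim. The single place where 0-based
half-open coordinates appear is BED/bedGraph export, and the conversion
there-and-back is the identity. Genomes default to circular (interval
arithmetic wraps modulo the genome length); this is a simulation convenience
that avoids edge artifacts in tests — the *S. coelicolor* chromosome itself
is linear, so `circular = FALSE` is available throughout and linear windows
truncate with a warning instead of wrapping. `"N.A."` is the only
missing-value token recognized in the peak-table dialect, matching the
printed table it mirrors.

## Peak calling

The caller works directly on per-base IP and control coverage; read
alignment is out of scope, and coverage is what the detection model actually
consumes. Windows of `window_size` (default 300 bp) slide by `step`
(default 50 bp). Each window's IP count is tested against a Poisson
background whose rate is the **local lambda**: the maximum, over several
spans centred on the window (1, 5 and 10 kb by default), of the
library-size-scaled control rate, floored by the genome-wide rate. Taking a
maximum over spans guards against local background inflation; scaling the
control by total-IP/total-control is the simplest defensible library-size
normalization. The window score is the MACS-style
$-10\log_{10} P(X \ge k)$, computed in log space so deeply enriched windows
do not overflow. Retained windows (score > `score_min`) within `merge_gap`
of each other merge into peaks; the summit is the leftmost maximum of IP
coverage (leftmost for determinism); fold enrichment is the IP count of the
window centred on the summit divided by that window's local lambda.

The default cutoffs — score > 100 (equivalently $p < 10^{-10}$) and fold
enrichment > 3 — are the stringent thresholds under which the 19 NdgR
binding loci in the packaged table were selected; applying them to that
table removes no rows. The caller mirrors the central local-lambda idea of
MACS without claiming feature parity: duplicate filtering, fragment-shift
modelling and control-swap FDR are deliberately absent. How fold enrichment
was computed in the original analysis (summit versus region) is not
documented, so packaged fold values are treated as given and never
recomputed; the summit-window convention here applies only to newly called
peaks.

## Summit annotation and operon expansion

Distances are strand-aware offsets from annotated start codons — upstream
of a minus-strand gene means higher coordinates — since "upstream" is
meaningless in absolute coordinates. A summit at most 500 bp upstream or
100 bp downstream of a start codon (bounds inclusive, because the source
rules are stated with "≤") marks that gene as directly regulated. When
genes on opposite strands both match one shared intergenic summit, both are
returned with a divergent flag — the configuration of the regulator's own
gene and the *leuC* operon it faces. A summit matching no gene that way is
intragenic when it lies inside a gene at least 100 bp past the start codon
and at least 500 bp upstream of the next downstream start codon. The
upstream rule takes precedence; in fact a summit within 500 bp of the next
start codon always triggers the upstream rule for that downstream gene, so
the intragenic to-next-start condition is a guard rather than a reachable
rejection path.

Direct upstream hits expand through the transcription unit: every gene
downstream of the matched gene in transcription order becomes an operon
member (one binding region upstream of a six-gene sulfate-assimilation
operon contributes six regulon genes). Intragenic hits do **not** expand —
in the packaged regulon table the intragenically bound genes appear as
single genes, not operon blocks. Records deduplicate by locus tag with
evidence flags merged, and output order is by locus tag, so the regulon is
independent of peak input order. Transcription units are inputs, not
inferred.

## Motif discovery

Sequences of 400 nt centred on each summit (`[summit - 200, summit + 199]`;
"400 nucleotides surrounding" is ambiguous by one base, resolved
left-inclusive) are searched for one over-represented motif under the ZOOPS
assumption — zero or one occurrence per sequence — by expectation-
maximization over a hidden occurrence indicator, offset and strand, against
a 0-order background estimated from the windows themselves and symmetrized
over complements (so both strands are scored by one model). The M-step adds
a pseudocount of 0.5 per base. The algorithm maximizes the
pseudocount-penalized likelihood, and that penalized objective is asserted
non-decreasing at every iteration (with a Dirichlet-style pseudocount the
raw likelihood can in principle dip by a vanishing amount; the objective the
M-step actually maximizes cannot).

Restarts are seeded deterministically from candidate words: every w-mer in
the input is ranked by the summed log-enrichment (observed versus
background-expected counts, smoothed with pseudocount 5) of its constituent
6-mers. Plain word frequency fails here — when no two sites are identical,
every w-mer occurs once — while over-represented 6-mer cores (and the
smoothing, which stops rare AT-rich words in a 72% GC background from
dominating) reliably surface true site words. The best of 20 restarts per
width (5 EM iterations each) runs to convergence.

Width is selected over 6–20 by a BIC-penalized log-likelihood ratio against
the pure-background model, with penalty $\tfrac{3w}{2}\log n$ for $n$ input
sequences — the matrix has $3w$ free parameters and each sequence
contributes at most one site. An alternative penalty using the total number
of scanned positions was evaluated and rejected: at realistic cohort sizes
(about twenty windows) it exceeds any attainable likelihood ratio and flags
every real motif as insignificant. Because alignment freedom lets
uninformative flanking columns ride along with a real motif, flanks whose
contribution $n_{\text{sites}} \cdot KL(\text{column} \,\|\, \text{bg})$
falls below half the $\chi^2_3$ 1% critical value are trimmed and the model
refit at the trimmed width. The reported E-value estimate is a
restart-count-corrected transform of the penalized likelihood ratio — a
documented approximation, not a MEME E-value, which is why the original
analysis's E-value is not a target anywhere in the tests.

Palindromicity is summarized as
$\frac{1}{w}\sum_i \sum_b p_{i,b}\, p_{w+1-i,\mathrm{comp}(b)}$ — 1 for a
deterministic perfect palindrome (necessarily of even width), about
$\sum_b q_b q_{\mathrm{comp}(b)}$ for background columns. The IUPAC
consensus includes bases at probability ≥ 0.25 per column by default, with a
bracketed form (`[GT]...`) matching the notation used for the published
consensus.

## Genome scanning and summit–motif geometry

Scanning scores every position and strand with a log-odds matrix in bits,
$\log_2$ of regularized motif probability over background. P-values are
exact: scores are discretized to 0.01-bit bins (rounding error far below
any decision boundary at widths ≤ 20) and the null distribution of the
binned score is built by dynamic programming — convolving per-column score
distributions under the background — so the lookup agrees with full word
enumeration to rounding. Scanning uses the same binned matrix, making
lookups exact rather than approximate. The default reporting threshold is
$p \le 10^{-4}$, the conventional scanning default, recorded in
configuration because the source analysis states none. No multiple-testing
correction is applied to scan hits; occurrence counts are raw.

Summit–motif geometry uses the **midpoint** convention: the distance from a
summit to a motif is $|{\rm summit} - ({\rm start}+{\rm end})/2|$ with exact
half-integer arithmetic, compared inclusively against a 50-bp threshold.
On the packaged table this convention reproduces the published counts — 18
of 19 loci carry the motif and 13 of those lie within 50 bp of the summit —
whereas an edge-to-summit convention yields 14 and is therefore rejected.

## Factorial expression and feed-forward-loop logic

Raw qPCR cycle values normalize by the delta-delta-Ct method against a
housekeeping reference and a calibrator sample with efficiency 2.0 — the
reference gene is documented in the source system but no formula, so the
standard method is the natural choice. Replicates aggregate by geometric
mean, consistent with multiplicative (lognormal) noise in fold-change data.

Classification of a target's 2×2 factorial design (stress D × regulator
genotype N) proceeds in three steps. Cell means binarize against
$\theta \times$ the (0,0) baseline ("above threshold" in the source figure
is unquantified and its normalization sentence implies a baseline-relative
reading; both $\theta$ and the edge threshold $\alpha$ default to 2.0-fold
and are configuration keys, and raw cell means are reported alongside so
threshold sensitivity is auditable). The D→target edge is activating if
stress raises expression $\alpha$-fold at either genotype; the N→target
edge is judged primarily under stress — the key published contrast for the
repressed target is "in the presence of diamide" — falling back to the
unstressed comparison for constitutive regulation. Both edges activating
gives a coherent type-1 feed-forward loop, whose gate is OR when either
single input suffices to switch the target ON and AND when only the double
input does; an activating D edge with a repressing N edge gives an
incoherent type-1 loop. The stress→regulator edge is taken as activating
throughout, established independently of the factorial data. Only static
classification is in scope — pulse dynamics and fold-change detection of
the incoherent loop are properties discussed, not asserted.

## The synthetic-data generator

The generator stands in for the deposited raw sequencing data and defines
the conditions under which the pipeline is tested:

* **Genome**: i.i.d. bases at 72% GC (the organism's composition), 50 kb by
  default — large enough for eight transcription units with realistic
  spacing, small enough that the full test suite runs in minutes. Circular.
* **Landscape**: non-overlapping transcription units on both strands, 1–4
  genes of 900 bp each, 800 bp minimum between units so each planted site
  maps unambiguously to one unit under the 500-bp rule. Always includes one
  divergent pair sharing a 240-bp intergenic region and one long (2.5 kb)
  gene eligible for intragenic binding.
* **Sites**: sampled from a probability matrix estimated from the 18
  packaged 15-bp site sequences with pseudocount 0.5, so synthetic data
  share the real motif's statistics, including its imperfect
  palindromicity; planted centred 100 bp upstream of unit-leading start
  codons (the shared divergent site in the middle of its intergenic
  region), on a random strand, spliced into the genome verbatim.
* **Coverage**: control is Poisson at 2 reads/bp; IP is Poisson at the
  background rate times $1 + (f-1)k(d)$ with a triangular kernel of
  half-width 150 bp — about half the sonication-fragment mode of the
  emulated protocol, scaled for desk-sized genomes — and peak fold
  $f = 10$. The triangular kernel (rather than Gaussian) keeps expectations
  exactly computable in tests. Overlapping kernels sum, capped at a
  configured maximum.
* **Expression**: 2×2 factorial cell means per planted logic (coherent-OR:
  induced by either input; incoherent: stress-induced, regulator-repressed
  to induction/repression), three replicates, mean-preserving lognormal
  noise at CV 0.2 — typical qPCR fold-change dispersion.

Every generator is a pure function of its configuration and seed, and the
recorded ground truth (site coordinates, sequences, implied regulon,
planted logic) suffices to recompute every downstream expectation without
re-running the generator.

What the simulation does **not** emulate: read-level artefacts (duplicates,
mappability, GC bias), fragment-size distributions, background
non-uniformity from replication or expression, and motif-adjacent sequence
structure. Passing the recovery tests therefore demonstrates correctness of
the algorithms under their stated models, not performance on real
libraries; the packaged peak and regulon tables are the bridge to real
data, and the geometry, filter-consistency and width results on them are
exact.

## Problem sizes and numerical choices

Test and verification runs use 50-kb genomes (10 kb where a step-1
brute-force comparison runs alongside), 10 simulation seeds for recovery
rates, 10 replantings for width selection, and 20 seeds × 3 noise levels
for logic recovery — sizes chosen so the whole suite completes in a few
minutes while leaving the statistical margins wide (every planted-recovery
criterion passes at 100% against a 95% requirement). Ties in summit
location break leftmost; ties in seed-word ranking break lexicographically;
EM convergence is a relative objective change below $10^{-6}$ (cap 500
iterations); score binning is 0.01 bit. Degenerate inputs error early:
non-ACGT genomes, mixed-strand transcription units, summits outside peaks,
all-zero controls (warning plus genome-wide fallback), empty factorial
cells, zero cell means.

## Known limitations

* The peak caller is a deliberately transparent local-lambda detector;
  it will not match a production caller's behaviour on real libraries.
* ZOOPS discovery fits a single motif; multiple or gapped motifs are out of
  scope, and the E-value estimate is not comparable across tools.
* Regulon reconstruction is bounded by the supplied transcription units;
  wrong operon definitions propagate directly into the regulon.
* Logic classification is static. With default thresholds a weakly induced
  target (below 2-fold) classifies as not-a-loop even when a real edge
  exists; lowering $\alpha$ trades that against noise sensitivity.
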