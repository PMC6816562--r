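---
title: "Models and methods: coat-colour and morphology genetics in dog breed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: coat-colour and morphology genetics in dog breed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninetraits)
```

# The problem

Commercial genotyping panels assay a small set of causal variants at
twelve genes that together control most of the visible coat-colour and
morphology variation among dog breeds: the pigmentation loci ASIP, MC1R,
CBD103, TYRP1, MITF, PSMB7 and RALY, and the physical-trait loci FGF5
(hair length), KRT71 (curl), T (natural bobtail), BMP3 (muzzle length)
and a chromosome-10 ear-set marker. From per-variant copy counts this
package assembles diploid genotypes, predicts expressed phenotypes
through the dominance and epistasis structure of the pathway, estimates
breed allele frequencies, screens registry breed standards for "fault"
alleles and their random-mating expression probabilities, compares
same-breed subpopulations statistically, and maps how rare alleles could
have travelled between breeds along identity-by-descent (IBD)
haplotype-sharing relationships.

# Genotype assembly from marker copy counts

Each marker call is a copy count in $\{0, 1, 2\}$ (or missing on
sporadic assay failure). Genes assayed by a single variant map counts
0/1/2 directly onto wt/wt, wt/var, var/var; TYRP1 combines its two
tested brown variants ($b^s$, $b^c$) with a total of at most two copies.
ASIP and MC1R carry a *by-exclusion* allele ($a^w$ and $E$) with no
marker of its own: chromosomes not accounted for by a derived variant
are assigned the wild type.

At ASIP the assay can observe more than two derived copies. The only
cis combination known to produce this is the $a^y$ point mutations plus
the $a^t$ SINE insertion on one chromosome, written $a^{yt}$. With total
derived copies $T$:

* $T \le 2$: pad with $a^w$;
* $T = 3$ with at least one $a^y$ and one $a^t$: collapse one cis pair,
  e.g. $(a^y{=}2, a^t{=}1) \to a^{yt}/a^y$. When the remainder is the
  $a$ allele the call is flagged `ayt_vs_trans`, since cis combinations
  involving $a$ have never been described;
* $T = 4$ with $a^y = a^t = 2$: $a^{yt}/a^{yt}$;
* any other excess: `unresolved`, excluded from frequency counts rather
  than guessed.

MC1R uses the same padding rule with $E$, but no cis allele is described
there, so any excess is `unresolved`. A missing constituent marker
voids the whole gene's call (conservative; the frequency code then
excludes that dog at that gene only).

**Known blind spot.** A true $a^{yt}/a^w$ dog emits $a^y{=}1, a^t{=}1$
and is marker-identical to a trans $a^y/a^t$ heterozygote; it is
interpreted as the latter with no flag, because no assay-level
information distinguishes them. The unit tests assert this equivalence
explicitly, and the round-trip acceptance check uses a cohort without
$a^w$ at ASIP so that every remaining configuration is recoverable (or
correctly flagged). A green round-trip therefore establishes
correctness *up to* this acknowledged indistinguishability, not beyond
it.

# The phenotype cascade

Prediction applies epistasis in a fixed order: MC1R $e/e$ gives a solid
phaeomelanin (red/yellow) coat and hides everything downstream of
eumelanin patterning; otherwise one or more CBD103 $K^B$ copies give
solid eumelanin — or brindle, since the assay cannot separate $K^B$
from $k^{br}$, so the report carries an explicit ambiguity flag rather
than a guess; otherwise the most dominant ASIP allele
($a^y > a^w > a^t > a$) sets the base pattern. Modifiers then gate on
background: grizzle ($E^G$) expresses only on tan points and is
out-ranked by $E^M$; the RALY saddle duplication makes a dog saddle-
*capable* only on tan points and is never reported as certain, because
at least one unidentified additional modifier is required; a melanistic
mask is visible only over a phaeomelanin-bearing pattern; TYRP1 browns
eumelanin and the nose (the nose browns even under $e/e$); curl
requires a long coat (FGF5 long/long). Harlequin ($h$) and bobtail
(T) heterozygotes express (harlequin additionally requires merle, which
this panel does not test, hence "capable if merle"); their homozygotes
are flagged non-viable. BMP3 and the ear marker are echoed as genotypes
with a "polygenic context" qualifier — the ear locus in particular is
known not to account fully for ear phenotype.

Design choices where the sources leave the behaviour open:

* **$a^{yt}$ dominance is unknown.** The allele is ranked most dominant
  so that any $a^{yt}$-bearing genotype surfaces as
  `ayt_uncharacterized` instead of silently passing as fawn. This is a
  reporting posture, not a biological claim.
* **Grizzle background.** Expression is keyed on an *expressed
  tan-point pattern* (not on $a^t$ homozygosity specifically); flagged
  as an open interpretation.
* **Mask under $e/e$.** An $e/e$ genotype cannot carry $E^M$ at the
  same gene, but the report still marks mask/grizzle
  `masked_by_epistasis` under $e/e$ to keep rule (1) self-contained.
* **Mask on `ayt_uncharacterized`.** Since the pattern itself is
  uncharacterized, mask is reported `masked_by_epistasis` rather than
  `present`.

The whole three-gene cascade (10 ASIP x 10 MC1R x 3 CBD103 unordered
genotype combinations) is checked against an independently coded
rule-table oracle in the tests.

# Allele frequencies

Frequencies are chromosome-count estimates:
$\hat p = \text{count} / (2\,n_\text{genotyped})$ per breed (or breed x
population). Dogs missing or unresolved at a gene leave that gene's
denominator only. $a^{yt}$ is counted as its own allele class and
$K^B/k^{br}$ as one pooled class. Values are kept at full precision
internally; rounding is left to the presentation layer, which is why
worked examples recomputed from rounded published inputs can differ
slightly from published outputs (see below).

# Fault alleles and random-mating probabilities

A *fault* is a phenotype disallowed (N) or not preferred (n.p.) by a
registry's written breed standard; ambiguously worded standards (amb.)
are reported but flagged. The shipped standards table is a small
curated set covering the worked-example breeds (Bull Terrier,
Schipperke, Great Dane, Shetland Sheepdog, and a Black Russian Terrier
placeholder); reconstructing the full published supplement is out of
scope.

Under random mating the probability of producing a fault phenotype is a
product of independent Hardy-Weinberg factors, one per participating
gene. The published equation writes every factor in the dominant form
$p^2 + \sum 2pq$, yet its own worked examples require other modes, so
each factor carries an explicit expression mode:

| mode | factor | used for |
|---|---|---|
| `dominant_or_better` | $p^2 + \sum_q 2pq$ | dominant fault allele with recessive same-gene carriers |
| `homozygous_recessive` | $(p + \sum q)^2$ | recessive classes, incl. TYRP1 compound heterozygotes |
| `heterozygous_only` | $2p(1-p)$ | homozygous-lethal alleles (harlequin, bobtail) |
| `het_or_hom` | $p^2 + 2p(1-p)$ | co-dominant expression (e.g. MITF spotting in the Great Dane) |

Worked examples reproduced by the demo pipeline from exact frequency
inputs: Bull Terrier brown $(0.03 + 0.03)^2 = 0.0036$; UK Schipperke
red $0.5^2 = 0.25$; Great Dane fawn-and-white
$(1-0.66)^2 (1 - (1-0.06)^2) = 0.013456$ (published as 1.33%) and
fawn with one harlequin copy
$(1-0.66)^2 \cdot 2(0.21)(0.79) = 0.038356$ (published as 3.80%). The
~1% relative gap on the Great Dane values stems from the publication
computing from unrounded frequencies while printing rounded ones; the
package recomputes from the rounded inputs and documents the
difference rather than tuning. The Great Dane MITF factor is
`het_or_hom` (co-dominant) and the Shetland Sheepdog's is recessive,
per breed-specific findings; the harlequin example is deliberately
*not* live-birth-renormalized, matching the published value.

The live-birth correction divides by $\prod (1 - p_\text{lethal}^2)$,
i.e. renormalizes conception-level probabilities to the viable subset.
The closed form is verified against an exhaustive genotype-space
enumeration oracle to $10^{-12}$ across all mode combinations.

# Subpopulation comparison

Same-breed subpopulations are compared on the populations x alleles
chromosome-count table. Units are chromosomes (allele counts), not
dogs: the published cell-size rule is stated on allele counts. Pearson's
chi-square (no continuity correction) is used unless any cell is below
5, in which case Fisher's exact test is used — exact up to 200 total
chromosomes, seeded Monte-Carlo with $10^5$ resamples above that (a
tractability/reproducibility compromise). Tests are two-sided (the
sidedness is not stated in the source; two-sided is the conservative
convention). Significance is $p \le 0.05/30 = 0.00167$ by default
(Bonferroni over 30 tested breeds; 29 breeds give 0.00142 for a gene
missing in one breed). Pairwise follow-up for breeds with more than two
subpopulations uses $0.05/n$ with $n$ the maximum number of
subpopulations remaining (4 subpopulations give 0.0125, 6 give 0.0083).
Rare-allele pooling before testing is configurable but off by default;
the source does not state that pooling occurred.

# Carrier connectivity

Given a precomputed IBD edge list (breed pairs, sharing value,
significance flag) and a set of carrier breeds, the graph builder takes
the significant-edge subgraph induced on carriers, then greedily adds
the non-carrier breed that merges the most carrier components, breaking
ties lexicographically. The published work describes no algorithm for
its connector choice, so this is labelled a heuristic. One extension
proved necessary: when no *single* breed merges two components but a
chain of non-carriers still links them, the heuristic merges the
closest pair of components along a shortest path. Without this, the
greedy count could undercut the brute-force optimum while leaving the
graph disconnected, making the greedy-vs-optimal comparison
meaningless. A carrier with no significant sharing anywhere attaches
through its single highest non-significant partner, flagged as a
fallback (dashed) edge; carriers absent from the IBD study are reported
"not represented" and excluded. On random graphs of up to 10 nodes the
greedy count is compared against an exhaustive Steiner-subset oracle;
it is never below the optimum and the equality rate is reported by the
test (58/58 in the shipped seed).

# Synthetic cohorts: the stated world

The generator draws two haplotypes per dog per gene from stated allele
frequencies (Hardy-Weinberg), with three structural features of the
real assay: at homozygous-lethal loci (PSMB7 $h$, T *tailless*) draws
are rejection-sampled until viable, because only live births are ever
genotyped — the analytic equivalent (heterozygote fraction
$2pq/(1-p^2)$, lethal-allele chromosome share $p/(1+p)$) is a test, not
an implementation shortcut; $a^{yt}$ haplotypes emit both the $a^y$ and
$a^t$ markers from one chromosome; and missing calls are masked
independently per marker per dog at a stated rate ("sporadic failure"
is all the source states, so independence is the assumption).
Generation is fully seeded and byte-reproducible.

What the generator does **not** emulate: linkage disequilibrium between
genes, pedigree structure, genotyping error, or breed-realistic joint
frequency profiles. A green pipeline test on synthetic cohorts
therefore establishes computational correctness of the machinery, not
biological validity of any particular breed inference.

Default cohort parameters used by the calibration tests follow the
stated world: 2 populations x 50 dogs for null calibration (2,000
replicates, rejection rate at $\alpha = 0.00167$ bounded by 0.0035),
divergence 0.4 at $n = 50$/population for power, tailless frequency 0.3
with $n = 10{,}000$ for the lethal-locus check, and a 5,000-dog cohort
with $a^{yt}$ at 5% for the interpretation round trip. The round-trip
cohort omits $a^w$ at ASIP for the blind-spot reason above; all other
frequencies are mid-range values chosen once so that every allele class
appears often enough to be exercised.

# Numerical choices and degenerate inputs

* Frequencies must sum to 1 within $10^{-9}$ in cohort specs;
  estimated frequencies sum to 1 within $10^{-12}$ per gene.
* Contingency tables drop all-zero populations with a warning; a single
  remaining population is `untestable` (NA p-value), and a table with a
  single allele class is "identical by definition" ($p = 1$).
* Closed-form vs enumeration agreement is asserted to $10^{-12}$.
* Allele pairs are stored sorted, so unordered comparison is exact.
* Ties in the connector heuristic break lexicographically, making the
  graph deterministic under input reordering.

# Known limitations

* The published cohort-level counts (143 fault-carrying breeds, the
  82%/57% derived-allele totals, the 9-connector bobtail graph) depend
  on the proprietary 11,790-dog dataset and its external IBD matrix;
  they are not reproducible here and are covered instead by the
  property-based suite.
* The $K^B$ vs $k^{br}$ structural variant and merle (PMEL17) are out
  of assay scope; harlequin capability is conditional on an untested
  merle genotype.
* Phasing of triple-variant ASIP dogs involving the $a$ allele is
  flagged, not resolved.

# A worked run

```{r demo}
cfg <- write_demo_run()
res <- run_pipeline(cfg)
res$faults$probabilities
head(res$faults$findings)
```
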