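---
title: "Information-theoretic analysis of splice sites and splicing mutations"
author: "spliceinfo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic analysis of splice sites and splicing mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceinfo)
```

## The model

Spliceosomal recognition of a donor or acceptor splice site is quantified by
its *individual information* $R_i$, in bits. From a set of $n$ aligned
functional sites, the per-position base frequencies $f(b, l)$ give an
information weight matrix

$$w(b, l) = 2 + \log_2 f(b, l),$$

and the $R_i$ of any candidate site is the dot product of this matrix with
the one-hot encoding of its sequence — equivalently, the sum of the weights
of the observed bases. The average over the training set, $R_{sequence}$,
measures the total conservation of the motif, and equals
$\sum_l \left(2 - H(l)\right)$ with $H(l)$ the Shannon entropy at position
$l$. Because $R_i$ is tied to the free energy of binding, a change
$\Delta R_i = R_{i,final} - R_{i,initial}$ caused by a variant implies a
minimum fold change in binding affinity of $2^{|\Delta R_i|}$: a 7-bit
weakening is at least a 128-fold loss of affinity. This exponential relation
is the reason bitwise-small changes can have drastic molecular consequences,
and why reporting changes on a linear scale misleads.

Donor sites are modelled over the window $[-3, +6]$ and acceptors over
$[-25, +2]$ relative to a zero coordinate at the intron boundary (first
intronic base for donors, last intronic base for acceptors; zero is a real
position). Branch-point sites use a short window around the branch
adenosine.

Two further quantities are reported side by side because they are often
confused: the *residual strength* $100 \times R_{i,final}/R_{i,initial}$
(a bit-scale ratio) and the affinity fold change $2^{\Delta R_i}$. A site at
5.4 bits after a $-2.6$-bit change retains 67.5% of its information but at
most $2^{-2.6} \approx 16\%$ of its binding affinity.

## Interpreting variants

`analyzeVariant()` scores every model placement overlapping a variant within
a 54-nt analysis window (the default window a practitioner should state in
reports), before and after the change, and categorizes each site. Natural
sites falling below the minimum functional strength `riMin` are *abolished*;
significantly weakened but functional sites are *leaky*. `riMin` defaults to
1.6 bits, the empirical threshold for genome-wide-derived models, with 2.4
bits selectable for legacy models. Changes smaller than 1.0 bit are treated
as insignificant: they are not reliably detected experimentally. Severity
bins for natural-site substitutions (`classifySMC()`) follow the published
thresholds, with shared endpoints resolved half-open toward the less severe
bin ("more than 7.0 bits" is a strict inequality).

Cryptic-site activation events are typed by `classifyCrypticEvent()`:
Type 1 (cryptic strengthened or created, natural intact), Type 2 (one
variant weakens the natural site and strengthens the cryptic in a shared
footprint), Type 3 (natural weakened, pre-existing cryptic exposed).
`pipelineFlag()` applies the genome-pipeline triage rule — keep sites with
$R_{i,initial}$ or $R_{i,final} \ge 0$ bits and $|\Delta R_i| \ge 1$ bit —
then prioritizes weakened naturals and cryptics that pass
`predictActivation()` (functional, within 1 bit of the competing natural
site, and closer than 400 nt; distant sites are downgraded because they are
less likely to be recognized).

## Exon definition

Total exon information combines both sites and the plausibility of the exon
length: $R_{i,total} = R_{i,acceptor} + R_{i,donor} - GS(L)$, where the gap
surprisal $GS(L) = -\log_2 P(L)$ is the self-information of the exon length
under a binned genome-wide length distribution. A regulatory element
contributes $+ R_{i,reg} - GS_2(d)$ with a second surprisal on its distance
to the nearest natural site; only one factor is evaluated per run, and when
several sites of one factor are present the strongest is used.
`rankIsoforms()` enumerates acceptor/donor pairs around an exon and ranks
isoforms by $R_{i,total}$ pre- and post-variant; a natural-site drop of at
least 7 bits (configurable via `skipThresholdBits`, since smaller decreases
can sometimes partially induce skipping) puts the exon-skipping isoform on
top.

The bundled exon-length distribution is a synthetic log-normal (median
120 nt, $\sigma_{\log} = 0.6$) over 16 log-spaced bins spanning 1–10,000 nt
with a $2^{-20}$ floor for empty bins — a stand-in with the qualitative
shape of the constitutive exon-length distribution. Users should substitute
an empirical two-column table for production work; published per-gene
anchors that depend on the unpublished genome-wide table are therefore not
reproduced here.

Branch-point scanning (`findBranchpoints()`) reports motif hits with
$R_i \ge 0$ within 100 nt upstream of the acceptor by default (never beyond
a 400-nt hard maximum, the upper end of reported branch-point distances) and
flags hits inside annotated donor windows, a documented false-positive mode
of branch-point prediction.

## Synthetic data: what it emulates and what it does not

All fixtures are generated in code. The bundled donor, acceptor and
branch-point frequency matrices emulate the canonical human motifs — near
invariant GT/AG cores, a polypyrimidine tract, total information around 8
bits for donors (the average strength of natural donor sites) and about 9.6
bits for acceptors; the branch-point model is deliberately weak, as models
built from few validated sites are. They are design-time constants, not
genome-derived models, so tests that pass on them demonstrate algorithmic
correctness (identities, oracles, planted-truth recovery), not clinical
accuracy on real annotation.

`makeToyGene()` plants natural sites within ±0.5 bits of their targets by a
greedy per-position construction that protects near-invariant positions
(weight gap > 3 bits) and caps each degradation step at 2.5 bits so the
weakening spreads across the window — one large hit would leave long
homogeneous stretches shift-invariant and create competing placements.
Three decoy contexts make the activation types constructible by single
substitutions: a latent donor one substitution below threshold, a strong
pre-existing intronic donor, and a decoy overlapping the last natural
donor's footprint. Accidental same-polarity placements within 2 bits of a
natural site and within 100 nt of it are destroyed by targeted background
edits (or the background is re-drawn); weaker decoys are left in place on
purpose, since real genomes are replete with them. For typing an engineered
"abolished" variant, a pre-existing cryptic counts as Type 3 material only
when it is competitive with the original natural site (within 1.5 bits) —
bare functionality (1.6 bits) would be triggered by background decoys and
make planted truth ambiguous. The panel generator verifies every engineered
variant end-to-end before accepting it and skips, with a notice, effects the
gene cannot realize.

## Numerical choices

* Weights use pseudocount 0.5 by default; exact-identity computations
  (e.g. $R_{sequence}$ = training mean) require pseudocount 0, where
  unobserved bases receive a finite sentinel (−20 bits, configurable)
  instead of $-\infty$.
* The optional small-sample correction subtracts the first-order entropy
  bias $3L/(2 n \ln 2)$ bits from $R_{sequence}$ only; it is off by default
  and never applied to individual weights, since the original tools'
  correction is referenced but not specified.
* Ambiguous bases: N in a training sequence drops the record (with a
  warning); N in a scanned window contributes 0 bits and flags the site —
  a conservative choice that neither rewards nor penalizes unknown sequence.
* Coordinates are 1-based inclusive everywhere (files, reports, internals),
  the natural convention in R and Bioconductor; model windows are addressed
  by signed offsets around the zero point.
* Ranked outputs break ties by shorter exon, then lower coordinate.
* Minus-strand work is done by scanning the reverse complement and
  mirroring coordinates; reports always carry the strand, and the default
  analysis covers the annotated gene strand only (antisense hits have been
  misattributed in the literature), with both strands available on request.
* Model files round-trip byte-identically: weights are written with 17
  significant digits.

## Problem sizes in the test suite

The suite exercises parameter recovery at $n$ = 100/1,000/10,000 sampled
sites, scanning oracles on fifty 2-kb random sequences, a 10,000-row
pipeline-flag batch with five planted events, and the six-effect planted
panel on the default four-exon toy gene (~1.8 kb) — sizes chosen so the
whole suite runs in well under a minute per file on one CPU while still
giving the asymptotic checks (error decreasing as $O(1/\sqrt{n})$) room to
bind.

## Known limitations

* Only one regulatory factor per exon per run; multi-factor cooperation is
  not modelled (and is not predictable from these models alone).
* The c./IVS parser covers substitutions and single-interval indels on
  plus-strand transcripts; it is not a full HGVS grammar.
* Branch-point models built from ~20 sites are intrinsically unreliable;
  hits should be read together with the donor-context flag and distance.
* Predictions quantify spliceosomal binding, not phenotype: concordance
  with experiments (criteria a–e in `assessConcordance()`) depends on
  validation assays that can miss leaky splicing in heterozygotes or
  NMD-degraded isoforms, which is why those exceptions are built into the
  criteria.
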