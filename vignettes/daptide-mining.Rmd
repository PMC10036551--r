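---
title: "RRE-guided mining of RiPP precursor families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RRE-guided mining of RiPP precursor families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rremine)
```

## The problem

Ribosomally synthesized and post-translationally modified peptides (RiPPs)
are usually discovered by searching for known modification enzymes, which
restricts discovery to known chemistry. An alternative is to anchor on the
RiPP Recognition Element (RRE) — a small leader-binding domain found in
about half of prokaryotic RiPP classes — and to ask, class-independently,
which RRE-containing enzyme families consistently co-occur with families of
mutually similar short open reading frames (ORFs). A coherent enzyme family
whose gene neighborhoods repeatedly encode a coherent family of short ORFs
is strong evidence for an unrecognized precursor peptide class. The daptide
class — peptides carrying an (S)-N2,N2-dimethyl-1,2-propanediamine (Dmp)
unit built from an invariant C-terminal Thr — is the motivating discovery,
and the package also ships the elemental mass ledger for that pathway.

`rremine` implements this procedure as a tested pipeline: similarity-graph
construction, neighborhood ORF harvesting, the recursive family-pairing
algorithm, precursor profiling, the Dmp mass ledger, and a synthetic-data
generator with planted ground truth used to validate recovery.

## Similarity graphs and families

Input is all-by-all protein similarity in 12-column BLAST/DIAMOND tabular
form. `build_graph()` symmetrizes directional hits by keeping the **maximum**
of the two bitscores (conservative inclusion: a family link exists if either
direction reports it), collapses duplicate HSP rows the same way, removes
self-hits, and removes hits strictly below the threshold — a hit exactly at
the threshold is kept, mirroring the "below-threshold removed" filtering
convention. Families (`connected_families()`) are connected components of
the thresholded graph, i.e. single-linkage clusters; whether a stricter
criterion than single linkage was intended by the original description of
family formation is ambiguous, and single linkage is the documented choice
here. Ordering is deterministic: descending size, ties by smallest member
id.

*Enzyme connectivity* of a family at threshold *t* is the number of
within-family pairs with a qualifying hit divided by n(n−1)/2. A singleton
returns 1.0 by convention (avoids 0/0; singletons never survive the size
floor anyway).

## Neighborhoods and the short-ORF caller

Anchors (RRE-containing genes) are located in GFF3 annotations;
`extract_window()` takes the ±8-gene window (index distance, truncated at
contig ends). Within the window span `find_short_orfs()` scans both strands
in all three frames for start-to-stop ORFs with starts ATG/GTG/TTG
(initiator rendered M), bacterial genetic code (table 11), lengths 5–119
residues — calling ORFs as short as five amino acids and keeping candidates
strictly smaller than 120. Coordinates are reported on the forward strand,
1-based inclusive, and include the stop codon
(`end − start + 1 = 3·(length_aa + 1)`). We keep 1-based inclusive
coordinates throughout the package rather than switching to a 0-based
internal convention: it is the GFF3/GRanges idiom and removes a conversion
boundary.

A full gene-caller (Prodigal-style coding statistics) is deliberately not
reimplemented; dereplication among nested ORFs sharing a stop codon and
frame instead uses a transparent score, `ln(length) + start bonus`
(ATG 0.5, GTG 0.25, TTG 0), ties resolved by length then coordinate. This
keeps the property that matters for mining — one candidate per stop — while
being fully reproducible. ORFs overlapping annotated genes are retained;
candidates matching the anchor list by id or exact sequence are removed
(`exclude_rre_like()`) so RRE domains never enter precursor analysis.

## The recursive pairing algorithm

Configuration (`mining_config()`): initial RRE threshold 50 bits, ORF
threshold 10 bits (never escalated), minimum family size 30, connectivity
floor 0.2, threshold step +10, precursor/enzyme size-ratio bounds
[0.1, 10].

Each initial family enters a depth-first recursion at t = 50:

1. families below the size floor are dropped (the floor is re-applied at
   every depth — the original description states it only for the first
   pass, but re-application prevents fragment spam and is configurable);
2. if connectivity at *t* is ≤ 0.2 the family is too divergent: it is
   re-clustered at t + 10 and each subfamily recurses;
3. otherwise the largest precursor family is computed — the largest
   connected component of the ORF graph restricted to ORFs hosted in the
   family's neighborhoods — and the pairing is accepted if its size is
   within an order of magnitude of the enzyme family's size
   ([0.1, 10], two-sided; the original phrasing is one-sided-ambiguous);
   failing the ratio, the family re-enters at t + 10.

A branch terminates, emitting nothing, when the escalated threshold exceeds
the family's maximum internal edge weight (re-clustering could only produce
singletons) or after 50 iterations; the original procedure is silent on
termination, and this rule makes non-termination impossible. Traversal is
deterministic (families by descending size then id), thresholds visited are
recorded per emitted result, and the ORF threshold stays fixed during
escalation.

## Precursor profiling

Accepted precursor candidates are filtered for the class-defining
C-terminal residue (Thr by default), split into leader and core at the
conserved Pro (either the last Pro within the N-terminal 60% of the
sequence — a transparent heuristic standing in for an alignment-based
leader call — or after the first match of an explicit motif such as
ELExMEAP with `x` wildcard), and summarized as a right-anchored position
frequency matrix: column −1 is the C-terminus, because the invariant
residue is C-terminal and the peptides vary in length. Shorter sequences
contribute only to the positions they cover, and each column is normalized
over its contributors. `per_bgc_stats()` reports per-cluster precursor
counts; its mean is reported to one decimal, the precision at which the
per-cluster average (2.3 for the initial 184-precursor/80-cluster family)
is quoted.

## The mass ledger

Peptide formulas are sums of residue compositions plus water over
{H, C, N, O, S}. Three mass scales are supported: monoisotopic (H 1.007825,
C 12, N 14.003074, O 15.994915, S 31.972071), average, and **nominal** —
the sum of integer element masses (H 1, C 12, N 14, O 16, S 32), *not* a
rounding of the monoisotopic mass, which matches integer "Da lighter"
bookkeeping exactly.

The Thr → Dmp pathway steps and their elemental deltas:

| step | delta | nominal |
|---|---|---|
| oxidative decarboxylation (Thr → methyl ketone) | −CH2O2 | −46 |
| transamination (ketone → primary amine) | +NH3 −O | +1 (net −45) |
| N,N-dimethylation (amine → Dmp) | +C2H4 | +28 (net −17) |
| Ser → Ala (per site) | −O | −16 |
| benzyl oxime (ketone derivatization) | +C7H7N | +105 |

Ordering constraints are enforced (transamination needs the ketone,
dimethylation the amine, oxime formation only the ketone state), Ser → Ala
is site-multiplied, and Ser → Ala is modelled purely as −O per site —
the D-configuration of the resulting Ala carries no mass and is annotation
only. `match_intermediate()` enumerates all states (pathway states ×
Ser → Ala counts) and ranks those within a tolerance of an observed singly
protonated m/z; only [M+H]+ is supported, reflecting the MALDI context.

```{r mass}
delta_nominal("oxidative_decarboxylation")
delta_nominal(c("oxidative_decarboxylation", "transamination"))
delta_nominal(c("oxidative_decarboxylation", "transamination", "dimethylation"))
```

## The synthetic generator and what it does (not) emulate

`simulate_daptides()` plants ground truth: each anchor gets a
single-contig cluster of seven annotated genes with the anchor in the
middle; 1–4 precursor ORFs (M + leader motif ELEAMEAP +
hydrophobic-biased core of 6–15 residues + invariant C-terminal Thr) and
two decoy short ORFs are reverse-translated (alphabetically first codon
per residue — determinism over codon-usage realism) and embedded
downstream of the anchor with an in-frame `TAATAA` guard immediately
upstream of each start, which guarantees the planted start is the longest
candidate for its stop codon and therefore survives dereplication; all
planted ORFs sit on the forward strand (minus-strand calling is exercised
by unit fixtures instead). Bitscores follow a two-component model: within
planted families N(120, 20), between families N(20, 10) present for only
0.5% of pairs (all-vs-all searches report hits for well under 1% of
unrelated pairs), truncated at zero, written in both directions with ±5%
multiplicative jitter to exercise the max-symmetrization rule, self-hits
included. Default family sizes are 40/35/30.

Stress variants (`stress_variants()`) document the levels up to which
recovery is asserted: `high_noise` (ten-fold denser between-family hits,
p = 0.05, drawn from N(15, 8)), `low_separation` (within-family scores
N(60, 20), so roughly a third of within edges fall below the initial
threshold and connectivity drops toward the gate), and `bridged` (families
60/50/40/15/15 with one planted 55-bit inter-family edge joining the two
smallest families). A single spurious bridge between two cohesive families
is *not* separable by this algorithm — the merged family's connectivity is
about 0.5, well above the 0.2 gate, and the precursor ratio still passes —
so the bridged scenario measures how much a realistic merge costs globally
(adjusted Rand index ≈ 0.96 with these sizes) rather than pretending the
method splits it. Genuine splitting is exercised separately by fixtures in
which a chain of small cliques holds connectivity at or below 0.2, where
escalation to t + 10 drops the bridges.

The generator emulates the statistical structure the thresholds rely on —
not real evolution: no codon-usage or GC bias, no paralogs, no partial
hits, no E-value model, no contamination. Recovery results on it validate
the algorithm's logic (gates, escalation, induced-subgraph restriction),
not performance on real genomes.

## Numerical and design choices

- Threshold comparisons keep hits **at** the threshold (strictly-below
  removed).
- All orderings (families, members, candidates) are deterministic with
  documented tie-breaks; reports are byte-reproducible for identical
  inputs and configs.
- The hemolysis utility normalizes A410 readings linearly between the DMSO
  (0%) and Triton X-100 (100%) controls and refuses an undefined
  normalization (equal controls).
- Problem sizes used in the shipped tests: planted recovery runs on the
  default 105-anchor configuration and its three stress variants;
  clustering is verified against a brute-force transitive-closure oracle
  exhaustively for all edge subsets on up to 5 nodes and on 300 random
  subsets each for 6–8 nodes, at three thresholds; termination and
  monotonicity on 100 random graphs. These sizes give full coverage of the
  branching behavior while keeping the suite fast.

## Limitations

- Single linkage can chain families through weak intermediates; the
  connectivity gate mitigates but does not eliminate this (see the bridged
  stress scenario).
- The ORF score is not a coding-potential model; on real genomes a trained
  gene caller will rank nested candidates better.
- Leader/core splitting by the positional Pro rule is a heuristic; prefer
  the motif rule when the class motif is known.
- The mass ledger covers elemental arithmetic only — no isotope envelopes,
  fragment ions, or spectrum parsing; absolute m/z values of tagged
  constructs depend on sequences not bundled here.
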