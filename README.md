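# rremine

Class-independent genome mining for RiPP (ribosomally synthesized and
post-translationally modified peptide) precursor families, guided by the
RiPP Recognition Element (RRE), plus the elemental mass ledger of the
daptide Thr → Dmp modification pathway.

## What it does, and for whom

Most RiPP genome mining starts from known modification enzymes, so it can
only rediscover known chemistry. `rremine` implements the orthogonal,
class-independent strategy: anchor on RRE-containing proteins, cluster them
into families by all-by-all bitscore similarity, harvest short open reading
frames (5–119 aa) from the ±8-gene neighborhoods of every anchor, and
recursively test each enzyme family — at escalating bitscore thresholds —
for a co-occurring family of mutually similar short ORFs. The package is for
natural-product bioinformaticians who have all-by-all BLAST/DIAMOND tables
and genome annotations and want reproducible, planted-truth-validated family
pairing rather than ad hoc scripts.

The core recursion, per RRE family at threshold *t* (defaults: t₀ = 50 bits
for enzymes, 10 bits for ORFs, minimum family size 30):

1. compute *enzyme connectivity* — qualifying within-family pairs divided by
   n(n−1)/2; if ≤ 0.2, re-cluster at t + 10 and recurse on each subfamily;
2. otherwise find the largest precursor family: the largest connected
   component of the ORF similarity graph restricted to ORFs hosted in the
   family's neighborhoods;
3. accept the pairing if the precursor family's size is within an order of
   magnitude of the enzyme family's size (ratio in [0.1, 10]); otherwise
   re-enter at t + 10.

The mass ledger tracks the daptide pathway on elemental formulas:
oxidative decarboxylation of the C-terminal Thr (−CH₂O₂, −46 Da nominal),
transamination (+NH₃ −O, net −45), and N,N-dimethylation (+C₂H₄, net −17),
plus Ser → Ala (−O per site) and benzyl-oxime derivatization (+C₇H₇N, +105).

## Worked example

Generate a synthetic dataset with planted truth (three RRE families of
40/35/30 anchors, each cluster encoding 1–4 precursors with leader motif
ELEAMEAP and an invariant C-terminal Thr) and mine it:

```r
library(rremine)

b <- simulate_daptides(sim_config(seed = 42))
b
#> sim_bundle: 105 anchors in 3 families; 471 planted ORFs ( 261 precursors );
#>   3765 RRE hit rows, 24609 ORF hit rows

res <- mine_bundle(b)
res
#> paired_families: 3 accepted pairing(s)
#>   [1] 40 enzymes (t=50, connectivity 1.00) <-> 143 precursor ORFs; history: 50
#>   [2] 35 enzymes (t=50, connectivity 1.00) <-> 104 precursor ORFs; history: 50
#>   [3] 30 enzymes (t=50, connectivity 1.00) <-> 88 precursor ORFs; history: 50
```

All three planted families are recovered intact at the first threshold
(connectivity 1.00 > 0.2; precursor/enzyme ratios 3.6, 3.0, 2.9 all inside
[0.1, 10]); the precursor components exceed the planted precursor counts
because decoy ORFs with sparse low-bitscore hits attach to the components,
exactly as hypothetical ORFs do in real neighborhoods. Against the planted
labels the recovered partition has adjusted Rand index 1.0.

Mass ledger on a daptide-like precursor (leader MELEAMEAP, core VVAT):

```r
f0 <- peptide_formula("MELEAMEAPVVAT")
protonated_mz(f0)                        # 1390.659  unmodified [M+H]+
f3 <- apply_steps(f0, c("oxidative_decarboxylation", "transamination",
                        "dimethylation"), sequence = "MELEAMEAPVVAT")
protonated_mz(f3)                        # 1373.717  Dmp [M+H]+
formula_mass(f3, "nominal") - formula_mass(f0, "nominal")   # -17

split_leader_core("MELEAMEAPVVAT", motif = "ELExMEAP")
#>     aa_sequence    leader core split_ok
#> 1 MELEAMEAPVVAT MELEAMEAP VVAT     TRUE

match_intermediate(protonated_mz(f0) - 46.005, "MELEAMEAPVVAT", tolerance = 0.5)
#>    state       mz   error
#> 1 ketone 1344.654 0.00048
```

The −17 Da net loss is the class-diagnostic signature: the three-step
pathway converts the C-terminal Thr into Dmp. An observed ion 46 Da below
the unmodified peptide matches the ketone intermediate.

A file-based end-to-end run (`write_bundle()` then `run_mine()` with a YAML
or list config) and a thin command-line wrapper
(`inst/scripts/rremine.R` with subcommands `simulate`, `mine`, `cluster`,
`orfs`, `mass`, `hemolysis`) are also provided.

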