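# bacafinder

Identification and classification of **SbmA/BacA** and **BclA**
antimicrobial-peptide-transporter homologues across bacterial proteomes.

Several pathogens and nitrogen-fixing legume symbionts depend on the
inner-membrane peptide transporters SbmA/BacA (proton-motive-force driven) or
BclA (ATP-driven, "BacA-like") to survive exposure to host antimicrobial
peptides such as the legume NCR peptides. Separating genuine members of
these two families from the related ExsE and *Bradyrhizobium*-type families —
and from spurious long-branch matches — is unreliable from any single
signal. `bacafinder` is for comparative genomicists who want that
classification reproducibly: it reconciles **three evidence streams** per
candidate protein and applies an explicit, auditable rule list.

1. **Profile-HMM annotation** — candidates are mined from proteomes with a
   superfamily profile HMM (forward-algorithm log-odds scores in bits,
   E-values from an explicit Gumbel null calibration:
   `E(s) = N [1 − exp(−e^{−λ(s−μ)})]`), then labelled by their top-scoring
   family model.
2. **Sequence similarity network (SSN)** — all-vs-all Smith–Waterman
   (BLOSUM62, affine gaps 11/1) with Karlin–Altschul statistics
   (λ = 0.267, K = 0.041): `bits = (λS − ln K)/ln 2`, `E = mn·2^−bits`, and
   edges where the alignment score `AS = −log10 E ≥ 115` (≈ ≥35 % identity
   for full-length transporters). Connected components are the clusters.
3. **Protein phylogeny** — candidates aligned to the mining profile,
   gap-rich columns trimmed, neighbour joining on Poisson-corrected
   distances (`d = −ln(1−p)`, `p` capped at 0.95), rooted on the ExsE/Brady
   outgroup; clades A (outgroup), C (BacA+BclA core) and B (the rest) are
   delimited from seeded MRCAs.

A strict-precedence rule engine (R1–R7) merges the streams into final
`BacA` / `BclA` / `excluded` calls with recorded reasons, and distribution
summaries report per-species presence/absence and per-taxon percentages.
A synthetic benchmark module simulates species trees, gene gain/loss/HGT,
profile-emitted family sequences and decoys with known truth, so the whole
pipeline is testable offline.

## Worked example

```r
library(bacafinder)

bm  <- generate_benchmark(sim_config(seed = 1))   # 60 species, 5 families,
                                                  # 20 decoys/species
res <- classify_transporters(bm$proteins, bm$species, bm$seeds,
                             classify_config(seed = 2024))
print(res)
#> Transporter classification
#>   candidates: 65
#>   final SbmA/BacA: 9
#>   final BclA:      38
#>   excluded:        18
#>   species with either transporter: 45 of 60

score_recovery(res, bm$truth)$macro_f1
#> [1] 1
```

Of 1,265 simulated proteins, the superfamily model mines 65 candidates (all
true family members, no decoys). The 9 SbmA/BacA calls are the pure,
monophyletic BacA component (rule R3); the 38 BclA calls are the BclA and
*Mycobacterium*-BacA components in clade C (rule R4 — M-BacA is folded into
BclA, mirroring its reclassification); the 18 exclusions are the ExsE/Brady
outgroup clade. `summary(res)` adds per-taxon counts;
`as.data.frame(res)` gives the full per-protein evidence + call table;
`plot(res)` draws the candidate tree and the SSN. Each stage is also
exported on its own (`build_profile`, `search_proteome`, `annotate_top_hit`,
`all_vs_all`, `build_network`, `align_to_profile`, `nj_tree`,
`assign_clades`, `apply_rules`, ...), reading and writing the usual formats
(FASTA, Stockholm, Newick, TSV edge lists, iTOL annotations).

## Documentation

The methods vignette (`vignettes/transporter-classification.Rmd`) describes
the model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic benchmark does and does not emulate, and the
package's numerical conventions and limitations.
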