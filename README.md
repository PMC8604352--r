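# dnakscan

Physics-based prediction of where, and in which direction, the *E. coli*
Hsp70 chaperone **DnaK** binds a protein sequence.

DnaK patrols the proteome by binding short, hydrophobic segments of client
proteins — promiscuously enough to serve thousands of clients, selectively
enough to avoid folded surfaces. Structures of peptide-bound complexes show
that exactly five consecutive substrate residues occupy five nearly
independent sites on the substrate-binding cleft (labeled −2, −1, 0, +1,
+2, with site 0 a deep hydrophobic pocket), and that the backbone forms the
same hydrogen bonds whether the peptide runs N→C ("forward") or C→N
("reverse"). Side-chain energetics therefore decide three things this
package predicts for every five-residue window of an input sequence:

* whether it binds (a score in kcal/mol),
* the **register** — which residue sits in each of the five sites,
* the **orientation** — forward or reverse.

## The model

A window is scored with a linear model over a 5 × 20 × 6 basis set of mean
interaction energies derived from restrained molecular-dynamics
simulations of each amino acid at each site:

```
E(five-mer) = w_cp · E_cp + E_reverse + Σ_site w_site Σ_term w_term · E[site, res, term]
```

The six terms are van der Waals, electrostatics, backbone strain,
desolvation of the substrate side chain, desolvation of the site, and a
rotamer-propensity penalty; `E_cp` is the window's mean coil propensity and
`E_reverse` a scalar penalty for reverse binding (zero in the default
weights). The double sum is pre-combined into a 5 × 20 position-specific
scoring matrix (PSSM), so scoring is five lookups. Term weights are trained
against classed peptide-array data by Monte-Carlo maximization of a
class-separation objective; site weights encode the known relative
importance of the sites (site 0 dominates). The packaged defaults are the
published values. Lower scores mean stronger predicted binding; orientation
calls whose forward/reverse gap is within kT = 0.6 kcal/mol are reported
ambiguous.

The package also implements the closed-form energy-term formulas
(SASA-fraction desolvation, −kT·ln(P_r/P_0) rotamer propensity, coil
propensity) and the trajectory-aggregation rules used to assemble a basis
set from per-frame simulation records, ROC/PR evaluation against peptide
arrays, structural benchmarking of register/orientation calls, strict
readers/writers for every on-disk format, and a seeded synthetic-fixture
generator with planted ground truth so everything runs and tests offline.

## Worked example

```r
library(dnakscan)

# a seeded synthetic scoring model with planted ground truth
spec  <- fixture_spec(seed = 42)
truth <- gen_pssm(spec)          # $pssm (5 x 20), $terms (5 x 20 x 6)

scan <- scan_sequence("GKTLFIS", truth$pssm, id = "demo")
print(scan)
#> Scan of demo (7 residues): 6 scored window/orientation pairs
#>   best_forward: TLFIS (start 2) -4.885 kcal/mol
#>   best_reverse: KTLFI (start 1) -8.276 kcal/mol

po <- predict_orientation("GKTLFIS", truth$pssm)
sprintf("call: %s  delta: %.3f kcal/mol", po$call, po$delta)
#> call: reverse  delta: 3.391 kcal/mol
print(po$best_reverse)
#> KTLFI (reverse, start 1): -8.276 kcal/mol
#>   sites: -2:I -1.73 | -1:F -1.46 | 0:L -5.40 | +1:T 0.19 | +2:K 0.12
```

Reading this: of the six window/orientation pairs in GKTLFIS, the best is
KTLFI bound C→N (reverse), 3.4 kcal/mol below the best forward window —
an unambiguous reverse call. The per-site breakdown shows why: the reverse
register places all three hydrophobics (I, F, L) in the high-weight sites
−2, −1 and 0, with leucine buried in the central pocket at −5.40 kcal/mol.

Training and evaluation on a synthetic array:

```r
arr   <- gen_peptide_array(spec, truth$pssm)        # classed 13-mers
split <- split_dataset(arr, 0.8, seed = 42)
fit   <- monte_carlo_search(truth$terms, split$train,
                            training_config(steps = 1e5, seed = 42))
fitted <- combine_terms(truth$terms, fit$weights)
```

## Command line

A thin CLI over the same functions lives at `inst/cli/dnakscan.R`
(located via `system.file("cli", "dnakscan.R", package = "dnakscan")`):

```sh
Rscript dnakscan.R synth --seed 1 --out-dir fixtures
Rscript dnakscan.R train --array fixtures/array.tsv --terms fixtures/terms.tsv \
    --seed 1 --steps 100000 --out-weights weights.json
Rscript dnakscan.R score --fasta proteins.fasta --pssm fixtures/pssm.tsv \
    --weights weights.json --out windows.tsv --summary summary.tsv --reverse-margin 3
Rscript dnakscan.R bench --benchmark fixtures/benchmark.tsv \
    --pssm fixtures/pssm.tsv --mode register --out report
```

## File formats

Plain TSV/CSV with headers throughout (delimiter sniffed): a 5-row × 20-column
PSSM table, a tidy `site/residue/term/value/sem` basis-set table, a
`sequence/label` peptide-array table, a `sequence/orientation/core/offset`
benchmark table, per-frame energy traces, FASTA input, and flat JSON/YAML
weight configs. Readers validate schemas, name offending cells, and log
every excluded row with its reason (`dataset_provenance()`).
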