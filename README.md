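# famdev — residue-level biophysical deviation of a protein from its family

Small sets of substitutions can break a protein's function even when the
overall sequence stays family-like. famdev is for structural
bioinformaticians and protein scientists who have a reference protein (for
example a dysfunctional mutant), an alignment of its functional family, and
optionally a structure of a functional member, and who want to know *where*
and *in what biophysical respect* the reference departs from the family.

## The score

For an amino-acid index scale *p* (hydrophobicity, helix propensity, ...)
and aligned position *r*, famdev computes the deviation score

```
            i_ref(p, r) − mean_fam(p, r)
c(p, r) = ─────────────────────────────────
                 sigma_fam(p, r)
```

the reference residue's index value minus the family mean at that column,
divided by the family standard deviation. Dividing by the spread weights
deviations by conservation: the same difference scores higher where the
family is nearly invariant. Because hundreds of indices exist, famdev can
collapse each of six characteristic classes (alpha/turn propensity, beta
propensity, hydrophobicity, composition, physicochemical, other) to a
representative scale — the first principal axis of the class's standardized
scales in 20-dimensional residue space — and score those six instead.

Around the score sit the supporting artifacts: capped score histograms,
per-position stacked bars, per-characteristic conservation rows, Cα
distance matrices, focus-region proximity histograms and bundled chords,
all exported as one schema-described JSON bundle
(`inst/schema/vizbundle.schema.json`) for any front-end or notebook.

## Worked example

Synthetic study conditions: a 248-residue reference in a family of 200
homologues, with a 7-residue anomalous region implanted at positions
150–156; six classes of five correlated synthetic index scales.

```r
library(famdev)
spec   <- family_spec(seed = 7)            # L = 248, N = 200, anomaly 150:156
scales <- synth_scales(5, seed = 7)
fam    <- synth_family(spec, scales)
ca     <- crop_to_reference(fam$alignment)
m      <- build_score_matrix(ca, scales, mode = "pc1")
m
#> <c_score_matrix> 6 characteristic(s) x 248 positions (ref 'REF')
#>  characteristics: PC1_alpha_turn_propensity, PC1_beta_propensity, PC1_hydrophobicity, PC1_composition, PC1_physicochemical, PC1_other

round(sort(total_deviation(m), decreasing = TRUE)[1:8], 1)
#>  153  154  155  151  152  150  156   19
#> 21.6 21.2 19.3 18.5 12.5 12.4  9.4  4.4
```

All seven implanted positions (150–156) lead the ranking by summed |c|
over the six class representatives; the first background position (19)
trails far behind. The class representatives earn their keep:

```r
round(sapply(m$scales_used, `[[`, "variance_explained"), 2)
#> [1] 0.87 0.74 0.76 0.81 0.82 0.70
```

each first principal axis explains 70–87% of its class's variance. Adding
a structure links the anomaly to its spatial neighbourhood — residues
within the default 0–8 Å contact range of the focus region, bundled into
chords (rank 0 = closest):

```r
pdb <- tempfile(fileext = ".pdb")
writeLines(synth_pdb(248, seed = 7, seq = reference_sequence(ca)), pdb)
b <- run_deviation_analysis(fam$alignment, scales = scales, class_map = FALSE,
                            pdb = pdb, focus = c(150, 156), out = "bundle.json")
as.data.frame(b$chords$bundles)
#>   target_start target_end min_distance brightness_rank
#> 1          126        127     6.099565               3
#> 2          148        149     3.800484               1
#> 3          157        162     3.039531               0
#> 4          165        167     4.042924               2
```

`bundle.json` now holds the full visualization bundle (histograms, stacks,
conservation, chords, proximity histogram, focus metadata); `plot` writes
a static PNG overview. On real data, replace the synthetic pieces with an
aligned FASTA/Clustal file, an AAindex1 flat file plus class TSV, and a
PDB structure:

```sh
famdev run --msa family.fasta --ref-id dprot --aaindex aaindex1.txt \
           --classes classes.tsv --pdb model.pdb --focus 150:156 \
           --mode pc1 --out bundle.json --plot overview.png
```

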