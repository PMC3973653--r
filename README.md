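# canesrna

Small-RNA profiling, rule-based miRNA target prediction and secondary
siRNA discovery for plant drought studies.

## The problem

Bulk small-RNA sequencing of stressed plants — here the motivating case is
sugarcane under water depletion, profiled as pooled tolerant/sensitive
leaf libraries at 0 h and 24 h of stress — yields millions of 18–28 nt
reads mixing conserved miRNAs, repeat-derived siRNAs, degradation products
and t/rRNA fragments. In a polyploid crop without a reference genome, the
analysis rests on a chain of explicit, reproducible rules rather than on
genome alignment. `canesrna` implements that chain as a tested R pipeline:

1. **Preprocessing** — 3′ adapter and N trimming, an 18–28 nt length
   window, a low-complexity filter (≥ 3 distinct bases), sense+antisense
   exact removal of t/rRNA contaminants, and collapsing to unique
   sequences with counts.
2. **Conserved-miRNA profiling** — ungapped end-to-end matching of reads
   to a mature-miRNA reference (miRBase-style FASTA) with ≤ 3 Hamming
   mismatches, and an "electronic northern": per-library raw counts and
   RPM (`count × 10⁶ / total filtered reads`).
3. **Differential expression** — per-sequence two-sided Fisher exact tests
   between library pairs on raw counts with per-contrast Bonferroni
   control (`p_adj = min(1, p·m)`, significant at `p_adj < 0.05`), plus a
   concordance classifier that asks whether pooled libraries and
   individual genotypes call the same direction of change (comparison 1:
   genotype contrast; comparison 2: stress response per genotype).
4. **Target prediction** — ungapped antiparallel miRNA/target duplexes
   scored positionally from the miRNA 5′ end, G:U wobbles weighing 0.5
   mismatches: total ≤ 4.0; no run of > 2 adjacent mismatch positions; no
   adjacent mismatches within positions 2–12; positions 10–11 perfectly
   paired; ≤ 2.5 weighted mismatches in positions 1–12; and duplex MFE
   ≥ 74 % of the perfect-complement MFE, from an embedded nearest-neighbor
   stacking table. The cleavage site is the target base paired to miRNA
   position 10.
5. **Secondary siRNA discovery** — 22-nt miRNAs are selected as triggers;
   their predicted targets are scanned against the non-miRNA read pool for
   exact ungapped matches ≥ 18 nt on either strand; 1–2 nt end variants
   are merged under a maximal-count representative; candidates need > 50
   raw reads per library to count as present (core = present everywhere);
   a candidate is cleavage-concordant when one alignment end falls within
   ±1 nt of the predicted cleavage site.
6. **siRNA clusters** — exact full-length placement of the non-miRNA pool
   on repeat/EST references (multi-mappers weighted 1/k), interval
   clustering with a 100 nt merge gap, and per-library category fractions
   (LTR-gypsy and other retrotransposons, transposons, MITEs,
   centromere/telomere/ribosomal, TC ESTs, unannotated repeats,
   unannotated siRNA clusters) with per-category length histograms.

A deterministic synthetic-data generator (`synthetic_truth()`,
`generate_libraries()`) plants all of this structure — abundance designs
with known fold changes, a 5′-U bias, 21/22/24 nt length peaks,
contaminants, decoy target sites violating single rules, a
cleavage-anchored ta-siRNA, and a repeat-category mixture with an
LTR-gypsy 24→21 nt size shift under stress — so every stage is testable
without downloads.

## Worked example

```r
library(canesrna)

truth <- synthetic_truth(seed = 42, n_reads = 1e5)   # 4 leaf libraries
gen   <- generate_libraries(truth, dir = "demo")
inputs <- list(libraries  = unlist(gen$files[truth$libraries$id]),
               mirna_ref  = gen$files$mirna_ref,
               contaminants = gen$files$contaminants,
               transcripts  = gen$files$transcripts,
               repeats      = gen$files$repeats,
               repeat_annotation = gen$files$repeat_annotation,
               est_ids = truth$est_ids)
res <- run_pipeline(inputs, outdir = "demo_out")
res$profile
#> miRNA profile: 13 matched unique sequences, 11 families, 1 star sequences
#> libraries: T0h, T24h, S0h, S24h
```

The electronic northern carries raw counts and RPM per library:

```r
head(res$profile$expression[, c("mirna_id", "T0h", "rpm_T0h",
                                "T24h", "rpm_T24h")], 4)
#>    mirna_id  T0h  rpm_T0h T24h rpm_T24h
#> 1  miR156 I 1165 12665.66 1251 13588.96
#> 2  miR159 I 1838 19982.39 3684 40017.38
#> 3 miR159 II  171  1859.08  198  2150.77
#> 4  miR164 I 1954 21243.52 1000 10862.48
```

miR159's planted two-fold induction and miR164's two-fold repression are
called significantly by the Fisher test after Bonferroni control
(`p_adj` 2.1e-141 and 2.7e-70 in the T0h–T24h contrast). Target
prediction recovers the planted sites only, with the 22-nt trigger's site
on the ta-siRNA source transcript:

```r
res$sites[, c("mirna_id", "transcript", "start", "end", "mfe_ratio",
              "cleavage_position")]
#>    mirna_id   transcript start end mfe_ratio cleavage_position
#> 1  miR159 I     TC800002   211 230 1.0000000               221
#> 2 miR159 II     TC800002   211 230 0.8959031               221
#> 3  miR167 I TAS_TC900001   301 322 1.0000000               313
#> 4  miR398 I     TC800003   401 421 1.0000000               412
```

and siRNA discovery finds the planted cleavage-anchored candidate as the
only core (present-in-all-libraries) sequence, its 5′ end 1 nt from the
cleavage site at 313:

```r
res$sirna[, c("sequence", "coordinates", "trigger", "concordant", "core")]
#>                sequence coordinates  trigger concordant  core
#> 4 GCAGCTTCATGTGAGCGCGAA     314-334 miR167 I       TRUE  TRUE
#> 1 AAGACGGGACCACTAATATTT     501-521 miR167 I      FALSE FALSE
#> 3 GATGGGTGGCCTTGACGCTAC     621-601 miR167 I      FALSE FALSE
#> 2 GAATCAACTTGGAAGTCTCAC     651-671 miR167 I      FALSE FALSE
```

(Antisense alignments print high→low, e.g. `621-601`.) Every stage also
writes its TSVs (`filter_report.tsv`, `electronic_northern.tsv`,
`regulation_calls.tsv`, `target_sites.tsv`, `sirna_candidates.tsv`,
`cluster_table.tsv`, `category_fractions.tsv`) plus a JSON run manifest
under `demo_out/`. A command-line wrapper lives at
`inst/cli/run-pipeline.R`.

## The concordance classifier in brief

For each miRNA, comparison 1 is `+` when the pooled genotype ratio under
stress (T24h/S24h) and the individual-cultivar ratio point the same way;
comparison 2 is `+` when, in at least one genotype, the individual
cultivar's ratio to the pooled control agrees in direction with the
stressed pool's ratio to the same control. Zero counts take a one-read
pseudocount before ratio formation. The classes are `both`,
`comp1_only`, `comp2_only`, `neither`.
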