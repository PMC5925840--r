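# retentionshift

Position-specific intron retention analysis coupled to histone-mark
redistribution, for transcriptomics researchers studying how
co-transcriptional chromatin marks (H3K36me2/me3) shape splicing outcomes.

Intron retention (IR) is the predominant form of alternative splicing in
plants. Given spliced RNA-seq alignments for two conditions and ChIP-seq
libraries (with input controls) for one or more histone marks, the package
answers three questions:

1. **Which introns change retention, and where do they sit along the gene
   body?** Retention is quantified per intron by the intron retention index

   *IRI = FPKM(intron) / mean(FPKM(flanking exons))*,

   computed on non-overlapping intron/exon units (intron bases overlapping
   any annotated exon are subtracted, and reciprocally). Differential events
   are twofold IRI changes passing support filters (≥ 3 supporting reads,
   length coverage ≥ 80%, host gene ≥ 1 FPKM, flank exons > 1 FPKM); the
   positions of up- vs down-regulated events along the TSS→TTS axis are
   compared with a two-sample Kolmogorov–Smirnov test.
2. **Which genes redistribute a histone mark toward the promoter?** Each
   gene is summarised as 500 metagene bins (100 upstream + 300 body + 100
   downstream over ±2 kb), normalized to 10 M reads and input-calibrated. A
   gene is *shifted* when ≥ 30% of front-half body bins (45/150) of the
   mutant−WT difference are positive and ≥ 30% of rear-half bins negative;
   genes are typed I–IV by which of two marks shift.
3. **Which retained-intron transcripts are NMD candidates?** An ORF is
   predicted from the annotated start codon; a stop > 50 nt upstream of the
   last exon–exon junction is a premature termination codon, and PTC
   transcripts with > 2-fold abundance increase (p < 0.05) are flagged.

A first-class synthetic-data module generates seeded annotations, spliced
RNA-seq with programmable per-intron retention and 5′/3′ positional bias,
and ChIP libraries with flat / globally-reduced / promoter-shifted
profiles, so the full pipeline runs and is tested without any external
data.

## Worked example

```r
library(retentionshift)

sc  <- simulation_scenario(seed = 7, n_genes = 30,
                           rna_depth = 2e4, chip_depth = 1e5)
cfg <- pipeline_config("example_run", seed = 7, scenario = sc)
res <- run_pipeline(cfg)

table(res$diff_ir$direction)
res$ks
```

prints

```
     down unchanged        up
       27        80        27

Median gene-body position, up vs down: 0.26 vs 0.73
KS test: D = 0.741 , p = 1.82e-07
```

Of 134 simulated introns, 27 are called retention-up and 27 retention-down
(the generator planted 27 of each); up events sit in the 5′ quarter of the
gene body (median position 0.26) and down events in the 3′ quarter (0.73),
and the KS test rejects equal positional distributions at p ≈ 2 × 10⁻⁷ —
the position-specific coupling the pipeline is built to detect. The
histone-mark side of the same run classifies genes by which marks shift
toward the promoter; against the planted truth:

```
      planted
called  I II III IV
   I    7  0   0  0
   II   0  7   0  0
   III  0  0   1  0
   IV   0  0   0 15
```

All 30 genes are typed correctly (I: me2 shift only, II: me3 only,
III: both, IV: neither). `example_run/` contains every stage's TSV
(per-replicate IRI tables, differential calls, gene classes, KS summary,
difference-matrix orderings, shift types, truth tables) plus a JSON run
manifest; re-running with the same seed reproduces the tables byte for
byte.

Lower-level entry points mirror the pipeline stages: `parse_annotation()`,
`build_units()`, `read_alignments()`, `quantify_sample()`,
`call_differential_ir()`, `ks_location_test()`, `bin_coverage()`,
`diff_matrix()`, `call_shift()`, `classify_shift_types()`,
`predict_orf()`, `classify_ptc()`, `call_nmd_targets()`,
`intron_features()`. A command-line wrapper with subcommands
(`simulate`, `units`, `quantify`, `run`) is installed at
`inst/scripts/retentionshift-cli.R`.

## Further reading

`vignettes/methods.Rmd` documents the statistical model, every tunable
threshold with its default and rationale, what the synthetic generator
does and does not emulate, and known limitations.
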