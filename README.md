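# operonterm

Operon architecture and internal transcription termination analysis from
multi-layer transcriptomic evidence.

## What it is for

In prokaryotic genomes, many operons express their genes at markedly
different levels because a terminator inside the operon — in an intergenic
region between two operon genes — stops part of the transcribing
polymerases. `operonterm` is for genomicists who have single-base TSS maps
(dRNA-seq-type), single-base TTS maps (Term-seq-type), full-length transcript
reads (PacBio-type, as genomic intervals) and strand-specific coverage
(Illumina-type) for a prokaryote, and want to:

1. assemble transcription units (TUs) and operons from that evidence,
2. find internal operon TSSs/TTSs (ioTSS/ioTTS) and type the operons
   (I: no internal sites, II: ≥1 ioTTS, III: ≥1 ioTSS, IV: both),
3. quantify every internal terminator, and
4. profile the polyU terminator motif around the termination sites.

The statistics, per ioTTS with flanking-gene abundances A_up and A_down
(replicate-mean per-base coverage):

    TDER = A_up / A_down                  (differential expression ratio;
                                           tiers: >=2 high, [1.5,2) mid, <1.5 low)
    TTE  = 1 - 1/TDER                     (termination efficacy: the fraction of
                                           transcription events stopped at the site)
    dependency = TDER_depletion / TDER_reference
                                          (< 1: termination depends on the
                                           depleted termination factor)

plus a Welch t-test on log2 replicate abundances. Under the read-through
model a terminator of efficiency ε gives TDER = 1/(1−ε), so TTE estimates ε;
with every ε scaled by f in the depletion condition, the expected dependency
is (1−ε)/(1−fε).

A first-class synthetic-data module generates all evidence layers with known
per-terminator ε (polyU tracts embedded in the genome sequence, Poisson
noise, replicates, a depletion condition), so the entire pipeline is
verifiable by parameter recovery — see the methods vignette
(`vignettes/operon-termination.Rmd`) for the generative model and every
default.

## Worked example

```r
library(operonterm)

cfg <- simulation_config(seed = 7,
                         n_operons_by_type = c(I = 10, II = 10, III = 10, IV = 10))
run <- run_pipeline(cfg, "run_out")
summary(run$opset)
```

```
Transcription units: 40 (40 operons, 0 single-gene TUs)
  Type I     10 (25%)
  Type II    10 (25%)
  Type III   10 (25%)
  Type IV    10 (25%)
  with ioTTS: 20 (50%); with ioTSS: 20 (50%)
  median operon length: 4192 nt
```

All 40 simulated operons are recovered with their architecture types; half
contain an internal terminator (types II and IV). The per-ioTTS table
(`run$tder`, written to `run_out/tder.tsv`):

```r
head(run$tder[run$tder$condition == "wt", ])
```

```
      operon_id iotts_position tder tier   tte p_value
   OP_chr_100_+            747 1.65  mid 0.396 2.9e-08
  OP_chr_2199_-           4703 2.52 high 0.603 1.1e-08
 OP_chr_13082_+          13804 3.27 high 0.694 1.4e-05
 OP_chr_33594_-          35568 2.91 high 0.656 1.2e-06
```

The first terminator stops ~40% of transcription events (TTE 0.396, TDER
1.65, mid tier); the next three are high-tier terminators stopping 60–69%.
In the depletion condition the same sites show TDERs shrunk toward 1 and
dependencies well below 1 (e.g. 0.565, 0.468), i.e. factor-dependent
termination. Scoring against the generative truth:

```r
compare_to_truth(run)
```

```
<recovery_report>
  operon precision 1.0000, recall 1.0000, type accuracy 1.0000
  terminator recall 1.0000; TTE MAE 0.0012 (max |err| 0.0034)
  dependency MAE 0.0021 over 20 terminators
```

Measured TTE matches the true ε to ~0.001 under Poisson noise at coverage
depth 100. The classic ribosomal-protein/RNA-polymerase worked example — a
14.3-fold protein ratio across an internal terminator — is one line:

```r
round(compute_tder(0.86, 0.06), 1)
#> 14.3
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch on a seeded
40-operon synthetic evidence set (simulate → call operons → termination
statistics → motif profile), prints the operon summary and the recovery
report, and writes the results JSON to `--out`.
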