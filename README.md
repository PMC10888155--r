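# dardn

Dual-kernel residual convolutional networks with DeepLIFT attribution for
long DNA sequences.

## What this is for

Cancer cells acquire CTCF binding sites ("gained" sites) that normal
cells lack, and the oncogenic transcription factors cooperating with them
bind at unknown — often distal — positions within the surrounding
kilobases.  Standard motif search over 10-kb windows without localization
fails.  `dardn` is for regulatory-genomics analysts who have site lists
(gained vs. constitutive CTCF centers, BED format) and a genome, and want
candidate transcription-factor subsequences anywhere in the window:

1. a **classifier** — an ensemble of two convolutional branches with
   kernel sizes 4 and 8 bp and residual connections, over one-hot
   `4 × L` input, global average pooling and a dense head producing two
   logits (o1 constitutive, o2 gained), trained with binary cross-entropy

       BCE = −(1/N) Σᵢ yᵢ·log(pᵢ) + (1−yᵢ)·log(1−pᵢ)

   and evaluated with the Matthews correlation coefficient

       MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN));

2. an **attribution engine** — DeepLIFT (Rescale rule), implemented from
   scratch for this architecture, which decomposes o2(input) −
   o2(reference) into per-base contribution scores against a reference
   profile averaged over a sampled 80% of constitutive windows, then
   gates each position to its observed nucleotide;

3. **subsequence selection** — sliding-window means over the gated
   scores (w = 20, stride 1, L − w + 1 windows), top-1000 positive
   windows exported as FASTA/BED ready for `findMotifsGenome.pl -size
   200`, plus centered-peak localization, PWM/consensus logos, distance
   distributions and enrichment-rank utilities.

A motif-insertion simulation (scrub `CCTGGGAA` everywhere, re-insert it
at 10 known positions in 33% of sequences) validates the whole chain
end-to-end with retained ground truth.

## Worked example

```r
library(dardn)

report <- run_simulation_experiment(
  simulation_config(n_sequences = 3000, L = 1000),
  seed = 1)
print(report)
#> simulation experiment: 2400 train / 300 val / 300 test records
#> hold-out accuracy 100.0%  MCC 1.000  (TP 99 TN 201 FP 0 FN 0)
#> localization: mean 9.9 / min 9 of top-10 peaks on true insertions (99 positive records)
#> peak-slice consensus: AAAAAACCCTGGGAAACACGG
```

Reading the output: every one of the 300 hold-out sequences is classified
correctly (99 motif-carrying positives, 201 negatives); for each positive
hold-out record, at least 9 of the 10 top-scoring non-overlapping
attribution peaks fall on true insertion sites (9.9 on average); and the
consensus of the position weight matrix built from 21-bp slices around
each record's highest peak contains the inserted motif `CCTGGGAA`
exactly — the model found the planted signal, and the attribution
localized it.

On real data the same chain runs from site lists:

```r
report <- run_discovery("hg38.fa", "gained.bed", "constitutive.bed",
                        L = 10000, out_dir = "out/", seed = 7)
# out/selected.fasta, out/selected.bed, out/run_homer.sh, metrics.tsv ...
```

A thin CLI wraps the same drivers: `exec/dardn simulate|run-sim|run-discovery ...`.

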