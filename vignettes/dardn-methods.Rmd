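---
title: "Classifying CTCF-centered DNA windows and discovering regulatory motifs with dardn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CTCF-centered DNA windows and discovering regulatory motifs with dardn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dardn)
```

## The problem

CCCTC-binding factor (CTCF) anchors chromatin loops, and cancer cells
acquire binding sites ("gained" sites) that normal cells lack.  The
oncogenic transcription factors that cooperate with these gained sites
bind at unknown distances — possibly kilobases away — so conventional
motif search over multi-kilobase windows fails: the search space is huge,
there is no localization signal, and gained sites are rare relative to the
~22,000 constitutive sites conserved across cell types.

`dardn` attacks this in two stages.  A convolutional classifier learns to
separate long windows centered on gained sites (label 1) from windows
centered on constitutive sites (label 0) using sequence alone.  An
attribution engine then asks the trained model *which bases* pushed a
window toward the gained class, and sliding-window selection turns those
per-base scores into short candidate subsequences anywhere in the window,
suitable as input to motif-enrichment tools.

## Data representation and augmentation

Windows of length $L$ bp (0-based half-open, `[center - L/2, center +
L/2)`) are one-hot encoded into $4 \times L$ matrices with channel order
A, C, G, T; ambiguous bases become all-zero columns, so each column sums
to 1 for an observed base and 0 for `N`.  Windows with more than 10%
`N` are dropped with a warning.

Gained sites are heavily outnumbered, so they are augmented six-fold: the
original window, windows re-extracted after shifting the center left and
right by magnitudes drawn uniformly from 1–5 bp (one draw per direction
per site), and the reverse complements of all three.  Negatives are not
augmented.  Splits are assembled *by site*, not by record: every
augmented variant of a site lands in the same train/validation/test
partition, since shifted copies differ by a few base pairs and would
otherwise leak between training and evaluation.

## The classifier

Two convolutional branches process the same input in parallel, with
initial kernel sizes 4 and 8 bp: 8 spans a full motif consensus of typical
length (such as RBPJ's `CCTGGGAA`), 4 its shorter core fragments.  Each
branch applies two same-padded convolutions (32 channels, ReLU) and
carries a residual connection from the branch input, projected by a
width-1 convolution, onto the pre-activation of the second ReLU,
preserving raw-sequence signal through depth.  Branch outputs are
globally average-pooled to fixed-size embeddings — making the parameter
count independent of $L$ — concatenated, and passed through one dense
hidden layer (width 64) to two logits, $o_1$ (constitutive) and $o_2$
(gained).  The gained-site probability is the softmax of the pair taken
at $o_2$, thresholded at 0.5; how the two logits map to a probability is
a design choice recorded in the model configuration (a two-sigmoid head
would be the alternative).

Average pooling is used everywhere deliberately: it is a linear map, so
the attribution pass (below) treats it exactly, with no pooling-specific
rule.

Training minimizes binary cross-entropy
$-\tfrac{1}{N}\sum_i y_i \log p_i + (1-y_i)\log(1-p_i)$
with Adam (learning rate $10^{-3}$, mini-batches of 16, decoupled weight
decay $10^{-3}$ on weight matrices).  Mini-batches are plain shuffled by
default: class imbalance in the intended workflow is handled upstream by
augmenting the gained sites, and training at the natural class prior
keeps the fixed 0.5 decision threshold calibrated — oversampling the
minority (the `balanced_batches` option) trains at an artificial 50/50
prior and systematically inflates borderline negatives into false
positives at evaluation time.  Balanced batches and per-sample loss
weighting remain available for severely imbalanced inputs.
Two schedule elements matter for this problem and are defaults for a
reason.  The discriminative signal — a handful of motif occurrences in a
kilobase — is extremely sparse under global average pooling, and the
cross-entropy saturates long before the convolutional filters sharpen
from soft, partial-match detectors into near-exact ones; without
regularization the soft filters accumulate spurious mass on
partial-match clusters in motif-free sequence, which surfaces as rare
confident false positives.  Decoupled weight decay prunes exactly those
many-small-weight solutions while the consistently reinforced exact-motif
weights survive.  Second, the learning rate is halved every 6 epochs:
with a constant rate the validation Matthews correlation coefficient
(MCC) oscillates just below its ceiling instead of settling.  Per-epoch
validation loss and MCC are recorded; the checkpoint with the best
validation MCC (ties resolved toward lower validation loss, so a
longer-converged checkpoint wins) is returned, and training stops after
6 epochs without MCC improvement.  An optional rule stops as soon as
validation MCC reaches 1 with training loss below a threshold; it is off
by default because under weight decay the later, sharper checkpoint
generalizes measurably better than the first validation-perfect one.

Evaluation uses the confusion counts and MCC,
$\mathrm{MCC} = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$,
which is robust to the heavy class imbalance of this problem; a zero
marginal factor yields MCC 0 by convention rather than `NaN`.

The network core (forward pass, backpropagation, Adam, and the
attribution pass) is implemented in RcppArmadillo.  Batches are laid out
as a single $4 \times BL$ matrix; convolutions run as im2col matrix
products against single-threaded BLAS.  The backward pass is verified in
the test suite against central finite differences (worst relative error
below $10^{-5}$ at step $10^{-6}$).

## Attribution: DeepLIFT with the Rescale rule

DeepLIFT explains the difference between the model's output on an input
and on a *reference* (null) input by backpropagating multipliers.  The
reference here is the per-position average one-hot frequency over a
random 80% sample of the constitutive windows — "what sequence looks
like around a typical conserved site" — built once per run under a
recorded seed.

Multipliers start at the gained logit $o_2$ (the raw logit, not the
softmax: probabilities saturate and the softmax head is excluded from the
attribution path).  Linear layers — convolutions, the residual
projection, average pooling, dense layers — pass multipliers through
their transposed linear maps; the residual addition routes multipliers
into both summands; ReLUs use the Rescale rule
$m = \Delta a / \Delta z$, the ratio of the activation difference to the
pre-activation difference between input and reference, falling back to
the reference-point gradient when $|\Delta z| < 10^{-7}$ (the ratio is
numerically unstable there; the threshold is a stability choice, not a
tuning knob).  The contribution of input element $(c, i)$ is its
multiplier times $x_{ci} - r_{ci}$.

Because every rule is exact for its layer, the defining
*summation-to-delta* identity holds: contributions sum to
$o_2(x) - o_2(r)$.  The implementation satisfies it to machine precision;
the test suite asserts a $10^{-4}$ relative tolerance on trained models
and the exact closed form $\nabla o_2 \circ (x - r)$ when the network is
driven into its affine regime.  *Gating* then reduces the $4 \times L$
score matrix to one score per position: the score of the base actually
present (0 at `N`).

## From scores to candidate subsequences

Two window forms serve two purposes:

* **Selection for motif enrichment** uses length-$w$ stride-1 windows
  ($w = 20$ by default), scoring each of the $L - w + 1$ subsequences by
  its mean gated score.  Selection keeps the windows with the highest
  *positive* means — globally across records (default, $N = 1000$) or per
  record — with ties broken by record and start so results do not depend
  on input order.  Selected windows may overlap; an optional non-maximum
  suppression (minimum start separation) is available.  Selections are
  exported as FASTA plus, when genomic provenance is known, a 0-based
  half-open BED and a stub invoking `findMotifsGenome.pl` with a 200-bp
  search space.  Running the enrichment tool itself is out of scope; its
  ranked output table can be read back with `parse_motif_results()` and
  queried with `motif_rank()`, whose percentile is
  $(\mathrm{total} - \mathrm{rank})/\mathrm{total} \times 100$.

* **Peak localization** uses a centered mean over $w + 1$ positions
  ($w = 8$, matching the benchmark motif length): the score at index $i$
  averages $S_{i-w/2} \ldots S_{i+w/2}$.  Boundary-truncated windows are
  flagged and excluded from peak picking.  Top peaks are selected with
  non-maximum suppression at minimum separation $w$.  Slices of width
  $2 \cdot \mathrm{flank} + 1$ (flank 10) around each record's highest
  peak are stacked into a position weight matrix whose per-column argmax
  gives a consensus string.  Slice centers are refined to the
  positive-part score centroid of the peak window before alignment: the
  $(w+1)$-term centered mean of a $w$-bp signal block has a two-way
  argmax tie, and when different records resolve the tie differently the
  stacked columns blend adjacent motif positions and the consensus
  smears; centroiding aligns slices on the score mass instead.

Distances from selected windows or motif hits to the CTCF site (always
the window midpoint $L/2$) summarize *where* the signal sits;
`smooth_density()` wraps a fixed-bandwidth Gaussian kernel density for
plotting those distributions.

## The simulation benchmark

The end-to-end validation emulates a controlled insertion experiment:
generate background sequences, *scrub* every occurrence of a query motif
(each occurrence overwritten by a random same-length string, rescanning
until none remains — replacements can themselves recreate the motif),
then overwrite the motif at 10 random non-overlapping positions in a
random 33% of sequences, keeping the insertion coordinates as ground
truth.  Insertion is substitution, so $L$ is constant — required by the
fixed $4 \times L$ input.  Scrubbing is forward-strand only by default
(the classifier sees augmented reverse complements only for real gained
sites, not in the simulation); a flag enables double-strand scrubbing.
Non-overlapping placement retries up to 1000 times before erroring.

The default background is i.i.d. uniform (GC 0.5).  That is deliberately
simpler than real CTCF-free genomic sequence: no repeats, no CpG
depletion, no compositional heterogeneity.  Passing the benchmark
therefore demonstrates that the architecture, training loop, attribution
and peak machinery are correct and sensitive — not that the method's
real-data performance is reproduced; real site lists and a genome are
required for that, via `run_discovery()`.

`run_simulation_experiment()` chains all stages and reports hold-out
accuracy, confusion counts and MCC, per-record localization (how many of
the top-10 non-overlapping peaks land on true insertions), and the
peak-slice PWM consensus.  A single master seed derives all stage seeds,
and reruns are bit-identical.

## Problem sizes and numerical choices

The package's reference configuration of the benchmark uses 3000
sequences of 1000 bp with an 80/10/10 site-level split — large enough
that the test split holds ~99 positive records, small enough to train on
one CPU core in a few minutes.  At this scale the trained model reaches
100% hold-out accuracy, all top-10 peaks per positive record typically
overlap true insertions, and the central consensus equals the inserted
motif; the unit-test fixture shrinks further (200 sequences of 200 bp)
for fast property checks.  Robustness-style sweeps (window length,
input length, site resampling via `subsample_sites()` /
`run_robustness()`) are exposed as configuration and documented rather
than exhaustively rerun.

Other numerical conventions collected in one place: weight
initialization is He-scaled Gaussian under the model seed, biases zero;
probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$ inside the loss;
selection ties break by (record, start); PWM consensus ties break by
channel order A < C < G < T; split sizes use cumulative rounding so
fractions always partition the site set; training with `max_epochs = 0`
is a no-op that returns the initialized model.

## Known limitations

* The two-logit head is trained with softmax cross-entropy; alternatives
  (independent sigmoids) are not implemented, only configuration-visible.
* One residual block per branch; deeper stacks would need additional
  attribution-path bookkeeping and are intentionally unsupported.
* The i.i.d. background understates real-genome hardness (see above).
* Site prioritization ("most significant gained sites") is accepted as
  an input ordering, never computed — upstream ChIP-seq analysis owns it.
* Motif-enrichment software is written *for*, not run: exports and
  result parsing are covered, the enrichment computation is not.
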