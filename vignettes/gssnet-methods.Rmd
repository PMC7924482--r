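---
title: "gssnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gssnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sequence classifiers for genome annotation are usually trained on balanced
sets: as many random negative windows as there are annotated positive
windows.  A model tuned that way can score well on a held-aside test set
and still be nearly useless as an annotation tool, because a chromosome
scan confronts it with hundreds of negatives per true positive — a prior
it never saw during training — and its false-positive background drowns
the signal.  `gssnet` implements an imbalance-aware variant of this
workflow for gene start sites (GSS, the annotated transcription start
coordinate of a gene): train on *limited unbalanced* sets with Q negatives
per positive, re-weight the rare positive class in the loss by CW = Q,
scan whole chromosomes at 1-bp stride, and quantify genome-wide
performance with a metagene signal-to-noise score, lambda.

# The model

Windows are 299 bp of sequence (±149 bp around a GSS), one-hot encoded
into a 4 × 299 matrix with row order A, T, C, G (A = (1,0,0,0), …; `N`
becomes an all-zero column).  The network is a three-block 1-D
convolutional classifier:

| layer            | shape            | output    |
|------------------|------------------|-----------|
| input            | –                | 4 × 299   |
| conv + ReLU      | 32 kernels, k=4  | 32 × 296  |
| maxpool 2 + drop | –                | 32 × 148  |
| conv + ReLU      | 64 kernels, k=4  | 64 × 145  |
| maxpool 2 + drop | –                | 64 × 72   |
| conv + ReLU      | 128 kernels, k=4 | 128 × 69  |
| maxpool 2 + drop | –                | 128 × 34  |
| flatten          | –                | 4352      |
| dense + ReLU + drop | 128           | 128       |
| dense, sigmoid   | 1                | 1         |

Each convolution maps a length-T input to T − k + 1 positions; pooling
floor-halves odd lengths (145 → 72, 69 → 34).  `model_shapes()` walks this
chain programmatically and is what the shape tests assert against.

Training minimises the class-weighted binary cross-entropy

L = −(1/N) Σ [ CW · y · log ŷ + (1 − y) · log(1 − ŷ) ],

so that with CW = Q = (#negatives / #positives) the two classes contribute
comparable gradient mass even in heavily unbalanced sets.  With CW = 1
this is the ordinary binary cross-entropy.  Optimisation is Adam with
early stopping on the validation loss and best-weights restore.
Classification uses a 0.5 threshold; a score exactly at the threshold is
called positive.

The network, backpropagation and the Adam optimiser are implemented
natively in C++ (RcppArmadillo, im2col + BLAS matrix products, double
precision throughout), so the package has no deep-learning runtime
dependency.  Gradient correctness is covered by a finite-difference test.

# Genome scanning

`scan_chromosome()` scores every 299-bp window of a chromosome at 1-bp
stride and assigns the score to the window's *centre* coordinate, so a
track peak sits on the feature rather than at its left edge.  Windows
with more than 10% `N` are masked (`NA`), as are the 149 flanking
positions at each end; an all-ACGT chromosome of length L yields exactly
L − 298 defined scores.

A naive scan would run the full forward pass once per window — about
8 × 10⁶ floating-point operations per window, or ~10¹³ per megabase.
Instead the scanner exploits the structure of the network: convolutions
are translation-equivariant, and each 2× max-pool makes window starts
that are congruent modulo 2 share their pooled values.  After the three
pooling layers there are 2³ = 8 congruence classes ("phases") of window
starts; for each phase the whole convolution chain is computed once over
the full chromosome, and the dense head is applied as one more
convolution (kernel length 34) over the final pooled sequence.  Elements
dropped by odd-length pooling never reach the output, which makes the
phase chains exactly equivalent to per-window evaluation — the test suite
asserts agreement with direct single-window scoring to 1e−6.  This brings
a 1 Mb scan to roughly 10¹² operations, a few tens of seconds on one core.

Only the forward strand is scanned by default: training windows are
orientation-normalised (minus-strand windows are reverse-complemented),
so a model fires on reverse-strand GSS as well.  `both_strands = TRUE`
additionally scans the reverse complement and keeps the per-position
maximum.

# The lambda score

Test-set accuracy does not measure annotation quality on a chromosome.
`gssnet` uses the metagene statistic lambda instead:

1. Z-score the prediction track: Z_g = (y_g − μ) / σ, with μ and σ the
   mean and standard deviation over all defined positions of the scanned
   region.  (The evaluation region is whatever was scanned — typically
   one held-out chromosome — so normalisation uses that region's own
   moments; this is the only self-consistent reading when evaluation is
   per-chromosome.)
2. Extract Z over 10-kb windows centred on every GSS of the region whose
   window is fully defined (edge or masked GSS are excluded and counted);
   reverse minus-strand rows so positive offsets point downstream.
3. Average the rows element-wise into the curve S (10,001 offsets).
4. lambda = mean of S over the central r offsets; r defaults to 400 bp,
   implemented as offsets −200 … +199 (the even-r centring must break the
   off-by-one somehow; this package takes the left-closed reading).

A track that carries no information about GSS has S ≈ 0 everywhere and
lambda ≈ 0; larger lambda means more prediction mass concentrated at true
GSS relative to the background.  The pipeline is covered by a brute-force
oracle test (independent 10-line recomputation, agreement to 1e−10).

Conventional metrics (Sn, Sp, precision, recall, MCC) are available via
`confusion_metrics()`; degenerate denominators yield `NA` plus a flag in
`$undefined`, never a silent 0.  `binned_precision_recall()` evaluates
detection at coarser resolution: the chromosome is tiled into 600-bp bins,
a bin is truly positive if it contains a GSS, and called positive at
threshold t if its maximum defined score reaches t (the maximum is the
natural detector statistic for "is there a GSS in this bin").

# CpG analyses

Vertebrate promoters split into CpG classes: many mRNA gene starts sit in
CpG islands.  `cpg_classes()` counts CpG dinucleotides in the 299-bp
window around each GSS and splits the set at the 35% and 60% quantiles of
the count distribution into low / medium / high classes.  The published
bounds are stated as percentages and the groups as "of similar size",
which identifies them as distribution quantiles rather than raw counts;
the quantile reading is therefore implemented (and configurable).
`cpg_baseline_track()` turns sliding-window CpG content itself into a
predictor track that runs through the identical Z-score → metagene →
lambda pipeline, giving the natural sequence-composition baseline that a
trained model must beat.

# The synthetic benchmark

Real-genome runs (download a genome FASTA plus refGene, train for hours)
are supported but not testable at desk scale, so the package ships a
seeded generator.  It emulates exactly the features the pipeline needs:

* i.i.d. background sequence with configurable base frequencies;
* planted GSS with margins (≥ 5,150 bp from ends, so 10-kb metagene
  windows always fit) and minimum spacing (1 kb);
* a promoter-like consensus 8-mer written at fixed offsets (−30 and 0)
  relative to each GSS, with per-base substitution noise, mirrored and
  reverse-complemented for minus-strand GSS;
* CpG enrichment in ±149 bp of each GSS, via a first-order chain that
  multiplies the C→G transition probability (factor 1 reduces exactly to
  the background model) — this gives the CpG baseline a real signal;
* a truth table of every planted motif instance.

`standard_benchmark()` fixes the study design used by the acceptance
suite: 3 chromosomes × 1 Mb, 150 GSS each, substitution probability 0.15,
3× CpG enrichment, 50% minus-strand, chr3 held out.  These sizes keep a
full train + scan + evaluate cycle at a few minutes on one core while
leaving ~850 windows of training data and 150 evaluation GSS.

What the generator does **not** emulate: repeat families, isochores and
regional GC structure, TATA/Inr promoter grammar, alternative and
clustered gene starts, assembly gaps.  Background diversity is far lower
than in a real genome, so balanced (Q = 1) models generalise much better
here than they do on real chromosomes.  Passing tests on this benchmark
demonstrate the machinery is correct, not that a given Q is optimal for
any real genome.

One known consequence is a width mismatch in the headline comparison.
All planted signal lives within ±149 bp of a GSS, so a strictly trained
detector's response decays within roughly ±150 bp, while a permissive
model still fires on partial window overlap out to ±250 bp or so.  On
real genomes GSS-associated signal often extends over a kilobase, and
averaging S over r = 400 bp around the GSS sits comfortably inside it;
on this benchmark r = 400 averages mostly background for a sharp
detector, which rewards breadth over peak height.  The acceptance suite
nevertheless runs the comparison exactly as specified (lambda at r = 400,
Q = 20 vs Q = 1, five seeds) and prints the per-seed values alongside the
verdict — the S curves and lambda at smaller r are available from
`lambda_score()` for anyone studying the effect.

# Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| window (b) | 299 bp | ±149 bp around the GSS |
| Q | user | negatives per positive, 1–100 |
| CW | Q | positive-class loss weight |
| conv filters | 32, 64, 128 | kernels per block, length 4 |
| dropout | 0.2, 0.2, 0.2, 0.5 | after each pool; before the output |
| optimiser | Adam, lr 1e−3 | conventional rate |
| batch size | 64 | desk-scale sets (10³–10⁴ windows) need ≥ ~10 updates per epoch; 512 would give 1–2 |
| max epochs / patience | 150 / 10 | library defaults; `train_and_evaluate()` uses 15 / 4 because the benchmark separates within a handful of epochs |
| split | 70 / 15 / 15 | test fraction 0.15; validation mirrors it |
| r | 400 bp | lambda central window |
| metagene half-width | 5,000 bp | 10-kb windows |
| CpG class bounds | 0.35, 0.60 | count-distribution quantiles |

# Numerical and edge-case choices

* Predictions are clipped to [1e−7, 1 − 1e−7] inside the loss (the
  cross-entropy diverges at 0/1); gradients use the unclipped ŷ − y form.
* Max-pooling of an odd length drops the final element (floor), forced by
  the published shape chain; pooling ties resolve to the left element.
* Scores exactly at the decision threshold classify positive.
* The dense hidden layer uses ReLU (the published table states only its
  width; ReLU matches the rest of the architecture family).
* Dropout masks are "inverted" (survivors scaled by 1/(1−p)) so
  inference needs no rescaling.
* All training randomness (shuffling, dropout) flows from one integer
  seed through a dedicated generator, and weight initialisation
  (Glorot-uniform) from the model seed through R's RNG: rebuilding and
  retraining with the same seeds is bit-reproducible on a fixed BLAS.
* Negative sampling rejects a candidate window if any GSS *point* (either
  strand) lies inside its span — the minimal reading of "contains a
  GSS" — and redraws; windows >10% `N` are likewise redrawn, positives
  >10% `N` dropped with a warning.  A >99% rejection rate aborts with an
  explanatory error.
* Minus-strand GSS sit at txEnd − 1 (refGene's txEnd is half-open); all
  internal coordinates are 0-based half-open, BED-compatible.
* Deduplication of GSS is exact on (chrom, position, strand): isoforms
  sharing a start collapse, nearby alternative starts stay distinct.
* A sample set records its seed, Q, holdout and split so a run manifest
  can reproduce it exactly.

# Limitations

* The synthetic benchmark is a correctness harness, not a promoter
  simulator; conclusions about the best Q for real genomes must come from
  real-genome runs.
* Lambda depends on the GSS density and signal width of the evaluated
  region (see above); comparing lambda values is safest within one region
  and one r.
* Training is CPU-only and single-threaded by design; real-genome
  training (tens of thousands of windows, Q up to 100) is feasible but
  slow — expect hours, as with any CPU CNN training.
* The refGene reader covers the UCSC flat-file dialects (15/16 columns);
  GTF/GFF inputs are out of scope, as is coordinate liftover.
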