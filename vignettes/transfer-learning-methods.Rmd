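---
title: "Transfer learning for TF binding prediction: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for TF binding prediction: models, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Predicting whether a transcription factor (TF) binds a 200-bp genomic
region is a binary sequence-classification task. Deep convolutional
models do this well when tens of thousands of labelled regions are
available, but most TFs have been ChIP-profiled in few cell types and
offer only hundreds of usable peaks. `tftl` implements a two-step
transfer-learning strategy for exactly this regime: a multi-task model
is pre-trained on several TFs at once, its weights initialize a
single-task model for the data-poor target TF, and the single-task model
is then fine-tuned at a 10-fold lower learning rate. The package also
implements the selection of *biologically relevant* pre-training TFs
(shared binding mode, cofactors, functional partners), and the
interpretation machinery needed to see *what* was transferred.

# The three-state binding matrix

Labels come from a TF-by-region matrix built from three interval
sources matched by cell type: ChIP-seq peak summits, PWM-based TFBS
predictions, and accessible (DHS-like) regions, the latter defining the
region universe (resized to 200 bp around the interval midpoint). For a
TF--region pair:

* **1 (bound)** — some cell type has the region accessible *and* a peak
  summit of the TF inside the region *and* an overlapping TFBS, all in
  that same cell type;
* **0 (unbound)** — the region is accessible in at least one cell type
  where the TF was profiled, but no cell type is doubly supported;
* **NULL (unresolved)** — the region is not accessible in any cell type
  where the TF was profiled.

Cases supported by exactly one evidence kind are ambiguous. The
**sparse** dialect marks them NULL (used for single-task datasets, where
label quality matters most); the **less-sparse** dialect calls them 0
(used for multi-task datasets, which must drop every region whose label
column contains a NULL and therefore benefit from fewer NULLs). The two
dialects always agree on the set of 1s, and every NULL of the
less-sparse matrix is NULL in the sparse matrix too.

Overlap semantics: a ChIP-seq record supports a region when its summit
coordinate lies inside it; a TFBS supports it on ≥ 1 bp interval
overlap; all evidence is treated strandlessly, in BED-style 0-based
half-open coordinates. Regions whose 200-bp resize would cross a
chromosome boundary are dropped. The bound call requires all three
supports to coincide in one and the same cell type — the strictest
reading of "matched by cell and tissue type"; matching is exact after an
optional user-supplied label-correspondence table, with no fuzzy
matching.

Cofactors are defined from the sparse matrix: the binding vectors of two
TFs are compared by cosine similarity after removing positions
unresolved in either vector. A TF without bound regions has a zero-norm
vector; its similarity is reported as undefined (`NA`) rather than 0,
and such TFs are excluded from rankings. Ties in every ranking are
broken by descending score and then lexicographic TF identifier.

# Datasets

Single-task datasets take a TF's 1s (bound) and 0s (unbound) from the
sparse matrix. Because unbound regions vastly outnumber bound ones, the
unbound set is downsampled to a 50:50 ratio while matching the %GC
distribution of the bound set: GC content is binned at 5-percentage-point
width, each bin contributes as many unbound regions as the bound set has
in that bin, and exhausted bins borrow from the nearest non-empty bin
(ties toward lower GC). The 5-point width is a compromise between
matching fidelity and bin occupancy at a few hundred regions per class.

Datasets are split by region into 80% training, 10% validation and 10%
test *before* augmentation, so a region and its reverse complement can
never straddle partitions. Training and validation sets contain each
region in both orientations; the test set is forward-only (augmentation
is a training-time device; doubling test sequences would only average
two correlated predictions). Sequences containing non-ACGT characters
are discarded. Multi-task datasets are taken from the less-sparse
matrix and keep only regions fully resolved across all chosen TFs; task
labels are not rebalanced per TF, since multi-task training consumes the
label matrix as observed.

# Model architectures and training

Two architectures are provided. The convolutional model stacks three
conv/batch-norm/ReLU/max-pool blocks (100 filters of width 19, 200 of
width 7, 200 of width 4; 3x pooling throughout), two 1000-unit fully
connected layers with batch normalization and 30% dropout, and a
logistic output per task. The hybrid model uses 320 filters of width
26, 20% dropout, 13x pooling, two bidirectional LSTM layers with hidden
state 320 and 50% dropout, and a 925-unit fully connected layer.
Convolutions use "same" padding (left pad `floor((K-1)/2)`) so the
pooling arithmetic works for 200-, 500- and 1000-bp inputs; pooling
truncates remainders. These two decisions are conventions of common
deep-learning frameworks and are documented here because the layer
recipe alone does not determine them.

Training minimizes mean binary cross-entropy over tasks with Adam
(default hyperparameters beyond the learning rate), batch size 100 and
learning rate 0.003; fine-tuning uses 0.0003. Early stopping monitors
the validation loss (the simplest scalar consistent with "performance on
the validation set"), with a default patience of 10 epochs and
restoration of the best checkpoint. From-scratch baselines use the
pre-training rate 0.003, since they are not initialized from a
pre-trained model. All randomness of a run — initialization, shuffling,
dropout — is funnelled through one integer seed, and identical seeds
reproduce identical checkpoints bit for bit.

The engine itself (convolution via single-precision im2col/GEMM,
batch normalization, pooling, dense and LSTM layers, backpropagation,
Adam) is implemented in the package with compiled kernels; its gradients
are verified against central finite differences in the test suite.
Batch-normalization uses biased batch variance for normalization and for
the running statistics, and evaluation mode freezes those statistics;
dropout is inverted-scaled and disabled at inference.

Weight transfer copies named layers: `all_but_output` copies everything
except the output layer (the default fine-tuning mode), `conv1_only`
and `conv_all` copy only the stated convolutional blocks (including
their batch-norm parameters and running statistics, which travel with
the block) and leave the fully connected layers freshly initialized.
Freezing (`freeze = "conv_layers"`) excludes the convolutional blocks
from the optimizer so their weights stay bit-identical. Pre-training and
fine-tuning region sets must be disjoint; `finetune()` errors if given
overlapping region ids. Filters can also be initialized directly from
PWMs: each probability matrix is resized to the 19-bp filter width
(centred, padded with uniform 0.25 columns or truncated to the central
columns) and 0.25 is subtracted from every entry, leaving pad columns at
exactly zero weight.

# Evaluation

Performance is the area under the precision-recall curve, computed as
step-wise average precision with tied scores grouped at one threshold
(no trapezoidal interpolation) — the convention of standard
machine-learning toolkits. A TF's performance *in* a multi-task model is
the AUCPR of the output node corresponding to that TF on the test
partition. The PWM baseline scores a sequence by sum occupancy: the sum
over all windows on both strands of the product of per-position
probabilities (probability form, not log-odds, matching the "sum of
probabilities" definition of the score).

# Interpretation

First-layer filters are converted to motifs by scanning the first
convolutional block's post-ReLU activation map over a sequence set
(typically the correctly predicted test regions, thresholded at
predicted probability 0.5): every full-width window reaching at least
50% of the filter's maximum activation — the maximum taken globally over
the whole set, not per sequence — contributes its one-hot counts to a
position frequency matrix. PFMs become PWMs with a total pseudocount of
1, and information content is `2 + sum(p log2 p)` per column under the
uniform background. Filter influence silences one filter (zeroing its
post-ReLU activation map, so a filter whose activations are already all
zero has exactly zero influence) and reports the mean squared change of
the model's predictions.

Per-nucleotide attribution uses a reference-based backpropagation rule
(the "rescale" family): linear layers pass multipliers through their
weights, elementwise nonlinearities use the ratio of output to input
differences, and max pooling routes each window's output difference to a
single input position, which keeps the completeness identity — the
attributions of a sequence sum exactly to the model output minus the
reference output — true by construction, layer by layer. Attributions
are averaged over a set of reference sequences (10 in typical use). The
rule is implemented for the convolutional architecture; propagating
difference multipliers through LSTM gates is substantially more
involved and out of scope, so the recurrent model raises an informative
error. Internal motif comparisons (e.g., matching a filter motif to a
known PWM) use the best Pearson correlation of aligned probability
columns over all offsets with at least four overlapping columns, in both
orientations; external motif-comparison or motif-clustering tools can
consume the JASPAR/MEME files and attribution tables the package
exports.

# The synthetic world

Real inputs at genome scale are out of desk-top reach, so the package
ships a generator whose ground truth is known exactly. A world draws one
motif per binding mode; TFs sharing a mode get family variants in which
a `divergence` fraction of columns (at least one) is replaced by fresh
random columns annealed to the same per-column information content —
variants stay equally sharp while their similarity to the base decays
with divergence. (An earlier design that mixed probabilities column-wise
was rejected: mixing flattens the columns and silently destroys the
motif signal.) Defaults draw motifs of width 10–12 with total
information content 13–15 bits; at these values one stochastically
sampled instance per bound region makes the true-motif PWM baseline
strong but imperfect (AUCPR ≈ 0.95 against GC-matched negatives), which
leaves measurable room above it for learned models and below it for
small-data baselines.

Cell-type coverage is simulated (which TFs are profiled where, which
regions are accessible where) and induces unresolved entries exactly as
in real data; a configurable rate of single-evidence records produces
the sparse/less-sparse dialect difference; a cofactor table implants a
partner TF's motif in a configurable fraction of a TF's bound regions.
Evidence records are emitted per bound pair (summit plus TFBS in one
matched cell type) and the matrices are built by the same
`build_binding_matrices()` code path used for real data, so the
generator exercises the labelling logic rather than bypassing it.
Background sequences are i.i.d. at a configured GC content (41% by
default, genome-like); the generator does not model dinucleotide
structure, repeats, nucleosome positioning or signal-strength gradients,
so passing tests demonstrate the correctness and relative behaviour of
the machinery, not absolute performance on real chromatin.

# The benchmark and its scale

`tl_benchmark()` packages the study conditions used by the acceptance
checks: a 22,500-region world with a data-poor target TF (≈ 450 bound
regions, of which 250 enter a balanced 500-region fine-tuning dataset),
five TFs sharing the target's binding mode and six unrelated-mode TFs;
two 20,000-region multi-task pre-training datasets (family and random
different-mode), both excluding the fine-tuning regions; and five
fine-tuning replicate seeds, each with a fresh 80/10/10 split, comparing
transfer learning against from-scratch training.

The family is modelled on what a binding mode looks like in real data:
member motifs are closely related (column-replacement divergence 0.3,
so variants share most positions but each has a few private columns)
**and** the members co-bind (pairwise co-binding probability 0.4 within
the family, plus weak co-binding onto the target that leaves it
data-poor). Both ingredients are load-bearing, and pilot experiments
showed each failing mode. With independent family binding and
near-identical motifs, the multi-task problem is statistically
ill-posed — no model can tell which sibling bound a region — and
pre-training collapses to chance. With unrelated motifs the multi-model
trains well but encodes features carrying no information about the
target (output-node probes against target labels sit at chance), so
there is nothing to transfer. Correlated binding of related motifs —
exactly the clustering that homologs show in real binding-vector
similarity heatmaps — makes the family tasks learnable (per-task AUCPR
≈ 0.8 after three epochs) and makes the learned features transferable
(the multi-model's output nodes already score ≈ 0.79 against the
held-out target's labels before any fine-tuning). The moderate
divergence also leaves the refinement mechanism observable: pre-trained
filters match the target motif at ≈ 0.8 alignment correlation and
fine-tuning nudges them toward the target's own variant, whereas with
near-identical family motifs the filters start at the target and
fine-tuning can only wander away from it.

Pre-training runs up to 3 epochs and fine-tuning up to 8 with
patience 3 — the multi-task validation loss plateaus within 2–3 epochs
at these motif strengths and dataset sizes, and the fixed budget keeps
the whole benchmark reproducible in tens of minutes on one CPU core.
Filter refinement is quantified as the best alignment correlation
between any first-layer filter motif and the target's true motif,
computed on the full bound sequence set of the target dataset with the
same sequences before (multi-model) and after fine-tuning, so the two
models are compared on identical inputs.

A caution on that last readout. At this scale the fine-tuned model's
best validation checkpoint arrives after only tens of gradient updates,
so first-layer filters move very little, and the *maximum-over-filters*
similarity statistic is dominated by how the single best filter of the
particular pre-trained model responds to those few updates. Across
otherwise-equivalent pre-training runs (for example, permuting the task
order of the same five TFs) the statistic can consistently increase for
one multi-model and consistently decrease for another, even while
transfer performance is uniformly strong; tracking the statistic over
longer, non-early-stopped fine-tuning shows an initial disruption phase
(the freshly initialized output layer backpropagates large errors
through every layer) followed by a slow recovery. The per-filter
refinement readout should therefore be treated as qualitative at this
dataset size, and the package reports it per seed rather than
summarizing it.

# Known limitations

* The background model is i.i.d.; GC is the only composition covariate.
* One motif instance per bound region by default; no signal-strength or
  multiplicity gradients.
* Attribution is restricted to the convolutional architecture.
* The binding-mode table is consumed as given (no derivation from motif
  clustering), and partner confidences are consumed as given.
* The engine is CPU-only and single-threaded apart from BLAS; it is
  sized for the bundled benchmark, not for genome-scale training.
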