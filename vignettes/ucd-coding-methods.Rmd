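---
title: "Methods: statistical underlying-cause-of-death coding"
author: "ucdcoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical underlying-cause-of-death coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mortality statistics tabulate a single *underlying cause of death* (UCD)
per decedent: the disease or injury that initiated the chain of morbid
events, selected from everything the certifying physician wrote on the
death certificate. The WHO-standard certificate has two parts. Part I holds
up to four lines listing the causal chain in inverse causal order — the
immediate cause on line 1, underlying conditions on the last used lines.
Part II holds up to two lines of other significant conditions that
contributed to death without belonging to the main chain. After every line
has been converted to ICD-10 codes, a large body of WHO selection rules
(implemented in production by the Iris expert system, which rejects
certificates it deems too complex and leaves them to human coders) maps the
certificate to its UCD.

`ucdcoder` treats this mapping as a supervised prediction problem. The
model estimates

P(UCD | CCD, A, Y, G)

where CCD is the grid-encoded causal chain of death, A the age bin, Y the
year of death and G the gender, and the prediction is the argmax of the
estimated distribution over the code vocabulary.

## Certificate encoding

The six lines are laid out on a fixed L x W integer grid (default 6 x 20,
20 being a generous bound on codes per line): Part I lines on rows 1–4,
Part II lines on rows 5–6, each line left-justified in written order, with
a reserved pad index elsewhere. Codes are stored dotless and uppercase
("F11.2" is "F112"); codes unseen at training time map to a reserved
trainable unknown index rather than erroring, because real certificates
routinely contain such codes.

Age is factorized into 25 bins. Bin 0 is the neonatal period (under 28
days), which has its own coding rules; bin 1 covers the rest of the first
year; bin 2 ages 1–4; then 5-year bins up to 105–109, and 110+ as bin 24.
The boundaries are a package design choice: upstream descriptions of this
factorization fix the number of bins and the special treatment of the first
year, but not each boundary. The year covariate has 16 states (calendar
years 2000–2015 by default); gender two.

## Model

The coder is a convolutional network over categorical embeddings:

1. One shared linear projection (an embedding table) maps every code cell
   of the grid to a `embed_dim`-vector. Looking a row up in the table is
   exactly the product of the code's one-hot (dummy) vector with the
   projection matrix — the package tests assert this equivalence to 1e-6 —
   so this is the memory-tractable form of a full dummy-variable encoding.
2. The age, year and gender projections (same output width) are added to
   every **non-pad** cell. A trainable per-row embedding is also added
   (`use_row_embedding`, default on): with a fixed 6-line layout, rows are
   semantically distinct — the Part II promotion rules below depend on
   them — while the translation invariance that matters, along the
   rank-in-line axis, is untouched. Gender can be ablated with
   `use_gender = FALSE`.
3. A trunk of 3 x 3 convolutions (default channels 48, 64, 96) with ReLU
   activations and **no bias terms**, followed by global max pooling.
4. A softmax regression over the V vocabulary codes.

Training minimizes cross-entropy with Adam (defaults lr 1e-3, batch 256, 15
epochs) on mini-batches; the parameters of the best validation-accuracy
epoch are kept. All initialization and shuffling is driven by explicit
seeds, so runs are bit-reproducible on single-threaded BLAS.

### Numerical design: exact padding neutrality

Three choices make width padding *exactly* neutral rather than
approximately so: the pad embedding is frozen at the zero vector,
demographic projections are added to non-pad cells only, and convolutions
carry no biases. An all-padding region is then exactly zero through every
ReLU layer, and since ReLU activations are nonnegative it can never win the
global max pool. Two consequences:

* Widening the grid (W = 20 to W = 30, say) with padding provably leaves
  the output unchanged; the package asserts equality to 1e-4 on trained
  models and observes agreement at machine precision.
* The forward pass may skip convolution over columns beyond the last
  occupied one plus the trunk's receptive margin (`crop = TRUE`, the
  default) with bitwise-identical results. This is what makes CPU training
  on mostly-empty 6 x 20 grids cheap.

The defaults (embedding width 32, channels 48/64/96) are sized for
single-CPU desk experiments: the 20,000-certificate recovery run below
trains in a few minutes. They are declared design choices, not estimates of
any production system's configuration; a production-scale run would widen
the embedding and channels.

Ties in the argmax and in top-k ranking are broken toward the lower
vocabulary index, for reproducibility.

## The synthetic certificate simulator and rule oracle

Production certificate corpora are access-restricted, so the package ships
a generator whose output has the structural properties the coder must
learn, together with a deterministic rule-based oracle that plays the role
of the reference coding process (and of a reject-capable expert-system
baseline). A `cause_model` bundles:

* a random acyclic weighted transition graph over a synthetic vocabulary
  (200 codes in 20 chapters at desk scale), roots acting as underlying
  causes; a skewed prior over roots (a few prevalent causes, a long tail);
* chain-depth distribution (0.25, 0.35, 0.25, 0.15 for depths 1–4, so
  Part I line 4 is used under 20% of the time, matching the rarity of
  deep chains on real certificates);
* Part II comorbidity lines (probability 0.3) drawn from a comorbidity
  pool, and a spurious-code noise process (probability 0.1);
* *promotion pairs* in the AIDS/Kaposi mould: if a registered trigger
  appears in Part II while its pattern appears in Part I, the UCD becomes
  the trigger (8% of certificates are generated as promotion scenarios);
* a neonatal remap active only for age bin 0, and a year-dependent rule
  change: from a threshold year (2012) onward, selected causes are coded
  to different target codes — the synthetic analogue of coding-rule drift;
* a reject predicate: certificates that need the fallback rule while
  carrying at least 4 codes are rejected as too complex. Rejected
  certificates still receive a gold label from the fallback rule,
  mirroring corpora where rejects are completed by human coders.

The oracle applies, in order: the general principle (select the single
condition on the lowest used Part I line if the transition graph links it,
directly or transitively, to every condition above it), a fallback to the
most remote origin of the first-mentioned causal sequence (deterministic
tie-breaks: lowest line, then leftmost, then vocabulary order), promotion,
the neonatal remap, the year remap, then the reject predicate. It is a pure
function of (certificate, model), which the tests verify, including
agreement with an independent brute-force implementation whose reachability
comes from igraph.

The first year-remapped cause is given a 4% share of the UCD prior. This is
deliberate: rule changes worth harmonizing away in practice affect
prevalent causes, and a remap of a vanishingly rare cause would leave no
discontinuity visible above Poisson noise in the time series experiment.

What the simulator does *not* emulate: real ICD-10 semantics, French
certificate text, the actual WHO instruction volume or Iris decision
tables, realistic cause-specific mortality rates, or correlations between
demographics and causes beyond the neonatal rule. Consequently, passing
recovery tests shows that the coder can learn a rule system with this
structure from labeled certificates — not that it attains any particular
accuracy on real mortality data.

## Evaluation

`evaluate_coder()` reports accuracy with a percentile-bootstrap 95% CI
(B = 1000 seeded replicates; the method and replicate count are package
choices), per-chapter prevalence and error rates (with never-observed
chapters flagged), a chapter-level confusion matrix restricted to errors,
top-k accuracy for k in {1, 2} (short cause chains make large k
uninformative), the second-choice accuracy on mispredicted cases — these
satisfy exactly top2 = acc + (1 − acc) · second-choice — and a confidence
calibration histogram using the argmax probability as confidence, 10 bins.
`compare_with_baseline()` scores the reject-capable oracle both ways:
rejects-as-errors (overall) and rejects-excluded (nonrejected).

The bootstrap interval's coverage is itself tested: over 500 simulated
correctness vectors (n = 2000, p = 0.9) the 95% interval covers the truth
93–97% of the time and its half-width tracks the binomial standard error
within 20%.

## Harmonized recoding

`recode_certificates()` re-predicts every certificate with the year
covariate overridden to a reference year (2015 by default), so all
certificates are coded under one learned rule regime. On a corpus whose
oracle applies a year remap from 2012, the original UCD series of the
remapped cause group has a step discontinuity at 2012; the series recoded
at fixed year does not — its maximum year-over-year change is sampling
noise, and its change at 2012 is unexceptional among the other years. The
package asserts exactly this on the desk-scale corpus (20,000 certificates,
1250 per year), using the maximum absolute year-over-year change of the
grouped total as the smoothness surrogate. `overdose_groups()` ships the
standard six-group overdose surveillance code list (F11–F12, F14–F16, F19,
X42, X62, Y12) for use on real ICD-10 coded data.

## Problem sizes and reproducibility

The bundled experiments run on one CPU: the recovery experiment uses a
200-code vocabulary with 20,000 / 1,000 / 2,000 training / validation /
test certificates and trains in a few minutes; comparison runs at 2,000 and
5,000 training certificates establish that agreement with the oracle grows
with training-set size. `scripts/acceptance.R` re-runs the whole chain from
a single seed. Every stochastic step (vocabulary, cause model, corpus,
splits, initialization, shuffling, bootstrap) takes an explicit derived
seed, and two runs from the same configuration are identical.

## Known limitations

* The oracle's rule system is an intentional miniature; its fallback rule
  in particular is far simpler than real sequence-selection instructions.
* Global max pooling discards code multiplicity: a code appearing twice is
  indistinguishable from appearing once at the pooled layer (position
  information survives only through the convolutional receptive fields and
  the row embedding).
* The desk-scale coder spans the training vocabulary only; codes outside
  it can be consumed as inputs (unknown index) but never predicted.
* Accuracy figures on synthetic corpora do not transfer to real
  certificate data.
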