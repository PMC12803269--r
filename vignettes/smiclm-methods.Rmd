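---
title: "Methods: k-mer SMILES tokenization and desk-scale chemical language models for peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer SMILES tokenization and desk-scale chemical language models for peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, procedures and numerical choices behind
`smiclm`. Code chunks are illustrative and not evaluated at build time; every
empirical claim below is computed by the test suite
(`tests/testthat/`) or by `scripts/acceptance.R`.

## The problem

Therapeutic peptides — macrocycles, N-methylated backbones, noncanonical
side chains, lipidated conjugates — are outside the fixed 20-letter alphabet
of protein language models, and their SMILES strings are several times
longer than typical small-molecule inputs, which makes standard chemical
language models expensive (attention cost grows with the square of sequence
length). `smiclm` implements the ingredients of a SMILES-based encoder
stack that addresses both issues: a compressing k-mer tokenizer, a modern
BERT-style encoder family, self-supervised and descriptor-supervised
pretraining objectives, and a benchmarking harness, all exercisable at desk
scale on synthetic data.

## Tokenization

**Primitives.** The pre-tokenizer segments a SMILES string into atom-level
primitives: a bracket expression `[...]` is one primitive (this preserves
stereo and charge annotations such as `[C@@H]` or `[N+]`), as are the
two-letter halogens `Cl`/`Br` and `%nn` ring closures; every other character
(organic-subset atoms, bonds `= # / \ -`, branch parentheses, ring digits,
dots) stands alone. Structural symbols are primitives in their own right —
the minimal consistent completion of the atom/bracket rules, and the choice
that makes concatenation an exact inverse. Pretokenization is purely
lexical: chemically invalid but well-formed strings pass, so the tokenizer
is testable without a chemistry backend; validity is enforced only at
canonicalization.

**K-mers.** `mine_kmer_counts()` counts every contiguous window of 2–6
primitives (overlaps included). `kmer_vocabulary()` keeps the five specials
(`[PAD] [MASK] [UNK] [BOS] [EOS]`), every observed single primitive, and the
highest-count candidates that pass a validity filter, truncated to a target
size of 405 tokens (the compact size this tokenizer family is typically run
at; `min_count` defaults to 10). The validity filter's *strict* default
rejects candidates whose branch parentheses close more than they opened
reading left to right; a net surplus of opens is allowed, so peptide
backbone motifs like `N[C@@H](` survive. A *permissive* mode disables the
check. Encoding is greedy longest-match, left to right — deterministic and
linear-time; an optimal dynamic program (minimum token count) ships as the
oracle mode, and the property suite verifies that greedy matches it exactly
on the synthetic fixture corpus (documented gap: 0 tokens). Unknown
primitives map to `[UNK]` with a warning (configurable to an error, or
silent for batch pipelines).

On held-out synthetic natural-peptide SMILES, a vocabulary mined at
max k = 6 on 80% of a 2,000-peptide corpus (lengths 5–50) shortens
sequences by about 74% relative to primitive-level tokenization. Mining on
peptides alone compresses them harder than mining on a mixed
small-molecule/peptide reference corpus would, since every k-mer slot goes
to backbone motifs; mixed-corpus vocabularies land nearer 60–65%.

## Corpus curation

The small-molecule cascade applies, in order: length < 20 characters →
reject; silicon chain (two Si atoms bonded directly or through one bridging
O — detected with a configurable string-pattern list) → reject; repeating
silicon-oxide polymer motif `[Si](=O)[Si](=O)` → reject; strip
leading/trailing dot-separated fragments that are bare Br/Cl (neutral or
ionic bracket spellings); split the remaining dot-separated components into
independent entries; canonicalize each and drop failures. The length
threshold applies to the raw string before stripping (it is the first rule),
and the fixture test pins this order. Deduplication is on canonical SMILES.

Peptides pass when pTM > 0.7 and pLDDT > 0.7 (strict) and length ≤ 100
(inclusive). Clustering itself is an external-tool interface (a TSV of
member → cluster assignments); the package implements only representative
selection: the member maximizing pTM × pLDDT, ties broken by input order.

Epoch assembly repeats the lipid pool 5×, takes peptides in full, and
downsamples small molecules without replacement to the requested size, then
shuffles deterministically under the seed.

**Peptide builder.** Residues are joined by amide condensation from
L-configured fragments (`N[C@@H](R)C(=O)`; glycine achiral; proline's
pyrrolidine closes onto the backbone nitrogen). The 20 fragments are
validated in the test suite against reference free-amino-acid SMILES.
Head-to-tail cyclization closes a `%99` macrocycle bond between the first
nitrogen and the last carbonyl carbon; N-methylation substitutes the
backbone N–H (refused for proline, whose nitrogen is already tertiary).

## Encoder

`encoder_config()` fixes the named scales — small (6 layers, 384 hidden, 6
heads), base (12, 768, 12), large (24, 1024, 16) — all with per-head
dimension 64, asserted at construction. Blocks are pre-layer-norm:
`x + Attn(LN(x))`, then `x + FFN(LN(x))`. Positions enter only through
rotary rotation of query/key projections (base 10000, pairwise rotation);
there is no absolute position table. The feed-forward block is a gated
linear unit with SiLU gate (three projections) of width 4 × d_model — the
published scale descriptions do not fix the FFN width, so parameter totals
are reported, not asserted: with a 405-token vocabulary the base scale lands
at 114.3M (within 2% of its 114M label), while small (14.5M vs 32M) and
large (404M vs 337M) cannot be reconciled with any standard width and are
therefore only reported. The MLM head is tied to the input embedding table
(plus a per-token bias); the regression head is two affine layers with SiLU
between, output width 99.

Everything is plain R matrix algebra with hand-derived backward passes;
a finite-difference gradient check over every parameter tensor is part of
the test suite. Forward passes are deterministic; padded positions are
excluded from attention (additive −Inf bias, exact zeros after softmax) and
from mean pooling, so padding never changes real-token outputs. Checkpoints
are an RDS tensor archive plus a JSON config sidecar and round-trip to
bit-identical outputs.

## Pretraining

**Span masking.** The budget per sequence is round(rate × maskable), round
half up, with rate 0.25 and BOS/EOS protected. Span lengths are drawn from
Normal(3.5, 1.0), rounded to nearest, clamped to ≥ 1. Each span starts at a
uniformly random still-available position and extends over consecutive
available positions, truncating at boundaries, previously masked regions and
the remaining budget — so spans never overlap and the budget is met exactly
(the placement loop always masks at least one position per draw). Masked
positions are replaced by `[MASK]` only; the Methods-style description this
implements specifies pure-mask replacement, so there is no 80/10/10
corruption mixing.

**Objectives.** MLM is token-level cross-entropy at masked positions. MTR
is mean squared error from the mean-pooled final state, through the SiLU
head, onto 99 descriptors normalized to zero mean and unit variance with
training-split statistics (constant columns map to zero; failed molecules
are excluded from the regression loss). The hybrid loss is the weighted sum
with λ_MLM = 0.6, λ_MTR = 0.4. Both component losses are per-element means,
so the λ weights act on comparably scaled quantities.

**Descriptors.** RDKit is not available in R, so the 99-descriptor manifest
is the package's own frozen list: 8 OpenBabel molecular properties (MW,
logP, TPSA, molar refractivity, two HBA counts, HBD, fluorine count) plus 91
two-dimensional descriptors computed from the package's SMILES graph parser
— element and aromaticity composition, charge and stereo counts, bond-order
tallies, ring statistics, degree distribution, classical topological indices
(Wiener, Zagreb, Randić, Platt), functional-group motif counts, text-level
statistics, and bonded element-pair counts. The list is ordered and named
(`descriptor_names()`); determinism and duplicate-consistency are tested.

**Optimization.** AdamW with β = (0.9, 0.98), weight decay 0.01 applied to
matrices only (not layer-norm gains or biases); linear warmup over the first
5,000 steps to a peak of 3e-4, then half-cosine annealing to 10% of the
peak. These protocol constants ship as `pretrain_config()` defaults; toy
runs override only the loop controls (steps, warmup, batch size, peak).

**Dynamic randomization.** At each pseudo-epoch boundary the corpus is
re-spelled by re-rooting each molecule at a random non-stereo atom via the
OpenBabel writer, with a batched canonical-equivalence check (molecules that
cannot be safely re-rooted keep their spelling — the backend drops chirality
written on a string's first atom, so stereocenters are excluded as roots).

## Desk-scale study conditions

The toy study used by the tests fixes: a 2,000-molecule synthetic corpus
(1,600 train / 400 held out), a vocabulary mined on the training split
(min_count 5 — the corpus is 100× smaller than a realistic reference corpus,
so the frequency floor scales down), a 2-layer, d_model-64, 4-head encoder
(d_ffn 128), and 300 steps of hybrid pretraining at batch size 16 with
warmup 30 and peak 1e-3 under seed 7. Batch 16 × 300 steps over 1,600
molecules is exactly three pseudo-epochs, mirroring the full protocol's
three; the peak rate is scaled up from 3e-4 as usual for a model four
orders of magnitude smaller. At these conditions the final MLM loss falls
well below the uniform-prediction baseline ln(405) ≈ 6.0, and held-out
descriptor prediction beats the training-mean baseline (aggregate z-space
R² ≈ 0.09 — small, as expected from three epochs on 1,600 molecules, but
reliably positive). Identical seeds reproduce loss traces bit-for-bit on
one device.

## Downstream evaluation

**Finetuning.** At desk scale the encoder is frozen: final hidden states
are mean-pooled once, and a task head — two hidden layers (64, 64), GeLU,
dropout 0.1 — is trained with AdamW at batch size 16, validating every half
epoch with early-stopping patience of 5 epochs, inside nested
cross-validation (5 outer test folds; 4 inner folds each training one head
against its held-in validation fold; outer-test predictions are the
ensemble mean over the inner models). Standardization of embeddings and of
an optional condition column (e.g. pH, appended to the pooled embedding
before the head) uses outer-training statistics only; a canary test asserts
that test-fold rows cannot influence them. The head-only trainer defaults
to lr 1e-3 — the standard rate for training a fresh MLP head under Adam —
while `finetune_protocol_preset()` records the full-model protocol constant
of 1e-5, which is appropriate when gradients flow into a large pretrained
encoder rather than a randomly initialized head.

**Probing.** For each layer (embedding output through the final block),
frozen states are mean-pooled and fed to an L1-penalized linear regression
with the penalty chosen by 5-fold cross-validation over a 100-value path
(iteration cap 10,000; `glmnet`). The reported score is held-out R² pooled
across 5 outer folds — the pooling rule is a package choice, since
"held-out" needs an outer loop once the penalty is itself cross-validated.

**Baseline.** 2048-bit topological path fingerprints (all simple paths of
1–7 bonds over the heavy-atom graph, labeled by element/aromaticity and
bond order, canonical direction, 2 bits per path via two independent
polynomial hashes) with a 100-tree random forest (Gini, unlimited depth).
The fingerprint is implemented in-package from the same graph parser used
for descriptors; a sanity test shows near-perfect MCC when the label is the
presence of a literally hashed substructure and ~0 on random labels.

**Metrics.** MCC (closed form; degenerate single-class predictions defined
as 0), AUROC in rank/Wilcoxon form, R² against the truth mean.

**Scaling-ordering analog.** On the synthetic logP-threshold task (n = 500,
5% label flips — logP is both an MTR pretraining target and poorly captured
by binary path fingerprints, which record substructure presence, not the
additive atom contributions that drive logP), the finetuned toy
hybrid-pretrained encoder beats the fingerprint forest's MCC at the fixed
test seeds. This reproduces the *ordering* that motivates
descriptor-grounded pretraining at small scale, not any published score.

## Synthetic data: what it does and does not emulate

`gen_small_molecules()` assembles molecules from a curated fragment grammar
(starters, chain units, terminals, occasional `%10` macrocycles), which
guarantees validity by construction — no rejection loop — and covers the
primitive grammar's token categories (aromatics, brackets, stereo marks,
both ring-closure syntaxes, cis/trans bonds). `gen_peptide_corpus()` draws
uniform random sequences over the 20 canonical residues and converts them
with the internal builder, optionally cyclizing or N-methylating a fraction;
pTM/pLDDT are independent Uniform(0.4, 1) — they exercise the filter logic
only, with no pretense of structural realism. Labeled tasks tie the signal
to a computable descriptor so the achievable score is controlled by
construction. None of the generators attempts to match the property
distributions of real compound libraries; passing tests therefore
demonstrate correctness of the machinery and the direction of protocol-level
effects, not performance on real data.

## Numerical choices and degenerate inputs

- Layer-norm epsilon 1e-5; attention mask bias −Inf (exact zero weights);
  budget rounding half-up; span rounding nearest-then-clamp.
- Greedy segmentation ties are impossible (one longest match per position);
  vocabulary ranking ties break lexicographically for determinism.
- `canonicalize()` runs a package-side lexical validator (balanced
  branches, paired ring closures, well-formed brackets, no dangling bond)
  before the backend, because OpenBabel silently repairs some broken
  strings; backend parse failure is also a rejection.
- All-pad sequences cannot be pooled (error); empty corpora yield empty
  tables; a zero-step pretraining run returns the initialized checkpoint
  with an empty trace; a zero-epoch finetune returns untrained predictions
  flagged as such.
- MCC of a single-class prediction is defined as 0.

## Known limitations

- OpenBabel's stereo perception slows dramatically on long stereo-rich
  chains (minutes per molecule beyond ~25 residues), so backend-touching
  steps (canonicalization, property computation) are exercised on short
  peptides and small molecules; the tokenizer and compression pipeline are
  backend-free and handle full-length peptides.
- The descriptor manifest is not the RDKit set; models trained against it
  are internally consistent but not comparable to RDKit-descriptor models
  descriptor-by-descriptor.
- Head-only finetuning underestimates what full-model finetuning could
  reach; it is the appropriate desk-scale protocol, not a performance claim.
- Parameter totals of the named scales are reported, not asserted (the FFN
  width needed to reconcile the published totals is not derivable from the
  printed layer/hidden/head numbers).
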