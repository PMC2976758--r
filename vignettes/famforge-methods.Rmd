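---
title: "Subdividing protein superfamilies by iterative profile-HMM refinement"
author: "famforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subdividing protein superfamilies by iterative profile-HMM refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large enzyme superfamilies — the medium-chain dehydrogenases/reductases
(MDR) are the motivating case — contain thousands of members at typically
~25% pairwise identity, spread over families whose within-family identity
runs from ~40% to ~95%. Detection-level profile HMMs exist for such
superfamilies (e.g. one model per constituent domain), but they cannot say
*which family* a new sequence belongs to. Hand-curating a training set for
every family does not scale. famforge implements an automated procedure
that carves a superfamily database into stable, reliable family models:

1. **Extraction** — the two constituent domains (an N-terminal catalytic,
   GroES-like domain and a C-terminal Rossmann coenzyme-binding domain,
   ~350 residues per pair) are located with query models; adjacent N/C hits
   are fused into one region including the linker, lone hits are expanded
   towards the missing partner, and regions shorter than 250 residues are
   dropped.
2. **Clustering** — regions sharing more than 40% pairwise identity are
   greedily clustered; clusters of more than 20 sequences seed a family.
3. **Refinement** — each seed set is aligned, a glocal profile HMM is
   built, the database is searched, and every domain scoring at least as
   high as the worst-scoring current seed joins the next seed. The loop
   stops when membership stabilises. Seeds growing past a divergence cap
   (3000) are aborted and progressively curated: the lowest-scoring 5% of
   the initial seed is removed per round until refinement converges.
4. **Inclusion control** — a leave-one-out jackknife rebuilds each model
   without one seed at a time and asks whether that seed still looks like
   a member. Three spuriousness strategies of increasing permissiveness
   are supported (see below); flagged seeds are removed and the family
   re-enters refinement. Families retaining fewer than 20 members are kept
   but marked unreliable (an `x` postfix and a description warning).
5. **Overlap resolution** — families sharing members are resolved: subsets
   are shelved under their superset (useful for subfamily discrimination),
   partial overlaps whose shared members score low under one model are cut
   by raising that model's threshold slightly, and high-scoring partial
   overlaps are merged and re-refined (a failed, divergent merge is
   rejected and logged).
6. **Cutoffs and characterization** — each final model records gathering
   and trusted cutoffs equal to the minimum over its seeds of their best
   domain score, and a noise cutoff 0.1 bits lower. Families are then
   described by identity statistics, per-column conservation, conserved
   net charge, domain conservation ratios and kingdom distributions.

`run_pipeline()` executes all stages; `scan_sequences()` classifies new
sequences against the finished library using the recorded cutoffs.

## The profile-HMM engine

The engine is deliberately minimal and fully deterministic. Models have
plan7-style topology (match/insert/delete states per node, no
delete–insert transitions) and are scored **glocally**: the path must
traverse the model from its first to its last node (deletions allowed at
cost), while any prefix and suffix of the target sequence is skipped for
free. This is the `hmm_ls` alignment style: global in the model, local in
the sequence. Glocal scoring is what penalises fragments — a truncated
member must pay for every model position it cannot supply — and that
penalty is what keeps partial sequences from accumulating in seed sets
without any explicit model-coverage threshold.

Scores are log-odds in bits against a configurable background
distribution (uniform 1/20 by default, which gives closed-form scores for
small test models). Match emissions are add-k smoothed frequencies
(k = 0.1 by default; 0 yields maximum-likelihood models for exact tests).
Transitions mix observed counts with a fixed-composition prior
(match .9/.05/.05, insert .5/.5, delete .25/.75 DM/DD, begin .95/.05)
scaled by a weight (default 2). The delete prior is intentionally
asymmetric: *entering* a deletion is expensive (roughly −6 bits at
realistic seed sizes) while *extending* one is cheap (−0.415 bits per
position). A terminally truncated sequence therefore pays one entry plus
a long cheap run — a smooth, strictly monotone penalty — whereas a
diverged sequence that would need many short deletions to mask its
mismatches cannot profit. Viterbi ties are broken deterministically:
leftmost envelope, then fewest insertions, then a fixed predecessor
order.

Absolute bit scores from this engine are *not* comparable to HMMER's
(different priors, no Dirichlet mixtures, no null-model correction), and
parity is not a goal: every threshold in the pipeline is defined relative
to scores produced by this engine — primarily the minimum-seed rule —
so only score *ordering* within a model matters.

Two kernels implement the same recurrences in C++: a traceback kernel
(envelopes, alignments) and a score-only kernel used wherever only the
bit score is needed. Because a subsequence's best glocal score can never
exceed the whole sequence's, the score-only kernel also gates database
searches: sequences scoring below threshold are dismissed without any
traceback work. Both kernels are verified against each other and against
a brute-force path-enumeration oracle in the test suite.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| clustering identity | > 0.40 | greedy cluster membership (fraction of the longer sequence) |
| minimum cluster size | > 20 | clusters that may seed a family |
| region length filter | ≥ 250 aa | applied before clustering |
| characterization filter | ≥ 270 aa | applied before characterization alignments |
| divergence cap | 3000 seeds | refinement beyond this is aborted for curation |
| curation batch | 5% (≥ 1) | lowest-scoring initial seeds removed per round |
| redundancy ceiling | < 0.90 | representative identity ceiling |
| conservation threshold | > 95% | cscore level counted as conserved |
| noise cutoff offset | 0.1 bits | NC = GA − 0.1 |
| inclusion strategy | II | see below |
| reliability floor | 20 members | below it, models get an `x` postfix |
| max linker | 40 aa | N/C hits this close are fused |
| singlet expansion | linker 12 + partner length + margin 15 | boundary move for lone hits |

The linker and margin values are this implementation's choices, sized for
a two-domain architecture of ~350 residues and conservative expansion;
they are exposed in `pairing_rules()` and `pipeline_config()`.

Pairwise identity is computed as the number of identical residues on the
optimal global alignment divided by the length of the **longer** sequence
— a deterministic Needleman–Wunsch (BLOSUM62, gap open 11 / extend 1,
via Biostrings) standing in for pairwise BLAST. The longer-sequence
denominator makes fragments look dissimilar to full-length members, which
is what keeps heavily truncated regions out of seed clusters. A local
aligner could count identities differently for fragment pairs; the
aligner sits behind `pairwise_identity()` as the single substitution
point.

## Inclusion control strategies

For each seed, the model is rebuilt without it and the seed is rescored:

* **I (exclusive):** spurious if the left-out seed scores strictly below
  every remaining seed. Ties are not spurious (conservative removal).
* **II (intermediate, default):** additionally requires at least one
  non-seed sequence to outscore the left-out seed — membership strength
  below the noise level. Strategy II needs no user input beyond the
  initial models; it uses only relations found in data.
* **III (inclusive):** additionally requires the left-out score to fall
  below 90% of the lowest remaining seed score.

By construction III ⊆ II ⊆ I per observation. Two optimizations preserve
exact results: database comparisons are evaluated only for seeds that
already fail strategy I, and the internal comparison stops at the first
remaining seed scoring at or below the left-out one (a witness that it is
not spurious). The jackknife model is rebuilt directly from the
row-dropped seed alignment — removing one row leaves the other rows'
columns unchanged — with an optional full realignment behind a flag.

One engine-specific behaviour deserves note: with add-k emission
smoothing, a seed's own private residues contribute to the model it is
scored against, so a left-out member usually scores below all remaining
(self-included) members. Strategy I is therefore extremely exclusive
under this engine, and strategy II — which demands a non-seed witness
before removal — is the operating default.

## The synthetic superfamily generator

`generate_superfamily()` plants ground truth so that every stage is
testable without downloads. Each family descends from its own ancestor
(two random domain blocks of 160 and 180 residues joined by a 12-residue
linker), itself derived from a common superfamily root so that
between-family identity sits near but below the configured cap (default
0.30). Members are substitution-mutated copies of their family ancestor;
the per-site retention is solved analytically from the within-family
identity target (default drawn uniformly from 0.55–0.90 per family), so
measured identities land within a few points of target without indels.
Members carry random terminal flanks (5–30 residues); 10% are truncated
to fragments retaining 60–100% of their length (so a minority fall below
the 250-residue filter); 5% carry two tandem domain pairs; 50 unrelated
random orphans are appended; kingdom labels come from per-family
archetypes echoing a realistic mix (about half purely bacterial, few
purely eukaryotic, occasional all-kingdom families).

What the generator does **not** emulate: insertions and deletions within
domains (mutation is substitution-only by design, because identity
targets are exact without indels), rate heterogeneity across sites, phylogenetic correlation between members, compositional bias, and
low-complexity regions. Passing the recovery tests therefore demonstrates
the pipeline's bookkeeping and threshold logic under controlled identity
structure, not performance on real databases with indel-rich, biased
sequences.

The default test and acceptance problem sizes are 6 families of 25–60
members plus 50 orphans (~300 sequences of ~400 residues) per
superfamily, with 20 such superfamilies in the acceptance suite and 5 in
the acceptance script — sizes chosen so a full run exercises every stage,
including curation and overlap resolution, at desk scale.

## Numerical choices and degenerate inputs

* Match columns are alignment columns with gap fraction below 0.5; an MSA
  with no such column raises a degenerate-model error.
* Emission rows renormalize to 1 within 1e-12 before conversion to
  log-odds; unknown residues (`X`, mapped from ambiguity codes) emit the
  background (0 bits) and never enter counts.
* The all-delete glocal path exists but yields no envelope; it is never
  reported as a domain hit.
* Inclusion uses ≥ threshold (ties included) so current seeds always
  self-retain and seed growth is monotone — which is also why refinement
  terminates on any finite database.
* `refine()` carries a 50-iteration safety valve against floating-point
  rescoring oscillation; it is not a convergence criterion.
* "Slightly raising" a threshold during overlap resolution means the
  highest inconsistent score plus 0.1 bits, mirroring the noise-cutoff
  offset; raising that would evict more than 20% of a seed set escalates
  to the merge path instead.
* Subset shelving breaks exact ties (identical seed sets) by size then
  lexicographic id.
* The conservation score (cscore) defaults to the modal-residue frequency
  with gaps counted in the denominator — a stand-in for the published
  conservation index the field cites, pluggable via the `scorer`
  argument without touching callers.
* The catalytic/coenzyme boundary used for domain conservation counts is
  the N-domain query model's envelope end on the family consensus.

## Known limitations

* Self-training bias (above) means refinement reliably *validates and
  cleans* near-complete seed clusters but grows sparse seeds only toward
  sequences closer to the consensus than the current worst seed. The
  pipeline's clustering stage produces near-complete clusters, so this
  matches its operating regime.
* Fragments below the 250-residue filter are never recovered as seeds;
  they remain classifiable by `scan_sequences()` only if they clear a
  model's gathering cutoff, which glocal scoring makes deliberately hard.
* Model scores are engine-relative; serialized models are exchangeable
  between famforge installations but not with HMMER databases.
* The overlap-resolution guards replace the expert judgment (dendrogram
  inspection) used in manual curation with deterministic rules; every
  action is logged for review instead.
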