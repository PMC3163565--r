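---
title: "Model and methods: transcript quantification by EM and Gibbs sampling"
author: "rnaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: transcript quantification by EM and Gibbs sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

RNA-Seq reads rarely identify their source transcript uniquely: isoforms of
a gene share exons, paralogous genes share sequence, and poly(A) tails are
identical across the whole transcriptome. `rnaquant` estimates isoform- and
gene-level abundances from single-end (SE) or paired-end (PE) reads aligned
to *transcript* sequences, allocating multi-mapping reads probabilistically
under an explicit generative model, and quantifies the uncertainty of every
estimate with Bayesian credibility intervals. Because only transcript
sequences are required (no genome), the same pipeline applies to de novo
transcriptome assemblies.

# The generative read model

A sequenced fragment is modelled as generated in stages:

1. **Source.** With probability $\theta_i$ the fragment derives from
   transcript $i \in \{1,\dots,M\}$; $\theta_0$ is a *noise* component
   emitting reads that align nowhere.
2. **Fragment length** $F \sim \lambda_F(\cdot \mid \ell_i)$: a global
   fragment length distribution truncated at the transcript length
   $\ell_i$ and renormalized.
3. **Start position** $S$: drawn over the $\ell_i - f + 1$ feasible starts
   from the read start position distribution (RSPD) — uniform by default,
   or a binned distribution re-estimated from the data
   (`estimate_rspd`), which captures 3' bias.
4. **Orientation** $O$: forward or reverse with probability $1/2$
   ($P(\text{forward}) = 1$ for strand-specific protocols).
5. **Read length** $L \sim \lambda_R(\cdot \mid f)$, truncated at the
   fragment length — a point mass for fixed-length platforms, in which
   case this factor is 1 for all feasible fragments.
6. **Sequence.** The read (SE: the fragment's 5' read; PE: additionally
   the reverse complement of the 3' end) is emitted through a sequencing
   error model: either the **quality model**
   $P(r_i \mid q_i, c) = \varepsilon(r_i, q_i, c)$ conditioned on the
   Phred quality score at each position, or the **profile model**
   conditioned on read position, for data without reliable qualities.

The joint weight of a read under a candidate alignment multiplies these
factors (`alignment_weight()`); for SE reads the unobserved fragment
length is marginalized over all feasible values. Candidate alignments come
either from a SAM file produced by an aligner configured to report *all*
valid alignments, or from the built-in seed aligner (`align_reads()`,
a Bowtie-like policy: at most 2 mismatches in the first 25 bases,
both strands, full read inside the transcript).

# Maximum-likelihood estimation

`run_em()` maximizes the likelihood over $\theta$ by
expectation-maximization on the candidate alignments. Auxiliary
parameters — the PE fragment length distribution, the RSPD (if enabled)
and the error tables (confusion counts with add-one smoothing) — are
re-estimated together with $\theta$ during the first 20 iterations and
every 100 iterations thereafter; all other iterations update $\theta$
only. Iteration stops when every $\theta_i \ge 10^{-7}$ changes by less
than $10^{-3}$ relative (cap 10,000 iterations). The SE fragment length
distribution is *not* re-estimated: SE data carry almost no direct length
information, so the user-supplied prior (discretized Gaussian, default
mean 280 sd 17) is held fixed.

Two practical filters precede estimation: reads with at least 200
alignments and reads that look poly(A)-derived (A- or T-fraction at least
0.9 — the threshold is our concrete definition of "likely poly(A)"; the
antisense T-rule covers reverse reads) are excluded. Filtering biases
naive estimates against repetitive and tailed transcripts, so the M-step
is corrected: $\theta_i \propto c_i / (N m_i)$, where $c_i$ is the
expected fragment count and $m_i$ the probability that a fragment from
transcript $i$ *survives* the filters. `estimate_repeat_pass_prob()`
computes $m_i$ by enumerating each transcript's distinct read windows —
for fixed-length SE reads a forward read depends only on its start and a
reverse read is the reverse complement of a forward window, so both
orientations reduce to the $\ell - L + 1$ windows — weighting each window
by its generation probability under $\lambda_F$/RSPD, testing the poly(A)
rule directly and the multiplicity rule with the built-in aligner.
Transcripts too large for enumeration (length x fragment-support
$> 10^6$) fall back to seeded Monte-Carlo (10,000 draws). $m_i$ is
floored at $10^{-8}$ so fully repetitive transcripts stay finite. For PE
data $m_i$ uses the mate-1 window's alignment count as the multiplicity
proxy (an upper bound) and checks the poly(A) rule on the windows; the
$m$ computation also uses the mean read length, exact for fixed-length
data. $m$ is computed once from the initial distributions; for SE
defaults those are exactly the final ones (the SE $\lambda_F$ and uniform
RSPD are never re-estimated), and PE re-estimation moves $\lambda_F$
little in practice.

Abundances are reported as expected counts ($c_i$), transcript fractions
$\tau_i \propto \theta_i / \tilde\ell_i$ normalized over transcripts, and
$\mathrm{TPM} = 10^6 \tau$. The effective length
$\tilde\ell_i = \sum_f \lambda_F(f \mid \ell_i)(\ell_i - f + 1)$ is the
mean number of feasible fragment starts; when poly(A) tails are appended
(default 125 bases, mirroring poly(A)+ libraries) the post-tail length is
used throughout, keeping the simulator, the estimator and the
$\tau$-conversion mutually consistent. Gene abundance is the sum of
member $\tau$; `IsoPct` is the within-gene share.

# Posterior inference

With a symmetric Dirichlet prior ($\alpha = 1$, making the MAP equal the
ML estimate) the posterior is explored in two stages
(`gibbs_count_vectors()`, `theta_samples_from_counts()`):

1. **Collapsed Gibbs sampling** of fragment assignments: each read's
   assignment is resampled given all others with probability
   $\propto (\alpha + c_{-n,i}) w$, starting from the ML
   responsibilities; after 200 burn-in sweeps one count vector is
   recorded per sweep (burn-in and thinning are our choices — the chain
   starts at the ML solution, so a short burn-in suffices, and recording
   every sweep matches the stated totals; we verified that stronger
   thinning does not change interval coverage).
2. **Dirichlet draws**: for each count vector $c$, $\theta$ is sampled
   from $\mathrm{Dirichlet}(c + 1)$; the defaults (1000 vectors x 50
   draws) give 50,000 samples.

Each $\theta$ sample is converted to $\tau$ with the same $1/m_i$
de-biasing and effective-length normalization as the ML estimate (the
counts live in *observed*-fragment space; without the correction the
posterior would not be comparable to the ML point estimate), then
summarized into a posterior mean (PME) and an equal-tailed credibility
interval. Gene intervals are computed on per-sample gene sums — interval
endpoints do not add. Auxiliary parameters stay fixed at their ML values
during sampling; this is the main reason measured coverage sits slightly
below nominal even on model-true data.

# The simulator

`simulate_dataset()` draws reads from the same model: transcript
$\sim \theta$, fragment length from the truncated $\lambda_F$, start from
the RSPD, orientation, then quality strings from a first-order Markov
chain (`fit_quality_markov()` learns one from real FASTQ; a built-in
generic Illumina-like chain is the default) and substitution errors
either at the theoretical Phred rate $10^{-q/10}$ (uniform among wrong
bases) or from a learned error table ("empirical"). Ground truth
(transcript, fragment length, start, orientation per read) is emitted
alongside. Fragments shorter than the read length are clamped up to it —
with the default length priors this is a measure-zero event, noted for
completeness. Noise reads (off by default in simulation) are i.i.d.
draws from the background composition.

# The toy-world generator

`make_toy_reference()` builds deterministic synthetic transcriptomes for
closed-loop studies: each gene is a set of exon blocks and each isoform a
distinct exon subset (inducing realistic within-gene multireads), with
optional cross-gene shared blocks and exact repeat copies. Defaults are
chosen to emulate the structure of a curated mammalian annotation:
about 150 genes with 1-3 isoforms (mean ~2, matching the
roughly 1.7 isoforms per gene of RefSeq-style sets), lengths 0.5-3 kb,
designed transcript fractions log-uniform over $[10^{-6}, 10^{-2}]$
(normalized; several orders of magnitude, as in real libraries) with a
30% zero fraction. Isoform subsets are constrained to stay within the
declared length range — very short transcripts have near-zero effective
length, and a single Dirichlet pseudo-count on such a transcript
dominates the $\tau$ normalization, which is a real pathology of
annotation sets containing fragments shorter than the fragment-length
distribution rather than a property of the method.

What the toy world does *not* emulate: sequence-composition bias
(hexamer/GC effects), indels and soft-clipping, PCR duplicates, intron
retention or unannotated transcripts, and chimeric reads. Passing the
closed-loop checks therefore validates the inference machinery, not
robustness to model misspecification on real libraries.

# Validation studies and problem sizes

The package's validation (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) uses desk-scale versions of the standard
checks, sized to run on one CPU in minutes:

* **CI calibration**: ~300 transcripts, 100k SE 35 b reads, sampler at
  500 count vectors x 20 draws; coverage of the 95% CI among transcripts
  with true abundance >= 1 TPM, and its monotone decrease across
  credibility levels 95 -> 50. The standalone calibration script pools
  two independent replicate rounds, since a single round measures the
  coverage fraction on only ~200 eligible isoforms (Monte-Carlo error
  ~2 points). At this scale a 1-TPM transcript receives
  only ~0.1 fragments (vs ~10 in a full-depth mammalian experiment), so
  the uniform Dirichlet prior weighs more heavily on the low-abundance
  eligible transcripts than at publication scale; coverage a point or
  two below nominal is expected behaviour, consistent with the known
  downward bias of these intervals under sparse truths.
* **EM optimality**: on instances with <= 3 transcripts and <= 30 reads
  the EM log-likelihood matches a dense grid search over the simplex to
  $10^{-3}$, and is monotone per iteration.
* **Parameter recovery**: 200k reads from ~80 transcripts; gene-level
  median percent error (MPE) below 5%, global-isoform MPE below 8%.
* **Error-model parity**: on quality-driven simulated errors, quality
  and profile models agree to within 0.5 MPE points at every level.
* **Exactness checks**: filter threshold semantics (200 vs 199
  alignments), conservation laws ($\sum\theta = \sum\tau = 1$,
  $\sum \mathrm{TPM} = 10^6$, counts summing to N, per-read posteriors
  summing to 1), and agreement of the collapsed Gibbs sampler with exact
  enumeration on a 4-multiread instance.

# Numerical choices and edge cases

* `N` bases never match: their emission probability is the smallest
  positive mass of the error model, avoiding $-\infty$ log-likelihoods
  without letting `N` carry signal.
* Zero-weight candidate alignments (infeasible fragment geometry) get
  zero posterior mass; a read whose weights are all zero with
  $\theta_0 = 0$ raises an error naming the read.
* Identical transcripts are genuinely unidentifiable; uniform
  initialization makes EM return exactly symmetric estimates, which is
  documented behaviour rather than resolved arbitrarily.
* The indexed aligner requires N-free seeds (2-bit packing);
  `enumerate_alignments()` is the fully general exhaustive reference
  implementation and the two are cross-checked in the tests.
* Equal-tailed intervals use empirical quantiles of the sample matrix;
  with 10,000+ samples the Monte-Carlo error of the endpoints is well
  below the reported precision.
* Seeding: all stochastic steps (simulation, Monte-Carlo $m$, sampler
  initialization and sweeps via R's RNG inside the C++ kernels) are
  reproducible under `set.seed()`.

# Limitations

Beyond the toy-world caveats above: gapped alignments and color-space
reads are out of scope; the noise-read model is a simple background
composition; sequence-specific (hexamer) bias is not modelled; and
genome-coordinate projection of results (BAM/wiggle against a genome) is
not provided — outputs are in transcript coordinates.
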