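# rnaquant

Isoform- and gene-level abundance estimation from RNA-Seq reads aligned to
transcript sequences — no reference genome required — with
expectation-maximization (EM) point estimates, Bayesian credibility
intervals from collapsed Gibbs sampling, and a matching read simulator for
closed-loop validation.

## Who this is for

Anyone quantifying bulk RNA-Seq against a set of transcript sequences: a
curated annotation (RefSeq/Ensembl transcripts, or a GTF plus genome) or a
de novo assembly. The central difficulty is that reads multi-map —
isoforms share exons, paralogs share sequence, poly(A) tails are shared by
everything — so per-transcript read counting is ill-defined. `rnaquant`
resolves multireads with a generative model and reports how certain each
abundance actually is.

## The model in brief

A fragment comes from transcript `i` with probability `θ_i` (`θ_0` is a
noise component for unalignable reads). Its length follows a global
fragment length distribution `λ_F` truncated at the transcript length, its
start follows a read start position distribution (RSPD), its orientation
is uniform (or fixed, for stranded protocols), and the read sequence is
emitted through a quality-score– or position-dependent substitution error
model `ε`. EM maximizes the likelihood of the observed alignments over
`θ`, with a correction `θ_i ∝ c_i/(N·m_i)` for reads lost to the
multi-alignment and poly(A) filters (`m_i` = probability a fragment from
`i` survives them). Estimates are reported as expected counts, transcript
fractions `τ_i ∝ θ_i/ℓ̃_i` (with `ℓ̃` the effective length), and
`TPM = 10⁶·τ`. With `ci = TRUE`, a two-stage sampler (collapsed Gibbs over
read assignments under a Dirichlet(1) prior, then `θ ~ Dirichlet(c + 1)`
per count vector) yields posterior means and equal-tailed 95% credibility
intervals per isoform and gene.

Full details: `vignettes/transcript-quantification.Rmd`.

## Worked example

Simulate a small dataset from a known toy transcriptome, then quantify it
(runs in under a minute):

```r
library(rnaquant)
set.seed(1)

toy <- make_toy_reference(toy_spec(n_genes = 10, length_range = c(400, 800),
                                   zero_fraction = 0, seed = 71))
ts  <- append_polya(toy$ts, 125)                 # poly(A)+ reference
fd  <- gaussian_length_dist(180, 15)             # fragment length prior
par <- model_params(theta = tau_to_theta(toy$tau, effective_lengths(ts, fd)),
                    frag_dist = fd, read_dist = point_length_dist(35))
sim <- simulate_dataset(par, ts, 4000, read_len = 35)

fit <- quantify(sim$reads, ts, ci = TRUE,
                control = quant_control(fragment_length_mean = 180,
                                        fragment_length_sd = 15),
                sampler = sampler_config(n_count_vectors = 100,
                                         theta_per_vector = 10,
                                         burn_in = 20))
fit
```

```
RNA-Seq abundance fit
  transcripts: 17 (10 genes)
  reads: 4000 total, 426 filtered, 48.0 expected noise
  EM: 197 iterations, logLik -34544.10
  posterior: 95% credibility intervals available
```

(426 reads were filtered as poly(A)-like or highly multi-mapping; the
M-step `m_i` correction compensates for them.)

`coef(fit)` returns the isoform table (`coef(fit, "gene")` the gene
table): for each transcript its length, effective length, expected read
count, `TPM`, `tau`, within-gene percentage, and the posterior mean and
95% interval of TPM. For example (first rows, rounded):

```r
head(coef(fit)[c("transcript_id", "expected_count", "TPM", "pme_TPM",
                 "TPM_ci_lower", "TPM_ci_upper")], 3)
```

```
  transcript_id expected_count        TPM    pme_TPM TPM_ci_lower TPM_ci_upper
1       g001.t1        1.00011    255.791    494.965      57.0944      1315.72
2       g002.t1      355.99342 127730.427 114760.416   78226.3590    148087.71
3       g002.t2      597.00658 216314.579 228983.019  194959.7431    267365.46
```

Read: the model attributes ~356 fragments to isoform `g002.t1` and ~597
to its sibling `g002.t2`; after effective-length normalization their
abundances are ~128k and ~216k transcripts per million, with 95%
credibility intervals of roughly [78k, 148k] and [195k, 267k] — wide
because the two isoforms share most of their sequence. `g001.t1`, seen in
a single fragment, is correctly reported as barely expressed with a very
uncertain interval. Comparing `fit$estimates$tau` with `toy$tau` closes
the loop (`accuracy_stats()`, `ci_coverage()`).

A thin command-line interface wraps the same functions:

```sh
exec/rnaquant prepare-reference --fasta ref.fa --gene-map map.tsv --out ref
exec/rnaquant calculate-expression --reads reads.fq --reference ref \
    --calc-ci --out sample1
exec/rnaquant simulate-reads --model sample1.model.txt --reference ref \
    --n-reads 100000 --out simreads
```

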