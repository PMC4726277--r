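---
title: "Identifying parasitoid venom proteins from combined transcriptomic and proteomic evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying parasitoid venom proteins from combined transcriptomic and proteomic evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomics)
```

## The problem and the model

Parasitoid wasps inject venom into their hosts to manipulate host immunity,
development and metabolism. Venom proteins are made by venom-gland cells and
secreted into the gland lumen, so a transcript encoding a true venom protein
should satisfy three independent criteria:

1. it is strongly over-expressed in the venom gland relative to the rest of
   the female body (the "carcass");
2. its protein carries an N-terminal secretion signal peptide;
3. its tryptic peptides are detectable by LC-MS/MS in the venom reservoir.

`venomics` computes each evidence stream separately and takes their strict
intersection. The intersection is deliberately conservative: venom proteins
that are not gland-enriched (known in some systems), or too small to survive
gel separation, will be missed, and the package makes no attempt to rescue
them.

### Differential expression without replicates

The design is two libraries, one per tissue, with no biological replicates.
We therefore use the conditional exact binomial test: conditioning on a
gene's total count $t = n_{VG} + n_C$, under the null of equal relative
expression $n_{VG} \sim \mathrm{Binomial}(t,\, N_{VG}/(N_{VG}+N_C))$ with
$N$ the library sizes. The two-sided p-value sums the probabilities of all
outcomes no more likely than the one observed (minimum-likelihood ordering,
the same convention as `binom.test`). A normal-approximation variant is
available behind `method = "normal"`. P-values are Benjamini–Hochberg
adjusted, and a gene is called DE iff

* $\mathrm{FPKM}_{VG} > 10$,
* $\log_2(\mathrm{FPKM}_{VG}/\mathrm{FPKM}_{C}) > 1$, and
* $q < 0.001$,

all strict, exactly as printed in the study design this mirrors. A zero
carcass FPKM with positive venom-gland FPKM gives $+\infty$, which passes
the ratio criterion; 0/0 is an undefined marker and never passes.

An important caveat, which the tests encode explicitly: an unreplicated
two-library test measures *sampling* (Poisson) noise only. If counts carry
biological overdispersion, the test is anti-conservative — there is no
statistical fix without replicates. Accordingly, the BH calibration test
runs the generator at near-zero dispersion (the Poisson technical null, the
only null under which "BH validity" is well-posed), while the default
generator dispersion (0.1) represents the realistic overdispersed world in
which recovery, not calibration, is the claim being tested.

### Signal peptides

Two routes are implemented, mirroring common practice when many transcripts
are fragmentary:

* **Annotation transfer**: if a transcript's best database hit starts at
  subject position 1 (a complete N-terminus) and the subject's signal-peptide
  status is known, that status is transferred. Transcripts without a usable
  hit are *undetermined*, not negative.
* **Local heuristic**: a stand-in for neural predictors, scanning candidate
  cleavage sites at residues 10–40 and requiring (i) non-negative net charge
  in residues 1–5 (K/R = +1, D/E = −1), (ii) an 8-residue window of mean
  Kyte–Doolittle hydropathy ≥ 1.6 before the site, and (iii) small residues
  (A/G/S/C/T/V) at the −3 and −1 positions. The reported cleavage site
  maximizes the h-window hydropathy, earliest on ties.

The heuristic is not a SignalP replacement — it has no notion of
transmembrane segments and its thresholds are fixed, not learned. An
external-prediction TSV reader lets users substitute real predictor output.
When both routes give a determinate call, transfer wins by default
(`precedence` option), since the disagreement-resolution rule in such
studies is rarely stated.

### Proteomic confirmation

PSMs are filtered with the classic charge-dependent Sequest thresholds
(ΔCn ≥ 0.1; Xcorr ≥ 1.9, 2.2, 3.75 for charges 1, 2, 3; charges above 3 use
the charge-3 threshold, a stated extension since only 1–3 are printed).
Passing peptides map to a predicted protein only as exact substrings whose
boundaries coincide with tryptic cut sites (cleave after K/R unless followed
by P) or protein termini. Peptides matching several proteins confirm all of
them but flag them ambiguous; no parsimony inference is attempted, because
the emulated study describes none. One distinct peptide suffices by default
(`min_peptides`). Leucine and isoleucine are distinct (this is sequence-level
matching against an in-silico database, not spectral matching).

### Comparative analysis

Each venom protein's best hit against two reference venom sets (minimum
e-value; ties by maximum bit score, then subject id) is called homologous iff
e-value ≤ 1e−5 **and** bit score ≥ 50, both inclusive. The dual cutoffs
partition the set into unique / shared-with-A-only / shared-with-B-only /
shared-with-both, and a bit-score sweep (`cutoff_sensitivity`) shows how the
partition moves with the threshold. Paired score comparisons use:

* `paired_better_fraction`: strict comparisons, a present score beats an
  absent one (a documented choice — the emulated analysis does not state its
  absence rule);
* `wilcoxon_signed_rank`: exact over the $2^n$ sign assignments for
  $n \le 25$ (computed by an equivalent rank-sum dynamic program), normal
  approximation with continuity and tie corrections beyond; e-values are
  compared as $\log_{10}$ values floored at $10^{-180}$, and pairs with a
  missing side are excluded (no defined difference);
* `fisher_exact_2x2`: hypergeometric conditioning on both margins,
  two-sided by the minimum-likelihood convention with $10^{-7}$ relative
  slack, matching `fisher.test`.

## The synthetic world

`simulation_config()` states the world once; the generators derive
everything from it deterministically (each consumes `seed` plus a fixed
offset, so outputs are byte-identical across runs and independent of call
order).

| parameter | default | why |
|---|---|---|
| `n_transcripts` | 500 | desk-scale stand-in for a ~40k-unigene assembly |
| `n_venom` | 20 | scaled-down 70-protein venom set |
| `fold_change_venom` | 8 | the enrichment regime the recovery claim is stated for |
| `library_size_vg`, `library_size_carcass` | 29,540,102 / 28,109,926 | the emulated study's printed tissue read totals, used as the FPKM-to-count conversion depth |
| `dispersion` | 0.1 | typical biological overdispersion; 0 = rounded expectations |
| `sp_fraction_background` | 0.07 | matches the ~7% whole-transcriptome signal-peptide rate seen in such studies |
| `psm_depth` | 3 | mean passing PSMs per supported protein (min 1) |
| `venn_design` | proportional to (14, 25, 13, 18)/70 | the published three-set partition, rescaled |

Venom transcripts are built around an explicit ORF: a short 5' UTR ending in
an in-frame stop, then a textbook signal peptide (`MKK` + 10×L + `ALA`,
cleavage after residue 16), a random mature region of 80–200 residues, a
stop, and a short 3' UTR. Codon and UTR draws are resampled until the
planted ORF is the dominant six-frame ORF, so translation recovers the
planted protein by construction. Background transcripts are 80% coding (with
an acidic N-terminus, so the signal heuristic's charge rule fails) and 20%
non-coding, with a `sp_fraction_background` share carrying the same planted
signal.

Counts come from planted FPKM levels (log-normal background; venom genes
floored so expected venom-gland FPKM ≥ 50 at the configured fold change)
converted to negative-binomial means via the nominal library sizes. Because
realized library sizes are the column sums, venom-gene enrichment slightly
deflates all venom-gland FPKMs — the same composition bias real RNA-seq has;
at the default fold it costs ~0.4 log2 units and is absorbed by the planted
margin.

PSMs are drawn only from the **mature** region of each supported protein
(tryptic fragments starting after the cleavage site): a secreted proteome
does not contain signal-region peptides, and the shared planted signal would
otherwise create ambiguous cross-matches no real experiment would show.
Decoy PSMs (random peptides failing either the ΔCn or the Xcorr threshold)
are interleaved and must never survive filtering.

Homology tables realize the planted Venn design directly: shared pairs get
bit scores uniform on [55, 300], unshared on [20, 45], with e-values
$10^{-\mathrm{bit}/10}$ for internal consistency — any monotone pairing
would do; this one is stated so tests are stable.

**What a green test does not establish.** The generator's sequences are
uniform-random where real sequences have composition structure; its signal
peptides are a single planted motif, not the real diversity the heuristic
would face; PSM evidence is sampled at the peptide level with no spectral
noise, retention or missed-cleavage structure; homology scores are sampled,
not computed from alignments. Green tests establish that the pipeline's
logic — thresholds, intersections, statistics — is correct, not that its
heuristics match neural predictors or search engines on real data.

## Numerical choices

* N-containing codons translate to `X`; `X` never counts as a match in
  clustering identity.
* Clustering identity = exact matches in a global alignment (match 1,
  mismatch 0, gap −1) divided by the shorter sequence's length — the greedy
  length-sorted convention; the alignment exists only to position matches.
* ORF candidates are stop-free segments trimmed to their first Met when one
  exists; the longest trimmed candidate wins, earliest frame on ties; below
  10 aa the result is a no-call, distinct from an error.
* Nx statistics use the descending cumulative-sum definition; "longer than
  N50" is strict.
* The signed-rank exact/approximate switch sits at n = 25 and is exposed, so
  results are reproducible; the exact branch is a generating-function
  convolution over doubled ranks, mathematically identical to enumerating
  all sign assignments.
* Two-sided exact tests (binomial, Fisher) use minimum-likelihood ordering
  with `1e-7` relative slack against floating-point ties, the same
  convention as base R.
* Category keywords are matched case-insensitively in a fixed precedence
  order (inhibitor domains before enzyme words); "venom protein" followed by
  a single letter is *unknown*, longer tokens are informative and fall to
  *others*.

## Known limitations

* The DE test models technical sampling only; with unreplicated libraries,
  biological variability is attributed to expression difference. This is a
  property of the design, not the implementation.
* The signal heuristic's fixed thresholds were chosen from textbook values,
  not trained; on real proteomes expect lower sensitivity than transfer or
  neural predictors.
* `cluster_redundant` is $O(n^2 L^2)$ — fine for reference venom sets
  (tens to hundreds of proteins), not for whole proteomes.
* The published comparative p-values that depend on the original paired
  score lists (signed-rank p = 0.009 / 0.001) and all counts requiring the
  deposited reads or nr database (2714 signal-peptide unigenes, 2355 DE,
  630 confirmed, the 14/25/13/18 partition, N50 = 2226) are not
  desk-reproducible; the package covers the corresponding machinery with
  enumeration oracles and planted-truth recovery instead.
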