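---
title: "Designing and analysing engineered overlapping reading frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing engineered overlapping reading frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfoverlap)
```

## The problem

Synthetic gene circuits are usually costly to their host, so loss-of-function
mutants are selected and the circuit decays. One counter-measure is to
entangle the costly gene with an essential one: create a second reading frame
*inside* the costly coding sequence, open it with its own ribosome-binding
motif, and clone an essential gene (for example an antibiotic-resistance
marker) downstream so that its translation initiates inside the costly gene.
Polar mutations in the overlapped region — frameshift-causing indels,
insertion-sequence transpositions, rearrangements — then inactivate the
essential gene too and are purged by selection. The overlap converts much of
the costly gene's mutational target into evolutionary dead-ends.

`orfoverlap` implements the complete computational side of this strategy:

* the **sequence designer** (`designOverlaps()`): create a translation
  initiation motif in an alternate frame by recoding of the existing frame,
  then clear the new frame for expression;
* the **protection model** (`simulateProtection()`, `protectionExact()`):
  how much of the mutational supply the overlap removes;
* the **lifetime model** (`medianLifetime()`, `circuitSurvival()`,
  `multiGeneLifetimeSim()`): what that removal buys in circuit longevity;
* the **fluctuation statistics** (`escapeFraction()`,
  `mannWhitneyOneSided()`, `rankBiserial()`, `jonesEstimator()`) used to
  quantify protection experimentally;
* batch **screening** (`screenGenes()`) and **synthetic-data generators**
  (`randomCDS()`, `plantMotif()`, `synthFluctuationCounts()`).

## The designer

### Motif model

A translation-initiation motif is a Shine-Dalgarno hexamer within a Hamming
distance of the consensus `AGGAGG` (default tolerance: 1 mismatch), followed
by a 3–7 nt spacer, followed by a start codon (default `ATG` only; GTG/TTG
initiation exists in bacteria but is weaker and context-dependent, so it is
opt-in via `motifSpec(startCodons=)`). No thermodynamic scoring is applied:
the consensus motif is deliberately used as the least context-dependent
signal, and candidate constructs can be re-scored afterwards by any external
RBS model.

### Search strategy

Enumerating all synonymous variants of a whole gene is hopeless (a 300-codon
protein has up to $3.2^{300}$ of them), but motif creation is local: whether
a motif can open at a position depends only on the nucleotides under the SD
hexamer and the start codon, at most five existing-frame codons. The search
therefore walks every alternate-frame position, enumerates the synonym sets
of exactly those codons (a few hundred to a few thousand combinations), and
keeps, per position, the variant with the fewest amino-acid changes, then
the fewest nucleotide edits, then the lexicographically smallest edited
sequence — the last two rules are tie-breaks we fixed ourselves, chosen so
that output is deterministic. This is equivalent to brute-forcing an 18-nt
sliding window (the maximal motif span 6+7+3 rounded up to a codon) but
prunes the spacer codons, which are unconstrained; the test suite verifies
the equivalence against exhaustive full-sequence enumeration on small genes.

### Stringency levels

* **S0** — all edits synonymous in the existing frame; sites whose new-frame
  stop codons cannot be removed synonymously are rejected.
* **S1** — one amino-acid change allowed in total (motif creation or stop
  removal).
* **S2plus** — one amino-acid change for the motif; irremovable stops are
  reported as *remaining* manual substitutions with suggested replacements,
  because many alternative substitutions can remove a stop and their
  neutrality is best judged (or assayed) by the user.

### Frame clearing

After motif creation the new frame is scanned to the end of the gene. Stop
codons are removed by synonymous recoding of the one or two existing-frame
codons beneath them; a fix must not touch the created motif and must not
create a new stop elsewhere in the new frame. Three best-effort passes
follow, always synonymous and never at amino-acid cost: removal of secondary
initiation motifs downstream of the created one (they could found truncated,
unprotected proteins), of mononucleotide runs longer than 3 nt (frameshift
hotspots), and of rare codons in the new frame (they slow translation; the
default set is the eight least-used *E. coli* codons and is configurable,
since no canonical list exists). Failures of the best-effort passes are
recorded in the candidate's flags rather than causing rejection.

The host gene's own terminal stop codon is never edited. Stops that the new
frame forms over the junction are handled when the downstream gene is fused
(`applyOverlap()`): a 0–2 nt phasing pad puts the downstream CDS into the
candidate's frame, and the pad bases are chosen so that the junction codon
is not a stop and the pad creates no new initiation motif.

```{r designer}
cds <- CDSRecord("toy", "ATGAGGAGGCATCATCATGCATAA")
cand <- designOverlaps(cds, designConfig("S0"))
cand[[1]]
candidateTable(cand)
```

## The protection model

One mutation is drawn per replicate in the upstream (costly) gene: a
frameshift with probability `fs`, otherwise a substitution, uniformly
positioned. Effects:

* a frameshift at position $x$ scrambles all upstream codons downstream of
  $x$; if $x$ falls in the overlap (the 3'-terminal `overlapFraction` of the
  gene) the downstream gene's whole frame shifts and all its codons change;
* a substitution changes one upstream amino acid; in `riboverlap` mode it
  never touches the downstream protein (the overlap encodes only a
  non-functional N-terminal extension), in `protein_overlap` mode a
  substitution inside the overlap also changes one downstream amino acid.

Loss of function given $n$ amino-acid changes follows either the discrete
stochastic model (Bernoulli, probability $1-(1-P_e)^n$) or the continuous
deterministic model (activity $(1-P_e)^n$, loss below a threshold of 0.5 by
default; a normalized dot-product protection metric is also provided for
this model). $P_e$ is the average deleteriousness of one substitution;
literature estimates motivate the canonical grid $P_e \in \{0.1, 0.3, 0.5\}$
and $f_s \in \{0.1, 0.3, 0.7\}$ (wild-type *E. coli* sits around
$f_s = 0.1{-}0.4$; mismatch-repair-deficient mutators reach 0.7–0.9).

The **protection** is
$\Pr(\text{downstream LOF} \mid \text{upstream LOF})$, estimated over
100,000 replicates by default, with a binomial-normal 95% CI. Because every
ingredient is an expectation over position and type, the same rules yield a
closed form (`protectionExact()`), used both as a cross-check of the sampler
and as the fast protection curve for the lifetime simulations. The model
treats frameshift scrambling of all downstream codons as the frameshift
severity assumption; it makes frameshifts near-certainly deleterious except
very close to the 3' end. An optional refinement (nonsense-mutation creation
by substitutions) is deliberately not modelled in `riboverlap` mode, where
substitutions never harm the downstream gene.

```{r protection}
p <- protectionParams(Pe = 0.1, fs = 0.7, overlapFraction = 1,
                      nReps = 20000, seed = 1)
simulateProtection(p)
protectionExact(p)
```

## The lifetime model

Selectable loss-of-function mutations arrive as a Poisson process with rate
$\mu N$ per generation ($\mu$ per genome per generation, $N$ the constant
population size; generations are synchronous-equivalent, i.e. total
divisions divided by $N$). The waiting time to the first such mutation is
exponential, so the median circuit lifetime is $\ln 2 / (\mu N)$; an overlap
with protection $p$ scales $\mu$ by $(1-p)$ and hence the lifetime by
$1/(1-p)$. For an $n$-gene circuit the survival probability is
$e^{-Nt\sum_i \mu_i(1-p_i)}$. `multiGeneLifetimeSim()` samples circuits from
a pool of (gene length, best overlap fraction) pairs — such as a
`screenGenes()` table — and reports the median lifetime with and without the
overlaps; the relative gain is approximately independent of circuit size.

## Fluctuation statistics

The experimental read-out is a Luria-Delbrück design: parallel cultures grow
without selection, then each is plated on a counter-selective medium (counts
all costly-gene mutants) and on the same medium plus the essential gene's
selection (counts the mutants that escaped the protection). The per-culture
escape fraction is compared between the overlap construct and an operon
control with a one-sided Mann-Whitney U test (exact for small samples,
normal approximation with tie correction otherwise — the behaviour of
`stats::wilcox.test`, which backs the implementation), with the rank-biserial
correlation $r = 1 - 2U/(n_1 n_2)$ as effect size. The expected *number of
mutations* per culture (distinct from the number of mutants, because mutant
clones expand) is estimated from the median count $\tilde r$ with the Jones
median estimator $m = (\tilde r - 0.693)/(\ln \tilde r + 0.3665)$, which
tracks the Lea-Coulson median equation $\tilde r / m - \ln m = 1.24$ within
a few percent over the practically relevant range; when the median is zero
the $P_0$ method $m = -\ln(\text{fraction of zero cultures})$ is used.
Because the published summary of "avoided mutations" does not state whether
means or medians were compared, `avoidedMutations()` reports both.

## Synthetic data

The generators exist so that every operation is testable without any
downloaded sequence:

* `randomCDS()` draws valid CDSs (start codon, stop-free body, terminal
  stop) under configurable codon-usage weights (uniform by default —
  adequate for exercising the designer, though real genomes are more
  GC-structured);
* `plantMotif()` writes a consensus motif into a CDS and repairs collateral
  frame-0 and new-frame stops using non-motif nucleotides, yielding a
  guaranteed zero-edit candidate at a known position together with the
  expected answer — the oracle for recovery tests;
* `synthFluctuationCounts()` simulates cultures by discrete doubling
  generations with mutation at division (clones founded at generation $g$
  grow to $2^{G-g}$ cells), reproducing the heavy-tailed Luria-Delbrück
  mutant-count distribution. It is adequate for estimator testing, not a
  research-grade sampler (no death, no differential fitness, no plating
  model beyond binomial thinning).

What passing tests on these fixtures do *not* show: performance on real
genomes with strong codon bias, GC skew, or overlapping regulatory elements;
nor whether a designed motif actually initiates translation in a given mRNA
context (secondary structure is explicitly out of scope).

## Numerical and design choices

* Coordinates are 0-based half-open everywhere, including written reports
  (stated in their headers).
* Only the sense strand is considered; antisense overlaps are out of scope.
* Ambiguity codes are rejected rather than expanded: the variant space is
  already combinatorial.
* Windows step by one codon, not one nucleotide: synonymous enumeration
  requires codon alignment, and consecutive windows overlap enough that no
  motif expressible within the window span is missed (verified against the
  exhaustive oracle).
* Candidate de-duplication key is (start position, frame); ties between
  equally cheap variants are broken by nucleotide-edit count, then
  lexicographic order of the edited sequence — the published method does not
  specify tie-breaking, so we fixed a deterministic rule.
* The Monte-Carlo / exact-expectation pair is held to 3 standard errors of
  agreement on a 3×3×3 parameter grid in the tests.
* Problem sizes in the test suite (CDSs of 12–50 codons for designer
  properties, 384 codons for the gene-scale sweep, $2\times 10^4$ replicates
  for simulator cross-checks, $10^5$ for the headline protection run, 4000
  circuits per lifetime point) were chosen as the smallest sizes at which the
  checked quantities are statistically stable.

## Reproducing published-scale results

The genome-scale numbers (candidate counts in a real bacterial gene such as
*galK*, the fraction of a genome's genes admitting an overlap) depend on the
input sequences and on the designer configuration, and the exact published
configuration is not fully specified — they are reproduction experiments,
not fixed targets. With a user-supplied FASTA of the *E. coli* MG1655 *galK*
CDS:

```{r galk, eval = FALSE}
galK <- readCDSFasta("galK.fasta")[[1]]
sweep <- lapply(c("S0", "S1", "S2plus"), function(st)
  candidateTable(designOverlaps(galK, designConfig(st))))
```

and compare candidate counts, overlap fractions and amino-acid costs across
the sweep. A genome screen is `screenGenes(readCDSGenBank("genome.gb"))`.

## Known limitations

* No mRNA secondary-structure or translation-rate model; no protein
  N-terminal-fusion tolerance prediction. Both are explicitly delegated to
  external tools applied to the candidate list.
* The protection model is position-and-count based, not sequence-explicit;
  it has no selection dynamics beyond the purge criterion and no clonal
  interference.
* The lifetime model is first-arrival only.
* The GenBank reader is a minimal offline CDS extractor (joins compound
  locations, honours `complement`), not a general feature parser.
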