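---
title: "Methods: phylogeny-aware ancestral synteny reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-aware ancestral synteny reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ancsyn` treats a syntenic block as a set of ortholog groups (OGs) whose
members were proximal in a chosen ancestral node `N` of a species cladogram,
with no collinearity requirement and no hard limit on block size. The
distance unit throughout is the **count of intervening annotated genes**:
for two genes at chromosome ranks `r_i < r_j`, `d = r_j - r_i - 1`, so
adjacent genes have `d = 0`. Base-pair spans, strand and gene length never
enter the computation; every annotation entry (including genes outside any
OG) consumes one rank and therefore counts as an intervening gene.

The pipeline has four stages:

1. Per species, the minimum `d` over all copy pairs of every unordered OG
   pair sharing a chromosome (self-pairs capture syntenic paralogs). Pairs
   with records in fewer than `min_species = 2` species are discarded.
2. For node `N`, its children define the ingroup clades; the sister lineage
   and the remaining species form the outgroup. A clade *supports* a pair if
   at least one of its species has a distance record. A pair is called
   syntenic in `N` when (a) at least `min_clades = 2` ingroup clades support
   it, or (b) one ingroup clade and at least one sister/outgroup species do —
   the parsimony argument being that presence on both sides of `N` implies
   presence in `N`. Each supporting clade `g` contributes
   `d_g = ` the major mode of a Gaussian KDE over its observed distances,
   and `d_N` is the arithmetic mean of the `d_g`.
3. Accepted pairs form the raw OG graph (edge weight `d_N`; paralog
   self-pairs are stored as node attributes and never participate in
   cliques). Edges with `d_N < nmax` (strict) survive trimming; each
   connected component of the trimmed graph is decomposed into the maximal
   cliques of the **raw** graph induced on the component. Cliques of at
   least `min_len = 3` OGs become ancestral OG sets: trimming decides which
   neighborhoods are close enough in `N`, while clique completeness is
   checked against all accepted evidence, including edges above `nmax`.
4. For every ancestral set and every genome, all genes of the set's OGs are
   collected wherever they lie; proximity affects only the classification
   labels, never membership. Per-species blocks sharing OGs merge into
   multi-species blocks (connected components of the OG-sharing relation),
   and a block is retained as inherited from `N` if its carrier species
   satisfy the same clade rule as stage 2. Rejected blocks are written to an
   audit file, not dropped.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_species` | 2 | species | pair retention before any node analysis |
| `min_clades` | 2 | ingroup clades | acceptance rule at `N` (route a) |
| `nmax` | 2 (flat) | intervening genes | trimming threshold, see below |
| `min_len` | 3 | OGs | smallest reported ancestral set |
| `min_ogs_extant` | min(3, set size) | OGs | per-species block completeness |
| `micro_gap` | 10 | intervening genes | `uSy` vs `MSy` display label |

`micro_gap` deliberately affects only labels: detection stays scale-free.
`min_len = 3` reflects that 2-OG cliques are overwhelmingly noise under any
pairwise criterion; they can be emitted with an explicit flag.

## KDE details

The clade-level ancestral distance is the argmax of a Gaussian KDE with
Silverman's rule-of-thumb bandwidth, floored at 0.5 so zero-variance samples
keep a finite bandwidth, evaluated on the integer grid spanning the
observations; ties break toward the smaller distance. Consequences worth
knowing: a single observation is returned as-is, and for exactly two
distinct observations the estimate always equals the smaller one (the two
boundary maxima tie whenever the bandwidth puts them below the midpoint
bump, and the tie rule picks the smaller). The batch implementation uses
these closed forms and falls back to the full estimator for three or more
distinct values; a property test pins batch and reference routes together.

## Choosing `nmax`: the noise-edge law

`nmax` separates "proximal in `N`" from "merely co-resident". The published
intuition — deeper nodes should tolerate larger `nmax` — is available via
`default_nmax(base, step)`, but the shipped default is a flat `base = 2`,
for a quantified reason. Consider a random (non-syntenic) OG pair in a
dataset of `n` genes per genome. The probability that one species yields a
record with `d < c` is about `2c/n` regardless of chromosome count (more
chromosomes mean fewer co-residencies but shorter chromosomes). A clade of
`S` species therefore shows a spurious small distance with probability about
`2Sc/n`, and because the KDE mode of few observations behaves like their
minimum, a pair acquires a spurious `d_N < nmax` with probability on the
order of `(2 S_A nmax / n)(2 S_B nmax / n)` for ingroup clades of sizes
`S_A, S_B`. Multiplying by the ~`n^2/2` candidate pairs, the expected number
of spurious trimmed edges is roughly

```
E[noise edges] ~ 2 * S_A * S_B * nmax^2
```

— independent of genome size. Once this count approaches half the number of
OGs, the trimmed graph percolates into giant components, and because the raw
graph is dense (any pair co-resident on both sides of `N` is an accepted
edge), clique decomposition of those components floods the output with
chance triangles that merge into false multi-species blocks. Measured on the
bundled 8-leaf world: shuffled-order null runs produce 8–31 false validated
blocks of ≥4 OGs per run at `nmax` 3–4 and zero at `nmax = 2`, while planted
blocks remain fully recoverable at `nmax = 2`. On datasets with many more
species per clade the balance shifts and `step > 0` becomes appropriate;
both constants are plain function arguments.

## The synthetic world

The simulator emulates the regime the method is designed for: a set of
selection-maintained microsyntenic blocks embedded in genomes whose
background gene order decays over time.

* 2000 background genes per genome over 24 chromosomes (a metazoan-like
  karyotype; co-residence of random OG pairs must be rare, which is also
  what keeps clique enumeration tractable). Each background gene founds its
  own OG present in all species.
* Planted blocks (default 10, of 4–8 OGs) are inserted as contiguous runs at
  their origin nodes during a top-down traversal.
* Per branch, each block independently suffers: expansion (1–3 OG-less genes
  inserted inside the span, p = 0.3), translocation of one member
  (p = 0.1), loss of one member copy (p = 0.1), whole-block loss
  (p = 0.05), tandem duplication creating a syntenic paralog (p = 0.05).
  The cladogram has no branch lengths, so rates are per branch.
* Each background gene relocates with p = 0.8 per branch, so background
  adjacency decays within about one branch. Relocated genes never land
  strictly inside a planted block span: insertions into a maintained cluster
  are what the expansion event models. Without background scrambling every
  chromosome would be one genuine ancestral block and "planted" recovery
  would be meaningless.

What a green end-to-end test does establish: the pipeline recovers planted
proximity relations at the correct ancestor, polarizes them correctly
(nothing confined to one clade is reported at its ancestors), and reports
zero ≥4-OG blocks on order-randomized genomes. What it does not establish:
behavior under unequal genome sizes, missing annotations, orthology errors,
branch-length-dependent rates, or clade counts approaching the published
80-genome analysis — none of which the generator models.

## Numerical and determinism choices

* Coordinates are 0-based half-open; ranks sort by `(start, end, gene_id)`;
  strand is stored but never used. Overlapping genes get distinct ranks.
* Unordered pairs are canonicalized lexically; chromosome ties at equal
  minimum distance resolve to the lexically smallest chromosome name.
* Components sort by (size desc, smallest member); cliques by (size desc,
  lexical); multi-species block ids are assigned in lexical order of the
  sorted OG union. Nothing in the core draws random numbers, so fixed
  inputs give byte-identical outputs; the pipeline additionally hashes
  inputs and parameters per stage (`manifest.json`) and skips stages whose
  outputs are current.
* `d_N == nmax` is always excluded (strict inequality as specified).

## Known limitations

* The acceptance rule is permissive by design (any co-residence polarized
  across the tree counts as support); on small trees with few clades this
  produces many accepted low-weight edges, and only the trimming threshold
  separates signal from chance. Reporting 3-OG sets on real data deserves
  skepticism.
* The minimum-clade rule and the per-dataset `nmax` optimization of the
  original method are replaced by fixed documented defaults behind single
  functions (`is_syntenic_at_node`, `default_nmax`).
* Ancestral gene *order* within a block is not reconstructed — only
  membership and proximity class.
* Root-level nodes have no outgroup, so clause (b) cannot fire there and
  presence must be supported by `min_clades` of the root's child clades.
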