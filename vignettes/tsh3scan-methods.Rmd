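---
title: "Discovering tandem-SH3-binding motifs with tsh3scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering tandem-SH3-binding motifs with tsh3scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsh3scan)
library(dplyr)
```

## The biological problem

SH3 domains are small (~60-residue) interaction modules that bind
proline-rich short linear motifs (SLiMs). In the p47^phox^/NCF1 organizer
family (NCF1, NOXO1, TKS4, TKS5), two *consecutive* SH3 domains associate
into a single composite binding groove — the "superSH3" or tandem-SH3
(tSH3) arrangement — and jointly bind one peptide. This binding mode
regulates NADPH-oxidase assembly and, in TKS4/TKS5, podosome and
invadopodium formation; mutations that break either the tandem interface or
the motif cause chronic granulomatous disease.

`tsh3scan` implements the discovery analysis for this motif class as a
reusable, tested pipeline:

1. **Motif model** — the tSH3-binding preference as a positional
   character-class pattern over window positions 0–7;
2. **Proteome scanning** — exhaustive overlapping-window matching with a
   sequence-shuffle null to control for Pro/Arg-rich composition;
3. **Ortholog conservation** — does the motif recur near the same alignment
   column in orthologs?
4. **Domain-side screening** — which multi-SH3 proteins carry the sequence
   signatures of tandemization?
5. **Ensemble geometry** — is a conformer ensemble's tandem arrangement
   compatible with the reference tSH3 geometry?

A synthetic-data generator produces every input class with known ground
truth, so the full pipeline is testable offline.

## The motif model

The strong tSH3-binding motif is `[PAVIL]PPR[PR][^DE][^DE]`: a five-residue
core (positions 1–5) that adopts a polyproline-II helix, followed by two
flank positions (6–7) where acidic residues abolish binding (they clash
with an acidic patch on the C-terminal SH3 domain; phosphomimetic
substitutions at these positions are known to weaken binding). The weak
variant `[PAVIL]P[PTAV]R[RP][^DE][^DE]` relaxes core position 3, as seen in
the weakly binding NOXO1 C-terminal autoregulatory motif. Position 0 is the
residue immediately preceding the core: an Arg there, together with an
acidic flank, marks candidates for the predicted *reverse* binding mode.

```{r}
tsh3_motif("strong")
tsh3_motif("weak")
```

`scan_motifs()` finds all windows matching the weak core (a superset of the
strong core), classifies each as `strong`, `weak_only` or `core_only`, and
annotates reverse-mode candidacy and phosphorylatable flanks:

```{r}
scan_motifs("QRPPPRRDM", protein_id = "TKS4", anchor = 344) |>
  select(core_start, matched_core, class_label, reverse_candidate)
```

Conventions worth stating precisely:

* **Coordinates** are 1-based, inclusive, UniProt-style; an `anchor`
  argument lets a peptide be scanned in its native protein numbering.
* **Overlapping matches are all reported** (ELM-style scanning); no
  greedy consumption.
* **Terminus truncation**: the 7-mer definitions require the full window,
  so a match whose flank positions fall beyond the sequence end is not
  reported; the `core` definition needs only positions 1–5.
* **Ambiguity**: `X` never satisfies any class, including flank
  "not-acidic" constraints — a window is only reported when every
  constraint is demonstrably met.
* **Unlabelled windows**: a window matching only the weak core whose flank
  fails the exclusion receives no class and is dropped; `core_only` is
  reserved for strong-core matches, mirroring how the reverse-mode
  candidates were defined.
* `reverse_candidate` requires the *conjunction* of Arg at position 0 and
  an acidic flank — the pattern shared by both instances predicted to bind
  in reverse. `phospho_flank` triggers on Ser or Thr at positions 6–7
  (the described cases involve Ser; Thr is included as the standard
  phospho-acceptor generalization).

## Shuffle null

A motif this degenerate arises by chance in Pro/Arg-rich sequences. For
each protein, the sequence is uniformly permuted `n_shuffles = 100` times
(exact residue multiset preserved) and rescanned with identical semantics.
The empirical p-value uses the add-one estimator
`(1 + #{shuffled >= observed}) / (n + 1)`, so it is never zero and is
bounded below by `1/(n+1)`. P-values are reported raw, with no
multiple-testing correction, as a composition-bias descriptor rather than
an inferential test.

Per-protein random streams are derived by hashing the protein id into the
master seed, so results are independent of proteome ordering and
reproducible bit-for-bit.

```{r}
glance(shuffle_null("PPPRPAAPPPRPAAGGGGGG", tsh3_motif("strong"),
                    "toy", seed = 1))
```

## Disorder, localization and partner context

Functional SLiMs reside in intrinsically disordered regions. The pipeline
consumes externally computed per-residue disorder scores and averages them
over each hit's window; the conventional 0.5 cutoff is the default
threshold. Since it is not established whether disorder should be a hard
filter or a descriptive column, both behaviours are available
(`disorder_hard_filter`), defaulting to descriptive. Hits without scores
are explicitly `not_evaluable`, never silently passed. Localization
(intracellular or not) is likewise annotated softly: unannotated proteins
are kept and flagged `unknown`. Partner overlap marks hits in proteins
known to interact with the family members (from BioGRID/IntAct-style pair
tables or PSI-MITAB), with self-interactions flagged so candidate lists can
exclude them.

## Ortholog conservation

Orthologs are selected per species from a homology hit table by the rule:
percent identity strictly above 20, query coverage at least 60%, highest
identity wins (ties: bitscore, then subject id). Conservation of a motif
hit is then assessed inside a multiple sequence alignment: each ortholog's
ungapped sequence is rescanned, hit positions are mapped to alignment
columns, and the ortholog counts as conserved if some hit lies within ±50
columns of the reference motif column.

The ±50 tolerance is measured in **alignment columns** by default: column
space absorbs indels, which is exactly why a tolerance is needed in poorly
alignable disordered regions. Measuring in the ortholog's own residue
coordinates is available via `space = "residue"` for sensitivity analysis.
The boundary is inclusive: 50 columns away is conserved, 51 is not. The
conserved fraction is computed over non-reference rows.

## Tandem screening

The domain-side screen takes protein sequences plus an InterPro-style
domain table and proceeds in three nested tiers: (a) proteins with at least
two SH3 domains; (b) consecutive SH3 pairs in which **both** domains carry
the `GWW` triplet (its Gly is sterically required for tandemization —
Gly→Ser changes abolish it and cause disease); (c) tier-b pairs whose
inter-domain linker is **shorter than 60 residues** (strict inequality).
Two further motif-binding signatures are flagged per pair: the C-domain
double-negative `[DE][DE]` dimer that salt-bridges the motif's position-4
Arg, and the N-domain `PxxΦL` hydrophobic patch (Φ aromatic: F/W/Y; a
relaxed variant allows Val in the last position, as in CIN85).

Choices made where the source analysis left details open:

* `[DE][DE]` is searched over the whole C-domain; its position is reported
  so users can impose stricter locality.
* `PxxΦL` is searched within the last 15 residues of the N-domain (the
  patch sits at the domain's C-terminal end); the window is configurable.
* Φ excludes His: every member observed in the motif-binding patches is
  F/W/Y-class.
* Domain coordinates are taken as given (no trimming); a supplementary
  domain table can be merged to repair incomplete annotations
  (`extra_domains`), the situation that arises when one domain of a
  genuine tandem is missing from an InterPro export.
* Linker net charge is `(#K + #R) − (#D + #E)`; genuine family tandem
  linkers are acidic, which is reported but not used as a filter.

## Ensemble geometry

Conformer ensembles (multi-model PDB, alpha-carbons) are compared to a
reference tandem arrangement by least-squares rigid-body superposition
(Kabsch, via SVD with the determinant correction so reflections are never
returned; no outlier-rejection cycles — every region atom contributes).
The default region, residues 160–211 and 229–283, corresponds to the two
SH3 domains of the reference crystal structure with the flexible linker
excluded. A conformer counts as tandem-like when its minimised RMSD is
below 5 Å, and two constructs are compared by a two-sided **Welch**
two-sample t-test on the raw RMSD lists — Welch because nothing guarantees
equal variances between, say, peptide-bound and peptide-free ensembles.
Residue correspondence is by residue number within the region; no sequence
alignment is attempted. Degenerate inputs: collinear point sets are solved
and flagged; two zero-variance samples with equal means give p = 1 by
convention (with unequal means, t = ±∞ and p = 0 — the one case where the
nominal p ∈ (0,1] range is abandoned rather than fabricating a value).
The `GWW` glycine–glycine distance (`gww_gly_distance()`) numerically
separates intrachain tandemization (glycines in contact) from interchain
SH3 clustering (glycines far apart).

## The synthetic-data generator

Every pipeline stage is validated on generated inputs whose ground truth is
recorded in a manifest; regeneration from the same seed is bit-identical.

* `gen_proteome()` draws backgrounds residue-wise from a stated composition
  (default: approximate human proteome frequencies) and overwrites planted
  peptides at recorded positions. Planted coordinates are exact by
  construction; tests that require *only* planted hits use Pro/Arg-free
  backgrounds, since no motif core can occur without Arg. Decoy
  compositions with inflated P/R stress the shuffle null.
* `gen_ortholog_family()` derives ortholog rows from a reference sequence
  by i.i.d. substitutions and indels outside the motif island (positions
  0–7 plus a one-column buffer), substituting the core's required Arg with
  Gly in "kill-list" species. Substitutions avoid Pro and Arg so the
  background cannot spawn spurious cores; with that, conservation labels
  are exact whenever the input sequence carries a single motif. Edits are
  tracked, so the emitted alignment is exact and no aligner is needed.
  The defaults (10 species, substitution rate 0.1, indel rate 0.02) are in
  the range typical of vertebrate ortholog sets in disordered regions.
* `gen_domain_architectures()` renders "SH3 domains" as 60-residue sequence
  mimics: backgrounds drawn from residues that cannot form any screened
  signature, with `GWW`/`SWW`, `EE`, and `PAAYL`/`PAAYV` planted at fixed
  offsets, and acidic linkers of requested lengths. Expected screen tiers
  follow from the construction flags.
* `gen_conformers()` builds ensembles of 30 models (the ensemble size used
  for conformer classification) from a deterministic two-block helical
  reference trace: near-native models are rigid motions plus Gaussian noise
  (0.3 Å per coordinate, i.e. RMSD ≈ 0.5 Å, far below threshold);
  non-native models first displace the second domain block by 60 Å. The
  displacement is calibrated so a displaced model's minimised RMSD always
  exceeds the 5 Å threshold — a helical block displaced along its own axis
  is partially absorbed by the global rotation (helix self-similarity), so
  smaller displacements do not guarantee the contract. All geometry
  fixtures are abstract synthetic point sets; no experimental structure is
  redistributed.

What the generator deliberately does **not** emulate: realistic
substitution matrices or phylogenetic correlation between species (i.i.d.
edits only), folded-domain geometry, correlated conformational modes, or
the length/composition heterogeneity of a real proteome. Passing tests
therefore demonstrate the *machinery* is correct on inputs with known
truth, not that real-proteome hit lists are biologically validated.

## Statistical floor of the mixture t-test

One property of the planted-ensemble design is worth recording. Comparing
a 20%-near-native ensemble of 30 models against an all-non-native one by a
Welch t-test on raw RMSDs has a hard significance floor: with 6 of 30
values at the near-native level and 24 at the non-native level Δ, the
mixture's sample standard deviation is ≈ 0.41·Δ, so |t| ≤ 2.7 and the
two-sided p cannot drop below ≈ 0.012 regardless of how cleanly the two
populations separate; spread among non-native conformers only raises it
(the suite observes ≈ 0.014–0.05 across seeds). This mirrors the weak end
of real with/without-peptide ensemble comparisons, where small shifts in
tandem occupancy produce p-values near 0.01 despite a perfectly recovered
tandem fraction. The tandem *fraction*, not the t-test, is the sensitive
readout at this ensemble size.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run on deliberately small
problems — proteomes of 10–50 synthetic proteins, families of 10 species,
ensembles of 30 models, 100 shuffles (10,000 for the one
analytic-expectation check) — chosen so the whole suite re-runs in well
under a minute while still exercising every code path with exact oracles.
One master seed governs all stochastic stages; per-protein and per-stage
streams are derived from it by hashing, so outputs are byte-identical
across runs and machine word order never enters. Scanning a real proteome
FASTA with `scan_proteome()`/`run_scan()` is the same code path and scales
linearly in total sequence length.

## Known limitations

* The motif model is a character-class pattern, not a scoring matrix; it
  cannot rank two matching windows (by design — that is how the motif
  class is defined in ELM-style annotation).
* No reverse-motif pattern is exposed, only the candidacy flag: two
  instances are too few to define one.
* Disorder prediction, BLAST, ClustalΩ and conformer generation are
  external: the package consumes their outputs as files.
* The ±50-column conservation rule is a heuristic for disordered-region
  alignments; in well-aligned globular regions it is deliberately
  permissive.
* Signature screening is sequence-only; it proposes tandemization
  candidates but cannot confirm domain-domain contacts.
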