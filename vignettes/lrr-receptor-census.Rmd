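---
title: "Censusing leucine-rich-repeat receptor architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censusing leucine-rich-repeat receptor architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrcensus)
```

## The problem

Leucine-rich repeats (LRRs) are short (roughly 20–29 residue)
protein-interaction motifs.  Cell-surface receptors built from
extracellular LRR arrays are the workhorses of innate immune recognition:
Toll-like receptors in animals couple LRRs to an intracellular TIR domain,
and plant pattern-recognition receptors couple them to a protein kinase
domain.  Asking *which eukaryotic lineages encode which LRR receptor
architectures* is therefore a question about the distribution of a basic
immune-recognition mechanism — and it reduces to careful bookkeeping over
three per-protein annotation layers:

1. domain content (Pfam hits),
2. membrane topology (predicted transmembrane (TM) helices),
3. secretion signals (predicted signal peptides).

`lrrcensus` turns that bookkeeping into a reproducible pipeline: parse the
annotation layers, correct their known artifacts, classify every protein
against a declarative set of receptor-class rules, and tabulate
per-species counts with taxon-level summaries.  A companion Markov
clustering (MCL) stage groups the LRR-domain subsequences themselves by
sequence similarity.

## Receptor classes as declarative rules

A protein is an **LRR protein** when it carries at least one hit from the
three Pfam LRR families (PF00560, PF07723, PF07725), and an
**LRR-receptor** when it additionally has *exactly one* transmembrane
helix — the single-pass topology that puts an LRR ectodomain outside the
cell and a signalling tail inside it.  The remaining classes refine this
skeleton:

| class          | definition                                              |
|----------------|---------------------------------------------------------|
| `TLR`          | LRR + 1 TM + TIR domain (PF01582)                       |
| `LRR_RK`       | LRR + 1 TM + protein kinase domain (PF07714 or PF00069) |
| `SECRETED_LRR` | LRR + signal peptide + 0 TM                             |
| `LRR_AC`       | LRR + adenylate/guanylate cyclase catalytic (PF00211)   |
| `NBS_LRR`      | NB-ARC (PF00931) + LRR                                  |
| `LRR_NACHT`    | LRR + NACHT (PF05729)                                   |
| `STAND`        | HET + NACHT + WD-repeat                                 |
| `LYSM_RK`      | LysM + 1 TM + kinase                                    |

plus single-domain screens for the classical animal pattern-recognition
accessory domains (immunoglobulin, C-type lectin, TIR, NOD, NODP, ITAM,
Pyrin, CARD).  Each rule is a conjunction of: required accession groups
(at least one hit from each group), forbidden accessions, a TM-count
constraint, and a signal-peptide constraint — see `class_rule()`.  Rule
sets serialize to YAML (`write_rules()`), so new classes need no code.

Three design points deserve emphasis:

* **Classes are labels, not a partition.**  A protein with both TIR and
  kinase domains is counted in both `TLR` and `LRR_RK`; the census
  reports classes as separate columns, and the subset laws
  `TLR ⊆ LRR_RECEPTOR ⊆ LRR_PROTEIN` are asserted after every census.
* **TM constraints always read the corrected helix set** (below), never
  the raw predictions.
* **LRR counting is per hit.**  Repeat-family hits are counted
  individually and never merged into repeat regions; every class rule
  only requires *at least one* hit, so merged-versus-individual counting
  cannot change any class membership.
* **No score filtering happens here.**  Pfam gathering thresholds are
  assumed applied by the upstream scan; classification is set membership
  over already-thresholded hits (an optional e-value filter exists but is
  off by default).

Pfam assigns no single canonical accession for the HET, WD-repeat and
LysM domain *names*; the defaults (`PF06985`, `PF00400`, `PF01476`) are
the canonical families for those names and are exposed as arguments of
`builtin_rules()` for retargeting.

## Correcting the annotation layers

**Signal peptides masquerading as TM helices.**  Topology predictors
regularly call the hydrophobic core of an N-terminal signal peptide as a
transmembrane helix.  Left uncorrected, every secreted LRR protein with
this artifact becomes a spurious single-pass "receptor".
`correct_tm_helices()` removes every predicted helix sharing at least one
residue with the signal-peptide region (residues 1..end).  One shared
residue is the simplest defensible overlap notion; the threshold is an
argument (`min_overlap`).  The correction is idempotent and precedes all
counting.

**Spurious N-terminal gene-model extensions.**  A mispredicted gene model
can prepend hundreds of residues to a protein — and when the only
predicted TM helix sits in that extension, it manufactures a false
receptor.  Against a multiple alignment with close homologs
(`detect_nterm_extension()`), the extension shows up as query residues
before the first column where at least half the homolog rows are aligned
(`occupancy = 0.5`).  Overhangs of at least `min_overhang = 100` residues
are reported; both parameters are configurable, and the defaults sit far
below the multi-hundred-residue extensions this screen is meant for while
staying above ordinary alignment raggedness.  The procedure is invariant
to homolog row order and to all-gap columns.  A related screen,
`detect_misplaced_nterm_domain()`, flags proteins whose LRR *N-terminal
capping* domain sits beyond a quarter of the protein length — evidence
that the true start lies at the capping domain and everything upstream is
extension.  `apply_corrections()` then drops the TM helices falling
entirely inside a flagged overhang; reclassification afterwards can only
remove receptor labels on such proteins, never add them.  The symmetric
failure mode — a gene-model error that *deletes* a real TM helix —
cannot be detected from protein-space evidence alone, so it is supported
only as a manual `add_tm` correction record.

## Clustering LRR-domain subsequences

To relate LRR domains across proteins, `extract_subsequences()` slices
each LRR hit out of its parent sequence, and `build_graph()` turns an
all-vs-all similarity edge list into a weighted graph: edges with
e-value ≤ 10⁻¹⁵ are kept and weighted `-log10(e)` capped at 200 (an
e-value of exactly 0 takes the cap).  `mcl()` is an in-package sparse
implementation of the Markov Cluster algorithm: add self-loops (weight =
maximum incident edge weight, 1 for isolated nodes), column-normalize,
then iterate expansion (matrix square), inflation (elementwise power,
default 1.5), pruning (entries < 10⁻⁵) and re-normalization until the
largest entry change drops below 10⁻⁶.  Clusters are connected components
of the limit matrix's non-zero pattern; size-1 components and
never-matched sequences are both reported as singletons (they are
distinguishable from the graph if needed, but counted together).

The reference protocol this replaces wraps MCL in an ortholog-detection
normalization (reciprocal-best-hit weighting across species) whose
parameters are not part of the published record; only the e-value cutoff
and inflation are.  We therefore implement standard MCL on
`-log10(e)` weights and honor those two parameters; clusterings produced
by the full ortholog protocol will differ in detail.  The package also
does not compute the similarity edges themselves — any all-vs-all search
tool can produce the 3-column edge list.

Numerical notes: columns are re-normalized after pruning, and a column
emptied by pruning gets a unit self-loop before normalization (with
self-loops and inflation this is a degenerate case, but it keeps the
matrix stochastic unconditionally).  Column sums stay within 10⁻⁹ of 1 at
every iteration, and the test suite cross-checks the sparse
implementation against an independently coded dense-matrix MCL oracle on
random graphs of up to 50 nodes.

## The synthetic proteome generator

`generate()` produces annotated proteomes with planted ground truth so
the full pipeline is testable offline.  Each species draws protein
architectures from a configurable frequency table over nine templates
(LRR-only, LRR+1TM receptor, Toll-like, receptor kinase, secreted LRR,
the conserved multi-domain fungal adenylate cyclase laid out N-to-C as
G-alpha-binding → Ras-association → LRR → PP2C → catalytic domain,
NACHT+WD, HET+NACHT+WD, and background).  The default study conditions
(`default_sim_config()`) are 20 species × 500 proteins, fungus-heavy
(ten fungi, four plants, four metazoa, two oomycetes) with
taxon-specific frequencies chosen to mirror the qualitative pattern of
real censuses: plants rich in receptor kinases (frequencies around
0.04–0.10 per LRR template), metazoa carrying TLRs, fungi nearly
receptor-free but each carrying an LRR adenylate cyclase and occasional
NACHT/STAND architectures, oomycetes carrying receptor kinases.  Protein
lengths are normal (600 ± 150) truncated at each template's minimum
viable layout.

Two artifact channels plant the failure modes the corrections target:
`sp_tm_overlap` adds a TM helix inside the signal peptide of a secreted
protein; `nterm_extension` prepends 560 residues (configurable)
containing a TM helix to an LRR protein and emits a matching homolog
alignment whose homologs lack the extension.  Ground-truth labels are
computed on the *artifact-free* architecture at generation time, which
makes "pipeline output equals truth" a meaningful end-to-end statement:
the corrections must undo exactly the planted damage.

What the generator deliberately does **not** emulate: residues are
uniform over the 20 amino acids (hits are planted coordinates, not
discoverable motifs), domain scores and e-values are decorative, there
are no partial/fragmented gene models beyond the planted extensions, and
no correlation structure between domains beyond the templates.  Passing
tests therefore demonstrate the bookkeeping, correction and clustering
logic — not robustness to upstream scanner noise, which real inputs
carry.

Determinism: each species derives its own RNG stream from
`(seed, species_id)`, so regenerating any one species is independent of
the others and the same seed yields byte-identical files.

## Orchestration

`run_census()` fixes the stage order — parse, TM/SP correction,
architectures, anomaly detection, anomaly corrections, classification,
census, taxon summary — logs per-stage record counts to stderr, writes
all tables atomically (temp file + rename), and asserts the class subset
laws before returning.  `run_cluster()` and `run_simulate()` cover the
other stages, `run_all()` chains them, and a thin command-line wrapper
(`inst/cli/lrrcensus.R`) exposes `simulate`, `census`, `cluster` and
`all` subcommands over a YAML config.  The census summary reports, per
taxon group, the species counts above/below the 20/10 LRR-protein
thresholds and the receptor-free species; both thresholds are
config-exposed.

Test-suite problem sizes: the end-to-end recovery checks run on the full
default conditions (20 × 500 = 10,000 proteins, about 15 s), the MCL
oracle comparison on 100 random graphs of 5–50 nodes, and the
module-level property tests on dozens to hundreds of randomized small
cases each; these sizes give exact planted-truth recovery a real chance
to fail while keeping a full run around a minute.

## Known limitations

* Real protein IDs must be unique per dataset; species attribution for a
  pooled FASTA relies on `species_id_`-prefixed protein ids or a
  single-species taxonomy.
* The misplaced-N-terminal-domain screen needs the capping-domain
  accession supplied by the user; no default is asserted.
* MCL cluster *assignments* match standard MCL, not the full
  ortholog-normalized protocol (see above).
* Secreted-LRR proteins are screened with the same two anomaly detectors
  as receptors; no additional secreted-specific checks are invented.
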