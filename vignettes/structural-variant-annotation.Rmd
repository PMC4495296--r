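---
title: "Annotating coding variants on protein structures and interfaces"
author: "structvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating coding variants on protein structures and interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structvar)
```

## The model

`structvar` treats a coding variant as a *protein substitution in a spatial
context*. The pipeline composes five pieces, each with an explicit contract:

1. **Variant mapping.** Protein-level substitutions are taken as given;
   genomic SNVs are located within a transcript's CDS (1-based inclusive
   coordinates throughout, translation phase 0, strand-aware with the CDS
   read 3'→5' along genomic coordinates on the minus strand), the codon
   index is `floor((cds_offset - 1)/3) + 1`, and reference and mutated
   codons are translated with the standard genetic code. Synonymous and
   non-coding outcomes are explicit verdicts, never silent drops;
   substitutions to or from a stop codon are carried through as `*` and
   flagged. Variants are reported against the gene's *principal isoform*;
   a variant hitting only a non-principal isoform is annotated against the
   queried isoform and flagged `non_principal`, because silently remapping
   it to a different sequence would change its coordinates.

2. **Sequence–structure reconciliation.** Structure chains rarely match the
   isoform sequence exactly: crystals have unresolved loops, constructs
   carry engineered mutations, models may cover fragments. Each chain's
   observed-residue sequence (from ATOM records, deliberately not SEQRES,
   so density gaps become alignment gaps) is locally aligned to the isoform
   with Smith–Waterman under affine gaps. The resulting *position map*
   sends isoform positions to author residue numbers (plus insertion
   codes); mismatched columns are mapped but flagged; maps below an
   identity threshold are rejected and the structure skipped with a logged
   reason.

3. **Geometry.** Two residues are in contact when the minimum Euclidean
   distance over their heavy-atom pairs is at or below the cutoff
   (inclusive). Interface residues of a binary complex are the cross-chain
   contacts. Hydrogens are excluded because most structures lack them;
   waters and (by default) ligand HETATM records are excluded as well.

4. **Annotation joining.** The variant position, and every isoform position
   back-mapped from a contacted residue through *that chain's own* position
   map, are joined against three local tables: sequence features (sites and
   ranges, inclusive ends), somatic mutation records, and per-substitution
   damage predictions keyed by (protein, position, alternate residue).

5. **Calling and evaluation.** A configurable disjunction of five clauses
   (direct site, neighbour site, interface, somatic, predictor majority)
   produces damaging/neutral/no-evidence calls with one evidence string per
   fired clause; labelled sets are scored with accuracy, precision, recall
   and MCC, computed at full precision and displayed at two decimals.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 5.0 Å | maximum heavy-atom distance for spatial contact; inclusive |
| `min_identity` | 0.8 | fraction of identical residue–residue columns required to accept a position map |
| gap penalties | open 11, extend 1 | affine-gap costs under BLOSUM62; a gap of length L costs 11 + L |
| rule toggles | all on | each evidence clause can be disabled independently |
| `count_sequence_adjacent` | off | whether neighbours adjacent in sequence may fire the neighbour-site clause |

The 5 Å heavy-atom cutoff is the field's common operating point for
residue–residue contact; it is deliberately inclusive (a pair at exactly
5.0 Å is a contact) so that boundary behaviour is testable. Where the
contact definition could reasonably differ (Cβ–Cβ, centroid, all-atom),
minimum heavy-atom distance was chosen because it is monotone under adding
atoms and robust to missing side-chain density; the cutoff is a plain
argument everywhere.

BLOSUM62 with 11/1 is the ubiquitous protein default; the matrix is
replaceable by any NCBI-format file (`read_score_matrix()`), with the
ambiguity code `X` scoring 0 against everything. The 0.8 identity floor
guards against annotating through spurious local hits when a chain only
superficially resembles the isoform; chains below it are skipped, not
guessed at.

## Numerical and tie-break choices

- The alignment traceback prefers diagonal over up (gap in target) over
  left (gap in query), and the highest-scoring cell is chosen in
  column-major order, so outputs are bit-reproducible.
- Predictor consensus is a *strict* majority of methods with a non-unknown
  call; ties do not fire the clause.
- Alternate-location atoms resolve to the highest occupancy, ties to the
  first listed. Only the first MODEL of a multi-model file is read.
- Sequence-adjacent neighbours (author numbers differing by 1 on the same
  chain) are kept in neighbour sets but labelled, and by default do not
  fire the neighbour-site clause — otherwise every linear motif would be
  rediscovered as "spatial" evidence through the peptide bond.
- Zero-denominator metrics are `NaN`, never 0: a precision of 0/0 is
  undefined, not bad.
- Report rows order experimental structures before models, then by
  structure id; a variant covered by no accepted map gets exactly one
  structure-free row so it is never silently lost.
- Confusion counting treats `no_evidence` as a negative call by default
  (configurable), since an annotation-driven caller that stays silent has
  not called the variant damaging.

## The synthetic fixtures and what they show

`fixture_spec()` / `generate_validation_set()` build a complete synthetic
study with no network access: a two-chain complex whose chains are
Cα+Cβ pseudo-residue paths (4 Å spacing, ±0.3 Å jitter), 20 Å apart except
at engineered contact pairs placed to hit their target distance exactly;
an isoform catalog in which the first protein's structured region covers
positions 6–45 of a 50-residue sequence with author numbering offset by
+100, so isoform, chain and author coordinate systems all differ; and
feature/somatic/prediction tables plus a labelled variant set derived from
the plants.

The default design mirrors the shape of a published structure-aware
validation: 14 pathogenic and 10 neutral variants, with the pathogenic
evidence spread over all five clauses (3 direct sites, 2 interface contacts
whose partner residue is a binding site, 2 bare interface contacts,
2 somatic hotspots, 2 predictor majorities) and 3 pathogenic variants left
deliberately evidence-free. The implied confusion matrix is therefore
tp = 11, fp = 0, fn = 3, tn = 10 — accuracy 0.88, recall 0.79, precision
1.00, MCC 0.78 at two decimals — and the pipeline is required to reproduce
it exactly, at any seed, because the plants (not the random sequences or
jitter) determine every call.

What passing this does **not** show about real data: the fixture's geometry
is not protein-like (no side chains beyond Cβ, no packing, chains are
near-linear), its annotation tables are noiseless and perfectly indexed,
its alignments are near-identities, and the planted evidence is
unambiguous. Real structures bring missing density, insertion codes,
engineered constructs and genuinely ambiguous evidence; the unit suite
covers those mechanisms individually (mismatched and rejected maps,
alt-locs, insertion-code identities, boundary distances), but no synthetic
set certifies real-world calling accuracy.

## Problem sizes in the test suite

The oracle-equivalence tests run the alignment against an independently
coded exhaustive DP on 500 random pairs of length ≤ 12; the spatial search
against a quadratic all-pairs oracle on 50 random structures of 40–200
residues (with symmetry, cutoff-monotonicity and rigid-motion checks); and
the codon translation against whole-CDS re-translation for every coding
position × every alternate base on 20 random spliced transcripts on both
strands. These sizes exercise every code path (gap starts and extensions,
grid-cell boundaries, splice junctions, strand mirroring) while keeping the
default suite around a minute.

## Known limitations

- Only binary complexes: assemblies with more than two mapped chains are
  out of scope, as are symmetry expansion and solvent accessibility.
- PDB format only (no mmCIF); models are consumed, never built.
- SNVs only at the genomic level: indels, MNVs and splice-consequence
  prediction are out of scope.
- The damaging-call rule is an explicit, documented stand-in for whatever
  weighting a curated system might use: it reproduces the *shape* of
  structure-aware evidence (site, proximity, interface, recurrence,
  predictor consensus) and is fully configurable, but it is not a trained
  classifier and is not claimed to replicate any particular published
  call set variant-by-variant.
- Predictor scores are consumed from tables, never computed; running SIFT,
  PolyPhen-2 or CADD is out of scope.
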