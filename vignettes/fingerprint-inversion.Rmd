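---
title: "Deterministic enumeration of molecules from counted ECFPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic enumeration of molecules from counted ECFPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An extended-connectivity fingerprint (ECFP) hashes every circular atom
environment of radius 0..r of a molecule into a fixed-length count vector.
Fingerprints are the workhorse representation of similarity search and
QSAR, but they are designed to be one-way: given a counted ECFP, which
molecules could have produced it?  `sigenum` answers this question
deterministically.  It matters in two places: auditing how much structural
information a fingerprint actually leaks (two molecules sharing an ECFP are
indistinguishable to any model consuming it), and de novo design, where the
neighbors of a known ECFP are plausible analogues of a known drug.

## Objects and notation

For a molecular graph $G$ and heavy atom $x$, the *atomic signature*
$\sigma_x^r$ is the subgraph induced by all atoms at graph distance at most
$r$ from $x$ (including ring-closure bonds between frontier atoms), written
as a canonical rooted fragment string with the root tagged `:1`.
Stereochemistry is excluded from signatures, because fragmenting a molecule
can invalidate chirality perception.  The *molecular signature* $\Sigma_G^r$
is the multiset of atomic signatures over all heavy atoms.  The counted
fingerprint $ECFP(m) \in \mathbb{N}^{nbits}$ and the per-atom bit multisets
$ECFP(\sigma_x^r)$ come from the Morgan generator (radius 2, 2048 bits,
chirality-aware by default).  Three families of constraints tie these
together:

* **PE (partition equations)** — summing the per-atom bit multisets over
  all atoms reproduces the molecule fingerprint, one linear equation per
  non-zero bit.
* **CE (consistency equations)** — every directed boundary bond
  $(\sigma_x^{r-1} \to \sigma_y^{r-1}, b)$ must be matched by its reverse,
  and self-paired descriptors must occur an even number of times.
* **GE (graphicality equation)** — with $n_i$ the number of members of
  root degree $i$, $\sum_{i \ge 2}(i-2)n_i - n_1 + 2$ must be an even
  non-negative integer for a connected realization to exist.

## The pipeline

```{r}
library(sigenum)

mol <- parse_smiles("C[C@H](CO)CCCCCCO")[[1]]
fp  <- counted_ecfp(mol)                 # 18 non-zero bits, total 30
alphabet <- build_alphabet(list(mol))    # (bit multiset, signature) tuples
res <- invert_ecfp(fp, alphabet)         # 1 flat, 2 stereoisomers, 1 match
```

1. **Alphabet construction** (`build_alphabet`): every atom of every
   molecule contributes a tuple (counted Morgan-bit multiset, atomic
   signature).  Entries are unique by tuple, with occurrence counts; we
   count per atom across molecules rather than deduplicating per molecule,
   since the occurrence weights only feed diagnostics (evenness, growth),
   not the solver.
2. **Candidate selection** (`candidates`): entries whose bit multisets fit
   under the query counts elementwise, then an iterative prune of entries
   with a boundary descriptor whose reverse no remaining entry (including
   the entry's own class) carries.  The union of two reverse-closed subsets
   is reverse-closed, so the fixed point is the unique maximal candidate
   set.
3. **Diophantine solving** (`solve_system`): one partition equation per
   non-zero bit.  Per bit, solutions are integer partitions of the bit
   count into the active coefficient values (a coefficient exceeds 1 when
   one atom emits the same bit several times), expanded over the candidates
   carrying each value.  Candidates sharing bits are linked into orbits
   (union-find); within an orbit per-bit solutions are folded under the
   compatibility rule (agree on all candidates constrained by both sides,
   merge by elementwise max), across orbits by Cartesian max, which makes
   the PE solution count the product of the orbit set sizes.  CE and GE
   then filter the surviving multiplicity vectors.
4. **Reconstruction** (`reconstruct_molecules`): one node per signature
   member; a bond of order $b$ between $u$ and $v$ is allowed iff $u$
   carries the descriptor $(\sigma_u^{r-1} \to \sigma_v^{r-1}, b)$ and $v$
   its reverse.  Backtracking pairs descriptors; accepted graphs must be
   connected and must reproduce the input molecular signature exactly at
   radius $r$ (this final check also weeds out any subtly inconsistent
   assembly).
5. **Stereoisomer expansion and matching** (`expand_stereo`,
   `invert_ecfp`): flat skeletons are expanded over their unassigned
   stereocenters and only isomers whose counted chirality-aware ECFP equals
   the query bit-for-bit are reported.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 2 | environment radius (ECFP4); signatures use the same radius |
| `nbits` | 2048 | fingerprint length |
| `chirality` | `TRUE` | stereo-aware hashing; required for exact stereo matching |
| `solver_thresholds(T)` | `2e5` | at most `T/100` partitions per equation and `T` expansions per partition |
| `recon_thresholds(T)` | `2e5` | backtracking step cap (a step = one attempted bond placement) |
| `recon_thresholds(restarts)` | 10 | randomized re-orderings (seeds 1..10) after a cap hit |
| `recon_thresholds(stereo_cap_total)` | `2e5` | stereoisomer budget, divided by the number of flat molecules (ceiling, minimum 1) |
| `sanitize_config(mw_max)` | 500 | strict upper weight bound; `NULL` disables it |

Every cap sets a status flag when it truncates a search, so callers can
distinguish a complete enumeration from a possibly incomplete one; with
default caps none of the packaged examples or fixtures raises a flag.
When partition lists are truncated, partitions with fewer parts (smaller
L1 solution norm) are kept first, since small-norm per-bit solutions are
the ones most likely to remain consistent with the other equations.

## Numerical and design choices

* **Fragment canonicalization** is string-based: iterative color
  refinement with individualization on ties, the root forced into the
  first position, serialized as atom tokens (element, aromaticity,
  charge, hydrogen count) plus a sorted edge list.  Equality of rooted
  environments is string equality; any deterministic canonical form works
  because all comparisons are internal to the package.  Refinement color
  ids are zero-padded before ranking so that string order equals numeric
  order — without this the root-first invariant silently breaks on
  fragments with ten or more refinement classes.
* **Hydrogens** are attributes (per-atom total H count), not graph nodes;
  elements, formal charges and aromaticity flags are those perceived by
  the toolkit's default model, applied identically during alphabet
  construction and reconstruction so fragment strings are comparable.
* **Environment deduplication**: the Morgan generator drops structurally
  duplicated environments inside a molecule (hence the worked example's
  total of 30 rather than 3 x 11 = 33), and the surviving root atom
  reported by the generator owns the bit.  This is the only attribution
  consistent with the emitted counts, and it is re-checked on every call:
  per-atom multisets must sum exactly to the molecule fingerprint.
* **GE's parity condition** is read as even *and* non-negative; a
  negative value cannot correspond to a connected graph.
* **Reconstruction order** is fail-first (extend the node with the fewest
  legal pairings); untouched nodes with identical signatures and identical
  remaining descriptor multisets are interchangeable, so only one
  representative is branched on.  Duplicate assemblies that survive are
  removed by whole-graph canonicalization.
* **Stereo completion** during sanitization picks, reproducibly for a
  given seed, one entry of the sorted canonical stereoisomer list — the
  choice rule is arbitrary but fixed, which is all downstream exact
  matching needs.
* **Degenerate inputs**: an all-zero fingerprint enumerates nothing; a
  single-atom signature reconstructs iff its root degree is 0; an
  equation whose bit no candidate can supply makes the system
  unsatisfiable and returns an empty (not error) result.

## What the fixture generator emulates — and what it does not

`generate_fixture_set()` assembles sanitization-compliant molecules from a
seeded fragment grammar: alkyl chains, small carbo- and heterocycles
(including aromatics), O/N/S substituents, occasional double/triple bonds,
with deliberate over-representation of unbranched chains and symmetric
rings (20% plain chains, 30% ring-cored by default) because repeated local
environments are exactly what makes inversion ambiguous and
computationally hard.  Default study conditions used by the packaged
checks: 200 molecules, seed 7, radius 2, 2048 bits, default thresholds.

The grammar does *not* emulate the property distributions of real compound
collections: no polycyclic ring fusions, no charged species, no exotic
valences, molecular weights well below the 500 Da bound.  A perfect
round-trip score on these fixtures therefore shows the machinery is sound
and self-consistent at desk scale — it does not certify the
production-scale recovery rates reported for external million-molecule
collections, which also depend on alphabet coverage and on cap hits in
pathological (highly cyclic or highly repetitive) molecules.

## Problem sizes of the packaged checks

The test suite solves the staged system against a brute-force grid oracle
on 200 random systems (at most 5 candidates, bit counts at most 8), checks
attribution conservation and CE/GE validity on all 200 fixture molecules,
and runs the full round trip (alphabet from the fixtures themselves,
generous caps) on the same 200; the worked example runs end to end in
about a second.  These sizes were chosen so that exhaustive oracles remain
exact references.

## Known limitations

* Counted fingerprints only; binary ECFPs discard the counts the partition
  equations need.
* Signatures are stereo-free, so stereochemistry is recovered only through
  the final exact-match filter, and molecules differing solely in stereo
  centers the fingerprint cannot see are returned together.
* The alphabet bounds what can be enumerated: a query using an environment
  absent from the alphabet yields no match (the round-trip protocol
  sidesteps this by building the alphabet from the query set itself).
* Reconstruction is exponential in the worst case; the step cap plus
  restarts trade completeness for bounded runtime and say so via status
  flags.
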