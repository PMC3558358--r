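---
title: "Exhaustive structure generation by canonical augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive structure generation by canonical augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomgen)
```

## The problem

Given a molecular formula such as `C2H5NO2`, how many constitutional
isomers — molecules with that exact elemental composition but different
atom connectivity — exist, and what are they?  This question is central to
computer-assisted structure elucidation: when an unknown compound (for
example an unidentified metabolite) yields only an elemental composition
from mass spectrometry, the candidate list is exactly the set of
constitutional isomers, optionally narrowed by substructures inferred from
fragmentation spectra.  `isomgen` produces that list exhaustively and
without duplicates.

A molecule is modeled as a connected, vertex-colored multigraph: vertices
are the non-hydrogen atoms (plus monovalent halogens), colors are element
symbols, and each edge carries a bond order 1–3, so resonance partners
(the two Kekulé forms of benzene, say) are distinct structures.  Hydrogen
is never a vertex.  It enters only through the valence bookkeeping: an
atom in a valence state $v$ with heavy-bond order sum $d_v$ carries
$v - d_v$ implicit hydrogens, and a structure is *finished* when it is
connected and some choice of valence states makes the implicit hydrogens
total exactly the formula's hydrogen count.

## The valence-state dictionary

Each element has one or more valence states, and higher states carry
pattern rules restricting the multiset of heavy-bond orders:

| element | state | rule |
|---|---|---|
| C | 4 | any partition |
| O | 2 | any partition |
| N | 3 | any partition |
| N | 5 | no triple bond, no implicit H (fully heavy-substituted) |
| P | 3 | any partition |
| P | 5 | no triple bond, no implicit H (fully heavy-substituted) |
| S | 2 | any partition |
| S | 4 | exactly one double bond, no triple (sulfoxide-type) |
| S | 6 | exactly two double bonds, no triple (sulfone/sulfate-type) |
| F, Cl, Br, I | 1 | any |

These defaults mirror the consensus view of which neutral valence states
occur in real molecules (charged species, radicals and isotopes are out of
scope).  The pentavalent-nitrogen rule deserves a note, because it is the
one the package calibrated empirically rather than assumed.  Under the
fully-substituted no-triple rule the admissible N(V) patterns are
2+2+1, 2+1+1+1 and 1+1+1+1+1 (nitro and aci-nitro groups, and the fully
substituted case).  Three independent anchor compositions pin this rule
down exactly: the glycine composition `C2H5NO2` yields 84 trivalent-N
plus exactly 13 pentavalent-N structures (97 total), `C4H7NO3` yields
26,530, and `C4H7N3O` — with three nitrogens mixing both valences in one
molecule — yields 303,601.  Superficially plausible alternatives fail at
least one anchor: "exactly one double bond" admits 70 pentavalent
glycine isomers instead of 13; "exactly two double bonds regardless of
hydrogens" happens to give 13 on glycine (its two classes coincide in
size with the correct rule's two classes there) but undercounts both
larger anchors, which is why the rule is stated in terms of hydrogens
and triples, not double-bond counts.  The dictionary is a plain config
file (`read_valence_dictionary()`), so it can be revised without
touching code; `restrict_valences()` reproduces the behavior of
single-valence generators when a valence is known a priori.

During generation only the *maximum* degree per element is enforced (an
intermediate N atom may hold 4 bonds on its way to a pentavalent state);
the per-state pattern rules are checked only when a structure is
finished.  This two-tier scheme is what lets one run produce structures
mixing different valences of the same element.

## Canonical augmentation

The search is a depth-first tree.  The root is the set of fully isolated
atoms; each step increments the order of one atom pair by one (creating
the bond if absent); leaves are fully saturated structures.  Two
mechanisms make the enumeration duplicate-free without any global
registry of previously seen molecules:

1. **Sibling deduplication.**  All one-bond extensions of the current
   structure are canonized (colors = elements) and extensions with equal
   canonical hashes are collapsed — they are the same child up to
   isomorphism.  The map lives only for one extension batch.
2. **The canonical augmentation test.**  Each surviving child is accepted
   only if deleting its *canonically last* bond — the edge that sorts
   last in the canonical edge order of its canonical form — yields a
   structure isomorphic to the actual parent.  Every isomorphism class of
   structures has exactly one canonical deletion, hence exactly one
   parent from which it is accepted, so each class is visited exactly
   once no matter how many augmentation paths lead to it.

A structure that is finished is emitted *and* extension continues while
atoms remain below their maximum degree: a finished trivalent-N molecule
may be the canonical parent of a pentavalent-N molecule two bonds deeper.
Treating finished structures as terminal would silently lose such
higher-valence structures.

One bound prunes the tree: since every finished structure satisfies
$2B + n_H = \sum_a v_a \le \sum_a \mathrm{md}(a)$ (with $B$ the total
bond-order sum), and $B$ only grows along a path while the right side is
fixed, extensions beyond $B_{\max} = \lfloor(\sum_a \mathrm{md}(a) -
n_H)/2\rfloor$ can never reach a finished structure and are refused.
Every finished structure and every prefix of its deletion chain respects
the bound, so the emitted set is provably unchanged; the oracle-equality
tests (below) confirm this empirically through an enumeration that does
not share the pruning logic.

### Hydrogen assignments and counting

When a finished skeleton admits several hydrogen assignments with the
right total (possible only with several multi-valence atoms), each
assignment is a distinct output molecule; assignments that differ only by
an automorphism of the skeleton are collapsed by canonizing under
(element, valence, implicit-H) colors.  For compositions with at most one
multi-valence atom this convention coincides with counting finished
skeletons.

### Prescribed substructures

Fragments read from an SDF file (explicit hydrogens stripped) are seeded
into the root at fixed atom indices with their bonds pre-placed, and the
augmentation test walks the canonical edge sequence backwards past every
bond still *owned* by a fragment — its pair is prescribed and its current
order does not exceed the prescribed order $d_f$ — deleting the first
free bond instead.  Increments above $d_f$ are ordinary augmentations
(containment only requires $d_f \le d$), while deletions below $d_f$
would break containment.  If nothing is deletable the structure is the
seeded root and is accepted.  Fragments must be pairwise atom-disjoint;
this is a user contract the tool cannot check semantically, though
per-element totals are validated.  For possibly-overlapping substructures
the supported workaround is to seed the largest and post-filter with
`contains_substructure()` (subgraph matching with order dominance); the
test suite verifies on a two-fragment toy case that both routes produce
the same molecule set.

## Canonical labeling

The isomorphism authority is a McKay-style canonizer implemented natively
on order-weighted multigraphs in compiled code: equitable partition
refinement, where a vertex's refinement invariant is the multiset of
(neighbor cell, bond order) pairs, followed by individualization
backtracking on the first non-singleton cell.  The canonical labeling is
the one minimizing the encoding (vertex count, colors in label order,
then the edge list `(i, j, order)` sorted lexicographically); the hash
string is that encoding and the canonically last bond is the
lexicographically largest edge.  Any fixed edge order consistent between
canonization and deletion yields a correct enumeration; the
lexicographic one is the simplest.  One sound pruning is applied during
backtracking: a candidate vertex whose adjacency row is identical to an
already-explored sibling's (a transposition automorphism) is skipped.
Correctness does not depend on pruning, and is cross-validated against a
brute-force permutation-search isomorphism test on ~1,000 random
multigraph pairs in the acceptance suite.

Hash strings are bit-stable across runs of one package version; stability
across versions is not promised.

## The reference oracle

`brute_force_enumerate()` independently enumerates every assignment of
orders 0–3 to all atom pairs (depth-first with capacity and
hydrogen-budget cutoffs), keeps finished structures, and deduplicates by
permutation search — sharing no code with the canonizer or the engine.
Its role is purely evidential: on every formula where both run (the test
grid covers all heavy-atom multisets up to four atoms over C/N/O at every
feasible hydrogen count, plus N/P/S multi-valence spot checks up to six
heavy atoms), engine and oracle must agree exactly.
`random_multigraph()` supplies seeded random fixtures for the canonizer
property tests.  What these fixtures emulate is the combinatorial space
of small organic skeletons; they do not emulate 3-D geometry, ring
strain, tautomeric preference or stability, so agreement demonstrates
enumeration correctness, not chemical plausibility ranking.

## Problem sizes and determinism

The test suite runs the generator end-to-end up to the malic acid
composition `C4H6O5` (8,070 structures, a few seconds in compiled code)
and the oracle up to six heavy atoms; these sizes were chosen so the full
suite completes in minutes while still covering every code path,
including multi-valence states of N, P and S.  Everything is
deterministic: child enumeration is in ascending pair order, ties in the
canonizer are broken by the minimal encoding, emitted atom order is the
final canonical label order, and repeated runs produce byte-identical SDF
files.  Recursion depth equals the total bond count (≤ ~200 for any
molecule within the V2000 atom limit), well within the compiled engine's
stack budget.

## Known limitations

* Neutral molecules only: no charges, radicals, isotopes, or aromatic
  perception (type-4 bonds are rejected on input).
* Counts grow combinatorially; beyond roughly ten heavy atoms an
  unconstrained run is better replaced by fragment-constrained runs.
* Overlapping prescribed substructures are not reconciled; use the
  posterior-filtering workaround.
* The valence dictionary is a pragmatic consensus; unusual valence states
  (hypervalent halogens, for instance) require a user dictionary.
* Atom-type dictionaries differ between structure-generation tools, and
  counts for compositions with multi-valence S or P are sensitive to the
  exact higher-valence pattern rules; the N(V) rule here is anchored by
  three independent reference compositions, while the S(IV)/S(VI) rules
  rest on the sulfoxide/sulfone consensus types and the P(V) rule on
  uniformity with N(V).  Users comparing against other tools should
  expect, and can configure away, dictionary-level differences.
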