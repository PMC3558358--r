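# isomgen

Exhaustive, duplicate-free generation of constitutional isomers: given a
molecular formula, `isomgen` produces every connected, valence-valid
chemical structure (as a Kekulé multigraph with implicit hydrogens)
matching that elemental composition — each isomorphism class exactly once
— optionally constrained to contain one or more non-overlapping prescribed
substructures supplied as an SDF file.

The intended users are people doing structure elucidation, in particular
metabolite identification: when an unknown compound yields an elemental
composition (from accurate mass) and perhaps some substructures (from
MS/MS), the candidate list is the set of constitutional isomers consistent
with that evidence.

## Method

A molecule is a colored multigraph $G=(V,E)$: vertices are non-hydrogen
atoms colored by element, and $d(a,b)\in\{0,1,2,3\}$ is the bond order of
each pair. Each element has one or more valence states (C 4; O 2; N 3/5;
P 3/5; S 2/4/6; halogens 1), higher states carrying bond-order pattern
rules (pentavalent N and P: fully heavy-substituted with no triple bond;
tetravalent S: exactly one double bond; hexavalent S: exactly two). An
atom in state $v$ with heavy
bond-order sum $d_v$ carries $v-d_v$ implicit hydrogens; a structure is
finished when it is connected and some state assignment makes the implicit
hydrogens total the formula's H count.

Enumeration is McKay-style canonical augmentation by bond addition.
Starting from isolated atoms (with prescribed fragment bonds pre-placed),
one bond order is added at a time; at each level, sibling extensions with
equal canonical hashes are merged, and a child is accepted only if deleting
the canonically last (non-prescribed) bond of its canonical form recreates
its parent. This guarantees the output is exhaustive and free of
isomorphic duplicates without keeping any global registry of generated
molecules. Canonical labeling of the order-weighted, element-colored
multigraphs is computed natively (partition refinement plus
individualization backtracking, in C++ via Rcpp). An independent
brute-force enumerator (`brute_force_enumerate()`) certifies the engine on
small formulas in the test suite.

## Worked example

```r
library(isomgen)

generate_structures("C2H6O")$molecule_count
#> [1] 2            # ethanol and dimethyl ether

r <- generate_structures("C3H4O3")   # pyruvic acid's composition
r
#> <generation_result> C3H4O3 : 152 molecules
#>   search nodes: 879 | extensions tested: 3,617 | sibling duplicates suppressed: 1,386

# both nitrogen valences in one run: 84 trivalent + 13 pentavalent
full <- generate_structures("C2H5NO2", emit_structures = TRUE)
full$molecule_count
#> [1] 97
generate_structures("C2H5NO2", restrict = c(N = 3))$molecule_count
#> [1] 84

# constrain by a prescribed substructure (sulfate group) and write SDF
sulfate <- load_fragments(system.file("extdata", "sulfate.sdf",
                                      package = "isomgen"))
generate_structures("C7H8O4S", fragments = sulfate)$molecule_count
#> [1] 13177
```

The counts are the number of non-isomorphic structures; with
`emit_structures = TRUE` (or `output_path = "out.sdf"`) the structures
themselves are returned/written, atoms ordered canonically so repeated
runs give byte-identical files.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/isomgen", package="isomgen"))')" \
    C2H5NO2 --restrict-valence N=3
# 84
```

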