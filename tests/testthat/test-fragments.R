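test_that("fragment loading strips explicit hydrogens and keeps orders", {
  fs <- load_fragments(write_acetyl_sdf())
  expect_length(fs$fragments, 1L)
  f <- fs$fragments[[1]]
  expect_equal(f$elements, c("C", "C", "O"))
  expect_equal(fs$declared_h_removed, 3L)
  expect_equal(bond_order(f, 1, 2), 1L)
  expect_equal(bond_order(f, 2, 3), 2L)
  # heavy atoms and heavy-bond orders conserved by stripping
  expect_equal(sum(f$bonds$order), 3L)
})

test_that("an empty SDF yields an empty fragment set and unconstrained runs", {
  f <- tempfile(fileext = ".sdf")
  writeLines(character(0), f)
  fs <- load_fragments(f)
  expect_length(fs$fragments, 0L)
  r <- generate_structures("C2H6O", fragments = fs)
  expect_equal(r$molecule_count, 2)
})

test_that("the sulfate group fixture loads as drawn", {
  fs <- load_fragments(system.file("extdata", "sulfate.sdf",
                                   package = "isomgen"))
  f <- fs$fragments[[1]]
  expect_equal(sort(f$elements), c("O", "O", "O", "O", "S"))
  s <- which(f$elements == "S")
  inc <- c(f$bonds$order[f$bonds$i == s], f$bonds$order[f$bonds$j == s])
  expect_equal(sort(inc), c(1L, 1L, 2L, 2L))
})

test_that("fragment embedding seeds the root and validates totals", {
  comp <- parse_formula("C4H8O")
  fs <- load_fragments(co_fragment_sdf())
  root <- embed_fragments(comp, fs)
  expect_equal(length(root$elements), 5L)
  expect_equal(nrow(root$bonds), 1L)
  expect_equal(nrow(root$fragment_bonds), 1L)
  expect_equal(root$elements[1:2], c("C", "O"))  # fragment atoms first
  # per-element totals must fit the composition
  expect_error(embed_fragments(parse_formula("CH4"), fs),
               "exceed the composition")
  # a fragment overloading an atom's degree is rejected
  expect_error(
    molgraph(c("C", "O", "O", "O", "O", "O"),
             data.frame(i = 1, j = 2:6, order = 1)),
    "maximum degree")
})

test_that("substructure containment uses order dominance", {
  mol <- mg(c("C", "C", "O"), c(1, 2, 1), c(2, 3, 2))  # C-C=O
  expect_true(contains_substructure(mol, mg(c("C", "O"), c(1, 2, 2))))
  expect_true(contains_substructure(mol, mg(c("C", "O"), c(1, 2, 1))))
  expect_true(contains_substructure(mol, mg(c("C", "C"), c(1, 2, 1))))
  expect_false(contains_substructure(mol, mg(c("C", "C"), c(1, 2, 2))))
  expect_false(contains_substructure(mol, mg(c("O", "O"))))
  # order dominance must fail when only single bonds exist
  allsingle <- mg(c("C", "C", "C"), c(1, 2, 1), c(2, 3, 1))
  expect_false(contains_substructure(allsingle, mg(c("C", "C"), c(1, 2, 2))))
})

test_that("fragment-constrained generation is sound and monotone", {
  fs <- load_fragments(co_fragment_sdf())
  unc <- generate_structures("C2H6O", emit_structures = TRUE)
  con <- generate_structures("C2H6O", fragments = fs, emit_structures = TRUE)
  expect_lte(con$molecule_count, unc$molecule_count)
  frag <- fs$fragments[[1]]
  for (m in con$molecules)
    expect_true(contains_substructure(m, frag))
  # constrained output equals posterior filtering of the unconstrained run
  keep <- vapply(unc$molecules, contains_substructure, logical(1),
                 fragment = frag)
  expect_setequal(final_hashes(con),
                  final_hashes(unc)[keep])
})

test_that("two seeded fragments equal one seeded plus posterior filtering", {
  one <- load_fragments(co_fragment_sdf(1L))
  two <- load_fragments(co_fragment_sdf(2L))
  frag <- one$fragments[[1]]
  with_both <- generate_structures("C2H6O2", fragments = two,
                                   emit_structures = TRUE)
  with_one <- generate_structures("C2H6O2", fragments = one,
                                  emit_structures = TRUE)
  # posterior filter: a second disjoint C-O bond must also be present,
  # i.e. two disjoint C-O fragments embed simultaneously
  both_embed <- vapply(with_one$molecules, function(m) {
    M <- molgraph(m$elements, m$bonds)
    contains_substructure(M, molgraph(c("C", "O", "C", "O"),
                                      data.frame(i = c(1, 3), j = c(2, 4),
                                                 order = 1L)))
  }, logical(1))
  expect_setequal(final_hashes(with_both),
                  final_hashes(with_one)[both_embed])
})

test_that("the seeded root itself passes the fragment augmentation test", {
  comp <- parse_formula("C3H8O")
  fs <- load_fragments(co_fragment_sdf())
  root <- embed_fragments(comp, fs)
  cf <- canonize(root)
  expect_true(is_canonical_augmentation_fragments(cf, root, root))
  # a bond increment above the prescribed order is deletable again
  kid <- add_bond(root, 1, 2)
  expect_true(is_canonical_augmentation_fragments(canonize(kid), kid, root))
})
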