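test_that("extend lists each legal one-bond augmentation exactly once", {
  two <- mg(c("C", "C"))
  kids <- extend(two)
  expect_length(kids, 1L)
  expect_equal(bond_order(kids[[1]], 1, 2), 1L)
  three <- mg(c("C", "C", "C"))
  expect_length(extend(three), 3L)  # the three unordered pairs
  # fully saturated: CF4-like star has no legal extension
  cf4 <- mg(c("C", "F", "F", "F", "F"),
            c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1))
  expect_length(extend(cf4), 0L)
  # children differ from the parent by exactly one order increment
  parent <- mg(c("C", "C", "O"), c(1, 2, 1))
  for (k in extend(parent)) {
    d <- sum(k$bonds$order) - sum(parent$bonds$order)
    expect_equal(d, 1L)
  }
})

test_that("the canonical augmentation test accepts exactly one parent class", {
  # first bond from the all-isolated root is always canonical
  root <- mg(c("C", "C", "O"))
  child <- add_bond(root, 1, 2)
  expect_true(is_canonical_augmentation(canonize(child), child, root))

  # for random structures, deleting the canonically last bond is accepted,
  # and deletions leading to non-isomorphic parents are rejected
  set.seed(5)
  for (seed in 1:12) {
    Mp <- random_multigraph(4, c("C", "C", "N", "O"), rng_seed = seed)
    if (nrow(Mp$bonds) == 0L) next
    cf <- canonize(Mp)
    lb <- last_bond(cf)
    canonical_parent <- remove_bond(Mp, lb$pair[1], lb$pair[2])
    expect_true(is_canonical_augmentation(cf, Mp, canonical_parent))
    for (k in seq_len(nrow(Mp$bonds))) {
      other <- remove_bond(Mp, Mp$bonds$i[k], Mp$bonds$j[k])
      accepted <- is_canonical_augmentation(cf, Mp, other)
      expect_identical(accepted, are_the_same(other, canonical_parent))
    }
  }
})

test_that("tiny formulas generate the expected structure counts", {
  expect_equal(generate_structures("CH4")$molecule_count, 1)
  # ethanol and dimethyl ether
  expect_equal(generate_structures("C2H6O")$molecule_count, 2)
  # acetaldehyde, ethylene oxide, vinyl alcohol
  expect_equal(generate_structures("C2H4O")$molecule_count, 3)
  # impossible hydrogen budget gives a clean zero
  expect_equal(generate_structures("CH5")$molecule_count, 0)
  expect_equal(generate_structures("C2H8")$molecule_count, 0)
})

test_that("engine counts equal the brute-force oracle on small formulas", {
  grid <- c("CH4", "C2H6", "C2H4", "C2H2", "CH4O", "C2H6O", "C2H4O",
            "C3H8", "C2H7N", "CH4S", "C2H6S", "CH5N3", "C2H4O2",
            "CH4N2O", "C2H5NO", "CH5O3P", "CH4O2S")
  for (f in grid) {
    eng <- generate_structures(f)$molecule_count
    ora <- brute_force_enumerate(f)$count
    expect_equal(eng, ora, info = f)
  }
})

test_that("emitted molecules are valid, unique and order-independent", {
  r <- generate_structures("C3H4O3", emit_structures = TRUE)
  expect_equal(r$molecule_count, length(r$molecules))
  hashes <- final_hashes(r)
  expect_equal(anyDuplicated(hashes), 0L)
  for (m in r$molecules[seq(1, length(r$molecules), by = 25)]) {
    M <- molgraph(m$elements, m$bonds, composition = r$composition)
    expect_true(is_connected(M))
    expect_equal(sum(m$implicit_h), 4L)
    dv <- atom_degrees(M)
    expect_true(all(m$valence - dv == m$implicit_h))
    # every atom sits in an admissible state
    A <- adjacency_matrix(M)
    for (v in seq_along(m$elements)) {
      adm <- admissible_states(m$elements[v], A[v, ][A[v, ] > 0L])
      expect_true(m$valence[v] %in% adm$valence)
    }
  }
  # atom instantiation order (formula order) does not change the output set
  r2 <- generate_structures("O3C3H4", emit_structures = TRUE)
  expect_setequal(final_hashes(r2), hashes)
  r3 <- generate_structures("H4OC2OCO", emit_structures = TRUE)
  expect_setequal(final_hashes(r3), hashes)
})

test_that("valence restriction partitions the multi-valence output", {
  full <- generate_structures("C2H5NO", emit_structures = TRUE)
  n3 <- generate_structures("C2H5NO", restrict = c(N = 3))
  penta <- sum(vapply(full$molecules, function(m)
    any(m$elements == "N" & m$valence == 5L), logical(1)))
  expect_equal(n3$molecule_count + penta, full$molecule_count)
  # restricted output is a subset of the full output
  n3e <- generate_structures("C2H5NO", restrict = c(N = 3),
                             emit_structures = TRUE)
  expect_true(all(final_hashes(n3e) %in% final_hashes(full)))
})

test_that("the safety valve truncates without affecting full runs", {
  r <- generate_structures("C3H4O3", max_count = 10)
  expect_equal(r$molecule_count, 10)
  expect_gt(generate_structures("C3H4O3")$statistics$nodes,
            r$statistics$nodes)
})
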