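test_that("formula parsing handles counts, repeats and Hill round-trips", {
  expect_equal(parse_formula("C3H4O3")$counts, c(C = 3L, H = 4L, O = 3L))
  expect_equal(parse_formula("CH4")$counts, c(C = 1L, H = 4L))
  expect_equal(parse_formula("C2H5NO2")$counts,
               c(C = 2L, H = 5L, N = 1L, O = 2L))
  expect_equal(parse_formula("C2H5NO2")$heavy_count, 5L)
  # repeated symbols are summed
  expect_equal(parse_formula("CCl3C")$counts, c(C = 2L, Cl = 3L))
  # formula writing is a left inverse of parsing
  for (f in c("C3H4O3", "C2H5NO2", "C7H8O4S", "CH4", "C3H5O6P", "CBrClFI")) {
    p <- parse_formula(f)
    expect_equal(parse_formula(format_formula(p))$counts[order(names(p$counts))],
                 p$counts[order(names(p$counts))], info = f)
  }
})

test_that("formula parsing rejects bad input", {
  expect_error(parse_formula("C2Xq3"), "unknown element")
  expect_error(parse_formula("Qx4"), "unknown element|malformed")
  expect_error(parse_formula("C0H4"), "invalid count")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("H4"), "at least one non-hydrogen")
  expect_error(parse_formula("c2h6"), "malformed|unknown")
})

test_that("valence states follow the dictionary in ascending order", {
  expect_equal(valence_states("C")$valence, 4L)
  expect_equal(valence_states("O")$valence, 2L)
  expect_equal(valence_states("N")$valence, c(3L, 5L))
  expect_equal(valence_states("S")$valence, c(2L, 4L, 6L))
  expect_equal(valence_states("P")$valence, c(3L, 5L))
  for (hal in c("F", "Cl", "Br", "I"))
    expect_equal(valence_states(hal)$valence, 1L)
  expect_error(valence_states("Xx"), "unknown element")
  d <- valence_dictionary()
  expect_equal(unname(d$max_degree[c("C", "N", "S", "H")]), c(4L, 5L, 6L, 1L))
  expect_false(d$generated[["H"]])
  expect_true(all(d$generated[c("F", "Cl", "Br", "I")]))
})

test_that("admissible states pair valence with implicit hydrogens", {
  # pentavalent P carries exactly one double bond and three single bonds
  p <- admissible_states("P", c(2, 1, 1, 1))
  expect_equal(p$valence, 5L)
  expect_equal(p$implicit_h, 0L)
  c1 <- admissible_states("C", 1)
  expect_equal(c1$valence, 4L)
  expect_equal(c1$implicit_h, 3L)
  # S with two single bonds is a thioether, not a higher-valence state
  s <- admissible_states("S", c(1, 1))
  expect_equal(s$valence, 2L)
  expect_equal(s$implicit_h, 0L)
  # pentavalent N is fully heavy-substituted with no triple bond
  n <- admissible_states("N", c(2, 2, 1))
  expect_equal(n$valence, 5L)
  expect_equal(n$implicit_h, 0L)
  expect_equal(admissible_states("N", c(2, 1, 1, 1))$valence, 5L)
  expect_equal(admissible_states("N", c(1, 1, 1, 1, 1))$valence, 5L)
  # ...but not with implicit hydrogens left over or with a triple bond
  expect_equal(nrow(admissible_states("N", c(2, 2))), 0L)
  expect_equal(nrow(admissible_states("N", c(3, 2))), 0L)
  # sulfone-type S6
  s6 <- admissible_states("S", c(2, 2, 1, 1))
  expect_equal(s6$valence, 6L)
  expect_equal(s6$implicit_h, 0L)
})

test_that("admissible states obey capacity and minimum-state invariants", {
  d <- valence_dictionary()
  set.seed(7)
  for (el in c("C", "O", "N", "S", "P", "F")) {
    md <- d$max_degree[[el]]
    # bare atom always admits its minimum-valence state fully hydrogenated
    bare <- admissible_states(el, integer(0), d)
    expect_equal(bare$valence[1], min(d$states[[el]]$valence))
    expect_equal(bare$implicit_h[1], bare$valence[1])
    for (rep in 1:20) {
      k <- sample(1:4, 1)
      orders <- sample(1:3, k, replace = TRUE)
      adm <- admissible_states(el, orders, d)
      if (sum(orders) > md) {
        expect_equal(nrow(adm), 0L)
      } else if (nrow(adm)) {
        expect_true(all(adm$implicit_h >= 0L))
        expect_true(all(adm$valence - sum(orders) == adm$implicit_h))
      }
    }
  }
})

test_that("a user dictionary file round-trips and restriction filters states", {
  f <- tempfile()
  writeLines(c("# custom dictionary", "H 1", "C 4 any", "O 2",
               "N 3 any", "N 5 doubles=2,triples=0"), f)
  d <- read_valence_dictionary(f)
  expect_equal(valence_states("N", d)$valence, c(3L, 5L))
  expect_equal(d$max_degree[["N"]], 5L)
  expect_equal(admissible_states("N", c(2, 2), d)$valence, 5L)
  expect_error(suppressWarnings(read_valence_dictionary(tempfile())))
  writeLines("N 5 doubles=2,triples=1", f)
  expect_error(read_valence_dictionary(f), "exceeds valence")

  r <- restrict_valences(valence_dictionary(), c(N = 3))
  expect_equal(valence_states("N", r)$valence, 3L)
  expect_equal(r$max_degree[["N"]], 3L)
  expect_error(restrict_valences(valence_dictionary(), c(N = 4)),
               "not a dictionary valence")
  expect_error(restrict_valences(valence_dictionary(), 3), "named")
})
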