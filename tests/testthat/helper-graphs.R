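# shared fixtures: small graph builders and permutation helpers

mg <- function(elements, ..., composition = NULL, dict = valence_dictionary()) {
  bonds <- list(...)
  bdf <- if (length(bonds))
    do.call(rbind, lapply(bonds, function(b)
      data.frame(i = b[1], j = b[2], order = b[3])))
  else NULL
  molgraph(elements, bdf, composition = composition, dict = dict)
}

# relabel atoms: p[i] is the new index of old atom i
permute_molgraph <- function(M, p) {
  n <- length(M$elements)
  el <- character(n)
  el[p] <- M$elements
  b <- M$bonds
  if (nrow(b)) {
    b$i <- p[M$bonds$i]
    b$j <- p[M$bonds$j]
  }
  fb <- M$fragment_bonds
  if (nrow(fb)) {
    fb$i <- p[M$fragment_bonds$i]
    fb$j <- p[M$fragment_bonds$j]
  }
  molgraph(el, b, composition = M$composition, fragment_bonds = fb,
           dict = M$dict)
}

# final-mode canonical hashes of the molecules emitted by a generation run
final_hashes <- function(result) {
  vapply(result$molecules, function(m) {
    M <- molgraph(m$elements, m$bonds, composition = result$composition,
                  dict = result$dict)
    canonize(M, "final",
             assignment = list(valence = m$valence,
                               implicit_h = m$implicit_h))$hash
  }, character(1))
}

# molfile text of a 2-carbon acetyl fragment written with explicit hydrogens
acetyl_sdf_lines <- function() {
  c("acetyl fragment",
    "  test fixture",
    "",
    "  6  5  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  2  0  0  0  0",
    "  1  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "  1  6  1  0  0  0  0",
    "M  END",
    "$$$$")
}

write_acetyl_sdf <- function() {
  f <- tempfile(fileext = ".sdf")
  writeLines(acetyl_sdf_lines(), f)
  f
}

# single C-O single-bond fragment as an SDF record
co_fragment_sdf <- function(n_records = 1L) {
  rec <- c("C-O fragment", "  test fixture", "",
           "  2  1  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "M  END", "$$$$")
  f <- tempfile(fileext = ".sdf")
  writeLines(rep(rec, n_records), f)
  f
}
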