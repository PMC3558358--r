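#' Generate all constitutional isomers of a molecular formula
#'
#' Exhaustive, duplicate-free enumeration of every connected, valence-valid
#' structure (as a Kekule multigraph with implicit hydrogens) matching the
#' elemental composition, optionally constrained to contain one or more
#' non-overlapping prescribed substructures.  The search is a depth-first
#' canonical augmentation: starting from fully isolated atoms (with any
#' prescribed fragment bonds pre-placed), one bond order is added at a time;
#' sibling extensions with equal canonical hashes are suppressed, and an
#' extension is accepted only when the canonical deletion of the child's
#' canonically last (non-prescribed) bond recreates its parent.  Every
#' isomorphism class is therefore visited exactly once.  A structure is
#' counted when all atoms are connected and a hydrogen assignment exists
#' placing every atom in an admissible valence state with implicit
#' hydrogens totalling the formula's H count; the search then continues
#' extending while atoms remain below their maximum degree, so structures
#' using higher valence states (e.g. pentavalent N) are also reached.
#' Distinct hydrogen assignments of one skeleton count as distinct
#' molecules, deduplicated by canonical hash under (element, valence,
#' implicit H) colors.
#'
#' @param formula molecular formula string or an
#'   \code{elemental_composition}.
#' @param fragments optional \code{fragment_set} (see
#'   \code{\link{load_fragments}}) of prescribed substructures, or a path
#'   to an SDF file of them.
#' @param dict a \code{valence_dictionary}.
#' @param restrict optional named vector fixing elements to a single
#'   valence, e.g. \code{c(N = 3)}.
#' @param emit_structures keep the generated molecules in the result (and
#'   allow writing them to SDF)?  With \code{FALSE} only the count and
#'   search statistics are returned.
#' @param output_path optional SDF path; implies \code{emit_structures}.
#' @param explicit_h write explicit hydrogen atoms in the SDF output?
#' @param max_count stop after this many molecules (safety valve for
#'   exploratory runs; \code{Inf} for exhaustive generation).
#' @return object of class \code{generation_result}: list with
#'   \code{molecule_count}, \code{molecules} (when emitted: list of
#'   molecules, each with \code{elements}, \code{bonds},
#'   \code{valence}, \code{implicit_h}, atoms in final canonical label
#'   order), \code{statistics} (search-tree nodes, extensions tested,
#'   duplicates suppressed) and \code{emitted_file}.
#' @examples
#' generate_structures("C2H6O")$molecule_count  # 2: ethanol, dimethyl ether
#' @export
generate_structures <- function(formula, fragments = NULL,
                                dict = valence_dictionary(), restrict = NULL,
                                emit_structures = FALSE, output_path = NULL,
                                explicit_h = FALSE, max_count = Inf) {
  if (inherits(formula, "elemental_composition")) dict <- formula$dict
  if (!is.null(restrict)) dict <- restrict_valences(dict, restrict)
  composition <- if (inherits(formula, "elemental_composition")) {
    parse_formula(format_formula(formula), dict)
  } else {
    parse_formula(formula, dict)
  }
  if (is.character(fragments)) fragments <- load_fragments(fragments, dict)
  if (!is.null(output_path)) emit_structures <- TRUE

  if (!is.null(fragments) && length(fragments$fragments) > 0L) {
    root <- embed_fragments(composition, fragments, dict)
    elements <- root$elements
    frag <- fragment_matrix(root)
    use_frags <- TRUE
  } else {
    elements <- composition_atoms(composition)
    frag <- matrix(0L, length(elements), length(elements))
    use_frags <- FALSE
  }

  etab <- names(dict$states)[names(dict$states) %in% unique(elements)]
  elem_idx <- match(elements, etab) - 1L
  states <- lapply(etab, function(el) {
    s <- dict$states[[el]]
    cbind(valence = s$valence, any = as.integer(s$rule == "any"),
          doubles = ifelse(is.na(s$doubles), -1L, s$doubles),
          triples = ifelse(is.na(s$triples), -1L, s$triples),
          h = ifelse(is.na(s$h), -1L, s$h))
  })
  md <- dict$max_degree[elements]

  raw <- .engine_generate_cpp(elem_idx, as.integer(md), states,
                              frag, use_frags, h_count(composition),
                              emit_structures,
                              if (is.finite(max_count)) max_count else -1)

  molecules <- NULL
  if (emit_structures) {
    molecules <- lapply(raw$molecules, function(m) {
      nb <- length(m$bond_i)
      list(elements = etab[m$elem + 1L],
           bonds = data.frame(i = m$bond_i, j = m$bond_j,
                              order = m$bond_order),
           valence = m$valence, implicit_h = m$implicit_h)
    })
  }
  res <- structure(
    list(molecule_count = raw$count,
         molecules = molecules,
         formula = format_formula(composition),
         composition = composition,
         dict = dict,
         statistics = list(nodes = raw$nodes,
                           extensions_tested = raw$extensions_tested,
                           duplicates_suppressed = raw$duplicates_suppressed),
         emitted_file = output_path),
    class = "generation_result")
  if (!is.null(output_path)) {
    write_sdf(res, output_path, explicit_h = explicit_h)
  }
  res
}

#' @export
print.generation_result <- function(x, ...) {
  cat("<generation_result>", x$formula, ":", format(x$molecule_count,
      big.mark = ","), "molecules\n")
  cat("  search nodes:", format(x$statistics$nodes, big.mark = ","),
      "| extensions tested:",
      format(x$statistics$extensions_tested, big.mark = ","),
      "| sibling duplicates suppressed:",
      format(x$statistics$duplicates_suppressed, big.mark = ","), "\n")
  if (!is.null(x$emitted_file)) cat("  written to:", x$emitted_file, "\n")
  invisible(x)
}

#' All legal one-bond extensions of a structure
#'
#' One child per unordered atom pair whose bond order can be increased by
#' one without exceeding order 3 or either atom's maximum degree, in
#' ascending pair order.
#'
#' @param M a \code{molgraph}.
#' @return list of \code{molgraph} children (empty when saturated).
#' @export
extend <- function(M) {
  n <- length(M$elements)
  dv <- atom_degrees(M)
  md <- M$dict$max_degree[M$elements]
  out <- list()
  for (a in seq_len(n)) {
    if (dv[a] >= md[[a]]) next
    for (b in seq_len(n)) {
      if (b <= a || dv[b] >= md[[b]]) next
      if (bond_order(M, a, b) >= 3L) next
      out[[length(out) + 1L]] <- add_bond(M, a, b)
    }
  }
  out
}

#' Canonical augmentation test
#'
#' Accepts the child \code{Mp} (an augmentation of \code{M} by one bond
#' order) exactly when removing the canonically last bond of \code{Mp}
#' recreates a structure isomorphic to \code{M}.  This is the pruning rule
#' that makes the search duplicate-free across branches.
#'
#' @param canonMp the \code{canonical_form} of \code{Mp} (generation color
#'   mode).
#' @param Mp the augmented \code{molgraph}.
#' @param M the parent \code{molgraph}.
#' @return logical.
#' @export
is_canonical_augmentation <- function(canonMp, Mp, M) {
  lb <- last_bond(canonMp)
  Mpp <- remove_bond(Mp, lb$pair[1], lb$pair[2])
  are_the_same(Mpp, M)
}

#' Canonical augmentation test with prescribed fragments
#'
#' As \code{\link{is_canonical_augmentation}}, but the canonical edge
#' sequence is walked backwards skipping every bond still owned by a
#' prescribed fragment (its pair is prescribed and its current order does
#' not exceed the prescribed order); the first deletable bond found is
#' removed.  When every bond is a fragment bond the structure is the seeded
#' root and is accepted.
#'
#' @inheritParams is_canonical_augmentation
#' @return logical.
#' @export
is_canonical_augmentation_fragments <- function(canonMp, Mp, M) {
  es <- canonMp$edge_sequence
  F <- fragment_matrix(Mp)
  for (k in rev(seq_len(nrow(es)))) {
    a <- which(canonMp$labeling == es$label_i[k])
    b <- which(canonMp$labeling == es$label_j[k])
    if (F[a, b] >= 1L && bond_order(Mp, a, b) <= F[a, b]) next
    Mpp <- remove_bond(Mp, a, b)
    return(are_the_same(Mpp, M))
  }
  TRUE
}
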