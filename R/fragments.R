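#' Load prescribed substructures from an SDF file
#'
#' Each record of the (MDL molfile V2000) file becomes one prescribed
#' fragment.  Explicit hydrogen atoms and their bonds are removed before
#' generation, since hydrogens are implicit throughout; the number removed
#' per fragment is recorded.  Fragments must be pairwise non-overlapping
#' (they may not share atoms); this is a user contract the tool cannot
#' verify semantically, but per-element totals exceeding the composition
#' are rejected at embedding time.
#'
#' @param path SDF file path.
#' @param dict a \code{valence_dictionary}; every element in the file must
#'   be present in it.
#' @return object of class \code{fragment_set}: list with
#'   \code{fragments} (list of \code{molgraph}s, hydrogens stripped) and
#'   \code{declared_h_removed} (integer per fragment).
#' @export
load_fragments <- function(path, dict = valence_dictionary()) {
  records <- read_sdf(path, dict = dict, allow_h = TRUE)
  fragments <- vector("list", length(records))
  h_removed <- integer(length(records))
  for (r in seq_along(records)) {
    rec <- records[[r]]
    keep <- rec$elements != "H"
    h_removed[r] <- sum(!keep)
    newidx <- cumsum(keep)
    b <- rec$bonds
    drop <- !keep[b$i] | !keep[b$j]
    b <- b[!drop, , drop = FALSE]
    b$i <- newidx[b$i]; b$j <- newidx[b$j]
    if (sum(keep) == 0L)
      stop("fragment record ", r, " contains no heavy atoms")
    fragments[[r]] <- molgraph(rec$elements[keep], b, dict = dict)
  }
  structure(list(fragments = fragments, declared_h_removed = h_removed),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set>", length(x$fragments), "fragment(s):",
      paste(vapply(x$fragments, function(f)
        format_formula(f$composition), character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Seed the search root with prescribed fragments
#'
#' Builds the root structure of a fragment-constrained run: fragment atoms
#' occupy the lowest indices (fragment by fragment, in file order) with
#' their bonds placed and flagged as prescribed; all remaining composition
#' atoms are isolated.  Symmetry-induced duplicates arising from the fixed
#' embedding are removed later by final canonical deduplication.
#'
#' @param composition an \code{elemental_composition}.
#' @param fs a \code{fragment_set}.
#' @param dict a \code{valence_dictionary}.
#' @return the root \code{molgraph} with \code{fragment_bonds} set.
#' @export
embed_fragments <- function(composition, fs, dict = valence_dictionary()) {
  elements <- character(0)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  for (f in fs$fragments) {
    off <- length(elements)
    elements <- c(elements, f$elements)
    if (nrow(f$bonds))
      bonds <- rbind(bonds, data.frame(i = f$bonds$i + off,
                                       j = f$bonds$j + off,
                                       order = f$bonds$order))
  }
  counts <- composition$counts
  for (el in unique(elements)) {
    avail <- if (el %in% names(counts)) counts[[el]] else 0L
    if (sum(elements == el) > avail)
      stop("fragment atoms exceed the composition count for element '",
           el, "'")
  }
  rest <- character(0)
  for (el in setdiff(names(counts)[counts > 0L], "H")) {
    extra <- counts[[el]] - sum(elements == el)
    if (extra > 0L) rest <- c(rest, rep(el, extra))
  }
  all_elements <- c(elements, rest)
  M <- molgraph(all_elements, bonds, composition = composition,
                fragment_bonds = bonds, dict = dict)
  M
}

#' Substructure containment with order dominance
#'
#' True when an injective, element-preserving map of the fragment's atoms
#' into the molecule exists such that for every fragment bond the molecule
#' carries a bond of at least the prescribed order between the image atoms
#' (d_f <= d).  Used for posterior filtering when several substructures
#' cannot all be seeded (e.g. possibly overlapping ones).
#'
#' @param M a \code{molgraph} (or an emitted molecule from
#'   \code{\link{generate_structures}}).
#' @param fragment a \code{molgraph}.
#' @return logical.
#' @export
contains_substructure <- function(M, fragment) {
  if (!inherits(M, "molgraph"))
    M <- molgraph(M$elements, M$bonds)
  nf <- length(fragment$elements)
  nm <- length(M$elements)
  if (nf > nm) return(FALSE)
  Af <- adjacency_matrix(fragment)
  Am <- adjacency_matrix(M)
  degf <- atom_degrees(fragment)
  degm <- atom_degrees(M)
  # match fragment atoms in order of decreasing constraint
  ord <- order(-degf)
  map <- integer(nf)
  used <- logical(nm)
  bt <- function(k) {
    if (k > nf) return(TRUE)
    v <- ord[k]
    for (w in seq_len(nm)) {
      if (used[w]) next
      if (M$elements[w] != fragment$elements[v]) next
      if (degm[w] < degf[v]) next
      ok <- TRUE
      for (kk in seq_len(k - 1L)) {
        u <- ord[kk]
        if (Af[v, u] > Am[w, map[u]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[v] <<- w; used[w] <<- TRUE
      if (bt(k + 1L)) return(TRUE)
      used[w] <<- FALSE
    }
    FALSE
  }
  bt(1L)
}
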