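#' Construct a molecular multigraph
#'
#' The central data structure of the generator: heavy atoms (plus valence-1
#' non-H atoms such as halogens) colored by element, and a bond map sending
#' an unordered atom pair to an order in 1..3 (absent pair = order 0).
#' Hydrogen is never a vertex; it is carried implicitly through the attached
#' composition and assigned only when a molecule is finished.  Bonds marked
#' in \code{fragment_bonds} record prescribed-substructure bonds seeded at
#' the search root.
#'
#' @param elements character vector of element symbols, one per atom; atom
#'   indices are positions in this vector.
#' @param bonds data frame with columns \code{i}, \code{j}, \code{order}
#'   (or NULL for no bonds).
#' @param composition optional \code{elemental_composition} the graph is
#'   being generated towards; defaults to the graph's own atoms with zero
#'   hydrogens.
#' @param fragment_bonds optional data frame (\code{i}, \code{j},
#'   \code{order}) of prescribed bonds; orders here are the prescribed
#'   minima (d_f), each must not exceed the current bond order.
#' @param dict a \code{valence_dictionary}.
#' @return object of class \code{molgraph}.
#' @export
molgraph <- function(elements, bonds = NULL, composition = NULL,
                     fragment_bonds = NULL, dict = valence_dictionary()) {
  elements <- as.character(elements)
  if (length(elements) < 1L) stop("a multigraph needs at least one atom")
  bad <- setdiff(unique(elements), names(dict$states))
  if (length(bad)) stop("unknown element symbol: '", bad[1], "'")
  if (any(elements == "H"))
    stop("hydrogen is implicit and cannot be a graph vertex")
  bonds <- normalize_bonds(bonds, length(elements))
  fragment_bonds <- normalize_bonds(fragment_bonds, length(elements))
  if (is.null(composition)) {
    counts <- table(elements)
    counts <- stats::setNames(as.integer(counts), names(counts))
    composition <- structure(
      list(counts = counts, heavy_count = length(elements), dict = dict),
      class = "elemental_composition")
  }
  M <- structure(list(elements = elements, bonds = bonds,
                      fragment_bonds = fragment_bonds,
                      composition = composition, dict = dict),
                 class = "molgraph")
  dv <- atom_degrees(M)
  md <- dict$max_degree[elements]
  if (any(dv > md))
    stop("atom ", which(dv > md)[1], " (", elements[which(dv > md)[1]],
         ") exceeds its maximum degree")
  M
}

normalize_bonds <- function(bonds, n) {
  if (is.null(bonds) || NROW(bonds) == 0L)
    return(data.frame(i = integer(0), j = integer(0), order = integer(0)))
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.integer(bonds$order))
  if (any(bonds$i == bonds$j)) stop("self-loops are not allowed")
  if (any(bonds$i < 1L | bonds$j < 1L | bonds$i > n | bonds$j > n))
    stop("bond endpoint out of range")
  if (any(bonds$order < 1L | bonds$order > 3L))
    stop("bond orders must be in 1..3")
  ii <- pmin(bonds$i, bonds$j)
  jj <- pmax(bonds$i, bonds$j)
  bonds$i <- ii; bonds$j <- jj
  if (anyDuplicated(bonds[c("i", "j")]))
    stop("duplicate bond entries for one atom pair")
  bonds[order(bonds$i, bonds$j), , drop = FALSE]
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph>", length(x$elements), "atoms (",
      paste(x$elements, collapse = " "), "),",
      nrow(x$bonds), "bond pairs, total order", sum(x$bonds$order), "\n")
  invisible(x)
}

# order of the (a,b) pair, 0 when absent
bond_order <- function(M, a, b) {
  i <- min(a, b); j <- max(a, b)
  hit <- M$bonds$i == i & M$bonds$j == j
  if (any(hit)) M$bonds$order[hit] else 0L
}

# heavy-bond order sum per atom (d_v)
atom_degrees <- function(M) {
  dv <- integer(length(M$elements))
  if (nrow(M$bonds)) {
    for (k in seq_len(nrow(M$bonds))) {
      dv[M$bonds$i[k]] <- dv[M$bonds$i[k]] + M$bonds$order[k]
      dv[M$bonds$j[k]] <- dv[M$bonds$j[k]] + M$bonds$order[k]
    }
  }
  dv
}

# dense adjacency-order matrix
adjacency_matrix <- function(M) {
  n <- length(M$elements)
  A <- matrix(0L, n, n)
  if (nrow(M$bonds)) {
    idx <- cbind(M$bonds$i, M$bonds$j)
    A[idx] <- M$bonds$order
    A[idx[, c(2, 1), drop = FALSE]] <- M$bonds$order
  }
  A
}

fragment_matrix <- function(M) {
  n <- length(M$elements)
  A <- matrix(0L, n, n)
  if (nrow(M$fragment_bonds)) {
    idx <- cbind(M$fragment_bonds$i, M$fragment_bonds$j)
    A[idx] <- M$fragment_bonds$order
    A[idx[, c(2, 1), drop = FALSE]] <- M$fragment_bonds$order
  }
  A
}

#' Increase a bond order by one
#'
#' A single bond becomes a double bond, a double a triple; an absent bond
#' becomes a single bond.  Value semantics: the input graph is unchanged.
#'
#' @param M a \code{molgraph}.
#' @param a,b distinct atom indices.
#' @return the augmented \code{molgraph}.
#' @export
add_bond <- function(M, a, b) {
  if (a == b) stop("cannot bond an atom to itself")
  cur <- bond_order(M, a, b)
  if (cur >= 3L) stop("bond order would exceed 3")
  dv <- atom_degrees(M)
  md <- M$dict$max_degree[M$elements]
  if (dv[a] + 1L > md[[a]])
    stop("atom ", a, " (", M$elements[a], ") would exceed its maximum degree")
  if (dv[b] + 1L > md[[b]])
    stop("atom ", b, " (", M$elements[b], ") would exceed its maximum degree")
  i <- min(a, b); j <- max(a, b)
  bonds <- M$bonds
  hit <- bonds$i == i & bonds$j == j
  if (any(hit)) {
    bonds$order[hit] <- cur + 1L
  } else {
    bonds <- rbind(bonds, data.frame(i = i, j = j, order = 1L))
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  }
  M$bonds <- bonds
  M
}

#' Decrease a bond order by one
#'
#' Exact inverse of \code{\link{add_bond}}; an order-1 bond is removed
#' entirely.
#'
#' @inheritParams add_bond
#' @return the reduced \code{molgraph}.
#' @export
remove_bond <- function(M, a, b) {
  cur <- bond_order(M, a, b)
  if (cur < 1L) stop("no bond between atoms ", a, " and ", b)
  i <- min(a, b); j <- max(a, b)
  hit <- M$bonds$i == i & M$bonds$j == j
  if (cur == 1L) {
    M$bonds <- M$bonds[!hit, , drop = FALSE]
  } else {
    M$bonds$order[hit] <- cur - 1L
  }
  M
}

#' Is the multigraph connected?
#'
#' All atoms in one component, any bond of order >= 1 counting as adjacency.
#' Intermediate structures during generation may legally be disconnected;
#' only finished molecules must be connected.
#'
#' @param M a \code{molgraph}.
#' @return logical.
#' @export
is_connected <- function(M) {
  n <- length(M$elements)
  if (n == 1L) return(TRUE)
  if (nrow(M$bonds) < n - 1L) return(FALSE)
  g <- igraph::graph_from_edgelist(
    cbind(M$bonds$i, M$bonds$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::is_connected(g)
}

#' Enumerate hydrogen assignments of a multigraph
#'
#' Every choice of one admissible valence state per atom whose implicit
#' hydrogen total equals the composition's hydrogen count.  An empty list
#' signals the structure cannot be finished as it stands.
#'
#' @param M a \code{molgraph} with an attached composition.
#' @return list of assignments, each a list with integer vectors
#'   \code{valence} and \code{implicit_h} (one entry per atom), in a
#'   deterministic order.
#' @export
hydrogen_assignments <- function(M) {
  n <- length(M$elements)
  A <- adjacency_matrix(M)
  per_atom <- vector("list", n)
  for (v in seq_len(n)) {
    orders <- A[v, ][A[v, ] > 0L]
    per_atom[[v]] <- admissible_states(M$elements[v], orders, M$dict)
    if (nrow(per_atom[[v]]) == 0L) return(list())
  }
  target <- h_count(M$composition)
  min_h <- vapply(per_atom, function(s) min(s$implicit_h), integer(1))
  max_h <- vapply(per_atom, function(s) max(s$implicit_h), integer(1))
  out <- list()
  rec <- function(v, val, hs, tot) {
    if (v > n) {
      if (tot == target)
        out[[length(out) + 1L]] <<- list(valence = val, implicit_h = hs)
      return()
    }
    if (tot + sum(min_h[v:n]) > target || tot + sum(max_h[v:n]) < target)
      return()
    s <- per_atom[[v]]
    for (k in seq_len(nrow(s))) {
      val[v] <- s$valence[k]; hs[v] <- s$implicit_h[k]
      rec(v + 1L, val, hs, tot + s$implicit_h[k])
    }
  }
  rec(1L, integer(n), integer(n), 0L)
  out
}

#' Is the structure a finished molecule?
#'
#' True when (i) every atom of the composition is instantiated, (ii) at
#' least one hydrogen assignment exists (so every atom sits in an admissible
#' valence state and the implicit hydrogens total the formula's H count) and
#' (iii) the graph is connected.
#'
#' @param M a \code{molgraph}.
#' @return logical.
#' @export
is_finished <- function(M) {
  counts <- M$composition$counts
  want <- counts[setdiff(names(counts)[counts > 0L], "H")]
  have <- table(factor(M$elements, levels = names(want)))
  if (length(want) && !all(as.integer(have) == as.integer(want))) return(FALSE)
  if (length(M$elements) != M$composition$heavy_count) return(FALSE)
  if (!is_connected(M)) return(FALSE)
  length(hydrogen_assignments(M)) > 0L
}
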