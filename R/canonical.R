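#' Canonical form of a molecular multigraph
#'
#' Computes a canonical labeling (a bijection from atom indices to labels
#' 1..n) of the element-colored multigraph by partition refinement with
#' individualization backtracking, together with a canonical hash string
#' that two multigraphs share exactly when they are isomorphic
#' (color- and order-preserving).  The canonical edge sequence orders edges
#' lexicographically by their (min label, max label) pair; the "last bond"
#' used in the canonical-deletion test is the lexicographic maximum.
#'
#' Two color modes are supported: \code{"generation"} colors atoms by
#' element only (the mode used for duplicate suppression during the
#' search); \code{"final"} colors by (element, chosen valence, implicit
#' hydrogen count) and is used to deduplicate finished molecules that
#' differ only by an automorphic reassignment of valence states.
#'
#' @param M a \code{molgraph}.
#' @param color_mode \code{"generation"} or \code{"final"}.
#' @param assignment for \code{"final"} mode, a hydrogen assignment as
#'   returned by \code{\link{hydrogen_assignments}} (a list with
#'   \code{valence} and \code{implicit_h} vectors).
#' @return object of class \code{canonical_form}: list with
#'   \code{labeling} (integer vector, atom index -> canonical label),
#'   \code{hash} (string), \code{edge_sequence} (data frame
#'   \code{label_i}, \code{label_j}, \code{order} in canonical edge order)
#'   and \code{code} (the integer encoding behind the hash).
#' @export
canonize <- function(M, color_mode = c("generation", "final"),
                     assignment = NULL) {
  color_mode <- match.arg(color_mode)
  col <- atom_colors(M, color_mode, assignment)
  res <- .canon_cpp(adjacency_matrix(M), col)
  canonical_form_from_code(res$labels, res$code, length(M$elements))
}

atom_colors <- function(M, color_mode, assignment = NULL) {
  base <- match(M$elements, names(M$dict$states))
  if (color_mode == "generation") return(base)
  if (is.null(assignment))
    stop("final color mode requires a hydrogen assignment")
  base * 1000L + assignment$valence * 10L + assignment$implicit_h
}

canonical_form_from_code <- function(labels, code, n) {
  ntrip <- (length(code) - 1L - n) %/% 3L
  if (ntrip > 0L) {
    m <- matrix(code[(2L + n):length(code)], ncol = 3L, byrow = TRUE)
    es <- data.frame(label_i = m[, 1], label_j = m[, 2], order = m[, 3])
  } else {
    es <- data.frame(label_i = integer(0), label_j = integer(0),
                     order = integer(0))
  }
  structure(list(labeling = as.integer(labels),
                 hash = paste0(code[1], ";",
                               paste(code[2:(1L + n)], collapse = ","), ";",
                               if (ntrip > 0L)
                                 paste(code[(2L + n):length(code)],
                                       collapse = ",") else ""),
                 edge_sequence = es,
                 code = as.integer(code)),
            class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("<canonical_form>", length(x$labeling), "atoms, hash", x$hash, "\n")
  invisible(x)
}

#' Are two multigraphs the same molecule skeleton?
#'
#' Isomorphism test through canonical hash equality in generation color
#' mode (element colors only).
#'
#' @param M1,M2 \code{molgraph} objects.
#' @return logical.
#' @export
are_the_same <- function(M1, M2) {
  identical(canonize(M1)$hash, canonize(M2)$hash)
}

#' Canonically last bond of a structure
#'
#' The bond maximal in the canonical edge order, mapped back through the
#' inverse labeling to the original atom indices.  This is the bond removed
#' by a canonical deletion.
#'
#' @param cf a \code{canonical_form} with at least one bond.
#' @return list with \code{pair} (original atom indices) and
#'   \code{position} (index into the canonical edge sequence).
#' @export
last_bond <- function(cf) {
  es <- cf$edge_sequence
  if (nrow(es) == 0L) stop("structure has no bonds")
  k <- nrow(es)
  a <- which(cf$labeling == es$label_i[k])
  b <- which(cf$labeling == es$label_j[k])
  list(pair = c(a, b), position = k)
}
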