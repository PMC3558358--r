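#' Brute-force reference enumeration of constitutional isomers
#'
#' An independent oracle for verifying the canonical-augmentation engine on
#' small formulas: it enumerates assignments of orders 0..3 to every
#' unordered heavy-atom pair directly (depth-first with per-atom capacity
#' and hydrogen-budget cutoffs), keeps the connected assignments admitting
#' a hydrogen assignment that totals the formula's H count, expands each
#' surviving skeleton into its distinct hydrogen assignments, and removes
#' duplicates by brute-force permutation-search isomorphism under
#' (element, valence, implicit H) colors.  It deliberately shares no code
#' with the canonical-labeling module, so agreement between the two is
#' evidence of correctness rather than tautology.
#'
#' @param composition formula string or \code{elemental_composition}.
#' @param dict a \code{valence_dictionary}.
#' @param max_heavy complexity guard on the heavy atom count.
#' @return list with \code{count} and \code{representatives} (one molecule
#'   per isomorphism class: \code{elements}, \code{bonds}, \code{valence},
#'   \code{implicit_h}).
#' @export
brute_force_enumerate <- function(composition, dict = valence_dictionary(),
                                  max_heavy = 6L) {
  if (is.character(composition)) composition <- parse_formula(composition, dict)
  elements <- composition_atoms(composition)
  n <- length(elements)
  if (n > max_heavy)
    stop("brute-force oracle is guarded to <= ", max_heavy, " heavy atoms")
  md <- as.integer(dict$max_degree[elements])
  target_h <- h_count(composition)
  bmax <- (sum(md) - target_h) %/% 2L
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  npair <- nrow(pairs)
  reps <- list()
  rep_colors <- list()
  A <- matrix(0L, n, n)
  dv <- integer(n)

  consider <- function() {
    # connectivity by neighbour expansion
    if (n > 1L) {
      seen <- logical(n); seen[1] <- TRUE; queue <- 1L
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(A[v, ] > 0L & !seen)
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      if (!all(seen)) return()
    }
    per_atom <- vector("list", n)
    for (v in seq_len(n)) {
      per_atom[[v]] <- admissible_states(elements[v], A[v, ][A[v, ] > 0L], dict)
      if (nrow(per_atom[[v]]) == 0L) return()
    }
    assigns <- list()
    recA <- function(v, val, hs, tot) {
      if (v > n) {
        if (tot == target_h)
          assigns[[length(assigns) + 1L]] <<- list(valence = val,
                                                   implicit_h = hs)
        return()
      }
      if (tot > target_h) return()
      s <- per_atom[[v]]
      for (k in seq_len(nrow(s))) {
        val[v] <- s$valence[k]; hs[v] <- s$implicit_h[k]
        recA(v + 1L, val, hs, tot + s$implicit_h[k])
      }
    }
    recA(1L, integer(n), integer(n), 0L)
    for (asg in assigns) {
      colr <- paste(elements, asg$valence, asg$implicit_h, sep = "/")
      dup <- FALSE
      for (r in seq_along(reps)) {
        if (!identical(sort(rep_colors[[r]]), sort(colr))) next
        if (colored_multigraphs_isomorphic(rep_colors[[r]], reps[[r]]$A,
                                           colr, A)) { dup <- TRUE; break }
      }
      if (!dup) {
        reps[[length(reps) + 1L]] <<- list(A = A, valence = asg$valence,
                                           implicit_h = asg$implicit_h)
        rep_colors[[length(rep_colors) + 1L]] <<- colr
      }
    }
  }

  recB <- function(p, bsum) {
    if (p > npair) { consider(); return() }
    i <- pairs[p, 1]; j <- pairs[p, 2]
    cap <- min(3L, md[i] - dv[i], md[j] - dv[j], bmax - bsum)
    for (o in 0:max(0L, cap)) {
      if (o > 0L) {
        A[i, j] <<- o; A[j, i] <<- o
        dv[i] <<- dv[i] + o; dv[j] <<- dv[j] + o
      }
      recB(p + 1L, bsum + o)
      if (o > 0L) {
        dv[i] <<- dv[i] - o; dv[j] <<- dv[j] - o
      }
    }
    A[i, j] <<- 0L; A[j, i] <<- 0L
  }

  if (bmax >= 0L) recB(1L, 0L)
  representatives <- lapply(reps, function(r) {
    idx <- which(upper.tri(r$A) & r$A > 0L, arr.ind = TRUE)
    list(elements = elements,
         bonds = data.frame(i = idx[, 1], j = idx[, 2],
                            order = r$A[idx]),
         valence = r$valence, implicit_h = r$implicit_h)
  })
  list(count = length(reps), representatives = representatives)
}

#' Brute-force isomorphism of colored multigraphs
#'
#' Permutation search over color-preserving bijections; independent of the
#' canonical-labeling module (used to cross-validate it).
#'
#' @param col1,col2 per-vertex colors (any vector type).
#' @param A1,A2 adjacency order matrices.
#' @return logical.
#' @export
colored_multigraphs_isomorphic <- function(col1, A1, col2, A2) {
  n <- length(col1)
  if (length(col2) != n) return(FALSE)
  if (!identical(sort(as.character(col1)), sort(as.character(col2))))
    return(FALSE)
  d1 <- rowSums(A1); d2 <- rowSums(A2)
  if (!identical(sort(paste(col1, d1)), sort(paste(col2, d2)))) return(FALSE)
  map <- integer(n); used <- logical(n)
  bt <- function(v) {
    if (v > n) return(TRUE)
    for (w in seq_len(n)) {
      if (used[w]) next
      if (as.character(col2[w]) != as.character(col1[v])) next
      if (d2[w] != d1[v]) next
      ok <- TRUE
      for (u in seq_len(v - 1L)) {
        if (A1[v, u] != A2[w, map[u]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[v] <<- w; used[w] <<- TRUE
      if (bt(v + 1L)) return(TRUE)
      used[w] <<- FALSE
    }
    FALSE
  }
  bt(1L)
}

#' Deterministic pseudo-random valence-respecting multigraph
#'
#' Fixture generator for canonizer property tests: starting from isolated
#' atoms, repeatedly increments the order of a randomly chosen legal pair.
#' Same seed, same graph.
#'
#' @param n atom count (<= 8).
#' @param elements element symbols, recycled to length \code{n}.
#' @param rng_seed integer seed.
#' @param steps number of bond increments to attempt.
#' @param dict a \code{valence_dictionary}.
#' @return a \code{molgraph}.
#' @export
random_multigraph <- function(n, elements = "C", rng_seed = 1L,
                              steps = 2L * n, dict = valence_dictionary()) {
  stopifnot(n <= 8L)
  elements <- rep_len(elements, n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(rng_seed)
  M <- molgraph(elements, dict = dict)
  md <- dict$max_degree[elements]
  for (s in seq_len(steps)) {
    dv <- atom_degrees(M)
    legal <- which(outer(seq_len(n), seq_len(n), function(a, b) a < b),
                   arr.ind = TRUE)
    ok <- vapply(seq_len(nrow(legal)), function(k) {
      a <- legal[k, 1]; b <- legal[k, 2]
      dv[a] < md[[a]] && dv[b] < md[[b]] && bond_order(M, a, b) < 3L
    }, logical(1))
    if (!any(ok)) break
    cand <- legal[ok, , drop = FALSE]
    pick <- cand[sample.int(nrow(cand), 1L), ]
    M <- add_bond(M, pick[1], pick[2])
  }
  M
}
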