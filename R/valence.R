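#' Default valence-state dictionary
#'
#' The chemistry model used throughout the package: for every supported
#' element, the list of allowed valence states and, per state, the rule
#' restricting the multiset of heavy-bond orders the atom may carry in that
#' state.  Valence counts total bonding capacity, so implicit hydrogens for a
#' state are \code{valence - sum(heavy bond orders)}.
#'
#' The defaults encode the consensus organic-chemistry valences: C 4; O 2;
#' N 3 or 5, the pentavalent state being fully heavy-substituted (no
#' implicit hydrogens) with no triple bond — the nitro / aci-nitro-like
#' patterns 2+2+1, 2+1+1+1 and 1+1+1+1+1; P 3 or 5, the pentavalent state
#' following the same fully-substituted no-triple rule (phosphate and
#' phosphorane patterns); S 2, 4 or 6, the tetravalent
#' state requiring exactly one double bond (sulfoxide-type) and the
#' hexavalent state exactly two double bonds (sulfone-type); halogens
#' (F, Cl, Br, I) 1.  Hydrogen has a
#' single state of valence 1 and is terminal: it is never instantiated as a
#' graph vertex during generation, only accounted for implicitly.
#'
#' @param path optional path to a plain-text dictionary file; see
#'   \code{\link{read_valence_dictionary}}.  When \code{NULL} the built-in
#'   defaults are returned.
#' @return an object of class \code{valence_dictionary}: a list with
#'   \itemize{
#'     \item \code{states}: named list mapping element symbol to a data frame
#'       with columns \code{valence}, \code{rule} (\code{"any"} or
#'       \code{"exact"}), \code{doubles}, \code{triples}, ordered by ascending
#'       valence;
#'     \item \code{max_degree}: named integer vector, the maximum valence per
#'       element (the \emph{md} bound used during generation);
#'     \item \code{generated}: named logical, whether atoms of the element are
#'       instantiated as vertices (FALSE only for H).
#'   }
#' @examples
#' d <- valence_dictionary()
#' d$max_degree[["C"]]  # 4
#' valence_states("S", d)$valence  # 2 4 6
#' @export
valence_dictionary <- function(path = NULL) {
  if (!is.null(path)) {
    return(read_valence_dictionary(path))
  }
  st <- function(valence, doubles = NA_integer_, triples = NA_integer_,
                 h = NA_integer_) {
    data.frame(valence = as.integer(valence),
               rule = if (all(is.na(c(doubles, triples, h)))) "any" else "exact",
               doubles = as.integer(doubles), triples = as.integer(triples),
               h = as.integer(h), stringsAsFactors = FALSE)
  }
  states <- list(
    H  = st(1L),
    C  = st(4L),
    N  = rbind(st(3L), st(5L, triples = 0L, h = 0L)),
    O  = st(2L),
    P  = rbind(st(3L), st(5L, triples = 0L, h = 0L)),
    S  = rbind(st(2L), st(4L, doubles = 1L, triples = 0L),
               st(6L, doubles = 2L, triples = 0L)),
    F  = st(1L),
    Cl = st(1L),
    Br = st(1L),
    I  = st(1L)
  )
  new_valence_dictionary(states)
}

new_valence_dictionary <- function(states) {
  states <- lapply(states, function(s) s[order(s$valence), , drop = FALSE])
  max_degree <- vapply(states, function(s) max(s$valence), integer(1))
  generated <- vapply(names(states), function(e) e != "H", logical(1))
  structure(list(states = states, max_degree = max_degree,
                 generated = generated),
            class = "valence_dictionary")
}

#' Read a valence dictionary from a plain-text file
#'
#' Each non-empty, non-comment (\code{#}) line declares one valence state:
#' \preformatted{element valence rule}
#' where \code{rule} is either \code{any} (any partition of the valence into
#' heavy-bond orders and implicit hydrogens) or a comma-separated list of
#' constraints among \code{doubles=k}, \code{triples=m} and \code{h=j}
#' (exact counts of double bonds, triple bonds and implicit hydrogens;
#' omitted counts are unconstrained).  Multiple lines per element
#' accumulate states, so one valence may carry several alternative
#' patterns.
#'
#' @param path file path.
#' @return a \code{valence_dictionary}.
#' @export
read_valence_dictionary <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty valence dictionary file: ", path)
  states <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 2L || length(tok) > 3L)
      stop("malformed dictionary line: '", ln, "'")
    el <- tok[1]
    v <- suppressWarnings(as.integer(tok[2]))
    if (is.na(v) || v < 1L)
      stop("invalid valence in dictionary line: '", ln, "'")
    rule <- if (length(tok) == 3L) tok[3] else "any"
    if (rule == "any") {
      row <- data.frame(valence = v, rule = "any", doubles = NA_integer_,
                        triples = NA_integer_, h = NA_integer_,
                        stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(rule, ",", fixed = TRUE)[[1]]
      vals <- c(doubles = NA_integer_, triples = NA_integer_,
                h = NA_integer_)
      for (p in parts) {
        m <- regmatches(p, regexec("^(doubles|triples|h)=([0-9]+)$", p))[[1]]
        if (length(m) != 3L)
          stop("invalid pattern rule '", rule, "' (expected 'any' or ",
               "comma-separated doubles=k, triples=m, h=j)")
        vals[m[2]] <- as.integer(m[3])
      }
      row <- data.frame(valence = v, rule = "exact", doubles = vals[["doubles"]],
                        triples = vals[["triples"]], h = vals[["h"]],
                        stringsAsFactors = FALSE)
      lo <- 2L * max(0L, row$doubles, na.rm = TRUE) +
        3L * max(0L, row$triples, na.rm = TRUE) +
        max(0L, row$h, na.rm = TRUE)
      if (lo > v)
        stop("pattern rule '", rule, "' exceeds valence ", v)
    }
    states[[el]] <- rbind(states[[el]], row)
  }
  new_valence_dictionary(states)
}

#' Valence states of an element
#'
#' @param element element symbol.
#' @param dict a \code{valence_dictionary}.
#' @return data frame of the element's states, ascending valence.
#' @export
valence_states <- function(element, dict = valence_dictionary()) {
  if (!element %in% names(dict$states))
    stop("unknown element symbol: '", element, "'")
  dict$states[[element]]
}

#' Valence states admissible for a multiset of heavy-bond orders
#'
#' Given the orders of the heavy bonds an atom currently carries, return
#' every valence state that accepts that pattern, paired with the implicit
#' hydrogen count \code{valence - sum(orders)}.  An empty result signals
#' that no state of the element accommodates the pattern.
#'
#' @param element element symbol.
#' @param heavy_orders integer vector of incident heavy-bond orders, each in
#'   1..3 (may be empty).
#' @param dict a \code{valence_dictionary}.
#' @return data frame with columns \code{valence}, \code{implicit_h} (possibly
#'   zero rows).
#' @examples
#' admissible_states("P", c(2, 1, 1, 1))  # pentavalent P, no hydrogens
#' admissible_states("C", 1)              # CH3 group
#' @export
admissible_states <- function(element, heavy_orders = integer(0),
                              dict = valence_dictionary()) {
  heavy_orders <- as.integer(heavy_orders)
  if (length(heavy_orders) && (any(heavy_orders < 1L) || any(heavy_orders > 3L)))
    stop("heavy bond orders must be in 1..3")
  s <- valence_states(element, dict)
  tot <- sum(heavy_orders)
  n2 <- sum(heavy_orders == 2L)
  n3 <- sum(heavy_orders == 3L)
  ok <- s$valence >= tot & (s$rule == "any" |
    ((is.na(s$doubles) | s$doubles == n2) &
     (is.na(s$triples) | s$triples == n3) &
     (is.na(s$h) | s$h == s$valence - tot)))
  out <- s[ok, c("valence", "rule"), drop = FALSE]
  out$implicit_h <- out$valence - tot
  rownames(out) <- NULL
  # one valence may be admissible through several alternative patterns
  out <- out[!duplicated(out$valence), c("valence", "implicit_h")]
  rownames(out) <- NULL
  out
}

#' Restrict elements to a single valence
#'
#' Compatibility mode with single-valence generators: fix the named elements
#' to exactly one of their dictionary valences (keeping that state's pattern
#' rule) and drop the others.
#'
#' @param dict a \code{valence_dictionary}.
#' @param restrict named integer vector, e.g. \code{c(N = 3)}.
#' @return the restricted \code{valence_dictionary}.
#' @export
restrict_valences <- function(dict, restrict) {
  if (is.null(names(restrict)) || any(!nzchar(names(restrict))))
    stop("'restrict' must be a named vector of element = valence pairs")
  states <- dict$states
  for (el in names(restrict)) {
    if (!el %in% names(states))
      stop("unknown element symbol: '", el, "'")
    v <- as.integer(restrict[[el]])
    keep <- states[[el]]$valence == v
    if (!any(keep))
      stop(v, " is not a dictionary valence of ", el)
    states[[el]] <- states[[el]][keep, , drop = FALSE]
  }
  new_valence_dictionary(states)
}

#' Parse a molecular formula
#'
#' Strict element-symbol + optional-count grammar (no parentheses, isotopes
#' or charges); repeated symbols are summed.  Hydrogen is recorded in the
#' composition but never instantiated as a vertex.
#'
#' @param text formula string, e.g. \code{"C2H5NO2"}.
#' @param dict a \code{valence_dictionary}; every symbol in the formula must
#'   be present in it.
#' @return an object of class \code{elemental_composition}: list with
#'   \code{counts} (named integer vector of the symbols present),
#'   \code{heavy_count} (all non-H atoms) and \code{dict}.
#' @examples
#' parse_formula("C3H4O3")$counts
#' parse_formula("C2H5NO2")$heavy_count  # 5
#' @export
parse_formula <- function(text, dict = valence_dictionary()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text))
    stop("malformed formula '", text, "': unparsable characters remain")
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(dict$states))
      stop("unknown element symbol: '", sym, "'")
    k <- if (nzchar(num)) as.integer(num) else 1L
    if (is.na(k) || k < 1L)
      stop("invalid count for element '", sym, "' in formula '", text, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
  }
  heavy <- sum(counts[setdiff(names(counts), "H")])
  if (heavy < 1L)
    stop("formula must contain at least one non-hydrogen atom")
  structure(list(counts = counts, heavy_count = as.integer(heavy),
                 dict = dict),
            class = "elemental_composition")
}

#' Write a composition back as a formula string
#'
#' Hill-style ordering: C first, then H, then remaining elements
#' alphabetically.  A left inverse of \code{\link{parse_formula}}.
#'
#' @param composition an \code{elemental_composition}.
#' @return formula string.
#' @export
format_formula <- function(composition) {
  counts <- composition$counts
  counts <- counts[counts > 0L]
  syms <- names(counts)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    if (counts[[s]] == 1L) s else paste0(s, counts[[s]])
  }, character(1)), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental_composition>", format_formula(x),
      sprintf("(%d heavy atoms, %d H)\n", x$heavy_count,
              if ("H" %in% names(x$counts)) x$counts[["H"]] else 0L))
  invisible(x)
}

# H count accessor (0 when absent)
h_count <- function(composition) {
  if ("H" %in% names(composition$counts)) composition$counts[["H"]] else 0L
}

# expand a composition into the generator's atom list: heavy atoms and
# valence-1 non-H atoms, grouped by element in formula order
composition_atoms <- function(composition) {
  counts <- composition$counts
  syms <- setdiff(names(counts)[counts > 0L], "H")
  rep(syms, counts[syms])
}
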