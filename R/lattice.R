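# ---------------------------------------------------------------------------
# Finite posets and bounded lattices
#
# A poset is stored extensionally: a character vector of element identifiers
# and a logical matrix `leq` with leq[i, j] == TRUE iff element i <= element j.
# All certification is by exhaustive scan with early exit; the intended scale
# is desk-sized lattices (|L| <= 4098), where O(|L|^3) checks are immediate.
# ---------------------------------------------------------------------------

#' Create a finite partially ordered set
#'
#' @param elements character vector of distinct element identifiers.
#' @param leq logical matrix; `leq[i, j]` is TRUE iff element `i` is below or
#'   equal to element `j`. Row/column order follows `elements`.
#' @param validate check the poset axioms (reflexivity, antisymmetry,
#'   transitivity)? Disable only for relations already known valid.
#' @return an object of class `finite_poset`.
#' @export
finite_poset <- function(elements, leq, validate = TRUE) {
  elements <- as.character(elements)
  if (anyDuplicated(elements)) stop("element identifiers must be distinct")
  leq <- as.matrix(leq)
  storage.mode(leq) <- "logical"
  n <- length(elements)
  if (!all(dim(leq) == c(n, n))) stop("leq must be a square matrix matching elements")
  dimnames(leq) <- list(elements, elements)
  p <- structure(list(elements = elements, leq = leq), class = "finite_poset")
  if (validate) {
    v <- check_poset_axioms(p)
    if (!v$ok) stop("not a poset: ", v$message)
  }
  p
}

# Axiom scan used both by the constructor and by certify_lattice().
check_poset_axioms <- function(p) {
  leq <- p$leq
  if (!all(diag(leq))) {
    bad <- p$elements[which(!diag(leq))[1]]
    return(list(ok = FALSE, message = paste0("reflexivity fails at ", bad)))
  }
  both <- leq & t(leq)
  diag(both) <- FALSE
  if (any(both)) {
    ij <- which(both, arr.ind = TRUE)[1, ]
    return(list(ok = FALSE, message = paste0(
      "antisymmetry fails at (", p$elements[ij[1]], ", ", p$elements[ij[2]], ")")))
  }
  # composition of <= with itself must stay inside <=
  closure <- (leq %*% leq) > 0
  if (any(closure & !leq)) {
    ij <- which(closure & !leq, arr.ind = TRUE)[1, ]
    return(list(ok = FALSE, message = paste0(
      "transitivity fails at (", p$elements[ij[1]], ", ", p$elements[ij[2]], ")")))
  }
  list(ok = TRUE, message = "")
}

elem_index <- function(l, x) {
  i <- match(x, l$elements)
  if (anyNA(i)) stop("unknown element: ", paste(x[is.na(i)], collapse = ", "))
  i
}

# Greatest lower bound of elements i, j (indices); NA_integer_ if none unique.
glb_index <- function(leq, i, j) {
  lb <- which(leq[, i] & leq[, j])
  if (length(lb) == 0L) return(NA_integer_)
  # the glb is the lower bound that dominates all lower bounds
  up <- colSums(leq[lb, lb, drop = FALSE])
  g <- lb[up == length(lb)]
  if (length(g) == 1L) g else NA_integer_
}

lub_index <- function(leq, i, j) {
  ub <- which(leq[i, ] & leq[j, ])
  if (length(ub) == 0L) return(NA_integer_)
  dn <- rowSums(leq[ub, ub, drop = FALSE])
  g <- ub[dn == length(ub)]
  if (length(g) == 1L) g else NA_integer_
}

#' Meet (greatest lower bound) and join (least upper bound)
#'
#' Computed by scanning all common bounds of the pair; symmetric in `x`, `y`.
#'
#' @param l a `finite_poset` or any lattice object built on one.
#' @param x,y element identifiers.
#' @return the identifier of the meet (resp. join).
#' @export
meet <- function(l, x, y) {
  i <- elem_index(l, x); j <- elem_index(l, y)
  g <- glb_index(l$leq, i, j)
  if (is.na(g)) stop("not a lattice: no meet for (", x, ", ", y, ")")
  l$elements[g]
}

#' @rdname meet
#' @export
join <- function(l, x, y) {
  i <- elem_index(l, x); j <- elem_index(l, y)
  g <- lub_index(l$leq, i, j)
  if (is.na(g)) stop("not a lattice: no join for (", x, ", ", y, ")")
  l$elements[g]
}

#' Create a bounded lattice from a poset
#'
#' Locates the least and greatest elements and verifies every pair has a meet
#' and a join.
#'
#' @param elements,leq as in [finite_poset()].
#' @param complement optional named character vector mapping each element to
#'   its orthocomplement; attaching one yields an ortholattice.
#' @return an object of class `bounded_lattice` (and `ortho_lattice` when a
#'   complement map is supplied).
#' @export
bounded_lattice <- function(elements, leq, complement = NULL) {
  p <- finite_poset(elements, leq)
  v <- certify_lattice(p)
  if (!v$is_lattice) {
    stop("not a lattice: pair (", v$witness[1], ", ", v$witness[2],
         ") lacks a ", v$missing)
  }
  bot <- which(rowSums(p$leq) == length(elements))  # below everything
  top <- which(colSums(p$leq) == length(elements))  # above everything
  if (length(bot) != 1L || length(top) != 1L) stop("lattice must have unique bounds")
  l <- structure(
    list(elements = p$elements, leq = p$leq,
         bottom = p$elements[bot], top = p$elements[top]),
    class = c("bounded_lattice", "finite_poset"))
  if (!is.null(complement)) l <- add_orthocomplement(l, complement)
  l
}

add_orthocomplement <- function(l, complement) {
  complement <- complement[l$elements]
  if (anyNA(complement)) stop("complement map must be total")
  if (!all(complement %in% l$elements)) stop("complement maps outside the lattice")
  l$complement <- stats::setNames(as.character(complement), l$elements)
  class(l) <- unique(c("ortho_lattice", class(l)))
  l
}

#' @export
print.bounded_lattice <- function(x, ...) {
  cat(sprintf("<%s> %d elements, bottom = %s, top = %s\n",
              class(x)[1], length(x$elements), x$bottom, x$top))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Boolean algebras (power-set lattices)
# ---------------------------------------------------------------------------

subset_id <- function(mask, n) {
  if (mask == 0L) return("{}")
  paste0("{", paste(which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L),
                    collapse = ","), "}")
}

#' Power-set Boolean algebra on n generators
#'
#' Elements are all subsets of \{1, ..., n\} ordered by inclusion, with
#' set-theoretic complement; there are 2^n elements and the n singletons are
#' the atoms. `n = 0` yields the one-element lattice where bottom = top.
#'
#' @param n nonnegative number of generators; capped at 12 to keep exhaustive
#'   certification tractable.
#' @return an object of class `boolean_algebra`.
#' @export
make_boolean_algebra <- function(n) {
  if (length(n) != 1L || is.na(n) || n != round(n) || n < 0)
    stop("ground size must be a nonnegative integer")
  if (n > 12) stop("ground size capped at 12 (2^n elements)")
  n <- as.integer(n)
  masks <- 0:(2^n - 1)
  ids <- vapply(masks, subset_id, character(1), n = n)
  leq <- outer(masks, masks, function(a, b) bitwAnd(a, b) == a)
  full <- 2L^n - 1L
  comp <- stats::setNames(ids[match(bitwAnd(bitwNot(masks), full), masks)], ids)
  l <- structure(
    list(elements = ids, leq = leq, bottom = ids[1], top = ids[length(ids)],
         ground_size = n, masks = masks),
    class = c("boolean_algebra", "ortho_lattice", "bounded_lattice", "finite_poset"))
  dimnames(l$leq) <- list(ids, ids)
  l$complement <- comp
  l
}

#' Atoms of a bounded lattice
#'
#' Elements covering the bottom element.
#' @param l a `bounded_lattice`.
#' @return character vector of atom identifiers.
#' @export
atoms <- function(l) {
  covers <- hasse_covers(l)
  covers$upper[covers$lower == l$bottom]
}

# ---------------------------------------------------------------------------
# Certification (exhaustive scans with early exit)
# ---------------------------------------------------------------------------

#' Certify that a finite poset is a lattice
#'
#' Scans every unordered pair for a unique least upper bound and greatest
#' lower bound.
#'
#' @param p a `finite_poset`.
#' @return list with `is_lattice` flag and, on failure, `witness` (the
#'   offending pair) and `missing` ("meet" or "join").
#' @export
certify_lattice <- function(p) {
  ax <- check_poset_axioms(p)
  if (!ax$ok) stop("poset axioms violated: ", ax$message)
  n <- length(p$elements)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (is.na(glb_index(p$leq, i, j)))
        return(list(is_lattice = FALSE, witness = p$elements[c(i, j)], missing = "meet"))
      if (is.na(lub_index(p$leq, i, j)))
        return(list(is_lattice = FALSE, witness = p$elements[c(i, j)], missing = "join"))
    }
  }
  list(is_lattice = TRUE, witness = NULL, missing = NULL)
}

# Precompute meet and join index tables (n x n integer matrices).
op_tables <- function(l) {
  n <- length(l$elements)
  mt <- jt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    mt[i, i] <- jt[i, i] <- i
    if (i < n) for (j in (i + 1):n) {
      m <- glb_index(l$leq, i, j); u <- lub_index(l$leq, i, j)
      if (is.na(m) || is.na(u))
        stop("not a lattice: pair (", l$elements[i], ", ", l$elements[j], ")")
      mt[i, j] <- mt[j, i] <- m
      jt[i, j] <- jt[j, i] <- u
    }
  }
  list(meet = mt, join = jt)
}

#' Certify distributivity
#'
#' Checks x AND (y OR z) == (x AND y) OR (x AND z) over all triples by
#' exhaustive scan. The first violating triple in lexicographic element order
#' is returned as the witness.
#'
#' @param l a `bounded_lattice`.
#' @return list with `distributive` flag and optional `witness` triple
#'   (x, y, z).
#' @export
certify_distributive <- function(l) {
  tb <- op_tables(l)
  n <- length(l$elements)
  for (x in seq_len(n)) {
    mx <- tb$meet[x, ]
    lhs <- matrix(mx[tb$join], n, n)           # x ^ (y v z), indexed [y, z]
    rhs <- matrix(tb$join[cbind(rep(mx, times = n), rep(mx, each = n))], n, n)
    bad <- which(lhs != rhs, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      bad <- bad[order(bad[, 1], bad[, 2]), , drop = FALSE]
      w <- l$elements[c(x, bad[1, 1], bad[1, 2])]
      return(list(distributive = FALSE, witness = w))
    }
  }
  list(distributive = TRUE, witness = NULL)
}

#' Certify the orthocomplement axioms
#'
#' Checks, for the attached complement map: complementation
#' (x AND x' = 0, x OR x' = 1), order reversal (x <= y implies y' <= x'),
#' and involution ((x')' = x). All failures are collected.
#'
#' @param l an `ortho_lattice`.
#' @return list with `ok` flag and a `failures` list of (axiom, elements).
#' @export
certify_orthocomplement <- function(l) {
  if (is.null(l$complement)) stop("no complement map attached")
  comp <- elem_index(l, l$complement[l$elements])
  n <- length(l$elements)
  bot <- elem_index(l, l$bottom); top <- elem_index(l, l$top)
  failures <- list()
  for (i in seq_len(n)) {
    ci <- comp[i]
    m <- glb_index(l$leq, i, ci); u <- lub_index(l$leq, i, ci)
    if (is.na(m) || m != bot || is.na(u) || u != top)
      failures[[length(failures) + 1]] <- list(axiom = "complementation",
                                               elements = l$elements[i])
    if (comp[ci] != i)
      failures[[length(failures) + 1]] <- list(axiom = "involution",
                                               elements = l$elements[i])
  }
  # order reversal: leq[i, j] must imply leq[comp[j], comp[i]]
  viol <- l$leq & !t(l$leq[comp, comp])
  if (any(viol)) {
    ij <- which(viol, arr.ind = TRUE)
    for (r in seq_len(nrow(ij)))
      failures[[length(failures) + 1]] <- list(
        axiom = "order_reversal", elements = l$elements[ij[r, ]])
  }
  list(ok = length(failures) == 0, failures = failures)
}

#' Certify orthomodularity
#'
#' Checks the orthomodular law: x <= y implies y = x OR (y AND x'). The first
#' violating ordered pair is returned as witness.
#'
#' @param l an `ortho_lattice` whose orthocomplement axioms hold.
#' @return list with `orthomodular` flag and optional `witness` pair (x, y).
#' @export
certify_orthomodular <- function(l) {
  if (is.null(l$complement)) stop("no complement map attached")
  tb <- op_tables(l)
  comp <- elem_index(l, l$complement[l$elements])
  n <- length(l$elements)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && l$leq[i, j]) {
      if (tb$join[i, tb$meet[j, comp[i]]] != j)
        return(list(orthomodular = FALSE, witness = l$elements[c(i, j)]))
    }
  }
  list(orthomodular = TRUE, witness = NULL)
}

# ---------------------------------------------------------------------------
# Gluing
# ---------------------------------------------------------------------------

#' Glue Boolean algebras at shared bounds
#'
#' Builds one lattice from several Boolean algebras by identifying all their
#' least elements with a single shared bottom and all their greatest elements
#' with a single shared top. Interior elements keep their block identity (tag
#' `Bk:` prefix); the order holds within a block or through the shared bounds;
#' the orthocomplement acts blockwise. Gluing more than two algebras realizes
#' the iterated construction directly.
#'
#' Whenever at least two blocks contribute interior elements and some block
#' contributes an antichain, the result is orthomodular but not distributive:
#' quantum logic without any Hilbert-space machinery.
#'
#' @param algebras list of `boolean_algebra` objects, or a numeric vector of
#'   ground sizes (each passed to [make_boolean_algebra()]). Ground size 0 is
#'   rejected inside a gluing (its block would force bottom = top); ground
#'   size 1 is permitted as a no-op block (no interior) with a warning.
#' @return an object of class `glued_lattice`.
#' @export
glue <- function(algebras) {
  if (is.numeric(algebras)) algebras <- lapply(algebras, make_boolean_algebra)
  if (!is.list(algebras) || length(algebras) == 0)
    stop("glue requires a non-empty list of Boolean algebras")
  if (!all(vapply(algebras, inherits, logical(1), "boolean_algebra")))
    stop("all blocks must be Boolean algebras")
  sizes <- vapply(algebras, function(a) a$ground_size, integer(1))
  if (any(sizes == 0L))
    stop("ground size 0 not allowed inside a gluing (block would collapse the bounds)")
  if (any(sizes == 1L))
    warning("ground size 1 blocks contribute no interior elements")

  ids <- c("0", "1")
  block_of <- c(NA_integer_, NA_integer_)
  local_id <- c(NA_character_, NA_character_)
  for (k in seq_along(algebras)) {
    a <- algebras[[k]]
    interior <- setdiff(a$elements, c(a$bottom, a$top))
    if (length(interior) == 0) next
    ids <- c(ids, paste0("B", k, ":", interior))
    block_of <- c(block_of, rep(k, length(interior)))
    local_id <- c(local_id, interior)
  }
  n <- length(ids)
  leq <- diag(n) > 0
  leq[1, ] <- TRUE        # bottom below everything
  leq[, 2] <- TRUE        # everything below top
  leq[2, ] <- c(FALSE, TRUE, rep(FALSE, n - 2))
  leq[, 1] <- c(TRUE, rep(FALSE, n - 1))
  comp <- character(n)
  comp[1] <- "1"; comp[2] <- "0"
  for (k in seq_along(algebras)) {
    a <- algebras[[k]]
    idx <- which(block_of == k)
    if (length(idx) == 0) next
    loc <- local_id[idx]
    leq[idx, idx] <- a$leq[loc, loc]
    ac <- a$complement[loc]
    comp[idx] <- ifelse(ac == a$bottom, "0",
                 ifelse(ac == a$top, "1", paste0("B", k, ":", ac)))
  }
  dimnames(leq) <- list(ids, ids)
  l <- structure(
    list(elements = ids, leq = leq, bottom = "0", top = "1",
         complement = stats::setNames(comp, ids),
         block_sizes = sizes,
         block_of = stats::setNames(block_of, ids),
         block_local = stats::setNames(local_id, ids)),
    class = c("glued_lattice", "ortho_lattice", "bounded_lattice", "finite_poset"))
  l
}

#' Find a witness against distributivity in a glued lattice
#'
#' Searches for x, y interior to the same block and forming an antichain, and
#' z interior to a different block. For such a triple the join y OR z is the
#' shared top, so x AND (y OR z) = x while (x AND y) OR (x AND z) = x AND y,
#' which differs from x. Returns the first such triple in lexicographic
#' element order, or NULL when no block supplies an antichain next to a second
#' nontrivial block.
#'
#' @param g a `glued_lattice`.
#' @return character vector (x, y, z) or NULL.
#' @export
find_nondistributive_witness <- function(g) {
  stopifnot(inherits(g, "glued_lattice"))
  interior <- which(!is.na(g$block_of))
  if (length(interior) == 0) return(NULL)
  for (xi in interior) {
    for (yi in interior) {
      if (g$block_of[xi] != g$block_of[yi]) next
      if (g$leq[xi, yi] || g$leq[yi, xi]) next   # need an antichain
      for (zi in interior) {
        if (g$block_of[zi] == g$block_of[xi]) next
        x <- g$elements[xi]; y <- g$elements[yi]; z <- g$elements[zi]
        lhs <- meet(g, x, join(g, y, z))
        rhs <- join(g, meet(g, x, y), meet(g, x, z))
        if (lhs == x && rhs == meet(g, x, y) && rhs != x)
          return(c(x, y, z))
      }
    }
  }
  NULL
}

# ---------------------------------------------------------------------------
# Hasse diagrams
# ---------------------------------------------------------------------------

#' Covering relation of a lattice
#'
#' Pairs (x, y) with x < y and no element strictly between. The reflexive
#' transitive closure of the covers reconstructs the order exactly, so the
#' Hasse diagram omits all implied edges.
#'
#' @param l a `finite_poset` (usually a `bounded_lattice`).
#' @return data.frame with character columns `lower` and `upper`.
#' @export
hasse_covers <- function(l) {
  strict <- l$leq
  diag(strict) <- FALSE
  two_step <- (strict %*% strict) > 0
  cov <- strict & !two_step
  ij <- which(cov, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(lower = l$elements[ij[, 1]], upper = l$elements[ij[, 2]],
             stringsAsFactors = FALSE)
}

#' Reconstruct the order relation from a covering relation
#'
#' Reflexive-transitive closure of the cover edges; used to verify round
#' trips with [hasse_covers()].
#'
#' @param elements character vector of element identifiers.
#' @param covers data.frame with columns `lower`, `upper`.
#' @return logical `leq` matrix.
#' @export
leq_from_covers <- function(elements, covers) {
  n <- length(elements)
  leq <- diag(n) > 0
  dimnames(leq) <- list(elements, elements)
  adj <- matrix(FALSE, n, n, dimnames = list(elements, elements))
  adj[cbind(covers$lower, covers$upper)] <- TRUE
  repeat {
    nxt <- leq | ((leq %*% adj) > 0)
    if (identical(nxt, leq)) break
    leq <- nxt
  }
  leq
}

#' Write a Hasse diagram as a DOT digraph
#'
#' Edges are drawn upward (cover to covered-by, `rankdir=BT`).
#'
#' @param l a lattice.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(l, path) {
  cov <- hasse_covers(l)
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph hasse {", "  rankdir=BT;",
             paste0("  ", q(l$elements), ";"),
             paste0("  ", q(cov$lower), " -> ", q(cov$upper), ";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a Hasse diagram as a plain edge list
#'
#' One cover pair per line: `child<TAB>parent`.
#'
#' @inheritParams write_dot
#' @export
write_hasse_edges <- function(l, path) {
  cov <- hasse_covers(l)
  writeLines(paste(cov$lower, cov$upper, sep = "\t"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Canonical small lattices
# ---------------------------------------------------------------------------

#' The benzene-ring ortholattice O6
#'
#' Six elements 0 < a < b < 1 and 0 < b' < a' < 1 with complement a <-> a',
#' b <-> b'. Orthocomplemented but not orthomodular: a <= b yet
#' a OR (b AND a') = a, the canonical negative control for the orthomodular
#' law.
#'
#' @return an `ortho_lattice`.
#' @export
o6_lattice <- function() {
  el <- c("0", "a", "b", "b'", "a'", "1")
  leq <- matrix(FALSE, 6, 6, dimnames = list(el, el))
  diag(leq) <- TRUE
  leq["0", ] <- TRUE
  leq[, "1"] <- TRUE
  leq["a", "b"] <- TRUE
  leq["b'", "a'"] <- TRUE
  comp <- stats::setNames(c("1", "a'", "b'", "b", "a", "0"), el)
  bounded_lattice(el, leq, complement = comp)
}

#' Serialize a lattice (with complement map) to JSON
#'
#' Stores elements, cover pairs, bounds, and the complement map; the order
#' relation is reconstructed from the covers on read.
#'
#' @param l a lattice.
#' @param path output file.
#' @export
write_lattice_json <- function(l, path) {
  cov <- hasse_covers(l)
  obj <- list(elements = l$elements, bottom = l$bottom, top = l$top,
              covers = cov)
  if (!is.null(l$complement))
    obj$complement <- as.list(l$complement)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lattice_json
#' @return for `read_lattice_json`, a `bounded_lattice` (with complement if
#'   one was stored).
#' @export
read_lattice_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  leq <- leq_from_covers(obj$elements, obj$covers)
  comp <- if (!is.null(obj$complement))
    stats::setNames(unlist(obj$complement), names(obj$complement))
  bounded_lattice(obj$elements, leq, complement = comp)
}
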