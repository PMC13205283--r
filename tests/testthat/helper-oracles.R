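# Independent oracles and small generators used across the suite. These
# deliberately re-derive results by brute force, on a different code path
# from the package internals they check.

# Random poset on n elements: random DAG edges, then reflexive-transitive
# closure. Antisymmetry holds because edges only go from lower to higher
# index.
random_poset <- function(n, p_edge = 0.3) {
  leq <- diag(n) > 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) leq[i, j] <- TRUE
  repeat {
    nxt <- leq | ((leq %*% leq) > 0)
    if (identical(nxt, leq)) break
    leq <- nxt
  }
  els <- paste0("e", seq_len(n))
  dimnames(leq) <- list(els, els)
  finite_poset(els, leq)
}

# Brute-force lattice oracle: for every pair, enumerate all upper (lower)
# bounds and ask whether one of them is below (above) all the others.
oracle_is_lattice <- function(p) {
  leq <- p$leq
  n <- nrow(leq)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ub <- Filter(function(k) leq[i, k] && leq[j, k], seq_len(n))
    if (!any(vapply(ub, function(k) all(vapply(ub, function(l) leq[k, l],
                                               logical(1))), logical(1))))
      return(FALSE)
    lb <- Filter(function(k) leq[k, i] && leq[k, j], seq_len(n))
    if (!any(vapply(lb, function(k) all(vapply(lb, function(l) leq[l, k],
                                               logical(1))), logical(1))))
      return(FALSE)
  }
  TRUE
}

# Brute-force Bayes oracle: lay out the full joint table P(h, d), slice the
# observed column, renormalize.
oracle_bayes <- function(prior, likelihood, d) {
  joint <- likelihood * prior           # recycles prior down rows
  col <- joint[, d + 1]
  unname(col / sum(col))
}

random_simplex <- function(n, floor = 0.01) {
  x <- stats::runif(n, floor, 1)
  x / sum(x)
}

random_model <- function(m, n_outcomes) {
  lik <- t(vapply(seq_len(m), function(i) random_simplex(n_outcomes),
                  numeric(n_outcomes)))
  hypothesis_model(random_simplex(m), lik)
}

# Evaluate the distributive law on a concrete triple.
distributive_holds <- function(l, x, y, z) {
  meet(l, x, join(l, y, z)) == join(l, meet(l, x, y), meet(l, x, z))
}

# Evaluate the orthomodular law on a concrete ordered pair x <= y.
orthomodular_holds <- function(l, x, y) {
  join(l, x, meet(l, y, l$complement[[x]])) == y
}
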