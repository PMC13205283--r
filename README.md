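# orthoglue

Quantum logic from glued Boolean algebras, and Bayesian + inverse Bayesian
inference in nonstationary binary environments.

## What it is for

Finite Boolean algebras model fixed causal contexts: every proposition is a
combination of atoms, and inference inside one context is classical. When
several contexts coexist — sharing only the trivial bounds "nothing" (0) and
"everything" (1) — the combined structure is no longer Boolean. `orthoglue`
builds such structures and certifies their logic, and couples that algebraic
picture to an online inference system in which the contexts themselves are
rewritten by experience.

Two components:

1. **Lattice construction and certification.** `make_boolean_algebra(n)`
   builds the power-set lattice on *n* generators (2^n elements).
   `glue(c(n1, n2, ...))` identifies all the blocks' least elements with one
   shared 0 and all their greatest elements with one shared 1; interior
   elements stay tagged by block, order holds only within a block or through
   the bounds, and the orthocomplement acts blockwise. Certifiers
   (`certify_lattice`, `certify_distributive`, `certify_orthocomplement`,
   `certify_orthomodular`) check every axiom by exhaustive scan and return
   witnesses on failure. The glued lattice is always orthomodular
   (x ≤ y ⇒ y = x ∨ (y ∧ x⊥)) and — with at least two nontrivial blocks —
   never distributive: for x, y an antichain in one block and z interior to
   another, x ∧ (y ∨ z) = x ∧ 1 = x while (x ∧ y) ∨ (x ∧ z) = x ∧ y ≠ x.
   That combination (orthomodular, non-distributive) is quantum logic,
   obtained with no Hilbert-space machinery.

2. **Inference.** A `hypothesis_model` is a prior P(h) over m hypotheses and
   a likelihood matrix P(d|h) over binary outcomes. Bayesian updating
   (`bayes_update`, Bayes' rule with the posterior fed back as the next
   prior) moves belief inside a fixed hypothesis space; it is the fixed point
   of the free energy F = D_KL(P(h) ‖ P(h|d)) − ln P(d) (`free_energy`,
   `kl_divergence`). Inverse Bayesian inference (`inverse_bayes_rewrite`)
   instead rewrites the likelihood row of one hypothesis to the empirical
   event frequency of the last W observations, P(d=1|h_i) ← (1/W)Σd — it
   transforms the hypothesis space itself. `run_inference` runs either system
   over a seeded piecewise-constant Bernoulli environment
   (`slow_environment`: 0.2 → 0.35 → 0.5; `abrupt_environment`: cycling
   0.8, 0.2, 0.65, 0.35) and records predictions p̂_t = Σ P(h)P(d=1|h),
   squared errors and cumulative MSE.

A bridge (`model_to_lattice`, `lattice_log`) renders each hypothesis as one
Boolean block whose atoms are its supported outcomes, and replays every
likelihood rewrite as the replacement of one sub-Boolean algebra by another
(the hypothesis gets a fresh label). Every snapshot along a run stays
orthomodular and non-distributive: the inference dynamics maintain quantum
logic indefinitely.

## Worked example

```r
library(orthoglue)

g <- glue(c(2, 3))                     # glue a 2^2 and a 2^3 Boolean algebra
length(g$elements)                     # 10   (= 2 + (4-2) + (8-2))
certify_orthomodular(g)$orthomodular   # TRUE
certify_distributive(g)$distributive   # FALSE
find_nondistributive_witness(g)        # "B1:{1}" "B1:{2}" "B2:{1}"

cfg <- run_config("abrupt", segment_length = 200, T = 1600,
                  seed = 1, window = 20, replicates = 100)
res <- paired_runs(cfg)                # same data, both inference systems
mean(res$summary$cumMSE_bayes)         # 0.2500
mean(res$summary$cumMSE_ibayes)        # 0.2109
sum(res$summary$cumMSE_ibayes < res$summary$cumMSE_bayes)  # 100 (of 100)
```

The witness triple violates distributivity exactly as expected: with x and y
the two atoms of the first block and z an atom of the second,
x ∧ (y ∨ z) = x but (x ∧ y) ∨ (x ∧ z) = 0. In the abruptly switching
environment, rewriting the most relevant hypothesis's likelihood from the
recent window beats prior-updating alone in every one of 100 paired
replicates, cutting mean final cumulative MSE from 0.250 to 0.211.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/orthoglue.R glue --sizes 2,3 --out out/
Rscript inst/cli/orthoglue.R simulate --config run.cfg
```

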