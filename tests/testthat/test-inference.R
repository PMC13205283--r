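# Bayesian updating, inverse Bayesian rewriting, prediction and error
# accounting.

test_that("KL divergence matches direct evaluation and its sign law", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "infinite divergence")

  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(2:6, 1)
      p <- random_simplex(n); q <- random_simplex(n)
      expect_gte(kl_divergence(p, q), 0)
      expect_equal(kl_divergence(p, p), 0)
      if (max(abs(p - q)) > 1e-9) expect_gt(kl_divergence(p, q), 0)
    }
  })
})

test_that("free energy reduces to surprise at the Bayesian fixed point", {
  expect_equal(free_energy(c(0.5, 0.5), c(0.5, 0.5), 1), 0)
  expect_equal(free_energy(c(0.5, 0.5), c(0.5, 0.5), 0.5), log(2))
  expect_equal(free_energy(c(1, 0), c(0.5, 0.5), 1), log(2))
  expect_error(free_energy(c(0.5, 0.5), c(0.5, 0.5), 0), "\\(0, 1\\]")

  # F >= -ln p(d), equality iff prior = posterior
  withr::with_seed(6, {
    for (i in 1:30) {
      n <- sample(2:5, 1)
      p <- random_simplex(n); q <- random_simplex(n)
      pd <- stats::runif(1, 0.05, 1)
      expect_gte(free_energy(p, q, pd), -log(pd) - 1e-12)
      expect_equal(free_energy(p, p, pd), -log(pd))
    }
  })
})

test_that("bayes_update matches the brute-force joint-table oracle", {
  m <- hypothesis_model(c(0.5, 0.5), rbind(c(0.2, 0.8), c(0.8, 0.2)))
  expect_equal(unname(bayes_update(m, 1)$prior), c(0.8, 0.2))

  # identical rows: constant factor cancels, prior unchanged
  m2 <- hypothesis_model(c(0.3, 0.7), rbind(c(0.4, 0.6), c(0.4, 0.6)))
  expect_equal(unname(bayes_update(m2, 0)$prior), c(0.3, 0.7))

  # degenerate prior is a fixed point
  m3 <- hypothesis_model(c(1, 0), rbind(c(0.4, 0.6), c(0.5, 0.5)))
  expect_equal(unname(bayes_update(m3, 1)$prior), c(1, 0))

  withr::with_seed(7, {
    for (i in 1:100) {
      mm <- sample(2:5, 1); nn <- sample(2:4, 1)
      mod <- random_model(mm, nn)
      d <- sample(0:(nn - 1), 1)
      expect_equal(unname(bayes_update(mod, d)$prior),
                   oracle_bayes(mod$prior, mod$likelihood, d),
                   tolerance = 1e-12)
    }
  })
})

test_that("priors and likelihood rows stay normalized through update and rewrite", {
  withr::with_seed(8, {
    mod <- random_model(4, 2)
    for (i in 1:200) {
      d <- sample(0:1, 1)
      mod <- bayes_update(mod, d)
      expect_equal(sum(mod$prior), 1, tolerance = 1e-12)
      if (i %% 5 == 0) {
        mod <- inverse_bayes_rewrite(mod, sample(1:4, 1), stats::runif(1))
        expect_equal(unname(rowSums(mod$likelihood)), rep(1, 4),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("empirical probability is the window mean", {
  expect_equal(empirical_probability(c(1, 1, 1, 1)), 1)
  expect_equal(empirical_probability(c(1, 0, 1, 0)), 0.5)
  expect_equal(empirical_probability(0), 0)
  expect_error(empirical_probability(numeric(0)), "non-empty")
})

test_that("rewrite target selection follows the rule with lowest-index ties", {
  m <- hypothesis_model(c(0.5, 0.3, 0.2),
                        rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(select_rewrite_target(m, "least_used"), 3)
  expect_equal(select_rewrite_target(m, "most_relevant"), 1)
  tie <- hypothesis_model(c(0.5, 0.5), rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(select_rewrite_target(tie, "least_used"), 1)
  expect_equal(select_rewrite_target(tie, "most_relevant"), 1)
})

test_that("inverse Bayesian rewrite replaces exactly one row, preserving sums", {
  m <- default_model(3)
  m2 <- inverse_bayes_rewrite(m, 2, 0.7)
  expect_equal(unname(m2$likelihood[2, ]), c(0.3, 0.7))
  expect_equal(m2$likelihood[-2, ], m$likelihood[-2, ])
  expect_equal(unname(m2$prior), unname(m$prior))
  # idempotent when p_hat equals the current row
  m3 <- inverse_bayes_rewrite(m2, 2, 0.7)
  expect_identical(m3$likelihood, m2$likelihood)
  for (ph in c(0, 0.123, 1))
    expect_equal(sum(inverse_bayes_rewrite(m, 1, ph)$likelihood[1, ]), 1)
  expect_error(inverse_bayes_rewrite(m, 1, 1.2), "\\[0, 1\\]")
  expect_error(inverse_bayes_rewrite(m, 9, 0.5), "target")
  # general form: empirical distribution over more than two outcomes
  mg <- hypothesis_model(c(0.5, 0.5), rbind(c(0.2, 0.3, 0.5), c(0.6, 0.2, 0.2)))
  mg2 <- inverse_bayes_rewrite(mg, 1, c(0.1, 0.1, 0.8))
  expect_equal(unname(mg2$likelihood[1, ]), c(0.1, 0.1, 0.8))
})

test_that("prediction is the prior mixture of success probabilities", {
  m <- hypothesis_model(c(0.8, 0.2), rbind(c(0.2, 0.8), c(0.8, 0.2)))
  expect_equal(predict(m), 0.68)
  single <- hypothesis_model(1, matrix(c(0.4, 0.6), 1))
  expect_equal(predict(single), 0.6)
  const <- hypothesis_model(c(0.25, 0.75), rbind(c(0.7, 0.3), c(0.7, 0.3)))
  expect_equal(predict(const), 0.3)
})

test_that("decision is the nested argmax with lowest-index ties", {
  m <- hypothesis_model(c(0.9, 0.1), rbind(c(0.2, 0.8), c(0.9, 0.1)))
  expect_equal(decide(m), 1)
  tie <- hypothesis_model(c(0.5, 0.5), rbind(c(0.3, 0.7), c(0.8, 0.2)))
  expect_equal(decide(tie), 1)  # hypothesis 1 wins the tie, its best outcome is 1
  flat <- hypothesis_model(1, matrix(c(0.5, 0.5), 1))
  expect_equal(decide(flat), 0)
})

test_that("squared error and cumulative MSE follow their definitions", {
  expect_equal(step_error(1, 1), 0)
  expect_equal(step_error(0.5, 0), 0.25)
  expect_equal(cumulative_mse(c(0, 0.25), 2), 0.125)
  expect_equal(cumulative_mse(c(0, 0.25, 1), 2), 0.125)
  expect_error(cumulative_mse(c(0.1), 0), "T must")
})

test_that("moving-average smoothing warms up and damps alternation", {
  expect_equal(smooth_predictions(rep(0.4, 10), 5), rep(0.4, 10))
  x <- stats::runif(20)
  expect_equal(smooth_predictions(x, 1), x)
  alt <- rep(c(0, 1), 10)
  s <- smooth_predictions(alt, 2)
  expect_equal(s[2:20], rep(0.5, 19))
  expect_error(smooth_predictions(x, 0), "positive integer")
  # larger L never increases sample variance on stationary Bernoulli input
  withr::with_seed(9, {
    for (i in 1:10) {
      d <- stats::rbinom(500, 1, 0.4)
      v20 <- stats::var(smooth_predictions(d, 20)[100:500])
      v60 <- stats::var(smooth_predictions(d, 60)[100:500])
      expect_lte(v60, v20)
    }
  })
})

test_that("Bayesian-only runs never touch the likelihood; rewrites are exact", {
  m <- default_model()
  env <- abrupt_environment(100, seed = 3)
  s <- sample_environment(env, 400)
  tb <- run_inference(s$d, m, rewrite = NULL)
  expect_identical(attr(tb, "final_model")$likelihood, m$likelihood)
  expect_equal(attr(tb, "n_rewrites"), 0)
  expect_equal(tb$cumMSE, cumsum(tb$E) / tb$t)

  ti <- run_inference(s$d, m, rewrite_config("most_relevant", window = 20))
  rw <- which(!is.na(ti$rewrite_target))
  expect_gt(length(rw), 0)
  # every recorded rewrite value is exactly the window mean of observations
  for (t in rw)
    expect_identical(ti$rewrite_value[t], mean(s$d[(t - 19):t]))
  # the final model's target row is bit-exact (1 - p_hat, p_hat)
  last <- max(rw)
  fm <- attr(ti, "final_model")
  expect_identical(unname(fm$likelihood[ti$rewrite_target[last], ]),
                   c(1 - ti$rewrite_value[last], ti$rewrite_value[last]))
})

test_that("posterior concentrates on the matching hypothesis in a stationary world", {
  m <- default_model()   # success probabilities 0.1, 0.3, 0.5, 0.7, 0.9
  for (seed in 1:3) {
    env <- bernoulli_environment(data.frame(duration = 3000, p_true = 0.7),
                                 seed = seed)
    s <- sample_environment(env, 3000)
    tr <- run_inference(s$d, m, rewrite = NULL)
    expect_gt(tr$prior.h4[3000], 0.95)
  }
})

test_that("rewritten likelihood recovers a stationary truth to binomial error", {
  W <- 20
  for (seed in 4:6) {
    env <- bernoulli_environment(data.frame(duration = 1000, p_true = 0.6),
                                 seed = seed)
    s <- sample_environment(env, 1000)
    tr <- run_inference(s$d, default_model(),
                        rewrite_config("most_relevant", window = W))
    fm <- attr(tr, "final_model")
    last <- max(which(!is.na(tr$rewrite_target)))
    row_p1 <- fm$likelihood[tr$rewrite_target[last], 2]
    expect_lte(abs(row_p1 - 0.6), 3 * sqrt(0.6 * 0.4 / W))
  }
})

test_that("trace CSV includes smoothed columns and round-trips", {
  m <- default_model()
  s <- sample_environment(slow_environment(50, seed = 2), 150)
  tr <- run_inference(s$d, m, rewrite_config())
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f, smoothing = c(20, 60))
  back <- utils::read.csv(f)
  expect_true(all(c("t", "d", "p_hat", "E", "cumMSE", "p_hat_s20", "p_hat_s60",
                    "prior.h1", "prior.h5") %in% names(back)))
  expect_equal(back$p_hat_s20, smooth_predictions(tr$p_hat, 20))
})
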