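# ---------------------------------------------------------------------------
# Online Bayesian inference with inverse Bayesian likelihood rewriting.
#
# The hypothesis model is a prior vector over m hypotheses and an
# m x n_outcomes likelihood matrix (rows on the simplex). Bayesian updating
# moves the prior; inverse Bayesian rewriting replaces one likelihood row with
# the empirical distribution of recent data, which is the "horizontal"
# transformation of the hypothesis space itself.
# ---------------------------------------------------------------------------

SIMPLEX_TOL <- 1e-8
LIK_FLOOR <- 1e-9

#' Construct a hypothesis model
#'
#' @param prior numeric vector on the probability simplex, one entry per
#'   hypothesis.
#' @param likelihood numeric matrix, rows = hypotheses, columns = data
#'   outcomes d = 0, 1, ..., n; every row sums to 1.
#' @return an object of class `hypothesis_model`.
#' @export
hypothesis_model <- function(prior, likelihood) {
  likelihood <- as.matrix(likelihood)
  m <- length(prior)
  if (nrow(likelihood) != m) stop("likelihood must have one row per hypothesis")
  if (any(prior < 0) || any(prior > 1) ||
      any(likelihood < 0) || any(likelihood > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(prior) - 1) > SIMPLEX_TOL) stop("prior must sum to 1")
  rs <- rowSums(likelihood)
  if (any(abs(rs - 1) > SIMPLEX_TOL)) stop("each likelihood row must sum to 1")
  dimnames(likelihood) <- list(paste0("h", seq_len(m)),
                               paste0("d", seq_len(ncol(likelihood)) - 1))
  structure(list(prior = stats::setNames(as.numeric(prior), rownames(likelihood)),
                 likelihood = likelihood,
                 m = m, n_outcomes = ncol(likelihood)),
            class = "hypothesis_model")
}

#' Default binary hypothesis model
#'
#' Uniform prior over `m` hypotheses with success probabilities P(d=1|h)
#' evenly spaced between 0.1 and 0.9 — a spread of fixed "contexts" the prior
#' can move between before any likelihood is rewritten.
#'
#' @param m number of hypotheses.
#' @return a `hypothesis_model` with binary outcomes.
#' @export
default_model <- function(m = 5) {
  p1 <- seq(0.1, 0.9, length.out = m)
  hypothesis_model(rep(1 / m, m), cbind(1 - p1, p1))
}

#' @export
print.hypothesis_model <- function(x, ...) {
  cat(sprintf("<hypothesis_model> %d hypotheses, %d outcomes\n", x$m, x$n_outcomes))
  cat("prior:", signif(x$prior, 4), "\n")
  invisible(x)
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' D(p || q) = sum_i p_i log(p_i / q_i), with the convention
#' 0 log(0/q) = 0. Nonnegative, and zero exactly when p = q.
#'
#' @param p,q numeric probability vectors of equal length.
#' @return nonnegative number (natural log units).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (abs(sum(p) - 1) > SIMPLEX_TOL || abs(sum(q) - 1) > SIMPLEX_TOL)
    stop("p and q must each sum to 1")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be nonnegative")
  pos <- p > 0
  if (any(pos & q == 0))
    stop("infinite divergence: p puts mass where q is zero",
         call. = FALSE)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Free energy of a prior/posterior pair
#'
#' F = D(prior || posterior) - ln P(d): the divergence between the current
#' prior over hypotheses and the posterior given the data, plus the surprise
#' of the data. Minimized (at -ln P(d)) exactly when the prior already equals
#' the posterior, the Bayesian fixed point.
#'
#' @param prior,posterior probability vectors over hypotheses.
#' @param p_data marginal probability of the observed data, in (0, 1].
#' @return numeric free energy (natural log units).
#' @export
free_energy <- function(prior, posterior, p_data) {
  if (length(p_data) != 1 || is.na(p_data) || p_data <= 0 || p_data > 1)
    stop("p_data must lie in (0, 1]")
  kl_divergence(prior, posterior) - log(p_data)
}

#' Bayesian prior update
#'
#' Replaces the prior with the posterior given one observed outcome:
#' P(h|d) proportional to P(d|h) P(h). Likelihood entries are clamped to
#' [1e-9, 1 - 1e-9] before use so that an extreme rewrite can never zero the
#' normalizing constant; a clamp is reported via the "clamped" attribute.
#'
#' @param model a `hypothesis_model`.
#' @param d observed outcome value in 0, ..., n_outcomes - 1.
#' @return the updated `hypothesis_model` (likelihood unchanged).
#' @export
bayes_update <- function(model, d) {
  if (length(d) != 1 || is.na(d) || d != round(d) || d < 0 || d >= model$n_outcomes)
    stop("d must be an outcome value in 0..", model$n_outcomes - 1)
  lik <- model$likelihood[, d + 1]
  clamped <- any(lik < LIK_FLOOR | lik > 1 - LIK_FLOOR)
  lik <- pmin(pmax(lik, LIK_FLOOR), 1 - LIK_FLOOR)
  num <- lik * model$prior
  den <- sum(num)
  if (den <= 0) stop("inconsistent model: observation impossible under all hypotheses")
  model$prior[] <- num / den
  attr(model, "clamped") <- clamped
  model
}

#' Empirical event probability over a recent window
#'
#' Mean of a window of binary outcomes; with a window of length W this is the
#' fraction of 1s among the last W observations.
#'
#' @param window non-empty numeric/integer vector of 0/1 outcomes.
#' @return number in [0, 1].
#' @export
empirical_probability <- function(window) {
  if (length(window) == 0) stop("window must be non-empty")
  if (!all(window %in% c(0, 1))) stop("window must contain binary outcomes")
  mean(window)
}

#' Select the hypothesis whose likelihood will be rewritten
#'
#' `"least_used"` picks the hypothesis with the smallest prior probability
#' (modifying a weakly supported hypothesis perturbs the recognition
#' structure least); `"most_relevant"` picks the largest. Ties break to the
#' lowest index.
#'
#' @param model a `hypothesis_model`.
#' @param rule `"most_relevant"` or `"least_used"`.
#' @return integer hypothesis index (1-based).
#' @export
select_rewrite_target <- function(model, rule = c("most_relevant", "least_used")) {
  rule <- match.arg(rule)
  unname(if (rule == "least_used") which.min(model$prior) else which.max(model$prior))
}

#' Inverse Bayesian likelihood rewrite
#'
#' Overwrites the likelihood row of one hypothesis with the empirical
#' distribution of recent data: for binary outcomes the row becomes
#' (1 - p_hat, p_hat). The prior and all other rows are untouched, so row
#' normalization is preserved exactly. This is the operation that transforms
#' the hypothesis space itself rather than the belief over it.
#'
#' @param model a `hypothesis_model`.
#' @param target hypothesis index to rewrite.
#' @param p_hat for binary models, the empirical probability of d = 1 in
#'   [0, 1]; alternatively a full empirical distribution vector of length
#'   `n_outcomes` summing to 1.
#' @return the modified `hypothesis_model`.
#' @export
inverse_bayes_rewrite <- function(model, target, p_hat) {
  if (length(target) != 1 || is.na(target) || target < 1 || target > model$m)
    stop("invalid target hypothesis index")
  if (length(p_hat) == 1) {
    if (model$n_outcomes != 2) stop("scalar p_hat requires a binary-outcome model")
    if (is.na(p_hat) || p_hat < 0 || p_hat > 1) stop("p_hat must lie in [0, 1]")
    row <- c(1 - p_hat, p_hat)
  } else {
    if (length(p_hat) != model$n_outcomes)
      stop("empirical distribution must have one entry per outcome")
    if (any(p_hat < 0) || abs(sum(p_hat) - 1) > SIMPLEX_TOL)
      stop("empirical distribution must be on the simplex")
    row <- as.numeric(p_hat)
  }
  model$likelihood[target, ] <- row
  model
}

#' Predicted event probability
#'
#' Mixture prediction for a binary model: p_hat = sum_k P(h_k) P(d=1|h_k).
#'
#' @param object a `hypothesis_model` with binary outcomes.
#' @param ... unused.
#' @return number in [0, 1].
#' @export
predict.hypothesis_model <- function(object, ...) {
  if (object$n_outcomes != 2) stop("prediction is defined for binary-outcome models")
  sum(object$prior * object$likelihood[, 2])
}

#' Decision by nested maximization
#'
#' Picks the outcome with the highest likelihood under the hypothesis with
#' the highest prior probability; ties break to the lowest index.
#'
#' @param model a `hypothesis_model`.
#' @return outcome value in 0, ..., n_outcomes - 1.
#' @export
decide <- function(model) {
  h_star <- which.max(model$prior)
  unname(which.max(model$likelihood[h_star, ])) - 1L
}

#' Squared prediction error and cumulative mean squared error
#'
#' E_t = (p_hat_t - d_t)^2; cumMSE(T) = mean of E_1..E_T.
#'
#' @param p_hat predicted probability in [0, 1].
#' @param d observed binary outcome.
#' @return squared error in [0, 1].
#' @export
step_error <- function(p_hat, d) {
  if (any(p_hat < 0) || any(p_hat > 1)) stop("p_hat must lie in [0, 1]")
  if (!all(d %in% c(0, 1))) stop("d must be binary")
  (p_hat - d)^2
}

#' @rdname step_error
#' @param errors numeric vector of per-step squared errors.
#' @param T number of steps to average over (defaults to all).
#' @export
cumulative_mse <- function(errors, T = length(errors)) {
  if (length(T) != 1 || is.na(T) || T < 1 || T > length(errors))
    stop("T must lie in 1..length(errors)")
  mean(errors[seq_len(T)])
}

#' Moving-average smoothing of a prediction series
#'
#' p_bar_t is the mean of the last min(L, t) values, so the output has the
#' same length as the input: early steps average over everything available.
#' Longer L suppresses short-term fluctuations at the cost of slower response
#' after an environmental switch.
#'
#' @param predictions numeric vector.
#' @param L smoothing length (window size), >= 1.
#' @return numeric vector, same length as `predictions`.
#' @export
smooth_predictions <- function(predictions, L) {
  if (length(L) != 1 || is.na(L) || L < 1 || L != round(L))
    stop("L must be a positive integer")
  n <- length(predictions)
  cs <- cumsum(predictions)
  t <- seq_len(n)
  lo <- pmax(t - L, 0L)
  (cs - c(0, cs)[lo + 1]) / (t - lo)
}

#' Rewrite configuration
#'
#' @param rule rewrite-target rule, `"most_relevant"` (default, used for the
#'   nonstationary prediction study) or `"least_used"` (the conservative
#'   variant that perturbs the dominant structure least).
#' @param window window length W for the empirical event probability.
#' @param stride steps between rewrite attempts once t >= W.
#' @return an object of class `rewrite_config`.
#' @export
rewrite_config <- function(rule = c("most_relevant", "least_used"),
                           window = 20, stride = 1) {
  rule <- match.arg(rule)
  if (window < 1 || window != round(window)) stop("window must be a positive integer")
  if (stride < 1 || stride != round(stride)) stop("stride must be a positive integer")
  structure(list(rule = rule, window = as.integer(window),
                 stride = as.integer(stride)),
            class = "rewrite_config")
}

#' Run online inference over an observation sequence
#'
#' At each step t the model first predicts p_hat_t from its current prior and
#' likelihood, then observes d_t and records the squared error, then performs
#' the Bayesian prior update. If a rewrite configuration is supplied and
#' t >= W (and t is a stride multiple), the likelihood row of the selected
#' hypothesis is rewritten to the empirical distribution of the last W
#' observations — inverse Bayesian inference. With `rewrite = NULL` the
#' likelihood matrix is never touched and the run is Bayesian inference
#' alone.
#'
#' Each rewrite retires the old hypothesis label and assigns a fresh one
#' (h2 becomes h6, say): the index position is reused but the hypothesis is a
#' new recognition unit.
#'
#' @param observations integer/numeric vector of binary outcomes d_t.
#' @param model starting `hypothesis_model` (binary outcomes).
#' @param rewrite a [rewrite_config()], or NULL for Bayesian-only inference.
#' @return an `inference_trace`: a data.frame with columns `t`, `d`, `p_hat`,
#'   `E`, `cumMSE`, `rewrite_target`, `rewrite_value` and one `prior.h<k>`
#'   column per hypothesis; attributes `final_model`, `labels` (current label
#'   per index position), `n_rewrites`, `n_clamped`.
#' @export
run_inference <- function(observations, model, rewrite = NULL) {
  stopifnot(inherits(model, "hypothesis_model"))
  if (model$n_outcomes != 2) stop("the prediction task is binary")
  if (!all(observations %in% c(0, 1))) stop("observations must be binary")
  if (!is.null(rewrite) && !inherits(rewrite, "rewrite_config"))
    stop("rewrite must be a rewrite_config or NULL")
  d <- as.integer(observations)
  T_total <- length(d)
  m <- model$m
  prior <- as.numeric(model$prior)
  lik <- unname(model$likelihood)
  labels <- seq_len(m)          # label numbers; rewrites advance a counter
  label_max <- m
  p_hat <- E <- numeric(T_total)
  rw_target <- rep(NA_integer_, T_total)
  rw_value <- rep(NA_real_, T_total)
  priors <- matrix(NA_real_, T_total, m)
  n_clamped <- 0L

  for (t in seq_len(T_total)) {
    priors[t, ] <- prior
    p_hat[t] <- sum(prior * lik[, 2])
    dt <- d[t]
    E[t] <- (p_hat[t] - dt)^2
    lc <- pmin(pmax(lik[, dt + 1], LIK_FLOOR), 1 - LIK_FLOOR)
    if (any(lc != lik[, dt + 1])) n_clamped <- n_clamped + 1L
    num <- lc * prior
    den <- sum(num)
    if (den <= 0) stop("inconsistent model at step ", t)
    prior <- num / den
    if (!is.null(rewrite) && t >= rewrite$window && t %% rewrite$stride == 0L) {
      ph <- mean(d[(t - rewrite$window + 1):t])
      tgt <- if (rewrite$rule == "least_used") which.min(prior) else which.max(prior)
      lik[tgt, ] <- c(1 - ph, ph)
      label_max <- label_max + 1L
      labels[tgt] <- label_max
      rw_target[t] <- tgt
      rw_value[t] <- ph
    }
  }

  trace <- data.frame(t = seq_len(T_total), d = d, p_hat = p_hat, E = E,
                      cumMSE = cumsum(E) / seq_len(T_total),
                      rewrite_target = rw_target, rewrite_value = rw_value)
  colnames(priors) <- paste0("prior.h", seq_len(m))
  trace <- cbind(trace, priors)
  final <- hypothesis_model(prior, lik)
  structure(trace,
            class = c("inference_trace", "data.frame"),
            final_model = final,
            labels = paste0("h", labels),
            n_rewrites = sum(!is.na(rw_target)),
            n_clamped = n_clamped,
            rewrite = rewrite)
}

#' Write an inference trace to CSV
#'
#' Optionally appends one smoothed-prediction column per smoothing length
#' (`p_hat_s<L>`).
#'
#' @param trace an `inference_trace`.
#' @param path output CSV path.
#' @param smoothing integer vector of smoothing lengths, or NULL.
#' @export
write_trace <- function(trace, path, smoothing = NULL) {
  out <- as.data.frame(trace)
  for (L in smoothing)
    out[[paste0("p_hat_s", L)]] <- smooth_predictions(trace$p_hat, L)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot an inference trace
#'
#' Base-graphics view of the predicted event probability (optionally
#' smoothed) against the true probability schedule, if one is supplied.
#'
#' @param x an `inference_trace`.
#' @param p_true optional numeric vector of true event probabilities.
#' @param L optional smoothing length applied before plotting.
#' @param ... passed to [plot()].
#' @export
plot.inference_trace <- function(x, p_true = NULL, L = NULL, ...) {
  y <- if (is.null(L)) x$p_hat else smooth_predictions(x$p_hat, L)
  plot(x$t, y, type = "l", xlab = "t", ylab = "predicted P(d = 1)",
       ylim = c(0, 1), ...)
  if (!is.null(p_true)) lines(seq_along(p_true), p_true, lty = 2)
  invisible(x)
}
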