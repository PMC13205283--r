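# ---------------------------------------------------------------------------
# Bridge between the inference model and the glued-lattice picture.
#
# Each hypothesis is rendered as one Boolean block whose atoms are the data
# outcomes it supports; the blocks share only the global bottom and top. An
# inverse Bayesian rewrite replaces one sub-Boolean algebra with another and
# retires the old hypothesis label, so the run leaves a log of lattice events
# while the whole stays orthomodular (and non-distributive with >= 2 blocks).
# ---------------------------------------------------------------------------

#' Render a hypothesis model as a glued lattice
#'
#' One Boolean block per hypothesis; the block's ground set is the set of
#' outcomes whose likelihood exceeds `support_eps` (a block needs at least
#' two atoms to have any interior). The prior P(h) is attached as a weight
#' annotation per block, not as lattice structure.
#'
#' @param model a `hypothesis_model`.
#' @param support_eps atoms are outcomes with likelihood above this
#'   threshold.
#' @return a `glued_lattice` with attributes `block_labels` (hypothesis
#'   labels) and `block_weights` (prior probabilities).
#' @export
model_to_lattice <- function(model, support_eps = 1e-6) {
  stopifnot(inherits(model, "hypothesis_model"))
  support <- rowSums(model$likelihood > support_eps)
  if (any(support < 2))
    stop("degenerate hypothesis: index ",
         paste(which(support < 2), collapse = ", "),
         " has fewer than 2 supported outcomes")
  g <- glue(as.integer(support))
  attr(g, "block_labels") <- rownames(model$likelihood)
  attr(g, "block_weights") <- as.numeric(model$prior)
  g
}

new_lattice_event <- function(step, kind, old_label, new_label, block_sizes) {
  data.frame(step = step, kind = kind,
             old_label = old_label, new_label = new_label,
             block_sizes = paste(block_sizes, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Apply an inverse Bayesian rewrite to a glued lattice
#'
#' Rebuilds the target hypothesis's Boolean block from the support of its new
#' likelihood row and retires the old label in favor of a fresh one (the
#' index position is reused; the hypothesis is a new recognition unit). The
#' resulting lattice is re-certified orthomodular before it is returned.
#'
#' @param g a `glued_lattice` produced by [model_to_lattice()].
#' @param target hypothesis index whose block is replaced.
#' @param new_row likelihood row after the rewrite (must support >= 2
#'   outcomes).
#' @param step time step recorded on the event.
#' @param support_eps support threshold, as in [model_to_lattice()].
#' @return list with the updated `lattice` and a one-row `event` data.frame.
#' @export
apply_rewrite_event <- function(g, target, new_row, step = NA_integer_,
                                support_eps = 1e-6) {
  stopifnot(inherits(g, "glued_lattice"))
  labels <- attr(g, "block_labels")
  if (is.null(labels)) labels <- paste0("h", seq_along(g$block_sizes))
  if (target < 1 || target > length(g$block_sizes)) stop("invalid block index")
  supp <- sum(new_row > support_eps)
  if (supp < 2) stop("degenerate rewrite: new row supports fewer than 2 outcomes")
  sizes <- g$block_sizes
  sizes[target] <- as.integer(supp)
  g2 <- suppressWarnings(glue(sizes))
  counter <- attr(g, "label_counter")
  if (is.null(counter))
    counter <- max(as.integer(sub("^h", "", labels)))
  counter <- counter + 1L
  old_label <- labels[target]
  labels[target] <- paste0("h", counter)
  om <- certify_orthomodular(g2)
  if (!om$orthomodular)
    stop("internal error: rewritten lattice lost orthomodularity")
  attr(g2, "block_labels") <- labels
  attr(g2, "block_weights") <- attr(g, "block_weights")
  attr(g2, "label_counter") <- counter
  ev <- new_lattice_event(step, "block_replaced", old_label, labels[target], sizes)
  list(lattice = g2, event = ev)
}

#' Lattice-event log of an inference run
#'
#' Replays the rewrite records of an inference trace as sub-Boolean-algebra
#' replacements on the lattice rendering of the starting model: one initial
#' event plus one `block_replaced` event per rewrite, in step order, with
#' strictly increasing hypothesis labels.
#'
#' Replayed rows are floored at `2 * support_eps` (then renormalized) before
#' block construction, mirroring the likelihood floor used by the inference
#' loop: an outcome of the alphabet never leaves a hypothesis's support just
#' because a finite window happened to miss it.
#'
#' @param trace an `inference_trace` produced by [run_inference()] on
#'   `model0`.
#' @param model0 the starting `hypothesis_model` of that run.
#' @param support_eps support threshold for block construction.
#' @return data.frame of events (columns step, kind, old_label, new_label,
#'   block_sizes) with the final lattice attached as attribute
#'   `final_lattice`.
#' @export
lattice_log <- function(trace, model0, support_eps = 1e-6) {
  stopifnot(inherits(trace, "inference_trace"),
            inherits(model0, "hypothesis_model"))
  npr <- sum(grepl("^prior\\.h", colnames(trace)))
  if (npr != model0$m)
    stop("trace and model disagree on the number of hypotheses")
  g <- model_to_lattice(model0, support_eps)
  events <- new_lattice_event(0L, "initial", NA_character_, NA_character_,
                              g$block_sizes)
  rw <- which(!is.na(trace$rewrite_target))
  for (t in rw) {
    tgt <- trace$rewrite_target[t]
    ph <- trace$rewrite_value[t]
    row <- pmax(c(1 - ph, ph), 2 * support_eps)
    row <- row / sum(row)
    res <- apply_rewrite_event(g, tgt, row, step = trace$t[t],
                               support_eps = support_eps)
    g <- res$lattice
    events <- rbind(events, res$event)
  }
  attr(events, "final_lattice") <- g
  events
}
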