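# ---------------------------------------------------------------------------
# Experiment runner: flat key=value config files, paired simulation of the
# two inference systems, and file-emitting commands mirrored by the
# command-line front end in inst/cli/orthoglue.R.
# ---------------------------------------------------------------------------

#' Run configuration
#'
#' All knobs of a simulation run in one validated object. Serializes
#' losslessly to a flat `key = value` text file.
#'
#' @param environment `"abrupt"` or `"slow"`.
#' @param segment_length steps per environment segment.
#' @param T total number of steps.
#' @param seed base seed; replicate r uses seed + r - 1.
#' @param m number of hypotheses.
#' @param likelihood_p1 numeric vector of initial P(d=1|h) per hypothesis.
#' @param rule rewrite rule (`"most_relevant"` or `"least_used"`).
#' @param window rewrite window length W.
#' @param stride steps between rewrites.
#' @param rewrite enable inverse Bayesian rewriting in the second arm?
#' @param smoothing integer vector of moving-average lengths for extra trace
#'   columns.
#' @param replicates number of paired replicates.
#' @param out_dir output directory for emitted files.
#' @return an object of class `run_config`.
#' @export
run_config <- function(environment = "abrupt", segment_length = 200, T = 1600,
                       seed = 1, m = 5,
                       likelihood_p1 = seq(0.1, 0.9, length.out = m),
                       rule = "most_relevant", window = 20, stride = 1,
                       rewrite = TRUE, smoothing = c(20, 60),
                       replicates = 100, out_dir = ".") {
  if (!environment %in% c("abrupt", "slow"))
    stop("environment must be 'abrupt' or 'slow'")
  if (!rule %in% c("most_relevant", "least_used"))
    stop("rule must be 'most_relevant' or 'least_used'")
  if (segment_length < 1 || T < 1 || m < 1 || window < 1 || stride < 1 ||
      replicates < 1)
    stop("segment_length, T, m, window, stride, replicates must be >= 1")
  if (length(likelihood_p1) != m || any(likelihood_p1 < 0) || any(likelihood_p1 > 1))
    stop("likelihood_p1 must be m probabilities")
  if (length(smoothing) && (any(smoothing < 1) || any(smoothing != round(smoothing))))
    stop("smoothing lengths must be positive integers")
  structure(list(environment = environment,
                 segment_length = as.integer(segment_length),
                 T = as.integer(T), seed = as.integer(seed), m = as.integer(m),
                 likelihood_p1 = as.numeric(likelihood_p1), rule = rule,
                 window = as.integer(window), stride = as.integer(stride),
                 rewrite = isTRUE(rewrite), smoothing = as.integer(smoothing),
                 replicates = as.integer(replicates), out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as flat key = value text
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(tolower(as.character(v)))
    if (is.numeric(v)) return(paste(format(v, digits = 17), collapse = ","))
    as.character(v)
  }
  writeLines(paste0(names(config), " = ",
                    vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @return for `read_run_config`, the reconstructed `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3)) stop("malformed config line: ",
                                  lines[which(lengths(kv) != 3)[1]])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  get1 <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ",")[[1]])
  d <- run_config()
  run_config(
    environment   = get1("environment", d$environment),
    segment_length = as.integer(get1("segment_length", d$segment_length)),
    T             = as.integer(get1("T", d$T)),
    seed          = as.integer(get1("seed", d$seed)),
    m             = as.integer(get1("m", d$m)),
    likelihood_p1 = num(get1("likelihood_p1",
                             paste(d$likelihood_p1, collapse = ","))),
    rule          = get1("rule", d$rule),
    window        = as.integer(get1("window", d$window)),
    stride        = as.integer(get1("stride", d$stride)),
    rewrite       = tolower(get1("rewrite", tolower(d$rewrite))) == "true",
    smoothing     = as.integer(num(get1("smoothing",
                                        paste(d$smoothing, collapse = ",")))),
    replicates    = as.integer(get1("replicates", d$replicates)),
    out_dir       = get1("out_dir", d$out_dir))
}

config_environment <- function(config, seed) {
  switch(config$environment,
         abrupt = abrupt_environment(config$segment_length, seed),
         slow = slow_environment(config$segment_length, seed))
}

config_model <- function(config) {
  hypothesis_model(rep(1 / config$m, config$m),
                   cbind(1 - config$likelihood_p1, config$likelihood_p1))
}

#' Paired comparison of Bayesian-only and Bayesian + inverse Bayesian runs
#'
#' For each replicate, one observation sequence is sampled (seed + r - 1) and
#' both inference systems are run on the identical sequence: a paired design
#' that removes sampling noise from the comparison of final cumulative MSE.
#'
#' @param config a `run_config`.
#' @return list with `summary` (data.frame: replicate, seed,
#'   cumMSE_bayes, cumMSE_ibayes, n_rewrites) and `traces` (list of
#'   per-replicate lists with `bayes`, `ibayes`, `p_true`).
#' @export
paired_runs <- function(config) {
  model0 <- config_model(config)
  rw <- if (config$rewrite)
    rewrite_config(config$rule, config$window, config$stride)
  reps <- config$replicates
  summary <- data.frame(replicate = seq_len(reps),
                        seed = config$seed + seq_len(reps) - 1L,
                        cumMSE_bayes = NA_real_, cumMSE_ibayes = NA_real_,
                        n_rewrites = NA_integer_)
  traces <- vector("list", reps)
  for (r in seq_len(reps)) {
    env <- config_environment(config, config$seed + r - 1L)
    s <- sample_environment(env, config$T)
    tb <- run_inference(s$d, model0, rewrite = NULL)
    ti <- run_inference(s$d, model0, rewrite = rw)
    summary$cumMSE_bayes[r] <- tb$cumMSE[config$T]
    summary$cumMSE_ibayes[r] <- ti$cumMSE[config$T]
    summary$n_rewrites[r] <- attr(ti, "n_rewrites")
    traces[[r]] <- list(bayes = tb, ibayes = ti, p_true = s$p_true)
  }
  list(summary = summary, traces = traces)
}

#' Glue command: build, certify and export a glued lattice
#'
#' Writes `lattice.dot`, `lattice_edges.tsv`, `lattice.json` and
#' `verdict.json` (element count, distributivity, orthomodularity, witness)
#' to `out_dir`.
#'
#' @param sizes integer vector of Boolean-algebra ground sizes; a single size
#'   builds that Boolean algebra, several are glued at shared bounds.
#' @param out_dir output directory (created if missing).
#' @return the verdict list, invisibly.
#' @export
cmd_glue <- function(sizes, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  l <- if (length(sizes) == 1) make_boolean_algebra(sizes)
       else suppressWarnings(glue(sizes))
  dv <- certify_distributive(l)
  ov <- certify_orthomodular(l)
  verdict <- list(sizes = as.integer(sizes),
                  elements = length(l$elements),
                  distributive = dv$distributive,
                  orthomodular = ov$orthomodular)
  if (!dv$distributive) verdict$witness <- dv$witness
  write_dot(l, file.path(out_dir, "lattice.dot"))
  write_hasse_edges(l, file.path(out_dir, "lattice_edges.tsv"))
  write_lattice_json(l, file.path(out_dir, "lattice.json"))
  jsonlite::write_json(verdict, file.path(out_dir, "verdict.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(verdict)
}

#' Simulate command: run the paired comparison and write CSVs
#'
#' Per replicate, writes `trace_bayes_r<k>.csv` and `trace_ibayes_r<k>.csv`
#' (with one smoothed column per smoothing length), plus `summary.csv` with
#' the final cumulative MSE of each arm, and echoes the configuration to
#' `config.txt`.
#'
#' @param config a `run_config`.
#' @return the summary data.frame, invisibly.
#' @export
cmd_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- paired_runs(config)
  for (r in seq_len(config$replicates)) {
    write_trace(res$traces[[r]]$bayes,
                file.path(config$out_dir, sprintf("trace_bayes_r%d.csv", r)),
                smoothing = config$smoothing)
    write_trace(res$traces[[r]]$ibayes,
                file.path(config$out_dir, sprintf("trace_ibayes_r%d.csv", r)),
                smoothing = config$smoothing)
  }
  utils::write.csv(res$summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(config$out_dir, "config.txt"))
  invisible(res$summary)
}

#' Bridge command: lattice-event log of one replicate
#'
#' Runs one replicate with rewriting enabled, writes `lattice_events.csv` and
#' DOT snapshots of the initial and final lattices.
#'
#' @param config a `run_config` (rewrite must be on).
#' @return the event data.frame, invisibly.
#' @export
cmd_bridge <- function(config) {
  if (!config$rewrite) stop("cmd_bridge requires rewrite = TRUE")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model0 <- config_model(config)
  env <- config_environment(config, config$seed)
  s <- sample_environment(env, config$T)
  tr <- run_inference(s$d, model0,
                      rewrite_config(config$rule, config$window, config$stride))
  events <- lattice_log(tr, model0)
  utils::write.csv(as.data.frame(events),
                   file.path(config$out_dir, "lattice_events.csv"),
                   row.names = FALSE)
  write_dot(model_to_lattice(model0), file.path(config$out_dir, "initial.dot"))
  write_dot(attr(events, "final_lattice"), file.path(config$out_dir, "final.dot"))
  invisible(events)
}

#' Check command: re-certify a saved lattice
#'
#' Reads a lattice written by [write_lattice_json()] and re-runs all
#' certifiers, writing `check.json` next to nothing (returned instead).
#'
#' @param path path to a `lattice.json`.
#' @return list of verdicts (lattice, distributive, orthocomplement,
#'   orthomodular where applicable).
#' @export
cmd_check <- function(path) {
  l <- read_lattice_json(path)
  out <- list(elements = length(l$elements),
              is_lattice = certify_lattice(l)$is_lattice,
              distributive = certify_distributive(l)$distributive)
  if (!is.null(l$complement)) {
    oc <- certify_orthocomplement(l)
    out$orthocomplemented <- oc$ok
    if (oc$ok) out$orthomodular <- certify_orthomodular(l)$orthomodular
  }
  out
}
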