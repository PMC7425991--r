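# Worked-example fixtures (decision table), the pcLNA-vs-SSA validation
# harness, and the toy-model fixture generator.

#' Load the packaged gene-expression decision table
#'
#' Conditions are TNFa stimulation patterns crossed with temperature; each
#' carries a symbolic gene-expression code over EGR1 (E), COX-2 (C) and
#' IL-8 (I) at 30 and 130 minutes, with `+`/`-` marking high/low
#' expression. Cells not fixed by the published caption are reconstructed
#' stand-ins (see the fixture's `meta$provenance`).
#'
#' @param path optional path to an alternative decision-table JSON file.
#' @return object of class `DecisionTable`.
#' @export
decision_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fig2b_decision_table.json",
                        package = "sigmux", mustWork = TRUE)
  tab <- jsonlite::read_json(path)
  keys <- unique(unlist(lapply(tab$conditions, function(cn) names(cn$code))))
  for (cn in tab$conditions) {
    if (is.null(cn$code) || !all(keys %in% names(cn$code)))
      stop("every condition must carry a complete code")
    if (!all(unlist(cn$code) %in% c("+", "-")))
      stop("code symbols must be '+' or '-'")
  }
  structure(list(conditions = tab$conditions, keys = keys, meta = tab$meta),
            class = "DecisionTable")
}

#' @export
print.DecisionTable <- function(x, ...) {
  cat(sprintf("DecisionTable: %d conditions, keys %s\n",
              length(x$conditions), paste(x$keys, collapse = " ")))
  for (cn in x$conditions)
    cat(sprintf("  %-40s %s\n", cn$label,
                paste(names(cn$code), unlist(cn$code), sep = "", collapse = " ")))
  invisible(x)
}

#' Conditions compatible with an observed code
#'
#' Matches a (possibly partial) symbol set against the table; a singleton
#' result means the input-signal combination is uniquely identified.
#'
#' @param table a `DecisionTable`.
#' @param code named character vector over the table's keys (e.g.
#'   `c(E30 = "+", I30 = "-")`), values `+` or `-`.
#' @return character vector of compatible condition labels.
#' @export
classify_condition <- function(table, code) {
  if (!length(code) || is.null(names(code))) stop("code must be named")
  bad <- setdiff(names(code), table$keys)
  if (length(bad)) stop("unknown code keys: ", paste(bad, collapse = ", "))
  if (!all(code %in% c("+", "-")))
    stop("unknown symbols: ", paste(setdiff(code, c("+", "-")), collapse = ", "))
  hits <- vapply(table$conditions, function(cn)
    all(unlist(cn$code[names(code)]) == code), logical(1))
  vapply(table$conditions[hits], `[[`, character(1), "label")
}

#' Distinguishable input-signal combinations
#'
#' Partitions the conditions into equivalence classes by their codes
#' restricted to the requested observation times and returns the class count
#' and the corresponding information in bits.
#'
#' @param table a `DecisionTable`.
#' @param times observation times (min) whose codes are used, e.g. `30` or
#'   `c(30, 130)`.
#' @return list with `count` (distinguishable classes), `bits`
#'   (`log2(count)`), and `classes` (condition labels per class).
#' @export
distinguishable_info <- function(table, times = 30) {
  keys <- table$keys[sub("^[A-Z]+", "", table$keys) %in% as.character(times)]
  if (!length(keys)) stop("no code keys at the requested times")
  sig <- vapply(table$conditions, function(cn)
    paste(unlist(cn$code[keys]), collapse = ""), character(1))
  labs <- vapply(table$conditions, `[[`, character(1), "label")
  classes <- split(labs, sig)
  list(count = length(classes), bits = log2(length(classes)),
       classes = unname(classes))
}

#' Kolmogorov-Smirnov comparison of two sample ensembles
#'
#' Two-sample KS tests per coordinate per phase, with a Bonferroni-corrected
#' decision at the stated level (the default multiple-comparison handling).
#'
#' @param samples_a,samples_b arrays `n x coords x phases` (matrices are
#'   treated as one phase).
#' @param level familywise significance level.
#' @param bonferroni apply the Bonferroni correction across coordinates x
#'   phases.
#' @return object of class `ValidationReport`: data frame of KS statistics
#'   and p-values per (coordinate, phase), with pass/fail at the stated
#'   level.
#' @export
ks_compare <- function(samples_a, samples_b, level = 0.01,
                       bonferroni = TRUE) {
  as_arr <- function(x) if (length(dim(x)) == 2) array(x, c(dim(x), 1),
                          dimnames = c(dimnames(x), list(NULL))) else x
  a <- as_arr(samples_a); b <- as_arr(samples_b)
  if (nrow(a) < 50 || nrow(b) < 50) stop("need at least 50 samples each")
  if (!all(dim(a)[-1] == dim(b)[-1])) stop("coordinate/phase mismatch")
  nc <- dim(a)[2]; np <- dim(a)[3]
  cn <- dimnames(a)[[2]] %||% as.character(seq_len(nc))
  res <- expand.grid(coord = cn, phase = seq_len(np),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$statistic <- NA_real_; res$p.value <- NA_real_
  for (r in seq_len(nrow(res))) {
    i <- match(res$coord[r], cn); k <- res$phase[r]
    kt <- suppressWarnings(ks.test(a[, i, k], b[, i, k]))
    res$statistic[r] <- unname(kt$statistic)
    res$p.value[r] <- kt$p.value
  }
  m <- nrow(res)
  cut <- if (bonferroni) level / m else level
  res$reject <- res$p.value < cut
  attr(res, "level") <- level
  attr(res, "bonferroni") <- bonferroni
  attr(res, "pass") <- !any(res$reject)
  attr(res, "n") <- c(nrow(a), nrow(b))
  class(res) <- c("ValidationReport", "data.frame")
  res
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat(sprintf("ValidationReport: %d KS tests, max statistic %.4f, %s at level %g%s\n",
              nrow(x), max(x$statistic), if (attr(x, "pass")) "PASS" else "FAIL",
              attr(x, "level"),
              if (attr(x, "bonferroni")) " (Bonferroni)" else ""))
  invisible(as.data.frame(x))
}

#' Toy oscillator fixture
#'
#' Builds the two-species limit-cycle network together with reference
#' statistics computed at build time: the deterministic peak schedule and an
#' SSA summary (mean copy numbers at the first peak) under a recorded seed.
#'
#' @param seed RNG seed recorded in the fixture.
#' @param n_ssa SSA trajectories for the summary statistics.
#' @return list with `net`, `schedule` (first peaks/troughs), `ssa_mean`
#'   (mean copy numbers at the first peak), `seed`, `n_ssa`, `horizon`.
#' @export
make_toy_fixture <- function(seed = 1, n_ssa = 100) {
  net <- build_model("toy")
  horizon <- 40
  traj <- solve_macroscopic(net, grid = seq(0, horizon, by = 0.05),
                            x0 = initial_state(net))
  schedule <- observation_schedule(traj, "X", q = 8)
  sched1 <- fixed_schedule(schedule$times[1])
  sam <- ssa_ensemble(net, NULL, sched1, n = n_ssa, seed = seed,
                      x0 = round(net$omega * initial_state(net)))
  list(net = net, schedule = schedule, traj = traj,
       ssa_mean = colMeans(sam[, , 1]), seed = seed, n_ssa = n_ssa,
       horizon = horizon)
}
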