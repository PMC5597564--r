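## Benchmark harness: repeated seeded runs, lowest-energy / smallest-RMSD
## tables, convergence traces, box statistics, and one-sided rank-sum
## comparisons between algorithms.

algorithmRunner <- function(name) {
  switch(name,
    cepga = function(ctx, cfg) runCEPGA(ctx, cfg),
    ga = function(ctx, cfg) runGA(ctx, cfg, withLocalSearch = FALSE),
    "ga+ls" = function(ctx, cfg) runGA(ctx, cfg, withLocalSearch = TRUE),
    stop("unknown algorithm: ", name))
}

#' Run a repeated-docking experiment
#'
#' Executes `runs` independently seeded runs (seed = `baseSeed + run index`)
#' of each algorithm on each instance, mirroring the ten-independent-runs
#' protocol of docking benchmarks.  Per (instance, algorithm) cell the summary
#' aggregates the lowest final energy, the smallest RMSD, and the success
#' count (RMSD strictly below 2.0 A).  A crashed run is recorded as failed
#' and the experiment continues.
#'
#' @param instances named list of context factories: each element is a
#'   zero-argument function returning a fresh evaluation context (e.g.
#'   `function() fixtureContext(fix, maxEvaluations = 25000)`).
#' @param algorithms subset of `c("cepga", "ga", "ga+ls")`.
#' @param runs runs per cell (default 10).
#' @param config a [searchConfig()]; its seed is overridden per run.
#' @param baseSeed base of the per-run seeds.
#' @return list with `runs` (per-run data.frame), `summary` (per-cell
#'   data.frame), `traces` (named list of trace data.frames)
#' @export
runExperiment <- function(instances, algorithms = c("cepga", "ga"),
                          runs = 10L, config = reducedSearchConfig(),
                          baseSeed = 1L) {
  stopifnot(runs >= 1L, length(instances) >= 1L)
  if (is.null(names(instances)))
    names(instances) <- paste0("instance", seq_along(instances))
  rows <- list()
  traces <- list()
  for (inst in names(instances)) {
    for (alg in algorithms) {
      runner <- algorithmRunner(alg)
      for (r in seq_len(runs)) {
        cfg <- config
        cfg$seed <- as.integer(baseSeed + r)
        res <- tryCatch(runner(instances[[inst]](), cfg),
                        error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            instance = inst, algorithm = alg, run = r, seed = cfg$seed,
            energy = NA_real_, rmsd = NA_real_, evaluations = NA_integer_,
            success = NA, failed = TRUE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          instance = inst, algorithm = alg, run = r, seed = cfg$seed,
          energy = bestEnergy(res), rmsd = finalRmsd(res),
          evaluations = res@evaluations,
          success = !is.na(finalRmsd(res)) && isValidPose(finalRmsd(res)),
          failed = FALSE)
        traces[[sprintf("%s.%s.%d", inst, alg, r)]] <-
          cbind(runTrace(res), instance = inst, algorithm = alg, run = r)
      }
    }
  }
  runsDf <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(
    runsDf, list(runsDf$instance, runsDf$algorithm), drop = TRUE),
    function(d) data.frame(
      instance = d$instance[1], algorithm = d$algorithm[1],
      n_runs = nrow(d), n_failed = sum(d$failed),
      lowest_energy = suppressWarnings(min(d$energy, na.rm = TRUE)),
      smallest_rmsd = if (all(is.na(d$rmsd))) NA_real_
                      else min(d$rmsd, na.rm = TRUE),
      success_count = sum(d$success, na.rm = TRUE))))
  rownames(summ) <- NULL
  list(runs = runsDf, summary = summ, traces = traces)
}

#' Tukey box-plot statistics
#'
#' Quartiles by linear interpolation (`quantile()` type 7); the edges
#' (whiskers) are the most extreme observed values within 1.5 IQR of the
#' quartiles.
#'
#' @param values numeric vector (at least one value).
#' @return named numeric: `lower_edge`, `lower_quartile`, `median`,
#'   `upper_quartile`, `upper_edge`
#' @export
boxStats <- function(values) {
  if (!length(values)) stop("boxStats needs at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  c(lower_edge = min(values[values >= q[1] - 1.5 * iqr]),
    lower_quartile = q[1],
    median = q[2],
    upper_quartile = q[3],
    upper_edge = max(values[values <= q[3] + 1.5 * iqr]))
}

#' One-sided rank-sum comparison of two algorithms
#'
#' Wilcoxon-Mann-Whitney test of the hypothesis that `a` yields lower final
#' energies than `b` (alternative: stochastic dominance of `a` toward low
#' values).  With at most 10 observations per arm and no cross-sample ties
#' the p-value is computed by exact enumeration of the rank-sum distribution,
#' so a maximally separated 3-vs-3 split gives exactly `1/choose(6,3)`;
#' larger samples use the normal approximation (with tie correction, no
#' continuity correction), for which the two opposite one-sided p-values of
#' tie-free data sum to exactly 1.  For the exact path they sum to
#' `1 + P(W = w_obs)`, the discrete mass at the observed statistic.
#' All-tied samples report p = 0.5 with `tied = TRUE`.
#'
#' @param a,b numeric samples (sizes >= 2), e.g. final energies per run.
#' @return list with `p.value`, `statistic` (Mann-Whitney W of `a`),
#'   `method` ("exact" or "normal"), `tied`
#' @export
pairwiseTest <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(m)]) - m * (m + 1) / 2   # Mann-Whitney statistic of a
  anyTies <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1L)
    return(list(p.value = 0.5, statistic = W, method = "degenerate", tied = TRUE))
  if (m <= 10L && n <= 10L && !anyTies) {
    p <- pwilcox(W, m, n)                      # exact: P(W <= w_obs)
    return(list(p.value = p, statistic = W, method = "exact", tied = FALSE))
  }
  ## normal approximation with tie correction
  mu <- m * n / 2
  tieTab <- table(pooled)
  N <- m + n
  sig2 <- m * n / 12 * ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
  z <- (W - mu) / sqrt(sig2)
  list(p.value = pnorm(z), statistic = W, method = "normal", tied = anyTies)
}

#' Plot convergence traces
#'
#' Best-so-far energy against the number of energy evaluations, one step
#' curve per run, colored by algorithm.
#'
#' @param traces list of trace data.frames as returned in
#'   `runExperiment()$traces`.
#' @param main plot title.
#' @return invisibly NULL
#' @export
plotConvergence <- function(traces, main = "Convergence") {
  if (!length(traces)) stop("no traces to plot")
  algs <- unique(vapply(traces, function(t) as.character(t$algorithm[1]),
                        character(1)))
  cols <- setNames(rainbow(length(algs)), algs)
  xr <- range(unlist(lapply(traces, `[[`, "neval")))
  yr <- range(unlist(lapply(traces, `[[`, "energy")))
  plot(NA, xlim = xr, ylim = yr, xlab = "energy evaluations (Neval)",
       ylab = "best energy", main = main)
  for (t in traces)
    lines(t$neval, t$energy, type = "s", col = cols[as.character(t$algorithm[1])])
  legend("topright", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(NULL)
}

#' Box plots of final energies per algorithm
#'
#' @param runsDf the `runs` data.frame of [runExperiment()].
#' @param main plot title.
#' @return invisibly the list returned by [boxplot()]
#' @export
plotEnergyBoxes <- function(runsDf, main = "Final energies") {
  invisible(boxplot(energy ~ algorithm, data = runsDf, range = 1.5,
                    ylab = "final energy", main = main))
}
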