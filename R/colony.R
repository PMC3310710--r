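#' Simulate one colony work phase
#'
#' Runs `T` time steps for one colony. Each step the two stimuli first rise
#' by `delta`; workers are then polled in a fresh uniform random order. A
#' polled worker serving a switching penalty only counts the penalty down.
#' Otherwise it perceives both stimuli with Gaussian error, computes its
#' activation energies (adding the self-feedback term under the recurrent
#' architecture) and acts on a task whose energy exceeds its threshold (fair
#' coin when both do). Performing a task immediately lowers that stimulus by
#' `alpha` (floored at 0), so later workers in the same step see the reduced
#' demand. Choosing a task different from the previous one is a switch: it is
#' tallied at decision time and, when `switch_cost > 0`, triggers
#' `switch_cost` inactive steps instead of an act.
#'
#' @param mother,father parental [genotype()]s; `N` workers are bred from
#'   them as `mutate(inherit(mother, father))` unless `workers` is given.
#' @param config a [simulation_config()]; supplies `N`, `T_steps`,
#'   `switch_cost`, stimulus dynamics, noise, fitness weighting and genetic
#'   parameters.
#' @param seed integer seed for the phase's RNG stream.
#' @param workers optional 8 x N matrix of worker genotypes (rows in locus
#'   order), bypassing inheritance.
#' @param history record the per-step colony history (stimuli and activity
#'   counts at the end of each step).
#' @param trace record every individual assessment (perceived stimuli,
#'   energies, decision, tie-break) plus the polling order; only for small
#'   `N * T`.
#' @return A list of class `"work_phase"`: `A1`, `A2`, `p1`, `D`, `F`,
#'   `F_rel`, a per-worker matrix `workers` (acts per task, stays, switches),
#'   the worker `genotypes`, and optionally `history`, `trace`, `order`.
#' @export
run_work_phase <- function(mother, father, config, seed = config$seed,
                           workers = NULL, history = FALSE, trace = FALSE) {
  stopifnot(inherits(config, "dol_config"))
  recurrent <- config$architecture == "recurrent"
  if (is.null(workers)) {
    mother <- validate_genotype(mother)
    father <- validate_genotype(father)
    res <- cpp_run_colony(as.numeric(mother), as.numeric(father),
                          config$N, config$T_steps, config$switch_cost,
                          config$delta, config$alpha,
                          config$init_stimulus[1], config$init_stimulus[2],
                          config$noise_sd, recurrent, config$beta,
                          config$r, config$mu, config$sigma_m,
                          as.integer(seed), history, trace)
  } else {
    stopifnot(is.matrix(workers), nrow(workers) == 8L)
    res <- cpp_work_phase(workers, config$T_steps, config$switch_cost,
                          config$delta, config$alpha,
                          config$init_stimulus[1], config$init_stimulus[2],
                          config$noise_sd, recurrent, config$beta,
                          as.integer(seed), history, trace)
    res$genotypes <- workers
  }
  # recompute the derived statistics through the R metrics layer; the C++
  # engine computes the same quantities internally and the two must agree
  w <- res$workers
  res$p1 <- if (res$A1 + res$A2 > 0) work_proportion(res$A1, res$A2)
            else NA_real_
  res$D <- if (res$A1 + res$A2 > 0 && any(w[, "stays"] + w[, "switches"] > 0))
    specialization_from_counts(w[, "stays"], w[, "switches"], res$p1)
  else NA_real_
  res$F <- colony_fitness(res$A1, res$A2, config$beta)
  res$F_rel <- relative_fitness(res$F, config$N, config$T_steps, config$beta)
  if (!is.null(res$history)) res$history <- as.data.frame(res$history)
  if (!is.null(res$trace)) res$trace <- as.data.frame(res$trace)
  res$config <- config
  res$seed <- as.integer(seed)
  class(res) <- "work_phase"
  res
}

#' @export
print.work_phase <- function(x, ...) {
  cat("<colony work phase>\n")
  cat(sprintf("  acts: A1 = %.0f, A2 = %.0f (p1 = %s)\n", x$A1, x$A2,
              format(round(x$p1, 3))))
  cat(sprintf("  specialization D = %s\n", format(round(x$D, 3))))
  cat(sprintf("  fitness F = %s (%.1f%% of maximum)\n",
              format(round(x$F, 2)), 100 * x$F_rel))
  invisible(x)
}
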