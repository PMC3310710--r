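#' Colony fitness: weighted geometric mean of task output
#'
#' `F = A1^beta * A2^(1 - beta)`. The geometric mean makes fitness zero
#' whenever either task goes unperformed; for a fixed total work `A1 + A2`,
#' fitness is maximized when the proportion of work on task 1 equals `beta`.
#'
#' @param A1,A2 total acts per task (non-negative).
#' @param beta fitness weighting in (0, 1).
#' @return Fitness value.
#' @export
colony_fitness <- function(A1, A2, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0 ||
      beta >= 1)
    stop("beta must lie strictly between 0 and 1")
  if (any(c(A1, A2) < 0)) stop("act counts must be non-negative")
  ifelse(A1 == 0 | A2 == 0, 0, A1^beta * A2^(1 - beta))
}

#' @rdname colony_fitness
#' @param N workers per colony.
#' @param T_steps work-phase length.
#' @return `max_fitness()`: the maximum attainable fitness
#'   `N * T * beta^beta * (1-beta)^(1-beta)` (all worker-steps worked, split
#'   `beta : 1-beta`).
#' @export
max_fitness <- function(N, T_steps, beta) {
  N * T_steps * beta^beta * (1 - beta)^(1 - beta)
}

#' @rdname colony_fitness
#' @param F fitness value(s).
#' @return `relative_fitness()`: `F` as a fraction of `max_fitness()`.
#' @export
relative_fitness <- function(F, N, T_steps, beta) {
  F / max_fitness(N, T_steps, beta)
}

#' Produce the next generation of parent pairs
#'
#' The population's `2M` sexuals are sampled colony-by-colony with
#' replacement, each colony drawn in proportion to its fitness (a
#' multinomial). Every sexual genotype is `mutate(inherit(mother, father))`
#' of its colony of origin. The sexuals are then shuffled into `M` disjoint
#' pairs, each founding one colony of the next generation; the old colonies
#' are discarded, keeping the population size fixed. Uses R's RNG; the
#' simulation engine repeats the same procedure internally.
#'
#' @param pop list with `mothers` and `fathers` (8 x M genotype matrices,
#'   rows in locus order) and `fitness` (length M, non-negative).
#' @param config a [simulation_config()] (supplies architecture and genetic
#'   parameters).
#' @return A list like `pop` (without `fitness`) for the next generation,
#'   with an `origin` attribute giving each sexual's colony of origin.
#' @export
produce_next_generation <- function(pop, config) {
  stopifnot(inherits(config, "dol_config"))
  m <- pop$mothers
  f <- pop$fathers
  fit <- pop$fitness
  stopifnot(is.matrix(m), is.matrix(f), nrow(m) == 8L, nrow(f) == 8L,
            ncol(m) == ncol(f), length(fit) == ncol(m))
  M <- ncol(m)
  if (all(fit <= 0))
    stop("population extinction: every colony has zero fitness",
         call. = FALSE)
  gp <- genetic_params(config$r, config$mu, config$sigma_m)
  origin <- sample.int(M, 2 * M, replace = TRUE, prob = fit / sum(fit))
  arch <- config$architecture
  sexuals <- vapply(origin, function(j) {
    as.numeric(mutate(inherit(as_genotype(m[, j], arch),
                              as_genotype(f[, j], arch), gp), gp))
  }, numeric(8))
  ord <- sample.int(2 * M)
  out <- list(mothers = sexuals[, ord[seq(1, 2 * M, by = 2)], drop = FALSE],
              fathers = sexuals[, ord[seq(2, 2 * M, by = 2)], drop = FALSE])
  attr(out, "origin") <- origin
  out
}

#' Run an evolutionary simulation
#'
#' Starts from a monomorphic population (every colony founded by a pair
#' carrying the configured initial genotype) and iterates the life cycle for
#' `generations` generations: breed `N` workers per colony, run the work
#' phase, score fitness and worker specialization, then produce the next
#' generation's `M` founder pairs by fitness-proportional sampling and random
#' pairing. The whole run is executed by the compiled engine from a single
#' RNG stream, so a seed fully determines the outcome.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return An object of class `"dol_sim"`: list with `config`, `seed`,
#'   `generations` (data.frame of per-colony summaries: generation, colony,
#'   A1, A2, p1, D, F, F_rel), `alleles` (data.frame of parent allele
#'   snapshots), and `final` (the last generation's parent genotype
#'   matrices).
#' @export
run_evolution <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dol_config"))
  g0 <- initial_genotype(config$architecture, theta = config$init_theta,
                         w_direct = config$init_w_direct,
                         w_cross = config$init_w_cross)
  mothers0 <- matrix(as.numeric(g0), 8, config$M)
  if (config$generations == 0L) {
    # nothing to simulate: log the initial (founder) state only
    alleles <- cbind(genotype_table(mothers0, generation = 0L,
                                    colony = seq_len(config$M),
                                    role = "mother"),
                     genotype_table(mothers0)[, 4:11])
    names(alleles) <- c("generation", "colony", "role",
                        paste0("mother_", .loci), paste0("father_", .loci))
    alleles$role <- NULL
    return(structure(list(config = config, seed = as.integer(seed),
                          generations = data.frame(),
                          alleles = alleles,
                          final = list(mothers = mothers0,
                                       fathers = mothers0)),
                     class = "dol_sim"))
  }
  res <- cpp_run_evolution(mothers0, mothers0, config$N, config$T_steps,
                           config$generations, config$beta,
                           config$switch_cost, config$r, config$mu,
                           config$sigma_m, config$delta, config$alpha,
                           config$init_stimulus[1], config$init_stimulus[2],
                           config$noise_sd,
                           config$architecture == "recurrent",
                           config$summary_every, config$log_every,
                           as.integer(seed))
  if (res$extinct)
    stop(sprintf(paste0("population extinction: every colony has zero ",
                        "fitness at generation %d"), res$extinct_generation),
         call. = FALSE)
  summary <- as.data.frame(res$summary[seq_len(res$n_summary), ,
                                       drop = FALSE])
  alleles <- as.data.frame(res$alleles[seq_len(res$n_alleles), ,
                                       drop = FALSE])
  structure(list(config = config, seed = as.integer(seed),
                 generations = summary, alleles = alleles,
                 final = list(mothers = res$final_mothers,
                              fathers = res$final_fathers)),
            class = "dol_sim")
}

#' Population state at quasi-equilibrium
#'
#' Aggregates the final generations of a run: per-generation population means
#' of `p1` and relative fitness averaged over a trailing window, the folded
#' work proportion `min(p1, 1 - p1)` (which task ends up preferred differs
#' among replicates), the per-generation minimum colony fitness, and
#' final-generation colony tallies used by the outcome classifier.
#'
#' @param sim a `"dol_sim"` object.
#' @param window number of trailing generations to average over.
#' @return List with `mean_p1`, `mean_p1_folded`, `mean_F_rel`,
#'   `min_F_rel` (trailing-window mean of the per-generation minimum),
#'   `final` (final-generation per-colony data.frame), `pct_D_above_half`
#'   and `mean_D` at the final generation.
#' @export
quasi_equilibrium <- function(sim, window = 100) {
  stopifnot(inherits(sim, "dol_sim"))
  gen <- sim$generations
  gens <- sort(unique(gen$generation))
  keep <- gens[gens > max(gens) - window]
  gs <- gen[gen$generation %in% keep, ]
  per_gen <- aggregate(gs[c("p1", "F_rel")], by = list(g = gs$generation),
                       FUN = mean, na.rm = TRUE)
  per_gen_min <- aggregate(gs["F_rel"], by = list(g = gs$generation),
                           FUN = min)
  final <- gen[gen$generation == max(gens), ]
  mean_p1 <- mean(per_gen$p1)
  list(mean_p1 = mean_p1,
       mean_p1_folded = min(mean_p1, 1 - mean_p1),
       mean_F_rel = mean(per_gen$F_rel),
       min_F_rel = mean(per_gen_min$F_rel),
       final = final,
       pct_D_above_half = 100 * mean(!is.na(final$D) & final$D > 0.5),
       mean_D = mean(final$D, na.rm = TRUE))
}

#' Run replicate simulations
#'
#' Runs the same configuration under distinct seeds and summarizes each
#' replicate's end state in the reporting style used for this model family:
#' population mean `p1`, percentage of colonies specialized (`D > 0.5`),
#' percentage of colonies at the optimal work ratio, and mean relative
#' fitness, plus across-replicate mean and SD.
#'
#' @param config a [simulation_config()].
#' @param n number of replicates.
#' @param seeds optional vector of `n` distinct seeds; derived from
#'   `config$seed` when omitted.
#' @param tol tolerance for counting a colony as at the optimal ratio.
#' @param window trailing-generation window for [quasi_equilibrium()].
#' @return An object of class `"dol_replicates"`: `replicates` (per-replicate
#'   data.frame), `across` (mean and SD per summary column; SD is `NA` for a
#'   single replicate), and `final_colonies` (list of final-generation colony
#'   tables, one per replicate, for [classify_outcome()]).
#' @export
run_replicates <- function(config, n = 10, seeds = NULL, tol = 0.02,
                           window = 100) {
  stopifnot(inherits(config, "dol_config"))
  if (is.null(seeds)) {
    set.seed(config$seed)
    seeds <- sample.int(.Machine$integer.max, n)
  }
  if (length(seeds) != n) stop("need exactly n seeds")
  if (anyDuplicated(seeds)) stop("replicate seeds must be distinct")
  rows <- vector("list", n)
  finals <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- run_evolution(config, seed = seeds[i])
    qe <- quasi_equilibrium(sim, window = window)
    finals[[i]] <- qe$final
    rows[[i]] <- data.frame(
      replicate = i, seed = seeds[i], mean_p1 = qe$mean_p1,
      mean_p1_folded = qe$mean_p1_folded,
      pct_D_above_half = qe$pct_D_above_half,
      pct_p1_at_beta = 100 * mean(!is.na(qe$final$p1) &
                                    abs(qe$final$p1 - config$beta) <= tol),
      mean_F_rel = qe$mean_F_rel)
  }
  reps <- do.call(rbind, rows)
  stat_cols <- setdiff(names(reps), c("replicate", "seed"))
  across <- data.frame(
    statistic = stat_cols,
    mean = vapply(reps[stat_cols], mean, numeric(1)),
    sd = if (n > 1) vapply(reps[stat_cols], sd, numeric(1)) else NA_real_,
    row.names = NULL)
  structure(list(config = config, replicates = reps, across = across,
                 final_colonies = finals),
            class = "dol_replicates")
}
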