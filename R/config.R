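#' Simulation configuration
#'
#' Collects and validates every tunable of an evolutionary run. `alpha`
#' (stimulus decrease per act) defaults to `3 * delta / N`, following the
#' convention of the classic fixed-threshold simulations (inflow `delta`,
#' total absorption capacity `3 * delta` per stimulus when scaled by colony
#' size). At this operating point pure stimulus-following can sustain at most
#' two thirds of the colony's worker-steps as work, so idleness is costly and
#' strategies that decouple work from the depleted stimulus are selectively
#' favored. Values of `alpha` at or below `2 * delta / N` make full
#' employment reachable by stimulus-following alone and remove that selection
#' pressure entirely.
#'
#' @param architecture `"feedforward"` or `"recurrent"`.
#' @param M number of colonies (population size is fixed at `M`).
#' @param N workers per colony.
#' @param T_steps work-phase length in time steps.
#' @param generations number of generations to simulate.
#' @param beta fitness weighting in (0, 1); the optimal work proportion for
#'   task 1 equals `beta`.
#' @param switch_cost non-negative integer `c`: enforced inactive time steps
#'   after a task switch.
#' @param r recombination rate in `[0, 1]`.
#' @param mu per-locus mutation probability in `[0, 1]`.
#' @param sigma_m mutation step SD (>= 0).
#' @param delta stimulus increase per time step (> 0).
#' @param alpha stimulus decrease per act (> 0); default `3 * delta / N`.
#' @param noise_sd perception error SD (>= 0).
#' @param init_theta initial threshold value(s) of the founder network.
#' @param init_w_direct,init_w_cross initial direct / cross connection
#'   weights of the founder network (direct 1, cross 0 reproduces the
#'   response-threshold rule).
#' @param init_stimulus numeric(2) non-negative initial stimulus levels.
#' @param seed integer master seed.
#' @param summary_every log per-colony summaries every this many generations.
#' @param log_every log parent allele snapshots every this many generations.
#' @return A validated list with class `"dol_config"`.
#' @export
simulation_config <- function(architecture = c("feedforward", "recurrent"),
                              M = 100L, N = 100L, T_steps = 100L,
                              generations = 5000L, beta = 0.5,
                              switch_cost = 0L, r = 0.5, mu = 0.01,
                              sigma_m = 0.1, delta = 1, alpha = NULL,
                              noise_sd = 1, init_theta = 1,
                              init_w_direct = 1, init_w_cross = 0,
                              init_stimulus = c(0, 0), seed = 1L,
                              summary_every = 1L, log_every = 50L) {
  architecture <- match.arg(architecture)
  chk_count <- function(x, key, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != floor(x))
      stop(sprintf("config key '%s' must be an integer >= %d", key, min))
    as.integer(x)
  }
  chk_num <- function(x, key, lo = -Inf, hi = Inf, lo_open = FALSE,
                      hi_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) stop(sprintf("config key '%s' out of range", key))
    as.numeric(x)
  }
  M <- chk_count(M, "M")
  N <- chk_count(N, "N")
  T_steps <- chk_count(T_steps, "T")
  generations <- chk_count(generations, "generations", min = 0)
  beta <- chk_num(beta, "beta", 0, 1, lo_open = TRUE, hi_open = TRUE)
  switch_cost <- chk_count(switch_cost, "c", min = 0)
  r <- chk_num(r, "r", 0, 1)
  mu <- chk_num(mu, "mu", 0, 1)
  sigma_m <- chk_num(sigma_m, "sigma_m", 0)
  delta <- chk_num(delta, "delta", 0, lo_open = TRUE)
  if (is.null(alpha)) alpha <- 3 * delta / N
  alpha <- chk_num(alpha, "alpha", 0, lo_open = TRUE)
  noise_sd <- chk_num(noise_sd, "noise_sd", 0)
  if (length(init_theta) == 1L) init_theta <- rep(init_theta, 2)
  if (any(init_theta < 0)) stop("config key 'init_theta' out of range")
  if (length(init_stimulus) != 2L || any(init_stimulus < 0))
    stop("config key 'init_stimulus' out of range")
  seed <- chk_count(seed, "seed", min = 0)
  summary_every <- chk_count(summary_every, "summary_every")
  log_every <- chk_count(log_every, "log_every")

  structure(list(architecture = architecture, M = M, N = N,
                 T_steps = T_steps, generations = generations, beta = beta,
                 switch_cost = switch_cost, r = r, mu = mu,
                 sigma_m = sigma_m, delta = delta, alpha = alpha,
                 noise_sd = noise_sd, init_theta = as.numeric(init_theta),
                 init_w_direct = as.numeric(init_w_direct),
                 init_w_cross = as.numeric(init_w_cross),
                 init_stimulus = as.numeric(init_stimulus), seed = seed,
                 summary_every = summary_every, log_every = log_every),
            class = "dol_config")
}

#' Scaled-down preset configuration
#'
#' A preset at reduced colony number, colony size and work-phase length
#' (`M = N = T = 50`, 2000 generations) for test-scale runs; any field can
#' still be overridden.
#'
#' @param ... overrides passed on to [simulation_config()].
#' @return A `"dol_config"`.
#' @export
preset_scaled <- function(...) {
  args <- modifyList(list(M = 50L, N = 50L, T_steps = 50L,
                          generations = 2000L), list(...))
  do.call(simulation_config, args)
}

# keys accepted in a config file; "c" and "T" are the compact aliases
.config_keys <- c("architecture", "M", "N", "T", "T_steps", "beta", "c",
                  "switch_cost", "r", "mu", "sigma_m", "delta", "alpha",
                  "noise_sd", "generations", "init_theta", "init_w_direct",
                  "init_w_cross", "init_stimulus", "seed", "summary_every",
                  "log_every")

#' Load a configuration file
#'
#' Reads a YAML file, rejects unknown keys, applies defaults for missing
#' ones, and validates every range. The keys `c` and `T` are accepted as
#' aliases for `switch_cost` and `T_steps`.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `"dol_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep YAML-1.1 boolean-looking tokens (N, T, yes, ...) as literal text:
  # they occur here as key names, never as config values
  raw <- yaml::read_yaml(path,
                         handlers = list("bool#yes" = function(x) x,
                                         "bool#no" = function(x) x))
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$c)) { raw$switch_cost <- raw$c; raw$c <- NULL }
  if (!is.null(raw$T)) { raw$T_steps <- raw$T; raw$T <- NULL }
  do.call(simulation_config, raw)
}

#' Write the resolved run manifest
#'
#' Emits every resolved configuration value together with the seed, package
#' version and the RNG algorithm, and marks which keys were left at package
#' defaults, so a run directory is self-describing and reproducible.
#'
#' @param config a `"dol_config"`.
#' @param dir output directory (created if needed).
#' @param user_keys keys the user supplied explicitly (everything else is
#'   marked as defaulted).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, dir, user_keys = character()) {
  stopifnot(inherits(config, "dol_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    config = unclass(config),
    defaulted_keys = setdiff(names(config), user_keys),
    rng = paste("xoshiro256++ seeded via splitmix64; Marsaglia-Tsang",
                "ziggurat normals (C++ engine)"),
    package = "dolsim",
    version = as.character(packageVersion("dolsim")))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @export
print.dol_config <- function(x, ...) {
  cat("<dolsim configuration>\n")
  cat(sprintf("  %-13s %s\n", "architecture", x$architecture))
  num <- c("M", "N", "T_steps", "generations", "beta", "switch_cost", "r",
           "mu", "sigma_m", "delta", "alpha", "noise_sd", "seed")
  for (k in num) cat(sprintf("  %-13s %s\n", k, format(x[[k]])))
  cat(sprintf("  %-13s theta=%s w_direct=%s w_cross=%s stimuli=(%s)\n",
              "initial", paste(x$init_theta, collapse = ","),
              x$init_w_direct, x$init_w_cross,
              paste(x$init_stimulus, collapse = ",")))
  invisible(x)
}
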