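#' Noisy stimulus perception
#'
#' Each input node perceives its task-associated stimulus with an independent
#' Gaussian error: `s_tilde_j = s_j + e_j`, `e_j ~ N(0, noise_sd)`. The
#' perceived values are deliberately not clamped at zero; downstream the
#' network operates on the raw perceived values. Uses R's RNG.
#'
#' @param s numeric(2) non-negative stimulus levels.
#' @param noise_sd perception error standard deviation (>= 0; the model's
#'   standard value is 1).
#' @return numeric(2) perceived stimuli.
#' @export
perceive <- function(s, noise_sd = 1) {
  if (length(s) != 2L || anyNA(s) || any(s < 0))
    stop("s must be two non-negative stimulus values")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0)
    stop("noise_sd must be a single value >= 0")
  s + rnorm(2, 0, noise_sd)
}

#' Activation energies of the two output neurons
#'
#' Linear units: `E_i = w_1i * s_tilde_1 + w_2i * s_tilde_2`, plus the
#' self-feedback term `u_i * E_i(prev)` under the recurrent architecture
#' (`u = 0` makes the two architectures identical). No squashing function is
#' applied.
#'
#' @param g a [genotype()].
#' @param s_tilde numeric(2) perceived stimuli (may be negative).
#' @param prev numeric(2) previous post-feedback activation energies;
#'   `c(0, 0)` at the start of a work phase.
#' @return numeric(2) activation energies.
#' @export
activation_energies <- function(g, s_tilde, prev = c(0, 0)) {
  g <- validate_genotype(g)
  if (length(s_tilde) != 2L || length(prev) != 2L)
    stop("s_tilde and prev must have length 2")
  c(g[["w11"]] * s_tilde[1] + g[["w21"]] * s_tilde[2] + g[["u1"]] * prev[1],
    g[["w12"]] * s_tilde[1] + g[["w22"]] * s_tilde[2] + g[["u2"]] * prev[2])
}

#' Task decision from activation energies
#'
#' Output neuron `i` is active iff `E_i > theta_i` (strict inequality; a tie
#' at equality counts as not active). No active neuron gives `"idle"`, one
#' gives that task, and when both are active one task is chosen by a fair
#' coin (R's RNG).
#'
#' @param E numeric(2) activation energies.
#' @param theta numeric(2) thresholds.
#' @return One of `"idle"`, `"task1"`, `"task2"`.
#' @export
decide <- function(E, theta) {
  if (length(E) != 2L || length(theta) != 2L)
    stop("E and theta must have length 2")
  active <- E > theta
  if (all(active)) {
    if (runif(1) < 0.5) "task1" else "task2"
  } else if (active[1]) "task1" else if (active[2]) "task2" else "idle"
}

#' Deterministic stimulus-response map of a network
#'
#' Labels every point of a stimulus grid by the activation pattern the
#' network shows there with perception noise disabled: motivated for task 1
#' only, task 2 only, both (one would then be chosen at random), or none.
#' Used to characterize evolved phenotypes across stimulus space.
#'
#' @param g a [genotype()].
#' @param s1,s2 finite ascending grids of non-negative stimulus values.
#' @param prev numeric(2) previous activation energies fed back under the
#'   recurrent architecture (default none).
#' @return A data.frame with columns `s1`, `s2` and `label` (factor with
#'   levels `none`, `task1`, `task2`, `both`).
#' @export
response_map <- function(g, s1, s2, prev = c(0, 0)) {
  g <- validate_genotype(g)
  if (length(s1) < 1L || length(s2) < 1L)
    stop("stimulus grids must be non-empty")
  if (is.unsorted(s1, strictly = TRUE) || is.unsorted(s2, strictly = TRUE))
    stop("stimulus grids must be strictly ascending")
  grid <- expand.grid(s1 = s1, s2 = s2, KEEP.OUT.ATTRS = FALSE)
  E1 <- g[["w11"]] * grid$s1 + g[["w21"]] * grid$s2 + g[["u1"]] * prev[1]
  E2 <- g[["w12"]] * grid$s1 + g[["w22"]] * grid$s2 + g[["u2"]] * prev[2]
  a1 <- E1 > g[["theta1"]]
  a2 <- E2 > g[["theta2"]]
  lab <- ifelse(a1 & a2, "both",
                ifelse(a1, "task1", ifelse(a2, "task2", "none")))
  grid$label <- factor(lab, levels = c("none", "task1", "task2", "both"))
  grid
}

#' Write a response map as a delimited grid file
#'
#' @param map output of [response_map()].
#' @param path output file (tab-separated: s1, s2, label).
#' @export
write_response_map <- function(map, path) {
  stopifnot(all(c("s1", "s2", "label") %in% names(map)))
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
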