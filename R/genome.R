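#' Construct a worker/sexual genotype
#'
#' A genotype is the heritable parameter set of one individual's network:
#' two output-neuron thresholds `theta1, theta2` (stimulus units, always
#' >= 0), four connection weights `w11, w21, w12, w22` (`w_ji` connects
#' stimulus input `j` to output neuron `i`), and two self-feedback weights
#' `u1, u2` which are identically 0 under the feedforward architecture.
#' Thresholds and weights form two linkage groups that segregate
#' independently at inheritance.
#'
#' @param theta numeric(2), non-negative thresholds.
#' @param w numeric(4), connection weights in the order `w11, w21, w12, w22`.
#' @param u numeric(2), self-feedback weights; must be 0 for feedforward.
#' @param architecture `"feedforward"` or `"recurrent"`.
#' @return A named numeric vector of length 8 with class `"genotype"` and an
#'   `"architecture"` attribute. Locus order: `theta1, theta2, w11, w21, w12,
#'   w22, u1, u2`.
#' @examples
#' genotype(theta = c(1, 1), w = c(1, 0, 0, 1))
#' @export
genotype <- function(theta = c(0, 0), w = c(1, 0, 0, 1), u = c(0, 0),
                     architecture = c("feedforward", "recurrent")) {
  architecture <- match.arg(architecture)
  theta <- as.numeric(theta)
  w <- as.numeric(w)
  u <- as.numeric(u)
  if (length(theta) != 2L || length(w) != 4L || length(u) != 2L)
    stop("genotype needs 2 thresholds, 4 weights and 2 self-feedback weights")
  g <- c(theta, w, u)
  names(g) <- .loci
  attr(g, "architecture") <- architecture
  class(g) <- "genotype"
  validate_genotype(g)
}

#' @rdname genotype
#' @param g object to validate.
#' @export
validate_genotype <- function(g) {
  if (length(g) != 8L || anyNA(g) || any(!is.finite(g)))
    stop("genotype must be 8 finite loci")
  if (any(g[.theta_loci] < 0))
    stop("thresholds must be >= 0")
  arch <- attr(g, "architecture")
  if (is.null(arch) || !arch %in% c("feedforward", "recurrent"))
    stop("genotype must carry a valid architecture attribute")
  if (arch == "feedforward" && any(g[7:8] != 0))
    stop("self-feedback weights must be 0 under the feedforward architecture")
  g
}

# wrap a bare 8-vector produced by the C++ engine
as_genotype <- function(x, architecture) {
  x <- as.numeric(x)
  names(x) <- .loci
  attr(x, "architecture") <- architecture
  class(x) <- "genotype"
  x
}

#' Initial (founder) genotype
#'
#' The starting network of an evolutionary run. Self-feedback weights are
#' always initialized at zero, so the recurrent architecture starts out
#' behaving exactly like the feedforward one. With the default direct weights
#' 1 and cross weights 0 the network is the fixed response-threshold rule:
#' each task is taken on when its own perceived stimulus exceeds the
#' corresponding threshold.
#'
#' @param architecture `"feedforward"` or `"recurrent"`.
#' @param theta numeric(2) non-negative initial thresholds.
#' @param w_direct initial value of the direct weights `w11`, `w22`.
#' @param w_cross initial value of the cross weights `w21`, `w12`.
#' @return A [genotype()].
#' @export
initial_genotype <- function(architecture = c("feedforward", "recurrent"),
                             theta = c(1, 1), w_direct = 1, w_cross = 0) {
  architecture <- match.arg(architecture)
  if (length(theta) == 1L) theta <- rep(theta, 2)
  genotype(theta = theta,
           w = c(w_direct, w_cross, w_cross, w_direct),
           u = c(0, 0), architecture = architecture)
}

#' Genetic transmission parameters
#'
#' @param r recombination rate in `[0, 1]`: probability that the loci of a
#'   linkage group are transmitted independently rather than as a parental
#'   block.
#' @param mu per-locus mutation probability in `[0, 1]`.
#' @param sigma_m standard deviation (>= 0) of the Gaussian mutation step.
#' @return A list with class `"genetic_params"`.
#' @export
genetic_params <- function(r = 0.5, mu = 0.01, sigma_m = 0.1) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("r must be a single value in [0, 1]")
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1)
    stop("mu must be a single value in [0, 1]")
  if (!is.numeric(sigma_m) || length(sigma_m) != 1L || is.na(sigma_m) ||
      sigma_m < 0)
    stop("sigma_m must be a single value >= 0")
  structure(list(r = r, mu = mu, sigma_m = sigma_m),
            class = "genetic_params")
}

#' Haploid inheritance with two linkage blocks
#'
#' The two threshold loci form one linkage group and the six weight loci
#' (connection plus self-feedback) the other; the groups always segregate
#' independently. Within a group, with probability `1 - r` the whole block is
#' copied from one uniformly chosen parent; with probability `r` every locus
#' picks its parent uniformly and independently. Uses R's RNG.
#'
#' @param mother,father parental [genotype()]s of the same architecture.
#' @param params a [genetic_params()] object.
#' @return Offspring [genotype()].
#' @export
inherit <- function(mother, father, params = genetic_params()) {
  mother <- validate_genotype(mother)
  father <- validate_genotype(father)
  if (!identical(attr(mother, "architecture"), attr(father, "architecture")))
    stop("parents must share the same architecture")
  child <- unclass(mother)
  for (group in list(.theta_loci, .weight_loci)) {
    if (runif(1) >= params$r) {
      from <- if (runif(1) < 0.5) mother else father
      child[group] <- from[group]
    } else {
      take_mother <- runif(length(group)) < 0.5
      child[group] <- ifelse(take_mother, unclass(mother)[group],
                             unclass(father)[group])
    }
  }
  as_genotype(child, attr(mother, "architecture"))
}

#' Gaussian mutation
#'
#' Each expressed locus (6 under feedforward, 8 under recurrent) is
#' independently perturbed with probability `mu` by adding a draw from
#' `N(0, sigma_m)`. Threshold loci are clamped at 0 afterwards; weight loci
#' may take either sign. Uses R's RNG.
#'
#' @param g a [genotype()].
#' @param params a [genetic_params()] object.
#' @return Mutated [genotype()].
#' @export
mutate <- function(g, params = genetic_params()) {
  g <- validate_genotype(g)
  arch <- attr(g, "architecture")
  nloci <- if (arch == "recurrent") 8L else 6L
  hit <- runif(nloci) < params$mu
  if (any(hit)) {
    out <- unclass(g)
    out[seq_len(nloci)][hit] <- out[seq_len(nloci)][hit] +
      rnorm(sum(hit), 0, params$sigma_m)
    out[.theta_loci] <- pmax(out[.theta_loci], 0)
    g <- as_genotype(out, arch)
  }
  g
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("<genotype: %s>\n", attr(x, "architecture")))
  print(setNames(as.numeric(x), .loci))
  invisible(x)
}

#' Produce a colony's workers
#'
#' Each of the `n` workers receives `mutate(inherit(mother, father))` and a
#' fresh dynamic state (no previous task, no switching penalty, zero previous
#' activation energies). Uses R's RNG; the simulation engine repeats the same
#' construction internally with its own stream.
#'
#' @param mother,father parental [genotype()]s.
#' @param n number of workers (>= 1).
#' @param params a [genetic_params()] object.
#' @return A list of `n` worker states; each has elements `genotype`,
#'   `last_task` (0 = none), `penalty`, `acts` (length 2), `stays`,
#'   `switches`, `prev_E` (length 2).
#' @export
make_workers <- function(mother, father, n, params = genetic_params()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    list(genotype = mutate(inherit(mother, father, params), params),
         last_task = 0L, penalty = 0L, acts = c(0L, 0L),
         stays = 0L, switches = 0L, prev_E = c(0, 0))
  })
}

#' Genotypes as a population-snapshot table
#'
#' One row per individual, matching the layout of `population.tsv`.
#'
#' @param genotypes 8 x n matrix of genotypes (rows = loci) or a list of
#'   [genotype()]s.
#' @param generation,colony,role metadata columns recycled across rows.
#' @return A data.frame with columns generation, colony, role and the 8 loci.
#' @export
genotype_table <- function(genotypes, generation = NA_integer_,
                           colony = NA_integer_, role = NA_character_) {
  if (is.list(genotypes))
    genotypes <- vapply(genotypes, as.numeric, numeric(8))
  stopifnot(is.matrix(genotypes), nrow(genotypes) == 8L)
  out <- data.frame(generation = generation, colony = colony, role = role,
                    t(genotypes))
  names(out)[4:11] <- .loci
  rownames(out) <- NULL
  out
}
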