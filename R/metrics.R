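#' Work proportion of task 1
#'
#' @param A1,A2 total acts performed for each task (non-negative).
#' @return `A1 / (A1 + A2)`; `NA` with a warning when no acts were performed.
#' @export
work_proportion <- function(A1, A2) {
  if (any(c(A1, A2) < 0)) stop("act counts must be non-negative")
  if (A1 + A2 == 0) {
    warning("work proportion undefined: no acts performed")
    return(NA_real_)
  }
  A1 / (A1 + A2)
}

#' Worker specialization statistic D
#'
#' For every worker with at least two work decisions, `C_k` is the fraction
#' of consecutive decision pairs that stayed on the same task (idle and
#' penalty steps in between are skipped). The worker mean `Cbar` is
#' normalized by the chance-stay probability `q1^2 + q2^2`, where `q_i` is
#' the colony-level proportion of work devoted to task `i`, and shifted:
#' `D = Cbar / (q1^2 + q2^2) - 1`. `D` is 1 when every worker always repeats
#' its previous task at an even work split, about 0 when workers pick tasks
#' at random, and negative when workers alternate more than chance predicts.
#' `D` is reported unclamped; the `[-1, 1]` range is guaranteed only when the
#' chance-stay probability is at least 1/2, which always holds since
#' `q1^2 + q2^2 >= 1/2`.
#'
#' @param sequences list of per-worker task sequences (integer vectors of 1s
#'   and 2s, in performance order).
#' @param q1 colony work proportion for task 1; computed by pooling the
#'   sequences when omitted.
#' @return `D`, or `NA` with a warning when undefined (no worker with two or
#'   more decisions, or no acts at all).
#' @export
specialization_D <- function(sequences, q1 = NULL) {
  stopifnot(is.list(sequences))
  all_acts <- unlist(sequences, use.names = FALSE)
  if (length(all_acts) == 0) {
    warning("specialization undefined: no acts")
    return(NA_real_)
  }
  if (!all(all_acts %in% c(1, 2))) stop("sequences must contain only 1 and 2")
  if (is.null(q1)) q1 <- mean(all_acts == 1)
  stays <- vapply(sequences, function(s) {
    if (length(s) < 2) return(c(0, 0))
    same <- s[-1] == s[-length(s)]
    c(sum(same), length(same))
  }, numeric(2))
  qual <- stays[2, ] > 0
  if (!any(qual)) {
    warning("specialization undefined: no worker with >= 2 acts")
    return(NA_real_)
  }
  cbar <- mean(stays[1, qual] / stays[2, qual])
  specialization_from_counts_cbar(cbar, q1)
}

specialization_from_counts_cbar <- function(cbar, q1) {
  p_chance <- q1^2 + (1 - q1)^2
  cbar / p_chance - 1
}

#' @rdname specialization_D
#' @param stays,switches per-worker counts of stay and switch transitions
#'   over consecutive work decisions.
#' @export
specialization_from_counts <- function(stays, switches, q1) {
  ntr <- stays + switches
  qual <- ntr > 0
  if (!any(qual)) {
    warning("specialization undefined: no worker with >= 2 acts")
    return(NA_real_)
  }
  specialization_from_counts_cbar(mean(stays[qual] / ntr[qual]), q1)
}

#' Detect evolutionary branching at a locus
#'
#' Splits the population's allele values into two clusters by exact 1-D
#' two-means and reports a bimodal (branched) state when the cluster
#' separation exceeds `k` pooled within-cluster standard deviations and both
#' clusters hold at least `min_frac` of the values. The default `k = 3` sits
#' above the separation/spread ratio that two-means produces on unimodal
#' Gaussian samples (about 2.65), keeping the false-positive rate below 5%.
#'
#' @param values numeric allele values across the population (>= 20).
#' @param k separation threshold in pooled within-cluster SD units.
#' @param min_frac minimum fraction of values per cluster.
#' @return List with `bimodal` (logical), `means` (ascending cluster means),
#'   `sizes`, and `ratio` (separation / pooled within SD; `Inf` for two point
#'   masses, `NA` when monomorphic at a single value).
#' @export
detect_branching <- function(values, k = 3, min_frac = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 20) stop("need at least 20 values")
  if (anyNA(values)) stop("values must not contain NA")
  n <- length(values)
  x <- sort(values)
  if (x[n] == x[1])
    return(list(bimodal = FALSE, means = c(x[1], x[1]), sizes = c(n, 0L),
                ratio = NA_real_))
  # exact two-means: scan all split points of the sorted sample
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  i <- seq_len(n - 1)
  ssw_left <- cs2[i] - cs[i]^2 / i
  nr <- n - i
  ssw_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / nr
  ssw <- ssw_left + ssw_right
  best <- which.min(ssw)
  m1 <- cs[best] / best
  m2 <- (cs[n] - cs[best]) / (n - best)
  sizes <- c(best, n - best)
  pooled <- sqrt(max(ssw[best], 0) / max(n - 2, 1))
  sep <- m2 - m1
  ratio <- if (pooled == 0) Inf else sep / pooled
  bimodal <- (ratio > k) && all(sizes / n >= min_frac)
  list(bimodal = bimodal, means = c(m1, m2), sizes = sizes, ratio = ratio)
}

#' Classify replicate outcomes as Y / N / P
#'
#' Summarizes, across replicate simulations, whether colonies achieved a
#' result: the optimal work ratio (`|p1 - beta| <= tol`) or worker
#' specialization (`D > 0.5`). A replicate counts as satisfying the result
#' population-wide when at least `frac_hi` of its colonies do. `"Y"` means
#' every replicate satisfied it population-wide; `"P"` means that in the
#' majority of replicates at least a nontrivial fraction (`frac_lo`) of
#' colonies did; `"N"` otherwise.
#'
#' @param colony_values list with one numeric vector per replicate: colony
#'   `p1` values (for `"p1_equals_beta"`) or colony `D` values (for
#'   `"D_above_half"`). `NA` colonies count as not satisfying.
#' @param criterion `"p1_equals_beta"` or `"D_above_half"`.
#' @param beta fitness weighting, required for `"p1_equals_beta"`.
#' @param tol tolerance on `|p1 - beta|`.
#' @param frac_lo,frac_hi colony-fraction thresholds for a partial /
#'   population-wide replicate.
#' @return `"Y"`, `"N"` or `"P"`.
#' @export
classify_outcome <- function(colony_values,
                             criterion = c("p1_equals_beta", "D_above_half"),
                             beta = NULL, tol = 0.02,
                             frac_lo = 0.1, frac_hi = 0.9) {
  criterion <- match.arg(criterion)
  stopifnot(is.list(colony_values), length(colony_values) >= 1)
  if (criterion == "p1_equals_beta" && is.null(beta))
    stop("beta is required for the p1_equals_beta criterion")
  frac <- vapply(colony_values, function(v) {
    ok <- switch(criterion,
                 p1_equals_beta = abs(v - beta) <= tol,
                 D_above_half = v > 0.5)
    mean(ok & !is.na(ok))
  }, numeric(1))
  if (all(frac >= frac_hi)) return("Y")
  if (mean(frac >= frac_lo) > 0.5) return("P")
  "N"
}
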