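#' @export
print.dol_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dolsim run: %s, M=%d, N=%d, T=%d, beta=%g, c=%d, r=%g>\n",
              cfg$architecture, cfg$M, cfg$N, cfg$T_steps, cfg$beta,
              cfg$switch_cost, cfg$r))
  ngen <- if (nrow(x$generations)) max(x$generations$generation) else 0
  cat(sprintf("  %d generations simulated (seed %d)\n", ngen, x$seed))
  if (nrow(x$generations)) {
    qe <- quasi_equilibrium(x, window = min(100, ngen))
    cat(sprintf("  final state: mean p1 = %.3f, mean D = %.3f, mean F_rel = %.3f\n",
                qe$mean_p1, qe$mean_D, qe$mean_F_rel))
  }
  invisible(x)
}

#' @export
summary.dol_sim <- function(object, window = 100, ...) {
  qe <- quasi_equilibrium(object, window = window)
  out <- list(config = object$config, window = window,
              mean_p1 = qe$mean_p1, mean_p1_folded = qe$mean_p1_folded,
              mean_F_rel = qe$mean_F_rel, min_F_rel = qe$min_F_rel,
              mean_D = qe$mean_D, pct_D_above_half = qe$pct_D_above_half)
  class(out) <- "summary.dol_sim"
  out
}

#' @export
print.summary.dol_sim <- function(x, ...) {
  cat(sprintf("Quasi-equilibrium over the final %d generations:\n",
              x$window))
  cat(sprintf("  mean p1             %.4f (folded: %.4f)\n", x$mean_p1,
              x$mean_p1_folded))
  cat(sprintf("  mean F_rel          %.4f\n", x$mean_F_rel))
  cat(sprintf("  min colony F_rel    %.4f\n", x$min_F_rel))
  cat(sprintf("  mean D (final gen)  %.4f\n", x$mean_D))
  cat(sprintf("  %% colonies D > 0.5  %.1f\n", x$pct_D_above_half))
  invisible(x)
}

#' Plot an evolutionary trajectory
#'
#' Shows the population mean and the across-colony interquartile band for
#' the work proportion `p1` and the specialization `D` over generations.
#'
#' @param x a `"dol_sim"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dol_sim <- function(x, ...) {
  gen <- x$generations
  if (!nrow(gen)) {
    warning("nothing to plot: no generations simulated")
    return(invisible(x))
  }
  qtl <- function(v, p) tapply(v, gen$generation, stats::quantile, probs = p,
                               na.rm = TRUE)
  g <- sort(unique(gen$generation))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (stat in c("p1", "D")) {
    lo <- qtl(gen[[stat]], 0.25)
    hi <- qtl(gen[[stat]], 0.75)
    md <- qtl(gen[[stat]], 0.5)
    ylim <- if (stat == "p1") c(0, 1) else c(-1, 1)
    graphics::plot(g, md, type = "n", ylim = ylim, xlab = "generation",
                   ylab = stat, ...)
    graphics::polygon(c(g, rev(g)), c(lo, rev(hi)), border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.35))
    graphics::lines(g, md, col = "steelblue4", lwd = 1.5)
    graphics::abline(h = if (stat == "p1") x$config$beta else 0, lty = 3)
  }
  invisible(x)
}

#' @export
print.dol_replicates <- function(x, ...) {
  cat(sprintf("<dolsim replicates: %d runs of %s, beta=%g, c=%d, r=%g>\n",
              nrow(x$replicates), x$config$architecture, x$config$beta,
              x$config$switch_cost, x$config$r))
  print(x$across, digits = 4)
  if (nrow(x$replicates) == 1)
    cat("  (SD undefined with a single replicate)\n")
  invisible(x)
}
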