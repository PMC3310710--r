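# Independent plain-R re-simulation of a recorded work phase.
#
# The engine can record, for every assessment, the perceived stimuli, the
# tie-break outcome and the polling order. These are the only random inputs
# of a work phase, so an independent implementation of the behavioral rules
# can replay them and must reproduce every action, stimulus value and tally
# exactly. `rule` chooses the decision logic:
#   "network"   - full model: weighted sums (+ self-feedback), thresholds
#   "threshold" - hand-coded response-threshold rule (s_tilde_j > theta_j),
#                 valid for identity-weight feedforward genotypes; it never
#                 looks at the weights, making it an independent oracle for
#                 the reduction of the network to the threshold model.
replay_phase <- function(wp, genotypes, config, rule = c("network",
                                                         "threshold")) {
  rule <- match.arg(rule)
  tr <- wp$trace
  ord <- wp$order
  N <- ncol(genotypes)
  T_steps <- config$T_steps
  cc <- config$switch_cost
  s <- config$init_stimulus
  last <- integer(N)
  pen <- integer(N)
  prevE <- matrix(0, 2, N)
  a <- matrix(0L, 2, N)
  stays <- integer(N)
  switches <- integer(N)
  recurrent <- config$architecture == "recurrent"
  row <- 0L
  for (t in seq_len(T_steps)) {
    s <- s + config$delta
    for (slot in seq_len(N)) {
      row <- row + 1L
      stopifnot(tr$step[row] == t, tr$slot[row] == slot)
      w <- ord[t, slot]
      stopifnot(tr$worker[row] == w)
      if (pen[w] > 0) {
        stopifnot(tr$penalized[row] == 1)
        pen[w] <- pen[w] - 1L
      } else {
        stopifnot(tr$penalized[row] == 0)
        st <- c(tr$s1_tilde[row], tr$s2_tilde[row])  # recorded random input
        g <- genotypes[, w]
        if (rule == "network") {
          E <- c(g[3] * st[1] + g[4] * st[2], g[5] * st[1] + g[6] * st[2])
          if (recurrent) E <- E + g[7:8] * prevE[, w]
          prevE[, w] <- E
          active <- E > g[1:2]
        } else {
          active <- st > g[1:2]
        }
        action <- if (all(active)) {
          stopifnot(tr$coin[row] %in% c(1, 2))  # recorded tie-break
          tr$coin[row]
        } else if (active[1]) 1 else if (active[2]) 2 else 0
        stopifnot(identical(as.numeric(action), as.numeric(tr$action[row])))
        if (action > 0) {
          if (last[w] == action || last[w] == 0) {
            if (last[w] == action) stays[w] <- stays[w] + 1L
            last[w] <- action
            a[action, w] <- a[action, w] + 1L
            s[action] <- max(0, s[action] - config$alpha)
          } else {
            switches[w] <- switches[w] + 1L
            last[w] <- action
            if (cc == 0) {
              a[action, w] <- a[action, w] + 1L
              s[action] <- max(0, s[action] - config$alpha)
            } else {
              pen[w] <- cc
            }
          }
        }
      }
      stopifnot(isTRUE(all.equal(s[1], tr$s1_after[row])),
                isTRUE(all.equal(s[2], tr$s2_after[row])))
    }
  }
  list(A1 = as.numeric(sum(a[1, ])), A2 = as.numeric(sum(a[2, ])),
       acts1 = a[1, ], acts2 = a[2, ], stays = stays, switches = switches,
       s_final = s)
}
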