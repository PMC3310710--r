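# shared fixture builders (everything generated in code)

# genotype from loose parts, defaulting to the response-threshold identity net
make_g <- function(theta = c(1, 1), w11 = 1, w21 = 0, w12 = 0, w22 = 1,
                   u = c(0, 0),
                   architecture = if (any(u != 0)) "recurrent"
                                  else "feedforward") {
  genotype(theta = theta, w = c(w11, w21, w12, w22), u = u,
           architecture = architecture)
}

# column-bind genotypes into the 8 x N worker matrix the engine takes
geno_matrix <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "genotype"))
    gs <- gs[[1]]
  vapply(gs, as.numeric, numeric(8))
}

# N copies of one genotype
clone_matrix <- function(g, n) matrix(rep(as.numeric(g), n), nrow = 8)

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(M = 5L, N = 5L, T_steps = 10L, generations = 5L, log_every = 1L,
         seed = 42L),
    list(...))
  do.call(simulation_config, args)
}
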