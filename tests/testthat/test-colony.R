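test_that("an all-idle colony performs no acts and stimuli grow linearly", {
  cfg <- simulation_config(M = 1L, N = 4L, T_steps = 12L, generations = 1L,
                           init_theta = 1e9, seed = 3L)
  g <- initial_genotype("feedforward", theta = c(1e9, 1e9))
  wp <- run_work_phase(g, g, cfg, workers = clone_matrix(g, 4),
                       history = TRUE)
  expect_identical(wp$A1 + wp$A2, 0)
  expect_identical(wp$F, 0)
  expect_true(is.na(wp$D))
  # unopposed growth: s = s0 + k * delta exactly at the end of step k
  expect_equal(wp$history$s1, cfg$init_stimulus[1] + cfg$delta * 1:12)
  expect_equal(wp$history$s2, cfg$init_stimulus[2] + cfg$delta * 1:12)
})

test_that("a hard-wired worker acts every step and pins its stimulus", {
  # one worker, theta1 = 0, task 2 unreachable, noise off, delta = alpha:
  # each step the stimulus gains delta and loses alpha, so A1 = T and s1
  # returns to its fixed point after every step
  cfg <- simulation_config(M = 1L, N = 1L, T_steps = 20L, generations = 1L,
                           noise_sd = 0, delta = 1, alpha = 1, seed = 3L)
  g <- make_g(theta = c(0, 1e9))
  wp <- run_work_phase(g, g, cfg, workers = clone_matrix(g, 1),
                       history = TRUE)
  expect_identical(wp$A1, 20)
  expect_identical(wp$A2, 0)
  expect_true(all(wp$history$s1 == 0))  # +1 then -1, floored at 0
  expect_equal(wp$history$s2, 1:20)
})

test_that("stimulus never goes negative even when alpha overshoots", {
  cfg <- simulation_config(M = 1L, N = 6L, T_steps = 30L, generations = 1L,
                           delta = 1, alpha = 10, seed = 4L)
  g <- make_g(theta = c(0, 0))
  wp <- run_work_phase(g, g, cfg, workers = clone_matrix(g, 6),
                       history = TRUE, trace = TRUE)
  expect_true(all(wp$trace$s1_after >= 0))
  expect_true(all(wp$trace$s2_after >= 0))
  expect_true(all(wp$history$s1 >= 0))
})

test_that("switch decisions enforce c act-free steps and the accounting balances", {
  cfg <- simulation_config(M = 1L, N = 8L, T_steps = 40L, generations = 1L,
                           switch_cost = 2L, seed = 5L)
  g <- make_g(theta = c(0.5, 0.5))
  wp <- run_work_phase(g, g, cfg, workers = clone_matrix(g, 8),
                       history = TRUE, trace = TRUE)
  tr <- wp$trace
  expect_gt(sum(wp$workers[, "switches"]), 0)  # switches actually happened
  for (w in 1:8) {
    rows <- tr[tr$worker == w, ]
    last <- 0
    n <- nrow(rows)
    for (i in seq_len(n)) {
      if (rows$penalized[i] == 1) next
      act <- rows$action[i]
      if (is.na(act) || act == 0) next
      if (last != 0 && act != last && i < n) {
        # switch decision: the worker is penalized (act-free) for the next
        # `c` assessments
        idx <- (i + 1):min(i + 2, n)
        expect_true(all(rows$penalized[idx] == 1))
      }
      last <- act
    }
  }
  # act conservation: acts + idle + penalty worker-steps = N * T
  h <- wp$history
  expect_identical(sum(h$n_task1) + sum(h$n_task2) + sum(h$n_idle) +
                     sum(h$n_penalty), 8 * 40)
  expect_identical(sum(h$n_task1) + sum(h$n_task2), wp$A1 + wp$A2)
})

test_that("with c = 0 no penalty steps ever occur", {
  cfg <- simulation_config(M = 1L, N = 10L, T_steps = 50L, generations = 1L,
                           switch_cost = 0L, seed = 6L)
  g <- make_g(theta = c(0.5, 0.5))
  wp <- run_work_phase(g, g, cfg, workers = clone_matrix(g, 10),
                       history = TRUE)
  expect_true(all(wp$history$n_penalty == 0))
})

test_that("zero-threshold identity workers are fully employed", {
  # alpha small and stimuli started high so both stimuli stay strictly
  # positive: zero thresholds are then always exceeded
  cfg <- simulation_config(M = 1L, N = 10L, T_steps = 30L, generations = 1L,
                           noise_sd = 0, switch_cost = 0L, alpha = 0.05,
                           init_stimulus = c(5, 5), seed = 7L)
  g <- make_g(theta = c(0, 0))
  wp <- run_work_phase(g, g, cfg, workers = clone_matrix(g, 10))
  expect_identical(wp$A1 + wp$A2, 10 * 30)
})

test_that("the polling order is a fair fresh permutation each step", {
  cfg <- simulation_config(M = 1L, N = 10L, T_steps = 500L, generations = 1L,
                           init_theta = 1e9, seed = 8L)
  g <- initial_genotype("feedforward", theta = c(1e9, 1e9))
  wp <- run_work_phase(g, g, cfg, workers = clone_matrix(g, 10),
                       trace = TRUE)
  ord <- wp$order
  expect_true(all(apply(ord, 1, sort) == 1:10))  # true permutations
  # mean polling rank of every worker ~ (N + 1) / 2
  ranks <- vapply(1:10, function(w) mean(apply(ord, 1, function(r)
    which(r == w))), numeric(1))
  se <- sqrt((10^2 - 1) / 12 / 500)
  expect_true(all(abs(ranks - 5.5) < 5 * se))
})

test_that("engine work phases replay exactly under an independent R simulator", {
  # stochastic colonies with noise, ties and switching costs: the recorded
  # random inputs fully determine the outcome under the documented rules
  for (cc in c(0L, 2L)) {
    cfg <- simulation_config(M = 1L, N = 6L, T_steps = 25L, generations = 1L,
                             switch_cost = cc, seed = 100L + cc)
    set.seed(20 + cc)
    gs <- lapply(1:6, function(i)
      make_g(theta = runif(2, 0, 2), w11 = rnorm(1, 1, 0.5),
             w21 = rnorm(1), w12 = rnorm(1), w22 = rnorm(1, 1, 0.5)))
    wk <- geno_matrix(gs)
    wp <- run_work_phase(NULL, NULL, cfg, workers = wk, history = TRUE,
                         trace = TRUE)
    rep <- replay_phase(wp, wk, cfg, rule = "network")
    expect_identical(rep$A1, wp$A1)
    expect_identical(rep$A2, wp$A2)
    expect_identical(rep$acts1, unname(wp$workers[, "acts1"]))
    expect_identical(rep$stays, unname(wp$workers[, "stays"]))
    expect_identical(rep$switches, unname(wp$workers[, "switches"]))
  }

  # recurrent colony: self-feedback energies carried across steps
  cfgr <- simulation_config(architecture = "recurrent", M = 1L, N = 5L,
                            T_steps = 20L, generations = 1L,
                            switch_cost = 1L, seed = 31L)
  set.seed(32)
  gs <- lapply(1:5, function(i)
    genotype(theta = runif(2, 0, 2), w = rnorm(4, 0.5, 0.5),
             u = runif(2, -0.5, 1), architecture = "recurrent"))
  wk <- geno_matrix(gs)
  wp <- run_work_phase(NULL, NULL, cfgr, workers = wk, trace = TRUE)
  rep <- replay_phase(wp, wk, cfgr, rule = "network")
  expect_identical(rep$A1, wp$A1)
  expect_identical(rep$stays, unname(wp$workers[, "stays"]))
})

test_that("worker production from parents follows Mendelian expectation", {
  # parents differing at one weight locus: ~50% of workers carry each variant
  mother <- make_g(w21 = 0)
  father <- make_g(w21 = 5)
  wk <- cpp_make_workers(as.numeric(mother), as.numeric(father), 1000,
                         r = 0.5, mu = 0, sigma_m = 0, recurrent = FALSE,
                         seed = 33)
  frac <- mean(wk[4, ] == 5)
  expect_lt(abs(frac - 0.5), 4 * 0.5 / sqrt(1000))

  # identical parents with mu = 0: all workers identical
  wk2 <- cpp_make_workers(as.numeric(mother), as.numeric(mother), 50,
                          r = 0.5, mu = 0, sigma_m = 0, recurrent = FALSE,
                          seed = 34)
  expect_true(all(wk2 == as.numeric(mother)))

  # R-level surface produces valid worker states
  ws <- make_workers(mother, father, 5, genetic_params(mu = 0))
  expect_length(ws, 5)
  expect_identical(ws[[1]]$last_task, 0L)
  expect_identical(ws[[1]]$penalty, 0L)
  expect_error(make_workers(mother, father, 0), ">= 1")
})

test_that("colony metrics agree between the engine and the R metrics layer", {
  set.seed(35)
  for (i in 1:20) {
    n <- 12
    a1 <- rpois(n, 5); a2 <- rpois(n, 3)
    stays <- rpois(n, 4); switches <- rpois(n, 2)
    beta <- runif(1, 0.2, 0.8)
    fmax <- max_fitness(n, 10, beta)
    m <- cpp_colony_metrics(a1, a2, stays, switches, beta, fmax)
    A1 <- sum(a1); A2 <- sum(a2)
    expect_equal(m[["F"]], colony_fitness(A1, A2, beta))
    expect_equal(m[["F_rel"]], relative_fitness(colony_fitness(A1, A2, beta),
                                                n, 10, beta))
    if (A1 + A2 > 0) {
      expect_equal(m[["p1"]], work_proportion(A1, A2))
      expect_equal(m[["D"]],
                   specialization_from_counts(stays, switches,
                                              work_proportion(A1, A2)))
    }
  }
})
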