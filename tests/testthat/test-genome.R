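test_that("genotype construction enforces the invariants", {
  g <- initial_genotype("recurrent", theta = c(2, 3))
  expect_identical(unname(g[c("u1", "u2")]), c(0, 0))
  expect_identical(attr(g, "architecture"), "recurrent")

  # boundary of non-negativity is allowed
  g0 <- initial_genotype("feedforward", theta = c(0, 0))
  expect_identical(unname(g0[c("theta1", "theta2")]), c(0, 0))

  expect_error(initial_genotype("feedforward", theta = c(-1, 1)),
               ">= 0")
  expect_error(genotype(u = c(0.5, 0), architecture = "feedforward"),
               "self-feedback")

  # default start is the response-threshold special case
  gd <- initial_genotype("feedforward")
  expect_identical(unname(gd[c("w11", "w22")]), c(1, 1))
  expect_identical(unname(gd[c("w21", "w12")]), c(0, 0))
})

test_that("inheritance at r = 0 transmits each linkage group as one block", {
  mother <- make_g(theta = c(1, 2), w11 = 10, w21 = 11, w12 = 12, w22 = 13)
  father <- make_g(theta = c(3, 4), w11 = 20, w21 = 21, w12 = 22, w22 = 23)
  gp <- genetic_params(r = 0, mu = 0)
  set.seed(1)
  both_sources <- matrix(FALSE, 2, 2)  # group x parent seen
  for (i in 1:200) {
    ch <- inherit(mother, father, gp)
    th_m <- identical(unname(ch[1:2]), unname(unclass(mother)[1:2]))
    th_f <- identical(unname(ch[1:2]), unname(unclass(father)[1:2]))
    w_m <- identical(unname(ch[3:8]), unname(unclass(mother)[3:8]))
    w_f <- identical(unname(ch[3:8]), unname(unclass(father)[3:8]))
    expect_true(xor(th_m, th_f))  # never a within-group mosaic
    expect_true(xor(w_m, w_f))
    both_sources <- both_sources | matrix(c(th_m, w_m, th_f, w_f), 2)
  }
  expect_true(all(both_sources))  # both parents actually used

  # same contract through the compiled path
  wk <- cpp_make_workers(as.numeric(mother), as.numeric(father), 500,
                         r = 0, mu = 0, sigma_m = 0.1, recurrent = FALSE,
                         seed = 9)
  th_match <- apply(wk[1:2, ], 2, function(v)
    identical(v, as.numeric(mother)[1:2]) ||
      identical(v, as.numeric(father)[1:2]))
  w_match <- apply(wk[3:8, ], 2, function(v)
    identical(v, as.numeric(mother)[3:8]) ||
      identical(v, as.numeric(father)[3:8]))
  expect_true(all(th_match) && all(w_match))
})

test_that("identical parents produce identical offspring at any r", {
  g <- make_g(theta = c(1, 2), w11 = 0.3, w21 = -0.7)
  gp <- genetic_params(r = 0.7, mu = 0)
  set.seed(2)
  for (i in 1:25)
    expect_identical(as.numeric(inherit(g, g, gp)), as.numeric(g))
})

test_that("r = 1 gives independent per-locus transmission at frequency 1/2", {
  # mark every locus so the parent of origin is identifiable
  mother <- make_g(theta = c(1, 2), w11 = 10, w21 = 11, w12 = 12, w22 = 13)
  father <- make_g(theta = c(101, 102), w11 = 110, w21 = 111, w12 = 112,
                   w22 = 113)
  n <- 10000
  wk <- cpp_make_workers(as.numeric(mother), as.numeric(father), n,
                         r = 1, mu = 0, sigma_m = 0, recurrent = FALSE,
                         seed = 11)
  from_mother <- wk[1:6, ] == as.numeric(mother)[1:6]
  # per-locus origin frequencies ~ 1/2
  for (l in 1:6) {
    tab <- table(factor(from_mother[l, ], levels = c(FALSE, TRUE)))
    expect_gt(stats::chisq.test(tab, p = c(0.5, 0.5))$p.value, 1e-4)
  }
  # loci uncorrelated, including within a linkage group (w11 vs w22)
  for (pair in list(c(1, 2), c(3, 6), c(2, 5))) {
    tab <- table(from_mother[pair[1], ], from_mother[pair[2], ])
    expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
  }

  # same through the R path
  set.seed(3)
  rch <- replicate(4000, as.numeric(inherit(mother, father,
                                            genetic_params(r = 1, mu = 0))))
  fm <- rch[1:6, ] == as.numeric(mother)[1:6]
  expect_true(all(abs(rowMeans(fm) - 0.5) < 4 * sqrt(0.25 / 4000)))
})

test_that("mutation respects mu, sigma_m and the threshold clamp", {
  g <- make_g(theta = c(1, 1), w11 = 0.5)
  expect_identical(as.numeric(mutate(g, genetic_params(mu = 0))),
                   as.numeric(g))
  expect_identical(as.numeric(mutate(g, genetic_params(mu = 1, sigma_m = 0))),
                   as.numeric(g))

  # Monte-Carlo contract of the clamped Gaussian: thresholds at 0 stay >= 0,
  # weight perturbations have mean ~0 and sd ~sigma_m
  g0 <- make_g(theta = c(0, 0), w11 = 0)
  gp <- genetic_params(mu = 1, sigma_m = 0.1)
  set.seed(4)
  draws <- replicate(10000, as.numeric(mutate(g0, gp)))
  expect_true(all(draws[1:2, ] >= 0))
  w_pert <- draws[3, ]
  expect_lt(abs(mean(w_pert)), 4 * 0.1 / sqrt(10000))
  expect_lt(abs(sd(w_pert) - 0.1), 0.005)
  # clamped thresholds follow a half-normal: about half the draws sit at 0
  expect_lt(abs(mean(draws[1, ] == 0) - 0.5), 0.02)

  # compiled path obeys the same contract
  wk <- cpp_make_workers(as.numeric(g0), as.numeric(g0), 10000,
                         r = 0, mu = 1, sigma_m = 0.1, recurrent = FALSE,
                         seed = 5)
  expect_true(all(wk[1:2, ] >= 0))
  expect_lt(abs(mean(wk[3, ])), 4 * 0.1 / sqrt(10000))
  expect_lt(abs(sd(wk[3, ]) - 0.1), 0.005)
  # feedforward genotypes never mutate their self-feedback loci
  expect_true(all(wk[7:8, ] == 0))
})

test_that("with mu = 0 no new allele values ever appear", {
  cfg <- tiny_config(mu = 0, generations = 10L)
  sim <- run_evolution(cfg)
  init <- as.numeric(initial_genotype("feedforward",
                                      theta = cfg$init_theta))
  al <- sim$alleles
  loci <- c(paste0("mother_", dolsim:::.loci), paste0("father_", dolsim:::.loci))
  vals <- unique(unlist(al[loci]))
  expect_true(all(vals %in% init))
})

test_that("genetic_params validates its ranges", {
  expect_error(genetic_params(r = 1.2), "r")
  expect_error(genetic_params(mu = -0.1), "mu")
  expect_error(genetic_params(sigma_m = -1), "sigma_m")
  expect_silent(genetic_params(sigma_m = 0))
})
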