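test_that("model registry exposes the expected structure and bounds", {
  counts <- c(M0 = 0, M1a = 1, M1b = 2, M2a = 3, M2b = 4, M2c = 5,
              M3a = 5, M3b = 6, M3c = 5, M3d = 5)
  for (m in model_names())
    expect_length(model_spec(m)$par_names, counts[[m]])
  expect_equal(model_spec("M1a")$bounds$alpha, c(0.1, 100))
  expect_equal(model_spec("M2a")$bounds$theta, c(0.1, 1000))
  expect_equal(model_spec("M2b")$bounds$theta_slope, c(0.1, 500))
  expect_equal(model_spec("M3d")$bounds$beta, c(0.01, 0.99))
  expect_error(model_spec("M9"))
  expect_error(check_params("M3d", c(alpha_uncertain = 1)), "named")
  expect_error(check_params("M1a", c(alpha = 500)), "bounds")
})

test_that("belief counts follow the unit-prior beta-count update", {
  # worked example: 45 mushrooms, first estimate 20% blue
  cts <- e1_counts(20, 45)
  expect_equal(cts$blue, 10)
  expect_equal(cts$red, 37)
  expect_equal(e1_counts(50, 0), list(blue = 1, red = 1))

  post <- posterior_counts(list(blue = 10, red = 37), p = 60, n_peer = 25)
  expect_equal(post, list(blue = 25, red = 47))
  # conservation: total pseudo-count grows by exactly n_peer
  for (np in c(0, 3.7, 25, 400)) {
    po <- posterior_counts(cts, p = 33, n_peer = np)
    expect_equal(po$blue + po$red, cts$blue + cts$red + np)
  }
  expect_equal(posterior_counts(cts, p = 60, n_peer = 0), cts)
})

test_that("perceived and peer counts honour each model's switches", {
  expect_equal(perceived_n("M0", numeric(0), "certain", 45), 45)
  expect_equal(perceived_n("M1b", c(alpha_uncertain = 28, alpha_certain = 4),
                           "uncertain", 5), 140)
  # single-alpha model with alpha = 1 collapses onto the base model
  expect_equal(perceived_n("M1a", c(alpha = 1), c("uncertain", "certain"),
                           c(5, 45)),
               perceived_n("M0", numeric(0), c("uncertain", "certain"),
                           c(5, 45)))
  expect_equal(peer_n("M0", numeric(0), 1:3), rep(25, 3))
  expect_equal(peer_n("M2b", c(theta_ic = 10, theta_slope = 5), 2), 15)
  expect_equal(peer_n("M2b", c(theta_ic = 10, theta_slope = 5), 1), 10)
  expect_equal(peer_n("M2c", c(theta_low = 1, theta_medium = 7,
                               theta_high = 300), c(3, 1)), c(300, 1))
})

test_that("response pmfs are normalised with the right shape", {
  u <- response_pmf(1, 1)
  expect_equal(as.numeric(u), rep(1 / 101, 101))
  lin <- response_pmf(2, 1)
  expect_equal(as.numeric(lin), (0:100) / sum(0:100))
  # mode of the discrete pmf sits at the beta mode (blue-1)/(blue+red-2)
  for (cts in list(c(10, 37), c(25, 47), c(3, 3), c(80, 20))) {
    pm <- response_pmf(cts[1], cts[2])
    expect_equal(which.max(pm) - 1,
                 round(100 * (cts[1] - 1) / (cts[1] + cts[2] - 2)))
  }
  # normalisation across a lattice of shapes
  ab <- expand.grid(a = c(1, 1.5, 5, 50, 400), b = c(1, 2, 30, 1000))
  pm <- response_pmf(ab$a, ab$b)
  expect_equal(rowSums(pm), rep(1, nrow(ab)), tolerance = 1e-9)
  expect_true(all(pm >= 0))
})

test_that("stay weights implement the four bias variants", {
  base <- c(M2B_PARS, beta = 0.5)
  expect_equal(stay_weight("M2b", M2B_PARS, 2, "certain"), 0)
  expect_equal(stay_weight("M3a", base, 1:3, "certain"), rep(0.5, 3))
  expect_equal(stay_weight("M3d", base, c(1, 3), "certain"), c(0.5, 0.125))
  expect_equal(stay_weight("M3c", c(M2B_PARS, beta = 0.6), 3, "certain"),
               0.2)
  bb <- c(M2B_PARS, beta_uncertain = 0.8, beta_certain = 0.2)
  expect_equal(stay_weight("M3b", bb, 2, c("uncertain", "certain")),
               c(0.8, 0.2))
})

test_that("trial likelihoods form a proper mixture distribution", {
  rec <- sim_one(seed = 21)[1:10, ]
  probs <- trial_response_probs(rec, "M3d", M3D_PARS)
  # enumerating all 101 candidate responses exhausts the probability
  expect_equal(rowSums(probs), rep(1, nrow(rec)), tolerance = 1e-9)
  expect_true(all(probs >= 0 & probs <= 1))

  # without stay bias the likelihood is exactly the posterior pmf entry
  q <- trial_response_probs(rec, "M2b", M2B_PARS)
  expect_equal(trial_likelihood(rec, "M2b", M2B_PARS),
               q[cbind(seq_len(nrow(rec)), rec$e2 + 1)])

  # near-total stay mass concentrates on e1
  heavy <- c(M2B_PARS, beta = 0.99)
  rec1 <- rec[1, ]; rec1$e2 <- rec1$e1; rec1$peer_confidence <- 1
  expect_gte(trial_likelihood(rec1, "M3a", heavy), 0.99)
})

test_that("participant nll is additive and matches the slow route", {
  rec <- sim_one(seed = 22)
  rec1 <- rec[!rec$is_filler, ][1, ]
  expect_equal(as.numeric(participant_nll(rec1, "M3d", M3D_PARS)),
               -log(trial_likelihood(rec1, "M3d", M3D_PARS)))
  half1 <- rec[1:37, ]; half2 <- rec[38:75, ]
  expect_equal(as.numeric(participant_nll(rec, "M3d", M3D_PARS)),
               as.numeric(participant_nll(half1, "M3d", M3D_PARS)) +
                 as.numeric(participant_nll(half2, "M3d", M3D_PARS)))
  # the fitting fast path agrees with the reference computation
  f <- socbayes:::make_nll(rec, model_spec("M3d"))
  expect_equal(f(M3D_PARS), as.numeric(participant_nll(rec, "M3d", M3D_PARS)))
})

test_that("the model family is properly nested", {
  rec <- sim_one(seed = 23)
  p0 <- trial_response_probs(rec, "M0", numeric(0))
  expect_equal(trial_response_probs(rec, "M1a", c(alpha = 1)), p0,
               tolerance = 1e-12)
  expect_equal(trial_response_probs(
    rec, "M1b", c(alpha_uncertain = 1, alpha_certain = 1)), p0,
    tolerance = 1e-12)

  # equal condition-specific stay biases collapse M3b onto M3a
  expect_equal(
    trial_response_probs(rec, "M3b", c(M2B_PARS, beta_uncertain = 0.3,
                                       beta_certain = 0.3)),
    trial_response_probs(rec, "M3a", c(M2B_PARS, beta = 0.3)),
    tolerance = 1e-12)

  # vanishing stay bias approaches the pure Bayesian model (checked on
  # stay-free data, where no trial gets a large boost from the stay mass)
  rec_b <- sim_one(seed = 24, model = "M2b", pars = M2B_PARS)
  nll_m3d <- as.numeric(participant_nll(rec_b, "M3d",
                                        c(M2B_PARS, beta = 0.01)))
  nll_m2b <- as.numeric(participant_nll(rec_b, "M2b", M2B_PARS))
  expect_lt(abs(nll_m3d - nll_m2b), 1.5)

  # slope at its lower bound approximates the single-theta model
  nll_m2b_flat <- as.numeric(participant_nll(
    rec, "M2b", c(M2B_PARS[c("alpha_uncertain", "alpha_certain")],
                  theta_ic = 40, theta_slope = 0.1)))
  nll_m2a <- as.numeric(participant_nll(
    rec, "M2a", c(M2B_PARS[c("alpha_uncertain", "alpha_certain")],
                  theta = 40)))
  expect_lt(abs(nll_m2b_flat - nll_m2a), 0.5)
})

test_that("posterior-mean advice weight is n_peer/(n_peer+n_perceived+2)", {
  grid <- expand.grid(npv = c(2, 5, 45, 140, 500), np = c(1, 25, 100, 300),
                      e1 = c(20, 50, 80), p = c(35, 66))
  m_prior <- with(grid, (1 + e1 / 100 * npv) / (2 + npv))
  post <- with(grid, list(blue = 1 + e1 / 100 * npv + p / 100 * np,
                          red = 1 + (1 - e1 / 100) * npv + (1 - p / 100) * np))
  m_post <- post$blue / (post$blue + post$red)
  w <- with(grid, np / (np + npv + 2))
  expect_equal(m_post, m_prior + w * (grid$p / 100 - m_prior),
               tolerance = 1e-12)
  # monotone: more peer observations pull harder, more own observations less
  W <- outer(c(1, 25, 100, 300), c(2, 5, 45, 140, 500),
             function(np, npv) np / (np + npv + 2))
  expect_true(all(apply(W, 2, diff) > 0))
  expect_true(all(apply(W, 1, diff) < 0))
})
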