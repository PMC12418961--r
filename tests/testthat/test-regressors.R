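test_that("model-based certainty and peer confidence follow the fits", {
  trials <- data.frame(condition = c("uncertain", "certain"),
                       n_shown = c(5L, 45L),
                       peer_confidence = c(1L, 3L),
                       is_filler = FALSE)
  expect_equal(model_based_certainty(trials, M3D_PARS), c(140, 180))
  expect_equal(model_based_certainty(trials, c(alpha_uncertain = 1,
                                               alpha_certain = 1)),
               trials$n_shown)

  mbpc <- model_based_peer_confidence(trials, M3D_PARS)
  expect_equal(mbpc[1], unname(M3D_PARS["theta_ic"]))
  expect_equal(mbpc[2] - mbpc[1], 2 * unname(M3D_PARS["theta_slope"]))
  # strictly increasing in confidence for positive slopes
  tr3 <- data.frame(condition = "certain", n_shown = 45L,
                    peer_confidence = 1:3, is_filler = FALSE)
  expect_true(all(diff(model_based_peer_confidence(tr3, M3D_PARS)) > 0))
  tr3$is_filler <- TRUE
  expect_error(model_based_peer_confidence(tr3, M3D_PARS), "non-filler")
})

test_that("KL belief updates are nonnegative and match the closed form", {
  # fixed widths, growing shift: KL grows with |e2 - e1|
  shifts <- c(0, 2, 5, 10, 20)
  tr <- data.frame(condition = "certain", n_shown = 45L,
                   peer_confidence = 2L, is_filler = FALSE,
                   e1 = 40L, e2 = 40L + shifts)
  kl <- kl_update(tr, M3D_PARS)
  expect_true(all(kl >= 0))
  expect_true(all(diff(kl) > 0))
  # positive even for stay responses: the posterior is strictly narrower
  expect_gt(kl[1], 0)

  # continuous beta-beta closed form (digamma expression) as oracle
  kl_beta <- function(a1, b1, a2, b2) {
    lbeta(a2, b2) - lbeta(a1, b1) + (a1 - a2) * digamma(a1) +
      (b1 - b2) * digamma(b1) + (a2 - a1 + b2 - b1) * digamma(a1 + b1)
  }
  cases <- expand.grid(e1 = c(20, 40, 70), e2 = c(35, 60),
                       conf = 1:3)
  pars <- c(alpha_uncertain = 4, alpha_certain = 1,
            theta_ic = 20, theta_slope = 15, beta = 0.5)
  tr <- data.frame(condition = "uncertain", n_shown = 5L,
                   peer_confidence = cases$conf, is_filler = FALSE,
                   e1 = cases$e1, e2 = cases$e2)
  npv <- 5 * pars[["alpha_uncertain"]]
  npeer <- pars[["theta_ic"]] + pars[["theta_slope"]] * (cases$conf - 1)
  a1 <- 1 + cases$e2 / 100 * (npv + npeer)   # updated belief
  b1 <- 1 + (1 - cases$e2 / 100) * (npv + npeer)
  a2 <- 1 + cases$e1 / 100 * npv             # prior belief
  b2 <- 1 + (1 - cases$e1 / 100) * npv
  expect_true(all(c(a1, b1, a2, b2) >= 2 & c(a1, b1, a2, b2) <= 100))
  expected <- kl_beta(a1, b1, a2, b2)
  expect_equal(kl_update(tr, pars), expected, tolerance = 0.02)
})

test_that("KL tracks the size of the estimate revision on simulated data", {
  rec <- sim_one(seed = 61)
  nf <- rec[!rec$is_filler, ]
  kl <- kl_update(nf, M3D_PARS)
  ct <- suppressWarnings(
    cor.test(kl, abs(nf$e2 - nf$e1), method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("regressor sets are centred within run over entering trials", {
  rec <- sim_one(seed = 62)
  rs <- build_regressors(rec, M3D_PARS)
  expect_equal(nrow(rs), nrow(rec))
  for (v in c("certainty_c", "peer_confidence_reg_c", "kl_c")) {
    means <- tapply(rs[[v]], rs$run, mean, na.rm = TRUE)
    expect_equal(as.numeric(means), rep(0, 3), tolerance = 1e-9)
  }
  # peer-based regressors exist only on non-filler trials
  expect_true(all(is.na(rs$kl[rs$is_filler])))
  expect_true(all(is.na(rs$peer_confidence_reg[rs$is_filler])))
  expect_false(anyNA(rs$certainty))
  # stay-bias modulator is the exponential mixture weight
  nf <- !rs$is_filler
  expect_equal(rs$stay_bias[nf],
               M3D_PARS[["beta"]] ^ rec$peer_confidence[order(rec$run, rec$trial_index)][nf])
})

test_that("event files are 3-column, centred, and free of fillers", {
  rec <- sim_one(seed = 63)
  rs <- build_regressors(rec, M3D_PARS)
  dir <- withr::local_tempdir()
  paths_kl <- export_events(rs, "kl", dir = dir)
  paths_cert <- export_events(rs, "certainty", dir = dir)
  expect_length(paths_kl, 3)

  for (p in paths_kl) {
    ev <- read.table(p, col.names = c("onset", "duration", "value"))
    expect_true(all(ev$duration == 4))
    expect_lt(abs(mean(ev$value)), 1e-6)  # centred up to print precision
    run <- as.integer(sub(".*_(\\d)_kl.txt", "\\1", p))
    # one row per non-filler trial of the run, none for fillers
    expect_equal(nrow(ev), sum(rs$run == run & !rs$is_filler))
    # round trip: file reproduces values at the printed precision
    expect_equal(ev$value,
                 as.numeric(sprintf("%.6f", rs$kl_c[rs$run == run &
                                                      !rs$is_filler])))
  }
  ev1 <- read.table(paths_cert[1], col.names = c("onset", "duration", "value"))
  expect_true(all(ev1$duration == 0.5))
  expect_equal(nrow(ev1), sum(rs$run == 1))  # all trials enter certainty
  expect_true(all(diff(ev1$onset) > 0))
})
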