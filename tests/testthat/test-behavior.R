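test_that("social information use is the normalised adjustment", {
  expect_equal(social_info_use(40, 40, 56), 0)
  expect_equal(social_info_use(40, 56, 56), 1)
  expect_equal(social_info_use(40, 48, 56), 0.5)
  expect_equal(social_info_use(c(40, 10), c(48, 10), c(56, 10)),
               c(0.5, NA))
})

test_that("trial filters assign reasons with the documented precedence", {
  rec <- scripted_cohort(n_participants = 6, seed = 2)
  out <- apply_trial_filters(rec)

  expect_true(all(out$exclusion_reason[out$is_filler] == "filler"))
  expect_true(all(out$included == (out$exclusion_reason == "none")))
  # conservation: every trial has exactly one reason
  expect_equal(sum(table(out$exclusion_reason)), nrow(out))
  # idempotence
  expect_equal(apply_trial_filters(out)$exclusion_reason,
               out$exclusion_reason)
  # equation inversion holds on every evaluable trial
  ev <- out[!is.na(out$s), ]
  expect_equal(ev$e2, ev$e1 + ev$s * (ev$p - ev$e1), tolerance = 1e-12)

  # overshooting the peer is flagged
  rec2 <- rec
  i <- which(!rec2$is_filler)[1]
  rec2$e2[i] <- rec2$e1[i] + as.integer(1.2 * (rec2$p[i] - rec2$e1[i]))
  out2 <- apply_trial_filters(rec2)
  expect_equal(as.character(out2$exclusion_reason[i]), "s_out_of_range")

  # a missed filler trial is still counted as filler (precedence)
  rec3 <- rec
  j <- which(rec3$is_filler)[1]
  rec3$missed[j] <- TRUE
  expect_equal(as.character(apply_trial_filters(rec3)$exclusion_reason[j]),
               "filler")

  # peer equal to first estimate leaves s undefined
  rec4 <- rec
  k <- which(!rec4$is_filler)[2]
  rec4$p[k] <- rec4$e1[k]
  expect_equal(as.character(apply_trial_filters(rec4)$exclusion_reason[k]),
               "no_peer")
})

test_that("a 4-SD estimate in its cell is caught by the 3-SD rule", {
  rec <- scripted_cohort(n_participants = 8, seed = 3)
  # make e1 vary within cells so cell SDs are nonzero
  set.seed(4)
  rec$e1 <- rec$e1 + sample(-3:3, nrow(rec), replace = TRUE)
  rec$p <- rec$e1 + 16L
  rec$e2 <- rec$e1 + 6L
  i <- which(!rec$is_filler)[5]
  cell <- !rec$is_filler & rec$condition == rec$condition[i] &
    rec$true_pct == rec$true_pct[i]
  # brute-force cell statistics excluding nothing (full-cohort stats)
  m <- mean(rec$e1[cell]); sdev <- sd(rec$e1[cell])
  rec$e1[i] <- as.integer(round(m + 4 * sdev)) + 1L
  out <- apply_trial_filters(rec)
  expect_equal(as.character(out$exclusion_reason[i]), "outlier_3sd")
})

test_that("participants staying on more than 70% of trials are dropped", {
  mk <- function(id, n_stay, n = 100) {
    data.frame(participant = id, trial_index = 1:n, run = 1L,
               condition = "uncertain", n_shown = 5L,
               peer_confidence = 2L, true_pct = 50, is_filler = FALSE,
               e1 = 50L, p = 66L,
               e2 = c(rep(50L, n_stay), rep(58L, n - n_stay)),
               missed = FALSE)
  }
  rec <- rbind(mk("over", 71), mk("at", 70), mk("under", 10))
  rec <- apply_trial_filters(rec)
  res <- apply_participant_filters(rec)
  lg <- res$log
  expect_false(lg$retained[lg$participant == "over"])
  expect_true(lg$retained[lg$participant == "at"])   # strict inequality
  expect_true(lg$retained[lg$participant == "under"])
  expect_false("over" %in% res$records$participant)
  expect_equal(lg$stay_proportion[lg$participant == "at"], 0.70)

  # manual flags override the stay criterion
  res2 <- apply_participant_filters(rec, manual_exclusions = "under")
  expect_equal(res2$log$reason[res2$log$participant == "under"], "manual")
})

test_that("heavy stay bias simulations lose most of the cohort", {
  pars <- c(M2B_PARS, beta = 0.97)
  cohort <- simulate_cohort(6, "M3a", pars, experiment = 1, seed = 9)
  cohort <- apply_trial_filters(cohort)
  res <- apply_participant_filters(cohort)
  expect_gte(sum(!res$log$retained), 4)
})

test_that("null cohorts give null fixed effects, effect cohorts signed ones", {
  null_rec <- apply_trial_filters(scripted_cohort(14, seed = 5))
  fit <- fit_condition_regression(null_rec)
  fx <- fit$fixed
  for (term in c("certainty_c", "confidence_c", "certainty_c:confidence_c")) {
    row <- fx[fx$term == term, ]
    expect_lt(abs(row$estimate), 2 * row$se)
  }
  expect_equal(fit$n_trials, sum(null_rec$included))

  eff_rec <- apply_trial_filters(
    scripted_cohort(14, seed = 6, certainty_effect = -0.15,
                    confidence_effect = 0.1))
  fx2 <- fit_condition_regression(eff_rec)$fixed
  cert <- fx2[fx2$term == "certainty_c", ]
  conf <- fx2[fx2$term == "confidence_c", ]
  expect_lt(cert$estimate + 2 * cert$se, 0)
  expect_gt(conf$estimate - 2 * conf$se, 0)
  expect_lt(cert$p, 0.05)
  expect_lt(conf$p, 0.05)
})

test_that("trial tables round-trip through the tab-delimited dialect", {
  rec <- apply_trial_filters(sim_one(seed = 31))
  rec$participant <- "sim01"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(rec, path)
  back <- read_trials(path)
  expect_equal(back$e2, rec$e2)
  expect_equal(back$is_filler, rec$is_filler)
  expect_equal(back$true_pct, rec$true_pct)

  # non-integer estimates are rounded onto the grid with a message
  raw <- rec
  raw$e1 <- raw$e1 + 0.4
  write_trials(raw, path)
  expect_message(back2 <- read_trials(path), "rounded")
  expect_equal(back2$e1, as.integer(round(raw$e1)))

  rep_path <- withr::local_tempfile(fileext = ".tsv")
  report <- write_exclusion_report(rec, rep_path)
  expect_equal(sum(report$n_trials), nrow(rec))
})
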