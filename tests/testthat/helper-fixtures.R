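# Shared fixtures: small deterministic cohorts built in code.

M3D_PARS <- c(alpha_uncertain = 28, alpha_certain = 4,
              theta_ic = 10, theta_slope = 40, beta = 0.5)
M2B_PARS <- M3D_PARS[c("alpha_uncertain", "alpha_certain",
                       "theta_ic", "theta_slope")]

# one simulated participant on the scanner design
sim_one <- function(seed = 7, model = "M3d", pars = M3D_PARS,
                    experiment = 2) {
  simulate_participant(generate_design(experiment, seed = seed),
                       model, pars, seed = seed + 1)
}

# hand-built records with full experimental structure but scripted
# responses: s drawn around s_mean with no condition dependence unless
# effects are supplied (additive shifts on the s scale)
scripted_cohort <- function(n_participants = 10, seed = 1, s_mean = 0.4,
                            s_sd = 0.15, certainty_effect = 0,
                            confidence_effect = 0) {
  set.seed(seed)
  recs <- lapply(seq_len(n_participants), function(i) {
    d <- as.data.frame(generate_design(2, seed = seed + i))
    d$participant <- sprintf("p%02d", i)
    d$e1 <- 50L
    dir <- sample(c(-1L, 1L), nrow(d), replace = TRUE)
    d$p <- d$e1 + dir * ifelse(d$is_filler, 45L, 16L)
    mu <- s_mean + i * 0 +
      certainty_effect * ifelse(d$condition == "certain", 0.5, -0.5) +
      confidence_effect * (d$peer_confidence - 2)
    s_true <- pmin(pmax(stats::rnorm(nrow(d), mu, s_sd), 0), 1)
    d$e2 <- as.integer(round(d$e1 + s_true * (d$p - d$e1)))
    d$missed <- FALSE
    d
  })
  do.call(rbind, recs)
}
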