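test_that("reproductive exposure spans the sex-specific window", {
  cfg <- survey_config()
  # female born 1930, alive in 2017: 15 to 50, all inside the window
  expect_equal(reproductive_exposure(1930L, NA, "F", cfg), 35)
  # same but dying at 40: exposure truncated at death
  expect_equal(reproductive_exposure(1930L, 1970L, "F", cfg), 25)
  # male window extends to 60
  expect_equal(reproductive_exposure(1930L, NA, "M", cfg), 45)
  # born too recently: window truncated at the survey
  expect_equal(reproductive_exposure(2010L, NA, "F", cfg), 0)
  # equal-exposure mode comes through skew_input
  cen <- make_census(
    census_row("a", sex = "M", birth_year = 1930L),
    census_row("b", sex = "M", birth_year = 1940L)
  )
  si <- skew_input(cen, sex = "M", equal_exposure = TRUE)
  expect_equal(si$tau, c(1, 1))
})

test_that("Nonacs' B matches the closed form on worked examples", {
  # equal shares: S = 0, B = -(1 - 1/2) / 10
  expect_equal(nonacs_B(skew_input_raw(c(5, 5))), -0.05)
  # complete monopoly of 10 offspring between two equally exposed adults
  expect_equal(nonacs_B(skew_input_raw(c(10, 0))), 0.45)
  expect_error(nonacs_B(skew_input_raw(c(0, 0))), "R = 0")
})

test_that("B is centred on zero under multinomial allocation", {
  set.seed(21)
  N <- 8; R <- 40
  tau <- rgamma(N, 4, 1)
  t <- tau / sum(tau)
  draws <- rmultinom(10000, R, prob = t)
  Bs <- apply(draws, 2, function(r) nonacs_B(skew_input_raw(r, tau)))
  se <- stats::sd(Bs) / sqrt(length(Bs))
  expect_lt(abs(mean(Bs)), 3 * se)
})

test_that("M is 1 under full monopoly and slightly negative when even", {
  for (N in c(2, 5, 20)) {
    r <- c(20, rep(0, N - 1))
    expect_equal(m_index(skew_input_raw(r)), 1)
  }
  # proportional allocation undershoots expectation, so M < 0
  expect_lt(m_index(skew_input_raw(c(5, 5))), 0)
  expect_error(m_index(skew_input_raw(7)), "single individual")
})

test_that("null M is insensitive to group size", {
  set.seed(31)
  mean_M <- sapply(c(20, 100, 500), function(N) {
    draws <- rmultinom(400, 3 * N, prob = rep(1 / N, N))
    mean(apply(draws, 2, function(r) m_index(skew_input_raw(r))))
  })
  # all means are near zero on the M scale
  expect_true(all(abs(mean_M) < 0.02))
  expect_lt(max(mean_M) - min(mean_M), 0.02)
})

test_that("posterior draws are reproducible and concentrate under monopoly", {
  si <- skew_input_raw(c(200, 0, 0, 0, 0))
  cfg <- skew_config(n_draws = 1000, seed = 4)
  a <- m_posterior(si, cfg)
  b <- m_posterior(si, cfg)
  expect_identical(a$draws, b$draws)
  expect_gt(a$mean, 0.9)
  expect_lt(a$ci[1], a$ci[2])
  expect_lte(a$M_point, 1)
})

test_that("group differences pair draws and respect interval levels", {
  si <- skew_input_raw(c(4, 2, 0, 1, 3))
  a <- m_posterior(si, skew_config(n_draws = 500, seed = 7))
  d0 <- group_difference(a, a)
  expect_equal(d0$mean, 0)
  expect_equal(unname(d0$ci), c(0, 0))
  b <- m_posterior(si, skew_config(n_draws = 500, seed = 8, ci_level = 0.5))
  expect_error(group_difference(a, b), "ci_level mismatch")
  # two identically generated groups: interval straddles zero
  set.seed(9)
  r1 <- as.vector(rmultinom(1, 120, rep(1 / 40, 40)))
  r2 <- as.vector(rmultinom(1, 120, rep(1 / 40, 40)))
  g1 <- m_posterior(skew_input_raw(r1), skew_config(n_draws = 2000, seed = 10))
  g2 <- m_posterior(skew_input_raw(r2), skew_config(n_draws = 2000, seed = 11))
  d <- group_difference(g1, g2)
  expect_lt(d$ci[1], 0)
  expect_gt(d$ci[2], 0)
})

test_that("skew cohort filter keeps only the configured birth window", {
  cen <- make_census(
    census_row("a", sex = "M", birth_year = 1905L),
    census_row("b", sex = "M", birth_year = 1930L),
    census_row("c", sex = "M", birth_year = 1949L),
    census_row("d", sex = "M", birth_year = 1960L)
  )
  si <- skew_input(cen, sex = "M")
  expect_setequal(si$id, c("b", "c"))
  expect_equal(si$N, 2L)
})

test_that("skew analysis returns tidy per-group results and contrasts", {
  cfg <- small_sim_config(seed = 3, male_k = c(A = 0.3, B = Inf))
  cen <- generate_population(cfg)
  out <- suppressWarnings(
    skew_analysis(cen, skew_cfg = skew_config(n_draws = 500, seed = 5)))
  expect_true(all(c("ethnicity", "sex", "N", "R", "M_point",
                    "posterior_mean", "ci_low", "ci_high") %in%
                    names(out$results)))
  expect_true(nrow(out$results) >= 2)
  expect_true(all(out$results$ci_low <= out$results$ci_high))
  expect_true(!is.null(out$contrasts))
})
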