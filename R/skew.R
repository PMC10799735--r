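# Multinomial reproductive-skew indices.
#
# Nonacs' B compares observed reproductive shares p_i = r_i / R with
# exposure shares t_i = tau_i / sum(tau), subtracting the expectation of
# the squared deviation under multinomial allocation of the R offspring
# with probabilities t:
#
#   B = sum_i (p_i - t_i)^2 - (1 - sum_i t_i^2) / R
#
# so E[B] = 0 when reproduction is allocated at random given exposure.
# The M index normalizes B by its value under complete monopoly (the
# individual with the smallest expected share holding all R offspring),
# giving an index that is 1 under full monopoly, has null expectation ~0,
# and is comparable across group sizes and mean fertilities. Posterior
# uncertainty comes from a Dirichlet model on the reproductive shares:
# p ~ Dirichlet(r_1 + alpha, ..., r_N + alpha), with M recomputed per draw
# under the same null correction and normalization.

#' Reproductive exposure (years at risk)
#'
#' Years an individual spent inside the sex-specific reproductive window
#' (from `maturity_age` to `terminal_age_f`/`terminal_age_m`), truncated at
#' death or at the survey.
#'
#' @param birth_year,death_year,sex Vectors describing the individuals
#'   (`death_year` `NA` when alive at the survey).
#' @param config A [survey_config()].
#' @return Numeric vector of exposures in years (0 for those who died
#'   before maturity).
#' @export
reproductive_exposure <- function(birth_year, death_year, sex,
                                  config = survey_config()) {
  terminal <- ifelse(sex == "M", config$terminal_age_m, config$terminal_age_f)
  start <- birth_year + config$maturity_age
  end <- pmin(birth_year + terminal,
              ifelse(is.na(death_year), config$survey_year, death_year),
              config$survey_year)
  pmax(end - start, 0)
}

#' Assemble skew input for one group
#'
#' Collects per-individual surviving-offspring counts and exposures for a
#' (typically ethnicity x sex) subgroup of the completed-fertility cohort.
#' Individuals outside `config$skew_cohort` birth years are excluded, as
#' are individuals with non-positive exposure (with a warning).
#'
#' @param census A `census` data frame.
#' @param ethnicity,sex Subgroup selectors (either may be `NULL` to skip).
#' @param config A [survey_config()].
#' @param equal_exposure If `TRUE`, set all exposures to 1 (the
#'   completed-cohort simplification in which every member had a full
#'   reproductive career).
#' @param group Group label; default built from the selectors.
#' @return Object of class `skew_input`: list with `group`, `r`
#'   (offspring counts), `tau` (exposures), `id`, and the derived `N`, `R`,
#'   `t` (normalized exposure shares).
#' @export
skew_input <- function(census, ethnicity = NULL, sex = NULL,
                       config = survey_config(), equal_exposure = FALSE,
                       group = NULL) {
  keep <- !is.na(census$birth_year) &
    census$birth_year >= config$skew_cohort[1] &
    census$birth_year <= config$skew_cohort[2]
  if (!is.null(ethnicity)) keep <- keep & census$ethnicity %in% ethnicity
  if (!is.null(sex)) keep <- keep & census$sex %in% sex
  sub <- census[which(keep), , drop = FALSE]
  if (nrow(sub) == 0) stop("no individuals in the skew cohort for this group")
  rep_tab <- derive_reproduction(census, ego = sub$person_id, config = config)
  tau <- if (equal_exposure) {
    rep(1, nrow(sub))
  } else {
    reproductive_exposure(sub$birth_year, sub$death_year, sub$sex, config)
  }
  pos <- tau > 0
  if (any(!pos)) {
    warning(sum(!pos), " individual(s) with non-positive exposure excluded")
  }
  r <- rep_tab$offspring_surviving[pos]
  tau <- tau[pos]
  if (is.null(group)) group <- paste(c(ethnicity, sex), collapse = " ")
  structure(list(
    group = group, id = sub$person_id[pos],
    r = as.integer(r), tau = as.numeric(tau),
    N = sum(pos), R = sum(r), t = tau / sum(tau)
  ), class = "skew_input")
}

#' Build a skew input from raw counts and exposures
#'
#' @param r Integer vector of offspring counts.
#' @param tau Numeric vector of exposures (default equal).
#' @param group Group label.
#' @return A `skew_input`.
#' @export
skew_input_raw <- function(r, tau = rep(1, length(r)), group = "group") {
  stopifnot(length(r) == length(tau), all(r >= 0), all(tau > 0))
  structure(list(
    group = group, id = as.character(seq_along(r)),
    r = as.integer(r), tau = as.numeric(tau),
    N = length(r), R = sum(r), t = tau / sum(tau)
  ), class = "skew_input")
}

#' @export
print.skew_input <- function(x, ...) {
  cat(sprintf("<skew_input> %s: N = %d, R = %d offspring\n",
              x$group, x$N, x$R))
  invisible(x)
}

#' Nonacs' B skew index
#'
#' `B = sum((p - t)^2) - (1 - sum(t^2)) / R` with `p = r / R`. Zero in
#' expectation under multinomial allocation of the R offspring with
#' probabilities t; positive when reproduction is more concentrated than
#' chance, negative when more even.
#'
#' @param input A [skew_input()].
#' @return The B value.
#' @export
nonacs_B <- function(input) {
  if (input$R < 1) stop("no offspring in group (R = 0); B undefined")
  p <- input$r / input$R
  sum((p - input$t)^2) - (1 - sum(input$t^2)) / input$R
}

.m_from_shares <- function(p, t, R) {
  S <- sum((p - t)^2)
  null_term <- (1 - sum(t^2)) / R
  # full monopoly by the individual with the smallest expected share
  S_max <- max((1 - t)^2 - t^2) + sum(t^2)
  B_max <- S_max - null_term
  (S - null_term) / B_max
}

#' Multinomial skew index M (point estimate)
#'
#' B normalized by its full-monopoly maximum: `M = B / B_max`, where
#' `B_max` is B evaluated at the allocation giving every offspring to the
#' individual with the smallest exposure share. M = 1 under that monopoly,
#' M has expectation near 0 under the multinomial null, and the
#' normalization makes it comparable across group sizes and fertilities.
#'
#' @param input A [skew_input()].
#' @return The M value (at most 1).
#' @export
m_index <- function(input) {
  if (input$N < 2) stop("skew undefined for a single individual")
  if (input$R < 1) stop("no offspring in group (R = 0); M undefined")
  .m_from_shares(input$r / input$R, input$t, input$R)
}

#' Skew estimation configuration
#'
#' @param prior_alpha Dirichlet concentration added per individual
#'   (default 1, a flat prior on the reproductive shares).
#' @param n_draws Number of posterior draws (default 4000).
#' @param ci_level Probability mass of the equal-tailed interval
#'   (default 0.90).
#' @param seed Integer seed.
#' @return List of class `skew_config`.
#' @export
skew_config <- function(prior_alpha = 1, n_draws = 4000L, ci_level = 0.90,
                        seed = NULL) {
  stopifnot(prior_alpha > 0, n_draws >= 100, ci_level > 0, ci_level < 1)
  structure(list(prior_alpha = prior_alpha, n_draws = as.integer(n_draws),
                 ci_level = ci_level, seed = seed), class = "skew_config")
}

#' Posterior draws of the M index
#'
#' Dirichlet posterior on the reproductive shares,
#' `p ~ Dirichlet(r + alpha)`, with the skew functional recomputed for
#' each draw. Each draw's squared-deviation statistic `S(p)` is centred
#' with the exact expectation of that statistic when reproduction is
#' random given exposure (offspring multinomial with probabilities t,
#' shares then drawn from the resulting Dirichlet posterior), so that
#' posterior draws from null-generated data straddle zero regardless of
#' group size, total fertility or prior strength. Without this centring,
#' the posterior's own sampling variance and prior shrinkage shift the
#' draws off zero by an amount that differs between groups of different N
#' and R, which would bias group contrasts.
#'
#' @param input A [skew_input()].
#' @param config A [skew_config()].
#' @return Object of class `skew_result`: `group`, `N`, `R`, `M_point`,
#'   `draws`, `mean`, `ci` (equal-tailed), `ci_level`, `seed`.
#' @export
m_posterior <- function(input, config = skew_config()) {
  if (input$N < 2) stop("skew undefined for a single individual")
  if (input$R < 1) stop("no offspring in group (R = 0)")
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$n_draws
  alpha <- config$prior_alpha
  shape <- input$r + alpha
  gm <- matrix(stats::rgamma(G * input$N, shape = rep(shape, each = G)),
               nrow = G)
  p <- gm / rowSums(gm)
  t <- input$t
  R <- input$R
  N <- input$N
  # E[S(p)] under r ~ Multinomial(R, t), p ~ Dirichlet(r + alpha):
  # the posterior-mean deviation term plus the Dirichlet variance term
  A <- R + N * alpha
  u <- (R * t + alpha) / A
  c0 <- sum(R * t * (1 - t) + alpha^2 * (1 - N * t)^2) / A^2 +
    (1 - sum(u^2) - sum(R * t * (1 - t)) / A^2) / (A + 1)
  S_max <- max((1 - t)^2 - t^2) + sum(t^2)
  S <- rowSums((p - matrix(t, G, N, byrow = TRUE))^2)
  draws <- (S - c0) / (S_max - c0)
  a <- (1 - config$ci_level) / 2
  structure(list(
    group = input$group, N = input$N, R = input$R,
    M_point = m_index(input),
    draws = draws,
    mean = mean(draws),
    ci = stats::quantile(draws, c(a, 1 - a), names = FALSE),
    ci_level = config$ci_level,
    seed = config$seed
  ), class = "skew_result")
}

#' @export
print.skew_result <- function(x, ...) {
  cat(sprintf(
    "<skew_result> %s: N = %d, R = %d\n  M = %.3f, posterior mean %.3f, %d%% CI (%.3f, %.3f)\n",
    x$group, x$N, x$R, x$M_point, x$mean, round(100 * x$ci_level),
    x$ci[1], x$ci[2]))
  invisible(x)
}

#' Posterior contrast between two groups' skew
#'
#' Draw-wise difference `M_a - M_b`, pairing draws by index (the shorter
#' draw vector is recycled if lengths differ; the groups are independent so
#' pairing is arbitrary).
#'
#' @param a,b [m_posterior()] results.
#' @param ci_level Interval level; must match both inputs.
#' @return List of class `skew_contrast`: `mean`, `ci`, `draws`, group
#'   labels.
#' @export
group_difference <- function(a, b, ci_level = 0.90) {
  if (abs(a$ci_level - ci_level) > 1e-12 || abs(b$ci_level - ci_level) > 1e-12) {
    stop("ci_level mismatch between the two skew results")
  }
  G <- max(length(a$draws), length(b$draws))
  d <- rep_len(a$draws, G) - rep_len(b$draws, G)
  al <- (1 - ci_level) / 2
  structure(list(
    group_a = a$group, group_b = b$group,
    mean = mean(d),
    ci = stats::quantile(d, c(al, 1 - al), names = FALSE),
    ci_level = ci_level,
    draws = d
  ), class = "skew_contrast")
}

#' @export
print.skew_contrast <- function(x, ...) {
  cat(sprintf(
    "<skew_contrast> %s - %s: mean difference = %.2f, %d%% CI = (%.2f, %.2f)\n",
    x$group_a, x$group_b, x$mean, round(100 * x$ci_level),
    x$ci[1], x$ci[2]))
  invisible(x)
}

#' Skew analysis over all ethnicity-by-sex groups
#'
#' Runs [m_posterior()] for each (ethnicity, sex) cell of the completed
#' cohort and computes the within-sex between-ethnicity contrasts.
#'
#' @param census A `census` data frame.
#' @param ethnicities Groups to compare (default the census ethnicities
#'   other than "Other").
#' @param config A [survey_config()].
#' @param skew_cfg A [skew_config()].
#' @return List with `results` (tidy data frame), `contrasts` (tidy data
#'   frame), and the underlying `skew_result` objects.
#' @export
skew_analysis <- function(census, ethnicities = NULL,
                          config = survey_config(),
                          skew_cfg = skew_config(seed = 1L)) {
  if (is.null(ethnicities)) {
    ethnicities <- setdiff(unique(census$ethnicity), c(NA, "Other"))
  }
  objs <- list()
  rows <- list()
  for (eth in ethnicities) for (sx in c("F", "M")) {
    key <- paste(eth, sx)
    cfg_g <- skew_cfg
    cfg_g$seed <- if (is.null(skew_cfg$seed)) NULL else
      (as.integer(skew_cfg$seed) + 7919L * length(objs)) %% .Machine$integer.max
    res <- tryCatch({
      m_posterior(skew_input(census, eth, sx, config), cfg_g)
    }, error = function(e) e)
    if (inherits(res, "error")) next
    objs[[key]] <- res
    rows[[key]] <- data.frame(
      ethnicity = eth, sex = sx, N = res$N, R = res$R,
      M_point = res$M_point, posterior_mean = res$mean,
      ci_low = res$ci[1], ci_high = res$ci[2],
      seed = if (is.null(cfg_g$seed)) NA_integer_ else cfg_g$seed,
      stringsAsFactors = FALSE)
  }
  contr <- list()
  if (length(ethnicities) >= 2) {
    pairs <- utils::combn(ethnicities, 2, simplify = FALSE)
    for (sx in c("F", "M")) for (pr in pairs) {
      ka <- paste(pr[1], sx); kb <- paste(pr[2], sx)
      if (is.null(objs[[ka]]) || is.null(objs[[kb]])) next
      d <- group_difference(objs[[ka]], objs[[kb]], skew_cfg$ci_level)
      contr[[paste(ka, "vs", kb)]] <- data.frame(
        sex = sx, group_a = pr[1], group_b = pr[2],
        mean_diff = d$mean, ci_low = d$ci[1], ci_high = d$ci[2],
        excludes_zero = d$ci[1] > 0 | d$ci[2] < 0,
        stringsAsFactors = FALSE)
    }
  }
  list(
    results = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL,
    contrasts = if (length(contr)) do.call(rbind, c(contr, make.row.names = FALSE)) else NULL,
    objects = objs
  )
}
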