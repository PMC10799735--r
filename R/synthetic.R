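# Synthetic census generation with known ground truth.
#
# The generator emulates the study system: two co-residing ethnic groups
# with contrasting kinship systems (duolocal/matrilineal vs patrilocal),
# occasional intermarriage, multi-generation pedigrees, binary and ordinal
# cultural traits whose adoption is correlated among close kin, and
# per-male fertility heterogeneity (gamma-distributed mating weights) that
# plants a controllable amount of reproductive skew. Female fertility is
# assigned by pairing - every child has both parents - so male skew arises
# from heterogeneity in mating numbers.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a larger duolocal group
#' ("Mosuo", ~1700 surveyed adults) and a smaller patrilocal group
#' ("Han", ~700), three generations, pre-transition completed fertility
#' around four children per woman, high child survival, modest
#' intermarriage, and kin-correlated adoption of three binary language
#' traits plus an ordinal jeans trait.
#'
#' @param seed Integer seed; every draw in [generate_population()] follows
#'   from it.
#' @param groups Data frame with columns `name`, `kinship`
#'   (`"duolocal"`/`"patrilocal"`), `intermarriage_rate`,
#'   `n_founder_couples`.
#' @param n_generations Number of generations including the founders
#'   (default 3).
#' @param mean_offspring Named numeric: mean completed family size per
#'   woman, by group.
#' @param male_k Named numeric: gamma shape of male mating weights by
#'   group; `Inf` = homogeneous males (multinomial-null skew only);
#'   smaller values plant more male reproductive skew. The default gives
#'   the duolocal group exponentially distributed male mating weights
#'   (shape 1), emulating the stronger mate competition hypothesized for
#'   visiting-marriage men, and homogeneous males in the patrilocal group.
#' @param child_survival Probability a child survives to age 15.
#' @param pairing_rate Probability an adult woman partners (and can
#'   reproduce).
#' @param founder_birth Range of founder birth years.
#' @param survey_year Census year.
#' @param traits Named list per trait: `baseline` (named logit vector
#'   `c(F=..., M=...)` per group, see default), `cohort_slope` (logit per
#'   decade of birth after 1950), `beta_kin`, `beta_aff` (log-odds effect
#'   of the fraction of close kin / affines adopting).
#' @param missingness Per-cell missingness rate applied to trait columns.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       groups = data.frame(
                         name = c("Mosuo", "Han"),
                         kinship = c("duolocal", "patrilocal"),
                         intermarriage_rate = c(0.08, 0.15),
                         n_founder_couples = c(170L, 100L),
                         stringsAsFactors = FALSE),
                       n_generations = 3L,
                       mean_offspring = c(Mosuo = 4.0, Han = 4.0),
                       male_k = c(Mosuo = 1, Han = Inf),
                       child_survival = 0.93,
                       pairing_rate = 0.9,
                       founder_birth = c(1920L, 1940L),
                       survey_year = 2017L,
                       traits = default_trait_params(),
                       missingness = 0.01) {
  stopifnot(all(groups$kinship %in% c("duolocal", "patrilocal")),
            all(groups$intermarriage_rate >= 0),
            all(groups$intermarriage_rate <= 1),
            n_generations >= 2,
            child_survival > 0, child_survival <= 1,
            all(male_k > 0))
  structure(list(
    seed = as.integer(seed), groups = groups,
    n_generations = as.integer(n_generations),
    mean_offspring = mean_offspring, male_k = male_k,
    child_survival = child_survival, pairing_rate = pairing_rate,
    founder_birth = as.integer(founder_birth),
    survey_year = as.integer(survey_year),
    traits = traits, missingness = missingness
  ), class = "sim_config")
}

#' Default trait-adoption parameters
#'
#' Baselines chosen so realized adult adoption frequencies resemble the
#' study system (out-group language adoption higher in males, near-universal
#' mother-tongue retention in the larger group, jeans wearing around half);
#' kin and affinal effects of 1-2 log-odds units plant detectable
#' assortment.
#'
#' @return Named list of per-trait parameter lists.
#' @export
default_trait_params <- function() {
  list(
    mandarin = list(
      baseline = list(Mosuo = c(F = -1.2, M = -0.4), Han = c(F = -0.9, M = -0.5)),
      cohort_slope = 0.35, beta_kin = 1.0, beta_aff = 0.5),
    sichuan = list(
      baseline = list(Mosuo = c(F = 1.5, M = 2.3), Han = c(F = 3.2, M = 4.0)),
      cohort_slope = 0.1, beta_kin = 1.0, beta_aff = 0.5),
    naru = list(
      baseline = list(Mosuo = c(F = 3.5, M = 3.5), Han = c(F = -1.8, M = -1.2)),
      cohort_slope = 0, beta_kin = 2.0, beta_aff = 1.0),
    jeans = list(
      baseline = list(Mosuo = c(F = -0.4, M = 0.3), Han = c(F = -0.5, M = -0.2)),
      cohort_slope = 0.4, beta_kin = 1.0, beta_aff = 1.0)
  )
}

.logistic <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic census
#'
#' Builds a multi-generation two-group population: founder couples,
#' generation-by-generation pairing (within-group or intermarried, males
#' sampled proportionally to gamma mating weights), Poisson female
#' fertility, Bernoulli child survival, household assignment by kinship
#' rule (duolocal partners keep natal households, patrilocal wives move),
#' adult lifespans, then a single forward pass (in birth order) assigning
#' traits with adoption log-odds = baseline + cohort effect +
#' `beta_kin` x (fraction of close kin adopting) + `beta_aff` x (fraction
#' of affines adopting), and finally missingness.
#'
#' @param config A [sim_config()].
#' @return A validated `census` data frame; attribute `"sim_log"` holds
#'   realized summary statistics (sizes, intermarriage rate, fertility,
#'   trait frequencies).
#' @export
generate_population <- function(config = sim_config()) {
  set.seed(config$seed)
  gnames <- config$groups$name
  kinship <- stats::setNames(config$groups$kinship, gnames)
  imr <- stats::setNames(config$groups$intermarriage_rate, gnames)

  ids <- character(0); sex <- character(0); eth <- character(0)
  by <- integer(0); dy <- integer(0)
  mom <- character(0); dad <- character(0); par <- character(0)
  vil <- character(0); hh <- character(0); gen <- integer(0)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("P%06d", counter)
  }

  # founders
  for (g in gnames) {
    ncp <- config$groups$n_founder_couples[config$groups$name == g]
    for (i in seq_len(ncp)) {
      for (s in c("F", "M")) {
        id <- new_id()
        ids <- c(ids, id); sex <- c(sex, s); eth <- c(eth, g)
        by <- c(by, sample(seq(config$founder_birth[1],
                               config$founder_birth[2]), 1))
        dy <- c(dy, NA); mom <- c(mom, NA); dad <- c(dad, NA)
        par <- c(par, NA)
        vil <- c(vil, paste0(g, "_v", 1 + (i %% 3)))
        hh <- c(hh, paste0("H", id)); gen <- c(gen, 1L)
      }
    }
  }
  child_died <- logical(length(ids))  # died before 15
  cur_gen <- 1L
  while (cur_gen < config$n_generations) {
    gi <- which(gen == cur_gen & !child_died)
    fem <- gi[sex[gi] == "F"]
    mal <- gi[sex[gi] == "M"]
    if (length(fem) == 0 || length(mal) == 0) {
      stop("no eligible partners in generation ", cur_gen)
    }
    # per-male mating weight: gamma(shape k, mean 1); Inf -> equal
    wts <- numeric(length(mal))
    for (g in gnames) {
      sel <- eth[mal] == g
      k <- config$male_k[[g]]
      wts[sel] <- if (is.infinite(k)) 1 else
        stats::rgamma(sum(sel), shape = k, rate = k)
    }
    for (f in fem) {
      if (cur_gen > 1L && stats::runif(1) > config$pairing_rate) next
      g <- eth[f]
      cross <- stats::runif(1) < imr[[g]]
      pool_groups <- if (cross) setdiff(gnames, g) else g
      pool <- which(eth[mal] %in% pool_groups)
      if (length(pool) == 0) next
      m <- mal[if (length(pool) == 1) pool else
        sample(pool, 1, prob = wts[pool])]
      par[f] <- ids[m]
      if (is.na(par[m])) par[m] <- ids[f]
      husband <- m
      # patrilocal: wife joins husband's household
      if (kinship[[eth[husband]]] == "patrilocal") {
        hh[f] <- hh[husband]
      }
      nk <- stats::rpois(1, config$mean_offspring[[g]])
      if (nk == 0) next
      base_by <- max(by[f], by[husband])
      kid_by <- sort(base_by + sample(18:38, nk, replace = TRUE))
      for (kb in kid_by) {
        id <- new_id()
        s <- if (stats::runif(1) < 0.5) "F" else "M"
        # child joins mother's group under duolocal (matrilineal) descent,
        # father's under patrilocal
        cg <- if (kinship[[g]] == "duolocal") g else eth[husband]
        ids <- c(ids, id); sex <- c(sex, s); eth <- c(eth, cg)
        by <- c(by, kb); dy <- c(dy, NA)
        mom <- c(mom, ids[f]); dad <- c(dad, ids[husband]); par <- c(par, NA)
        vil <- c(vil, vil[if (kinship[[g]] == "duolocal") f else husband])
        hh <- c(hh, hh[if (kinship[[g]] == "duolocal") f else husband])
        gen <- c(gen, cur_gen + 1L)
        died <- stats::runif(1) > config$child_survival
        child_died <- c(child_died, died)
        if (died) {
          d <- kb + sample(0:14, 1)
          # deaths after the census are unknown to it
          dy[length(dy)] <- if (d < config$survey_year) d else NA_integer_
        }
      }
    }
    cur_gen <- cur_gen + 1L
  }

  n <- length(ids)
  # adult lifespans for those who survived childhood
  for (i in which(!child_died)) {
    life <- max(45, round(stats::rnorm(1, 75, 10)))
    d <- by[i] + life
    dy[i] <- if (d < config$survey_year) d else NA_integer_
  }
  alive <- is.na(dy)
  age <- config$survey_year - by
  surveyed <- as.integer(alive & age >= 15)

  census <- data.frame(
    person_id = ids, sex = sex, ethnicity = eth,
    birth_year = as.integer(by), death_year = as.integer(dy),
    mother_id = mom, father_id = dad, partner_id = par,
    village = vil, household_id = hh,
    education_years = NA_integer_, occupation = NA_integer_,
    income_level = NA_integer_, tourism = NA_integer_,
    mandarin = NA_integer_, sichuan = NA_integer_, naru = NA_integer_,
    jeans = NA_integer_, surveyed = surveyed,
    intermarriage = NA_integer_,
    stringsAsFactors = FALSE
  )

  # socio-demographic covariates for surveyed individuals
  sv <- which(surveyed == 1L)
  census$education_years[sv] <- pmin(16L, stats::rpois(
    length(sv), ifelse(census$sex[sv] == "M", 5.5, 4.0)))
  census$occupation[sv] <- stats::rbinom(
    length(sv), 1, ifelse(census$sex[sv] == "M", 0.35, 0.15))
  census$income_level[sv] <- sample(1:6, length(sv), replace = TRUE,
                                    prob = c(.1, .2, .3, .25, .1, .05))
  hh_tour <- stats::setNames(
    stats::rbinom(length(unique(census$household_id)), 1, 0.3),
    unique(census$household_id))
  census$tourism[sv] <- hh_tour[census$household_id[sv]]

  # intermarriage status of partnered individuals
  pidx <- match(census$partner_id, census$person_id)
  has_p <- !is.na(pidx)
  peth <- census$ethnicity[pidx]
  census$intermarriage[has_p] <- ifelse(
    census$ethnicity[has_p] == peth[has_p], 0L,
    ifelse(peth[has_p] == "Han", 1L, 2L))

  census <- .assign_traits(census, config)

  # missingness on trait cells of surveyed individuals
  if (config$missingness > 0) {
    for (col in c("mandarin", "sichuan", "naru", "jeans")) {
      drop <- sv[stats::runif(length(sv)) < config$missingness]
      census[[col]][drop] <- NA_integer_
    }
  }

  census <- as_census(census, config = survey_config(
    survey_year = config$survey_year))
  attr(census, "sim_log") <- .sim_log(census, config)
  census
}

# single forward pass in birth order; close kin = parents + full siblings
# with already-assigned values, affines = partner + partner's parents and
# full siblings with already-assigned values
.assign_traits <- function(census, config) {
  sv <- which(census$surveyed == 1L)
  ord <- sv[order(census$birth_year[sv], census$person_id[sv])]
  idx <- stats::setNames(seq_len(nrow(census)), census$person_id)
  mi <- match(census$mother_id, census$person_id)
  fi <- match(census$father_id, census$person_id)
  pi <- match(census$partner_id, census$person_id)
  sib_key <- ifelse(is.na(census$mother_id) | is.na(census$father_id), NA,
                    paste(census$mother_id, census$father_id))
  adopted <- list()
  for (tr in names(config$traits)) {
    adopted[[tr]] <- rep(NA_integer_, nrow(census))
  }
  decade <- (census$birth_year - 1950) / 10

  kin_of <- function(i) {
    kin <- c(mi[i], fi[i])
    if (!is.na(sib_key[i])) {
      kin <- c(kin, which(!is.na(sib_key) & sib_key == sib_key[i] &
                            seq_along(sib_key) != i))
    }
    kin[!is.na(kin)]
  }
  aff_of <- function(i) {
    p <- pi[i]
    if (is.na(p)) return(integer(0))
    aff <- c(p, mi[p], fi[p])
    if (!is.na(sib_key[p])) {
      aff <- c(aff, which(!is.na(sib_key) & sib_key == sib_key[p] &
                            seq_along(sib_key) != p))
    }
    aff[!is.na(aff)]
  }
  frac <- function(vals, set) {
    v <- vals[set]
    v <- v[!is.na(v)]
    if (length(v) == 0) 0 else mean(v)
  }

  for (i in ord) {
    kin <- kin_of(i)
    aff <- aff_of(i)
    for (tr in names(config$traits)) {
      tp <- config$traits[[tr]]
      b <- tp$baseline[[census$ethnicity[i]]]
      if (is.null(b)) b <- tp$baseline[[1]]
      eta <- b[[census$sex[i]]] + tp$cohort_slope * decade[i] +
        tp$beta_kin * frac(adopted[[tr]], kin) +
        tp$beta_aff * frac(adopted[[tr]], aff)
      adopted[[tr]][i] <- stats::rbinom(1, 1, .logistic(eta))
    }
  }
  census$mandarin[ord] <- adopted$mandarin[ord]
  census$sichuan[ord] <- adopted$sichuan[ord]
  census$naru[ord] <- adopted$naru[ord]
  # ordinal jeans from the binary high/low adoption state
  jl <- rep(NA_integer_, nrow(census))
  hi <- ord[adopted$jeans[ord] == 1L]
  lo <- ord[adopted$jeans[ord] == 0L]
  jl[hi] <- sample(3:4, length(hi), replace = TRUE)
  jl[lo] <- sample(1:2, length(lo), replace = TRUE, prob = c(0.45, 0.55))
  census$jeans <- jl
  census
}

.sim_log <- function(census, config) {
  sv <- census$surveyed == 1L
  im <- census$intermarriage[!is.na(census$intermarriage)]
  list(
    n_total = nrow(census),
    n_surveyed = sum(sv),
    n_surveyed_by_group = table(census$ethnicity[sv]),
    realized_intermarriage_rate = if (length(im)) mean(im > 0) else NA,
    mean_fertility = mean(tabulate(match(
      c(census$mother_id, census$father_id), census$person_id))) / 2,
    trait_frequencies = vapply(
      c("mandarin", "sichuan", "naru"),
      function(tr) mean(census[[tr]][sv], na.rm = TRUE), numeric(1)),
    seed = config$seed
  )
}

#' Minimal census reproducing planted per-cell counts
#'
#' Builds the smallest census whose [comparison_table()] reproduces a
#' specified set of adoption counts exactly: for each (ethnicity, sex)
#' cell, `max(n)` surveyed unrelated adults are created, and for each
#' trait block the first `k` get the trait, the next `n - k` do not, and
#' any remainder is missing. The two jeans binarizations are planted as a
#' single ordinal column (level 3 for high wearers, 2 for
#' rarely-wearers, 1 for never), so both published collapsings come out
#' right; this requires both jeans blocks of a cell to share `n` and
#' `k_ever >= k_high`.
#'
#' @param counts Data frame with columns `block` (one of `"mandarin"`,
#'   `"sichuan"`, `"naru"`, `"jeans_high"`, `"jeans_ever"`), `ethnicity`,
#'   `sex`, `k`, `n`. Default: the published survey counts from
#'   [lugu_survey_counts()].
#' @param survey_year Census year written into birth years (all planted
#'   individuals are adults).
#' @return A validated `census` data frame.
#' @export
planted_counts_census <- function(counts = lugu_survey_counts()$counts,
                                  survey_year = 2017L) {
  stopifnot(all(c("block", "ethnicity", "sex", "k", "n") %in% names(counts)))
  if (any(counts$k > counts$n)) stop("planted k exceeds n")
  if (any(counts$k < 0 | counts$n < 0)) stop("planted counts must be >= 0")
  rows <- list()
  for (eth in unique(counts$ethnicity)) {
    for (sx in unique(counts$sex[counts$ethnicity == eth])) {
      cell <- counts[counts$ethnicity == eth & counts$sex == sx, ]
      n_max <- max(cell$n)
      df <- data.frame(
        person_id = sprintf("%s_%s_%04d", eth, sx, seq_len(n_max)),
        sex = sx, ethnicity = eth,
        birth_year = 1980L, death_year = NA_integer_,
        mother_id = NA_character_, father_id = NA_character_,
        partner_id = NA_character_,
        village = paste0(eth, "_v1"), household_id = paste0(eth, "_", sx),
        education_years = 0L, occupation = 0L, income_level = 1L,
        tourism = 0L,
        mandarin = NA_integer_, sichuan = NA_integer_, naru = NA_integer_,
        jeans = NA_integer_, surveyed = 1L, intermarriage = NA_integer_,
        stringsAsFactors = FALSE)
      plant_binary <- function(k, n) {
        v <- rep(NA_integer_, n_max)
        v[seq_len(n)] <- c(rep(1L, k), rep(0L, n - k))
        v
      }
      for (tr in c("mandarin", "sichuan", "naru")) {
        cc <- cell[cell$block == tr, ]
        if (nrow(cc) == 1) df[[tr]] <- plant_binary(cc$k, cc$n)
      }
      ch <- cell[cell$block == "jeans_high", ]
      ce <- cell[cell$block == "jeans_ever", ]
      if (nrow(ch) == 1 && nrow(ce) == 1) {
        if (ch$n != ce$n) stop("jeans_high and jeans_ever must share n")
        if (ce$k < ch$k) stop("jeans_ever k must be >= jeans_high k")
        v <- rep(NA_integer_, n_max)
        v[seq_len(ce$n)] <- c(rep(3L, ch$k), rep(2L, ce$k - ch$k),
                              rep(1L, ce$n - ce$k))
        df$jeans <- v
      } else if (nrow(ch) == 1) {
        df$jeans <- ifelse(is.na(plant_binary(ch$k, ch$n)), NA_integer_,
                           ifelse(plant_binary(ch$k, ch$n) == 1L, 3L, 1L))
      }
      rows[[paste(eth, sx)]] <- df
    }
  }
  as_census(do.call(rbind, c(rows, make.row.names = FALSE)),
            config = survey_config(survey_year = survey_year))
}
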