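# Fixture builders shared across test files. All fixtures are constructed
# in code; no data files.

# A census row with sensible defaults; override any field by name.
census_row <- function(person_id, ...) {
  row <- list(
    person_id = person_id, sex = "F", ethnicity = "Mosuo",
    birth_year = 1980L, death_year = NA_integer_,
    mother_id = NA_character_, father_id = NA_character_,
    partner_id = NA_character_, village = "v1", household_id = "h1",
    education_years = 0L, occupation = 0L, income_level = 1L, tourism = 0L,
    mandarin = NA_integer_, sichuan = NA_integer_, naru = NA_integer_,
    jeans = NA_integer_, surveyed = 1L, intermarriage = NA_integer_
  )
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

make_census <- function(..., validate = TRUE) {
  as_census(do.call(rbind, list(...)), validate = validate)
}

# mother, father, and their children; extra rows appended as-is
trio_census <- function() {
  make_census(
    census_row("mom", sex = "F", birth_year = 1950L),
    census_row("dad", sex = "M", birth_year = 1948L),
    census_row("kid", sex = "F", birth_year = 1975L,
               mother_id = "mom", father_id = "dad")
  )
}

# random valid pedigree as a plain data frame (ids "i1".."in"), founders
# first so parent links always point backwards
random_pedigree_df <- function(n, seed) {
  set.seed(seed)
  sex <- c("F", "M", "F", "M", sample(c("F", "M"), max(0, n - 4), TRUE))
  mother <- rep(NA_character_, n)
  father <- rep(NA_character_, n)
  for (i in 5:n) {
    if (stats::runif(1) < 0.25) next  # founder
    fem <- which(sex[1:(i - 1)] == "F")
    mal <- which(sex[1:(i - 1)] == "M")
    if (length(fem) == 0 || length(mal) == 0) next
    mother[i] <- paste0("i", sample(fem, 1))
    father[i] <- paste0("i", sample(mal, 1))
  }
  data.frame(person_id = paste0("i", 1:n), sex = sex,
             mother_id = mother, father_id = father,
             stringsAsFactors = FALSE)
}

# Gene-dropping estimate of the additive relationship matrix: drop unique
# founder alleles through the pedigree n_drops times and average IBD
# sharing. Returns list(mean = matrix, se = matrix of Monte-Carlo SEs).
gene_drop_relatedness <- function(ped_df, n_drops = 10000, seed = 1) {
  set.seed(seed)
  ped <- build_pedigree(ped_df)
  n <- length(ped$id)
  A1 <- matrix(0L, n_drops, n)  # maternal allele
  A2 <- matrix(0L, n_drops, n)  # paternal allele
  next_allele <- 0L
  for (i in seq_len(n)) {
    m <- ped$mother[i]; f <- ped$father[i]
    if (is.na(m)) {
      next_allele <- next_allele + 1L
      A1[, i] <- next_allele
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A1[, i] <- ifelse(pick, A1[, m], A2[, m])
    }
    if (is.na(f)) {
      next_allele <- next_allele + 1L
      A2[, i] <- next_allele
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A2[, i] <- ifelse(pick, A1[, f], A2[, f])
    }
  }
  mean_mat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se_mat <- mean_mat
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      draws <- 1 + (A1[, i] == A2[, i])  # 1 + inbreeding indicator
    } else {
      draws <- 0.5 * ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                        (A2[, i] == A1[, j]) + (A2[, i] == A2[, j]))
    }
    mean_mat[i, j] <- mean_mat[j, i] <- mean(draws)
    se_mat[i, j] <- se_mat[j, i] <- stats::sd(draws) / sqrt(n_drops)
  }
  list(mean = mean_mat, se = se_mat)
}

# Build a labelled undirected graph directly (bypassing build_network)
# from an edge list and a label vector named by node.
labelled_graph <- function(edges, labels) {
  nodes <- names(labels)
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = nodes, label_value = unname(labels),
                          stringsAsFactors = FALSE))
}

# Exhaustive node-label permutation null: every distinct assignment of the
# label multiset to nodes, with its multiplicity-weighted probability.
# Returns the vector of r values over all n! permutations (by weighting
# distinct assignments) for graphs small enough to enumerate.
exhaustive_null <- function(g) {
  labels <- igraph::V(g)$label_value
  n <- length(labels)
  ones <- sum(labels == 1)
  sets <- utils::combn(n, ones, simplify = FALSE)
  r <- numeric(length(sets))
  for (k in seq_along(sets)) {
    lab <- rep(0L, n)
    lab[sets[[k]]] <- 1L
    r[k] <- tryCatch(nominal_assortativity(g, labels = lab),
                     error = function(e) NA_real_)
  }
  r
}

# Small fast simulation config for calibration/power tests.
small_sim_config <- function(seed, male_k = c(A = Inf, B = Inf),
                             beta_kin = 1, beta_aff = 0.5,
                             n_couples = 30L, intermarriage = 0.1) {
  tr <- default_trait_params()
  for (nm in names(tr)) {
    tr[[nm]]$beta_kin <- beta_kin
    tr[[nm]]$beta_aff <- beta_aff
    tr[[nm]]$baseline <- list(A = c(F = 0, M = 0), B = c(F = 0, M = 0))
    tr[[nm]]$cohort_slope <- 0
  }
  sim_config(
    seed = seed,
    groups = data.frame(
      name = c("A", "B"), kinship = c("duolocal", "patrilocal"),
      intermarriage_rate = c(intermarriage, intermarriage),
      n_founder_couples = c(n_couples, n_couples),
      stringsAsFactors = FALSE),
    mean_offspring = c(A = 3.5, B = 3.5),
    male_k = male_k,
    traits = tr,
    missingness = 0
  )
}
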