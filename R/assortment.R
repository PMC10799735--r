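# Categorical assortativity and its node-label permutation null.
#
# The coefficient is Newman's nominal assortativity computed from the
# symmetrized mixing matrix e (fractions of edge ends joining label g to
# label h): r = (sum_g e_gg - sum_g a_g^2) / (1 - sum_g a_g^2), where
# a_g = sum_h e_gh. r = 1 for perfect within-label mixing; negative values
# indicate disassortative mixing (a star of 1s around a 0 hub gives -1).

#' Mixing matrix of node labels over edges
#'
#' @param network An undirected [igraph::graph] with a `label_value` vertex
#'   attribute.
#' @param labels Optional vector of labels to use instead of the stored
#'   vertex attribute (in vertex order).
#' @return Symmetric matrix of edge-end fractions summing to 1.
#' @export
mixing_matrix <- function(network, labels = NULL) {
  if (is.null(labels)) labels <- igraph::V(network)$label_value
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  lv <- sort(unique(labels))
  la <- factor(labels[ends[, 1]], levels = lv)
  lb <- factor(labels[ends[, 2]], levels = lv)
  tab <- table(la, lb)
  e <- (tab + t(tab)) / (2 * sum(tab))
  unclass(as.matrix(e))
}

.assort_from_mixing <- function(e) {
  a <- rowSums(e)
  denom <- 1 - sum(a^2)
  if (denom <= .Machine$double.eps) return(NA_real_)
  (sum(diag(e)) - sum(a^2)) / denom
}

#' Nominal (categorical) assortativity coefficient
#'
#' @param network A [build_network()] graph (or any undirected graph with a
#'   `label_value` vertex attribute).
#' @param labels Optional label vector overriding the vertex attribute.
#' @return The coefficient, in \[-1, 1\].
#' @export
nominal_assortativity <- function(network, labels = NULL) {
  if (igraph::ecount(network) < 1) stop("network has no edges")
  e <- mixing_matrix(network, labels)
  r <- .assort_from_mixing(e)
  if (is.na(r)) {
    stop("assortativity undefined: all edge ends carry a single label ",
         "[ERR_SINGLE_LABEL]")
  }
  r
}

#' Node-label permutation test of assortment
#'
#' Shuffles the trait labels across all nodes of the fixed graph (egos and
#' alters jointly, preserving label counts) and compares the observed
#' assortativity with the permutation null. The p-value is one-sided
#' (upper tail: is the observed assortment higher than chance?) with the
#' add-one correction `p = (1 + #(r_null >= r_obs)) / (1 + n_perm)`, so it
#' is never exactly zero. Rare degenerate shuffles for which the
#' coefficient is undefined are redrawn.
#'
#' @param network A [build_network()] graph.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `assortment_result`: list with `r_obs`,
#'   `null_draws`, `p_value`, `n_perm`, `seed`, plus the network's trait,
#'   tie type and ego group and the node/edge counts.
#' @export
permutation_test <- function(network, n_perm = 1000L, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  r_obs <- nominal_assortativity(network)
  labels <- igraph::V(network)$label_value
  if (!is.null(seed)) set.seed(seed)
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  # integer label codes for a fast tabulated mixing matrix
  lv <- sort(unique(labels))
  L <- length(lv)
  codes <- match(labels, lv)
  e1 <- ends[, 1]; e2 <- ends[, 2]
  two_m <- 2 * length(e1)
  null_draws <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    r <- NA_real_
    tries <- 0L
    while (is.na(r)) {
      perm <- sample(codes)
      la <- perm[e1]; lb <- perm[e2]
      tab <- matrix(tabulate(la + L * (lb - 1L), nbins = L * L), L, L)
      e <- (tab + t(tab)) / two_m
      r <- .assort_from_mixing(e)
      tries <- tries + 1L
      if (tries > 100L) stop("permutation null degenerate: labels nearly constant")
    }
    null_draws[b] <- r
  }
  structure(list(
    r_obs = r_obs,
    null_draws = null_draws,
    p_value = (1 + sum(null_draws >= r_obs)) / (1 + n_perm),
    n_perm = as.integer(n_perm),
    seed = seed,
    trait = igraph::graph_attr(network, "trait"),
    tie_type = igraph::graph_attr(network, "tie_type"),
    ego_group = igraph::graph_attr(network, "ego_group"),
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    statistic = "nominal assortativity (Newman)"
  ), class = "assortment_result")
}

#' Five-number summary of the permutation null
#'
#' Quantiles and 1.5 x IQR whisker bounds of the null draws, following the
#' boxplot convention used to display permutation nulls: whiskers extend to
#' the most extreme draws within 1.5 interquartile ranges of the box.
#'
#' @param result An [permutation_test()] result.
#' @return Named numeric vector: `min`, `q1`, `median`, `q3`, `max`,
#'   `whisker_low`, `whisker_high`.
#' @export
null_summary <- function(result) {
  x <- result$null_draws
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  iqr <- q[4] - q[2]
  lo <- q[2] - 1.5 * iqr
  hi <- q[4] + 1.5 * iqr
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    whisker_low = min(x[x >= lo]), whisker_high = max(x[x <= hi]))
}

#' @export
print.assortment_result <- function(x, ...) {
  cat(sprintf("<assortment> %s | %s ties | trait %s\n",
              x$ego_group, x$tie_type, x$trait))
  cat(sprintf("  nodes %d, edges %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  r_obs = %.4f, null mean = %.4f, p = %.4g (%d permutations)\n",
              x$r_obs, mean(x$null_draws), x$p_value, x$n_perm))
  invisible(x)
}

#' Run the assortment grid over ego groups, tie types and traits
#'
#' Builds every (ethnicity x sex) x (biological, affinal) x trait network
#' and runs the permutation test on each, collecting tidy rows. Networks
#' that cannot be built (e.g. no qualifying egos) are skipped with a note
#' column.
#'
#' @param census A `census` data frame.
#' @param matrix A [relatedness_matrix()].
#' @param traits Traits to analyse (default all four).
#' @param ethnicities,sexes Ego groups (defaults from the census).
#' @param n_perm,seed Passed to [permutation_test()]; each cell gets a
#'   distinct deterministic sub-seed derived from `seed`.
#' @param jeans_scheme Jeans binarization.
#' @param config A [survey_config()].
#' @return Data frame with one row per analysed network: `ego_ethnicity`,
#'   `ego_sex`, `tie_type`, `trait`, `n_nodes`, `n_edges`, `r_obs`,
#'   `p_value`, `n_perm`, `seed`, null quantiles, `note`.
#' @export
assortment_grid <- function(census, matrix, traits = c("mandarin", "sichuan",
                                                       "naru", "jeans"),
                            ethnicities = NULL, sexes = c("F", "M"),
                            n_perm = 1000L, seed = 1L,
                            jeans_scheme = "high",
                            config = survey_config()) {
  if (is.null(ethnicities)) {
    ethnicities <- setdiff(unique(census$ethnicity), c(NA, "Other"))
  }
  rows <- list()
  cell <- 0L
  for (eth in ethnicities) for (sx in sexes) {
    for (tt in c("biological", "affinal")) for (tr in traits) {
      cell <- cell + 1L
      sub_seed <- (as.integer(seed) + 104729L * cell) %% .Machine$integer.max
      res <- tryCatch({
        g <- build_network(census, matrix, tie_type = tt,
                           ego_filter = list(ethnicity = eth, sex = sx),
                           trait = tr, jeans_scheme = jeans_scheme,
                           config = config)
        permutation_test(g, n_perm = n_perm, seed = sub_seed)
      }, error = function(err) err)
      if (inherits(res, "error")) {
        rows[[cell]] <- data.frame(
          ego_ethnicity = eth, ego_sex = sx, tie_type = tt, trait = tr,
          n_nodes = NA_integer_, n_edges = NA_integer_, r_obs = NA_real_,
          p_value = NA_real_, n_perm = as.integer(n_perm), seed = sub_seed,
          null_median = NA_real_, null_q1 = NA_real_, null_q3 = NA_real_,
          note = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        ns <- null_summary(res)
        rows[[cell]] <- data.frame(
          ego_ethnicity = eth, ego_sex = sx, tie_type = tt, trait = tr,
          n_nodes = res$n_nodes, n_edges = res$n_edges, r_obs = res$r_obs,
          p_value = res$p_value, n_perm = res$n_perm, seed = sub_seed,
          null_median = ns["median"], null_q1 = ns["q1"], null_q3 = ns["q3"],
          note = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
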