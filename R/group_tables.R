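# Trait proportions by ethnicity x sex and Pearson chi-square comparisons.

#' Pearson chi-square test for a 2x2 table
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected
#' counts from the margins; df = 1; upper-tail p-value. No Yates continuity
#' correction is applied (the correction is deliberately off so that
#' recomputed statistics match published uncorrected values).
#'
#' @param table A 2x2 matrix of non-negative counts, or missing if `k1,
#'   n1, k2, n2` are given.
#' @param k1,n1,k2,n2 Alternative interface: successes and totals for the
#'   two groups.
#' @return List of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `observed`.
#' @export
pearson_chi2 <- function(table = NULL, k1 = NULL, n1 = NULL, k2 = NULL,
                         n2 = NULL) {
  if (is.null(table)) {
    table <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  }
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) == 2)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    observed = table
  ), class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p %s\n",
              x$statistic, x$df, format_p(x$p_value)))
  invisible(x)
}

#' Format a p-value like a published table
#'
#' Three decimals, with values below 0.001 printed as `"<0.001"`.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Format a proportion cell as `"0.525 (387/737)"`
#'
#' @param k,n Successes and total.
#' @return Character scalar/vector.
#' @export
format_proportion <- function(k, n) {
  sprintf("%.3f (%d/%d)", k / n, as.integer(k), as.integer(n))
}

#' Parse a `"0.525 (387/737)"` proportion cell back to counts
#'
#' @param cell Character vector of formatted cells.
#' @return Data frame with columns `k` and `n`.
#' @export
parse_proportion <- function(cell) {
  m <- regmatches(cell, regexec("\\((\\d+)/(\\d+)\\)", cell))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("cannot parse proportion cell: ", cell[bad][1])
  data.frame(k = as.integer(vapply(m, `[`, "", 2)),
             n = as.integer(vapply(m, `[`, "", 3)))
}

.table_traits <- function() {
  data.frame(
    trait = c("mandarin", "sichuan", "naru", "jeans", "jeans"),
    scheme = c(NA, NA, NA, "high", "ever"),
    block = c("mandarin", "sichuan", "naru", "jeans_high", "jeans_ever"),
    stringsAsFactors = FALSE
  )
}

#' Trait comparison table by ethnicity and sex
#'
#' For each trait block (the three languages plus both jeans
#' binarizations): adoption proportions per ethnicity x sex among surveyed
#' adults, the within-ethnicity sex-difference chi-square, and the
#' within-sex between-ethnicity chi-square. Missing trait values are
#' dropped per trait (pairwise deletion), so denominators differ across
#' blocks. Cells whose 2x2 table is degenerate are marked, not fabricated.
#'
#' @param census A `census` data frame.
#' @param ethnicities The two groups to compare (default the first two
#'   non-"Other" ethnicities present).
#' @param config A [survey_config()].
#' @return List of class `comparison_table`: `counts` (tidy data frame of
#'   k/n per block x ethnicity x sex), `tests` (tidy data frame of all
#'   chi-square comparisons), `ethnicities`.
#' @export
comparison_table <- function(census, ethnicities = NULL,
                             config = survey_config()) {
  if (is.null(ethnicities)) {
    ethnicities <- setdiff(unique(census$ethnicity), c(NA, "Other"))
  }
  stopifnot(length(ethnicities) == 2)
  age <- age_at_survey(census, config)
  adult <- census$surveyed %in% 1L & !is.na(age) & age >= config$adult_age
  blocks <- .table_traits()
  counts <- list(); tests <- list()
  for (b in seq_len(nrow(blocks))) {
    tr <- blocks$trait[b]
    sch <- blocks$scheme[b]
    blk <- blocks$block[b]
    v <- if (tr == "jeans") trait_values(census, "jeans", sch) else census[[tr]]
    for (eth in ethnicities) for (sx in c("F", "M")) {
      sel <- adult & census$ethnicity %in% eth & census$sex %in% sx & !is.na(v)
      counts[[paste(blk, eth, sx)]] <- data.frame(
        block = blk, ethnicity = eth, sex = sx,
        k = sum(v[sel] == 1L), n = sum(sel), stringsAsFactors = FALSE)
    }
    cnt <- do.call(rbind, counts[paste(blk, rep(ethnicities, each = 2),
                                       rep(c("F", "M"), 2))])
    get_kn <- function(eth, sx) {
      r <- cnt[cnt$ethnicity == eth & cnt$sex == sx, ]
      c(r$k, r$n)
    }
    add_test <- function(comparison, a, bkn) {
      res <- tryCatch(pearson_chi2(k1 = a[1], n1 = a[2], k2 = bkn[1],
                                   n2 = bkn[2]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        data.frame(block = blk, comparison = comparison,
                   chi2 = NA_real_, p_value = NA_real_,
                   note = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        data.frame(block = blk, comparison = comparison,
                   chi2 = res$statistic, p_value = res$p_value, note = "",
                   stringsAsFactors = FALSE)
      }
    }
    for (eth in ethnicities) {
      tests[[paste(blk, "sex", eth)]] <- add_test(
        paste0("sex within ", eth), get_kn(eth, "M"), get_kn(eth, "F"))
    }
    for (sx in c("M", "F")) {
      tests[[paste(blk, "group", sx)]] <- add_test(
        paste0("group within ", sx),
        get_kn(ethnicities[1], sx), get_kn(ethnicities[2], sx))
    }
  }
  structure(list(
    counts = do.call(rbind, c(counts, make.row.names = FALSE)),
    tests = do.call(rbind, c(tests, make.row.names = FALSE)),
    ethnicities = ethnicities
  ), class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  for (blk in unique(x$counts$block)) {
    cat(blk, "\n")
    cc <- x$counts[x$counts$block == blk, ]
    for (i in seq_len(nrow(cc))) {
      cell <- if (cc$n[i] > 0) format_proportion(cc$k[i], cc$n[i]) else
        "unavailable"
      cat(sprintf("  %-8s %s  %s\n", cc$ethnicity[i], cc$sex[i], cell))
    }
    tt <- x$tests[x$tests$block == blk, ]
    for (i in seq_len(nrow(tt))) {
      if (is.na(tt$chi2[i])) {
        cat(sprintf("  %-18s %s\n", tt$comparison[i], tt$note[i]))
      } else {
        cat(sprintf("  %-18s chi2 = %.3f (p %s)\n", tt$comparison[i],
                    tt$chi2[i], format_p(tt$p_value[i])))
      }
    }
  }
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param tab A [comparison_table()].
#' @param counts_path,tests_path Output paths (either may be `NULL`).
#' @return Invisibly, `tab`.
#' @export
write_comparison_table <- function(tab, counts_path = NULL,
                                   tests_path = NULL) {
  if (!is.null(counts_path)) {
    cc <- tab$counts
    cc$cell <- ifelse(cc$n > 0, format_proportion(cc$k, cc$n), "")
    utils::write.csv(cc, counts_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(tests_path)) {
    utils::write.csv(tab$tests, tests_path, row.names = FALSE, quote = FALSE)
  }
  invisible(tab)
}

#' Published Lugu Lake trait-comparison counts
#'
#' The adoption counts (k adopters out of n respondents) per trait block,
#' ethnicity and sex from the published 2017 survey of Mosuo and Han
#' adults around Lugu Lake, together with the published chi-square
#' statistics for each comparison. Two published statistics (the jeans
#' often/always Mosuo sex difference and its female group difference) are
#' not reproducible from any 2x2 table of the published counts; they are
#' flagged `consistent = FALSE` and should be excluded from recomputation
#' checks.
#'
#' @return List with `counts` (block, ethnicity, sex, k, n) and
#'   `published_tests` (block, comparison, chi2_published, consistent).
#' @export
lugu_survey_counts <- function() {
  counts <- data.frame(
    block = rep(c("mandarin", "sichuan", "naru", "jeans_high", "jeans_ever"),
                each = 4),
    ethnicity = rep(c("Mosuo", "Mosuo", "Han", "Han"), 5),
    sex = rep(c("M", "F"), 10),
    k = c(387, 309, 146, 133,
          695, 834, 320, 370,
          724, 962, 103, 73,
          484, 506, 171, 175,
          583, 616, 211, 243),
    n = c(737, 982, 323, 380,
          737, 982, 323, 380,
          737, 982, 323, 380,
          727, 968, 321, 382,
          727, 968, 321, 382),
    stringsAsFactors = FALSE
  )
  published <- data.frame(
    block = c("mandarin", "mandarin", "mandarin", "mandarin",
              "sichuan", "sichuan", "sichuan", "sichuan",
              "naru", "naru", "naru", "naru",
              "jeans_high", "jeans_high", "jeans_high", "jeans_high",
              "jeans_ever", "jeans_ever", "jeans_ever", "jeans_ever"),
    comparison = rep(c("sex within Mosuo", "sex within Han",
                       "group within M", "group within F"), 5),
    chi2_published = c(77.378, 7.591, 4.799, 1.561,
                       37.619, 2.789, 12.57, 41.344,
                       0.166, 14.953, 576.453, 931.357,
                       59.803, 3.883, 16.816, 0.403,
                       54.979, 0.343, 25.358, 0.000),
    consistent = c(rep(TRUE, 12), FALSE, TRUE, TRUE, FALSE, rep(TRUE, 4)),
    stringsAsFactors = FALSE
  )
  list(counts = counts, published_tests = published)
}
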