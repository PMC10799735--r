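# A small extended family for network assembly: two maternal half-sibling
# egos sharing their mother, plus a partnered couple for affinal ties.
half_sib_census <- function() {
  make_census(
    census_row("m0", sex = "F", birth_year = 1950L, mandarin = 1L),
    census_row("f1", sex = "M", birth_year = 1948L, mandarin = 0L),
    census_row("f2", sex = "M", birth_year = 1946L, mandarin = 0L),
    census_row("s1", sex = "F", birth_year = 1975L, mother_id = "m0",
               father_id = "f1", mandarin = 1L),
    census_row("s2", sex = "F", birth_year = 1978L, mother_id = "m0",
               father_id = "f2", mandarin = 0L)
  )
}

test_that("union of ego stars deduplicates shared alters and edges", {
  cen <- half_sib_census()
  A <- relatedness_matrix(build_pedigree(cen))
  g <- build_network(cen, A, "biological",
                     ego_filter = list(ethnicity = "Mosuo", sex = "F"),
                     trait = "mandarin")
  # egos m0, s1, s2; half sibs are not close kin of each other, so the
  # graph is the star around m0 plus each ego's own parents
  expect_true(igraph::is_simple(g))
  nm <- igraph::V(g)$name
  expect_setequal(nm, c("m0", "f1", "f2", "s1", "s2"))
  # m0-s1 and s1-m0 found from both directions must be stored once
  expect_equal(igraph::ecount(g),
               nrow(unique(t(apply(igraph::ends(g, igraph::E(g)), 1, sort)))))
  expect_setequal(
    apply(igraph::ends(g, igraph::E(g)), 1, function(x)
      paste(sort(x), collapse = "-")),
    c("m0-s1", "m0-s2", "f1-s1", "f2-s2"))
})

test_that("egos without surveyed labelled kin are dropped", {
  cen <- make_census(
    census_row("m", sex = "F", birth_year = 1950L, mandarin = NA_integer_),
    census_row("e1", sex = "F", birth_year = 1975L, mother_id = "m",
               mandarin = 1L),
    census_row("m2", sex = "F", birth_year = 1950L, mandarin = 0L),
    census_row("e2", sex = "F", birth_year = 1976L, mother_id = "m2",
               mandarin = 1L)
  )
  A <- relatedness_matrix(build_pedigree(cen))
  g <- build_network(cen, A, "biological",
                     ego_filter = list(ethnicity = "Mosuo", sex = "F"),
                     trait = "mandarin")
  # e1's only kin has an unknown label, so e1 is not in the network
  expect_false("e1" %in% igraph::V(g)$name)
  expect_setequal(igraph::V(g)$name, c("e2", "m2"))
  # all endpoints carry a non-missing label
  expect_false(anyNA(igraph::V(g)$label_value))
})

test_that("affinal network on unpartnered egos errors as empty", {
  cen <- make_census(
    census_row("a", sex = "F", mandarin = 1L),
    census_row("b", sex = "F", mandarin = 0L)
  )
  A <- relatedness_matrix(build_pedigree(cen))
  expect_error(
    build_network(cen, A, "affinal",
                  ego_filter = list(ethnicity = "Mosuo", sex = "F"),
                  trait = "mandarin"),
    "no affinal ties")
  expect_error(
    build_network(cen, A, "biological",
                  ego_filter = list(ethnicity = "Han", sex = "F"),
                  trait = "mandarin"),
    "empty ego set")
})

test_that("kin adoption count is the number of neighbours with the trait", {
  cen <- half_sib_census()
  A <- relatedness_matrix(build_pedigree(cen))
  g <- build_network(cen, A, "biological",
                     ego_filter = list(ethnicity = "Mosuo", sex = "F"),
                     trait = "mandarin")
  # s1's neighbours are m0 (mandarin 1) and f1 (mandarin 0)
  expect_equal(kin_adoption_count(g, "s1"), 1L)
  # m0's neighbours are s1 (1) and s2 (0)
  expect_equal(kin_adoption_count(g, "m0"), 1L)
  expect_error(kin_adoption_count(g, "nobody"), "not in network")
})

test_that("edge weights are coded relatedness values", {
  cen <- half_sib_census()
  A <- relatedness_matrix(build_pedigree(cen))
  g <- build_network(cen, A, "biological",
                     ego_filter = list(ethnicity = "Mosuo", sex = "F"),
                     trait = "mandarin")
  expect_true(all(igraph::E(g)$weight >= 0.5 & igraph::E(g)$weight <= 1))
  expect_true(all(igraph::E(g)$tie_type == "biological"))
})
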