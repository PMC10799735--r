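test_that("pedigree builds topologically and rejects cycles", {
  ped <- build_pedigree(trio_census())
  kid <- match("kid", ped$id)
  expect_false(is.na(ped$mother[kid]))
  expect_false(is.na(ped$father[kid]))
  expect_true(kid > max(ped$mother[kid], ped$father[kid]))
  self <- data.frame(person_id = "x", mother_id = "x",
                     father_id = NA_character_, stringsAsFactors = FALSE)
  expect_error(build_pedigree(self), "cycle.*x")
  # three-generation chain sorts grandparent, parent, child in order
  chain <- data.frame(person_id = c("c", "p", "g"),
                      mother_id = c("p", "g", NA),
                      father_id = NA_character_, stringsAsFactors = FALSE)
  ped2 <- build_pedigree(chain)
  expect_equal(ped2$id, c("g", "p", "c"))
})

test_that("recursion reproduces textbook relatedness values", {
  # unrelated parents, two full sibs, one half sib through the father
  cen <- make_census(
    census_row("m", sex = "F", birth_year = 1940L),
    census_row("f", sex = "M", birth_year = 1940L),
    census_row("m2", sex = "F", birth_year = 1942L),
    census_row("s1", birth_year = 1965L, mother_id = "m", father_id = "f"),
    census_row("s2", birth_year = 1967L, mother_id = "m", father_id = "f"),
    census_row("h1", birth_year = 1969L, mother_id = "m2", father_id = "f")
  )
  A <- relatedness_matrix(build_pedigree(cen))
  expect_equal(A["m", "s1"], 0.5)   # parent-offspring
  expect_equal(A["s1", "s2"], 0.5)  # full siblings
  expect_equal(A["s1", "h1"], 0.25) # half siblings
  expect_equal(A["m", "f"], 0)      # founders unrelated
  expect_equal(unname(diag(A)), rep(1, 6))
})

test_that("full-sib mating inflates the diagonal and parent-child values", {
  ped <- data.frame(
    person_id = c("gm", "gf", "c1", "c2", "e"),
    sex = c("F", "M", "F", "M", "F"),
    mother_id = c(NA, NA, "gm", "gm", "c1"),
    father_id = c(NA, NA, "gf", "gf", "c2"),
    stringsAsFactors = FALSE)
  A <- relatedness_matrix(build_pedigree(ped))
  # hand-unrolled: a(c1,c2) = 0.5, so a(e,e) = 1 + 0.25 and
  # a(c1,e) = (a(c1,c1) + a(c1,c2)) / 2 = 0.75
  expect_equal(A["e", "e"], 1.25)
  expect_equal(A["c1", "e"], 0.75)
  # the inbred parent-child pair passes the close-kin threshold
  kin <- close_biological_kin(A, "e")
  expect_true(all(c("c1", "c2") %in% names(kin)))
})

test_that("recursion matches gene-dropping IBD estimates on random pedigrees", {
  for (seed in 1:4) {
    df <- random_pedigree_df(n = 12, seed = seed)
    A <- relatedness_matrix(build_pedigree(df))
    gd <- gene_drop_relatedness(df, n_drops = 4000, seed = seed + 100)
    A <- A[rownames(gd$mean), colnames(gd$mean)]
    tol <- pmax(3 * gd$se, 0.005)
    expect_true(all(abs(A - gd$mean) <= tol),
                label = sprintf("gene-drop agreement, seed %d", seed))
  }
})

test_that("relatedness is invariant to census row order", {
  df <- random_pedigree_df(n = 15, seed = 9)
  A1 <- relatedness_matrix(build_pedigree(df))
  set.seed(1)
  df2 <- df[sample(nrow(df)), ]
  A2 <- relatedness_matrix(build_pedigree(df2))
  ids <- rownames(A1)
  expect_equal(A2[ids, ids], A1)
  # pairwise relatedness is bounded by the diagonal on non-inbred pedigrees
  if (all(abs(diag(A1) - 1) < 1e-12)) {
    expect_true(all(A1 <= 1 + 1e-12))
  }
})

test_that("close kin are alters at or above the 0.5 threshold", {
  cen <- make_census(
    census_row("m", sex = "F", birth_year = 1940L),
    census_row("f", sex = "M", birth_year = 1940L),
    census_row("m2", sex = "F", birth_year = 1942L),
    census_row("ego", birth_year = 1965L, mother_id = "m", father_id = "f"),
    census_row("sib", birth_year = 1967L, mother_id = "m", father_id = "f"),
    census_row("half", birth_year = 1969L, mother_id = "m2", father_id = "f"),
    census_row("iso", sex = "M", birth_year = 1930L)
  )
  A <- relatedness_matrix(build_pedigree(cen))
  kin <- close_biological_kin(A, "ego")
  expect_setequal(names(kin), c("m", "f", "sib"))
  expect_equal(unname(kin), rep(0.5, 3))
  expect_length(close_biological_kin(A, "iso"), 0)  # founder, no kin at all
  expect_error(close_biological_kin(A, "nope"), "not in")
})

test_that("affinal kin are the partner, partner's parents and full sibs", {
  cen <- make_census(
    census_row("pm", sex = "F", birth_year = 1940L),
    census_row("pf", sex = "M", birth_year = 1940L),
    census_row("px", sex = "F", birth_year = 1944L),
    census_row("p", sex = "M", birth_year = 1965L, mother_id = "pm",
               father_id = "pf"),
    census_row("ps", sex = "F", birth_year = 1967L, mother_id = "pm",
               father_id = "pf"),
    census_row("phalf", sex = "M", birth_year = 1969L, mother_id = "px",
               father_id = "pf"),
    census_row("ego", sex = "F", birth_year = 1966L, partner_id = "p")
  )
  A <- relatedness_matrix(build_pedigree(cen))
  aff <- affinal_kin(cen, A, "ego")
  expect_setequal(names(aff), c("p", "pm", "pf", "ps"))
  expect_equal(aff[["p"]], 1)
  expect_equal(unname(aff[c("pm", "pf", "ps")]), rep(0.5, 3))
  expect_false("phalf" %in% names(aff))  # half sibling of partner excluded
  expect_length(affinal_kin(cen, A, "pm"), 0)  # unpartnered
})
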