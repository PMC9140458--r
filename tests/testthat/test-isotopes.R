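test_that("single-element distributions reproduce quoted heavy abundances", {
  min_tab <- isotope_table("minimal")
  expect_equal(element_distribution("S", 1, 4, min_tab)$abundance[["2"]],
               0.0421)
  expect_equal(element_distribution("C", 1, 2, min_tab)$abundance[["1"]],
               0.0111)
  expect_equal(unname(element_distribution("C", 0, 5)$abundance),
               c(1, rep(0, 5)))
  expect_error(element_distribution("Xq", 2, 2), "unknown element")
})

test_that("convolution has a delta identity and closed squared forms", {
  min_tab <- isotope_table("minimal")
  a <- formula_distribution("C5H5N5", max_k = 3)
  delta <- element_distribution("C", 0, 3)
  expect_equal(convolve_distributions(a, delta)$abundance, a$abundance)
  s1 <- element_distribution("S", 1, 4, min_tab)
  expect_equal(convolve_distributions(s1, s1)$abundance[["4"]], 0.0421^2)
})

test_that("formula distributions match multinomial enumeration", {
  cases <- c("C2H3NOS", "H10", "S2", "C5H5N5", "C5H8O4", "O5",
             "C9H13N3O4S", "C10H13N5O4")
  for (f in cases) {
    d <- formula_distribution(f, max_k = 3)
    expect_equal(unname(d$abundance), oracle_formula_dist(f, 3),
                 tolerance = 1e-10, label = f)
  }
})

test_that("distribution entries sum with the truncation bound to one", {
  for (f in c("C10H13N5O4", "C9H12N2O5S", "C19H26N6O7")) {
    d <- formula_distribution(f, max_k = 2)
    expect_equal(sum(d$abundance) + d$truncation_bound, 1, tolerance = 1e-9)
    d8 <- formula_distribution(f, max_k = 8)
    expect_lt(d8$truncation_bound, 1e-8)  # k > 8 is negligible mass
    expect_true(all(d$abundance >= 0 & d$abundance <= 1))
    light <- prod(vapply(names(parse_formula(f)), function(s) {
      tab <- isotope_table()
      tab$abundance[tab$symbol == s & tab$offset == 0]^parse_formula(f)[[s]]
    }, numeric(1)))
    expect_equal(unname(d$abundance[["0"]]), light, tolerance = 1e-12)
  }
})

test_that("distribution decomposes over any formula split", {
  whole <- formula_distribution("C10H13N5O4", max_k = 2)
  parts <- convolve_distributions(formula_distribution("C5H5N5", max_k = 2),
                                  formula_distribution("C5H8O4", max_k = 2))
  expect_equal(whole$abundance, parts$abundance, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    f <- parse_formula(sample(builtin_catalog()$formula, 1))
    split <- lapply(unclass(f), function(n) sample(0:n, 1))
    a <- mrmscreen:::formula_from_counts(unlist(split), names(split))
    b <- subtract_loss(f, a)
    lhs <- formula_distribution(f, max_k = 2)$abundance
    rhs <- convolve_distributions(formula_distribution(a, max_k = 2),
                                  formula_distribution(b, max_k = 2))$abundance
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("fragment crosstalk equals enumeration restricted to the base", {
  expect_equal(fragment_crosstalk_factor("C5H5N5", "C5H8O4", 1),
               oracle_crosstalk("C5H5N5", "C5H8O4", 1), tolerance = 1e-10)
  expect_equal(fragment_crosstalk_factor("C4H5N3S", "C5H8O4", 2),
               oracle_crosstalk("C4H5N3S", "C5H8O4", 2), tolerance = 1e-10)
})

test_that("conditioning on fragment placement only reduces abundance", {
  cat <- builtin_catalog()
  set.seed(3)
  for (ab in sample(cat$abbreviation[cat$glycosidic_bond == "N"], 12)) {
    sp <- catalog_lookup(cat, ab)
    loss <- if (sp$sugar_mod == "2'-O-methyl") "C6H10O4" else "C5H8O4"
    base <- subtract_loss(sp$formula, loss)
    whole <- formula_distribution(sp$formula, max_k = 2)$abundance
    for (k in 1:2) {
      expect_lte(fragment_crosstalk_factor(base, loss, k),
                 unname(whole[[as.character(k)]]))
    }
  }
  # no atoms lost: factor equals the whole-molecule abundance
  empty <- subtract_loss("C5H5N5", "C5H5N5")
  expect_equal(fragment_crosstalk_factor("C5H5N5", empty, 1),
               unname(formula_distribution("C5H5N5", max_k = 1)$abundance[["1"]]),
               tolerance = 1e-12)
})

test_that("sulfur dominates the +2 isotopologue of a thionucleoside", {
  # 2-thiocytidine: the 34S route to k = 2 outweighs all non-S routes
  rest <- "C9H13N3O4"
  s_part <- element_distribution("S", 1, 2)
  rest_d <- formula_distribution(rest, max_k = 2)
  via_s <- s_part$abundance[["2"]] * rest_d$abundance[["0"]]
  via_rest <- rest_d$abundance[["2"]] * s_part$abundance[["0"]]
  expect_gt(via_s, via_rest)
})

test_that("distribution export is a readable table with centroid masses", {
  d <- formula_distribution("C5H8O4", max_k = 2)
  path <- tempfile(fileext = ".tsv")
  export_distribution(d, path)
  back <- read.delim(path)
  expect_equal(back$abundance, unname(d$abundance))
  expect_equal(back$k, 0:2)
  # the k=0 centroid is the monoisotopic mass
  expect_equal(back$centroid_exact_mass[1], monoisotopic_mass("C5H8O4"),
               tolerance = 1e-9)
  # the k=1 centroid sits about one neutron higher
  expect_equal(back$centroid_exact_mass[2] - back$centroid_exact_mass[1],
               1.0, tolerance = 0.01)
})
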