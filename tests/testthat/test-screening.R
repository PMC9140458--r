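cat <- builtin_catalog()
tr <- transitions_for_catalog(cat)
chan <- function(ab) tr[tr$abbreviation == ab, , drop = FALSE][1, ]

test_that("channel sharing is judged on exact masses within resolution", {
  expect_true(same_channel(chan("m6,6A"), chan("f6A")))   # 0.0364 Da apart
  expect_false(same_channel(chan("m1A"), chan("Am")))     # 150 vs 136
  expect_true(same_channel(chan("m1A"), chan("m1A")))
  expect_false(same_channel(chan("m6,6A"), chan("f6A"),
                            screening_params(resolution = 0.01)))
})

test_that("pair classification reproduces the canonical examples", {
  pair <- function(a, b) classify_pair(catalog_lookup(cat, a),
                                       catalog_lookup(cat, b))
  r <- pair("s2U", "s4U")
  expect_equal(r$findings$type, "I")
  r <- pair("ho5U", "m5D")
  expect_equal(r$findings$type, "II")
  r <- pair("A", "I")
  expect_equal(r$findings$type, "III")
  expect_equal(r$findings$target, "I")
  expect_equal(r$findings$interferer, "A")
  expect_equal(r$findings$k, 1L)
  expect_equal(r$findings$shared_precursor, 269.1)
  expect_equal(r$findings$shared_product, 137)
  expect_equal(r$findings$crosstalk_abundance,
               fragment_crosstalk_factor("C5H5N5", "C5H8O4", 1))
  # isomers with distinguishable products are resolvable, not findings
  r <- pair("m1A", "Am")
  expect_equal(nrow(r$findings), 0L)
  expect_equal(sort(c(r$resolvable$species_a, r$resolvable$species_b)),
               c("Am", "m1A"))
  r <- pair("U", "Y")
  expect_equal(nrow(r$findings), 0L)
  expect_false(is.null(r$resolvable))
})

test_that("a species does not interfere with itself", {
  x <- catalog_lookup(cat, "m1A")
  r <- classify_pair(x, x)
  expect_equal(nrow(r$findings), 0L)
  expect_equal(nrow(screen_catalog(cat[cat$abbreviation == "m1A", ])$findings),
               0L)
})

test_that("the five-standard thiouridine panel shares one channel in all three ways", {
  rep5 <- screen_catalog(builtin_subset(c("s2U", "s4U", "ho5U", "m5D", "s2C")))
  expect_equal(nrow(rep5$channel_groups), 1L)
  expect_equal(rep5$channel_groups$precursor, 261.1)
  expect_equal(rep5$channel_groups$product, 129)
  expect_equal(rep5$channel_groups$n_members, 5L)
  expect_equal(strsplit(rep5$channel_groups$types, ";")[[1]],
               c("I", "II", "III"))
  # 6 symmetric findings among the four primaries + 4 directional
  # crosstalk findings from the thiocytidine isotopologue
  expect_equal(nrow(rep5$findings), 10L)
  expect_equal(sum(rep5$findings$type == "I"), 1L)
  expect_equal(sum(rep5$findings$type == "II"), 5L)
  expect_equal(sum(rep5$findings$type == "III"), 4L)
  expect_true(all(rep5$findings$interferer[rep5$findings$type == "III"] ==
                    "s2C"))
})

test_that("methoxycarbonylmethyluridine chain shows stepped +1 crosstalk", {
  r <- screen_catalog(builtin_subset(c("mcm5U", "ncm5s2U", "cm5s2U")))
  k1 <- r$findings[r$findings$type == "III" & r$findings$k == 1, ]
  expect_true(any(k1$interferer == "mcm5U" & k1$target == "ncm5s2U"))
  expect_true(any(k1$interferer == "ncm5s2U" & k1$target == "cm5s2U"))
})

test_that("finding sets are symmetric in pair order", {
  pairs <- list(c("s2U", "s4U"), c("ho5U", "m5D"), c("A", "I"),
                c("mcm5U", "ncm5s2U"))
  for (p in pairs) {
    fwd <- classify_pair(catalog_lookup(cat, p[1]), catalog_lookup(cat, p[2]))
    rev <- classify_pair(catalog_lookup(cat, p[2]), catalog_lookup(cat, p[1]))
    norm <- function(f) {
      f$pair <- vapply(seq_len(nrow(f)), function(i)
        paste(sort(c(f$target[i], f$interferer[i])), collapse = "|"),
        character(1))
      f[order(f$type, f$pair, f$k),
        c("type", "pair", "k", "shared_product")]
    }
    expect_equal(norm(fwd$findings), norm(rev$findings),
                 ignore_attr = TRUE)
    # directional findings keep their direction under either call order
    fIII <- fwd$findings[fwd$findings$type == "III", ]
    rIII <- rev$findings[rev$findings$type == "III", ]
    expect_setequal(paste(fIII$interferer, fIII$target),
                    paste(rIII$interferer, rIII$target))
  }
})

test_that("tightening thresholds never adds findings", {
  panel <- builtin_subset(c("s2U", "s4U", "ho5U", "m5D", "s2C",
                            "mcm5U", "ncm5s2U", "cm5s2U"))
  base <- screen_catalog(panel)
  tight_res <- screen_catalog(panel, screening_params(resolution = 0.03))
  high_floor <- screen_catalog(panel,
                               screening_params(min_crosstalk_abundance = 0.06))
  key <- function(r) paste(r$findings$type, r$findings$target,
                           r$findings$interferer, r$findings$k)
  expect_true(all(key(tight_res) %in% key(base)))
  expect_true(all(key(high_floor) %in% key(base)))
  expect_lt(nrow(high_floor$findings), nrow(base$findings))
})

test_that("full-catalog screen groups the monomethyladenosine channel", {
  full <- screen_catalog(cat)
  g <- full$channel_groups
  g282 <- g[g$precursor == 282.1 & g$product == 150, ]
  expect_equal(g282$members, "m1A;m2A;m6A;m8A")
  expect_equal(g282$types, "I")
  # monitorable C-glycosides are screened; nothing is silently skipped
  expect_equal(nrow(full$skipped), 0L)
})

test_that("retention tables flag co-eluting findings", {
  panel <- builtin_subset(c("s2U", "s4U", "ho5U"))
  rt <- data.frame(abbreviation = c("s2U", "s4U", "ho5U"),
                   rt = c(10, 10.2, 15))
  r <- screen_catalog(panel, screening_params(rt_window = 0.5), rt = rt)
  f <- r$findings
  expect_true(f$co_elution[f$target == "s2U" & f$interferer == "s4U"])
  expect_false(any(f$co_elution[f$interferer == "ho5U" | f$target == "ho5U"]))
})

test_that("reports serialize to tsv and round-trip through json", {
  rep5 <- screen_catalog(builtin_subset(c("s2U", "s4U", "ho5U", "m5D", "s2C")))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_report(rep5, "tsv", tsv)
  lines <- readLines(tsv)
  expect_true(any(grepl("^# channel groups", lines)))
  expect_true(any(grepl("261.1 129 5", lines, fixed = TRUE)))
  write_report(rep5, "json", js)
  back <- read_report(js)
  expect_equal(back$findings$type, rep5$findings$type)
  expect_equal(back$findings$crosstalk_abundance,
               rep5$findings$crosstalk_abundance, tolerance = 1e-12)
  expect_equal(back$channel_groups$members, rep5$channel_groups$members)
  expect_error(write_report(rep5, "xml"), "arg")
  # empty report still yields a valid document
  empty <- screen_catalog(cat[cat$abbreviation == "m1A", ])
  txt <- write_report(empty, "json", tempfile(fileext = ".json"))
  expect_silent(write_report(empty, "tsv", tempfile(fileext = ".tsv")))
})

test_that("brute-force double-loop classifier agrees on small panels", {
  params <- screening_params()
  panels <- list(c("s2U", "s4U", "ho5U", "m5D", "s2C"),
                 c("A", "I", "m1A", "Am"),
                 c("mcm5U", "ncm5s2U", "cm5s2U", "chm5U"))
  for (p in panels) {
    panel <- builtin_subset(p)
    got <- screen_catalog(panel, params)
    want <- oracle_screen(panel, params)
    expect_equal(finding_keys(got$findings), want$keys, label = paste(p, collapse = "+"))
    for (r in which(got$findings$type == "III")) {
      f <- got$findings[r, ]
      key <- paste("III", f$target, f$interferer, f$k, f$shared_precursor,
                   f$shared_product)
      expect_equal(f$crosstalk_abundance, unname(want$abundances[key]),
                   tolerance = 1e-9)
    }
  }
})
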