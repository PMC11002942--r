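# Derived-trait calculus: composition classification and peak aggregation.

test_that("type classification follows the documented rule set", {
  expect_equal(classify_composition("H3N2")$type, "paucimannosidic")
  expect_equal(classify_composition("H3N2F1")$type, "paucimannosidic")
  expect_equal(classify_composition("H5N2")$type, "high_mannose")
  expect_equal(classify_composition("H9N2")$type, "high_mannose")
  expect_equal(classify_composition("H5N2F1")$type, "unclassified") # fuc on HM
  expect_equal(classify_composition("H5N3")$type, "hybrid")
  expect_equal(classify_composition("H3N4F1")$type, "complex")
  expect_equal(classify_composition("H4N3")$type, "complex")
  expect_equal(classify_composition("H4N2")$type, "unclassified")
})

test_that("fucosylation, sialylation and sLex flags are compositional", {
  f <- classify_composition("H3N4F1")
  expect_equal(f$fucosylation, "mono")
  expect_equal(classify_composition("H5N4F2")$fucosylation, "multi")
  expect_equal(classify_composition("H5N4F3L1")$fucosylation, "multi")
  s <- classify_composition("H5N4E1L1")
  expect_setequal(s$sialylation, c("a23", "a26", "mixed"))
  expect_false(s$slex_candidate)
  expect_true(classify_composition("H5N4F1L1")$slex_candidate)
  expect_false(classify_composition("H5N4F1E1")$slex_candidate)
})

test_that("H/N ratio classes compare raw counts", {
  expect_equal(classify_composition("H5N4")$hn_class, "H>N")
  expect_equal(classify_composition("H4N4")$hn_class, "H=N")
  expect_equal(classify_composition("H4N5")$hn_class, "H<N")
})

test_that("antennarity labels match the anchor sequences", {
  expect_equal(classify_composition("H3N4F1")$antennarity, "di")
  expect_equal(classify_composition("H5N4")$antennarity, "di")
  expect_equal(classify_composition("H4N5")$antennarity, "tri")
  expect_equal(classify_composition("H6N5")$antennarity, c("di", "tri"))
  expect_equal(classify_composition("H7N6")$antennarity, c("tri", "tetra"))
  expect_equal(classify_composition("H6N6")$antennarity, c("tri", "tetra"))
  expect_equal(classify_composition("H4N6")$antennarity, "tetra")
  p <- classify_composition("H8N7")
  expect_true(p$poly)
  expect_equal(p$antennarity, "poly")
  expect_false(classify_composition("H8N6")$poly)
  expect_false(classify_composition("H7N7")$poly)
})

test_that("classification is a pure function of composition and rules", {
  a <- classify_composition("H6N5F1E1")
  b <- classify_composition(parse_composition("H6N5F1E1"))
  expect_identical(unclass(a), unclass(b))
  loose <- trait_rules(poly_hex = 5, poly_hexnac = 4)
  expect_true(classify_composition("H6N5", loose)$poly)
})

test_that("unambiguous toy spectrum matches the hand-computed trait table", {
  # five peaks, one candidate each:
  #  H5N2 30%  high-mannose, H>N
  #  H5N4F1 25% complex, monofuc, H>N, di
  #  H5N4F2L1 20% complex, multifuc, a23, sLex, H>N, di
  #  H4N5 15%  complex, H<N, tri
  #  H5N3 10%  hybrid, H>N, mono
  peaks <- tibble::tibble(
    percent = c(30, 25, 20, 15, 10),
    candidates = c("H5N2", "H5N4F1", "H5N4F2L1", "H4N5", "H5N3")
  )
  tt <- aggregate_traits(peaks)
  expect_equal(tt$high_mannose, 30)
  expect_equal(tt$complex, 60)
  expect_equal(tt$hybrid, 10)
  expect_equal(tt$paucimannosidic, 0)
  expect_equal(tt$monofucosylation, 25)
  expect_equal(tt$multifucosylation, 20)
  expect_equal(tt$total_fucosylation, 45)
  expect_equal(tt$a23_sialylation, 20)
  expect_equal(tt$a26_sialylation, 0)
  expect_equal(tt$slex, 20)
  expect_equal(tt$hex_gt_hexnac, 85)
  expect_equal(tt$hex_lt_hexnac, 15)
  expect_equal(tt$ant_mono, 10)
  expect_equal(tt$ant_di, 45)
  expect_equal(tt$ant_tri, 15)
  # unambiguous candidates: the four types + unclassified partition the signal
  expect_equal(tt$paucimannosidic + tt$high_mannose + tt$complex + tt$hybrid +
                 tt$unclassified, 100)
  expect_equal(tt$monofucosylation + tt$multifucosylation, tt$total_fucosylation)
})

test_that("ambiguous candidates produce group sums above 100 percent", {
  # three peaks; the first is nonunivocal across hybrid and complex
  peaks <- tibble::tibble(
    percent = c(50, 30, 20),
    candidates = c("H5N3;H3N4", "H5N2", "H5N4")
  )
  tt <- aggregate_traits(peaks)
  expect_equal(tt$hybrid, 50)
  expect_equal(tt$complex, 70)
  expect_equal(tt$high_mannose, 30)
  type_sum <- tt$paucimannosidic + tt$high_mannose + tt$complex + tt$hybrid +
    tt$unclassified
  expect_gt(type_sum, 100)
  expect_equal(type_sum, 150)
  # candidates spanning adjacent antennarity classes land in the
  # intermediate group
  peaks2 <- tibble::tibble(percent = c(60, 40), candidates = c("H4N5;H3N4", "H5N2"))
  tt2 <- aggregate_traits(peaks2)
  expect_equal(tt2$ant_di_tri, 60)
  expect_equal(tt2$ant_di, 0)
  expect_equal(tt2$ant_tri, 0)
})

test_that("aggregation validates its input", {
  expect_error(aggregate_traits(tibble::tibble(percent = c(10, 10),
                                               candidates = c("H5N2", "H5N4"))),
               "not normalized")
  expect_error(aggregate_traits(tibble::tibble(percent = numeric(0),
                                               candidates = character(0))),
               "no kept peaks")
})

test_that("trait rule sets round-trip through YAML config files", {
  skip_if_not_installed("yaml")
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  rules <- trait_rules(poly_hex = 8, hm_min_hex = 4)
  write_trait_rules(rules, f)
  back <- read_trait_rules(f)
  expect_identical(unclass(back), unclass(rules))
  writeLines("nonsense_field: 3", f)
  expect_error(read_trait_rules(f), "unknown trait rule field")
})

test_that("profile traits equal pipeline traits on a noise-free simulation", {
  p <- make_profile("ntc_like")
  truth <- profile_traits(p)
  sp <- simulate_spectrum(p, quiet_design(), 1, 1, "a", 1)
  pt <- process_spectrum(sp)
  got <- aggregate_traits(pt)
  for (tr in trait_names()) {
    expect_equal(got[[tr]], truth[[tr]], tolerance = 0.05,
                 label = paste("trait", tr))
  }
})
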