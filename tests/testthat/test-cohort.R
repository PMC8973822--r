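variants_fixture <- function() {
  read_variant_table(system.file("extdata", "belgian_variants.tsv",
                                 package = "cellcoloc"))
}

test_that("rarity filter keeps rare and database-absent variants only", {
  v <- variants_fixture()
  rare <- filter_rare(v)
  expect_true("L620P" %in% rare$variant_id)      # MAF 0.055%
  expect_false("E188G" %in% rare$variant_id)     # MAF 47.4%
  expect_false(any(c("G215S", "R1349Q", "G1527A") %in% rare$variant_id))
  expect_true("A845V" %in% rare$variant_id)      # absent from databases
  # boundary: exactly 1% passes (inclusive); excluded regions never pass
  edge <- data.frame(variant_id = c("edge", "rep"), maf_gnomad_nfe = c(1.0, 0.01),
                     in_excluded_region = c(FALSE, TRUE))
  kept <- filter_rare(edge)
  expect_equal(kept$variant_id, "edge")
  # idempotent and a subset of the input
  expect_identical(filter_rare(rare), rare)
  expect_true(all(rare$variant_id %in% v$variant_id))
})

test_that("HGVS classification follows the notation rules", {
  expect_equal(classify_variant("c.5458G>A", "p.G1820S"), "missense")
  expect_equal(classify_variant("c.3148-5C>T", ""), "splice")
  expect_equal(classify_variant("c.100del", "p.(fs)"), "indel")
  expect_equal(classify_variant("c.300+1G>A", ""), "ptc")     # canonical site
  expect_equal(classify_variant("c.300+7G>A", ""), "splice")  # beyond +/-2
  expect_equal(classify_variant("c.120G>A", "p.W40*"), "ptc")
  expect_equal(classify_variant("c.45_46insT", "p.(fs)"), "indel")
  expect_error(classify_variant("g.12345A>T", ""), "unparsable")
  # vectorized over the packaged table
  v <- variants_fixture()
  cls <- classify_variant(v$cdna_hgvs, v$protein_hgvs)
  expect_equal(sum(cls == "missense"), 18)
  expect_equal(sum(cls == "splice"), 1)
})

test_that("carrier frequencies reproduce the printed reporting convention", {
  expect_equal(carrier_frequency(115, 1376)$pct, 8.36)
  expect_equal(carrier_frequency(50, 976)$pct, 5.12)
  expect_equal(carrier_frequency(0, 976)$pct, 0)
  # rounding is half-up, applied only at reporting
  expect_equal(carrier_frequency(66, 96, digits = 1)$pct, 68.8)  # 68.75 exact
  expect_equal(carrier_frequency(66, 96)$exact_pct, 6875 / 100, tolerance = 1e-12)
  expect_error(carrier_frequency(5, 0), "cohort_size")
  expect_error(carrier_frequency(10, 5), "carriers")
})

test_that("Fisher exact test matches stats::fisher.test across random tables", {
  set.seed(19)
  for (i in 1:60) {
    a <- rpois(1, 5); b <- rpois(1, 40) + 1; c <- rpois(1, 5); d <- rpois(1, 40) + 1
    ct <- contingency_test(a, b, c, d)
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    expect_equal(ct$p_two_sided, ft$p.value, tolerance = 1e-10)
  }
  # symmetric table
  sym <- contingency_test(5, 95, 5, 95)
  expect_equal(sym$odds_ratio, 1); expect_equal(sym$p_two_sided, 1)
  # Haldane-Anscombe path for zero cells
  corr <- contingency_test(10, 1, 0, 10)
  expect_true(corr$corrected)
  expect_true(is.finite(corr$odds_ratio))
  expect_error(contingency_test(0, 0, 5, 5), "margin")
})

test_that("odds ratio and Woolf interval come from the sample cross-product", {
  ct <- contingency_test(11, 1365, 5, 971)
  expect_equal(ct$odds_ratio, (11 * 971) / (1365 * 5), tolerance = 1e-12)
  se <- sqrt(1 / 11 + 1 / 1365 + 1 / 5 + 1 / 971)
  expect_equal(ct$ci95, exp(log(ct$odds_ratio) + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
})

test_that("multi-variant carriers are counted on distinct variants", {
  roster <- list(A = c("v1", "v2"), B = "v1", C = c("v3", "v4", "v5"))
  expect_equal(multi_variant_carriers(roster), 2)
  expect_equal(multi_variant_carriers(list()), 0)
  # duplicate listings collapse
  expect_equal(multi_variant_carriers(list(A = c("v1", "v1"))), 0)
  df <- data.frame(individual_id = c("A", "A", "B"),
                   variant_id = c("v1", "v2", "v9"))
  expect_equal(multi_variant_carriers(df), 1)
})

test_that("the synthetic roster reproduces the printed cohort tallies", {
  fix <- synthetic_belgian_roster()
  tl <- tally_carriers(fix$roster, fix$variants, fix$cohort_sizes)
  get <- function(co, cl, col) tl[tl$cohort == co & tl$class == cl, ][[col]]
  expect_equal(get("patients", "missense", "mutations"), 101)
  expect_equal(get("patients", "missense", "carriers"), 96)
  expect_equal(get("patients", "splice", "mutations"), 10)
  expect_equal(get("patients", "indel", "mutations"), 4)
  expect_equal(get("patients", "multi_variant", "carriers"), 11)
  expect_equal(get("patients", "multi_variant", "pct"), 0.80)
  expect_equal(get("controls", "missense", "mutations"), 50)
  expect_equal(get("controls", "missense", "carriers"), 46)
  expect_equal(get("controls", "multi_variant", "carriers"), 5)
  expect_equal(get("controls", "multi_variant", "pct"), 0.51)
})

test_that("tally rejects rosters referencing unknown cohorts or variants", {
  fix <- synthetic_belgian_roster()
  bad <- fix$roster
  bad$cohort[3] <- "neither"
  expect_error(tally_carriers(bad, fix$variants, fix$cohort_sizes),
               "unknown cohort")
  bad2 <- fix$roster
  bad2$variant_id[1] <- "ghost"
  expect_error(tally_carriers(bad2, fix$variants, fix$cohort_sizes), "missing")
})
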