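test_that("window counts assign repeats by start coordinate", {
  L <- 123082
  reps <- features(seq(0, 120000, by = 3000), seq(0, 120000, by = 3000) + 40)
  wc <- window_counts(reps, L)
  expect_equal(length(wc$counts), 41)
  expect_true(all(wc$counts == 1))

  one <- features(rep(4500, 7), rep(4540, 7))
  wc1 <- window_counts(one, 30000)
  expect_equal(sum(wc1$counts > 0), 1)
  expect_equal(max(wc1$counts), 7)
  expect_error(window_counts(one, 2000), "exceeds")
})

test_that("window counts match an independent interval-arithmetic recount", {
  set.seed(31)
  for (i in 1:5) {
    L <- 60000
    reps <- place_repeats_null(L, 40, mode = "poisson")
    wc <- window_counts(reps, L)
    recount <- vapply(seq_len(floor(L / 3000)), function(k) {
      sum(reps$start >= (k - 1) * 3000 & reps$start < k * 3000)
    }, numeric(1))
    expect_equal(wc$counts, recount)
    expect_equal(sum(wc$counts), sum(reps$start < floor(L / 3000) * 3000))
  }
})

test_that("the two-tailed dispersion test reproduces published p-values", {
  ## chi2 89.71 / df 39: printed as 1.43e-5; the statistic itself is rounded
  ## to 2 dp, so agreement is to within one unit in the last printed digit
  r1 <- dispersion_from_stats(89.71, 39)
  expect_lt(abs(r1$p - 1.43e-5) / 1.43e-5, 0.01)
  expect_equal(r1$classification, "Overdispersed")
  r2 <- dispersion_from_stats(85.46, 39)
  expect_equal(signif(r2$p, 3), 5.06e-5)
  expect_equal(r2$classification, "Overdispersed")
  r3 <- dispersion_from_stats(63.98, 39)
  expect_equal(round(r3$p, 3), 0.014)
  expect_equal(r3$classification, "Overdispersed")
  r4 <- dispersion_from_stats(36.10, 40)
  expect_equal(round(r4$p, 3), 0.707)
  expect_equal(r4$classification, "Poisson")
})

test_that("dispersion internals: chi2 = df * variance:mean; degenerate cases", {
  set.seed(32)
  x <- rpois(40, 3)
  r <- dispersion_test(x)
  expect_equal(r$chi2, r$df * r$ratio)
  expect_equal(r$variance / r$mean, r$ratio)
  expect_equal(r$df, 39)
  ## equal counts: lower-tail extreme
  req <- dispersion_test(rep(3, 20))
  expect_equal(req$chi2, 0)
  expect_equal(req$ratio, 0)
  expect_equal(req$classification, "Underdispersed")
  expect_error(dispersion_test(rep(0, 10)), "mean")
  expect_error(dispersion_test(5), "two windows")
})

test_that("sliding density is flat for uniform fields and integrates correctly", {
  L <- 30000
  reps <- features(seq(0, L - 100, by = 100), seq(0, L - 100, by = 100) + 40)
  padded <- pad_features(reps, L)
  prof <- sliding_density(padded, L)
  expect_equal(nrow(prof), L / 100)
  expect_true(all(abs(prof$density - 30) < 1e-9))  # 30 repeats per 3 kb

  one <- pad_features(features(15000, 15040), L)
  p1 <- sliding_density(one, L)
  ## counting identity: each repeat start is covered by window/step windows
  expect_equal(sum(p1$density), 3000 / 100)
  expect_equal(max(p1$density), 1)
})

test_that("endpoint vicinity coverage handles partial overlap and wrap", {
  L <- 20000
  expect_equal(vicinity_repeat_content(empty_features(), 5000, 1000, L), 0)
  full <- features(3000, 7000)
  expect_equal(vicinity_repeat_content(full, 5000, 1000, L), 1)
  half <- features(5750, 6250)  # 250 bp inside [4000, 6000)
  expect_equal(vicinity_repeat_content(half, 5000, 1000, L), 0.125)
  ## circular wrap: vicinity of the origin sees a repeat near L
  near_end <- features(19500, 19600)
  expect_equal(vicinity_repeat_content(near_end, 0, 1000, L), 0.05)
})

test_that("enrichment test matches the hand-computed 2-cell goodness of fit", {
  L <- 100000
  reps <- features(seq(0, 99000, by = 1000), seq(0, 99000, by = 1000) + 40)
  region <- features(0, 10000)
  genome <- features(0, L)
  r <- enrichment_test(reps, region, genome, L)
  expect_equal(r$excess, 0)
  expect_equal(r$chi2, 0)

  reps10 <- features(c(seq(0, 900, by = 100), seq(2000, 91000, by = 1000)),
                     c(seq(0, 900, by = 100), seq(2000, 91000, by = 1000)) + 40)
  r2 <- enrichment_test(reps10, features(0, 1000), genome, L)
  expect_equal(r2$observed, 10)
  expect_equal(r2$expected, 1)
  expect_equal(r2$excess, 9)
  expect_equal(r2$chi2, 81 / 1 + 81 / 99)
  expect_lt(r2$p, 0.001)
  expect_error(enrichment_test(reps10, features(0, 1)[0, ], genome, L), "zero")
})

test_that("repeat length splits proportionally across annotation classes", {
  g <- circular_genome("x", strrep("A", 10000),
                       features(c(1000, 4000), c(2000, 6000), cls = "gene",
                                name = c("g1", "g2")))
  classes <- annotation_classes(g)
  expect_equal(sum(classes$end - classes$start), 10000)
  ## all repeats inside a gene body (no exon rows: gene counts as exon)
  inside <- features(c(1200, 1500), c(1300, 1700))
  expect_equal(content_by_class(inside, classes, 10000),
               c(exon = 1, intron = 0, intergenic = 0))
  ## straddling repeat splits proportionally: 500 in gene, 500 intergenic
  strad <- features(1500, 2500)
  cc <- content_by_class(strad, classes, 10000)
  expect_equal(unname(cc["exon"]), 0.5)
  expect_equal(unname(cc["intergenic"]), 0.5)
  expect_error(content_by_class(empty_features(), classes, 10000), "empty")
})

test_that("introns are classified from exon/intron annotation rows", {
  f <- rbind(features(1000, 2000, cls = "gene", name = "g1"),
             features(c(1000, 1700), c(1300, 2000), cls = "exon",
                      name = c("g1.e1", "g1.e2")),
             features(1300, 1700, cls = "intron", name = "g1.i1"))
  g <- circular_genome("x", strrep("C", 5000), f)
  classes <- annotation_classes(g)
  r <- features(1200, 1500)  # 100 exon + 200 intron
  cc <- content_by_class(r, classes, 5000)
  expect_equal(unname(cc["exon"]), 1 / 3)
  expect_equal(unname(cc["intron"]), 2 / 3)
})
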