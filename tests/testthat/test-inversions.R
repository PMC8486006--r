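test_that("anchor finding handles identity, full reverse complement, and toys", {
  set.seed(41)
  s <- rand_dna(2000)
  a <- find_anchors(s, s)
  expect_equal(nrow(a), 1)
  expect_equal(a$orientation, "forward")
  expect_gte(a$length, 1990)  # essentially the whole sequence

  ar <- find_anchors(rc_oracle(s), s)
  expect_equal(nrow(ar), 1)
  expect_equal(ar$orientation, "reverse")
  expect_gte(ar$length, 1990)
})

test_that("anchors match the brute-force maximal-unique-match oracle", {
  set.seed(42)
  for (i in 1:3) {
    r <- rand_dna(2000)
    q <- revert_segment(circular_genome("x", r), 600, 1400)$sequence
    got <- find_anchors(q, r)
    want <- oracle_mums(q, r)
    expect_equal(got, want, ignore_attr = TRUE)
    ## forward anchors outside, reverse anchors inside the inverted segment
    expect_true(all(got$q_start[got$orientation == "reverse"] >= 590))
    expect_true(all(got$q_start[got$orientation == "reverse"] +
                      got$length[got$orientation == "reverse"] <= 1410))
  }
})

test_that("inversion detection finds planted segments and nothing in self-comparison", {
  set.seed(43)
  r <- rand_dna(12000)
  expect_equal(length(detect_inversions(find_anchors(r, r))), 0)
  q <- revert_segment(circular_genome("x", r), 3000, 8000)
  invs <- detect_inversions(find_anchors(q, r), taxon_id = "x")
  expect_equal(length(invs), 1)
  expect_lt(abs(invs[[1]]$approx_left - 3000), 100)
  expect_lt(abs(invs[[1]]$approx_right - 8000), 100)
})

test_that("refinement recovers clean-junction endpoints exactly with zero score", {
  set.seed(44)
  for (i in 1:4) {
    r <- rand_dna(8000)
    q <- revert_segment(circular_genome("x", r), 2200, 5800)
    ## canonical leftmost representative given chance complementary runs
    qc <- strsplit(q$sequence, "")[[1]]
    r_out <- 0
    while (qc[2200 - r_out] == chartr("ACGT", "TGCA", qc[5800 + r_out + 1])) {
      r_out <- r_out + 1
    }
    inv <- detect_inversions(find_anchors(q, r))[[1]]
    inv <- refine_endpoints(q, r, inv)
    expect_equal(inv$refined_left, 2200 - r_out)
    expect_equal(inv$refined_right, 5800 + r_out)
    expect_equal(attr(inv, "junction_score"), 0)
    ## self-consistency: reverting at the refined endpoints restores colinearity
    back <- revert_segment(q, inv$refined_left, inv$refined_right)
    expect_identical(back$sequence, r)
  }
})

test_that("refinement stays exact under 1% divergence of the reference", {
  set.seed(3)
  ok <- 0; n <- 30
  for (i in 1:n) {
    s <- rand_dna(6000)
    q <- revert_segment(circular_genome("x", s), 1800, 4300)
    qc <- strsplit(q$sequence, "")[[1]]
    r_out <- 0
    while (qc[1800 - r_out] == chartr("ACGT", "TGCA", qc[4300 + r_out + 1])) {
      r_out <- r_out + 1
    }
    ref <- s; pos <- sample.int(6000, 60)
    for (k in pos) {
      substr(ref, k, k) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(ref, k, k)), 1)
    }
    inv <- refine_endpoints(q, ref,
                            detect_inversions(find_anchors(q, ref))[[1]])
    ok <- ok + (inv$refined_left == 1800 - r_out &&
                  inv$refined_right == 4300 + r_out)
  }
  expect_gte(ok, ceiling(0.93 * n))  # misses are +/- a chance-run shift
})

test_that("microhomology scan reads the junctions and flags MMBIR signatures", {
  set.seed(45)
  ## perfect 12-bp inverted complement just inside both endpoints
  s <- rand_dna(4000)
  mh <- rand_dna(12)
  s <- plant(s, 1000, mh)
  s <- plant(s, 2988, rc_oracle(mh))
  inv <- inversion_record("x", 900, 3100, refined_left = 1000, refined_right = 3000)
  hit <- scan_microhomology(s, inv)
  expect_gte(hit$leading_run, 12)
  expect_equal(hit$matches_in_window, 12)
  expect_true(hit$mmbir_consistent)

  ## five-of-six complementary sites in a 6-bp window
  s2 <- rand_dna(4000)
  mh6 <- "ACGTAC"
  bad <- mh6; substr(bad, 5, 5) <- "T"  # one non-complementary site
  s2 <- plant(s2, 1000, mh6)
  s2 <- plant(s2, 2994, rc_oracle(bad))
  hit2 <- scan_microhomology(s2, inversion_record("x", 900, 3100,
                                                  refined_left = 1000,
                                                  refined_right = 3000),
                             window = 6)
  expect_equal(hit2$matches_in_window, 5)

  ## null: leading run at random endpoints is geometric with p = 1/4
  set.seed(46)
  s3 <- rand_dna(40000)
  runs <- vapply(1:4000, function(i) {
    a <- sample(3000:15000, 1); b <- sample(20000:37000, 1)
    scan_microhomology(s3, inversion_record("x", a, b, refined_left = a,
                                            refined_right = b))$leading_run
  }, numeric(1))
  expect_lt(abs(mean(runs >= 1) - 0.25), 0.025)
  expect_lt(abs(mean(runs >= 2) - 0.0625), 0.02)
  expect_lt(abs(mean(runs) - 1 / 3), 0.03)
})

test_that("short-IR scan finds published-size pairs and matches the oracle", {
  set.seed(47)
  ## 13-bp pair with one mismatch (1/13 <= 10%)
  s <- rand_dna(400)
  m13 <- rand_dna(13)
  m13b <- m13; substr(m13b, 7, 7) <- setdiff(c("A","C","G","T"), substr(m13, 7, 7))[1]
  s <- plant(s, 50, m13); s <- plant(s, 300, rc_oracle(m13b))
  irs <- find_short_irs(s)
  found <- irs[irs$orientation == "inverted" & irs$startA <= 50 & irs$endA >= 63, ]
  expect_gte(nrow(found), 1)
  expect_lte(found$mismatches[1], floor(0.1 * found$length[1]))

  ## exact 69-bp inverted pair
  s2 <- rand_dna(600)
  m69 <- rand_dna(69)
  s2 <- plant(s2, 60, m69); s2 <- plant(s2, 450, rc_oracle(m69))
  irs2 <- find_short_irs(s2)
  expect_true(any(irs2$orientation == "inverted" & irs2$length >= 69 &
                    irs2$startA <= 60 & irs2$endA >= 129))

  ## brute-force parity on short regions
  set.seed(48)
  for (i in 1:2) {
    r <- rand_dna(140)
    r <- plant(r, 20, "ACGTACGTACGT")
    r <- plant(r, 100, rc_oracle("ACGTACGTACGT"))
    got <- find_short_irs(r)
    want <- oracle_short_irs(r)
    key <- function(d) do.call(paste, d[, c("startA", "endA", "startB", "endB",
                                            "orientation")])
    expect_setequal(key(got), key(want))
  }
})

test_that("endpoint geometry classifies the constructive inversion mechanism", {
  set.seed(49)
  for (i in 1:3) {
    g <- circular_genome("x", rand_dna(12000))
    pl <- plant_fig6_inversion(g, 3500, 8500)
    inv <- inversion_record("x", pl$canonical_left, pl$canonical_right,
                            refined_left = pl$canonical_left,
                            refined_right = pl$canonical_right)
    geom <- classify_endpoint_repeat_geometry(pl$genome, NULL, inv)
    expect_equal(geom$ancestral_arrangement, "direct-repeats-one-end")
    ## the two copies now sit inverted at opposite ends of the segment
    expect_gte(nrow(geom$flanking_irs), 1)
    expect_gte(geom$flanking_irs$length[1], 55)
    expect_gte(geom$microhomology$leading_run, 4)
    ## mechanism property: the repeat copies straddle opposite endpoints
    expect_lt(abs(pl$repeat_intervals["inner", 1] - pl$left), 300)
    expect_lt(abs(pl$repeat_intervals["outer", 1] - pl$right), 300)
  }
})

test_that("pre-existing IRs at both endpoints and bare junctions classify correctly", {
  set.seed(50)
  s <- rand_dna(12000)
  motif <- rand_dna(40)
  s <- plant(s, 3400, motif)                 # outside left endpoint
  s <- plant(s, 8540, rc_oracle(motif))      # outside right endpoint, inverted
  q <- revert_segment(circular_genome("x", s), 3500, 8500)
  inv <- inversion_record("x", 3500, 8500, refined_left = 3500,
                          refined_right = 8500)
  geom <- classify_endpoint_repeat_geometry(q, NULL, inv)
  expect_equal(geom$ancestral_arrangement, "inverted-repeats-both-ends")

  ## bare junctions: at 16 bp the expected number of chance pairs between the
  ## two 2-kb vicinities is ~0.05, so none should be found
  bare <- revert_segment(circular_genome("x", rand_dna(12000)), 3500, 8500)
  expect_warning(
    geom2 <- classify_endpoint_repeat_geometry(bare, NULL, inv, min_len = 16),
    "no flanking repeats")
  expect_equal(geom2$ancestral_arrangement, "none")
})
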