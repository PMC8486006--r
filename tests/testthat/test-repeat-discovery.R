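test_that("planted exact repeat pairs are recovered with exact coordinates", {
  set.seed(11)
  bg <- rand_dna(5000)
  motif <- rand_dna(40)
  s <- plant(plant(bg, 1000, motif), 3500, motif)
  p <- find_dispersed_repeats(s)
  expect_equal(nrow(p), 1)
  expect_equal(p$orientation, "direct")
  expect_equal(p$identity, 1)
  ## chance flanking matches legitimately extend the maximal run, so compare
  ## against the brute-force maximal-pair oracle, which must agree exactly
  want <- oracle_exact_pairs(s)
  expect_equal(c(p$startA, p$endA, p$startB, p$endB),
               c(want$startA, want$endA, want$startB, want$endB))
  expect_true(p$startA <= 1000 && p$endA >= 1040 &&
                p$startB <= 3500 && p$endB >= 3540)

  s2 <- plant(plant(bg, 1000, motif), 3500, rc_oracle(motif))
  p2 <- find_dispersed_repeats(s2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$orientation, "inverted")
  want2 <- oracle_exact_pairs(s2)
  expect_equal(c(p2$startA, p2$startB), c(want2$startA, want2$startB))
})

test_that("repeats with scattered mismatches still pass the identity filter", {
  set.seed(12)
  bg <- rand_dna(4000)
  motif <- rand_dna(40)
  copy2 <- motif
  substr(copy2, 13, 13) <- setdiff(c("A","C","G","T"), substr(copy2, 13, 13))[1]
  substr(copy2, 27, 27) <- setdiff(c("A","C","G","T"), substr(copy2, 27, 27))[1]
  s <- plant(plant(bg, 500, motif), 2500, copy2)
  p <- find_dispersed_repeats(s)
  expect_equal(nrow(p), 1)
  expect_gte(p$identity, 0.9)
  expect_gte(jaccard(p$startA, p$endA, 500, 540), 0.9)
})

test_that("oracle-certified repeat-free sequences give an empty pair list", {
  set.seed(13)
  for (i in 1:5) {
    s <- rand_dna(2000)
    if (oracle_has_repeat_window(s)) next  # would be astronomically unlikely
    expect_equal(nrow(find_dispersed_repeats(s)), 0)
  }
})

test_that("exact-identity output equals the brute-force diagonal oracle", {
  set.seed(14)
  for (i in 1:6) {
    s <- rand_dna(2500)
    motif <- rand_dna(sample(30:80, 1))
    pos <- sort(sample(seq(0, 2300, by = 120), 3))
    s <- plant(s, pos[1], motif)
    s <- plant(s, pos[2], motif)
    s <- plant(s, pos[3], rc_oracle(motif))
    got <- find_dispersed_repeats(s, min_identity = 1.0, xdrop = 0)
    want <- oracle_exact_pairs(s)
    expect_equal(got[, c("startA", "endA", "startB", "endB", "orientation")],
                 want[, c("startA", "endA", "startB", "endB", "orientation")],
                 ignore_attr = TRUE)
  }
})

test_that("tandem arrays are found with correct period and copy number", {
  set.seed(15)
  bg <- rand_dna(3000)
  s <- paste0(substr(bg, 1, 800), strrep("ACGTT", 10), substr(bg, 851, 3000))
  arr <- find_tandem_repeats(s)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$period, 5)
  expect_lt(abs(arr$copy_number - 10), 1.5)
  expect_gte(jaccard(arr$start, arr$end, 800, 850), 0.85)

  sh <- paste0(substr(bg, 1, 500), strrep("A", 60), substr(bg, 561, 2000))
  arrh <- find_tandem_repeats(sh)
  expect_equal(arrh$period[1], 1)
  expect_equal(c(arrh$start[1], arrh$end[1]), c(500, 560))
})

test_that("tandem-free sequences (oracle-verified) give an empty array list", {
  set.seed(16)
  found <- 0
  for (i in 1:4) {
    s <- rand_dna(2000)
    if (oracle_has_tandem(s)) { found <- found + 1; next }
    expect_equal(nrow(find_tandem_repeats(s)), 0)
  }
  expect_lt(found, 4)  # at least one certified-clean fixture was exercised
})

test_that("interval merging unions overlaps and is idempotent", {
  p <- data.frame(startA = c(10, 100), endA = c(50, 140),
                  startB = c(40, 300), endB = c(80, 340),
                  orientation = "direct", length = 40, identity = 1)
  m <- merge_repeat_intervals(p, NULL)
  expect_equal(m$start, c(10, 100, 300))
  expect_equal(m$end, c(80, 140, 340))
  m2 <- merge_repeat_intervals(data.frame(startA = m$start, endA = m$end,
                                          startB = m$start, endB = m$end), NULL)
  expect_equal(m2[, c("start", "end")], m[, c("start", "end")])

  set.seed(17)
  bg <- rand_dna(6000)
  motif <- rand_dna(50)
  s <- plant(plant(plant(bg, 500, motif), 2000, motif), 4000, motif)
  merged <- merge_repeat_intervals(find_dispersed_repeats(s), NULL)
  ## planted span fully covered; chance flank matches may add a few bases
  for (st in c(500, 2000, 4000)) {
    expect_true(any(merged$start <= st & merged$end >= st + 50))
  }
  expect_gte(sum(merged$end - merged$start), 150)
  expect_lte(sum(merged$end - merged$start), 150 + 30)
})

test_that("repeat grouping is transitive over shared pairs", {
  merged <- features(c(0, 100, 200, 400, 500), c(50, 150, 250, 450, 550),
                     name = sprintf("r%d", 1:5))
  pairs <- data.frame(startA = c(0, 100, 400), endA = c(50, 150, 450),
                      startB = c(100, 200, 500), endB = c(150, 250, 550),
                      orientation = "direct", length = 50, identity = 1)
  g <- group_repeats(pairs, merged)
  expect_equal(length(unique(g$group_id)), 2)
  expect_equal(length(unique(g$group_id[1:3])), 1)       # {A,B},{B,C} -> one group
  expect_equal(g$member_count[1:3], rep(3L, 3))

  set.seed(18)
  bg <- rand_dna(6000); motif <- rand_dna(60)
  s <- plant(plant(plant(bg, 500, motif), 2500, motif), 4500, motif)
  pr <- find_dispersed_repeats(s)
  gg <- group_repeats(pr, merge_repeat_intervals(pr, NULL))
  expect_equal(unique(gg$group_id), 1L)                  # 3-copy family, one group
  expect_equal(nrow(gg), 3)
})

test_that("repeat content is invariant under rotation and reverse complement", {
  set.seed(19)
  bg <- rand_dna(6000); motif <- rand_dna(45)
  s <- plant(plant(bg, 1000, motif), 4000, motif)
  content_of <- function(x) {
    repeat_content(merge_repeat_intervals(find_dispersed_repeats(x), NULL),
                   nchar(x))
  }
  base <- content_of(s)
  expect_gt(base, 0)
  rot <- rotate_genome(circular_genome("x", s), 2222)$sequence
  expect_equal(content_of(rot), base)
  expect_equal(content_of(rc_oracle(s)), base)
})
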