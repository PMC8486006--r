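## Within-genome repeat discovery: seed-and-extend self-comparison for
## dispersed repeats (both orientations), k-mer period detection for tandem
## arrays, interval merging, and grouping of associated repeats.

#' Find dispersed repeats within a genome
#'
#' Seed-and-extend self-comparison of the genome sequence against itself in
#' both orientations. Exact `word`-length seeds shared by two positions are
#' merged along their diagonal and extended gaplessly with an X-drop rule
#' (match +1, mismatch -2); the extension is trimmed to its maximal-scoring
#' span. Pairs with aligned length >= `min_len` and identity >= `min_identity`
#' are reported. The trivial full-length self-match is excluded. Output is
#' deterministic: pairs sorted by orientation, then coordinates.
#'
#' @param genome A [circular_genome()] or a DNA string.
#' @param min_len Minimum aligned length in bp (default 30).
#' @param min_identity Minimum identity, matches / aligned columns (default 0.90).
#' @param word Seed word size in bp (default 11).
#' @param xdrop Score drop at which extension stops (default 6).
#' @return Data frame of repeat pairs: `startA`, `endA`, `startB`, `endB`
#'   (0-based half-open; `startA < startB` or equal with A before B),
#'   `orientation` (`"direct"`/`"inverted"`), `length`, `identity`. For
#'   inverted pairs both intervals are given on the forward strand.
#' @export
find_dispersed_repeats <- function(genome, min_len = 30, min_identity = 0.90,
                                   word = 11, xdrop = 6) {
  s <- if (inherits(genome, "circular_genome")) genome$sequence else toupper(genome)
  n <- nchar(s)
  if (n == 0) stop("empty sequence")
  if (n < min_len) return(empty_pairs())
  sc <- seq_chars(s)
  rc <- revcomp(s)
  rcc <- seq_chars(rc)

  direct <- scan_diagonals(sc, sc, word, min_len, min_identity, xdrop,
                           self = TRUE)
  inv <- scan_diagonals(sc, rcc, word, min_len, min_identity, xdrop,
                        self = FALSE)
  out <- list()
  if (nrow(direct)) {
    out$direct <- data.frame(startA = direct$a_start, endA = direct$a_end,
                             startB = direct$b_start, endB = direct$b_end,
                             orientation = "direct", length = direct$len,
                             identity = direct$identity)
  }
  if (nrow(inv)) {
    ## map B interval from reverse-complement coordinates back to forward
    bs <- n - inv$b_end; be <- n - inv$b_start
    startA <- inv$a_start; endA <- inv$a_end
    ## canonicalize so interval A precedes interval B; drop self-palindromes
    swap <- bs < startA
    tmp_s <- startA[swap]; tmp_e <- endA[swap]
    startA[swap] <- bs[swap]; endA[swap] <- be[swap]
    bs[swap] <- tmp_s; be[swap] <- tmp_e
    keep <- !(startA == bs & endA == be)
    inv <- data.frame(startA = startA, endA = endA, startB = bs, endB = be,
                      orientation = "inverted", length = inv$len,
                      identity = inv$identity)[keep, , drop = FALSE]
    inv <- inv[!duplicated(inv[, 1:4]), , drop = FALSE]
    out$inverted <- inv
  }
  if (length(out) == 0) return(empty_pairs())
  res <- do.call(rbind, out)
  res <- res[order(res$orientation, res$startA, res$startB), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_pairs <- function() {
  data.frame(startA = numeric(0), endA = numeric(0), startB = numeric(0),
             endB = numeric(0), orientation = character(0), length = numeric(0),
             identity = numeric(0))
}

## Seed, merge per diagonal, and extend. a and b are character vectors; for
## self-comparison (direct orientation) only pairs with positive diagonal are
## kept so each pair is reported once.
scan_diagonals <- function(a, b, word, min_len, min_identity, xdrop, self) {
  na <- length(a); nb <- length(b)
  if (na < word || nb < word) {
    return(data.frame(a_start = numeric(0), a_end = numeric(0),
                      b_start = numeric(0), b_end = numeric(0),
                      len = numeric(0), identity = numeric(0)))
  }
  akm <- kmer_strings(a, word)
  bkm <- if (self) akm else kmer_strings(b, word)
  seeds <- seed_pairs(akm, bkm, self)
  res <- list()
  if (nrow(seeds)) {
    seeds$diag <- seeds$j - seeds$i
    for (d in unique(seeds$diag)) {
      ii <- sort(seeds$i[seeds$diag == d])
      ## overlap window of the two sequences along diagonal d
      lo <- max(0, -d); hi <- min(na, nb - d)  # 0-based positions in a
      m <- a[(lo + 1):hi] == b[(lo + d + 1):(hi + d)]
      ## merge seed starts into runs, then extend each run on the match vector
      runs <- merge_seed_runs(ii, word)
      for (r in seq_len(nrow(runs))) {
        ext <- xdrop_extend(m, runs$start[r] - lo, runs$end[r] - lo, xdrop)
        len <- ext[2] - ext[1]
        if (len < min_len) next
        ident <- ext[3] / len
        if (ident < min_identity) next
        a0 <- lo + ext[1]
        res[[length(res) + 1]] <- c(a0, a0 + len, a0 + d, a0 + d + len, len, ident)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(a_start = numeric(0), a_end = numeric(0),
                      b_start = numeric(0), b_end = numeric(0),
                      len = numeric(0), identity = numeric(0)))
  }
  res <- as.data.frame(do.call(rbind, res))
  names(res) <- c("a_start", "a_end", "b_start", "b_end", "len", "identity")
  res <- res[!duplicated(res[, 1:4]), , drop = FALSE]
  drop_contained_pairs(res)
}

kmer_strings <- function(chars, k) {
  n <- length(chars)
  s <- paste(chars, collapse = "")
  substring(s, 1:(n - k + 1), k:n)
}

## all (i, j) seed pairs (0-based starts) sharing a k-mer; for self-comparison
## keeps i < j only (diagonal > 0)
seed_pairs <- function(akm, bkm, self) {
  shared <- if (self) akm[duplicated(akm)] else intersect(akm, bkm)
  shared <- unique(shared)
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (length(shared) == 0) return(data.frame(i = numeric(0), j = numeric(0)))
  ai <- which(akm %in% shared)
  bi <- if (self) ai else which(bkm %in% shared)
  asplit <- split(ai - 1, akm[ai])
  bsplit <- if (self) asplit else split(bi - 1, bkm[bi])
  out <- lapply(names(asplit), function(km) {
    ii <- asplit[[km]]; jj <- bsplit[[km]]
    if (is.null(jj)) return(NULL)
    g <- expand.grid(i = ii, j = jj)
    if (self) g <- g[g$j > g$i, , drop = FALSE]
    g
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) data.frame(i = numeric(0), j = numeric(0)) else out
}

## merge sorted 0-based seed starts (same diagonal) into runs [start, end)
merge_seed_runs <- function(starts, word) {
  starts <- sort(unique(starts))
  gaps <- which(diff(starts) > word)
  run_start <- starts[c(1, gaps + 1)]
  run_end <- starts[c(gaps, length(starts))] + word
  data.frame(start = run_start, end = run_end)
}

## Extend [s, e) (0-based on match vector m) outwards with X-drop scoring
## (+1 match, -2 mismatch); returns c(start, end, matches) of the
## maximal-scoring span containing the seed.
xdrop_extend <- function(m, s, e, xdrop) {
  n <- length(m)
  ## trim seed to actual matches then extend right
  right <- e; best_right <- e; score <- 0; best <- 0
  i <- e + 1
  while (i <= n) {
    score <- score + if (m[i]) 1 else -2
    if (score > best) { best <- score; best_right <- i }
    if (score < best - xdrop) break
    i <- i + 1
  }
  score <- 0; best <- 0; best_left <- s
  i <- s
  while (i >= 1) {
    score <- score + if (m[i]) 1 else -2
    if (score > best) { best <- score; best_left <- i - 1 }
    if (score < best - xdrop) break
    i <- i - 1
  }
  seg <- m[(best_left + 1):best_right]
  ## trim flanking mismatches
  idx <- which(seg)
  if (length(idx) == 0) return(c(best_left, best_left, 0))
  c(best_left + idx[1] - 1, best_left + idx[length(idx)],
    sum(seg[idx[1]:idx[length(idx)]]))
}

## drop pairs whose both intervals are contained in another pair's intervals
drop_contained_pairs <- function(res) {
  if (nrow(res) <= 1) return(res)
  o <- order(-res$len)
  res <- res[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    contained <- res$a_start[prior] <= res$a_start[i] & res$a_end[prior] >= res$a_end[i] &
      res$b_start[prior] <= res$b_start[i] & res$b_end[prior] >= res$b_end[i]
    if (any(contained)) keep[i] <- FALSE
  }
  res[keep, , drop = FALSE]
}

#' Find tandem repeat arrays
#'
#' Detects arrays by comparing the sequence with itself at every candidate
#' period `p` (1..`max_period`): positions where `s[i] == s[i + p]` form runs
#' that are merged across short interruptions while the within-array identity
#' stays at or above `min_identity`. An array of period `p` spanning `[i, j)`
#' is reported when its total span is at least `min_total`. Arrays explained by
#' a smaller period at the same location are dropped.
#'
#' @param genome A [circular_genome()] or DNA string.
#' @param min_total Minimum total array span in bp (default 30).
#' @param max_period Largest period searched in bp (default 500).
#' @param min_identity Minimum fraction of positions matching at the period
#'   (default 0.80).
#' @return Data frame with `start`, `end`, `period`, `copy_number`,
#'   `consensus`.
#' @export
find_tandem_repeats <- function(genome, min_total = 30, max_period = 500,
                                min_identity = 0.80) {
  s <- if (inherits(genome, "circular_genome")) genome$sequence else toupper(genome)
  n <- nchar(s)
  if (n < min_total) return(empty_tandems())
  sc <- seq_chars(s)
  max_period <- min(max_period, floor(n / 2))
  res <- list()
  for (p in seq_len(max_period)) {
    m <- sc[1:(n - p)] == sc[(p + 1):n]
    runs <- identity_runs(m, min_run = max(p, min_total - p), min_identity = min_identity)
    if (nrow(runs) == 0) next
    for (r in seq_len(nrow(runs))) {
      st <- runs$start[r]; en <- runs$end[r] + p  # span includes final copy
      if (en - st < min_total) next
      res[[length(res) + 1]] <- data.frame(
        start = st, end = en, period = p,
        copy_number = round((en - st) / p, 2),
        consensus = substr0(s, st, min(st + p, n)))
    }
  }
  if (length(res) == 0) return(empty_tandems())
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$period), , drop = FALSE]
  ## prefer the smallest period among arrays covering the same span
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    dup <- which(keep & seq_len(nrow(out)) != i &
                   out$start >= out$start[i] - out$period[i] &
                   out$end <= out$end[i] + out$period[i] &
                   out$period >= out$period[i])
    dup <- dup[out$period[dup] %% out$period[i] == 0 | out$period[dup] > out$period[i]]
    keep[dup] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_tandems <- function() {
  data.frame(start = numeric(0), end = numeric(0), period = numeric(0),
             copy_number = numeric(0), consensus = character(0))
}

## maximal runs (0-based half-open) of TRUE in m, merged across gaps while the
## overall identity stays >= min_identity, kept if length >= min_run
identity_runs <- function(m, min_run, min_identity) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  true_idx <- which(r$values & r$lengths >= 3)
  if (length(true_idx) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  out <- list()
  used_until <- -1
  for (k in true_idx) {
    if (starts[k] < used_until) next
    cs <- starts[k]; ce <- ends[k]; matches <- r$lengths[k]
    j <- k + 2
    while (j <= length(r$lengths) && r$values[j]) {
      gap <- r$lengths[j - 1]
      new_matches <- matches + r$lengths[j]
      new_len <- ends[j] - cs
      ## the incoming run must locally pay for the gap it bridges
      local_ok <- r$lengths[j] >= gap * min_identity / (1 - min_identity)
      if (local_ok && new_matches / new_len >= min_identity) {
        matches <- new_matches; ce <- ends[j]; j <- j + 2
      } else break
    }
    if (ce - cs >= min_run && matches / (ce - cs) >= min_identity) {
      out[[length(out) + 1]] <- data.frame(start = cs, end = ce)
      used_until <- ce
    }
  }
  if (length(out) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  do.call(rbind, out)
}

#' Merge repeat intervals into nonoverlapping repeat features
#'
#' Takes the union of all intervals implicated by dispersed repeat pairs and
#' tandem arrays; overlapping or bookended intervals are merged. The merged
#' set is disjoint and sorted; merging a merged set changes nothing.
#'
#' @param pairs Repeat pairs from [find_dispersed_repeats()] (or `NULL`).
#' @param arrays Tandem arrays from [find_tandem_repeats()] (or `NULL`).
#' @return Feature table (`cls = "repeat"`) of disjoint merged intervals, with
#'   names `r001`, `r002`, ...
#' @export
merge_repeat_intervals <- function(pairs = NULL, arrays = NULL) {
  starts <- c(pairs$startA, pairs$startB, arrays$start)
  ends <- c(pairs$endA, pairs$endB, arrays$end)
  if (length(starts) == 0) return(empty_features())
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- starts[i]; me <- ends[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  features(out_s, out_e, cls = "repeat", name = sprintf("r%03d", seq_along(out_s)))
}

#' Fraction of the genome covered by merged repeats
#' @param merged Merged repeat features.
#' @param L Genome length in bp.
#' @return Repeat content as a fraction in `[0, 1]`.
#' @export
repeat_content <- function(merged, L) {
  if (nrow(merged) == 0) return(0)
  sum(merged$end - merged$start) / L
}

#' Group associated repeats
#'
#' Builds the graph whose nodes are merged repeat features and whose edges join
#' features linked by any repeat pair (direct or inverted) or by interval
#' overlap; groups are the connected components. One representative sequence
#' per group (that of the longest member) can then be exported for cross-taxon
#' clustering.
#'
#' @param pairs Repeat pairs from [find_dispersed_repeats()].
#' @param merged Merged repeat features from [merge_repeat_intervals()].
#' @return `merged` with columns `group_id` (integer, 1-based, ordered by first
#'   member coordinate) and `member_count` (features in the group).
#' @export
group_repeats <- function(pairs, merged) {
  n <- nrow(merged)
  if (n == 0) { merged$group_id <- integer(0); merged$member_count <- integer(0); return(merged) }
  find_member <- function(s, e) {
    which(merged$start < e & merged$end > s)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  edges <- integer(0)
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- find_member(pairs$startA[i], pairs$endA[i])
      b <- find_member(pairs$startB[i], pairs$endB[i])
      if (length(a) && length(b)) {
        edges <- c(edges, as.vector(rbind(rep(a[1], length(b)), b)))
      }
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  ## relabel so group ids follow first-member coordinates
  first <- tapply(seq_len(n), comp, min)
  relabel <- rank(merged$start[first], ties.method = "first")
  merged$group_id <- as.integer(relabel[match(comp, names(first))])
  counts <- table(merged$group_id)
  merged$member_count <- as.integer(counts[as.character(merged$group_id)])
  merged
}

#' Representative sequence per repeat group
#'
#' @param genome A [circular_genome()].
#' @param grouped Output of [group_repeats()].
#' @return Data frame `taxon_id`, `group_id`, `sequence` (longest member of
#'   each group), ordered by `group_id`.
#' @export
group_representatives <- function(genome, grouped) {
  if (nrow(grouped) == 0) {
    return(data.frame(taxon_id = character(0), group_id = integer(0),
                      sequence = character(0)))
  }
  reps <- lapply(split(grouped, grouped$group_id), function(gg) {
    gg <- gg[order(-(gg$end - gg$start), gg$start), , drop = FALSE]
    data.frame(taxon_id = genome$taxon_id, group_id = gg$group_id[1],
               sequence = substr0(genome$sequence, gg$start[1],
                                  min(gg$end[1], genome$length)))
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out[order(out$group_id), , drop = FALSE]
}
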