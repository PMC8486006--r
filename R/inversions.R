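## Inversion detection between a query plastome and an uninverted reference:
## maximal-unique-match anchors, reverse-block detection, exact endpoint
## refinement by junction mismatch minimization, and endpoint sequence
## geometry (microhomology, short inverted repeats).

#' Find maximal unique match anchors between two sequences
#'
#' Exact matches at least `min_len` bp long built from `min_len`-mers that are
#' unique in both sequences, merged into maximal runs along their diagonal;
#' both orientations are scanned. Coordinates are 0-based; for reverse
#' anchors `q_start` refers to the forward strand of the query.
#'
#' @param query,reference DNA strings or [circular_genome()]s.
#' @param min_len Minimum anchor length in bp (default 20).
#' @return Data frame `q_start`, `r_start`, `length`, `orientation`
#'   (`"forward"`/`"reverse"`), sorted by `q_start`.
#' @export
find_anchors <- function(query, reference, min_len = 20) {
  q <- if (inherits(query, "circular_genome")) query$sequence else toupper(query)
  r <- if (inherits(reference, "circular_genome")) reference$sequence else toupper(reference)
  k <- min_len
  fwd <- unique_match_runs(q, r, k)
  qrc <- revcomp(q)
  rev <- unique_match_runs(qrc, r, k)
  out <- list()
  if (nrow(fwd)) out$f <- data.frame(q_start = fwd$a, r_start = fwd$b,
                                     length = fwd$len, orientation = "forward")
  if (nrow(rev)) {
    Lq <- nchar(q)
    out$r <- data.frame(q_start = Lq - (rev$a + rev$len), r_start = rev$b,
                        length = rev$len, orientation = "reverse")
  }
  if (length(out) == 0) {
    return(data.frame(q_start = numeric(0), r_start = numeric(0),
                      length = numeric(0), orientation = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$q_start, res$r_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## maximal runs of k-mers unique in both sequences; returns 0-based starts
unique_match_runs <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  none <- data.frame(a = numeric(0), b = numeric(0), len = numeric(0))
  if (na < k || nb < k) return(none)
  akm <- substring(a, 1:(na - k + 1), k:na)
  bkm <- substring(b, 1:(nb - k + 1), k:nb)
  a_uni <- !(duplicated(akm) | duplicated(akm, fromLast = TRUE))
  b_uni <- !(duplicated(bkm) | duplicated(bkm, fromLast = TRUE))
  hit <- match(akm, bkm)
  ok <- which(!is.na(hit) & a_uni & b_uni[pmax(hit, 1)])
  if (length(ok) == 0) return(none)
  ai <- ok - 1; bi <- hit[ok] - 1
  d <- bi - ai
  o <- order(d, ai)
  ai <- ai[o]; bi <- bi[o]; d <- d[o]
  new_run <- c(TRUE, diff(ai) != 1 | diff(d) != 0)
  run_id <- cumsum(new_run)
  a0 <- tapply(ai, run_id, min)
  a1 <- tapply(ai, run_id, max) + k
  data.frame(a = as.numeric(a0), b = as.numeric(a0 + d[new_run]),
             len = as.numeric(a1 - a0))
}

#' Detect large inversions from anchors
#'
#' Chains anchors by query coordinate into same-orientation blocks. A
#' reverse-oriented block spanning at least `min_block` bp between forward
#' blocks is reported as one inversion with approximate endpoints at the
#' midpoints of the anchor gaps. Nested candidates are collapsed to the
#' outermost block with a warning.
#'
#' @param anchors Output of [find_anchors()].
#' @param min_block Minimum inverted block span in bp (default 1000).
#' @param taxon_id Taxon label for the records (default `NA`).
#' @return List of [inversion_record()]s (empty when no reverse block). Each
#'   record carries `left_offset`/`right_offset` attributes: the
#'   query-to-reference coordinate offsets of the flanking forward blocks,
#'   used by [refine_endpoints()].
#' @export
detect_inversions <- function(anchors, min_block = 1000, taxon_id = NA_character_) {
  if (nrow(anchors) == 0) return(list())
  anchors <- anchors[order(anchors$q_start), , drop = FALSE]
  blk_id <- cumsum(c(TRUE, anchors$orientation[-1] != anchors$orientation[-nrow(anchors)]))
  blocks <- do.call(rbind, lapply(split(anchors, blk_id), function(bb) {
    data.frame(orientation = bb$orientation[1],
               q_lo = min(bb$q_start), q_hi = max(bb$q_start + bb$length),
               r_lo = min(bb$r_start), r_hi = max(bb$r_start + bb$length),
               first_fwd_off = bb$r_start[1] - bb$q_start[1])
  }))
  rev_idx <- which(blocks$orientation == "reverse" &
                     blocks$q_hi - blocks$q_lo >= min_block)
  if (length(rev_idx) == 0) return(list())
  ## collapse nested reverse blocks (ref span containment) to the outermost
  if (length(rev_idx) > 1) {
    outer <- rep(TRUE, length(rev_idx))
    for (i in seq_along(rev_idx)) for (j in seq_along(rev_idx)) {
      if (i != j && outer[j] &&
          blocks$q_lo[rev_idx[i]] >= blocks$q_lo[rev_idx[j]] &&
          blocks$q_hi[rev_idx[i]] <= blocks$q_hi[rev_idx[j]]) outer[i] <- FALSE
    }
    if (!all(outer)) warning("nested inversion candidates: reporting outermost only")
    rev_idx <- rev_idx[outer]
  }
  lapply(rev_idx, function(i) {
    ## chance matches can extend a flanking forward anchor a few bases past
    ## the junction, so flanks are chosen by start position and the gap
    ## midpoint is taken even when blocks marginally overlap
    prev_fwd <- max(which(blocks$orientation == "forward" &
                            blocks$q_lo < blocks$q_lo[i]), -Inf)
    next_fwd <- min(which(blocks$orientation == "forward" &
                            blocks$q_hi > blocks$q_hi[i]), Inf)
    left_gap <- if (is.finite(prev_fwd)) c(blocks$q_hi[prev_fwd], blocks$q_lo[i]) else
      c(blocks$q_lo[i], blocks$q_lo[i])
    right_gap <- if (is.finite(next_fwd)) c(blocks$q_hi[i], blocks$q_lo[next_fwd]) else
      c(blocks$q_hi[i], blocks$q_hi[i])
    o1 <- if (is.finite(prev_fwd)) blocks$r_hi[prev_fwd] - blocks$q_hi[prev_fwd] else 0
    o2 <- if (is.finite(next_fwd)) blocks$r_lo[next_fwd] - blocks$q_lo[next_fwd] else 0
    rec <- inversion_record(taxon_id,
                            approx_left = floor(mean(left_gap)),
                            approx_right = ceiling(mean(right_gap)))
    attr(rec, "left_gap") <- left_gap
    attr(rec, "right_gap") <- right_gap
    attr(rec, "left_offset") <- o1
    attr(rec, "right_offset") <- o2
    rec
  })
}

#' Refine inversion endpoints by junction mismatch minimization
#'
#' Over all candidate endpoint pairs `(a, b)` within `search` bp of the
#' approximate endpoints, scores the reversion at `(a, b)` by the total number
#' of mismatching positions in the four `context`-bp junction flanks of the
#' reverted query against the reference, and returns the argmin (ties broken
#' by smaller `a`, then smaller `b`). The candidate grid itself absorbs
#' positional shifts, so each flank comparison is gap-free and computed
#' exactly via diagonal match-vector cumulative sums.
#'
#' @param query,reference DNA strings or [circular_genome()]s (reference
#'   colinear with the query outside the inversion).
#' @param inv An [inversion_record()] from [detect_inversions()].
#' @param search Search radius around each approximate endpoint in bp
#'   (default 250).
#' @param context Junction flank length scored on each side in bp
#'   (default 250).
#' @return The record with `refined_left`/`refined_right` set and a
#'   `junction_score` attribute (total mismatches at the optimum).
#' @export
refine_endpoints <- function(query, reference, inv, search = 250, context = 250) {
  q <- if (inherits(query, "circular_genome")) query$sequence else toupper(query)
  r <- if (inherits(reference, "circular_genome")) reference$sequence else toupper(reference)
  qc <- seq_chars(q); rc <- seq_chars(r)
  qv <- seq_chars(revcomp(q))
  Lq <- length(qc); Lr <- length(rc)
  al <- inv$approx_left; bl <- inv$approx_right
  o1 <- attr(inv, "left_offset") %||% 0
  o2 <- attr(inv, "right_offset") %||% 0
  cx <- context
  a_cand <- max(cx + 1, al - search):min(al + search, Lq - cx - 1)
  b_cand <- max(cx + 1, bl - search):min(bl + search, Lq - cx - 1)
  a_cand <- a_cand[a_cand + o1 >= cx & a_cand + o1 + cx <= Lr]
  b_cand <- b_cand[b_cand + o2 >= cx & b_cand + o2 + cx <= Lr]
  if (!length(a_cand) || !length(b_cand)) stop("no admissible endpoint candidates")

  ## mismatch count between qx[x, x+len) and rc[x+d, x+d+len) via cumsums
  diag_cum <- function(qx, d, x0, x1) {
    x0 <- max(x0, 0, -d); x1 <- min(x1, length(qx), Lr - d)
    v <- qx[(x0 + 1):x1] != rc[(x0 + d + 1):(x1 + d)]
    list(x0 = x0, cum = c(0, cumsum(v)))
  }
  wsum <- function(dc, x, len) {
    i <- x - dc$x0
    dc$cum[i + len + 1] - dc$cum[i + 1]
  }

  ## outside-left f(a): q[a-cx, a) vs ref on diagonal o1
  f_dc <- diag_cum(qc, o1, min(a_cand) - cx, max(a_cand))
  f_a <- vapply(a_cand, function(a) wsum(f_dc, a - cx, cx), numeric(1))
  ## outside-right h(b): q[b, b+cx) vs ref on diagonal o2
  h_dc <- diag_cum(qc, o2, min(b_cand), max(b_cand) + cx)
  h_b <- vapply(b_cand, function(b) wsum(h_dc, b, cx), numeric(1))

  ## inside flanks live on diagonals of revcomp(query) vs reference indexed by
  ## s = a + b: term2 = qv[Lq-b, Lq-b+cx) vs ref[a+o1, .) on diagonal s+o1-Lq,
  ##            term3 = qv[Lq-a-cx, Lq-a) vs ref[b+o2-cx, .) on diagonal s+o2-Lq
  s_vals <- (min(a_cand) + min(b_cand)):(max(a_cand) + max(b_cand))
  x2_lo <- Lq - max(b_cand); x2_hi <- Lq - min(b_cand) + cx
  x3_lo <- Lq - max(a_cand) - cx; x3_hi <- Lq - min(a_cand)
  t2 <- lapply(s_vals, function(s) diag_cum(qv, s + o1 - Lq, x2_lo, x2_hi))
  t3 <- lapply(s_vals, function(s) diag_cum(qv, s + o2 - Lq, x3_lo, x3_hi))
  names(t2) <- names(t3) <- s_vals

  ## score matrix: rows = b candidates, cols = a candidates; inside-flank terms
  ## added per anti-diagonal (fixed a + b), vectorized over its grid points
  S <- outer(h_b, f_a, "+")
  for (k in seq_along(s_vals)) {
    s <- s_vals[k]
    a_ok <- a_cand[a_cand >= s - max(b_cand) & a_cand <= s - min(b_cand)]
    if (!length(a_ok)) next
    b_ok <- s - a_ok
    x2 <- Lq - b_ok
    w2 <- t2[[k]]$cum[x2 - t2[[k]]$x0 + cx + 1] - t2[[k]]$cum[x2 - t2[[k]]$x0 + 1]
    x3 <- Lq - a_ok - cx
    w3 <- t3[[k]]$cum[x3 - t3[[k]]$x0 + cx + 1] - t3[[k]]$cum[x3 - t3[[k]]$x0 + 1]
    idx <- cbind(match(b_ok, b_cand), match(a_ok, a_cand))
    S[idx] <- S[idx] + w2 + w3
  }
  ## column-major scan = smallest a first, then smallest b: the tie-break order
  best <- which.min(S)
  best_b <- b_cand[(best - 1) %% length(b_cand) + 1]
  best_a <- a_cand[(best - 1) %/% length(b_cand) + 1]

  ## baseline: no reversion, junctions compared directly at approximations
  a0 <- a_cand[which.min(abs(a_cand - al))]; b0 <- b_cand[which.min(abs(b_cand - bl))]
  in_l <- diag_cum(qc, o1, a0, a0 + cx)
  in_r <- diag_cum(qc, o2, b0 - cx, b0)
  baseline <- wsum(f_dc, a0 - cx, cx) + wsum(h_dc, b0, cx) +
    wsum(in_l, a0, cx) + wsum(in_r, b0 - cx, cx)
  if (S[best] >= baseline) {
    stop("refinement failed: no candidate improves on the unreverted alignment")
  }
  inv$refined_left <- best_a
  inv$refined_right <- best_b
  attr(inv, "junction_score") <- unname(S[best])
  inv
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Microhomology at refined inversion endpoints
#'
#' Compares the sequence entering the inverted segment at one refined endpoint
#' with the reverse complement of the sequence entering it at the other: site
#' `i` matches when the base at `refined_left + i - 1` complements the base at
#' `refined_right - i`. Because a microhomology makes the endpoints ambiguous
#' (any pair shifted symmetrically within the complementary run reverts to the
#' same genome) and [refine_endpoints()] resolves the tie leftward, the
#' microhomology lies just inside the refined junctions. Reports the leading
#' run of consecutive complementary sites and the number of complementary sites
#' within the first `window` sites. A hit is flagged MMBIR-consistent when the
#' leading run is at least 4 and at least 80% of the window sites complement —
#' descriptive thresholds for microhomology-mediated break-induced
#' replication, not a significance test.
#'
#' @param query DNA string or [circular_genome()] (the inverted plastome).
#' @param inv An [inversion_record()] with refined endpoints.
#' @param window Number of sites inspected (default 12; 10-12 is typical).
#' @return List `positionA`, `positionB`, `window`, `matches_in_window`,
#'   `leading_run`, `mmbir_consistent`.
#' @export
scan_microhomology <- function(query, inv, window = 12) {
  q <- if (inherits(query, "circular_genome")) query$sequence else toupper(query)
  a <- if (!is.na(inv$refined_left)) inv$refined_left else inv$approx_left
  b <- if (!is.na(inv$refined_right)) inv$refined_right else inv$approx_right
  n_max <- min(b - a, 4 * window)
  inward_left <- seq_chars(substr0(q, a, a + n_max))
  inward_right <- seq_chars(substr0(q, b - n_max, b))
  compl <- inward_left == comp_chars(rev(inward_right))
  leading <- if (!length(compl) || !compl[1]) 0 else {
    runs <- rle(compl); runs$lengths[1]
  }
  win <- compl[seq_len(min(window, length(compl)))]
  matches <- sum(win)
  list(positionA = a, positionB = b, window = window,
       matches_in_window = matches, leading_run = leading,
       mmbir_consistent = leading >= 4 && matches >= 0.8 * window)
}

#' Find short direct and inverted repeat pairs in a region
#'
#' Exhaustive diagonal scan for repeat pairs at least `min_len` bp long with at
#' most `floor(max_mismatch_frac * length)` mismatches, in both orientations,
#' within one region or between two regions. Reported pairs are
#' containment-maximal on their diagonal.
#'
#' @param seq_region DNA string (region A).
#' @param seq_region2 Optional second DNA string; when given, pairs are sought
#'   between the two regions instead of within one.
#' @param min_len Minimum pair length in bp (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction (default 0.10).
#' @param max_len Longest pair length considered (default 250 bp).
#' @return Data frame `startA`, `endA`, `startB`, `endB` (0-based within each
#'   region), `length`, `mismatches`, `orientation`.
#' @export
find_short_irs <- function(seq_region, seq_region2 = NULL, min_len = 10,
                           max_mismatch_frac = 0.10, max_len = 250) {
  x <- seq_chars(toupper(seq_region))
  cross <- !is.null(seq_region2)
  y <- if (cross) seq_chars(toupper(seq_region2)) else x
  n <- length(x); m <- length(y)
  res <- list()
  ## any valid segment (>= min_len, mismatches <= floor(frac * len)) contains
  ## an exact run of at least `seed` matches (pigeonhole over its gaps)
  seed <- min(vapply(min_len:max_len, function(L) {
    ceiling((L - floor(max_mismatch_frac * L)) / (floor(max_mismatch_frac * L) + 1))
  }, numeric(1)))
  max_gaps <- floor(max_mismatch_frac * max_len)
  scan_orient <- function(b, orientation, self_direct) {
    nb <- length(b)
    dmin <- if (self_direct) 1 else -(n - min_len)
    for (d in dmin:(nb - min_len)) {
      lo <- max(0, -d); hi <- min(n, nb - d)
      Ld <- hi - lo
      if (Ld < min_len) next
      mm <- x[(lo + 1):hi] != b[(lo + d + 1):(hi + d)]
      ## mismatch positions with boundary sentinels (0-based)
      M <- c(-1, which(mm) - 1, Ld)
      block_len <- diff(M) - 1
      seeds <- which(block_len >= seed)
      if (!length(seeds)) next
      cand <- list()
      for (t in seeds) {
        p <- max(1, t - max_gaps):t
        q <- (t + 1):min(length(M), t + 1 + max_gaps)
        g <- expand.grid(p = p, q = q)
        len <- M[g$q] - M[g$p] - 1
        mis <- g$q - g$p - 1
        ok <- len >= min_len & len <= max_len &
          mis <= floor(max_mismatch_frac * len) &
          block_len[g$p] > 0 & block_len[g$q - 1] > 0  # matching terminal bases
        if (any(ok)) cand[[length(cand) + 1]] <- cbind(g$p[ok], g$q[ok], len[ok], mis[ok])
      }
      if (!length(cand)) next
      cm <- unique(do.call(rbind, cand))
      maximal <- vapply(seq_len(nrow(cm)), function(i) {
        !any(cm[, 1] <= cm[i, 1] & cm[, 2] >= cm[i, 2] &
               (cm[, 1] < cm[i, 1] | cm[, 2] > cm[i, 2]))
      }, logical(1))
      cm <- cm[maximal, , drop = FALSE]
      for (i in seq_len(nrow(cm))) {
        a0 <- lo + M[cm[i, 1]] + 1
        len <- cm[i, 3]
        res[[length(res) + 1]] <<- data.frame(
          startA = a0, endA = a0 + len, startB = a0 + d, endB = a0 + d + len,
          length = len, mismatches = cm[i, 4], orientation = orientation)
      }
    }
  }
  scan_orient(y, "direct", self_direct = !cross)
  yr <- if (cross) comp_chars(rev(y)) else comp_chars(rev(x))
  scan_orient(yr, "inverted", self_direct = FALSE)
  if (length(res) == 0) {
    return(data.frame(startA = numeric(0), endA = numeric(0),
                      startB = numeric(0), endB = numeric(0),
                      length = numeric(0), mismatches = numeric(0),
                      orientation = character(0)))
  }
  out <- do.call(rbind, res)
  ## map inverted B coordinates back from the reverse complement
  invr <- out$orientation == "inverted"
  if (any(invr)) {
    nb <- if (cross) m else n
    bs <- nb - out$endB[invr]; be <- nb - out$startB[invr]
    out$startB[invr] <- bs; out$endB[invr] <- be
  }
  if (!cross) {
    ## canonicalize within-region pairs and drop self-palindromes / duplicates
    swap <- out$startB < out$startA
    tmp_s <- out$startA[swap]; tmp_e <- out$endA[swap]
    out$startA[swap] <- out$startB[swap]; out$endA[swap] <- out$endB[swap]
    out$startB[swap] <- tmp_s; out$endB[swap] <- tmp_e
    out <- out[!(out$startA == out$startB & out$endA == out$endB), , drop = FALSE]
    out <- out[!duplicated(out[, c(1:4, 7)]), , drop = FALSE]
  }
  out <- out[order(-out$length, out$startA, out$startB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify repeat geometry at inversion endpoints
#'
#' Looks for short inverted repeat pairs linking the two endpoint vicinities of
#' an inversion (within `flank` bp of each refined endpoint), then maps each
#' pair through [revert_features()] back to the ancestral arrangement:
#' `direct-repeats-one-end` when the two copies ancestrally sat on the same
#' side of the inversion in the same orientation, `inverted-repeats-both-ends`
#' when they ancestrally flanked both endpoints in opposite orientation, else
#' `none`.
#'
#' @param query DNA string or [circular_genome()] (inverted plastome).
#' @param reference Unused except for interface symmetry; may be `NULL`.
#' @param inv An [inversion_record()] with refined endpoints.
#' @param flank Vicinity width around each endpoint in bp (default 1000).
#' @param min_len,max_mismatch_frac Passed to [find_short_irs()].
#' @return List with `inversion`, `flanking_irs` (pairs in query coordinates),
#'   `ancestral_arrangement`, and `microhomology` (from
#'   [scan_microhomology()]).
#' @export
classify_endpoint_repeat_geometry <- function(query, reference = NULL, inv,
                                              flank = 1000, min_len = 10,
                                              max_mismatch_frac = 0.10) {
  q <- if (inherits(query, "circular_genome")) query$sequence else toupper(query)
  Lq <- nchar(q)
  a <- if (!is.na(inv$refined_left)) inv$refined_left else inv$approx_left
  b <- if (!is.na(inv$refined_right)) inv$refined_right else inv$approx_right
  a_lo <- max(0, a - flank); a_hi <- min(Lq, a + flank)
  b_lo <- max(0, b - flank); b_hi <- min(Lq, b + flank)
  vicA <- substr0(q, a_lo, a_hi)
  vicB <- substr0(q, b_lo, b_hi)
  irs <- find_short_irs(vicA, vicB, min_len = min_len,
                        max_mismatch_frac = max_mismatch_frac)
  irs <- irs[irs$orientation == "inverted", , drop = FALSE]
  mh <- scan_microhomology(q, inv)
  if (nrow(irs) == 0) {
    warning("no flanking repeats within ", flank, " bp of either endpoint")
    return(list(inversion = inv, flanking_irs = irs,
                ancestral_arrangement = "none", microhomology = mh))
  }
  ## query coordinates of the pair members
  irs$startA <- irs$startA + a_lo; irs$endA <- irs$endA + a_lo
  irs$startB <- irs$startB + b_lo; irs$endB <- irs$endB + b_lo
  best <- irs[1, ]  # longest pair
  pair_feats <- features(c(best$startA, best$startB), c(best$endA, best$endB),
                         strand = c("+", "-"), cls = "repeat",
                         name = c("copyA", "copyB"))
  anc <- suppressWarnings(revert_features(pair_feats, a, b))
  anc <- anc[anc$name %in% c("copyA", "copyB"), , drop = FALSE]
  if (nrow(anc) < 2) {
    return(list(inversion = inv, flanking_irs = irs,
                ancestral_arrangement = "none", microhomology = mh))
  }
  mid <- (anc$start + anc$end) / 2
  near_a <- abs(mid - a) <= 2 * flank
  near_b <- abs(mid - b) <= 2 * flank
  same_side <- (all(near_a) && !any(near_b & !near_a)) || all(near_b)
  same_orient <- anc$strand[1] == anc$strand[2]
  arrangement <- if (same_side && same_orient) {
    "direct-repeats-one-end"
  } else if (!same_side && !same_orient) {
    "inverted-repeats-both-ends"
  } else "none"
  list(inversion = inv, flanking_irs = irs,
       ancestral_arrangement = arrangement, microhomology = mh)
}
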