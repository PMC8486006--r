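## Independent brute-force oracles and small fixture builders used across the
## suite. Oracles are deliberately naive (diagonal scans, full enumeration,
## textbook DP) and share no code with the implementation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_oracle <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

plant <- function(s, at, motif) {          # at is 0-based
  substr(s, at + 1, at + nchar(motif)) <- motif
  s
}

jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / (max(e1, e2) - min(s1, s2))
}

## all maximal exact repeat pairs >= min_len within s, both orientations,
## by full per-diagonal run scanning; containment-filtered like the contract
oracle_exact_pairs <- function(s, min_len = 30) {
  x <- strsplit(s, "")[[1]]; n <- length(x)
  rows <- list()
  scan <- function(y, inverted) {
    for (d in (if (inverted) -(n - 1) else 1):(n - min_len)) {
      lo <- max(0, -d); hi <- min(n, n - d)
      if (hi - lo < min_len) next
      m <- x[(lo + 1):hi] == y[(lo + d + 1):(hi + d)]
      r <- rle(m); ends <- cumsum(r$lengths); starts <- ends - r$lengths
      for (k in which(r$values & r$lengths >= min_len)) {
        a0 <- lo + starts[k]; len <- r$lengths[k]
        b0 <- a0 + d
        if (inverted) { bs <- n - (b0 + len); be <- n - b0 } else { bs <- b0; be <- b0 + len }
        a <- c(a0, a0 + len)
        if (bs < a[1]) { tmp <- a; a <- c(bs, be); bs <- tmp[1]; be <- tmp[2] }
        if (a[1] == bs && a[2] == be) next
        rows[[length(rows) + 1]] <<- data.frame(
          startA = a[1], endA = a[2], startB = bs, endB = be,
          orientation = if (inverted) "inverted" else "direct", length = len)
      }
    }
  }
  scan(x, inverted = FALSE)
  scan(rev(chartr("ACGT", "TGCA", x)), inverted = TRUE)
  if (length(rows) == 0) {
    return(data.frame(startA = numeric(0), endA = numeric(0),
                      startB = numeric(0), endB = numeric(0),
                      orientation = character(0), length = numeric(0)))
  }
  out <- unique(do.call(rbind, rows))
  ## drop pairs contained (both intervals) in another pair
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$startA <= out$startA[i] & out$endA >= out$endA[i] &
           out$startB <= out$startB[i] & out$endB >= out$endB[i] &
           out$length > out$length[i] & out$orientation == out$orientation[i])
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$orientation, out$startA, out$startB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## does s contain any 30-bp window pair (any diagonal, either orientation)
## matching at >= min_id? used to certify repeat-free fixtures
oracle_has_repeat_window <- function(s, win = 30, min_id = 0.9) {
  x <- strsplit(s, "")[[1]]; n <- length(x)
  need <- ceiling(min_id * win)
  check <- function(y, self) {
    for (d in (if (self) 1 else -(n - 1)):(n - win)) {
      lo <- max(0, -d); hi <- min(n, n - d)
      if (hi - lo < win) next
      m <- x[(lo + 1):hi] == y[(lo + d + 1):(hi + d)]
      cs <- c(0, cumsum(m))
      if (max(cs[(win + 1):length(cs)] - cs[1:(length(cs) - win)]) >= need) return(TRUE)
    }
    FALSE
  }
  check(x, TRUE) || check(rev(chartr("ACGT", "TGCA", x)), FALSE)
}

## is there any tandem structure (period <= max_p) with window identity above
## threshold anywhere in s?
oracle_has_tandem <- function(s, min_total = 30, max_p = 500, min_id = 0.8) {
  x <- strsplit(s, "")[[1]]; n <- length(x)
  for (p in seq_len(min(max_p, n - 1))) {
    w <- max(p, min_total - p)
    if (n - p < w) next
    m <- x[1:(n - p)] == x[(p + 1):n]
    cs <- c(0, cumsum(m))
    if (length(cs) - w < 1) next
    if (max(cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) >= ceiling(min_id * w)) {
      return(TRUE)
    }
  }
  FALSE
}

## all maximal exact matches >= min_len between q and r (both orientations of
## q), keeping only matches whose substring occurs exactly once in each
count_fixed <- function(s, pat) {
  hits <- gregexpr(pat, s, fixed = TRUE)[[1]]
  if (identical(as.integer(hits[1]), -1L)) 0L else length(hits)
}

oracle_mums <- function(q, r, min_len = 20) {
  rows <- list()
  scan <- function(qq, orient) {
    x <- strsplit(qq, "")[[1]]; y <- strsplit(r, "")[[1]]
    nq <- length(x); nr <- length(y)
    for (d in -(nq - min_len):(nr - min_len)) {
      lo <- max(0, -d); hi <- min(nq, nr - d)
      if (hi - lo < min_len) next
      m <- x[(lo + 1):hi] == y[(lo + d + 1):(hi + d)]
      rl <- rle(m); ends <- cumsum(rl$lengths); starts <- ends - rl$lengths
      for (k in which(rl$values & rl$lengths >= min_len)) {
        a0 <- lo + starts[k]; len <- rl$lengths[k]
        pat <- substr(qq, a0 + 1, a0 + len)
        if (count_fixed(q, pat) + count_fixed(rc_oracle(q), pat) != 1) next
        if (count_fixed(r, pat) + count_fixed(rc_oracle(r), pat) != 1) next
        qs <- if (orient == "reverse") nq - (a0 + len) else a0
        rows[[length(rows) + 1]] <<- data.frame(
          q_start = qs, r_start = a0 + d, length = len, orientation = orient)
      }
    }
  }
  scan(q, "forward")
  scan(rc_oracle(q), "reverse")
  if (length(rows) == 0) {
    return(data.frame(q_start = numeric(0), r_start = numeric(0),
                      length = numeric(0), orientation = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$q_start, out$r_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## full-enumeration short repeat pair scan (both orientations) with matching
## terminal bases and per-diagonal containment maximality
oracle_short_irs <- function(s, min_len = 10, frac = 0.10, max_len = 200) {
  x <- strsplit(s, "")[[1]]; n <- length(x)
  rows <- list()
  scan <- function(y, orientation, self) {
    for (d in (if (self) 1 else -(n - 1)):(n - min_len)) {
      lo <- max(0, -d); hi <- min(n, n - d)
      Ld <- hi - lo
      if (Ld < min_len) next
      mm <- x[(lo + 1):hi] != y[(lo + d + 1):(hi + d)]
      cum <- c(0, cumsum(mm))
      grid <- expand.grid(i0 = 0:(Ld - min_len), len = min_len:min(max_len, Ld))
      grid <- grid[grid$i0 + grid$len <= Ld, ]
      mis <- cum[grid$i0 + grid$len + 1] - cum[grid$i0 + 1]
      ok <- mis <= floor(frac * grid$len) & !mm[grid$i0 + 1] &
        !mm[grid$i0 + grid$len]
      if (!any(ok)) next
      sm <- cbind(grid$i0[ok], grid$i0[ok] + grid$len[ok], mis[ok])
      maximal <- vapply(seq_len(nrow(sm)), function(i) {
        !any(sm[, 1] <= sm[i, 1] & sm[, 2] >= sm[i, 2] &
               (sm[, 2] - sm[, 1]) > (sm[i, 2] - sm[i, 1]))
      }, logical(1))
      for (i in which(maximal)) {
        a0 <- lo + sm[i, 1]; len <- sm[i, 2] - sm[i, 1]
        b0 <- a0 + d
        if (orientation == "inverted") { bs <- n - (b0 + len); be <- n - b0 }
        else { bs <- b0; be <- b0 + len }
        a <- c(a0, a0 + len)
        if (bs < a[1]) { tmp <- a; a <- c(bs, be); bs <- tmp[1]; be <- tmp[2] }
        if (a[1] == bs && a[2] == be) next
        rows[[length(rows) + 1]] <<- data.frame(
          startA = a[1], endA = a[2], startB = bs, endB = be, length = len,
          mismatches = sm[i, 3], orientation = orientation)
      }
    }
  }
  scan(x, "direct", self = TRUE)
  scan(rev(chartr("ACGT", "TGCA", x)), "inverted", self = FALSE)
  if (length(rows) == 0) {
    return(data.frame(startA = numeric(0), endA = numeric(0),
                      startB = numeric(0), endB = numeric(0),
                      length = numeric(0), mismatches = numeric(0),
                      orientation = character(0)))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(-out$length, out$startA, out$startB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## textbook affine-gap Smith-Waterman, for certifying absent similarity edges
oracle_local_align <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_ext = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1); Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- if (x[i - 1] == y[j - 1]) match else mismatch
    M[i, j] <- max(0, M[i - 1, j - 1] + sc, Ix[i - 1, j - 1] + sc,
                   Iy[i - 1, j - 1] + sc)
    Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
    Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
    best <- max(best, M[i, j])
  }
  best
}

## tiny annotated genome used by geometry and naming tests
toy_genome <- function(L = 16000, n_genes = 14, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- rand_dna(L)
  starts <- seq(300, L - 900, length.out = n_genes)
  f <- features(starts, starts + 500, strand = rep(c("+", "-"), length.out = n_genes),
                cls = "gene", name = sprintf("g%d", seq_len(n_genes)))
  circular_genome("toy", s, f)
}
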