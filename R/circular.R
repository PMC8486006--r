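## Circular-genome coordinate system: features, padding, windows, reversion.
## Convention: 0-based half-open intervals; a feature crossing the origin of a
## genome of length L keeps start < L and encodes the wrap with end in (L, 2L].

FEATURE_CLASSES <- c("gene", "exon", "intron", "intergenic", "repeat",
                     "endpoint", "window")

#' Construct a feature table
#'
#' Features are plain data frames with columns `start`, `end` (0-based,
#' half-open; `end > L` encodes an origin wrap), `strand` (`"+"` or `"-"`),
#' `cls` (one of gene, exon, intron, intergenic, repeat, endpoint, window) and
#' `name`.
#'
#' @param start,end Integer vectors of interval bounds (0-based, half-open).
#' @param strand Strand, `"+"` or `"-"` (recycled).
#' @param cls Feature class (recycled).
#' @param name Feature names (recycled).
#' @return A data frame with one row per feature.
#' @export
#' @examples
#' features(c(0, 100), c(50, 160), cls = "repeat")
features <- function(start, end, strand = "+", cls = "repeat", name = NA_character_) {
  if (length(start) != length(end)) stop("start and end must have equal length")
  stopifnot(all(cls %in% FEATURE_CLASSES))
  data.frame(start = as.numeric(start), end = as.numeric(end),
             strand = rep_len(strand, length(start)),
             cls = rep_len(cls, length(start)),
             name = rep_len(as.character(name), length(start)),
             stringsAsFactors = FALSE)
}

empty_features <- function() features(numeric(0), numeric(0))

#' Construct a circular genome
#'
#' @param taxon_id Taxon identifier.
#' @param sequence DNA string over `{A,C,G,T,N}` (uppercased on input).
#' @param features Feature table (see [features()]); validated against the
#'   sequence length.
#' @return An object of class `circular_genome` with elements `taxon_id`,
#'   `sequence`, `length`, `features`.
#' @export
circular_genome <- function(taxon_id, sequence, features = empty_features()) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence)) stop("sequence has characters outside {A,C,G,T,N}")
  validate_features(features, L)
  structure(list(taxon_id = taxon_id, sequence = sequence, length = L,
                 features = features),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp, %d features\n",
              x$taxon_id, format(x$length, big.mark = ","), nrow(x$features)))
  invisible(x)
}

validate_features <- function(features, L) {
  if (nrow(features) == 0) return(invisible(TRUE))
  with(features, {
    if (any(start < 0 | start >= L)) stop("feature start outside [0, L)")
    if (any(end <= 0 | end > 2 * L)) stop("feature end outside (0, 2L]")
    if (any(end - start < 1)) stop("feature length < 1")
    if (any(end - start > L)) stop("feature longer than genome")
  })
  invisible(TRUE)
}

#' Canonicalize an interval on a circular genome
#'
#' Wrapping intervals (given either with `end <= start`, meaning the end
#' coordinate is taken modulo `L`, or directly with `end > L`) are encoded with
#' `start < L` and `end` in `(L, 2L]`.
#'
#' @param start,end Interval bounds (0-based half-open).
#' @param L Genome length in bp.
#' @param ... Passed to [features()] (`strand`, `cls`, `name`).
#' @return A one-row feature table.
#' @export
#' @examples
#' normalize_interval(90, 10, 100)  # wraps: end becomes 110
normalize_interval <- function(start, end, L, ...) {
  if (start < 0 || end < 0) stop("invalid interval: negative coordinates")
  if (start >= L) stop("invalid interval: start must be < L")
  if (end <= start) end <- end + L  # wrap given modulo L
  if (end - start > L) stop("invalid interval: length > L")
  features(start, end, ...)
}

#' Pad features across the origin
#'
#' Mirrors the linearization trick for circular molecules: features overlapping
#' the first `pad` bp are appended again shifted by `+L`, and features
#' overlapping the final `pad` bp are prepended shifted by `-L`, so statistics
#' near the origin see the same neighbourhood as interior positions. The
#' resulting coordinate axis is `[-pad, L + pad)`.
#'
#' @param features Feature table.
#' @param L Genome length in bp.
#' @param pad Pad width in bp (default 3000).
#' @return Feature table including the shifted copies.
#' @export
pad_features <- function(features, L, pad = 3000) {
  if (pad > L) stop("pad > genome length")
  if (nrow(features) == 0) return(features)
  first <- features[features$start < pad, , drop = FALSE]
  last <- features[features$end > L - pad, , drop = FALSE]
  if (nrow(first)) { first$start <- first$start + L; first$end <- first$end + L }
  if (nrow(last)) { last$start <- last$start - L; last$end <- last$end - L }
  out <- rbind(features, first, last)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Nonoverlapping windows over a genome
#'
#' Exactly `floor(L / size)` windows of exactly `size` bp starting at 0; any
#' trailing partial window is discarded, so a dispersion test over the counts
#' has `floor(L / size) - 1` degrees of freedom.
#'
#' @param L Genome length in bp.
#' @param size Window size in bp (default 3000).
#' @return Feature table of windows (`cls = "window"`).
#' @export
make_nonoverlapping_windows <- function(L, size = 3000) {
  if (size <= 0) stop("window size must be positive")
  if (size > L) stop("window size exceeds genome length")
  n <- floor(L / size)
  starts <- (seq_len(n) - 1) * size
  features(starts, starts + size, cls = "window",
           name = sprintf("w%03d", seq_len(n)))
}

#' Reverse-complement a segment in place
#'
#' Replaces the sequence in `[left, right)` by its reverse complement and maps
#' the genome's features through [revert_features()]. Applying the same call
#' twice returns the input exactly (involution). Wrap-crossing segments are not
#' supported; rotate the genome first (see [rotate_genome()]).
#'
#' @param genome A [circular_genome()].
#' @param left,right Segment bounds, `0 <= left < right <= L`.
#' @return The modified genome.
#' @export
revert_segment <- function(genome, left, right) {
  L <- genome$length
  if (!(left >= 0 && left < right && right <= L)) {
    stop("segment must satisfy 0 <= left < right <= L (rotate the genome first)")
  }
  f <- genome$features
  if (nrow(f) && any(f$end > L & (f$start < right | f$end - L > left))) {
    stop("wrapping feature overlaps the reverted segment; rotate first")
  }
  seg <- substr(genome$sequence, left + 1, right)
  genome$sequence <- paste0(substr(genome$sequence, 1, left), revcomp(seg),
                            substr(genome$sequence, right + 1, L))
  genome$features <- revert_features(genome$features, left, right)
  genome
}

#' Map features through a segment reversion
#'
#' Features wholly inside `[left, right)` are mapped to
#' `[left + right - end, left + right - start)` with the strand flipped;
#' features outside are unchanged. A feature straddling a boundary is split at
#' the boundary (with a warning) and each part handled separately; total
#' feature length is conserved.
#'
#' @param features Feature table.
#' @param left,right Segment bounds.
#' @return The mapped feature table.
#' @export
revert_features <- function(features, left, right) {
  if (nrow(features) == 0) return(features)
  straddle <- (features$start < left & features$end > left) |
    (features$start < right & features$end > right)
  if (any(straddle)) {
    warning(sum(straddle), " feature(s) straddle a reversion boundary; split at the boundary")
    pieces <- lapply(which(straddle), function(i) {
      f <- features[i, , drop = FALSE]
      cuts <- sort(unique(c(f$start, f$end, left[left > f$start & left < f$end],
                            right[right > f$start & right < f$end])))
      out <- f[rep(1, length(cuts) - 1), , drop = FALSE]
      out$start <- cuts[-length(cuts)]
      out$end <- cuts[-1]
      out
    })
    features <- rbind(features[!straddle, , drop = FALSE], do.call(rbind, pieces))
  }
  inside <- features$start >= left & features$end <= right
  if (any(inside)) {
    s <- features$start[inside]; e <- features$end[inside]
    features$start[inside] <- left + right - e
    features$end[inside] <- left + right - s
    features$strand[inside] <- ifelse(features$strand[inside] == "+", "-", "+")
  }
  rownames(features) <- NULL
  features[order(features$start, features$end), , drop = FALSE]
}

#' Rotate a circular genome
#'
#' Moves position `offset` to coordinate 0. Features are shifted modulo `L`
#' and re-encoded with the wrap convention.
#'
#' @param genome A [circular_genome()].
#' @param offset New origin, in `[0, L)`.
#' @return The rotated genome.
#' @export
rotate_genome <- function(genome, offset) {
  L <- genome$length
  offset <- offset %% L
  if (offset == 0) return(genome)
  genome$sequence <- paste0(substr(genome$sequence, offset + 1, L),
                            substr(genome$sequence, 1, offset))
  f <- genome$features
  if (nrow(f)) {
    len <- f$end - f$start
    f$start <- (f$start - offset) %% L
    f$end <- f$start + len
    genome$features <- f[order(f$start, f$end), , drop = FALSE]
  }
  genome
}

#' Name an inversion by its outermost moved loci
#'
#' Returns `"A ∼ B"` where `A` and `B` are the outermost annotated loci
#' (class `gene`) wholly inside the inverted segment, in the order they appear
#' in the inverted plastome. `annotations` must therefore be the feature table
#' of the *inverted* genome.
#'
#' @param annotations Feature table of the inverted genome.
#' @param left,right Inversion bounds in the inverted genome.
#' @return The inversion name, a single string.
#' @export
name_inversion <- function(annotations, left, right) {
  g <- annotations[annotations$cls == "gene" &
                     annotations$start >= left & annotations$end <= right, , drop = FALSE]
  if (nrow(g) == 0) stop("unnamed inversion: no annotated locus inside segment")
  g <- g[order(g$start), , drop = FALSE]
  sprintf("%s \u223c %s", g$name[1], g$name[nrow(g)])
}

#' Create an inversion record
#'
#' @param taxon_id Taxon carrying the inversion.
#' @param approx_left,approx_right Approximate endpoints from anchor gaps (bp).
#' @param refined_left,refined_right Refined endpoints (bp), or `NA` before
#'   refinement.
#' @param name Inversion name (`"A ∼ B"`), or `NA`.
#' @return An object of class `inversion_record`.
#' @export
inversion_record <- function(taxon_id, approx_left, approx_right,
                             refined_left = NA_real_, refined_right = NA_real_,
                             name = NA_character_) {
  structure(list(taxon_id = taxon_id,
                 approx_left = approx_left, approx_right = approx_right,
                 refined_left = refined_left, refined_right = refined_right,
                 name = name),
            class = "inversion_record")
}

#' @export
print.inversion_record <- function(x, ...) {
  cat(sprintf("<inversion> %s %s approx [%s, %s) refined [%s, %s)\n",
              x$taxon_id, ifelse(is.na(x$name), "(unnamed)", x$name),
              x$approx_left, x$approx_right, x$refined_left, x$refined_right))
  invisible(x)
}

## ---- sequence utilities ----

#' Reverse complement of a DNA string
#' @param s A DNA character scalar.
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## complement of a character vector of bases (fast path for scans)
comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

## sequence as a character vector
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## substring with 0-based half-open coordinates
substr0 <- function(s, start, end) substr(s, start + 1, end)

## total length of a union of (possibly overlapping) intervals
union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { tot <- tot + ce - cs; cs <- start[i]; ce <- end[i] }
  }
  tot + ce - cs
}

## overlap length of one interval [s,e) with a set of intervals
overlap_length <- function(s, e, starts, ends) {
  if (length(starts) == 0) return(0)
  sum(pmax(0, pmin(e, ends) - pmax(s, starts)))
}
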