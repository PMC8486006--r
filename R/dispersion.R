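## Window counting and the two-tailed Pearson chi-square Poisson-dispersion
## test, sliding-window repeat density, endpoint vicinity content, and
## enrichment tests.

#' Count repeats in nonoverlapping windows
#'
#' Each repeat is assigned to exactly one window by its start coordinate, so
#' window counts sum to the number of repeats starting before
#' `floor(L/window) * window`. The trailing partial window is discarded (see
#' [make_nonoverlapping_windows()]).
#'
#' @param repeats Merged repeat features (unpadded, starts in `[0, L)`).
#' @param L Genome length in bp.
#' @param window Window size in bp (default 3000).
#' @return An object of class `window_counts`: list with `counts`, `window`,
#'   `L`.
#' @export
window_counts <- function(repeats, L, window = 3000) {
  if (window > L) stop("window exceeds genome length")
  nwin <- floor(L / window)
  starts <- repeats$start[repeats$start >= 0 & repeats$start < nwin * window]
  counts <- tabulate(floor(starts / window) + 1, nbins = nwin)
  structure(list(counts = counts, window = window, L = L),
            class = "window_counts")
}

#' Two-tailed Pearson chi-square test of Poisson dispersion
#'
#' Tests whether window counts deviate from the Poisson expectation of equal
#' variance and mean. The statistic is the sum of squared deviations from the
#' mean divided by the mean, `chi2 = sum((x - xbar)^2) / xbar`, with
#' `df = n - 1`; `chi2 = df * (variance / mean)` with the sample (n-1)
#' variance. The two-tailed p-value is `min(1, 2 * min(F(chi2), 1 - F(chi2)))`
#' where F is the chi-square CDF.
#'
#' @param wc A `window_counts` object (or a plain count vector).
#' @param alpha Significance level for classification (default 0.05).
#' @return An object of class `dispersion_result`: list with `mean`,
#'   `variance`, `ratio`, `chi2`, `df`, `p`, `classification`
#'   (`"Overdispersed"`, `"Poisson"`, or `"Underdispersed"`).
#' @export
dispersion_test <- function(wc, alpha = 0.05) {
  x <- if (inherits(wc, "window_counts")) wc$counts else wc
  n <- length(x)
  if (n < 2) stop("need at least two windows")
  m <- mean(x)
  if (m == 0) stop("undefined test: mean window count is zero")
  v <- var(x)
  chi2 <- sum((x - m)^2) / m
  res <- dispersion_from_stats(chi2, n - 1, alpha)
  res$mean <- m
  res$variance <- v
  res$ratio <- v / m
  res
}

#' Dispersion p-value and classification from a chi-square statistic
#'
#' Computes the two-tailed Poisson-dispersion p-value and classification from
#' an already-computed chi-square statistic and its degrees of freedom, e.g.
#' when re-analysing published window statistics.
#'
#' @param chi2 Chi-square statistic, `sum((x - xbar)^2) / xbar`.
#' @param df Degrees of freedom, number of windows minus one.
#' @param alpha Significance level (default 0.05).
#' @return A `dispersion_result` (without `mean`/`variance`; `ratio` is
#'   `chi2/df`).
#' @export
dispersion_from_stats <- function(chi2, df, alpha = 0.05) {
  lower <- pchisq(chi2, df)
  p <- min(1, 2 * min(lower, 1 - lower))
  ratio <- chi2 / df
  classification <- if (p <= alpha) {
    if (ratio > 1) "Overdispersed" else "Underdispersed"
  } else "Poisson"
  structure(list(mean = NA_real_, variance = NA_real_, ratio = ratio,
                 chi2 = chi2, df = df, p = p, classification = classification),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("chi2 = %.2f, df = %d, variance:mean = %.2f, p = %.3g -> %s\n",
              x$chi2, x$df, x$ratio, x$p, x$classification))
  invisible(x)
}

#' Sliding-window repeat density
#'
#' Repeat density (repeats per `window` bp) profiled along the genome: sliding
#' windows advance by `step` bp over the padded axis and count repeats by start
#' coordinate; the value of each `step`-bp segment is the mean count over all
#' windows overlapping that segment. Pass *padded* (and, for taxa with
#' inversions, *reverted*) repeat features so windows near the origin are
#' complete; padding segments are removed before output.
#'
#' @param repeats Repeat features, padded with [pad_features()].
#' @param L Genome length in bp.
#' @param window Window size in bp (default 3000).
#' @param step Step size in bp (default 100); must divide `window`.
#' @param pad Pad width used in [pad_features()] (default `window`).
#' @return Data frame `pos` (segment start) and `density` (mean repeats per
#'   window), `ceiling(L/step)` rows.
#' @export
sliding_density <- function(repeats, L, window = 3000, step = 100,
                            pad = window) {
  if (window %% step != 0) stop("step must divide window")
  w <- window / step
  nbin <- ceiling((L + 2 * pad) / step)
  starts <- repeats$start
  starts <- starts[starts >= -pad & starts < nbin * step - pad]
  bin <- floor((starts + pad) / step) + 1
  cnt <- tabulate(bin, nbins = nbin)
  ## window count for window starting at bin j: sum over w bins
  nwin <- nbin - w + 1
  cc <- c(0, cumsum(cnt))
  wins <- cc[(w + 1):(w + nwin)] - cc[seq_len(nwin)]
  ## segment j value: mean over windows overlapping segment j
  val <- vapply(seq_len(nbin), function(j) {
    lo <- max(1, j - w + 1); hi <- min(nwin, j)
    if (hi < lo) return(NA_real_)
    mean(wins[lo:hi])
  }, numeric(1))
  segs <- (seq_len(nbin) - 1) * step - pad
  keep <- segs >= 0 & segs < L
  data.frame(pos = segs[keep], density = val[keep])
}

#' Repeat coverage near an endpoint
#'
#' Fraction of the `2 * flank` bp vicinity `[endpoint - flank, endpoint +
#' flank)` covered by repeats, with circular wrap. For taxa carrying an
#' inversion, revert it first so the two endpoints are comparable across taxa.
#'
#' @param repeats Merged repeat features (starts in `[0, L)`, wrap encoded with
#'   `end > L`).
#' @param endpoint Endpoint position in bp.
#' @param flank Flank width in bp (default 1000).
#' @param L Genome length in bp.
#' @return Coverage fraction in `[0, 1]`.
#' @export
vicinity_repeat_content <- function(repeats, endpoint, flank = 1000, L) {
  lo <- endpoint - flank; hi <- endpoint + flank
  if (nrow(repeats) == 0) return(0)
  ## replicate repeats at +/- L so a linear intersection sees the wrap
  s <- c(repeats$start, repeats$start - L, repeats$start + L)
  e <- c(repeats$end, repeats$end - L, repeats$end + L)
  sel <- e > lo & s < hi
  if (!any(sel)) return(0)
  cov <- union_length(pmax(s[sel], lo), pmin(e[sel], hi))
  cov / (2 * flank)
}

#' Chi-square enrichment test for repeats in a region set
#'
#' Tests whether `regions` hold more repeats than expected from the repeat
#' frequency across `reference_regions` (the whole genome, or e.g. the union
#' of intergenic spacers). Repeats are assigned to regions by start
#' coordinate. `expected = total * region_length / reference_length`; the
#' statistic is the 1-df Pearson goodness of fit over \{region, complement\},
#' reported one-sided for enrichment: p is halved when observed > expected,
#' else `1 - p/2`.
#'
#' @param repeats Merged repeat features.
#' @param regions Feature table of the candidate regions.
#' @param reference_regions Feature table of the reference regions (must
#'   contain `regions`).
#' @param L Genome length in bp (used to validate inputs).
#' @return List with `observed`, `expected`, `chi2`, `p`, `excess`.
#' @export
enrichment_test <- function(repeats, regions, reference_regions, L) {
  region_len <- union_length(regions$start, regions$end)
  ref_len <- union_length(reference_regions$start, reference_regions$end)
  if (region_len == 0) stop("region length is zero")
  in_set <- function(pos, set) {
    vapply(pos, function(p) any(p >= set$start & p < set$end), logical(1))
  }
  total <- sum(in_set(repeats$start, reference_regions))
  observed <- sum(in_set(repeats$start, regions))
  expected <- total * region_len / ref_len
  if (expected <= 0) stop("expected count is zero")
  comp_exp <- total - expected
  chi2 <- (observed - expected)^2 / expected +
    if (comp_exp > 0) ((total - observed) - comp_exp)^2 / comp_exp else 0
  p2 <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p <- if (observed > expected) p2 / 2 else 1 - p2 / 2
  list(observed = observed, expected = expected, chi2 = chi2, p = p,
       excess = observed - expected)
}

#' Repeat length fractions by annotation class
#'
#' Splits the total merged repeat length among exon, intron, and intergenic
#' positions by interval intersection. Positions not covered by the annotation
#' are assigned to intergenic with a warning. The three fractions sum to 1.
#'
#' @param repeats Merged repeat features.
#' @param classes Annotation class intervals from [annotation_classes()] (a
#'   feature table with `cls` in exon/intron/intergenic covering the genome).
#' @param L Genome length in bp.
#' @return Named numeric vector `c(exon=, intron=, intergenic=)`.
#' @export
content_by_class <- function(repeats, classes, L) {
  if (nrow(repeats) == 0) stop("empty repeat set: class fractions undefined")
  total <- sum(repeats$end - repeats$start)
  out <- c(exon = 0, intron = 0, intergenic = 0)
  ## unwrap repeats and classes onto [0, 2L) so wrap intersections are seen
  cl <- classes
  cl2 <- classes; cl2$start <- cl2$start + L; cl2$end <- cl2$end + L
  cl <- rbind(cl, cl2)
  for (k in names(out)) {
    set <- cl[cl$cls == k, , drop = FALSE]
    out[k] <- sum(vapply(seq_len(nrow(repeats)), function(i) {
      overlap_length(repeats$start[i], repeats$end[i], set$start, set$end)
    }, numeric(1)))
  }
  if (sum(out) < total - 1e-9) {
    warning("annotation does not cover all repeat positions; residual assigned to intergenic")
    out["intergenic"] <- out["intergenic"] + (total - sum(out))
  }
  out / sum(out)
}

#' Derive exon/intron/intergenic class intervals from gene annotations
#'
#' Intergenic spacers are the complement of gene spans; positions inside genes
#' but in no exon or intron (e.g. genes annotated without exon rows) count as
#' exon.
#'
#' @param genome A [circular_genome()] with gene (and optionally exon/intron)
#'   features.
#' @return Feature table with `cls` in exon/intron/intergenic covering
#'   `[0, L)`.
#' @export
annotation_classes <- function(genome) {
  f <- genome$features
  L <- genome$length
  genes <- f[f$cls == "gene", , drop = FALSE]
  exons <- f[f$cls == "exon", , drop = FALSE]
  introns <- f[f$cls == "intron", , drop = FALSE]
  ## genes without exon annotation contribute their whole span as exon
  if (nrow(genes)) {
    covered <- function(g) {
      overlap_length(g[1], g[2], c(exons$start, introns$start),
                     c(exons$end, introns$end)) >= (g[2] - g[1])
    }
    bare <- genes[!apply(cbind(genes$start, genes$end), 1, covered), , drop = FALSE]
    if (nrow(bare)) { bare$cls <- "exon"; exons <- rbind(exons, bare) }
  }
  ## intergenic = complement of gene spans on the circle
  inter <- if (nrow(genes) == 0) features(0, L, cls = "intergenic") else {
    gs <- genes[order(genes$start), , drop = FALSE]
    merged_s <- numeric(0); merged_e <- numeric(0)
    cs <- gs$start[1]; ce <- gs$end[1]
    if (nrow(gs) > 1) for (i in 2:nrow(gs)) {
      if (gs$start[i] <= ce) ce <- max(ce, gs$end[i])
      else { merged_s <- c(merged_s, cs); merged_e <- c(merged_e, ce)
             cs <- gs$start[i]; ce <- gs$end[i] }
    }
    merged_s <- c(merged_s, cs); merged_e <- c(merged_e, ce)
    gap_s <- c(merged_e[-length(merged_e)], merged_e[length(merged_e)])
    gap_e <- c(merged_s[-1], merged_s[1] + L)  # final gap wraps to first gene
    ok <- gap_e > gap_s
    if (!any(ok)) empty_features() else
      features(gap_s[ok] %% L, gap_s[ok] %% L + (gap_e[ok] - gap_s[ok]),
               cls = "intergenic",
               name = sprintf("igs%03d", seq_len(sum(ok))))
  }
  out <- rbind(exons[, names(inter)], introns[, names(inter)], inter)
  out$cls[out$cls == "gene"] <- "exon"
  out[order(out$start), , drop = FALSE]
}
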