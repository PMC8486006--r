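## Readers and writers: FASTA (one record per genome, 70-column), GFF3
## (1-based inclusive at the boundary), BED-like TSVs for repeat/window/
## endpoint features, newick trees, and the dispersion summary report.

#' Write a genome to FASTA
#'
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$taxon_id
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

#' Write genome annotations to GFF3
#'
#' Converts the package's 0-based half-open coordinates to GFF3 1-based
#' inclusive. Features crossing the origin (`end > L`) are split into two
#' records at the origin, suffixed `__wrap1`/`__wrap2`; [read_genome()] rejoins
#' them.
#'
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @param classes Feature classes to export (default gene/exon/intron).
#' @export
write_gff3 <- function(genome, path, classes = c("gene", "exon", "intron")) {
  f <- genome$features[genome$features$cls %in% classes, , drop = FALSE]
  L <- genome$length
  wrap <- f$end > L
  if (any(wrap)) {
    w <- f[wrap, , drop = FALSE]
    p1 <- w; p1$end <- L; p1$name <- paste0(p1$name, "__wrap1")
    p2 <- w; p2$start <- 0; p2$end <- w$end - L; p2$name <- paste0(p2$name, "__wrap2")
    f <- rbind(f[!wrap, , drop = FALSE], p1, p2)
    f <- f[order(f$start, f$end), , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genome$taxon_id,
    ranges = IRanges::IRanges(start = f$start + 1, end = f$end),
    strand = f$strand)
  gr$type <- f$cls
  gr$ID <- f$name
  gr$Name <- f$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genome from FASTA + GFF3
#'
#' The sequence is uppercased; GFF3 1-based inclusive coordinates are converted
#' to 0-based half-open; feature types outside gene/exon/intron are dropped;
#' records split at the origin by [write_gff3()] are rejoined into single
#' wrap-encoded features.
#'
#' @param fasta_path Path to a single-record FASTA.
#' @param gff3_path Optional GFF3 annotation path.
#' @param taxon_id Taxon id; defaults to the FASTA record name.
#' @return A [circular_genome()].
#' @export
read_genome <- function(fasta_path, gff3_path = NULL, taxon_id = NULL) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  if (length(x) != 1) stop("expected exactly one FASTA record in ", fasta_path)
  name <- sub("\\s.*", "", names(x)[1])
  if (!is.null(taxon_id) && taxon_id != name) {
    stop(sprintf("taxon/sequence name mismatch: wanted %s, FASTA has %s",
                 taxon_id, name))
  }
  feats <- empty_features()
  if (!is.null(gff3_path)) {
    gr <- rtracklayer::import(gff3_path)
    keep <- as.character(gr$type) %in% c("gene", "exon", "intron")
    gr <- gr[keep]
    nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    feats <- features(BiocGenerics::start(gr) - 1, BiocGenerics::end(gr),
                      strand = strand, cls = as.character(gr$type), name = nm)
    ## rejoin origin-split features
    is1 <- grepl("__wrap1$", feats$name); is2 <- grepl("__wrap2$", feats$name)
    if (any(is1)) {
      L <- nchar(as.character(x[[1]]))
      base1 <- sub("__wrap1$", "", feats$name[is1])
      p2 <- feats[is2, , drop = FALSE]
      j <- match(base1, sub("__wrap2$", "", p2$name))
      joined <- feats[is1, , drop = FALSE]
      joined$end <- L + p2$end[j]
      joined$name <- base1
      feats <- rbind(feats[!(is1 | is2), , drop = FALSE], joined)
      feats <- feats[order(feats$start, feats$end), , drop = FALSE]
    }
  }
  circular_genome(name, as.character(x[[1]]), feats)
}

#' Write features as BED-like TSV
#'
#' Six columns: chrom, start, end, name, score, strand (0-based half-open, as
#' BED). Extra columns in `features` (e.g. `group_id`) are appended.
#'
#' @param feats Feature table.
#' @param path Output path.
#' @param chrom Chromosome/taxon label.
#' @param score Score column value (default ".").
#' @export
write_features_tsv <- function(feats, path, chrom, score = ".") {
  base <- data.frame(chrom = chrom, start = feats$start, end = feats$end,
                     name = feats$name, score = score, strand = feats$strand)
  extra <- setdiff(names(feats), c("start", "end", "strand", "cls", "name"))
  if (length(extra)) base <- cbind(base, feats[, extra, drop = FALSE])
  write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BED-like feature TSV written by [write_features_tsv()]
#' @param path Input path.
#' @param cls Feature class to assign (default "repeat").
#' @return Feature table.
#' @export
read_features_tsv <- function(path, cls = "repeat") {
  d <- read.delim(path, stringsAsFactors = FALSE)
  f <- features(d$start, d$end, strand = d$strand, cls = cls, name = d$name)
  extra <- setdiff(names(d), c("chrom", "start", "end", "name", "score", "strand"))
  if (length(extra)) f <- cbind(f, d[, extra, drop = FALSE])
  f
}

#' Write the per-taxon dispersion summary report
#'
#' One row per taxon with repeat content (%, 2 dp), total repeat count,
#' variance:mean ratio (2 dp), chi-square statistic (2 dp), df, two-tailed
#' p-value (3 significant figures), and the dispersion classification.
#'
#' @param results Data frame with columns `taxon_id`, `content_pct`, `count`,
#'   `ratio`, `chi2`, `df`, `p`, `classification`.
#' @param path Output path.
#' @export
write_summary_report <- function(results, path) {
  out <- data.frame(
    taxon_id = results$taxon_id,
    repeat_content_pct = sprintf("%.2f", results$content_pct),
    total_repeat_count = results$count,
    variance_mean_ratio = sprintf("%.2f", results$ratio),
    chi2 = sprintf("%.2f", results$chi2),
    df = results$df,
    p_value = signif(results$p, 3),
    dispersion = results$classification)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated plastome set to a run directory
#'
#' Emits `<taxon>.fasta` + `<taxon>.gff3` per genome, `tree.nwk`,
#' `truth_repeats.tsv`, `truth_inversions.tsv`, `traits.tsv`, and
#' `config.yaml`. Output is byte-identical for identical configurations.
#'
#' @param sim Output of [simulate_plastome_set()].
#' @param dir Output directory (created if needed).
#' @export
write_run <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in sim$genomes) {
    write_fasta(g, file.path(dir, paste0(g$taxon_id, ".fasta")))
    write_gff3(g, file.path(dir, paste0(g$taxon_id, ".gff3")))
  }
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write.table(sim$truth$repeats, file.path(dir, "truth_repeats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$inversions, file.path(dir, "truth_inversions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(taxon_id = names(sim$truth$traits),
                         trait = as.numeric(sim$truth$traits)),
              file.path(dir, "traits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  scal <- vapply(cfg, function(v) length(v) == 1 && !is.list(v), logical(1))
  lines <- c(
    sprintf("%s: %s", names(cfg)[scal],
            vapply(cfg[scal], as.character, character(1))),
    sprintf("%s: [%s]", names(cfg)[!scal],
            vapply(cfg[!scal], function(v) paste(v, collapse = ", "), character(1))))
  writeLines(c("# plastrep simulation config", lines), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a run directory back into genomes + tree
#'
#' @param dir Run directory written by [write_run()].
#' @return List `genomes` (named list of [circular_genome()]s), `tree`, and
#'   (when present) `truth` tables.
#' @export
read_run <- function(dir) {
  fastas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fastas) == 0) stop("no FASTA files in ", dir)
  genomes <- lapply(fastas, function(fp) {
    gp <- sub("\\.fasta$", ".gff3", fp)
    read_genome(fp, if (file.exists(gp)) gp else NULL)
  })
  names(genomes) <- vapply(genomes, function(g) g$taxon_id, character(1))
  tree_path <- file.path(dir, "tree.nwk")
  tree <- if (file.exists(tree_path)) ape::read.tree(tree_path) else NULL
  truth <- list()
  for (nm in c("truth_repeats", "truth_inversions", "traits")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(p)) truth[[nm]] <- read.delim(p, stringsAsFactors = FALSE)
  }
  list(genomes = genomes, tree = tree, truth = truth)
}

#' Published repeat dispersion statistics for 30 Astragalus taxa and
#' Oxytropis bicolor
#'
#' The printed per-taxon plastome repeat summary used as reference input:
#' repeat content (% of sites in repeats), total nonoverlapping repeat count,
#' variance:mean ratio of counts in 3-kb windows, the Pearson chi-square
#' dispersion statistic with its df and two-tailed p-value, and the published
#' dispersion classification.
#'
#' @return Data frame with one row per taxon.
#' @export
astragalus_repeat_stats <- function() {
  read.delim(system.file("extdata", "astragalus_repeat_dispersion.tsv",
                         package = "plastrep"), stringsAsFactors = FALSE)
}

#' Published plastome lengths for 25 newly assembled Astragalus taxa
#'
#' @return Data frame `taxon`, `length_bp`.
#' @export
astragalus_plastome_lengths <- function() {
  read.delim(system.file("extdata", "astragalus_plastome_lengths.tsv",
                         package = "plastrep"), stringsAsFactors = FALSE)
}
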