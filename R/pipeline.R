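## End-to-end pipeline over a set of annotated plastomes, and a small
## command-line front end.

#' Run the full repeat/inversion analysis over a genome set
#'
#' Per taxon: dispersed + tandem repeat discovery, interval merging, grouping;
#' inversion detection against an uninverted reference taxon with endpoint
#' refinement, naming, microhomology, and endpoint repeat geometry; reversion
#' of detected inversions before window statistics; the window dispersion test;
#' cross-taxon Markov clustering with occupancy categories; and (when a tree is
#' given) Pagel's lambda fits on log-transformed repeat traits plus a
#' phylogenetic t-test of the variance:mean ratio against inversion status.
#'
#' @param genomes Named list of [circular_genome()]s.
#' @param tree Optional `ape::phylo` whose tips match the genome names.
#' @param reference_taxon Taxon used as the uninverted reference for inversion
#'   detection (default: the first genome).
#' @param min_len,min_identity Repeat discovery thresholds (defaults 30 bp,
#'   0.90).
#' @param window Window size in bp for dispersion statistics (default 3000).
#' @param min_block Minimum inversion block span in bp (default 1000).
#' @param alpha Significance level for dispersion classification (default
#'   0.05).
#' @param out_dir Optional output directory for TSV reports.
#' @return List with `repeats` (per-taxon grouped repeat features),
#'   `dispersion` (Table-style data frame), `inversions` (per-taxon list of
#'   records with `name`, `geometry`, `microhomology`), `clusters`,
#'   `category_lengths`, `traits`, `lambda_fits`, `ttest_inversion`.
#' @export
run_pipeline <- function(genomes, tree = NULL, reference_taxon = NULL,
                         min_len = 30, min_identity = 0.90, window = 3000,
                         min_block = 1000, alpha = 0.05, out_dir = NULL) {
  taxa <- names(genomes)
  if (is.null(taxa)) stop("genomes must be a named list")
  reference_taxon <- reference_taxon %||% taxa[1]

  repeats <- list(); representatives <- list()
  for (tx in taxa) {
    g <- genomes[[tx]]
    pairs <- find_dispersed_repeats(g, min_len = min_len,
                                    min_identity = min_identity)
    arrays <- find_tandem_repeats(g, min_total = min_len)
    merged <- merge_repeat_intervals(pairs, arrays)
    grouped <- group_repeats(pairs, merged)
    repeats[[tx]] <- grouped
    representatives[[tx]] <- group_representatives(g, grouped)
  }

  ## inversions against the reference
  ref <- genomes[[reference_taxon]]
  inversions <- list()
  for (tx in setdiff(taxa, reference_taxon)) {
    g <- genomes[[tx]]
    anchors <- find_anchors(g, ref)
    invs <- detect_inversions(anchors, min_block = min_block, taxon_id = tx)
    recs <- lapply(invs, function(inv) {
      inv <- tryCatch(refine_endpoints(g, ref, inv),
                      error = function(e) { warning(conditionMessage(e)); inv })
      if (!is.na(inv$refined_left)) {
        inv$name <- tryCatch(
          name_inversion(g$features, inv$refined_left, inv$refined_right),
          error = function(e) NA_character_)
        geom <- suppressWarnings(
          classify_endpoint_repeat_geometry(g, ref, inv))
        list(record = inv, geometry = geom$ancestral_arrangement,
             microhomology = geom$microhomology)
      } else list(record = inv, geometry = NA_character_, microhomology = NULL)
    })
    if (length(recs)) inversions[[tx]] <- recs
  }

  ## dispersion statistics on (reverted) repeat features
  disp <- lapply(taxa, function(tx) {
    g <- genomes[[tx]]
    merged <- repeats[[tx]]
    for (rec in inversions[[tx]] %||% list()) {
      inv <- rec$record
      if (!is.na(inv$refined_left)) {
        merged <- suppressWarnings(
          revert_features(merged, inv$refined_left, inv$refined_right))
      }
    }
    wc <- window_counts(merged, g$length, window = window)
    dt <- dispersion_test(wc, alpha = alpha)
    data.frame(taxon_id = tx,
               content_pct = 100 * repeat_content(repeats[[tx]], g$length),
               count = nrow(merged), ratio = dt$ratio, chi2 = dt$chi2,
               df = dt$df, p = dt$p, classification = dt$classification)
  })
  disp <- do.call(rbind, disp)

  ## cross-taxon clustering
  clusters <- NULL; cat_lengths <- NULL
  if (sum(vapply(representatives, nrow, integer(1))) > 1) {
    clusters <- cluster_repeats(representatives)
    cat_lengths <- category_length_summary(repeats, clusters)
  }

  ## comparative tests on log traits
  traits <- data.frame(
    taxon_id = taxa,
    total_repeat_len = vapply(repeats, function(r) sum(r$end - r$start), numeric(1)),
    content = disp$content_pct,
    density = disp$count / (vapply(genomes, function(g) g$length, numeric(1)) / window),
    ratio = disp$ratio)
  lambda_fits <- NULL; ttest_inv <- NULL
  if (!is.null(tree)) {
    lambda_fits <- lapply(c("total_repeat_len", "content", "density", "ratio"),
                          function(v) {
      y <- log(traits[[v]]); names(y) <- traits$taxon_id
      tryCatch(fit_pagel_lambda(tree, y), error = function(e) NULL)
    })
    names(lambda_fits) <- c("total_repeat_len", "content", "density", "ratio")
    has_inv <- as.numeric(taxa %in% names(inversions))
    names(has_inv) <- taxa
    y <- log(traits$ratio); names(y) <- taxa
    ttest_inv <- tryCatch(phylo_ttest(tree, y, has_inv, alternative = "greater"),
                          error = function(e) NULL)
  }

  res <- list(repeats = repeats, dispersion = disp, inversions = inversions,
              clusters = clusters, category_lengths = cat_lengths,
              traits = traits, lambda_fits = lambda_fits,
              ttest_inversion = ttest_inv)
  if (!is.null(out_dir)) write_pipeline_reports(res, genomes, out_dir)
  res
}

write_pipeline_reports <- function(res, genomes, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_report(res$dispersion, file.path(out_dir, "dispersion.tsv"))
  for (tx in names(res$repeats)) {
    write_features_tsv(res$repeats[[tx]],
                       file.path(out_dir, paste0("repeats_", tx, ".tsv")),
                       chrom = tx)
  }
  if (!is.null(res$clusters)) {
    write.table(res$clusters[, setdiff(names(res$clusters), "sequence")],
                file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$category_lengths, file.path(out_dir, "category_lengths.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  inv_rows <- list()
  for (tx in names(res$inversions)) for (rec in res$inversions[[tx]]) {
    inv <- rec$record
    inv_rows[[length(inv_rows) + 1]] <- data.frame(
      taxon_id = tx, name = gsub("\u223c", "~", inv$name %||% NA_character_),
      approx_left = inv$approx_left, approx_right = inv$approx_right,
      refined_left = inv$refined_left, refined_right = inv$refined_right,
      geometry = rec$geometry,
      mh_leading_run = rec$microhomology$leading_run %||% NA,
      mh_matches = rec$microhomology$matches_in_window %||% NA)
  }
  inv_df <- if (length(inv_rows)) do.call(rbind, inv_rows) else
    data.frame(taxon_id = character(0), name = character(0))
  write.table(inv_df, file.path(out_dir, "inversions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S --out DIR [--n-taxa N] [--genome-length L]`,
#' `dispersion --in DIR --out DIR`, and
#' `all --in DIR --out DIR` / `all --seed S --out DIR` (simulate then analyse).
#' Returns the exit status (0 success, 2 usage error) instead of quitting so
#' the function is testable; a thin wrapper script calls
#' `quit(status = run_cli(commandArgs(TRUE)))`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
run_cli <- function(argv) {
  usage <- function() {
    message("usage: plastrep <simulate|dispersion|all> [--seed S] [--in DIR] --out DIR\n",
            "               [--n-taxa N] [--genome-length L]")
    2L
  }
  if (length(argv) == 0) return(usage())
  cmd <- argv[1]
  opts <- list()
  i <- 2
  while (i <= length(argv)) {
    key <- argv[i]
    if (!grepl("^--", key) || i == length(argv)) return(usage())
    opts[[sub("^--", "", key)]] <- argv[i + 1]
    i <- i + 2
  }
  known <- c("seed", "in", "out", "n-taxa", "genome-length")
  if (!cmd %in% c("simulate", "dispersion", "all") ||
      any(!names(opts) %in% known)) return(usage())
  if (is.null(opts$out)) return(usage())

  status <- tryCatch({
    if (cmd %in% c("simulate", "all") && !is.null(opts$seed)) {
      cfg <- simulation_config(
        seed = as.integer(opts$seed),
        n_taxa = as.integer(opts[["n-taxa"]] %||% 12),
        genome_length = as.integer(opts[["genome-length"]] %||% 20000))
      sim <- simulate_plastome_set(cfg)
      sim_dir <- if (cmd == "simulate") opts$out else file.path(opts$out, "sim")
      write_run(sim, sim_dir)
      message("simulated ", length(sim$genomes), " genomes -> ", sim_dir)
      if (cmd == "simulate") return(0L)
      opts$`in` <- sim_dir
    }
    if (cmd %in% c("dispersion", "all")) {
      if (is.null(opts$`in`)) return(usage())
      if (!dir.exists(opts$`in`)) stop("input directory not found: ", opts$`in`)
      run <- read_run(opts$`in`)
      run_pipeline(run$genomes, tree = run$tree, out_dir = opts$out)
      message("reports written to ", opts$out)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
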