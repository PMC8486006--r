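## Cross-taxon repeat clustering: all-vs-all local alignment of repeat-group
## representatives, Markov clustering of the similarity graph, and taxon
## occupancy categories.

#' Build a similarity graph over repeat-group representatives
#'
#' All-vs-all local alignment (match +2, mismatch -3, gap open -5, gap extend
#' -2) of one representative sequence per repeat group per taxon; both strands
#' are aligned and the better score used, so repeats carried inside an
#' inverted segment still cluster with their forward-strand relatives. An edge
#' is drawn when the best local alignment score reaches `min_score` and the
#' aligned span covers at least `min_overlap_frac` of the shorter
#' representative; its weight is the alignment score. Node order is the
#' deterministic (`taxon_id`, `group_id`) lexicographic order.
#'
#' @param representatives Data frame `taxon_id`, `group_id`, `sequence` (see
#'   [group_representatives()]).
#' @param min_score Minimum local alignment score for an edge (default 50,
#'   i.e. 25 exactly matching bases).
#' @param min_overlap_frac Minimum aligned fraction of the shorter sequence
#'   (default 0.5).
#' @return A `similarity_graph`: list with `nodes` (the representative table)
#'   and `adj` (symmetric weight matrix, zero diagonal).
#' @export
build_similarity_graph <- function(representatives, min_score = 50,
                                   min_overlap_frac = 0.5) {
  if (nrow(representatives) == 0) stop("empty representative set")
  reps <- representatives[order(representatives$taxon_id, representatives$group_id), ,
                          drop = FALSE]
  rownames(reps) <- NULL
  n <- nrow(reps)
  adj <- matrix(0, n, n)
  if (n > 1) {
    subs <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = TRUE)
    seqs <- Biostrings::DNAStringSet(reps$sequence)
    lens <- nchar(reps$sequence)
    for (i in seq_len(n - 1)) {
      idx <- (i + 1):n
      best_sc <- rep(-Inf, length(idx)); best_ov <- rep(0, length(idx))
      for (subject in list(seqs[[i]],
                           Biostrings::reverseComplement(seqs[[i]]))) {
        aln <- Biostrings::pairwiseAlignment(seqs[idx], subject, type = "local",
                                             substitutionMatrix = subs,
                                             gapOpening = 5, gapExtension = 2)
        sc <- Biostrings::score(aln)
        better <- sc > best_sc
        best_sc[better] <- sc[better]
        best_ov[better] <- (Biostrings::nchar(aln) / pmin(lens[idx], lens[i]))[better]
      }
      ok <- best_sc >= min_score & best_ov >= min_overlap_frac
      adj[i, idx[ok]] <- best_sc[ok]
      adj[idx[ok], i] <- best_sc[ok]
    }
  }
  structure(list(nodes = reps, adj = adj), class = "similarity_graph")
}

#' Markov clustering (MCL)
#'
#' From-scratch implementation of the Markov Cluster algorithm: self-loops are
#' added (weight = column maximum), columns are normalized to stochastic form,
#' then expansion (matrix square) and inflation (elementwise power, pruning,
#' renormalization) alternate until the matrix change falls below tolerance.
#' Clusters are read off the limit matrix as connected components over its
#' nonzero entries, which groups each node with its attractor(s).
#'
#' @param graph A `similarity_graph` from [build_similarity_graph()], or a
#'   symmetric nonnegative weight matrix.
#' @param inflation Inflation exponent (> 1; default 2, the classical default).
#' @param max_iter Maximum expansion/inflation iterations (default 100).
#' @param prune_tol Entries below this are set to zero each iteration; also the
#'   convergence tolerance on the maximum entry change (default 1e-6).
#' @return A data frame with one row per node: the node columns of the graph
#'   plus `cluster_id` (1-based, ordered by first node index).
#' @export
markov_cluster <- function(graph, inflation = 2, max_iter = 100,
                           prune_tol = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (inherits(graph, "similarity_graph")) {
    adj <- graph$adj; nodes <- graph$nodes
  } else {
    adj <- graph
    nodes <- data.frame(node = seq_len(nrow(adj)))
  }
  n <- nrow(adj)
  M <- adj
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune_tol] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < prune_tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge after ", max_iter,
                          " iterations; returning current clustering")
  g <- igraph::graph_from_adjacency_matrix((M > prune_tol) | t(M > prune_tol),
                                           mode = "max")
  comp <- igraph::components(g)$membership
  first <- tapply(seq_len(n), comp, min)
  relabel <- rank(first, ties.method = "first")
  nodes$cluster_id <- as.integer(relabel[match(comp, names(first))])
  nodes
}

#' Categorize repeat clusters by taxon occupancy
#'
#' Occupancy is the number of distinct taxa with a member in the cluster.
#' Categories: `all` (every taxon), `majority` (more than half but not all),
#' `minority` (at least two taxa up to half), `unique` (single taxon; such
#' repeats belong to no multi-taxon cluster).
#'
#' @param clustered Output of [markov_cluster()] with a `taxon_id` column.
#' @param n_taxa Total number of taxa analysed.
#' @return `clustered` with columns `occupancy` and `category` added.
#' @export
categorize_occupancy <- function(clustered, n_taxa) {
  occ <- tapply(clustered$taxon_id, clustered$cluster_id,
                function(x) length(unique(x)))
  if (any(occ > n_taxa)) stop("cluster occupancy exceeds the number of taxa")
  cat_of <- function(o) {
    if (o == n_taxa) "all"
    else if (o > n_taxa / 2) "majority"
    else if (o >= 2) "minority"
    else "unique"
  }
  cats <- vapply(occ, cat_of, character(1))
  clustered$occupancy <- as.integer(occ[as.character(clustered$cluster_id)])
  clustered$category <- cats[as.character(clustered$cluster_id)]
  clustered
}

#' Cluster repeat groups across taxa
#'
#' Convenience wrapper: pools group representatives from several genomes,
#' builds the similarity graph, runs [markov_cluster()], and assigns occupancy
#' categories.
#'
#' @param representative_list List of representative tables (one per taxon,
#'   from [group_representatives()]).
#' @param inflation,min_score,min_overlap_frac See [markov_cluster()] and
#'   [build_similarity_graph()].
#' @return Node table with `cluster_id`, `occupancy`, `category`.
#' @export
cluster_repeats <- function(representative_list, inflation = 2,
                            min_score = 50, min_overlap_frac = 0.5) {
  reps <- do.call(rbind, representative_list)
  graph <- build_similarity_graph(reps, min_score = min_score,
                                  min_overlap_frac = min_overlap_frac)
  clustered <- markov_cluster(graph, inflation = inflation)
  categorize_occupancy(clustered, n_taxa = length(unique(reps$taxon_id)))
}

#' Per-taxon repeat length by occupancy category
#'
#' Decomposes each taxon's total merged repeat length into the four occupancy
#' categories; the four totals sum exactly to the taxon's total repeat length.
#'
#' @param grouped_list Named list (by taxon) of [group_repeats()] outputs.
#' @param clustered Output of [cluster_repeats()].
#' @return Data frame `taxon_id`, `category`, `length_bp`.
#' @export
category_length_summary <- function(grouped_list, clustered) {
  out <- list()
  for (taxon in names(grouped_list)) {
    gg <- grouped_list[[taxon]]
    if (nrow(gg) == 0) next
    cl <- clustered[clustered$taxon_id == taxon, , drop = FALSE]
    cat_by_group <- cl$category[match(gg$group_id, cl$group_id)]
    cat_by_group[is.na(cat_by_group)] <- "unique"
    len <- tapply(gg$end - gg$start, factor(cat_by_group,
                  levels = c("all", "majority", "minority", "unique")), sum)
    len[is.na(len)] <- 0
    out[[taxon]] <- data.frame(taxon_id = taxon, category = names(len),
                               length_bp = as.numeric(len))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
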