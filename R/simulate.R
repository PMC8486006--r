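## Synthetic plastome sets with known truth: pure-birth trees, BM(lambda)
## traits, repeat families with controlled occupancy and spatial dispersion,
## and constructive inversion scenarios (ancestral direct repeats flanking one
## endpoint plus complementary microhomologies at both endpoints).

#' Simulation configuration
#'
#' Collects every knob of the synthetic plastome generator. The defaults are
#' the package's test-scale study conditions: 12 taxa, 20-kb genomes (a
#' full-scale plastome preset uses `genome_length = 123000`), ten repeat
#' families whose occupancy mixture mirrors the empirical split of repeat
#' clusters present in all / a majority / a minority of taxa plus a quarter of
#' taxon-unique repeats, family lengths drawn so the three length bins
#' (30-99, 100-199, >=200 bp) contribute roughly 57/30/13% of repeat length,
#' Poisson (uniform) placement, and one planted inversion.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_taxa Number of tips (default 12).
#' @param genome_length Genome length in bp (default 20000).
#' @param birth_rate Pure-birth rate for the tree (default 1).
#' @param n_repeat_families Number of repeat families (default: one per 2 kb
#'   of genome, i.e. 10 at the 20-kb test scale — matching the empirical
#'   density of about one repeat per 2.5 kb once copy numbers and occupancy
#'   are applied).
#' @param copies_range Copies per family per occupying taxon, `c(min, max)`
#'   (default 2-3).
#' @param occupancy_mix Named probabilities over
#'   `c("all","majority","minority","unique")`; must sum to 1.
#' @param length_mix Probabilities of the three family-length bins
#'   30-99 / 100-199 / 200-300 bp; must sum to 1.
#' @param placement `"poisson"` (uniform independent starts) or `"clustered"`
#'   (Neyman-Scott).
#' @param cluster_kappa,cluster_sd Neyman-Scott parent count and normal offset
#'   sd in bp (defaults 4 and 400).
#' @param mutation_rate Substitutions per site per unit branch length along the
#'   tree (default 0.003).
#' @param n_inversions Number of tips given a planted inversion (default 1).
#' @param inversion_frac Inverted segment length as a fraction of the genome
#'   (default 0.3).
#' @param trait_lambda,trait_sigma2 Pagel's lambda and BM rate of the planted
#'   continuous trait (defaults 1 and 1).
#' @param gene_length,intergenic_length Gene skeleton spacing in bp
#'   (defaults 600 and 400).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed, n_taxa = 12, genome_length = 20000,
                              birth_rate = 1,
                              n_repeat_families = max(3, round(genome_length / 2000)),
                              copies_range = c(2, 3),
                              occupancy_mix = c(all = 0.10, majority = 0.20,
                                                minority = 0.45, unique = 0.25),
                              length_mix = c(0.79, 0.165, 0.045),
                              placement = c("poisson", "clustered"),
                              cluster_kappa = 4, cluster_sd = 400,
                              mutation_rate = 0.003, n_inversions = 1,
                              inversion_frac = 0.3, trait_lambda = 1,
                              trait_sigma2 = 1, gene_length = 600,
                              intergenic_length = 400) {
  placement <- match.arg(placement)
  stopifnot(n_taxa >= 2, genome_length >= 5000, n_repeat_families >= 0,
            abs(sum(occupancy_mix) - 1) < 1e-9, abs(sum(length_mix) - 1) < 1e-9,
            all(names(occupancy_mix) == c("all", "majority", "minority", "unique")))
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate an ultrametric pure-birth tree
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate (default 1).
#' @param seed Optional seed; when given, the same seed always yields the same
#'   newick string.
#' @return An `ape::phylo` with tips labelled `t01`, `t02`, ...
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tree
}

#' Simulate a trait under Brownian motion with Pagel's lambda
#'
#' Draws one multivariate normal sample with covariance
#' `sigma2 * C(lambda)` over the tips.
#'
#' @param tree An `ape::phylo`.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param sigma2 BM rate (>= 0; 0 gives a constant trait).
#' @param seed Optional seed.
#' @param mu Trait mean (default 0).
#' @return Named numeric vector over tips.
#' @export
simulate_bm_traits <- function(tree, lambda, sigma2, seed = NULL, mu = 0) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  y <- if (sigma2 == 0) rep(mu, n) else {
    Cl <- sigma2 * lambda_cov(tree, lambda)
    as.numeric(mu + t(chol(Cl)) %*% rnorm(n))
  }
  names(y) <- tree$tip.label
  y
}

#' Place repeats under a null spatial model
#'
#' `poisson`: independent uniform start positions (the Poisson null of the
#' dispersion test). `clustered`: Neyman-Scott process — `kappa` uniform
#' parent positions, offspring allocated multinomially and displaced by
#' normal offsets, wrapped on the circle.
#'
#' @param L Genome length in bp.
#' @param n Number of repeats.
#' @param seed Optional seed.
#' @param mode `"poisson"` or `"clustered"`.
#' @param rep_len Repeat length in bp (default 40).
#' @param kappa,cluster_sd Neyman-Scott parameters (defaults 5 and 300).
#' @return Feature table of `n` repeat intervals.
#' @export
place_repeats_null <- function(L, n, seed = NULL,
                               mode = c("poisson", "clustered"),
                               rep_len = 40, kappa = 5, cluster_sd = 300) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (n * rep_len > L) stop("requested repeats exceed genome capacity")
  if (n == 0) return(empty_features())
  starts <- if (mode == "poisson") {
    floor(runif(n, 0, L))
  } else {
    parents <- floor(runif(kappa, 0, L))
    alloc <- as.vector(stats::rmultinom(1, n, rep(1 / kappa, kappa)))
    floor(rep(parents, alloc) + rnorm(n, 0, cluster_sd)) %% L
  }
  starts <- sort(starts)
  features(starts, starts + rep_len, cls = "repeat",
           name = sprintf("r%03d", seq_len(n)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## all clade tip sets of a rooted tree, largest first
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- lapply((n + 1):(n + tree$Nnode), function(node) {
    tips <- ape::extract.clade(tree, node)$tip.label
    sort(tips)
  })
  sets[order(-vapply(sets, length, integer(1)))]
}

## pick a tip set for an occupancy category; falls back to augmenting or
## trimming the closest clade when no clade has a size in the category range
pick_occupants <- function(tree, category) {
  tips <- tree$tip.label
  n <- length(tips)
  if (category == "all") return(tips)
  if (category == "unique") return(sample(tips, 1))
  range_ok <- if (category == "majority") function(k) k > n / 2 && k < n else
    function(k) k >= 2 && k <= n / 2
  sets <- clade_tip_sets(tree)
  sets <- c(sets, lapply(tips, identity))
  ok <- sets[vapply(sets, function(s) range_ok(length(s)), logical(1))]
  if (length(ok)) return(ok[[sample.int(length(ok), 1)]])
  if (category == "majority") {
    base <- sets[[which.max(vapply(sets, length, integer(1)) < n)]]
    extra <- setdiff(tips, base)
    k <- floor(n / 2) + 1 - length(base)
    sort(c(base, sample(extra, max(0, k))))
  } else {
    sample(tips, 2)
  }
}

## sample non-colliding start positions; occupied is a 2-col matrix of
## reserved intervals (with margin applied by caller)
sample_positions <- function(n_pos, len, L, occupied, mode = "poisson",
                             cluster_sd = 400, margin = 10) {
  out <- numeric(0)
  center <- if (mode == "clustered") floor(runif(1, L * 0.1, L * 0.9)) else NA
  tries <- 0
  while (length(out) < n_pos) {
    tries <- tries + 1
    if (tries > 500) stop("requested repeats exceed genome capacity")
    s <- if (mode == "clustered") {
      floor(center + rnorm(1, 0, cluster_sd))
    } else floor(runif(1, 50, L - len - 50))
    if (s < 50 || s + len > L - 50) next
    if (nrow(occupied) &&
        any(occupied[, 1] < s + len + margin & occupied[, 2] > s - margin)) next
    occupied <- rbind(occupied, c(s, s + len))
    out <- c(out, s)
  }
  list(starts = sort(out), occupied = occupied)
}

#' Plant a constructive inversion scenario in one genome
#'
#' Builds, on an uninverted genome, the ancestral arrangement proposed for
#' microhomology-mediated inversion formation: two direct repeat copies
#' flanking the right endpoint (one just inside the segment, one just outside)
#' and a short microhomology — the `mh_len` bases entering the left endpoint
#' are made the reverse complement of the bases leaving the right endpoint —
#' then applies [revert_segment()] between the two endpoints. After the
#' inversion the two repeat copies are inverted relative to each other at
#' opposite ends of the segment, and the endpoint-outward sequences complement
#' at the first `mh_len` sites.
#'
#' @param genome A [circular_genome()].
#' @param left,right Inversion endpoints, `0 <= left < right <= L`, both at
#'   least `2 * repeat_len + 300` bp from the origin and from each other.
#' @param repeat_len Direct repeat length in bp (default 60).
#' @param mh_len Microhomology length in bp (default 10).
#' @param inside_gap,between_gap Distances (bp) from the right endpoint to the
#'   inner repeat copy and between the endpoint and the outer copy
#'   (defaults 150 and 90).
#' @return List `genome` (the inverted genome), `left`, `right` (the applied
#'   endpoints), `canonical_left`, `canonical_right` (the leftmost
#'   representative of the endpoint ambiguity interval created by the
#'   microhomology — the pair [refine_endpoints()] reports),
#'   `repeat_intervals` (positions of the two copies after the inversion, in
#'   the inverted genome), `mh_len`.
#' @export
plant_fig6_inversion <- function(genome, left, right, repeat_len = 60,
                                 mh_len = 10, inside_gap = 150, between_gap = 90) {
  L <- genome$length
  stopifnot(left > repeat_len + inside_gap + mh_len,
            right + between_gap + repeat_len < L,
            right - left > 2 * (repeat_len + inside_gap))
  s <- genome$sequence
  motif <- random_dna(repeat_len)
  in_start <- right - inside_gap - repeat_len
  out_start <- right + between_gap
  substr(s, in_start + 1, in_start + repeat_len) <- motif
  substr(s, out_start + 1, out_start + repeat_len) <- motif
  substr(s, left - mh_len + 1, left) <- revcomp(substr0(s, right, right + mh_len))
  genome$sequence <- s
  inverted <- revert_segment(genome, left, right)
  ## the microhomology makes every symmetric shift (left-k, right+k) within
  ## the outward complementary run an equivalent description of the same
  ## genome; record the leftmost (canonical) representative
  qc <- seq_chars(inverted$sequence)
  r_out <- 0
  while (left - r_out - 1 >= 1 && right + r_out + 1 <= L &&
         qc[left - r_out] == comp_chars(qc[right + r_out + 1])) {
    r_out <- r_out + 1
  }
  ## inner copy maps to the left end of the inverted segment
  in_new <- c(left + right - (in_start + repeat_len), left + right - in_start)
  list(genome = inverted, left = left, right = right,
       canonical_left = left - r_out, canonical_right = right + r_out,
       repeat_intervals = rbind(inner = in_new,
                                outer = c(out_start, out_start + repeat_len)),
       mh_len = mh_len)
}

#' Simulate a plastome set with known truth
#'
#' Generates a tree, a root genome with a gene skeleton, repeat families with
#' configured occupancy planted at conserved positions (single gain on the stem
#' of the occupying clade, no losses), per-branch point mutations, optional
#' constructive inversions (see [plant_fig6_inversion()]), and a
#' Brownian-motion trait. Identical configurations give byte-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `config`, `tree`, `genomes` (named list of
#'   [circular_genome()]s), and `truth`: `families` (family, category, length,
#'   occupants), `repeats` (per-taxon planted intervals in each tip's current
#'   coordinates), `inversions` (taxon, left, right, name), `traits`.
#' @export
simulate_plastome_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$genome_length
  tree <- simulate_tree(config$n_taxa, config$birth_rate)
  tips <- tree$tip.label

  ## gene skeleton on the root genome
  skel <- local({
    pos <- 200; i <- 0; rows <- list()
    while (pos + config$gene_length + 200 <= L) {
      i <- i + 1
      strand <- if (i %% 2) "+" else "-"
      gname <- sprintf("g%d", i)
      rows[[length(rows) + 1]] <- features(pos, pos + config$gene_length,
                                           strand, "gene", gname)
      if (i %% 4 == 0) {
        third <- floor(config$gene_length / 3)
        rows[[length(rows) + 1]] <- features(
          c(pos, pos + 2 * third), c(pos + third, pos + config$gene_length),
          strand, "exon", paste0(gname, c(".e1", ".e2")))
        rows[[length(rows) + 1]] <- features(pos + third, pos + 2 * third,
                                             strand, "intron", paste0(gname, ".i1"))
      }
      pos <- pos + config$gene_length + config$intergenic_length
    }
    do.call(rbind, rows)
  })

  root_seq <- random_dna(L)

  ## repeat families: category, length, motif, occupying tips, positions
  fam <- list(); occupied <- matrix(numeric(0), ncol = 2)
  bins <- list(c(30, 99), c(100, 199), c(200, 300))
  if (config$n_repeat_families > 0) for (f in seq_len(config$n_repeat_families)) {
    category <- sample(names(config$occupancy_mix), 1, prob = config$occupancy_mix)
    bin <- bins[[sample.int(3, 1, prob = config$length_mix)]]
    len <- sample(bin[1]:bin[2], 1)
    occupants <- pick_occupants(tree, category)
    copies <- sample(config$copies_range[1]:config$copies_range[2], 1)
    placed <- sample_positions(copies, len, L, occupied, mode = config$placement,
                               cluster_sd = config$cluster_sd)
    occupied <- placed$occupied
    fam[[f]] <- list(family = f, category = category, length = len,
                     motif = random_dna(len), occupants = occupants,
                     starts = placed$starts)
  }

  ## evolve the background sequence down the tree
  node_seq <- vector("list", max(tree$edge))
  root_node <- length(tips) + 1
  node_seq[[root_node]] <- root_seq
  tree <- stats::reorder(tree, "cladewise")  # edge rows in preorder
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    s <- node_seq[[parent]]
    n_mut <- rbinom(1, L, min(1, config$mutation_rate * tree$edge.length[e]))
    if (n_mut > 0) {
      pos <- sample.int(L, n_mut)
      old <- substring(s, pos, pos)
      new <- vapply(old, function(bse) sample(setdiff(c("A", "C", "G", "T"), bse), 1),
                    character(1))
      for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- new[k]
    }
    node_seq[[child]] <- s
  }

  ## assemble tip genomes: plant family motifs, record truth
  genomes <- list(); truth_rep <- list()
  for (t_i in seq_along(tips)) {
    taxon <- tips[t_i]
    s <- node_seq[[t_i]]
    for (fm in fam) {
      if (!(taxon %in% fm$occupants)) next
      for (st in fm$starts) {
        substr(s, st + 1, st + fm$length) <- fm$motif
        truth_rep[[length(truth_rep) + 1]] <- data.frame(
          taxon_id = taxon, family = fm$family, category = fm$category,
          start = st, end = st + fm$length)
      }
    }
    genomes[[taxon]] <- circular_genome(taxon, s, skel)
  }
  truth_rep <- if (length(truth_rep)) do.call(rbind, truth_rep) else
    data.frame(taxon_id = character(0), family = integer(0),
               category = character(0), start = numeric(0), end = numeric(0))

  ## inversions: deterministic choice of carrier tips; endpoints at intergenic
  ## midpoints clear of planted repeats
  truth_inv <- list()
  if (config$n_inversions > 0) {
    carriers <- tips[floor(seq(2, length(tips), length.out = config$n_inversions))]
    ## candidate endpoint positions: inside intergenic gaps, clear of planted
    ## repeats by 300 bp (covers the direct-repeat copies and microhomology)
    cand <- local({
      g <- skel[skel$cls == "gene", , drop = FALSE]
      g <- g[order(g$start), ]
      pos <- unlist(lapply(seq_len(nrow(g) - 1), function(i) {
        lo <- g$end[i] + 50; hi <- g$start[i + 1] - 50
        if (hi > lo) seq(lo, hi, by = 10) else numeric(0)
      }))
      pos[!vapply(pos, function(p)
        any(occupied[, 1] < p + 300 & occupied[, 2] > p - 300), logical(1))]
    })
    seg <- round(config$inversion_frac * L)
    for (taxon in carriers) {
      target_a <- round(L * 0.25)
      a <- cand[which.min(abs(cand - target_a))]
      b_ok <- cand[cand >= a + max(2000, seg / 2)]
      if (!length(a) || !length(b_ok)) stop("genome too short for the requested inversion")
      b <- b_ok[which.min(abs(b_ok - (a + seg)))]
      planted <- plant_fig6_inversion(genomes[[taxon]], a, b)
      genomes[[taxon]] <- planted$genome
      ## map planted intervals through the inversion row-by-row so the
      ## family bookkeeping keeps its correspondence (none straddle a or b)
      sel <- which(truth_rep$taxon_id == taxon)
      for (r in sel) {
        if (truth_rep$start[r] >= a && truth_rep$end[r] <= b) {
          s0 <- truth_rep$start[r]; e0 <- truth_rep$end[r]
          truth_rep$start[r] <- a + b - e0
          truth_rep$end[r] <- a + b - s0
        }
      }
      truth_inv[[length(truth_inv) + 1]] <- data.frame(
        taxon_id = taxon, left = planted$canonical_left,
        right = planted$canonical_right, applied_left = a, applied_right = b,
        name = name_inversion(genomes[[taxon]]$features, a, b))
    }
  }
  truth_inv <- if (length(truth_inv)) do.call(rbind, truth_inv) else
    data.frame(taxon_id = character(0), left = numeric(0), right = numeric(0),
               name = character(0))

  traits <- simulate_bm_traits(tree, config$trait_lambda, config$trait_sigma2)

  fam_df <- if (length(fam)) do.call(rbind, lapply(fam, function(fm)
    data.frame(family = fm$family, category = fm$category, length = fm$length,
               occupants = paste(fm$occupants, collapse = ",")))) else
    data.frame(family = integer(0), category = character(0),
               length = integer(0), occupants = character(0))

  list(config = config, tree = tree, genomes = genomes,
       truth = list(families = fam_df, repeats = truth_rep,
                    inversions = truth_inv, traits = traits))
}
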