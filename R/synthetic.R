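#' @title Synthetic deletion-experiment data
#' @description
#' Generators emulating the factorial design of a two-state deletion
#' experiment: 8 conditions per gene pair, replicate measurements with
#' Gaussian noise on the log2 scale (multiplicative on the raw scale),
#' exponentiated back to a raw, strictly positive trait. Replicate counts
#' default to the study design the package targets: 8 for wildtype and
#' single deletions, 4 for double deletions.
#' @name synthetic
NULL

# replicate count for one condition under the default design
replicates_for <- function(n_replicates, a_del, b_del) {
  if (length(n_replicates) == 1L && is.null(names(n_replicates))) {
    return(as.integer(n_replicates))
  }
  cls <- if (a_del + b_del == 0L) "wildtype" else if (a_del + b_del == 1L)
    "single" else "double"
  as.integer(n_replicates[[cls]])
}

default_replicates <- c(wildtype = 8L, single = 8L, double = 4L)

#' Simulate one gene pair's trait table
#'
#' Draws `n` replicate log2 trait values per condition around the forward
#' model prediction and exponentiates to the raw scale.
#'
#' @param arch A [pathway_architecture()] (its orientation decides whether
#'   gene A or gene B is upstream).
#' @param infl An [influence_set()] in log2 trait units.
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param n_replicates Integer (same count for every condition) or named
#'   vector `c(wildtype=, single=, double=)`.
#' @param seed Integer seed; identical spec and seed give identical tables.
#' @param gene_a,gene_b,trait_name Labels.
#' @return A raw-scale [trait_table()].
#' @export
simulate_pair <- function(arch, infl, noise_sd = 0.1,
                          n_replicates = default_replicates, seed = 1L,
                          gene_a = "geneA", gene_b = "geneB",
                          trait_name = "trait") {
  stopifnot(inherits(arch, "pathway_architecture"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  theta <- predicted_cell_means_model(arch, infl, gene_a, gene_b, trait_name)
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(theta)), function(i) {
      n <- replicates_for(n_replicates, theta$gene_a_deleted[i],
                          theta$gene_b_deleted[i])
      logv <- theta$mean[i] + stats::rnorm(n, 0, noise_sd)
      data.frame(gene_a_deleted = theta$gene_a_deleted[i],
                 gene_b_deleted = theta$gene_b_deleted[i],
                 signal = theta$signal[i],
                 replicate = seq_len(n),
                 value = 2^logv)
    })
  })
  trait_table(do.call(rbind, rows), gene_a = gene_a, gene_b = gene_b,
              trait_name = trait_name, log_base = NA)
}

#' Simulate a multi-gene signal-responsive cascade
#'
#' Generates, for every unordered gene pair of a linear cascade
#' S -> g1 -> g2 -> ... -> gK, the trait table obtained by deleting only
#' that pair (all other genes intact). The trait is evaluated on the full
#' Boolean cascade -- each gene's activity requires the gene to be present
#' and follows the activity of the factor directly upstream according to
#' the step sign -- so indirect relations arise naturally in the data
#' rather than by composing pairwise models. The gold standard returned is
#' the set of all direct and indirect ordered relations g_i -> g_j (i < j).
#'
#' @param genes Ordered character vector of gene names (upstream first),
#'   length >= 3.
#' @param signs Step signs, length equal to `length(genes)`: the first is
#'   the signal->g1 step, entry k > 1 the g(k-1)->g(k) step.
#' @param influences List with `theta0`, `sigmaS`, per-gene signal-specific
#'   effects `sigma` (length K) and per-gene basal effects `alpha`
#'   (length K).
#' @param noise_sd,n_replicates,seed As in [simulate_pair()].
#' @param trait_name Trait label stamped on every table.
#' @return List with `tables` (named list of [trait_table()], one per
#'   unordered pair) and `gold` (a [gold_standard()]).
#' @export
simulate_cascade <- function(genes, signs, influences, noise_sd = 0.1,
                             n_replicates = default_replicates, seed = 1L,
                             trait_name = "trait") {
  K <- length(genes)
  if (K < 3L) stop("a cascade needs at least 3 genes")
  if (length(signs) != K) stop("signs must have one entry per cascade step")
  if (length(influences$sigma) != K || length(influences$alpha) != K) {
    stop("influences$sigma and influences$alpha must have one entry per gene")
  }
  stopifnot(all(signs %in% c(-1, 1)))
  if (noise_sd < 0) stop("noise_sd must be non-negative")

  cascade_trait <- function(present, s) {
    # present: logical K-vector; activity propagates down the chain
    act <- logical(K)
    upstream_act <- s
    for (k in seq_len(K)) {
      input <- if (signs[k] > 0) upstream_act else !upstream_act
      act[k] <- present[k] && input
      upstream_act <- act[k]
    }
    influences$theta0 + s * influences$sigmaS +
      sum(act * influences$sigma) + sum(present * influences$alpha)
  }

  pairs <- utils::combn(K, 2)
  tables <- list()
  for (pcol in seq_len(ncol(pairs))) {
    i <- pairs[1, pcol]; j <- pairs[2, pcol]
    cond <- conditions()
    rows <- list()
    pair_seed <- (seed * 1000L + pcol) %% .Machine$integer.max
    rows <- with_seed(pair_seed, {
      lapply(seq_len(nrow(cond)), function(ci) {
        present <- rep(TRUE, K)
        present[i] <- cond$gene_a_deleted[ci] == 0
        present[j] <- cond$gene_b_deleted[ci] == 0
        mu <- cascade_trait(present, cond$signal[ci] == 1)
        n <- replicates_for(n_replicates, cond$gene_a_deleted[ci],
                            cond$gene_b_deleted[ci])
        data.frame(gene_a_deleted = cond$gene_a_deleted[ci],
                   gene_b_deleted = cond$gene_b_deleted[ci],
                   signal = cond$signal[ci],
                   replicate = seq_len(n),
                   value = 2^(mu + stats::rnorm(n, 0, noise_sd)))
      })
    })
    pair_name <- paste(genes[i], genes[j], sep = "__")
    tables[[pair_name]] <- trait_table(
      do.call(rbind, rows), gene_a = genes[i], gene_b = genes[j],
      trait_name = trait_name, log_base = NA)
  }
  gold_rel <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pcol) {
    data.frame(upstream = genes[pairs[1, pcol]],
               downstream = genes[pairs[2, pcol]],
               stringsAsFactors = FALSE)
  }))
  list(tables = tables,
       gold = gold_standard(gold_rel, genes = genes, source = "simulated cascade"))
}

#' Size of the hypothesis and design space
#'
#' Convenience counts for an analysis of `n_genes` genes: number of
#' candidate architectures, factorial conditions per pair, unordered gene
#' pairs, and deletion genotypes (singles plus doubles) to construct.
#'
#' @param n_genes Number of genes in the study.
#' @return Named list of counts.
#' @export
design_summary <- function(n_genes) {
  list(
    architectures_per_orientation = 8L,
    architectures = length(architectures()),
    conditions_per_pair = nrow(conditions()),
    gene_pairs = choose(n_genes, 2),
    deletion_genotypes = n_genes + choose(n_genes, 2)
  )
}
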