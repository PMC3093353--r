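# Shared fixtures: the reference pathway used across tests is the
# all-activation chain S -> X -> Y -> T with influences
# theta0 = 10, sigmaS = 1, sigmaX = 2, sigmaY = 3, alphaX = 0.5,
# alphaY = 0.25, alphaI = 0 (log2 trait units). Its exact regression
# parameters were derived once by forward-evaluating the model over the 8
# conditions and applying the cell-mean contrasts by hand:
#   betaS = 6, betaX = (-0.5, -5.5), betaY = (-0.25, -3.25),
#   betaI = (0, 3), deltaX = 5, deltaY = 3, deltaI = -3.

ref_arch <- function(upstream = "a") pathway_architecture(1, 1, 1, upstream)

ref_influences <- function() {
  influence_set(theta0 = 10, sigmaS = 1, sigmaX = 2, sigmaY = 3,
                alphaX = 0.5, alphaY = 0.25, alphaI = 0)
}

ref_cell_means <- function() {
  predicted_cell_means_model(ref_arch(), ref_influences())
}

ref_table <- function(noise_sd = 0, n_replicates = 4, seed = 7) {
  simulate_pair(ref_arch(), ref_influences(), noise_sd = noise_sd,
                n_replicates = n_replicates, seed = seed)
}

# delta_estimates with chosen point estimates, for unit tests of the
# order/threshold logic
fake_deltas <- function(dX, dY, dI, se_dI = 0.1, p_dI = 1e-6,
                        gene_a = "A", gene_b = "B") {
  est <- c(delta0 = 0, deltaX = dX, deltaY = dY, deltaI = dI)
  structure(list(
    estimate = est,
    se = c(delta0 = se_dI, deltaX = se_dI, deltaY = se_dI, deltaI = se_dI),
    df = c(delta0 = 10, deltaX = 10, deltaY = 10, deltaI = 10),
    p = c(delta0 = 1, deltaX = p_dI, deltaY = p_dI, deltaI = p_dI),
    noise_free = FALSE, replicated = TRUE,
    gene_a = gene_a, gene_b = gene_b, trait_name = "trait"),
    class = "delta_estimates")
}

all_architectures <- function() architectures()

# brute-force transitive reduction of an unsigned DAG: keep edge (u, v)
# iff no intermediate w with an edge u -> w and a path w ->* v; closure by
# iterated boolean matrix product (independent of the package's signed
# fixed-point implementation)
brute_reduction <- function(adj) {
  n <- nrow(adj)
  reach <- adj
  repeat {
    nxt <- (reach + reach %*% adj) > 0
    storage.mode(nxt) <- "integer"
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  keep <- adj
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (adj[u, v] == 0) next
    for (w in seq_len(n)) {
      if (w != u && w != v && adj[u, w] == 1 && reach[w, v] == 1) {
        keep[u, v] <- 0L
        break
      }
    }
  }
  keep
}

random_dag <- function(n_nodes, p_edge = 0.3) {
  adj <- matrix(0L, n_nodes, n_nodes)
  for (u in seq_len(n_nodes - 1)) for (v in (u + 1):n_nodes) {
    if (stats::runif(1) < p_edge) adj[u, v] <- 1L
  }
  dimnames(adj) <- list(paste0("g", seq_len(n_nodes)),
                        paste0("g", seq_len(n_nodes)))
  adj
}

network_from_adj <- function(adj, sign = "activates") {
  idx <- which(adj == 1, arr.ind = TRUE)
  ed <- data.frame(from = rownames(adj)[idx[, 1]],
                   to = colnames(adj)[idx[, 2]],
                   sign = rep(sign, nrow(idx)),
                   provenance = rep("test", nrow(idx)),
                   indirect = rep(FALSE, nrow(idx)),
                   stringsAsFactors = FALSE)
  structure(list(nodes = rownames(adj), edges = ed,
                 cohesive = NULL, conflicts = NULL),
            class = "network_model")
}

adj_from_network <- function(net, direct_only = TRUE) {
  adj <- matrix(0L, length(net$nodes), length(net$nodes),
                dimnames = list(net$nodes, net$nodes))
  ed <- net$edges
  if (direct_only) ed <- ed[!ed$indirect, , drop = FALSE]
  for (i in seq_len(nrow(ed))) adj[ed$from[i], ed$to[i]] <- 1L
  adj
}

# fake pair_inference with just the fields the network builder reads
fake_inference <- function(gene_a, gene_b, upstream = gene_a,
                           status = "inferred", x_to_y = 1, s_to_x = 1,
                           trait = "trait") {
  structure(list(
    gene_a = gene_a, gene_b = gene_b, trait_name = trait, status = status,
    architecture = pathway_architecture(s_to_x, x_to_y, 1,
                                        if (upstream == gene_a) "a" else "b"),
    upstream = if (status == "inferred") upstream else NA,
    influences = NULL, diagnostics = list()),
    class = "pair_inference")
}

cascade_influences <- function() {
  list(theta0 = 10, sigmaS = 0.5, sigma = c(3, 1.5, 0.75, 0.4),
       alpha = c(0.1, -0.1, 0.05, 0.15))
}
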