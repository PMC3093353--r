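#' Assemble pairwise inferences into a signed directed network
#'
#' Each inferred pair contributes one edge from the upstream to the
#' downstream gene, signed by the X->Y step of its matched architecture.
#' Optionally, an edge from the signal node to each upstream gene is added,
#' signed by the S->X step. Cohesive units (no feedforward loop, order
#' unresolvable) are recorded as undirected annotations, not edges.
#'
#' @param results List of `pair_inference` objects from one trait dataset.
#' @param include_signal Add signal->gene edges (default FALSE).
#' @param signal_node Name of the signal node.
#' @return Object of class `network_model`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `sign`, `provenance`, `indirect`),
#'   `cohesive` and `conflicts`.
#' @export
build_network <- function(results, include_signal = FALSE, signal_node = "S") {
  stopifnot(is.list(results))
  edges <- list()
  cohesive <- list()
  nodes <- character()
  conflicts <- list()
  for (r in results) {
    stopifnot(inherits(r, "pair_inference"))
    nodes <- union(nodes, c(r$gene_a, r$gene_b))
    if (r$status == "inferred") {
      up <- r$upstream
      down <- setdiff(c(r$gene_a, r$gene_b), up)
      edges[[length(edges) + 1L]] <- data.frame(
        from = up, to = down,
        sign = if (r$architecture$x_to_y > 0) "activates" else "represses",
        provenance = r$trait_name, indirect = FALSE,
        stringsAsFactors = FALSE)
      if (include_signal) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = signal_node, to = up,
          sign = if (r$architecture$s_to_x > 0) "activates" else "represses",
          provenance = r$trait_name, indirect = FALSE,
          stringsAsFactors = FALSE)
      }
    } else if (r$status == "cohesive_unit") {
      cohesive[[length(cohesive) + 1L]] <- data.frame(
        gene_a = r$gene_a, gene_b = r$gene_b, provenance = r$trait_name,
        stringsAsFactors = FALSE)
    }
  }
  ed <- if (length(edges)) do.call(rbind, edges) else empty_edges()
  # merge duplicates; contradictory duplicates (same pair of genes, opposite
  # direction or sign) are an input error for a single-trait network
  key_pair <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  key_full <- paste(ed$from, ed$to, ed$sign)
  keep <- !duplicated(key_full)
  for (kp in unique(key_pair)) {
    variants <- unique(key_full[key_pair == kp])
    if (length(variants) > 1L) {
      stop("contradictory inferences for gene pair ", kp, ": ",
           paste(variants, collapse = " vs "))
    }
  }
  ed <- ed[keep, , drop = FALSE]
  rownames(ed) <- NULL
  if (include_signal && length(results)) nodes <- union(signal_node, nodes)
  structure(list(nodes = nodes, edges = ed,
                 cohesive = if (length(cohesive)) do.call(rbind, cohesive) else NULL,
                 conflicts = NULL),
            class = "network_model")
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), sign = character(),
             provenance = character(), indirect = logical(),
             stringsAsFactors = FALSE)
}

#' Convert a network model to an igraph graph
#'
#' @param net A `network_model`.
#' @param direct_only Drop edges flagged as indirect.
#' @return An [igraph::graph] with edge attributes `sign` and `provenance`.
#' @export
as_igraph <- function(net, direct_only = TRUE) {
  ed <- net$edges
  if (direct_only) ed <- ed[!ed$indirect, , drop = FALSE]
  ed$indirect <- as.integer(ed$indirect)  # DOT/GraphML have no boolean type
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

# Signed reachability over paths of length >= 1: boolean matrices
# (positive-composition, negative-composition) by fixed-point iteration.
signed_reachability <- function(net) {
  n <- length(net$nodes)
  AP <- AN <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  ed <- net$edges[!net$edges$indirect, , drop = FALSE]
  for (i in seq_len(nrow(ed))) {
    if (ed$sign[i] == "activates") AP[ed$from[i], ed$to[i]] <- TRUE
    else AN[ed$from[i], ed$to[i]] <- TRUE
  }
  RP <- AP; RN <- AN
  repeat {
    RP2 <- RP | ((RP %*% AP + RN %*% AN) > 0)
    RN2 <- RN | ((RP %*% AN + RN %*% AP) > 0)
    if (identical(RP2, RP) && identical(RN2, RN)) break
    RP <- RP2; RN <- RN2
  }
  list(pos = RP, neg = RN, AP = AP, AN = AN)
}

#' Transitive reduction of an inferred network
#'
#' Removes every edge implied by a longer directed path with the same
#' composed sign (the product of activation/repression signs along the
#' path). For a DAG this minimal edge set is unique and preserves
#' reachability exactly. Removed edges are retained with `indirect = TRUE`
#' so that the evidence is not lost. Cyclic inputs are rejected: the
#' inference cannot resolve feedback.
#'
#' @param net A `network_model`.
#' @return The reduced `network_model`.
#' @export
transitive_reduction <- function(net) {
  stopifnot(inherits(net, "network_model"))
  g <- as_igraph(net)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    stop("network contains a cycle (e.g. involving edge ",
         paste(attr(cyc, "vnames"), collapse = ", "),
         "); transitive reduction requires a DAG")
  }
  r <- signed_reachability(net)
  # paths of length >= 2 with a given composed sign
  long_pos <- (r$pos %*% r$AP + r$neg %*% r$AN) > 0
  long_neg <- (r$pos %*% r$AN + r$neg %*% r$AP) > 0
  ed <- net$edges
  for (i in seq_len(nrow(ed))) {
    if (ed$indirect[i]) next
    implied <- if (ed$sign[i] == "activates") long_pos[ed$from[i], ed$to[i]]
               else long_neg[ed$from[i], ed$to[i]]
    if (implied) ed$indirect[i] <- TRUE
  }
  net$edges <- ed
  net
}

#' Merge networks inferred from different trait datasets
#'
#' Takes the union of the edge sets. Identical edges are merged with
#' combined provenance; edges asserted with opposite signs by the two
#' datasets are excluded from the merged network and recorded in
#' `conflicts`.
#'
#' @param a,b `network_model` objects over the same gene universe.
#' @return The merged `network_model`.
#' @export
combine_networks <- function(a, b) {
  stopifnot(inherits(a, "network_model"), inherits(b, "network_model"))
  ed <- rbind(a$edges[!a$edges$indirect, , drop = FALSE],
              b$edges[!b$edges$indirect, , drop = FALSE])
  nodes <- union(a$nodes, b$nodes)
  out <- empty_edges()
  conflicts <- empty_edges()
  if (nrow(ed)) {
    key_dir <- paste(ed$from, ed$to)
    for (k in unique(key_dir)) {
      grp <- ed[key_dir == k, , drop = FALSE]
      if (length(unique(grp$sign)) > 1L) {
        conflicts <- rbind(conflicts, grp)
      } else {
        merged <- grp[1L, , drop = FALSE]
        merged$provenance <- paste(sort(unique(grp$provenance)), collapse = ",")
        out <- rbind(out, merged)
      }
    }
  }
  rownames(out) <- NULL
  structure(list(nodes = nodes, edges = out,
                 cohesive = rbind(a$cohesive, b$cohesive),
                 conflicts = if (nrow(conflicts)) conflicts else NULL),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  direct <- x$edges[!x$edges$indirect, , drop = FALSE]
  cat("Network model:", length(x$nodes), "nodes,", nrow(direct),
      "direct edge(s)", sep = " ")
  if (any(x$edges$indirect)) cat(",", sum(x$edges$indirect), "indirect")
  cat("\n")
  if (nrow(direct)) {
    arrow <- ifelse(direct$sign == "activates", "->", "-|")
    cat(paste0("  ", direct$from, " ", arrow, " ", direct$to,
               "  [", direct$provenance, "]", collapse = "\n"), "\n")
  }
  if (!is.null(x$cohesive)) {
    cat("  cohesive units:",
        paste(x$cohesive$gene_a, x$cohesive$gene_b, sep = "~", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Export a network
#'
#' `write_sif()` writes the simple interaction format
#' (`source<TAB>activates|represses<TAB>target`); `write_dot()` and
#' `write_graphml()` delegate to igraph.
#'
#' @param net A `network_model`.
#' @param path Output file path.
#' @param direct_only Export only direct (non-reduced) edges.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(net, path, direct_only = TRUE) {
  ed <- net$edges
  if (direct_only) ed <- ed[!ed$indirect, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s", ed$from, ed$sign, ed$to)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_dot <- function(net, path, direct_only = TRUE) {
  igraph::write_graph(as_igraph(net, direct_only), path, format = "dot")
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(net, path, direct_only = TRUE) {
  igraph::write_graph(as_igraph(net, direct_only), path, format = "graphml")
  invisible(path)
}
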