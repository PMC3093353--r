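#' Construct a gold standard of known directed relations
#'
#' @param relations Data frame (or two-column matrix) with columns
#'   `upstream`, `downstream`: all well-established direct and indirect
#'   ordered relations in the analyzed gene universe, including both
#'   directions for feedback pairs.
#' @param genes Gene universe; defaults to the genes appearing in
#'   `relations`.
#' @param source Label for the provenance of the standard.
#' @return Object of class `gold_standard`.
#' @export
gold_standard <- function(relations, genes = NULL, source = "curated") {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  names(relations)[1:2] <- c("upstream", "downstream")
  if (is.null(genes)) genes <- sort(unique(c(relations$upstream, relations$downstream)))
  extra <- setdiff(unique(c(relations$upstream, relations$downstream)), genes)
  if (length(extra)) stop("gold relations mention genes outside the universe: ",
                          paste(extra, collapse = ", "))
  if (nrow(relations) == 0L) stop("empty gold standard")
  structure(list(relations = relations[c("upstream", "downstream")],
                 genes = genes, source = source),
            class = "gold_standard")
}

#' Read a gold standard from a two-column TSV
#'
#' @param path TSV with header columns `upstream`, `downstream`.
#' @param genes Optional gene universe.
#' @return A [gold_standard()].
#' @export
read_gold_standard <- function(path, genes = NULL) {
  rel <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  gold_standard(rel, genes = genes, source = path)
}

#' Write a gold standard to a two-column TSV
#'
#' @param gold A [gold_standard()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(gold$relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Directed relations asserted by a result set: one (upstream, downstream)
# row per pair with status "inferred".
inferred_relations <- function(results) {
  rows <- lapply(results, function(r) {
    if (!inherits(r, "pair_inference") || r$status != "inferred") return(NULL)
    data.frame(upstream = r$upstream,
               downstream = setdiff(c(r$gene_a, r$gene_b), r$upstream),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(upstream = character(), downstream = character())
}

#' Score inferred directed relations against a gold standard
#'
#' True positives are inferred ordered relations present in the gold
#' standard; false positives are inferred relations absent from it. TPR
#' divides by the number of gold relations, FPR by the number of candidate
#' ordered pairs of the gene universe not in the gold standard (both
#' orientations count as candidates, since the method emits directed
#' relations).
#'
#' @param inferred List of `pair_inference` objects, or a data frame with
#'   columns `upstream`, `downstream`.
#' @param gold A [gold_standard()].
#' @return List with `tpr`, `fpr` and the counts `tp`, `fp`, `n_gold`,
#'   `n_candidates`.
#' @export
score <- function(inferred, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  rel <- if (is.data.frame(inferred)) inferred else inferred_relations(inferred)
  gold_keys <- paste(gold$relations$upstream, gold$relations$downstream)
  rel_keys <- unique(paste(rel$upstream, rel$downstream))
  n_genes <- length(gold$genes)
  n_candidates <- n_genes * (n_genes - 1L)
  tp <- sum(rel_keys %in% gold_keys)
  fp <- length(rel_keys) - tp
  list(tpr = tp / length(gold_keys),
       fpr = fp / (n_candidates - length(gold_keys)),
       tp = tp, fp = fp,
       n_gold = length(gold_keys), n_candidates = n_candidates)
}

#' TPR/FPR as a function of the masking threshold
#'
#' Re-runs the order/architecture steps of [infer_pair()] at each masking
#' threshold (the Step-1 significance test is unaffected by the threshold)
#' and scores the resulting directed relations against the gold standard,
#' per trait dataset and for the union of all datasets ("combined").
#'
#' @param datasets Named list of trait datasets; each dataset is a list of
#'   [trait_table()] objects (one per gene pair).
#' @param gold A [gold_standard()].
#' @param thresholds Numeric vector of masking thresholds in \[0, 1\].
#' @param alpha Significance level.
#' @return Data frame with columns `threshold`, `trait`, `tpr`, `fpr`.
#' @export
threshold_sweep <- function(datasets, gold, thresholds, alpha = 0.05) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  if (inherits(datasets[[1]], "trait_table")) datasets <- list(trait = datasets)
  if (is.null(names(datasets))) names(datasets) <- paste0("trait", seq_along(datasets))
  out <- list()
  for (thr in thresholds) {
    combined <- NULL
    for (ds_name in names(datasets)) {
      results <- lapply(datasets[[ds_name]], infer_pair,
                        alpha = alpha, eps_thr = thr)
      rel <- inferred_relations(results)
      combined <- unique(rbind(combined, rel))
      sc <- score(rel, gold)
      out[[length(out) + 1L]] <- data.frame(
        threshold = thr, trait = ds_name, tpr = sc$tpr, fpr = sc$fpr)
    }
    sc <- score(combined, gold)
    out[[length(out) + 1L]] <- data.frame(
      threshold = thr, trait = "combined", tpr = sc$tpr, fpr = sc$fpr)
  }
  do.call(rbind, out)
}
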