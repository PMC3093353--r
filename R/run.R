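#' @title Pipeline entry points
#' @description
#' Thin orchestration over the analysis modules: read a dataset of per-pair
#' trait tables, infer every pair, assemble and reduce the network, write
#' machine-readable results; or sweep the masking threshold against a gold
#' standard. These functions back the `epistinfer` command-line script
#' (`inst/scripts/epistinfer`) with subcommands `simulate`, `infer` and
#' `benchmark`.
#' @name pipeline
NULL

schema_version <- "1.0"

#' Read a dataset of per-pair trait tables
#'
#' Accepts either a directory of files named `<geneA>__<geneB>.tsv` (one
#' pair each) or a single delimited file with additional `gene_a`,
#' `gene_b` columns identifying the pair of every row.
#'
#' @param input Directory or file path.
#' @param trait_name Trait label stamped on the tables.
#' @return Named list of [trait_table()] objects.
#' @export
read_pair_tables <- function(input, trait_name = "trait") {
  if (dir.exists(input)) {
    files <- list.files(input, pattern = "\\.(tsv|csv)$", full.names = TRUE)
    files <- files[!grepl("gold\\.tsv$", files)]
    if (length(files) == 0L) stop("no pair files found in ", input)
    tables <- lapply(files, function(f) {
      stem <- sub("\\.(tsv|csv)$", "", basename(f))
      genes <- strsplit(stem, "__", fixed = TRUE)[[1]]
      if (length(genes) != 2L) {
        stop("cannot derive the gene pair from file name '", basename(f),
             "'; expected <geneA>__<geneB>.tsv")
      }
      read_trait_table(f, gene_a = genes[1], gene_b = genes[2],
                       trait_name = trait_name)
    })
    names(tables) <- vapply(tables, function(t) paste(t$gene_a, t$gene_b, sep = "__"),
                            character(1))
    return(tables)
  }
  if (!file.exists(input)) stop("input ", input, " not found")
  sep <- if (grepl("\\.csv$", input, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(input, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "gene_a_deleted", "gene_b_deleted",
            "signal", "replicate", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("file ", input, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  raw$signal <- parse_signal(raw$signal, input)
  key <- paste(raw$gene_a, raw$gene_b, sep = "__")
  tables <- lapply(split(raw, key), function(chunk) {
    trait_table(chunk, gene_a = chunk$gene_a[1], gene_b = chunk$gene_b[1],
                trait_name = trait_name)
  })
  tables
}

#' Infer every pair of a dataset under one masking threshold
#'
#' When `eps_thr = "auto"`, the threshold is first derived from the whole
#' dataset via [epsilon_threshold()] and then applied to every pair.
#'
#' @param tables Named list of [trait_table()] objects.
#' @param alpha Significance level.
#' @param eps_thr Numeric threshold or `"auto"`.
#' @return List with `results` (list of `pair_inference`) and `eps_thr`
#'   (the threshold used).
#' @export
infer_dataset <- function(tables, alpha = 0.05, eps_thr = "auto") {
  stopifnot(length(tables) > 0L)
  if (identical(eps_thr, "auto")) {
    deltas <- lapply(tables, function(t) {
      if (is.na(t$log_base)) t <- log_transform(t)
      estimate_deltas(cell_means(t))
    })
    eps_thr <- epsilon_threshold(deltas, alpha)
  }
  results <- lapply(tables, infer_pair, alpha = alpha, eps_thr = eps_thr)
  list(results = results, eps_thr = eps_thr)
}

#' @export
as.list.pair_inference <- function(x, ...) {
  out <- list(gene_a = x$gene_a, gene_b = x$gene_b,
              trait = x$trait_name, status = x$status)
  out$architecture <- if (is.null(x$architecture)) NULL else arch_label(x$architecture)
  out$upstream <- if (is.na(x$upstream)) NULL else x$upstream
  if (!is.null(x$influences)) {
    out$influences <- as.list(unclass(x$influences$estimate))
    out$influence_se <- as.list(x$influences$se)
    out$influence_ci_lower <- as.list(x$influences$ci_lower)
    out$influence_ci_upper <- as.list(x$influences$ci_upper)
    out$fit_residual <- x$influences$residual
  }
  d <- x$diagnostics
  out$betas <- as.list(d$betas)
  out$deltas <- as.list(d$deltas)
  if (!is.null(d$masking)) {
    out$masking <- list(eps_a = d$masking$eps_a, eps_b = d$masking$eps_b,
                        eps_thr = d$masking$eps_thr, verdict = d$masking$verdict)
  }
  out
}

#' Run the full inference pipeline
#'
#' @param config List (e.g. from a YAML file) with fields `input` (dataset
#'   path or directory), `trait` (label, default `"trait"`), `alpha`
#'   (default 0.05), `eps_thr` (number or `"auto"`, default), `out_dir`
#'   and optionally `include_signal` (add signal->gene edges).
#' @param verbose Log each pair's status decision to stderr.
#' @return Invisibly, a list with `results`, `eps_thr`, `network` and
#'   `reduced`.
#' @export
run_infer <- function(config, verbose = FALSE) {
  cfg <- config
  stopifnot(!is.null(cfg$input), !is.null(cfg$out_dir))
  alpha <- cfg$alpha %||% 0.05
  trait <- cfg$trait %||% "trait"
  tables <- read_pair_tables(cfg$input, trait_name = trait)
  fit <- infer_dataset(tables, alpha = alpha, eps_thr = cfg$eps_thr %||% "auto")
  if (verbose) {
    for (r in fit$results) {
      message(sprintf("[%s/%s] %s (p_deltaI=%.3g)", r$gene_a, r$gene_b,
                      r$status, r$diagnostics$deltas$p[["deltaI"]]))
    }
    message("masking threshold: ", signif(fit$eps_thr, 4))
  }
  net <- build_network(fit$results,
                       include_signal = isTRUE(cfg$include_signal))
  reduced <- transitive_reduction(net)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(schema = schema_version, alpha = alpha,
                  eps_thr = fit$eps_thr,
                  pairs = lapply(unname(fit$results), as.list))
  jsonlite::write_json(payload, file.path(cfg$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_sif(net, file.path(cfg$out_dir, "network_full.sif"))
  write_sif(reduced, file.path(cfg$out_dir, "network_reduced.sif"))
  write_dot(reduced, file.path(cfg$out_dir, "network_reduced.dot"))
  write_graphml(reduced, file.path(cfg$out_dir, "network_reduced.graphml"))
  summary_df <- do.call(rbind, lapply(unname(fit$results), function(r) {
    data.frame(gene_a = r$gene_a, gene_b = r$gene_b, status = r$status,
               upstream = if (is.na(r$upstream)) "" else r$upstream,
               architecture = if (is.null(r$architecture)) ""
                              else arch_label(r$architecture),
               p_deltaI = r$diagnostics$deltas$p[["deltaI"]])
  }))
  utils::write.table(summary_df, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(results = fit$results, eps_thr = fit$eps_thr,
                 network = net, reduced = reduced))
}

#' Run a TPR/FPR threshold-sweep benchmark
#'
#' @param config List with fields `datasets` (named list: trait label ->
#'   dataset path/directory), `gold` (gold-standard TSV path), `thresholds`
#'   (numeric vector), `alpha`, `out_dir` and optionally `plot` (logical:
#'   also write `roc.pdf`).
#' @return Invisibly, the ROC data frame.
#' @export
run_benchmark <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$datasets), !is.null(cfg$gold), !is.null(cfg$out_dir))
  datasets <- lapply(cfg$datasets, function(path) read_pair_tables(path))
  for (nm in names(datasets)) {
    datasets[[nm]] <- lapply(datasets[[nm]], function(t) {
      t$trait_name <- nm
      t
    })
  }
  gold <- read_gold_standard(cfg$gold)
  thresholds <- cfg$thresholds %||% seq(0, 0.5, by = 0.05)
  roc <- threshold_sweep(datasets, gold, thresholds,
                         alpha = cfg$alpha %||% 0.05)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(roc, file.path(cfg$out_dir, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(cfg$plot)) {
    grDevices::pdf(file.path(cfg$out_dir, "roc.pdf"), width = 5, height = 5)
    on.exit(grDevices::dev.off())
    traits <- unique(roc$trait)
    cols <- stats::setNames(seq_along(traits), traits)
    plot(NA, xlim = c(0, max(roc$fpr, 0.1)), ylim = c(0, 1),
         xlab = "FPR", ylab = "TPR", main = "Threshold sweep ROC")
    for (tr in traits) {
      sub <- roc[roc$trait == tr, ]
      sub <- sub[order(sub$fpr, sub$tpr), ]
      graphics::lines(sub$fpr, sub$tpr, col = cols[tr], type = "b", pch = 16)
    }
    graphics::legend("bottomright", legend = traits, col = cols, lty = 1, pch = 16)
  }
  invisible(roc)
}

#' Simulate a cascade dataset to disk
#'
#' @param config List with fields `genes`, `signs`, `influences`
#'   (`theta0`, `sigmaS`, `sigma`, `alpha`), `noise_sd`, `n_replicates`,
#'   `seed`, `out_dir` (see [simulate_cascade()]); typically parsed from a
#'   YAML spec.
#' @return Invisibly, the list returned by [simulate_cascade()].
#' @export
run_simulate <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$genes), !is.null(cfg$out_dir))
  n_rep <- cfg$n_replicates %||% default_replicates
  if (is.list(n_rep)) n_rep <- unlist(n_rep)
  sim <- simulate_cascade(
    genes = cfg$genes,
    signs = cfg$signs %||% rep(1, length(cfg$genes)),
    influences = cfg$influences,
    noise_sd = cfg$noise_sd %||% 0.1,
    n_replicates = n_rep,
    seed = cfg$seed %||% 1L)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$tables)) {
    write_trait_table(sim$tables[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")))
  }
  write_gold_standard(sim$gold, file.path(cfg$out_dir, "gold.tsv"))
  invisible(sim)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
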