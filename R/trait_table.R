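#' Factorial conditions of a two-gene deletion experiment
#'
#' Each gene pair is assayed under all combinations of deleting gene A,
#' deleting gene B, and switching the external signal ON or OFF: eight
#' conditions in total.
#'
#' @return A data frame with 8 rows and integer columns `gene_a_deleted`,
#'   `gene_b_deleted`, `signal` (1 = signal ON).
#' @export
#' @examples
#' conditions()
conditions <- function() {
  out <- expand.grid(gene_a_deleted = 0:1, gene_b_deleted = 0:1, signal = 0:1,
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$signal, out$gene_a_deleted, out$gene_b_deleted), , drop = FALSE][
    , c("gene_a_deleted", "gene_b_deleted", "signal")] -> out
  rownames(out) <- NULL
  out
}

condition_key <- function(a_del, b_del, signal) {
  paste(a_del, b_del, signal, sep = ":")
}

#' Construct a trait table
#'
#' A trait table holds replicate measurements of one quantitative trait
#' (e.g. fitness or mean reporter expression) for one gene pair over the
#' 8 factorial deletion-by-signal conditions.
#'
#' @param data Data frame with columns `gene_a_deleted`, `gene_b_deleted`,
#'   `signal` (each 0/1), `replicate` (integer >= 1) and `value`.
#' @param gene_a,gene_b Gene identifiers.
#' @param trait_name Label for the measured trait.
#' @param log_base `NA` for raw (strictly positive) values, or `2` if the
#'   values are already log2-transformed.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(data, gene_a = "geneA", gene_b = "geneB",
                        trait_name = "trait", log_base = NA) {
  required <- c("gene_a_deleted", "gene_b_deleted", "signal", "replicate", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[required]
  for (col in c("gene_a_deleted", "gene_b_deleted", "signal")) {
    if (!all(data[[col]] %in% c(0, 1))) {
      stop("column '", col, "' must be 0/1")
    }
    data[[col]] <- as.integer(data[[col]])
  }
  data$replicate <- as.integer(data$replicate)
  data$value <- as.numeric(data$value)
  if (anyNA(data$value)) stop("non-numeric trait value(s)")
  if (is.na(log_base) && any(data$value <= 0)) {
    bad <- which(data$value <= 0)[1L]
    stop("raw trait values must be strictly positive (row ", bad,
         " has value ", data$value[bad], "); log-trait analysis requires ",
         "zero-trait genotypes to be floored upstream")
  }
  obj <- structure(
    list(gene_a = gene_a, gene_b = gene_b, trait_name = trait_name,
         log_base = log_base, data = data),
    class = "trait_table")
  check_complete(obj)
  obj
}

check_complete <- function(table) {
  have <- unique(condition_key(table$data$gene_a_deleted,
                               table$data$gene_b_deleted,
                               table$data$signal))
  cond <- conditions()
  want <- condition_key(cond$gene_a_deleted, cond$gene_b_deleted, cond$signal)
  absent <- setdiff(want, have)
  if (length(absent) > 0L) {
    stop("trait table for pair ", table$gene_a, "/", table$gene_b,
         " is missing condition(s) [gene_a_deleted:gene_b_deleted:signal]: ",
         paste(absent, collapse = ", "))
  }
  invisible(table)
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table:", x$trait_name, "for pair", x$gene_a, "/", x$gene_b, "\n")
  cat("  scale:", if (is.na(x$log_base)) "raw" else paste0("log", x$log_base), "\n")
  n <- stats::aggregate(value ~ gene_a_deleted + gene_b_deleted + signal,
                        data = x$data, FUN = length)
  cat("  replicates per condition:", paste(range(n$value), collapse = "-"), "\n")
  invisible(x)
}

parse_signal <- function(x, path = "<data>") {
  raw <- trimws(toupper(as.character(x)))
  out <- rep(NA_integer_, length(raw))
  out[raw %in% c("0", "OFF")] <- 0L
  out[raw %in% c("1", "ON")] <- 1L
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("cannot parse signal value '", raw[bad], "' in ", path,
         " (data row ", bad, "); expected 0/1/ON/OFF")
  }
  out
}

#' Read a trait table from a delimited file
#'
#' The file must have a header with columns `gene_a_deleted`,
#' `gene_b_deleted`, `signal`, `replicate`, `value`. Deletion flags are 0/1;
#' the signal column accepts 0/1/ON/OFF (case-insensitive). Tab or comma
#' separation is chosen from the file extension (`.csv` means comma).
#'
#' @param path File path.
#' @param gene_a,gene_b Gene identifiers for the pair measured in the file.
#' @param trait_name Trait label.
#' @param log_base `NA` for raw values (default) or 2 for pre-transformed.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, gene_a = "geneA", gene_b = "geneB",
                             trait_name = "trait", log_base = NA) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  required <- c("gene_a_deleted", "gene_b_deleted", "signal", "replicate", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("gene_a_deleted", "gene_b_deleted", "replicate", "value")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1L]
      stop("malformed value '", raw[[col]][bad], "' in column '", col,
           "' of ", path, " (line ", bad + 1L, ")")
    }
    raw[[col]] <- parsed
  }
  raw$signal <- parse_signal(raw$signal, path)
  trait_table(raw, gene_a = gene_a, gene_b = gene_b,
              trait_name = trait_name, log_base = log_base)
}

#' Write a trait table to a delimited file
#'
#' Writes the same five-column format accepted by [read_trait_table()].
#' Values are serialized with 17 significant digits so a write/read
#' round trip is bit-exact.
#'
#' @param table A [trait_table()].
#' @param path Output path (`.csv` for comma separation, else tab).
#' @return Invisibly, `path`.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- table$data
  out$value <- sprintf("%.17g", out$value)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform a trait table
#'
#' Replaces every trait value by its base-2 logarithm. All downstream
#' regression and inference operate on log traits, where multiplicative
#' neutrality of fitness effects becomes additivity.
#'
#' @param table A raw-scale [trait_table()].
#' @param base Logarithm base; only 2 is supported.
#' @return The transformed `trait_table` with `log_base = 2`.
#' @export
log_transform <- function(table, base = 2) {
  stopifnot(inherits(table, "trait_table"))
  if (base != 2) stop("only log base 2 is supported")
  if (!is.na(table$log_base)) {
    stop("trait table is already log", table$log_base, "-transformed")
  }
  table$data$value <- log2(table$data$value)
  table$log_base <- 2
  table
}

#' Per-condition means, standard errors and replicate counts
#'
#' Summarizes a log-transformed trait table into the eight cell means that
#' feed the saturated regression, with the standard error of each mean and
#' the replicate count.
#'
#' @param table A log2-transformed [trait_table()].
#' @return An object of class `cell_means`: a data frame with one row per
#'   condition and columns `gene_a_deleted`, `gene_b_deleted`, `signal`,
#'   `mean`, `se`, `n`.
#' @export
cell_means <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  if (is.na(table$log_base)) {
    stop("cell_means expects a log-transformed trait table; call log_transform() first")
  }
  d <- table$data
  key <- condition_key(d$gene_a_deleted, d$gene_b_deleted, d$signal)
  cond <- conditions()
  cond$mean <- NA_real_
  cond$se <- NA_real_
  cond$n <- NA_integer_
  for (i in seq_len(nrow(cond))) {
    k <- condition_key(cond$gene_a_deleted[i], cond$gene_b_deleted[i], cond$signal[i])
    v <- d$value[key == k]
    cond$n[i] <- length(v)
    cond$mean[i] <- mean(v)
    cond$se[i] <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  }
  structure(cond,
            gene_a = table$gene_a, gene_b = table$gene_b,
            trait_name = table$trait_name,
            class = c("cell_means", "data.frame"))
}

#' Swap the gene labels of a cell-means summary
#'
#' Relabels gene A as gene B and vice versa (the deletion-flag columns are
#' exchanged). Used to re-orient a pair so that the upstream gene plays the
#' role of X in the pathway model.
#'
#' @param cm A [cell_means()] object.
#' @return The relabeled `cell_means`.
#' @export
swap_genes <- function(cm) {
  stopifnot(inherits(cm, "cell_means"))
  tmp <- cm$gene_a_deleted
  cm$gene_a_deleted <- cm$gene_b_deleted
  cm$gene_b_deleted <- tmp
  ga <- attr(cm, "gene_a")
  attr(cm, "gene_a") <- attr(cm, "gene_b")
  attr(cm, "gene_b") <- ga
  cm[order(cm$signal, cm$gene_a_deleted, cm$gene_b_deleted), , drop = FALSE]
}

# Look up one cell; a/b are deletion flags, s the signal state.
cm_cell <- function(cm, a, b, s) {
  i <- which(cm$gene_a_deleted == a & cm$gene_b_deleted == b & cm$signal == s)
  stopifnot(length(i) == 1L)
  cm[i, , drop = FALSE]
}
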