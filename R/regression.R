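#' @title Saturated regression on the factorial deletion design
#' @description
#' The eight cell means of a two-gene deletion experiment are an exactly
#' identified (saturated) linear model with intercept `beta0`, signal effect
#' `betaS`, per-signal-state single-deletion effects `betaX`, `betaY`, and a
#' per-state genetic-interaction term `betaI`. On the log2 scale, `betaI = 0`
#' is multiplicative neutrality, and `betaI = -betaX` or `-betaY` is
#' epistasis (masking). All coefficients are computed as cell-mean
#' contrasts; their standard errors propagate the per-condition standard
#' errors in quadrature, with Welch-Satterthwaite degrees of freedom.
#' @name regression
NULL

beta_names <- c("beta0", "betaS", "betaX_off", "betaX_on",
                "betaY_off", "betaY_on", "betaI_off", "betaI_on")
delta_names <- c("delta0", "deltaX", "deltaY", "deltaI")

# Contrast weight vectors over condition keys "a:b:s" (a, b = deletion flags).
beta_contrasts <- function() {
  w <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  list(
    beta0     = w("0:0:0" = 1),
    betaS     = w("0:0:1" = 1, "0:0:0" = -1),
    betaX_off = w("1:0:0" = 1, "0:0:0" = -1),
    betaX_on  = w("1:0:1" = 1, "0:0:1" = -1),
    betaY_off = w("0:1:0" = 1, "0:0:0" = -1),
    betaY_on  = w("0:1:1" = 1, "0:0:1" = -1),
    betaI_off = w("1:1:0" = 1, "1:0:0" = -1, "0:1:0" = -1, "0:0:0" = 1),
    betaI_on  = w("1:1:1" = 1, "1:0:1" = -1, "0:1:1" = -1, "0:0:1" = 1)
  )
}

delta_contrasts <- function() {
  bc <- beta_contrasts()
  sub <- function(a, b) {
    keys <- union(names(a), names(b))
    out <- stats::setNames(numeric(length(keys)), keys)
    out[names(a)] <- out[names(a)] + a
    out[names(b)] <- out[names(b)] - b
    out[out != 0]
  }
  list(
    delta0 = -bc$betaS,
    deltaX = sub(bc$betaX_off, bc$betaX_on),
    deltaY = sub(bc$betaY_off, bc$betaY_on),
    deltaI = sub(bc$betaI_off, bc$betaI_on)
  )
}

# Estimate, SE, Welch-Satterthwaite df and two-sided p for one cell-mean
# contrast. With all-zero cell SEs (noise-free data) p is 0 for contrasts
# that are nonzero beyond rounding and 1 otherwise.
contrast_stat <- function(cm, w) {
  key <- condition_key(cm$gene_a_deleted, cm$gene_b_deleted, cm$signal)
  idx <- match(names(w), key)
  stopifnot(!anyNA(idx))
  mu <- cm$mean[idx]
  se <- cm$se[idx]
  n <- cm$n[idx]
  est <- sum(w * mu)
  v_terms <- w^2 * se^2
  v <- sum(v_terms)
  if (v > 0) {
    dfc <- pmax(n - 1L, 1L)
    df <- v^2 / sum(v_terms^2 / dfc)
    p <- 2 * stats::pt(-abs(est) / sqrt(v), df = df)
  } else {
    df <- 0
    tol <- 1e-8 * max(1, max(abs(cm$mean)))
    p <- if (abs(est) > tol) 0 else 1
  }
  list(estimate = est, se = sqrt(v), df = df, p = p)
}

estimate_from_contrasts <- function(cm, contrasts, class) {
  stats <- lapply(contrasts, function(w) contrast_stat(cm, w))
  structure(
    list(
      estimate = vapply(stats, `[[`, numeric(1), "estimate"),
      se = vapply(stats, `[[`, numeric(1), "se"),
      df = vapply(stats, `[[`, numeric(1), "df"),
      p = vapply(stats, `[[`, numeric(1), "p"),
      noise_free = all(cm$se == 0),
      replicated = any(cm$n > 1L),
      gene_a = attr(cm, "gene_a"), gene_b = attr(cm, "gene_b"),
      trait_name = attr(cm, "trait_name")
    ),
    class = class)
}

#' Estimate deletion-effect and interaction coefficients
#'
#' Computes the eight coefficients of the saturated regression from the cell
#' means: `beta0` (wildtype, signal OFF), `betaS` (signal effect),
#' `betaX_off/on` and `betaY_off/on` (single-deletion effects of gene A and
#' gene B per signal state) and `betaI_off/on` (interaction terms). Gene A
#' plays the role of X, gene B of Y; use [swap_genes()] to re-orient.
#'
#' @param cm A [cell_means()] summary over the 8 conditions.
#' @return An object of class `beta_estimates` with named vectors
#'   `estimate`, `se`, `df`, `p`, plus a `noise_free` flag set when every
#'   cell has zero standard error.
#' @export
estimate_betas <- function(cm) {
  stopifnot(inherits(cm, "cell_means"))
  estimate_from_contrasts(cm, beta_contrasts(), "beta_estimates")
}

#' Estimate signal-dependent (difference-trait) parameters
#'
#' The difference trait D(x, y) = T(x, y, OFF) - T(x, y, ON) eliminates all
#' signal-independent influences. Its regression parameters are differences
#' of beta coefficients between signal states: `deltaX = betaX_off -
#' betaX_on` (likewise `deltaY`, `deltaI`) and `delta0 = -betaS`. For log2
#' fitness, D is the log2 sensitivity, and `deltaI` equals the deviation of
#' double-mutant sensitivity from multiplicative neutrality,
#' log2[(S_XY S_wt)/(S_X S_Y)].
#'
#' @param x A [cell_means()] object, or a `beta_estimates` object (in which
#'   case only the point estimates are re-derived and the cell means must be
#'   supplied via `cm` for uncertainty propagation).
#' @param cm Cell means; required when `x` is a `beta_estimates`.
#' @return An object of class `delta_estimates` with `estimate`, `se`, `df`,
#'   `p` over `delta0`, `deltaX`, `deltaY`, `deltaI`.
#' @export
estimate_deltas <- function(x, cm = NULL) {
  if (inherits(x, "cell_means")) {
    cm <- x
  } else if (inherits(x, "beta_estimates")) {
    if (is.null(cm)) stop("supply the cell means to propagate uncertainties")
  } else {
    stop("x must be cell_means or beta_estimates")
  }
  estimate_from_contrasts(cm, delta_contrasts(), "delta_estimates")
}

#' Predicted cell means implied by a set of beta estimates
#'
#' Inverts the contrast definitions: the saturated model reproduces the
#' observed cell means exactly.
#'
#' @param b A `beta_estimates` object.
#' @return Data frame in [conditions()] order with a `mean` column.
#' @export
predicted_cell_means <- function(b) {
  stopifnot(inherits(b, "beta_estimates"))
  e <- b$estimate
  cond <- conditions()
  dA <- cond$gene_a_deleted
  dB <- cond$gene_b_deleted
  s <- cond$signal
  cond$mean <- e[["beta0"]] + s * e[["betaS"]] +
    dA * ifelse(s == 1, e[["betaX_on"]], e[["betaX_off"]]) +
    dB * ifelse(s == 1, e[["betaY_on"]], e[["betaY_off"]]) +
    dA * dB * ifelse(s == 1, e[["betaI_on"]], e[["betaI_off"]])
  cond
}

#' @export
print.beta_estimates <- function(x, ...) {
  cat("Deletion-effect estimates (", x$gene_a, " = X, ", x$gene_b, " = Y)\n", sep = "")
  print(data.frame(estimate = x$estimate, se = x$se, p = signif(x$p, 3)))
  invisible(x)
}

#' @export
print.delta_estimates <- function(x, ...) {
  cat("Signal-dependent (difference-trait) estimates (",
      x$gene_a, " = X, ", x$gene_b, " = Y)\n", sep = "")
  print(data.frame(estimate = x$estimate, se = x$se, p = signif(x$p, 3)))
  invisible(x)
}

#' Serialize estimates to a plain list (for JSON output)
#'
#' @param x A `beta_estimates` or `delta_estimates` object.
#' @param ... Unused.
#' @return A named list with `<name>`, `se_<name>` and `p_<name>` entries.
#' @export
as.list.beta_estimates <- function(x, ...) {
  out <- c(as.list(x$estimate),
           stats::setNames(as.list(x$se), paste0("se_", names(x$se))),
           stats::setNames(as.list(x$p), paste0("p_", names(x$p))))
  out$noise_free <- x$noise_free
  out
}

#' @rdname as.list.beta_estimates
#' @export
as.list.delta_estimates <- function(x, ...) as.list.beta_estimates(x, ...)
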