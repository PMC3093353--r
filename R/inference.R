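#' Test for a signal-dependent genetic interaction
#'
#' Step 1 of the inference algorithm: the pair is only analyzed further if
#' the signal-dependent interaction term deltaI differs significantly
#' from 0.
#'
#' @param d A `delta_estimates` object.
#' @param alpha Significance level (default 0.05).
#' @return Logical. With unreplicated data the test is undefined and FALSE
#'   is returned with a warning.
#' @export
detect_interaction <- function(d, alpha = 0.05) {
  stopifnot(inherits(d, "delta_estimates"))
  if (!isTRUE(d$replicated)) {
    warning("no replication: significance of deltaI is undefined; ",
            "treating the pair as having no detectable interaction")
    return(FALSE)
  }
  d$p[["deltaI"]] < alpha
}

#' Data-derived masking threshold
#'
#' The threshold used to declare that a deletion effect is negated by the
#' interaction term is taken from the precision of the data itself: the
#' mean, over all pairs with a significant interaction term, of the
#' relative standard error se(deltaI)/|deltaI|.
#'
#' @param all_pairs List of `delta_estimates`, one per gene pair.
#' @param alpha Significance level for deltaI.
#' @return The threshold (a fraction in (0, 1) for reasonable data).
#' @export
epsilon_threshold <- function(all_pairs, alpha = 0.05) {
  if (inherits(all_pairs, "delta_estimates")) all_pairs <- list(all_pairs)
  rel <- vapply(all_pairs, function(d) {
    if (d$replicated && d$p[["deltaI"]] < alpha) {
      d$se[["deltaI"]] / abs(d$estimate[["deltaI"]])
    } else NA_real_
  }, numeric(1))
  rel <- rel[!is.na(rel)]
  if (length(rel) == 0L) {
    stop("no significant interaction terms: the masking threshold cannot be ",
         "derived from the data; supply eps_thr explicitly")
  }
  mean(rel)
}

#' Infer gene order from signal-dependent masking
#'
#' Step 2: the model predicts that the signal-dependent effect of deleting
#' the downstream gene is exactly negated by the interaction term
#' (deltaY = -deltaI) for every architecture, so the masked gene is
#' downstream irrespective of the pathway wiring. Masking of gene i is
#' scored by the relative difference eps_i = |delta_i + deltaI| /
#' max(|delta_i|, |deltaI|), compared to the threshold `eps_thr`.
#'
#' @param d A `delta_estimates` object.
#' @param eps_thr Masking threshold (see [epsilon_threshold()]).
#' @return Object of class `masking_result`: list with `eps_a`, `eps_b` and
#'   `verdict` in `a_downstream`, `b_downstream`, `coequivalent` (both
#'   masked: no feedforward loop), `none` (interaction without masking).
#' @export
infer_order <- function(d, eps_thr) {
  stopifnot(inherits(d, "delta_estimates"), is.numeric(eps_thr), eps_thr >= 0)
  eps_one <- function(di) {
    dI <- d$estimate[["deltaI"]]
    den <- max(abs(di), abs(dI))
    if (den == 0) {
      warning("delta_i and deltaI are both zero: masking score undefined, using 0")
      return(0)
    }
    abs(di + dI) / den
  }
  eps_a <- eps_one(d$estimate[["deltaX"]])
  eps_b <- eps_one(d$estimate[["deltaY"]])
  verdict <- if (eps_a <= eps_thr && eps_b <= eps_thr) {
    "coequivalent"
  } else if (eps_b <= eps_thr) {
    "b_downstream"
  } else if (eps_a <= eps_thr) {
    "a_downstream"
  } else {
    "none"
  }
  structure(list(eps_a = eps_a, eps_b = eps_b, verdict = verdict,
                 eps_thr = eps_thr),
            class = "masking_result")
}

#' @export
print.masking_result <- function(x, ...) {
  cat(sprintf("Masking: eps_a = %.3g, eps_b = %.3g (threshold %.3g) -> %s\n",
              x$eps_a, x$eps_b, x$eps_thr, x$verdict))
  invisible(x)
}

#' Correct deletion effects for basal, signal-independent contributions
#'
#' Step 3a: for each of betaX, betaY, betaI, the signal state with the
#' smaller absolute value is taken to carry only the basal effect of the
#' deletion. The corrected parameter is zero in that state and the
#' between-state difference in the other, so the corrected values depend
#' only on signal-specific influences. The basal values are retained: they
#' estimate (minus) alphaX, alphaY and alphaI.
#'
#' @param b A `beta_estimates` object.
#' @return List with `corrected` (named estimates over the six slots, basal
#'   slots exactly 0), `p` (p-value of each corrected nonzero value, which
#'   equals the significance of the corresponding delta parameter),
#'   `basal` (named vector of the basal beta values) and `basal_state`.
#'   Magnitude ties are broken toward OFF as basal, with a warning.
#' @export
correct_betas <- function(b) {
  stopifnot(inherits(b, "beta_estimates"))
  corrected <- stats::setNames(numeric(6),
                               c("betaX_off", "betaX_on", "betaY_off",
                                 "betaY_on", "betaI_off", "betaI_on"))
  pvals <- stats::setNames(rep(NA_real_, 6), names(corrected))
  basal <- stats::setNames(numeric(3), c("betaX", "betaY", "betaI"))
  basal_state <- stats::setNames(character(3), names(basal))
  for (par in names(basal)) {
    off <- paste0(par, "_off"); on <- paste0(par, "_on")
    v_off <- b$estimate[[off]]; v_on <- b$estimate[[on]]
    if (abs(v_off) == abs(v_on) && v_off != v_on) {
      warning("basal-state tie for ", par, " (equal magnitudes); choosing OFF")
    }
    if (abs(v_off) <= abs(v_on)) {
      basal[par] <- v_off; basal_state[par] <- "off"
      corrected[on] <- v_on - v_off
      pvals[on] <- delta_p_for(b, par)
    } else {
      basal[par] <- v_on; basal_state[par] <- "on"
      corrected[off] <- v_off - v_on
      pvals[off] <- delta_p_for(b, par)
    }
  }
  list(corrected = corrected, p = pvals, basal = basal,
       basal_state = basal_state)
}

# The corrected nonzero value of betaX/Y/I equals +/- the corresponding
# delta parameter, so its significance is the delta test. Requires the
# delta estimates attached by infer_pair, or recomputable from attr "cm".
delta_p_for <- function(b, par) {
  d <- attr(b, "deltas")
  if (is.null(d)) return(NA_real_)
  d$p[[sub("beta", "delta", par)]]
}

#' Match corrected deletion effects to a pathway architecture
#'
#' Step 3b: the architecture family (signs of S->X and X->Y) is identified
#' by the signal states in which the corrected betaX, betaY and betaI are
#' nonzero -- each family leaves a distinct triple of states ([zero_pattern()]).
#' The sign of Y->T then follows from the sign of the nonzero interaction
#' term. A corrected value counts as zero when its p-value is >= `alpha`.
#' For a coequivalent pair (no feedforward loop), order can still be
#' recovered when the single-deletion effects sit in opposite signal states
#' (a negatively regulated pathway); otherwise the two genes form a
#' cohesive unit and only the family is identified.
#'
#' @param corr Result of [correct_betas()].
#' @param order A `masking_result`.
#' @param alpha Significance level used to call corrected values zero.
#' @return List with `status` (`"inferred"`, `"cohesive_unit"` or
#'   `"inconsistent"`), `architecture` (a [pathway_architecture()] or NULL;
#'   for a cohesive unit the orientation is arbitrary) and `upstream`
#'   (`"a"`, `"b"` or NA).
#' @export
match_architecture <- function(corr, order, alpha = 0.05) {
  stopifnot(order$verdict != "none")
  observed_state <- function(par, swap = FALSE) {
    # swap = TRUE reads gene B's effects as betaX and vice versa
    p2 <- par
    if (swap && par != "betaI") p2 <- if (par == "betaX") "betaY" else "betaX"
    off <- corr$p[[paste0(p2, "_off")]]
    on <- corr$p[[paste0(p2, "_on")]]
    if (!is.na(off) && off < alpha) return("off")
    if (!is.na(on) && on < alpha) return("on")
    NA_character_
  }
  family_state <- function(arch) {
    pat <- zero_pattern(arch)
    vapply(c("betaX", "betaY", "betaI"), function(par) {
      st <- c("off", "on")[pat[paste0(par, c("_off", "_on"))]]
      stopifnot(length(st) == 1L)
      st
    }, character(1))
  }
  orientations <- switch(order$verdict,
                         b_downstream = "a",
                         a_downstream = "b",
                         coequivalent = c("a", "b"))
  families <- list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  matches <- list()
  for (up in orientations) {
    obs <- vapply(c("betaX", "betaY", "betaI"), observed_state,
                  character(1), swap = (up == "b"))
    if (anyNA(obs)) next
    for (fam in families) {
      arch <- pathway_architecture(fam[1], fam[2], +1, upstream = up)
      if (identical(unname(family_state(arch)), unname(obs))) {
        matches[[length(matches) + 1L]] <- arch
      }
    }
  }
  if (length(matches) == 0L) {
    return(list(status = "inconsistent", architecture = NULL, upstream = NA,
                note = "corrected effects match no architecture family"))
  }
  if (length(matches) == 2L && order$verdict == "coequivalent" &&
      matches[[1]]$s_to_x == matches[[2]]$s_to_x &&
      matches[[1]]$x_to_y == matches[[2]]$x_to_y) {
    # symmetric pattern: both orientations fit the same positive-regulation
    # family; the genes act as one unit
    arch <- matches[[1]]
    arch <- set_y_sign(arch, corr)
    return(list(status = "cohesive_unit", architecture = arch, upstream = NA))
  }
  if (length(matches) > 1L) {
    return(list(status = "inconsistent", architecture = NULL, upstream = NA,
                note = "multiple architecture families match (degenerate effects)"))
  }
  arch <- set_y_sign(matches[[1]], corr)
  list(status = "inferred", architecture = arch, upstream = arch$upstream)
}

# Infer the sign of Y->T from the sign of the nonzero corrected interaction
# term, via the model-predicted relation betaI = family_i_sign * sigmaY.
set_y_sign <- function(arch, corr) {
  bi <- corr$corrected[c("betaI_off", "betaI_on")]
  bi_val <- bi[which.max(abs(bi))]
  arch$y_to_t <- sign(bi_val) * family_i_sign(arch)
  if (arch$y_to_t == 0) arch$y_to_t <- 1
  arch
}

#' Run the full step-wise inference on one gene pair
#'
#' Chains the pipeline: log2 transform, cell means, beta/delta estimation,
#' interaction detection (Step 1), order by masking (Step 2), basal
#' correction and architecture matching (Step 3), and influence
#' quantification with confidence intervals (Step 4).
#'
#' @param table A [trait_table()] (raw or already log2-transformed).
#' @param alpha Significance level for all tests.
#' @param eps_thr Masking threshold; if NULL it is derived from this pair's
#'   own interaction precision via [epsilon_threshold()] (for joint
#'   analyses, derive one threshold from all pairs and pass it here).
#' @return Object of class `pair_inference`: gene ids, `status` (one of
#'   `no_interaction`, `non_epistatic`, `cohesive_unit`, `inferred`,
#'   `inconsistent`), the matched `architecture`, `upstream` gene id,
#'   `influences` (an `influence_fit`, for inferred/cohesive pairs) and
#'   `diagnostics` (betas, deltas, masking scores).
#' @export
infer_pair <- function(table, alpha = 0.05, eps_thr = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (is.na(table$log_base)) table <- log_transform(table)
  cm <- cell_means(table)
  betas <- estimate_betas(cm)
  deltas <- estimate_deltas(cm)
  attr(betas, "deltas") <- deltas
  diag0 <- list(betas = betas, deltas = deltas, cell_means = cm)
  result <- function(status, architecture = NULL, upstream = NA,
                     influences = NULL, masking = NULL, corrected = NULL) {
    structure(list(gene_a = table$gene_a, gene_b = table$gene_b,
                   trait_name = table$trait_name, status = status,
                   architecture = architecture, upstream = upstream,
                   influences = influences,
                   diagnostics = c(diag0, list(masking = masking,
                                               corrected = corrected))),
              class = "pair_inference")
  }

  if (!detect_interaction(deltas, alpha)) return(result("no_interaction"))

  sig_gene <- function(par) {
    any(betas$p[paste0(par, c("_off", "_on"))] < alpha)
  }
  if (!sig_gene("betaX") || !sig_gene("betaY")) {
    return(result("non_epistatic"))
  }

  if (is.null(eps_thr)) eps_thr <- epsilon_threshold(list(deltas), alpha)
  masking <- infer_order(deltas, eps_thr)
  if (masking$verdict == "none") return(result("non_epistatic", masking = masking))

  corr <- correct_betas(betas)
  matched <- match_architecture(corr, masking, alpha)
  if (matched$status == "inconsistent") {
    return(result("inconsistent", masking = masking, corrected = corr))
  }

  arch <- matched$architecture
  infl <- solve_influences(arch, cm)
  upstream_id <- if (matched$status == "inferred") {
    if (arch$upstream == "a") table$gene_a else table$gene_b
  } else NA
  result(matched$status, architecture = arch, upstream = upstream_id,
         influences = infl, masking = masking, corrected = corr)
}

#' @export
print.pair_inference <- function(x, ...) {
  cat("Pair", x$gene_a, "/", x$gene_b, "(", x$trait_name, "):", x$status, "\n")
  if (!is.null(x$architecture)) {
    cat("  architecture:", arch_label(x$architecture))
    if (!is.na(x$upstream)) cat(", upstream gene:", x$upstream)
    cat("\n")
  }
  if (!is.null(x$influences)) {
    cat("  influences:",
        paste(sprintf("%s=%.3g", influence_names,
                      unclass(x$influences$estimate)), collapse = ", "), "\n")
  }
  invisible(x)
}
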