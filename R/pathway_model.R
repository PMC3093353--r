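#' Define a hypothetical pathway architecture
#'
#' A signal-responsive two-gene pathway S -> X -> Y -> T is described by the
#' sign of each of its three steps (activation `+1` or repression `-1`) and
#' by which observed gene plays the upstream role X. Eight sign combinations
#' times two orientations give 16 candidate architectures; a null model
#' (no interaction) completes the hypothesis space.
#'
#' @param s_to_x,x_to_y,y_to_t Step signs, `+1` (activation) or `-1`
#'   (repression).
#' @param upstream Which observed gene plays X: `"a"` or `"b"`.
#' @return An object of class `pathway_architecture`.
#' @export
#' @examples
#' pathway_architecture(+1, +1, +1)  # all-activation chain, gene A upstream
pathway_architecture <- function(s_to_x, x_to_y, y_to_t, upstream = "a") {
  stopifnot(s_to_x %in% c(-1, 1), x_to_y %in% c(-1, 1), y_to_t %in% c(-1, 1),
            upstream %in% c("a", "b"))
  structure(list(s_to_x = s_to_x, x_to_y = x_to_y, y_to_t = y_to_t,
                 upstream = upstream),
            class = "pathway_architecture")
}

#' Enumerate candidate pathway architectures
#'
#' @param orientations Orientations to enumerate (`"a"`, `"b"` or both).
#' @return List of [pathway_architecture()] objects: 8 per orientation.
#' @export
architectures <- function(orientations = c("a", "b")) {
  out <- list()
  for (o in orientations) {
    for (sx in c(1, -1)) for (xy in c(1, -1)) for (yt in c(1, -1)) {
      out[[length(out) + 1L]] <- pathway_architecture(sx, xy, yt, upstream = o)
    }
  }
  out
}

#' Compact string label for an architecture
#'
#' Activation is written `+`, repression `-`, e.g. `S+X+Y+T` for the
#' all-activation chain.
#'
#' @param arch A [pathway_architecture()].
#' @return Character scalar.
#' @export
arch_label <- function(arch) {
  sgn <- function(s) if (s > 0) "+" else "-"
  paste0("S", sgn(arch$s_to_x), "X", sgn(arch$x_to_y), "Y", sgn(arch$y_to_t), "T")
}

#' @export
print.pathway_architecture <- function(x, ...) {
  cat("Pathway architecture", arch_label(x), "(upstream gene:", x$upstream, ")\n")
  invisible(x)
}

arch_equal <- function(a, b) {
  a$s_to_x == b$s_to_x && a$x_to_y == b$x_to_y && a$y_to_t == b$y_to_t &&
    a$upstream == b$upstream
}

#' Construct a set of influence parameters
#'
#' The forward model distinguishes signal-specific influences -- `sigmaS`
#' (signal effect bypassing both genes), `sigmaX` (feedforward effect of the
#' upstream gene bypassing the downstream gene) and `sigmaY` (effect routed
#' through the downstream gene) -- from basal, signal-independent influences
#' `alphaX`, `alphaY` and their interaction `alphaI`. `theta0` is the
#' baseline trait (log2 units).
#'
#' @param theta0,sigmaS,sigmaX,sigmaY,alphaX,alphaY,alphaI Real-valued
#'   influences in log2 trait units.
#' @return Object of class `influence_set` (a named numeric vector).
#' @export
influence_set <- function(theta0 = 0, sigmaS = 0, sigmaX = 0, sigmaY = 0,
                          alphaX = 0, alphaY = 0, alphaI = 0) {
  structure(c(theta0 = theta0, sigmaS = sigmaS, sigmaX = sigmaX,
              sigmaY = sigmaY, alphaX = alphaX, alphaY = alphaY,
              alphaI = alphaI),
            class = "influence_set")
}

influence_names <- c("theta0", "sigmaS", "sigmaX", "sigmaY",
                     "alphaX", "alphaY", "alphaI")

#' Signal-specific gene activities under a pathway architecture
#'
#' The Boolean propagation rules: a gene's signal-specific activity is
#' present only when the gene is not deleted and not switched off by the
#' factor directly upstream. The upstream gene X responds to the signal, the
#' downstream gene Y responds to the activity of X.
#'
#' @param arch A [pathway_architecture()].
#' @param x_present,y_present Logical; FALSE means the gene is deleted.
#' @param s Logical signal state.
#' @return Named logical vector `c(x_S, y_S)`.
#' @export
signal_activities <- function(arch, x_present, y_present, s) {
  x_in <- if (arch$s_to_x > 0) s else !s
  x_S <- x_present & x_in
  y_in <- if (arch$x_to_y > 0) x_S else !x_S
  y_S <- y_present & y_in
  c(x_S = x_S, y_S = y_S)
}

#' Forward-predict the theoretical trait value
#'
#' Evaluates theta = theta0 + s sigmaS + x_S sigmaX + y_S sigmaY
#' + x alphaX + y alphaY + x y alphaI, where x, y are gene-presence
#' indicators and x_S, y_S the Boolean activities from
#' [signal_activities()].
#'
#' @param arch A [pathway_architecture()].
#' @param infl An [influence_set()].
#' @param x_present,y_present Gene presence (FALSE = deleted).
#' @param s Logical signal state.
#' @return Theoretical log2 trait value.
#' @export
forward_trait <- function(arch, infl, x_present, y_present, s) {
  act <- signal_activities(arch, x_present, y_present, s)
  infl[["theta0"]] + s * infl[["sigmaS"]] +
    act[["x_S"]] * infl[["sigmaX"]] + act[["y_S"]] * infl[["sigmaY"]] +
    x_present * infl[["alphaX"]] + y_present * infl[["alphaY"]] +
    x_present * y_present * infl[["alphaI"]]
}

#' Noise-free cell means predicted by the forward model
#'
#' Evaluates [forward_trait()] over all 8 factorial conditions. The
#' orientation of `arch` decides whether gene A or gene B plays X.
#'
#' @inheritParams forward_trait
#' @param gene_a,gene_b,trait_name Labels carried on the result.
#' @return A [cell_means()] object with `se = 0`, `n = 1`.
#' @export
predicted_cell_means_model <- function(arch, infl, gene_a = "geneA",
                                       gene_b = "geneB", trait_name = "theta") {
  cond <- conditions()
  cond$mean <- NA_real_
  for (i in seq_len(nrow(cond))) {
    del_x <- if (arch$upstream == "a") cond$gene_a_deleted[i] else cond$gene_b_deleted[i]
    del_y <- if (arch$upstream == "a") cond$gene_b_deleted[i] else cond$gene_a_deleted[i]
    cond$mean[i] <- forward_trait(arch, infl,
                                  x_present = del_x == 0,
                                  y_present = del_y == 0,
                                  s = cond$signal[i] == 1)
  }
  cond$se <- 0
  cond$n <- 1L
  structure(cond, gene_a = gene_a, gene_b = gene_b, trait_name = trait_name,
            class = c("cell_means", "data.frame"))
}

#' Model-predicted regression parameters
#'
#' Forward-evaluates the model on all 8 conditions and applies the
#' regression contrasts. This single routine regenerates the predicted
#' beta/delta parameter tables for every architecture; per-architecture
#' algebra is never hand-coded.
#'
#' @param arch A [pathway_architecture()] (orientation is ignored: X is
#'   taken as the upstream gene).
#' @param infl An [influence_set()].
#' @return A `beta_estimates` object (noise-free).
#' @export
predicted_betas <- function(arch, infl) {
  arch$upstream <- "a"
  estimate_betas(predicted_cell_means_model(arch, infl))
}

#' @rdname predicted_betas
#' @export
predicted_deltas <- function(arch, infl) {
  arch$upstream <- "a"
  estimate_deltas(predicted_cell_means_model(arch, infl))
}

# Draw generic signal-specific influences for a sign family; sign of sigmaY
# follows y_to_t. Magnitudes are kept away from 0 and from each other so
# that no beta vanishes by coincidence.
generic_influences <- function(arch, rng = stats::runif) {
  influence_set(
    theta0 = 10,
    sigmaS = sample(c(-1, 1), 1) * rng(1, 0.5, 1.5),
    sigmaX = sample(c(-1, 1), 1) * rng(1, 2.5, 3.5),
    sigmaY = arch$y_to_t * rng(1, 1.0, 1.5)
  )
}

#' Draw a random but generic influence set
#'
#' Draws influences consuming the current RNG stream, with magnitudes on
#' the scale of a log2 fitness analysis: `sigmaS` in +/-\[0.5, 1.5\],
#' `sigmaX` (feedforward) in +/-\[2.5, 3.5\], `sigmaY` in \[1, 1.5\] signed
#' by the Y->T step, and basal effects in +/-\[0, 0.2\]. The ranges keep
#' every generically nonzero deletion effect bounded away from zero and
#' keep basal effects smaller than the combined basal-plus-signal effect --
#' the validity domain of the basal-state correction, which holds for genes
#' whose primary function is signal-responsive.
#'
#' @param arch A [pathway_architecture()] (fixes the sign of `sigmaY`).
#' @param basal Draw nonzero basal influences (set FALSE for the classical
#'   no-basal-function setting).
#' @return An [influence_set()].
#' @export
random_influences <- function(arch, basal = TRUE) {
  infl <- generic_influences(arch)
  if (basal) {
    infl[["alphaX"]] <- stats::runif(1, -0.2, 0.2)
    infl[["alphaY"]] <- stats::runif(1, -0.2, 0.2)
    infl[["alphaI"]] <- stats::runif(1, -0.2, 0.2)
  }
  infl
}

#' Zero pattern of the predicted deletion effects
#'
#' For generic signal-specific influences and no basal effects, each
#' architecture family (sign of S->X and X->Y) leaves a characteristic
#' subset of the six deletion-effect slots identically zero. The pattern is
#' computed by evaluating [predicted_betas()] on two independent random
#' influence draws (which must agree), not transcribed from a table.
#'
#' @param arch A [pathway_architecture()]; only `s_to_x` and `x_to_y`
#'   matter.
#' @param seed Seed for the internal draws.
#' @return Named logical vector over `betaX_off`, `betaX_on`, `betaY_off`,
#'   `betaY_on`, `betaI_off`, `betaI_on`; TRUE marks a generically nonzero
#'   slot.
#' @export
zero_pattern <- function(arch, seed = 1L) {
  slots <- c("betaX_off", "betaX_on", "betaY_off", "betaY_on",
             "betaI_off", "betaI_on")
  pats <- with_seed(seed, lapply(1:2, function(i) {
    infl <- generic_influences(arch)
    b <- predicted_betas(arch, infl)
    abs(b$estimate[slots]) > 1e-9
  }))
  if (!identical(pats[[1]], pats[[2]])) {
    stop("zero pattern not stable across influence draws for ", arch_label(arch))
  }
  pats[[1]]
}

# Sign relating the nonzero interaction slot to sigmaY: predicted
# betaI = family_i_sign(arch) * sigmaY in the slot where it is nonzero.
family_i_sign <- function(arch) {
  probe <- influence_set(sigmaS = 0.7, sigmaX = 1.3, sigmaY = 1)
  b <- predicted_betas(arch, probe)
  bi <- b$estimate[c("betaI_off", "betaI_on")]
  sign(bi[which.max(abs(bi))])
}

# Design matrix of the forward model over the 8 conditions (columns follow
# influence_names). Rows follow conditions() order with a, b as deletion
# flags of X and Y respectively.
model_design <- function(arch) {
  cond <- conditions()
  M <- matrix(0, nrow = nrow(cond), ncol = length(influence_names),
              dimnames = list(NULL, influence_names))
  for (i in seq_len(nrow(cond))) {
    x <- cond$gene_a_deleted[i] == 0
    y <- cond$gene_b_deleted[i] == 0
    s <- cond$signal[i] == 1
    act <- signal_activities(arch, x, y, s)
    M[i, ] <- c(1, s, act[["x_S"]], act[["y_S"]], x, y, x && y)
  }
  M
}

#' Solve for influence parameters from measured cell means
#'
#' Inverts the forward model for a given architecture: the 8 cell means are
#' an over-determined linear system (7 unknowns) in the influences, solved
#' by least squares. On model-consistent data the solution is exact and the
#' residual is zero; otherwise the residual norm is reported as a model-fit
#' diagnostic. 95% confidence intervals propagate the per-condition
#' standard errors through the solution operator, with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param arch A [pathway_architecture()]; its orientation says which
#'   observed gene is X.
#' @param cm [cell_means()] in the observed gene-A/gene-B labeling.
#' @param conf Confidence level for the intervals.
#' @return List with `estimate` (an [influence_set()]), `se`, `df`,
#'   `ci_lower`, `ci_upper` and `residual`.
#' @export
solve_influences <- function(arch, cm, conf = 0.95) {
  stopifnot(inherits(arch, "pathway_architecture"), inherits(cm, "cell_means"))
  if (arch$upstream == "b") cm <- swap_genes(cm)
  ord <- order(cm$signal, cm$gene_a_deleted, cm$gene_b_deleted)
  cm <- cm[ord, , drop = FALSE]
  M <- model_design(arch)
  # solution operator A: estimates are linear in the cell means
  A <- solve(crossprod(M), t(M))
  est <- drop(A %*% cm$mean)
  names(est) <- influence_names
  resid <- sqrt(sum((drop(M %*% est) - cm$mean)^2))
  v_terms <- A^2 * matrix(cm$se^2, nrow = nrow(A), ncol = ncol(A), byrow = TRUE)
  v <- rowSums(v_terms)
  dfc <- pmax(cm$n - 1L, 1L)
  df <- ifelse(v > 0,
               v^2 / rowSums(sweep(v_terms^2, 2, dfc, "/")),
               0)
  se <- sqrt(v)
  q <- ifelse(df > 0, stats::qt(1 - (1 - conf) / 2, df = df), 0)
  out <- list(
    estimate = do.call(influence_set, as.list(est)),
    se = stats::setNames(se, influence_names),
    df = stats::setNames(df, influence_names),
    ci_lower = stats::setNames(est - q * se, influence_names),
    ci_upper = stats::setNames(est + q * se, influence_names),
    residual = resid
  )
  class(out) <- "influence_fit"
  out
}

#' @export
print.influence_fit <- function(x, ...) {
  cat("Influence parameters (95% CI); fit residual:", signif(x$residual, 3), "\n")
  print(data.frame(estimate = unclass(x$estimate), se = x$se,
                   lower = x$ci_lower, upper = x$ci_upper))
  invisible(x)
}

#' Check recovery of the classical Boolean epistasis rules
#'
#' With all basal influences zero, the model reduces to the classical
#' Boolean treatment of epistasis, and three rules should emerge from
#' enumeration: (1) each single deletion affects the trait in exactly one
#' signal state; (2) unique masking of the upstream gene (betaI = -betaX,
#' distinct from -betaY) occurs only when X represses Y and the feedforward
#' influence sigmaX is zero; (3) unique masking of the downstream gene
#' (betaI = -betaY, distinct from -betaX) occurs only when X activates Y
#' and sigmaX is nonzero. This routine verifies all three over every
#' architecture by direct evaluation of the forward model.
#'
#' @param seed Seed for the generic influence draws.
#' @param n_draws Random influence draws per architecture and sigmaX case.
#' @return List with logical `rule1`, `rule2`, `rule3`, overall `pass`, and
#'   the per-architecture evaluation table `detail`.
#' @export
avery_wasserman_check <- function(seed = 1L, n_draws = 5L) {
  tol <- 1e-9
  rows <- list()
  with_seed(seed, {
    for (arch in architectures("a")) {
      for (zero_sx in c(TRUE, FALSE)) {
        for (k in seq_len(n_draws)) {
          infl <- generic_influences(arch)
          if (zero_sx) infl[["sigmaX"]] <- 0
          b <- predicted_betas(arch, infl)$estimate
          nz <- function(p) {
            v <- b[paste0(p, c("_off", "_on"))]
            v[abs(v) > tol]
          }
          bx <- nz("betaX"); by <- nz("betaY"); bi <- nz("betaI")
          one_state <- length(bx) == 1L && length(by) == 1L
          masks <- function(target) {
            length(bi) == 1L && length(target) == 1L &&
              abs(unname(bi) + unname(target)) < tol
          }
          mask_up <- masks(bx) && !masks(by)
          mask_down <- masks(by) && !masks(bx)
          rows[[length(rows) + 1L]] <- data.frame(
            arch = arch_label(arch), sigmaX_zero = zero_sx,
            one_state = one_state, mask_up = mask_up, mask_down = mask_down,
            represses = arch$x_to_y < 0)
        }
      }
    }
  })
  detail <- do.call(rbind, rows)
  rule1 <- all(detail$one_state)
  rule2 <- all(detail$mask_up == (detail$represses & detail$sigmaX_zero))
  rule3 <- all(detail$mask_down == (!detail$represses & !detail$sigmaX_zero))
  list(rule1 = rule1, rule2 = rule2, rule3 = rule3,
       pass = rule1 && rule2 && rule3, detail = detail)
}

# Run code with a temporary RNG state; restores (or removes) .Random.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
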