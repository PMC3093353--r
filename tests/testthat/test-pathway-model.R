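test_that("Boolean activity propagation follows the wiring", {
  all_act <- pathway_architecture(1, 1, 1)
  expect_equal(unname(signal_activities(all_act, TRUE, TRUE, TRUE)), c(TRUE, TRUE))
  expect_equal(unname(signal_activities(all_act, FALSE, TRUE, TRUE)), c(FALSE, FALSE))
  # signal represses X: wildtype with signal ON has no X activity
  rep_sx <- pathway_architecture(-1, 1, 1)
  expect_false(signal_activities(rep_sx, TRUE, TRUE, TRUE)[["x_S"]])
  expect_true(signal_activities(rep_sx, TRUE, TRUE, FALSE)[["x_S"]])
  # X represses Y: Y active exactly when X is off
  rep_xy <- pathway_architecture(1, -1, 1)
  expect_false(signal_activities(rep_xy, TRUE, TRUE, TRUE)[["y_S"]])
  expect_true(signal_activities(rep_xy, TRUE, TRUE, FALSE)[["y_S"]])
})

test_that("forward trait sums the contributing influences", {
  arch <- ref_arch()
  infl <- ref_influences()
  expect_equal(forward_trait(arch, infl, TRUE, TRUE, TRUE), 16.75)
  expect_equal(forward_trait(arch, infl, FALSE, FALSE, FALSE), 10)
  base_only <- influence_set(theta0 = 3.5)
  for (x in c(TRUE, FALSE)) for (y in c(TRUE, FALSE)) for (s in c(TRUE, FALSE)) {
    expect_equal(forward_trait(arch, base_only, x, y, s), 3.5)
  }
})

test_that("the architecture hypothesis space has the expected size", {
  expect_length(architectures("a"), 8L)
  expect_length(architectures(), 16L)
  labels <- vapply(architectures("a"), arch_label, character(1))
  expect_length(unique(labels), 8L)
  expect_equal(nrow(conditions()), 8L)
})

test_that("predicted parameters come from the forward model, not a table", {
  b <- predicted_betas(ref_arch(), ref_influences())
  expect_equal(b$estimate[["betaI_on"]], 3)  # sigmaY + alphaI
  zero <- predicted_betas(ref_arch(), influence_set(theta0 = 2))
  expect_equal(zero$estimate[["beta0"]], 2)
  expect_equal(unname(zero$estimate[-1]), rep(0, 7))
  # X represses Y, no basal effects: interaction only in ON, equal to -sigmaY
  rep_xy <- pathway_architecture(1, -1, 1)
  infl <- influence_set(sigmaS = 0.8, sigmaX = 1.7, sigmaY = 2.2)
  b2 <- predicted_betas(rep_xy, infl)
  expect_equal(b2$estimate[["betaI_on"]], -2.2)
  expect_equal(b2$estimate[["betaI_off"]], 0)
})

test_that("betas are identical for architectures differing only in Y->T", {
  for (sx in c(1, -1)) for (xy in c(1, -1)) {
    infl <- influence_set(theta0 = 1, sigmaS = 0.6, sigmaX = 1.4, sigmaY = -0.9,
                          alphaX = 0.2, alphaY = -0.1, alphaI = 0.05)
    b_act <- predicted_betas(pathway_architecture(sx, xy, 1), infl)
    b_rep <- predicted_betas(pathway_architecture(sx, xy, -1), infl)
    expect_identical(b_act$estimate, b_rep$estimate)
  }
})

test_that("each sign family has a distinct zero pattern", {
  pat_pp <- zero_pattern(pathway_architecture(1, 1, 1))
  expect_equal(names(pat_pp)[pat_pp], c("betaX_on", "betaY_on", "betaI_on"))
  pat_mp <- zero_pattern(pathway_architecture(-1, 1, 1))
  expect_equal(names(pat_mp)[pat_mp], c("betaX_off", "betaY_off", "betaI_off"))
  pats <- lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)), function(f) {
    zero_pattern(pathway_architecture(f[1], f[2], 1))
  })
  expect_length(unique(pats), 4L)
  # exactly one nonzero state per parameter family
  for (p in pats) {
    expect_equal(sum(p[c("betaX_off", "betaX_on")]), 1L)
    expect_equal(sum(p[c("betaY_off", "betaY_on")]), 1L)
    expect_equal(sum(p[c("betaI_off", "betaI_on")]), 1L)
  }
})

test_that("one beta of each pair is defined entirely by basal effects", {
  # varying the sigmas must leave the basal slot of each pair unchanged
  set.seed(31)
  for (arch in all_architectures()) {
    base <- influence_set(theta0 = 5, alphaX = 0.3, alphaY = -0.2, alphaI = 0.1)
    b0 <- predicted_betas(arch, base)
    infl <- base
    infl[["sigmaS"]] <- stats::runif(1, 0.5, 2)
    infl[["sigmaX"]] <- stats::runif(1, 0.5, 2)
    infl[["sigmaY"]] <- arch$y_to_t * stats::runif(1, 0.5, 2)
    b1 <- predicted_betas(arch, infl)
    pat <- zero_pattern(arch)
    basal_slots <- names(pat)[!pat]
    expect_equal(b1$estimate[basal_slots], b0$estimate[basal_slots])
  }
})

test_that("the downstream deletion effect is negated by the interaction for every wiring", {
  # general ordering rule at the cell-mean level: deltaY = -deltaI always;
  # deltaX = -deltaI exactly when the feedforward influence is zero
  set.seed(5)
  for (arch in all_architectures()) {
    for (zero_sx in c(FALSE, TRUE)) {
      infl <- random_influences(arch)
      if (zero_sx) infl[["sigmaX"]] <- 0
      d <- predicted_deltas(arch, infl)
      expect_equal(d$estimate[["deltaY"]], -d$estimate[["deltaI"]],
                   tolerance = 1e-12)
      expect_equal(abs(d$estimate[["deltaX"]] + d$estimate[["deltaI"]]),
                   abs(infl[["sigmaX"]]), tolerance = 1e-12)
    }
  }
})

test_that("influences are recovered exactly from model-consistent cell means", {
  set.seed(17)
  for (arch in all_architectures()) {
    infl <- random_influences(arch)
    cm <- predicted_cell_means_model(arch, infl)
    fit <- solve_influences(arch, cm)
    expect_equal(unclass(fit$estimate), unclass(infl), tolerance = 1e-9)
    expect_lt(fit$residual, 1e-9)
  }
  # reference pathway: exact named values, baseline reported as theta0 = 10
  fit <- solve_influences(ref_arch(), ref_cell_means())
  expect_equal(unclass(fit$estimate),
               c(theta0 = 10, sigmaS = 1, sigmaX = 2, sigmaY = 3,
                 alphaX = 0.5, alphaY = 0.25, alphaI = 0),
               tolerance = 1e-10)
  # all-zero input stays all-zero
  zfit <- solve_influences(ref_arch(),
                           predicted_cell_means_model(ref_arch(), influence_set()))
  expect_equal(unname(unclass(zfit$estimate)), rep(0, 7))
})

test_that("influence confidence intervals widen with noise and cover noise-free truth", {
  infl <- ref_influences()
  tab <- simulate_pair(ref_arch(), infl, noise_sd = 0.1, n_replicates = 8, seed = 3)
  fit <- solve_influences(ref_arch(), cell_means(log_transform(tab)))
  expect_true(all(fit$ci_upper > fit$ci_lower))
  inside <- unclass(infl) >= fit$ci_lower & unclass(infl) <= fit$ci_upper
  expect_gte(mean(inside), 5 / 7)  # most parameters covered at one fixed seed
})

test_that("the classical Boolean epistasis rules emerge when basal effects vanish", {
  chk <- avery_wasserman_check(seed = 2)
  expect_true(chk$rule1)
  expect_true(chk$rule2)
  expect_true(chk$rule3)
  expect_true(chk$pass)

  # a basal influence breaks rule 1: the deletion now acts in both states
  infl <- influence_set(sigmaS = 1, sigmaX = 2, sigmaY = 1.2, alphaX = 0.4)
  b <- predicted_betas(ref_arch(), infl)
  expect_true(abs(b$estimate[["betaX_off"]]) > 1e-9 &&
                abs(b$estimate[["betaX_on"]]) > 1e-9)

  # positive regulation without feedforward: both genes are masked, so
  # there is no unique masking interaction
  infl2 <- influence_set(sigmaS = 1, sigmaX = 0, sigmaY = 1.5)
  b2 <- predicted_betas(ref_arch(), infl2)
  expect_equal(b2$estimate[["betaI_on"]], -b2$estimate[["betaX_on"]])
  expect_equal(b2$estimate[["betaI_on"]], -b2$estimate[["betaY_on"]])
})
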