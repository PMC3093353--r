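test_that("interaction detection follows the deltaI test", {
  flat_tab <- ref_table(noise_sd = 0, n_replicates = 4)
  flat_tab$data$value <- 4
  expect_false(detect_interaction(estimate_deltas(cell_means(
    log_transform(flat_tab)))))  # deltaI exactly 0
  nf <- estimate_deltas(cell_means(log_transform(
    ref_table(noise_sd = 0, n_replicates = 4))))
  expect_true(detect_interaction(nf))  # noise-free replicated, deltaI = -3

  noisy <- estimate_deltas(cell_means(log_transform(
    ref_table(noise_sd = 0.05, n_replicates = 4, seed = 7))))
  expect_true(detect_interaction(noisy))

  single_rep <- estimate_deltas(cell_means(log_transform(
    ref_table(noise_sd = 0, n_replicates = 1))))
  expect_warning(res <- detect_interaction(single_rep), "no replication")
  expect_false(res)
})

test_that("the masking threshold is the mean relative SE of significant interactions", {
  d1 <- fake_deltas(5, 3, -3, se_dI = 0.3)   # rel SE 0.10
  d2 <- fake_deltas(4, 2, -2, se_dI = 0.6)   # rel SE 0.30
  expect_equal(epsilon_threshold(list(d1, d2)), 0.20)
  d3 <- fake_deltas(4, 2, -2, se_dI = 0.26)  # rel SE 0.13
  expect_equal(epsilon_threshold(list(d3)), 0.13)
  none <- fake_deltas(1, 1, -1, p_dI = 0.5)
  expect_error(epsilon_threshold(list(none)), "supply eps_thr")
})

test_that("masking scores order the genes; the masked gene is downstream", {
  # reference values deltaA = 5, deltaB = 3, deltaI = -3
  m <- infer_order(fake_deltas(5, 3, -3), eps_thr = 0.2)
  expect_equal(m$eps_b, 0)
  expect_equal(m$eps_a, 0.4)
  expect_equal(m$verdict, "b_downstream")

  # no feedforward loop: both single deletions equivalent
  m2 <- infer_order(fake_deltas(3, 3, -3), eps_thr = 0.2)
  expect_equal(m2$verdict, "coequivalent")

  # interaction without masking: |4 - 1|/4 and |5 - 1|/5
  m3 <- infer_order(fake_deltas(4, 5, -1), eps_thr = 0.2)
  expect_equal(m3$eps_a, 0.75)
  expect_equal(m3$eps_b, 0.8)
  expect_equal(m3$verdict, "none")

  expect_warning(m4 <- infer_order(fake_deltas(0, 1, 0), eps_thr = 0.1),
                 "undefined")
  expect_equal(m4$eps_a, 0)
})

test_that("raising the threshold never flips the inferred direction", {
  set.seed(23)
  for (i in 1:50) {
    d <- fake_deltas(stats::rnorm(1, 0, 3), stats::rnorm(1, 0, 3),
                     stats::rnorm(1, 0, 3))
    verdicts <- vapply(seq(0, 1, by = 0.05), function(thr) {
      infer_order(d, thr)$verdict
    }, character(1))
    expect_false(any(verdicts == "a_downstream") &&
                   any(verdicts == "b_downstream"))
  }
})

test_that("basal correction zeroes the low-magnitude state and keeps the basal record", {
  cm <- ref_cell_means()
  b <- estimate_betas(cm)
  attr(b, "deltas") <- estimate_deltas(cm)
  corr <- correct_betas(b)
  expect_equal(unname(corr$corrected[c("betaX_off", "betaX_on")]), c(0, -5))
  expect_equal(unname(corr$corrected[c("betaY_off", "betaY_on")]), c(0, -3))
  expect_equal(unname(corr$corrected[c("betaI_off", "betaI_on")]), c(0, 3))
  expect_equal(unname(corr$basal), c(-0.5, -0.25, 0))
  expect_equal(unname(corr$basal_state), rep("off", 3))

  clean <- b
  clean$estimate[c("betaX_off", "betaX_on")] <- c(0, 4)
  corr2 <- correct_betas(clean)
  expect_equal(unname(corr2$corrected[c("betaX_off", "betaX_on")]), c(0, 4))
  expect_equal(corr2$basal[["betaX"]], 0)

  tied <- b
  tied$estimate[c("betaX_off", "betaX_on")] <- c(2, -2)
  expect_warning(corr3 <- correct_betas(tied), "tie")
  expect_equal(unname(corr3$corrected[c("betaX_off", "betaX_on")]), c(0, -4))
  expect_equal(corr3$basal_state[["betaX"]], "off")
})

test_that("corrected patterns identify the architecture family and Y->T sign", {
  cm <- ref_cell_means()
  b <- estimate_betas(cm)
  attr(b, "deltas") <- estimate_deltas(cm)
  corr <- correct_betas(b)
  order <- infer_order(estimate_deltas(cm), eps_thr = 0.2)
  m <- match_architecture(corr, order)
  expect_equal(m$status, "inferred")
  expect_equal(arch_label(m$architecture), "S+X+Y+T")
  expect_equal(m$upstream, "a")
})

test_that("a dual-function (activator ON, repressor OFF) profile is inconsistent", {
  # significant corrected effects at (betaX: ON, betaY: OFF, betaI: OFF)
  # match no architecture family
  corr <- list(
    corrected = c(betaX_off = 0, betaX_on = -2, betaY_off = 3, betaY_on = 0,
                  betaI_off = -3, betaI_on = 0),
    p = c(betaX_off = NA, betaX_on = 1e-5, betaY_off = 1e-5, betaY_on = NA,
          betaI_off = 1e-5, betaI_on = NA),
    basal = c(betaX = 0, betaY = 0, betaI = 0),
    basal_state = c(betaX = "off", betaY = "on", betaI = "on"))
  order <- structure(list(eps_a = 0.5, eps_b = 0.1, verdict = "b_downstream",
                          eps_thr = 0.2), class = "masking_result")
  m <- match_architecture(corr, order)
  expect_equal(m$status, "inconsistent")
})

test_that("coequivalent pairs with effects in opposite states are still ordered", {
  # negatively regulated pathway, no feedforward: betaA nonzero ON,
  # betaB nonzero OFF, betaI nonzero ON -> family S+X-Y, A upstream
  arch <- pathway_architecture(1, -1, 1)
  infl <- influence_set(theta0 = 8, sigmaS = 0.7, sigmaX = 0, sigmaY = 1.8)
  tab <- simulate_pair(arch, infl, noise_sd = 0, n_replicates = 4, seed = 2)
  r <- infer_pair(tab, eps_thr = 0.2)
  expect_equal(r$status, "inferred")
  expect_equal(r$upstream, "geneA")
  expect_equal(r$architecture$s_to_x, 1)
  expect_equal(r$architecture$x_to_y, -1)
})

test_that("end-to-end inference on the reference pathway recovers everything", {
  r <- infer_pair(ref_table(noise_sd = 0, n_replicates = 4), eps_thr = 0.2)
  expect_equal(r$status, "inferred")
  expect_equal(r$upstream, "geneA")
  expect_equal(arch_label(r$architecture), "S+X+Y+T")
  expect_equal(unclass(r$influences$estimate),
               c(theta0 = 10, sigmaS = 1, sigmaX = 2, sigmaY = 3,
                 alphaX = 0.5, alphaY = 0.25, alphaI = 0),
               tolerance = 1e-9)
})

test_that("degenerate pairs exit early with the right status", {
  flat <- ref_table(noise_sd = 0, n_replicates = 4)
  flat$data$value <- 4
  expect_equal(infer_pair(flat, eps_thr = 0.2)$status, "no_interaction")

  # no feedforward loop in a positively regulated pathway: cohesive unit
  infl <- ref_influences()
  infl[["sigmaX"]] <- 0
  tab <- simulate_pair(ref_arch(), infl, noise_sd = 0, n_replicates = 4, seed = 2)
  r <- infer_pair(tab, eps_thr = 0.2)
  expect_equal(r$status, "cohesive_unit")
  expect_true(is.na(r$upstream))
  expect_equal(r$architecture$x_to_y, 1)

  # strong interaction but no masking relation: non-epistatic
  cmvals <- c(10, 9, 8, 10.5, 12, 7, 6, 11)  # irregular pattern
  tab2 <- ref_table(noise_sd = 0.01, n_replicates = 4, seed = 11)
  cm0 <- conditions()
  for (i in seq_len(nrow(cm0))) {
    sel <- tab2$data$gene_a_deleted == cm0$gene_a_deleted[i] &
      tab2$data$gene_b_deleted == cm0$gene_b_deleted[i] &
      tab2$data$signal == cm0$signal[i]
    tab2$data$value[sel] <- 2^(cmvals[i] + log2(tab2$data$value[sel]) -
                                 mean(log2(tab2$data$value[sel])))
  }
  r2 <- infer_pair(tab2, eps_thr = 0.1)
  expect_true(r2$status %in% c("non_epistatic", "inconsistent"))
})

test_that("orientation is recovered when gene B is upstream", {
  arch_b <- ref_arch(upstream = "b")
  infl <- ref_influences()
  tab <- simulate_pair(arch_b, infl, noise_sd = 0, n_replicates = 4, seed = 5)
  r <- infer_pair(tab, eps_thr = 0.2)
  expect_equal(r$status, "inferred")
  expect_equal(r$upstream, "geneB")
  expect_equal(unclass(r$influences$estimate), unclass(infl), tolerance = 1e-9)
})
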