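test_that("AmFRET ratio is computed and unratioable events are flagged", {
  ev <- tibble::tibble(donor = c(1, 1, 1), acceptor = c(2000, 10, 0),
                       fret = c(500, 0, 5))
  out <- compute_amfret(ev)
  expect_equal(out$amfret[1], 0.25)
  expect_equal(out$amfret[2], 0)
  expect_true(is.na(out$amfret[3]))
  expect_equal(out$amfret_excluded, c(FALSE, FALSE, TRUE))
})

test_that("gating retains double positives inside the expression window", {
  ev <- tibble::tibble(donor = rep(1, 1000), acceptor = 1:1000,
                       fret = rep(0, 1000))
  expect_identical(nrow(gate_events(ev)), 1000L)
  expect_warning(out <- gate_events(ev, acceptor_min = 2000), "every event")
  expect_identical(nrow(out), 0L)
  # exactly 10% constructed below the window
  g <- gate_events(ev, acceptor_min = 101)
  expect_equal(nrow(g) / nrow(ev), 0.9)
  expect_equal(attr(g, "n_total"), 1000L)
})

test_that("negative gate reproduces a degenerate control exactly and records fallbacks", {
  acc <- exp(seq(log(10), log(1e4), length.out = 5000))
  control <- tibble::tibble(donor = 1, acceptor = acc, fret = 0.02 * acc)
  gate <- build_negative_gate(control, quantile = 0.99, n_bins = 16,
                              min_occupancy = 50)
  occupied <- gate$n >= 50
  expect_true(all(abs(gate$boundary[occupied] - 0.02) < 1e-12))

  # a sparse far bin falls back to the global quantile
  sparse <- tibble::tibble(donor = 1,
                           acceptor = c(acc, runif(10, 1, 2)),
                           fret = 0.02 * c(acc, runif(10, 1, 2)))
  g2 <- build_negative_gate(sparse, n_bins = 16)
  expect_true(any(g2$fallback & g2$n > 0))
  expect_true(all(g2$boundary[g2$fallback] == attr(g2, "global_boundary")))

  expect_error(build_negative_gate(control[0, ]), "empty")
})

test_that("held-out monomer events exceed the 0.99 gate at one percent", {
  ctl <- simulate_population(damfret_params(n_cells = 1e5,
                                            archetype = "monomer", seed = 51))
  held <- simulate_population(damfret_params(n_cells = 1e5,
                                             archetype = "monomer", seed = 52))
  gate <- build_negative_gate(gate_events(ctl, acceptor_min = 20))
  sc <- score_assembled(gate_events(held, acceptor_min = 20), gate)
  exceed <- mean(sc$assembled[!sc$amfret_excluded])
  expect_lt(abs(exceed - 0.01), 0.003)
})

test_that("binned fractions are plain ratios (and 1 when everything is assembled)", {
  acc <- exp(seq(log(1), log(1e3), length.out = 2000))
  control <- tibble::tibble(donor = 1, acceptor = acc, fret = 0.1 * acc)
  gate <- build_negative_gate(control, n_bins = 8)
  # 10 events in one bin, 3 above the boundary
  ev <- tibble::tibble(donor = 1, acceptor = rep(50, 10),
                       fret = c(rep(60, 3), rep(1, 7)))
  bins <- bin_fraction_assembled(ev, gate, n_bins = 1,
                                 background_correct = FALSE)
  expect_equal(bins$fraction[bins$n_total > 0], 0.3)

  all_hi <- tibble::tibble(donor = 1, acceptor = acc, fret = 0.9 * acc)
  b2 <- bin_fraction_assembled(all_hi, gate, n_bins = 8,
                               background_correct = FALSE)
  expect_true(all(b2$fraction[b2$n_total > 0] == 1))
})

test_that("noise-free Weibull fits recover parameters to machine precision and match the grid oracle", {
  bins <- noise_free_bins(ec50 = 10, delta = 3)
  fit <- fit_weibull(bins)
  expect_lt(abs(fit$ec50 - 10) / 10, 1e-6)
  expect_lt(abs(fit$delta - 3) / 3, 1e-6)

  # exhaustive 200 x 200 log-grid oracle cannot beat the optimizer
  occ <- bins[bins$n_total > 0, ]
  grid_obj <- function(e, d) {
    sum(occ$n_total * (occ$fraction - weibull_response(occ$center, e, d, 1))^2)
  }
  eg <- exp(seq(log(1), log(1e4), length.out = 200))
  dg <- exp(seq(log(0.1), log(50), length.out = 200))
  grid_min <- min(outer(eg, dg, Vectorize(grid_obj)))
  expect_lte(fit$rss, grid_min + 1e-12)

  # free-plateau mode recovers a sub-unit plateau exactly
  b2 <- noise_free_bins(ec50 = 10, delta = 3, plateau = 0.7)
  f2 <- fit_weibull(b2, fit_plateau = TRUE)
  expect_lt(abs(f2$plateau - 0.7), 1e-6)
  expect_lt(abs(f2$ec50 - 10) / 10, 1e-6)
})

test_that("all-zero fractions censor the fit as monomer, never extrapolating", {
  bins <- noise_free_bins(ec50 = 10, delta = 3)
  bins$fraction <- 0
  bins$fraction_raw <- 0
  bins$n_assembled <- 0L
  fit <- fit_weibull(bins)
  expect_identical(fit$class, "monomer")
  expect_true(fit$censored)
  expect_true(is.na(fit$ec50) && is.na(fit$delta))
  g <- glance(fit)
  expect_identical(g$class, "monomer")
})

test_that("fitting requires enough occupied bins over a decade", {
  bins <- noise_free_bins(ec50 = 10, delta = 3, n_bins = 6)
  expect_error(fit_weibull(bins), "8 occupied bins")
})

test_that("scaling acceptor intensities scales EC50 and leaves delta unchanged", {
  p <- damfret_params(n_cells = 5e4, ec50 = 100, delta = 3, seed = 61)
  res <- analyze_sim(p, control_seed = 62)
  k <- 7.5
  scale_events <- function(ev) {
    ev$acceptor <- ev$acceptor * k
    ev$fret <- ev$fret * k
    ev
  }
  gate_k <- build_negative_gate(scale_events(
    gate_events(simulate_population(damfret_params(
      n_cells = 5e4, archetype = "monomer", seed = 62)), acceptor_min = 20)))
  bins_k <- bin_fraction_assembled(scale_events(res$gated), gate_k)
  fit_k <- fit_weibull(bins_k)
  expect_lt(abs(fit_k$ec50 / res$fit$ec50 - k) / k, 1e-3)
  expect_lt(abs(fit_k$delta - res$fit$delta) / res$fit$delta, 1e-3)
})

test_that("estimator error shrinks as the sample grows", {
  err <- function(n, seed) {
    p <- damfret_params(n_cells = n, ec50 = 100, delta = 3, seed = seed)
    fit <- analyze_sim(p, control_seed = seed + 500,
                       n_control = min(n, 5e4))$fit
    c(ec50 = abs(fit$ec50 - 100) / 100, delta = abs(fit$delta - 3) / 3)
  }
  seeds <- 1:11
  small <- vapply(seeds, function(s) err(1e4, 70 + s), numeric(2))
  large <- vapply(seeds, function(s) err(1e5, 170 + s), numeric(2))
  expect_lt(median(large["ec50", ]), median(small["ec50", ]))
  expect_lt(median(large["delta", ]), median(small["delta", ]))
})

test_that("bootstrap intervals bracket the point estimates", {
  p <- damfret_params(n_cells = 3e4, ec50 = 100, delta = 3, seed = 81)
  res <- analyze_sim(p, control_seed = 82, fit = FALSE)
  fit <- fit_weibull(res$bins, events = res$gated, gate = res$gate,
                     n_boot = 50, seed = 83)
  expect_identical(nrow(fit$boot), 50L)
  ci <- fit$ci
  expect_lt(ci$lower[ci$term == "ec50"], fit$ec50)
  expect_gt(ci$upper[ci$term == "ec50"], fit$ec50)
  expect_lt(ci$lower[ci$term == "delta"], fit$delta)
  expect_gt(ci$upper[ci$term == "delta"], fit$delta)
  expect_equal(tidy(fit)$estimate, c(fit$ec50, fit$delta, 1))
})

test_that("profiles classify as monomer, discontinuous or continuous", {
  archetypes <- c(monomer = "monomer",
                  nucleated_polymer = "discontinuous",
                  threshold_polymer = "continuous",
                  constitutive_oligomer = "continuous")
  for (arch in names(archetypes)) {
    p <- damfret_params(n_cells = 5e4, archetype = arch, seed = 90)
    res <- analyze_sim(p, control_seed = 91)
    cl <- if (res$fit$censored) "monomer" else {
      classify_profile(res$gated, res$gate, res$fit)
    }
    expect_identical(cl, unname(archetypes[arch]), label = arch)
  }
})

test_that("sparse diagnostic windows yield an indeterminate call", {
  acc <- exp(seq(log(2000), log(1e4), length.out = 3000))
  control <- tibble::tibble(donor = 1, acceptor = acc, fret = 0.02 * acc)
  gate <- build_negative_gate(control, n_bins = 8)
  ev <- tibble::tibble(donor = 1, acceptor = acc,
                       fret = ifelse(seq_along(acc) %% 2 == 0,
                                     0.6 * acc, 0.001 * acc))
  fake_fit <- structure(list(ec50 = 100, censored = FALSE),
                        class = "damfret_fit")
  expect_identical(classify_profile(ev, gate, fake_fit), "indeterminate")
})

test_that("replicate fit comparison performs Welch tests against the reference", {
  mk <- function(ec50, delta) {
    structure(list(ec50 = ec50, delta = delta, plateau = 1),
              class = "damfret_fit")
  }
  same <- list(mk(10, 3), mk(12, 3.2), mk(10, 3), mk(12, 3.2))
  cmp <- compare_fits(same, groups = c("a", "a", "b", "b"))
  p_ec50 <- cmp$p.value[cmp$parameter == "ec50" & cmp$group == "b"]
  expect_equal(p_ec50, 1)
  expect_equal(cmp$t[cmp$parameter == "ec50" & cmp$group == "b"], 0)

  set.seed(1)
  wt <- lapply(rnorm(3, 10, 0.3), mk, delta = 3)
  mut <- lapply(rnorm(3, 100, 3), mk, delta = 3)
  cmp2 <- compare_fits(c(wt, mut), groups = rep(c("wt", "mut"), each = 3),
                       reference = "wt")
  expect_lt(cmp2$p.value[cmp2$parameter == "ec50" & cmp2$group == "mut"], 0.01)

  cmp3 <- compare_fits(c(wt, list(mk(50, 3))),
                       groups = c(rep("wt", 3), "single"),
                       reference = "wt")
  row <- cmp3[cmp3$parameter == "ec50" & cmp3$group == "single", ]
  expect_identical(row$n, 1L)
  expect_true(is.na(row$p.value))
})

test_that("seeding in trans collapses the supersaturated population in every bin", {
  p <- damfret_params(n_cells = 5e4, ec50 = 100, seeded = TRUE, seed = 71)
  res <- analyze_sim(p, control_seed = 72)
  # acceptor a.u. per concentration a.u. = photoconversion x gain
  onset_acc <- p$saturation_onset * p$photoconversion * p$acceptor_gain
  hot <- res$bins[res$bins$center > 1.2 * onset_acc & res$bins$n_total > 50, ]
  expect_gt(nrow(hot), 30)
  expect_true(all(hot$fraction >= 0.99))
})
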