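test_that("CV is exact on closed-form masks and scale-invariant", {
  labels <- matrix(1L, 10, 10)

  uniform <- matrix(7, 10, 10)
  m <- cv_punctum_call(uniform, labels)
  expect_identical(m$cv, 0)
  expect_false(m$punctum)

  # single bright pixel among N: CV = sqrt(N - 1)
  n <- 100
  single <- matrix(0, 10, 10)
  single[5, 5] <- 42
  m2 <- cv_punctum_call(single, labels)
  expect_equal(m2$cv, sqrt(n - 1))
  expect_true(m2$punctum)

  # exact CVs straddling the 0.8 threshold
  make_cv <- function(cv) matrix(rep(c(1 - cv, 1 + cv), 50), 10, 10)
  expect_false(cv_punctum_call(make_cv(0.79), labels)$punctum)
  expect_true(cv_punctum_call(make_cv(0.81), labels)$punctum)

  # invariance to multiplicative rescaling
  set.seed(4)
  img <- matrix(rlnorm(100, 2, 0.7), 10, 10)
  base <- cv_punctum_call(img, labels)$cv
  for (k in c(0.01, 3, 1000)) {
    expect_equal(cv_punctum_call(k * img, labels)$cv, base)
  }

  # degenerate masks are indeterminate, not wrong
  tiny <- matrix(0L, 10, 10); tiny[1:3, 1] <- 1L
  expect_true(is.na(cv_punctum_call(uniform, tiny)$punctum))
  expect_true(is.na(cv_punctum_call(matrix(0, 10, 10), labels)$punctum))
})

test_that("punctate cells concentrate intensity enough to push CV above 2", {
  # 80% of intensity in spots covering ~1% of area: two-level partition bound
  # CV^2 >= s^2/a - ... evaluated on the rendered field
  f <- render_field(n_cells = 6, state_mix = c(punctate = 1),
                    spot_fraction = 0.8, n_spots = 1, spot_sigma = 1,
                    dim = c(160, 160), seed = 9)
  m <- cv_punctum_call(f$channels$protein, f$truth$cell_labels)
  expect_true(all(m$cv > 2))
})

test_that("nuclear/cytoplasmic ratio is exact for uniform cells and censors empty cytoplasm", {
  f <- render_field(n_cells = 4, dim = c(128, 128), seed = 2)
  labels <- f$truth$cell_labels
  nlabels <- f$truth$nucleus_labels
  uniform <- matrix(1, 128, 128)
  nc <- nuc_cyt_ratio(uniform, labels, nlabels)
  for (i in nc$id) {
    a_nuc <- sum(nlabels == i)
    a_cyt <- sum(labels == i & nlabels != i)
    expect_equal(nc$nc_ratio[nc$id == i], a_nuc / a_cyt)
  }

  nuc_only <- matrix(0, 128, 128)
  nuc_only[nlabels > 0] <- 5
  cens <- nuc_cyt_ratio(nuc_only, labels, nlabels)
  expect_true(all(cens$censored_high))
  expect_true(all(is.na(cens$nc_ratio)))
})

test_that("rendered translocation series recovers monotonically increasing ratios", {
  targets <- c(0.5, 1, 2, 4)
  f <- render_field(n_cells = 4, dim = c(128, 128), nc_target = targets,
                    seed = 3)
  nc <- nuc_cyt_ratio(f$channels$p65, f$truth$cell_labels,
                      f$truth$nucleus_labels)
  expect_true(all(diff(nc$nc_ratio[order(f$truth$nc_target)]) > 0))
})

test_that("noise-free fields are segmented exactly; noisy fields above 0.9 IoU", {
  clean <- render_field(n_cells = 6, dim = c(160, 160), poisson = FALSE,
                        read_noise = 0, seed = 5)
  seg <- segment_field(clean)
  iou <- segmentation_iou(clean$truth$cell_labels, seg$cell_labels)
  expect_equal(iou$iou, rep(1, 6))

  noisy <- render_field(n_cells = 9, dim = c(200, 200),
                        state_mix = c(diffuse = 0.5, punctate = 0.5),
                        seed = 6)
  seg2 <- segment_field(noisy)
  iou2 <- segmentation_iou(noisy$truth$cell_labels, seg2$cell_labels)
  expect_gte(mean(iou2$iou), 0.9)
  expect_false(any(seg2$cells$unresolved))
})

test_that("touching cells are flagged unresolved and empty fields warn", {
  protein <- matrix(0, 80, 80)
  nucleus <- matrix(0, 80, 80)
  paint <- function(mat, cx, cy, r, v) {
    g <- expand.grid(r = 1:80, c = 1:80)
    d2 <- (g$r - cy)^2 + (g$c - cx)^2
    mat[cbind(g$r[d2 <= r^2], g$c[d2 <= r^2])] <- v
    mat
  }
  # two overlapping cells, two separate nuclei
  protein <- paint(protein, 30, 40, 14, 60)
  protein <- paint(protein, 50, 40, 14, 60)
  nucleus <- paint(nucleus, 30, 40, 5, 80)
  nucleus <- paint(nucleus, 50, 40, 5, 80)
  seg <- segment_field(list(protein = protein, nucleus = nucleus))
  expect_identical(nrow(seg$cells), 1L)
  expect_true(seg$cells$unresolved)

  empty <- render_field(n_cells = 0, dim = c(64, 64), seed = 1)
  expect_true(all(dim(empty$channels$protein) == c(64, 64)))
  expect_warning(seg0 <- segment_field(empty), "foreground")
  expect_identical(nrow(seg0$cells), 0L)

  expect_error(render_field(n_cells = 100, dim = c(64, 64), seed = 1),
               "Layout error")
})

test_that("puncta calls reach 0.95 sensitivity and specificity on default fixtures", {
  calls <- truth <- logical(0)
  for (s in 1:3) {
    f <- render_field(n_cells = 16, dim = c(256, 256),
                      state_mix = c(diffuse = 0.5, punctate = 0.5),
                      seed = 20 + s)
    m <- cv_punctum_call(f$channels$protein, f$truth$cell_labels)
    calls <- c(calls, m$punctum)
    truth <- c(truth, f$truth$states[m$id] == "punctate")
  }
  sens <- sum(calls & truth) / sum(truth)
  spec <- sum(!calls & !truth) / sum(!truth)
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("CV time courses locate transient peaks and flag persistent assemblies", {
  labels_from <- function(fields) fields[[1]]$truth$cell_labels

  flat <- matrix(5, 40, 40)
  lab <- matrix(0L, 40, 40); lab[10:20, 10:20] <- 1L
  const_tc <- cv_timecourse(list(flat, flat, flat, flat), lab)
  expect_true(all(const_tc$trace$cv == const_tc$trace$cv[1]))

  transient <- render_timecourse(
    spot_profile = c(0, 0, 0.7, 0.3, 0, 0, 0, 0),
    n_cells = 6, dim = c(160, 160), poisson = FALSE, read_noise = 0.5,
    seed = 30)
  tc <- cv_timecourse(transient, labels_from(transient))
  expect_true(all(tc$summary$peak_frame == 3))
  expect_true(all(!is.na(tc$summary$return_frame)))
  expect_true(all(tc$summary$return_frame > 3))

  persistent <- render_timecourse(
    spot_profile = c(0, 0, 0.4, 0.6, 0.7, 0.7, 0.7, 0.7),
    n_cells = 6, dim = c(160, 160), poisson = FALSE, read_noise = 0.5,
    seed = 31)
  tc2 <- cv_timecourse(persistent, labels_from(persistent))
  expect_true(all(is.na(tc2$summary$return_frame)))

  short <- cv_timecourse(list(flat, flat), lab)
  expect_null(short$summary)
})
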