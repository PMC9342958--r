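#' Render a synthetic fluorescence microscopy field
#'
#' Draws disk-shaped cells with inner-disk nuclei on a jittered grid (so cells
#' never touch) and paints the protein channel per the requested distribution
#' states:
#' * `diffuse` — flat intensity over the whole cell;
#' * `punctate` — `n_spots` Gaussian spots carrying `spot_fraction` of the
#'   cell's total intensity over a small area, the rest spread flat;
#' * `filament` — a line segment through the cell center carrying
#'   `spot_fraction` of the intensity.
#'
#' Each pixel's photon count is Poisson-distributed around its mean, plus
#' Gaussian read noise. An optional third channel emulates a
#' nucleus/cytoplasm-partitioned protein (e.g. a translocating transcription
#' factor) at a per-cell target integrated-density ratio `nc_target`.
#'
#' @param n_cells Number of cells; a layout error is raised when they cannot
#'   be placed disjointly on the field.
#' @param state_mix Named proportions over `diffuse`, `punctate`, `filament`;
#'   must sum to 1.
#' @param dim Field dimensions in pixels (rows, cols).
#' @param cell_radius,nucleus_radius Disk radii in pixels.
#' @param intensity Mean per-pixel intensity of a diffuse cell (a.u.).
#' @param nucleus_intensity Nucleus-marker per-pixel intensity.
#' @param spot_fraction Fraction of a punctate/filament cell's total intensity
#'   concentrated in its spots/filament.
#' @param n_spots,spot_sigma Number and Gaussian sigma (pixels) of puncta.
#' @param filament_width Filament width in pixels.
#' @param background Background level (a.u.).
#' @param read_noise Gaussian read-noise sd (a.u.).
#' @param poisson Apply Poisson shot noise to per-pixel means.
#' @param nc_target Target nuclear/cytoplasmic integrated-density ratio(s) for
#'   the third channel; `NULL` omits the channel.
#' @param p65_intensity Cytoplasmic per-pixel level of the third channel.
#' @param layout Reuse the cell layout (positions, states, spot geometry) of a
#'   previous field — required for time courses with consistent masks.
#' @param seed Optional RNG seed.
#' @return A `cell_field` list: `channels` (matrices `protein`, `nucleus`,
#'   optionally `p65`), `truth` (label matrices, states, `nc_target`),
#'   `layout`, `params`.
#' @export
render_field <- function(n_cells = 12,
                         state_mix = c(diffuse = 1, punctate = 0, filament = 0),
                         dim = c(256, 256), cell_radius = 14,
                         nucleus_radius = 6, intensity = 60,
                         nucleus_intensity = 80, spot_fraction = 0.6,
                         n_spots = 3, spot_sigma = 1.5, filament_width = 2,
                         background = 5, read_noise = 2, poisson = TRUE,
                         nc_target = NULL, p65_intensity = 40,
                         layout = NULL, seed = NULL) {
  states_all <- c("diffuse", "punctate", "filament")
  mix <- setNames(rep(0, 3), states_all)
  mix[names(state_mix)] <- state_mix
  if (abs(sum(mix) - 1) > 1e-8) abort("`state_mix` must sum to 1.")
  with_seed(seed, {
    if (is.null(layout)) {
      layout <- field_layout(n_cells, dim, cell_radius, mix, n_spots,
                             nucleus_radius)
    }
    n_cells <- nrow(layout$cells)
    nr <- dim[1]; nc <- dim[2]
    protein <- matrix(background, nr, nc)
    nucleus <- matrix(background, nr, nc)
    p65 <- if (!is.null(nc_target)) matrix(background, nr, nc) else NULL
    if (!is.null(nc_target)) {
      nc_target <- rep_len(nc_target, n_cells)
    }
    cell_labels <- matrix(0L, nr, nc)
    nucleus_labels <- matrix(0L, nr, nc)
    for (i in seq_len(n_cells)) {
      cell <- layout$cells[i, ]
      px <- disk_pixels(cell$x, cell$y, cell_radius, nr, nc)
      npx <- disk_pixels(cell$x, cell$y, nucleus_radius, nr, nc)
      ind <- cbind(px$r, px$c)
      nind <- cbind(npx$r, npx$c)
      cell_labels[ind] <- i
      nucleus_labels[nind] <- i
      area <- nrow(ind)
      total <- intensity * area
      state <- cell$state
      add <- rep(total / area, area)
      if (state == "punctate" && spot_fraction > 0) {
        ctr <- layout$spots[[i]]
        w <- rep(0, area)
        for (s in seq_len(nrow(ctr))) {
          d2 <- (px$r - ctr[s, 1])^2 + (px$c - ctr[s, 2])^2
          w <- w + exp(-d2 / (2 * spot_sigma^2))
        }
        w <- w / sum(w)
        add <- (1 - spot_fraction) * total / area + spot_fraction * total * w
      } else if (state == "filament" && spot_fraction > 0) {
        th <- layout$angles[i]
        u <- cos(th) * (px$r - cell$y) + sin(th) * (px$c - cell$x)
        v <- -sin(th) * (px$r - cell$y) + cos(th) * (px$c - cell$x)
        on_fil <- abs(v) <= filament_width / 2 & abs(u) <= 0.8 * cell_radius
        if (!any(on_fil)) on_fil[which.min(abs(v))] <- TRUE
        add <- (1 - spot_fraction) * total / area
        add <- rep(add, area)
        add[on_fil] <- add[on_fil] + spot_fraction * total / sum(on_fil)
      }
      protein[ind] <- add
      nucleus[nind] <- nucleus_intensity
      if (!is.null(p65)) {
        a_nuc <- nrow(nind)
        a_cyt <- area - a_nuc
        l_cyt <- p65_intensity
        l_nuc <- nc_target[i] * l_cyt * a_cyt / a_nuc
        p65[ind] <- l_cyt
        p65[nind] <- l_nuc
      }
    }
    noisify <- function(m) {
      v <- if (poisson) rpois(length(m), lambda = m) else m
      pmax(0, v + rnorm(length(m), 0, read_noise)) |> matrix(nr, nc)
    }
    channels <- list(protein = noisify(protein), nucleus = noisify(nucleus))
    if (!is.null(p65)) channels$p65 <- noisify(p65)
    structure(
      list(
        channels = channels,
        truth = list(cell_labels = cell_labels,
                     nucleus_labels = nucleus_labels,
                     states = layout$cells$state,
                     nc_target = nc_target),
        layout = layout,
        params = list(dim = dim, cell_radius = cell_radius,
                      nucleus_radius = nucleus_radius, intensity = intensity,
                      background = background, spot_fraction = spot_fraction,
                      read_noise = read_noise, poisson = poisson)
      ),
      class = "cell_field")
  })
}

# grid-with-jitter placement; layout error when the field cannot hold n_cells
field_layout <- function(n_cells, dim, cell_radius, mix, n_spots,
                         nucleus_radius) {
  pitch <- 2 * cell_radius + 8
  rows <- floor((dim[1] - 2 * cell_radius - 4) / pitch) + 1
  cols <- floor((dim[2] - 2 * cell_radius - 4) / pitch) + 1
  if (n_cells > rows * cols) {
    abort(sprintf(
      "Layout error: cannot place %d disjoint cells of radius %d on a %dx%d field (capacity %d).",
      n_cells, cell_radius, dim[1], dim[2], rows * cols))
  }
  centers <- expand.grid(
    y = cell_radius + 3 + pitch * (seq_len(rows) - 1),
    x = cell_radius + 3 + pitch * (seq_len(cols) - 1)
  )
  pick <- sample.int(nrow(centers), n_cells)
  jit <- 2
  cells <- tibble::tibble(
    id = seq_len(n_cells),
    y = centers$y[pick] + runif(n_cells, -jit, jit),
    x = centers$x[pick] + runif(n_cells, -jit, jit),
    state = sample(names(mix), n_cells, replace = TRUE, prob = mix)
  )
  spots <- lapply(seq_len(n_cells), function(i) {
    r <- runif(n_spots, 0, 0.6 * cell_radius)
    th <- runif(n_spots, 0, 2 * pi)
    cbind(cells$y[i] + r * sin(th), cells$x[i] + r * cos(th))
  })
  angles <- runif(n_cells, 0, pi)
  list(cells = cells, spots = spots, angles = angles)
}

disk_pixels <- function(cx, cy, radius, nr, nc) {
  rs <- max(1, floor(cy - radius)):min(nr, ceiling(cy + radius))
  cs <- max(1, floor(cx - radius)):min(nc, ceiling(cx + radius))
  g <- expand.grid(r = rs, c = cs)
  d2 <- (g$r - cy)^2 + (g$c - cx)^2
  g[d2 <= radius^2, , drop = FALSE]
}

#' Segment a rendered field by thresholding
#'
#' Global robust-background thresholding plus connected components: the
#' threshold is the background median plus six background MADs, interior
#' shot-noise holes are filled, and components smaller than `min_size` pixels
#' are dropped. Nuclei are segmented the same way on the
#' nucleus channel and each is assigned to the cell component containing its
#' centroid; a cell component claiming two or more nuclei is flagged
#' unresolved (touching cells). Synthetic fields are designed to be
#' segmentable this way; externally produced label images (e.g. from a learned
#' segmenter) can be substituted anywhere a label matrix is accepted.
#'
#' @param field A `cell_field`, or a list with `protein` and `nucleus`
#'   matrices.
#' @param min_size Minimum component area in pixels.
#' @return A `cell_segmentation` list: `cell_labels`, `nucleus_labels`
#'   (integer matrices relabelled so each nucleus shares its cell's label) and
#'   `cells` (tibble: `id`, `area`, `n_nuclei`, `unresolved`). Warns and
#'   returns empty labels when no foreground is found.
#' @export
segment_field <- function(field, min_size = 50) {
  channels <- if (inherits(field, "cell_field")) field$channels else field
  if (is.null(channels$nucleus)) abort("A nucleus channel is required.")
  seg_one <- function(mat) {
    bg <- mat[mat <= median(mat)]
    thr <- median(bg) + max(6 * mad(bg), 1)
    mask <- mat > thr
    if (!any(mask)) return(matrix(0L, nrow(mat), ncol(mat)))
    mask <- EBImage::fillHull(mask * 1)
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_size)
    if (length(drop)) lab[lab %in% drop] <- 0
    # compact labels
    u <- sort(unique(lab[lab > 0]))
    out <- matrix(0L, nrow(mat), ncol(mat))
    for (k in seq_along(u)) out[lab == u[k]] <- k
    out
  }
  cell_lab <- seg_one(channels$protein)
  nuc_lab <- seg_one(channels$nucleus)
  if (!any(cell_lab > 0)) {
    warn("No foreground found; returning empty segmentation.")
    return(structure(list(cell_labels = cell_lab, nucleus_labels = nuc_lab,
                          cells = tibble::tibble(id = integer(0),
                                                 area = integer(0),
                                                 n_nuclei = integer(0),
                                                 unresolved = logical(0))),
                     class = "cell_segmentation"))
  }
  # assign nuclei to cells via centroid
  n_nuc <- max(nuc_lab)
  owner <- integer(n_nuc)
  for (k in seq_len(n_nuc)) {
    w <- which(nuc_lab == k, arr.ind = TRUE)
    ctr <- round(colMeans(w))
    owner[k] <- cell_lab[ctr[1], ctr[2]]
  }
  n_cell <- max(cell_lab)
  n_nuclei <- tabulate(owner[owner > 0], nbins = n_cell)
  # relabel nuclei by their owning cell
  nuc_out <- matrix(0L, nrow(nuc_lab), ncol(nuc_lab))
  for (k in seq_len(n_nuc)) {
    if (owner[k] > 0) nuc_out[nuc_lab == k] <- owner[k]
  }
  cells <- tibble::tibble(
    id = seq_len(n_cell),
    area = tabulate(cell_lab[cell_lab > 0], nbins = n_cell),
    n_nuclei = n_nuclei,
    unresolved = n_nuclei >= 2
  )
  structure(list(cell_labels = cell_lab, nucleus_labels = nuc_out,
                 cells = cells),
            class = "cell_segmentation")
}

#' Mean intersection-over-union between two label images
#'
#' Each reference object is matched to the candidate object it overlaps most.
#'
#' @param truth,candidate Integer label matrices of identical dimensions.
#' @return Tibble with one row per reference object: `id`, `matched`, `iou`.
#' @export
segmentation_iou <- function(truth, candidate) {
  ids <- sort(unique(truth[truth > 0]))
  purrr::map_dfr(ids, function(i) {
    m <- truth == i
    cand_ids <- candidate[m]
    cand_ids <- cand_ids[cand_ids > 0]
    if (!length(cand_ids)) {
      return(tibble::tibble(id = i, matched = NA_integer_, iou = 0))
    }
    j <- as.integer(names(which.max(table(cand_ids))))
    inter <- sum(m & candidate == j)
    union <- sum(m | candidate == j)
    tibble::tibble(id = i, matched = j, iou = inter / union)
  })
}

# population CV (sd with denominator n) of in-mask pixels
pixel_cv <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}

#' Coefficient-of-variation puncta call
#'
#' For every labelled cell, CV = population standard deviation divided by the
#' mean of in-mask pixel intensities; cells with CV above `threshold`
#' (default 0.8) are called punctum-positive. Masks smaller than `min_pixels`
#' or with zero mean yield an indeterminate (`NA`) call.
#'
#' @param channel Intensity matrix.
#' @param labels Integer label matrix (cell masks).
#' @param threshold CV threshold for the positive call.
#' @param min_pixels Minimum mask size.
#' @return Tibble: `id`, `n_pixels`, `mean`, `sd`, `cv`, `punctum`.
#' @export
cv_punctum_call <- function(channel, labels, threshold = 0.8,
                            min_pixels = 25) {
  ids <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(ids, function(i) {
    x <- channel[labels == i]
    if (length(x) < min_pixels || mean(x) == 0) {
      return(tibble::tibble(id = i, n_pixels = length(x), mean = mean(x),
                            sd = NA_real_, cv = NA_real_, punctum = NA))
    }
    cv <- pixel_cv(x)
    tibble::tibble(id = i, n_pixels = length(x), mean = mean(x),
                   sd = cv * mean(x), cv = cv, punctum = cv > threshold)
  })
}

#' Nuclear/cytoplasmic integrated-density ratio
#'
#' Ratio of summed intensity inside the nucleus mask to summed intensity in
#' the cytoplasm (cell minus nucleus) for each cell. Cells whose cytoplasmic
#' integrated density is zero are reported censored-high (`nc_ratio = NA`,
#' `censored_high = TRUE`), never as infinity.
#'
#' @param channel Intensity matrix.
#' @param cell_labels,nucleus_labels Integer label matrices sharing ids.
#' @return Tibble: `id`, `nuclear_density`, `cytoplasmic_density`,
#'   `nc_ratio`, `censored_high`.
#' @export
nuc_cyt_ratio <- function(channel, cell_labels, nucleus_labels) {
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  purrr::map_dfr(ids, function(i) {
    nuc <- channel[nucleus_labels == i]
    cyt <- channel[cell_labels == i & nucleus_labels != i]
    nd <- sum(nuc)
    cd <- sum(cyt)
    if (length(cyt) == 0 || cd == 0) {
      return(tibble::tibble(id = i, nuclear_density = nd,
                            cytoplasmic_density = cd, nc_ratio = NA_real_,
                            censored_high = TRUE))
    }
    tibble::tibble(id = i, nuclear_density = nd, cytoplasmic_density = cd,
                   nc_ratio = nd / cd, censored_high = FALSE)
  })
}

#' Per-cell metrics of a rendered field
#'
#' Convenience wrapper: segments the field (unless a segmentation or label
#' matrices are provided), then computes the CV puncta call on the protein
#' channel and, when a third channel is present, the nuclear/cytoplasmic
#' ratio.
#'
#' @param field A `cell_field`.
#' @param seg Optional `cell_segmentation`; defaults to `segment_field(field)`.
#' @param cv_threshold CV threshold for the puncta call.
#' @return Tibble of per-cell metrics.
#' @export
quantify_field <- function(field, seg = NULL, cv_threshold = 0.8) {
  seg <- seg %||% segment_field(field)
  out <- cv_punctum_call(field$channels$protein, seg$cell_labels,
                         threshold = cv_threshold)
  if (!is.null(field$channels$p65)) {
    nc <- nuc_cyt_ratio(field$channels$p65, seg$cell_labels,
                        seg$nucleus_labels)
    out <- dplyr::left_join(out, nc, by = "id")
  }
  dplyr::left_join(out, seg$cells, by = "id")
}

#' Render a clustering time course
#'
#' Renders one field per time point with an identical cell layout, varying the
#' fraction of intensity concentrated in puncta according to `spot_profile`
#' (0 = fully diffuse). Emulates transient clustering (rise then decay) or
#' persistent filament growth, depending on the profile supplied.
#'
#' @param spot_profile Numeric vector in `[0, 1)`, one value per frame.
#' @param n_cells Number of cells.
#' @param seed RNG seed (layout and noise).
#' @param ... Passed to [render_field()].
#' @return List of `cell_field`s sharing one layout.
#' @export
render_timecourse <- function(spot_profile, n_cells = 9, seed = NULL, ...) {
  stopifnot(all(spot_profile >= 0 & spot_profile < 1))
  with_seed(seed, {
    first <- render_field(n_cells = n_cells,
                          state_mix = c(punctate = 1),
                          spot_fraction = spot_profile[1], ...)
    fields <- vector("list", length(spot_profile))
    fields[[1]] <- first
    for (t in seq_along(spot_profile)[-1]) {
      fields[[t]] <- render_field(state_mix = c(punctate = 1),
                                  spot_fraction = spot_profile[t],
                                  layout = first$layout, ...)
    }
    fields
  })
}

#' Per-cell CV traces and clustering kinetics
#'
#' Computes the pixel-intensity CV of every cell in every frame, then (given
#' at least three frames) summarises each cell's clustering kinetics: the peak
#' frame and the first post-peak frame at which the CV has returned to
#' baseline (baseline mean plus two baseline standard deviations, estimated
#' from the first `baseline_frames` frames).
#'
#' @param stack List of `cell_field`s or intensity matrices (frames).
#' @param labels Integer label matrix valid for every frame.
#' @param baseline_frames Number of leading frames regarded as baseline.
#' @return List with `trace` (tibble: `id`, `frame`, `cv`) and `summary`
#'   (tibble: `id`, `baseline`, `peak_frame`, `peak_cv`, `return_frame`;
#'   `NULL` when fewer than three frames are supplied).
#' @export
cv_timecourse <- function(stack, labels, baseline_frames = 2) {
  mats <- lapply(stack, function(f) {
    if (inherits(f, "cell_field")) f$channels$protein else f
  })
  ids <- sort(unique(labels[labels > 0]))
  trace <- purrr::map_dfr(seq_along(mats), function(t) {
    purrr::map_dfr(ids, function(i) {
      tibble::tibble(id = i, frame = t, cv = pixel_cv(mats[[t]][labels == i]))
    })
  })
  if (length(mats) < 3) {
    return(list(trace = trace, summary = NULL))
  }
  summary <- trace |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      base <- df$cv[df$frame <= baseline_frames]
      base_mean <- mean(base)
      base_sd <- sd(base)
      if (!is.finite(base_sd)) base_sd <- 0
      peak <- which.max(df$cv)
      after <- df$frame > df$frame[peak] &
        df$cv <= base_mean + 2 * base_sd
      tibble::tibble(
        baseline = base_mean,
        peak_frame = df$frame[peak],
        peak_cv = df$cv[peak],
        return_frame = if (any(after)) min(df$frame[after]) else NA_integer_
      )
    }) |>
    dplyr::ungroup()
  list(trace = trace, summary = summary)
}
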