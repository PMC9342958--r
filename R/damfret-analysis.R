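#' Compute AmFRET for every event
#'
#' AmFRET is the FRET-channel intensity divided by the acceptor intensity, a
#' dimensionless proximity proxy. Events with `acceptor <= 0` cannot be
#' ratioed; they are flagged in `amfret_excluded` (with `amfret = NA`) rather
#' than silently zeroed, and all downstream operations drop them.
#'
#' @param events Event tibble with `fret` and `acceptor` columns.
#' @return `events` with `amfret` and `amfret_excluded` columns appended.
#' @export
compute_amfret <- function(events) {
  if (!all(c("fret", "acceptor") %in% names(events))) {
    abort("`events` must contain `fret` and `acceptor` columns.")
  }
  excluded <- !(events$acceptor > 0) | !is.finite(events$acceptor)
  events$amfret <- ifelse(excluded, NA_real_, events$fret / events$acceptor)
  events$amfret_excluded <- excluded
  events
}

#' Gate events on positivity and an expression window
#'
#' Retains double-positive events (`donor > 0`, `acceptor > 0`) whose acceptor
#' intensity lies within the expression window. Counts in and out are recorded
#' in attributes `n_total` / `n_retained`.
#'
#' @param events Event tibble.
#' @param acceptor_min,acceptor_max Expression window bounds (a.u., inclusive).
#' @return The gated tibble; warns when the result is empty.
#' @export
gate_events <- function(events, acceptor_min = 0, acceptor_max = Inf) {
  if (!all(c("donor", "acceptor") %in% names(events))) {
    abort("`events` must contain `donor` and `acceptor` columns.")
  }
  keep <- events$donor > 0 & events$acceptor > 0 &
    events$acceptor >= acceptor_min & events$acceptor <= acceptor_max
  out <- events[keep & !is.na(keep), , drop = FALSE]
  if (nrow(out) == 0) {
    warn("Gating removed every event; downstream analyses will be empty.")
  }
  attr(out, "n_total") <- nrow(events)
  attr(out, "n_retained") <- nrow(out)
  attr(out, "damfret_params") <- attr(events, "damfret_params")
  out
}

# geometric bin edges over a strictly positive range
geometric_edges <- function(lo, hi, n_bins) {
  if (lo <= 0 || hi <= lo) abort("Binning needs a positive, nondegenerate range.")
  exp(seq(log(lo), log(hi), length.out = n_bins + 1))
}

#' Build a negative DAmFRET gate from a monomer control
#'
#' The monomer control defines, per logarithmic expression bin, the AmFRET
#' boundary below which cells are considered unassembled: the per-bin
#' `quantile` of the control's AmFRET distribution. Bins with fewer than
#' `min_occupancy` control events fall back to the control-wide global
#' quantile, and the fallback is recorded in the gate.
#'
#' @param control Monomer-control event tibble (e.g. an inert fluorophore).
#' @param quantile Upper quantile defining the boundary, in (0.5, 1).
#' @param n_bins Number of logarithmically spaced expression bins.
#' @param min_occupancy Minimum control events per bin for a bin-specific
#'   boundary.
#' @return A `damfret_gate` tibble (one row per bin: `lower`, `upper`,
#'   `center`, `n`, `boundary`, `fallback`) with attributes `quantile`,
#'   `global_boundary` and `acceptor_range`.
#' @export
build_negative_gate <- function(control, quantile = 0.99, n_bins = 64,
                                min_occupancy = 50) {
  if (quantile <= 0.5 || quantile >= 1) {
    abort("`quantile` must lie strictly between 0.5 and 1.")
  }
  control <- compute_amfret(control)
  control <- control[!control$amfret_excluded & control$donor > 0, , drop = FALSE]
  if (nrow(control) == 0) {
    abort("Monomer control is empty after excluding unratioable events.")
  }
  rng <- range(control$acceptor)
  edges <- geometric_edges(rng[1] * (1 - 1e-12), rng[2] * (1 + 1e-12), n_bins)
  idx <- findInterval(control$acceptor, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  global_boundary <- unname(stats::quantile(control$amfret, quantile, type = 7))
  per_bin <- vapply(seq_len(n_bins), function(b) {
    x <- control$amfret[idx == b]
    if (length(x) >= min_occupancy) {
      unname(stats::quantile(x, quantile, type = 7))
    } else NA_real_
  }, numeric(1))
  counts <- tabulate(idx, nbins = n_bins)
  gate <- tibble::tibble(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1)],
    upper = edges[-1],
    center = sqrt(edges[-(n_bins + 1)] * edges[-1]),
    n = counts,
    fallback = is.na(per_bin),
    boundary = ifelse(is.na(per_bin), global_boundary, per_bin)
  )
  attr(gate, "quantile") <- quantile
  attr(gate, "global_boundary") <- global_boundary
  attr(gate, "acceptor_range") <- rng
  class(gate) <- c("damfret_gate", class(gate))
  gate
}

# boundary applicable to each acceptor value; outside the control's range the
# global quantile applies
gate_boundary <- function(gate, acceptor) {
  edges <- c(gate$lower, gate$upper[nrow(gate)])
  idx <- findInterval(acceptor, edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= nrow(gate)
  out <- rep(attr(gate, "global_boundary"), length(acceptor))
  out[inside] <- gate$boundary[idx[inside]]
  out
}

#' Score events against a negative gate
#'
#' @param events Event tibble.
#' @param gate A `damfret_gate` from [build_negative_gate()].
#' @return `events` with `amfret` and a logical `assembled` column (AmFRET
#'   above the negative-gate boundary for that expression bin).
#' @export
score_assembled <- function(events, gate) {
  stopifnot(inherits(gate, "damfret_gate"))
  events <- compute_amfret(events)
  events$assembled <- !events$amfret_excluded &
    events$amfret > gate_boundary(gate, events$acceptor)
  events
}

#' Binned fraction of assembled cells
#'
#' Divides the gated expression (acceptor) range into `n_bins` logarithmically
#' spaced bins and computes, within each, the fraction of cells with AmFRET
#' above the monomer-control boundary. Because the boundary is an upper
#' quantile, a fraction `1 - quantile` of genuinely monomeric cells exceeds it
#' by design; with `background_correct = TRUE` (default) the per-bin fraction
#' is corrected for that known false-positive rate:
#' `fraction = max(0, (raw - fp) / (1 - fp))`.
#'
#' @param events Gated event tibble.
#' @param gate A `damfret_gate`.
#' @param n_bins Number of bins (64 matches the standard analysis).
#' @param background_correct Correct for the gate's design false-positive rate.
#' @return A `damfret_bins` tibble: `bin`, `lower`, `upper`, `center`,
#'   `n_total`, `n_assembled`, `fraction_raw`, `fraction` (NA in empty bins).
#' @export
bin_fraction_assembled <- function(events, gate, n_bins = 64,
                                   background_correct = TRUE) {
  scored <- score_assembled(events, gate)
  scored <- scored[!scored$amfret_excluded & scored$donor > 0, , drop = FALSE]
  if (nrow(scored) == 0) abort("No usable events to bin.")
  rng <- range(scored$acceptor)
  if (rng[1] <= 0) rng[1] <- min(scored$acceptor[scored$acceptor > 0])
  edges <- geometric_edges(rng[1] * (1 - 1e-12), rng[2] * (1 + 1e-12), n_bins)
  idx <- findInterval(scored$acceptor, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  n_total <- tabulate(idx, nbins = n_bins)
  n_assembled <- tabulate(idx[scored$assembled], nbins = n_bins)
  raw <- ifelse(n_total > 0, n_assembled / n_total, NA_real_)
  fp <- 1 - attr(gate, "quantile")
  corrected <- if (background_correct) {
    pmax(0, (raw - fp) / (1 - fp))
  } else raw
  bins <- tibble::tibble(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1)],
    upper = edges[-1],
    center = sqrt(edges[-(n_bins + 1)] * edges[-1]),
    n_total = n_total,
    n_assembled = n_assembled,
    fraction_raw = raw,
    fraction = corrected
  )
  attr(bins, "background_correct") <- background_correct
  attr(bins, "false_positive_rate") <- fp
  class(bins) <- c("damfret_bins", class(bins))
  bins
}

# weighted SSE objective on log-parameters
weibull_objective <- function(theta, center, fraction, weight, fit_plateau) {
  ec50 <- exp(theta[1])
  delta <- exp(theta[2])
  plateau <- if (fit_plateau) stats::plogis(theta[3]) else 1
  resid <- fraction - weibull_response(center, ec50, delta, plateau)
  sum(weight * resid^2)
}

weibull_optimize <- function(center, fraction, weight, fit_plateau,
                             start = NULL) {
  obj <- function(theta) weibull_objective(theta, center, fraction, weight,
                                           fit_plateau)
  starts <- list()
  if (!is.null(start)) starts <- list(start)
  else {
    ec50_grid <- exp(seq(log(min(center)), log(max(center)), length.out = 7))
    delta_grid <- c(0.5, 1, 2, 4, 8, 16)
    for (e in ec50_grid) for (d in delta_grid) {
      starts[[length(starts) + 1]] <-
        if (fit_plateau) c(log(e), log(d), stats::qlogis(0.9))
        else c(log(e), log(d))
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, obj, control = list(iter.max = 500, eval.max = 1000,
                                    rel.tol = 1e-14, x.tol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) abort("Weibull fit failed to converge from any start.")
  # polish with a derivative-free pass then a final gradient pass
  pol <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-15))
  if (pol$value < best$objective) {
    best <- nlminb(pol$par, obj, control = list(rel.tol = 1e-14, x.tol = 1e-14))
    best$objective <- min(best$objective, pol$value)
  }
  best
}

#' Fit the Weibull concentration-response to binned fractions
#'
#' Weighted least squares of
#' `F(c) = plateau * (1 - 2^-(c/EC50)^delta)` on (bin center, fraction), with
#' weights equal to bin occupancy and multi-start optimization over log-EC50
#' and log-delta. `EC50` is the median concentration at which nucleation
#' occurs; `delta` is a dimensionless proxy for the conformational free energy
#' of nucleation (higher = less concentration-dependent).
#'
#' When the overall assembled fraction is below 1% the sample is censored as
#' class `"monomer"`: EC50 and delta are reported as `NA`, never extrapolated.
#'
#' Bootstrap confidence intervals resample events (preserving the bin edges)
#' when `events` and `gate` are supplied and `n_boot > 0`.
#'
#' @param bins A `damfret_bins` tibble from [bin_fraction_assembled()].
#' @param fit_plateau If `TRUE` the plateau is a free parameter (logit scale);
#'   otherwise fixed to 1.
#' @param events,gate Optional: the gated events and gate used to build
#'   `bins`, required for bootstrapping.
#' @param n_boot Number of event-level bootstrap replicates (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return A `damfret_fit` object; see [tidy.damfret_fit()] /
#'   [glance.damfret_fit()].
#' @export
fit_weibull <- function(bins, fit_plateau = FALSE, events = NULL, gate = NULL,
                        n_boot = 0, seed = NULL) {
  stopifnot(inherits(bins, "damfret_bins"))
  occ <- bins[!is.na(bins$fraction) & bins$n_total > 0, , drop = FALSE]
  n_events <- sum(bins$n_total)
  overall <- sum(occ$fraction * occ$n_total) / sum(occ$n_total)
  if (overall < 0.01) {
    fit <- structure(
      list(ec50 = NA_real_, delta = NA_real_, plateau = NA_real_,
           fit_plateau = fit_plateau, class = "monomer", censored = TRUE,
           rss = NA_real_, n_bins_used = nrow(occ), n_events = n_events,
           overall_fraction = overall, convergence = NA_integer_,
           ci = NULL, boot = NULL, bins = bins),
      class = "damfret_fit")
    return(fit)
  }
  if (nrow(occ) < 8 || max(occ$center) / min(occ$center) < 10) {
    abort("Need >= 8 occupied bins spanning more than one decade to fit.")
  }
  best <- weibull_optimize(occ$center, occ$fraction, occ$n_total, fit_plateau)
  ec50 <- exp(best$par[1])
  delta <- exp(best$par[2])
  plateau <- if (fit_plateau) stats::plogis(best$par[3]) else 1
  boot_tbl <- ci <- NULL
  if (n_boot > 0) {
    if (is.null(events) || is.null(gate)) {
      abort("Bootstrapping needs `events` and `gate`.")
    }
    boot_tbl <- bootstrap_weibull(bins, events, gate, fit_plateau,
                                  n_boot, best$par, seed)
    probs <- c(0.025, 0.975)
    ci <- tibble::tibble(
      term = c("ec50", "delta", "plateau"),
      lower = c(stats::quantile(boot_tbl$ec50, probs[1], na.rm = TRUE),
                stats::quantile(boot_tbl$delta, probs[1], na.rm = TRUE),
                stats::quantile(boot_tbl$plateau, probs[1], na.rm = TRUE)),
      upper = c(stats::quantile(boot_tbl$ec50, probs[2], na.rm = TRUE),
                stats::quantile(boot_tbl$delta, probs[2], na.rm = TRUE),
                stats::quantile(boot_tbl$plateau, probs[2], na.rm = TRUE))
    )
  }
  structure(
    list(ec50 = ec50, delta = delta, plateau = plateau,
         fit_plateau = fit_plateau, class = NA_character_, censored = FALSE,
         rss = best$objective, n_bins_used = nrow(occ), n_events = n_events,
         overall_fraction = overall,
         convergence = best$convergence %||% 0L,
         ci = ci, boot = boot_tbl, bins = bins),
    class = "damfret_fit")
}

bootstrap_weibull <- function(bins, events, gate, fit_plateau, n_boot,
                              start, seed) {
  scored <- score_assembled(events, gate)
  scored <- scored[!scored$amfret_excluded & scored$donor > 0, , drop = FALSE]
  edges <- c(bins$lower, bins$upper[nrow(bins)])
  idx <- findInterval(scored$acceptor, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  assembled <- scored$assembled
  fp <- attr(bins, "false_positive_rate")
  correct <- isTRUE(attr(bins, "background_correct"))
  n <- length(idx)
  n_bins <- nrow(bins)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_boot), function(b) {
      take <- sample.int(n, n, replace = TRUE)
      tot <- tabulate(idx[take], nbins = n_bins)
      asm <- tabulate(idx[take][assembled[take]], nbins = n_bins)
      keep <- tot > 0
      frac <- asm[keep] / tot[keep]
      if (correct) frac <- pmax(0, (frac - fp) / (1 - fp))
      fit <- tryCatch(
        nlminb(start, weibull_objective, center = bins$center[keep],
               fraction = frac, weight = tot[keep], fit_plateau = fit_plateau,
               control = list(rel.tol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble::tibble(rep = b, ec50 = NA_real_, delta = NA_real_,
                              plateau = NA_real_))
      }
      tibble::tibble(
        rep = b,
        ec50 = exp(fit$par[1]),
        delta = exp(fit$par[2]),
        plateau = if (fit_plateau) stats::plogis(fit$par[3]) else 1
      )
    })
  })
}

#' @export
print.damfret_fit <- function(x, ...) {
  cat("<damfret_fit>\n")
  if (x$censored) {
    cat("  class: monomer (censored; overall assembled fraction ",
        sprintf("%.3f%%", 100 * x$overall_fraction), ")\n", sep = "")
  } else {
    cat(sprintf("  EC50: %.4g a.u.   delta: %.4g   plateau: %.3g\n",
                x$ec50, x$delta, x$plateau))
    cat(sprintf("  weighted RSS: %.4g on %d bins (%d events)\n",
                x$rss, x$n_bins_used, x$n_events))
    if (!is.null(x$ci)) {
      cat(sprintf("  95%% bootstrap CI: EC50 [%.4g, %.4g], delta [%.4g, %.4g]\n",
                  x$ci$lower[1], x$ci$upper[1], x$ci$lower[2], x$ci$upper[2]))
    }
  }
  invisible(x)
}

#' Tidy a DAmFRET Weibull fit
#'
#' @param x A `damfret_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate` and, when a bootstrap
#'   was run, `conf.low` / `conf.high`.
#' @export
#' @exportS3Method generics::tidy
tidy.damfret_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("ec50", "delta", "plateau"),
    estimate = c(x$ec50, x$delta, x$plateau)
  )
  if (!is.null(x$ci)) {
    out$conf.low <- x$ci$lower
    out$conf.high <- x$ci$upper
  }
  out
}

#' One-row summary of a DAmFRET Weibull fit
#'
#' @param x A `damfret_fit`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::glance
glance.damfret_fit <- function(x, ...) {
  tibble::tibble(
    ec50 = x$ec50, delta = x$delta, plateau = x$plateau,
    class = x$class, censored = x$censored, rss = x$rss,
    n_bins = x$n_bins_used, n_events = x$n_events,
    overall_fraction = x$overall_fraction
  )
}

#' Classify a DAmFRET profile
#'
#' Labels a sample `"monomer"`, `"continuous"` or `"discontinuous"`:
#' * `"monomer"` — overall assembled fraction (net of the gate's design
#'   false-positive rate) below `monomer_max_frac`;
#' * `"discontinuous"` — within the expression decade around the fitted EC50
#'   the AmFRET histogram is bimodal (midpoint-density dip index above
#'   `dip_threshold`) *and* assembled and unassembled cells coexist over a
#'   range of expression of at least `overlap_min_decades` — the
#'   supersaturation signature;
#' * `"continuous"` otherwise (e.g. solubility-limited polymerization with a
#'   sharp concentration threshold, or constitutive oligomers).
#' * `"indeterminate"` — fewer than `min_events` events in the diagnostic
#'   window.
#'
#' @param events Gated event tibble.
#' @param gate A `damfret_gate`.
#' @param fit A `damfret_fit` for the same sample.
#' @param dip_threshold Minimum dip index (1 - density at the inter-mode
#'   midpoint relative to the lower mode density) to call bimodality.
#' @param overlap_min_decades Minimum decades of expression overlap between
#'   assembled and unassembled cells (intersection of their 1%-99% acceptor
#'   quantile ranges). The default 0.1 sits between what sharp
#'   solubility-threshold transitions produce (under 0.05 decades, set by
#'   detection noise around the threshold) and what nucleation-limited
#'   transitions produce (0.15 decades at shape `delta = 6`, rising steeply
#'   as `delta` falls; ~0.4 at the default `delta = 3`).
#' @param monomer_max_frac Maximum net assembled fraction for the monomer call.
#' @param min_events Minimum events required in the diagnostic window.
#' @return A single character label.
#' @export
classify_profile <- function(events, gate, fit, dip_threshold = 0.5,
                             overlap_min_decades = 0.1,
                             monomer_max_frac = 0.01, min_events = 200) {
  scored <- score_assembled(events, gate)
  scored <- scored[!scored$amfret_excluded & scored$donor > 0, , drop = FALSE]
  fp <- 1 - attr(gate, "quantile")
  raw <- mean(scored$assembled)
  net <- max(0, (raw - fp) / (1 - fp))
  if (net < monomer_max_frac || fit$censored) return("monomer")

  window <- c(fit$ec50 / sqrt(10), fit$ec50 * sqrt(10))
  w <- scored[scored$acceptor >= window[1] & scored$acceptor <= window[2], ,
              drop = FALSE]
  if (nrow(w) < min_events) return("indeterminate")

  dip <- 0
  lo_grp <- w$amfret[!w$assembled]
  hi_grp <- w$amfret[w$assembled]
  if (length(lo_grp) >= 20 && length(hi_grp) >= 20) {
    lo_mode <- median(lo_grp)
    hi_mode <- median(hi_grp)
    mid <- (lo_mode + hi_mode) / 2
    d <- density(w$amfret, n = 512)
    dens_at <- function(v) stats::approx(d$x, d$y, xout = v, rule = 2)$y
    ref <- min(dens_at(lo_mode), dens_at(hi_mode))
    if (ref > 0) dip <- 1 - dens_at(mid) / ref
  }

  # 1%/99% quantiles keep the statistic above the gate's false-positive tail
  # (which otherwise drags the assembled group's lower edge far below any
  # genuine coexistence) and above single stray events
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  asm <- scored$acceptor[scored$assembled]
  una <- scored$acceptor[!scored$assembled]
  overlap <- 0
  if (length(asm) > 1 && length(una) > 1) {
    lo <- max(q(asm, 0.01), q(una, 0.01))
    hi <- min(q(asm, 0.99), q(una, 0.99))
    if (hi > lo) overlap <- log10(hi / lo)
  }

  if (dip > dip_threshold && overlap >= overlap_min_decades) {
    "discontinuous"
  } else {
    "continuous"
  }
}

#' Compare Weibull fits between groups of replicates
#'
#' Per-parameter group means and standard deviations, with Welch two-sided
#' t-tests of each group against the reference group. Groups with a single
#' replicate contribute a descriptive row only (no p-value).
#'
#' @param fits List of `damfret_fit` objects (replicates).
#' @param groups Character vector, one group label per fit.
#' @param reference Reference group label; defaults to the first.
#' @return A tibble with `parameter`, `group`, `n`, `mean`, `sd`, `t`,
#'   `p.value`.
#' @export
compare_fits <- function(fits, groups, reference = NULL) {
  stopifnot(length(fits) == length(groups), length(fits) >= 2)
  reference <- reference %||% groups[[1]]
  if (!reference %in% groups) abort("`reference` is not among `groups`.")
  vals <- purrr::map2_dfr(fits, groups, function(f, g) {
    tibble::tibble(group = g, ec50 = f$ec50, delta = f$delta,
                   plateau = f$plateau)
  })
  long <- tidyr::pivot_longer(vals, -"group", names_to = "parameter",
                              values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  ref_vals <- function(param) {
    long$value[long$parameter == param & long$group == reference]
  }
  out <- long |>
    dplyr::group_by(.data$parameter, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, sd(.data$value), NA_real_),
                     .groups = "drop")
  welch <- purrr::pmap(out, function(parameter, group, n, mean, sd) {
    if (group == reference) return(c(t = NA_real_, p = NA_real_))
    x <- long$value[long$parameter == parameter & long$group == group]
    y <- ref_vals(parameter)
    if (length(x) < 2 || length(y) < 2) return(c(t = NA_real_, p = NA_real_))
    if (isTRUE(all.equal(var(c(x, y)), 0)) ||
        (sd(x) == 0 && sd(y) == 0)) {
      if (mean(x) == mean(y)) return(c(t = 0, p = 1))
      return(c(t = Inf, p = 0))
    }
    tt <- tryCatch(t.test(x, y), error = function(e) NULL)
    if (is.null(tt)) return(c(t = NA_real_, p = NA_real_))
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  out$t <- vapply(welch, `[[`, numeric(1), "t")
  out$p.value <- vapply(welch, `[[`, numeric(1), "p")
  out$reference <- out$group == reference
  out
}
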