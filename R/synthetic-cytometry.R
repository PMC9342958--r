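#' Parameters for a synthetic DAmFRET population
#'
#' Bundles every knob of the single-cell event generator. The defaults describe
#' one flow sample as the assay collects it: ~500,000 events spanning four
#' decades of expression (plasmid copy-number variation), a partially
#' photoconverted green-to-red fluorophore, and a bimodal AmFRET readout in
#' which monomer-only and polymer-containing cells overlap in expression.
#'
#' Archetypes:
#' * `"monomer"` — never assembles (e.g. an inert fluorophore control).
#' * `"constitutive_oligomer"` — assembled with probability `plateau` at all
#'   expression levels (no nucleation barrier).
#' * `"threshold_polymer"` — assembles deterministically above `c_star`
#'   (solubility-limited polymerization with a negligible barrier).
#' * `"nucleated_polymer"` — assembles with probability
#'   `plateau * (1 - 2^-(c/ec50)^delta)`, the Weibull response used throughout
#'   the package, so `ec50` is literally the median concentration at which
#'   nucleation occurs and `delta` is the dimensionless shape parameter.
#'
#' @param n_cells Number of events to draw.
#' @param c_min,c_max Log-uniform expression sampling range, arbitrary
#'   concentration units (a.u.).
#' @param photoconversion Fraction of molecules photoconverted to the FRET
#'   acceptor form, in (0, 1).
#' @param archetype Assembly archetype, see Details.
#' @param ec50,delta Weibull median and shape for `"nucleated_polymer"`.
#' @param c_star Threshold concentration for `"threshold_polymer"` (a.u.).
#' @param plateau Responsive fraction at saturating expression, in (0, 1].
#' @param amfret_low_mean,amfret_low_sd,amfret_high_mean,amfret_high_sd
#'   Moments of the AmFRET distributions of unassembled / assembled cells
#'   (dimensionless).
#' @param noise_floor Additive per-channel Gaussian noise sd (intensity a.u.).
#' @param detection_sdlog sdlog of the mean-one multiplicative lognormal
#'   detection noise applied to each channel.
#' @param acceptor_gain,donor_gain Channel gains converting concentration to
#'   intensity a.u.
#' @param donor_loss Fractional donor quenching per unit AmFRET (FRET transfers
#'   energy out of the donor channel).
#' @param seeded If `TRUE`, a nucleating seed is present in trans: every cell
#'   above `saturation_onset` assembles regardless of its nucleation
#'   probability (monomer archetype excepted; it cannot polymerize).
#' @param saturation_onset Concentration above which seeds act. Defaults to
#'   `ec50 / 10` (nucleated) or `c_star / 10` (threshold): supersaturation
#'   begins well below the spontaneous nucleation midpoint.
#' @param label Construct label stored in the table metadata.
#' @param seed Integer RNG seed; a fixed seed reproduces the event table
#'   bit-identically.
#'
#' @return An object of class `damfret_params` (a validated list).
#' @examples
#' p <- damfret_params(n_cells = 1000, seed = 1)
#' ev <- simulate_population(p)
#' @export
damfret_params <- function(n_cells = 5e5,
                           c_min = 1,
                           c_max = 1e4,
                           photoconversion = 0.1,
                           archetype = c("nucleated_polymer", "monomer",
                                         "constitutive_oligomer",
                                         "threshold_polymer"),
                           ec50 = 100,
                           delta = 3,
                           c_star = 100,
                           plateau = 1,
                           amfret_low_mean = 0,
                           amfret_low_sd = 0.04,
                           amfret_high_mean = 0.6,
                           amfret_high_sd = 0.08,
                           noise_floor = 2,
                           detection_sdlog = 0.05,
                           acceptor_gain = 10,
                           donor_gain = 10,
                           donor_loss = 0.5,
                           seeded = FALSE,
                           saturation_onset = NULL,
                           label = "construct",
                           seed = NULL) {
  archetype <- match.arg(archetype)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0) {
    abort("`n_cells` must be a single nonnegative number.")
  }
  stop_if_not_number(c_min, "c_min", positive = TRUE)
  stop_if_not_number(c_max, "c_max", positive = TRUE)
  if (c_min > c_max) abort("`c_min` must be <= `c_max`.")
  stop_if_not_number(photoconversion, "photoconversion")
  if (photoconversion <= 0 || photoconversion >= 1) {
    abort("`photoconversion` must lie strictly between 0 and 1.")
  }
  stop_if_not_number(plateau, "plateau")
  if (plateau <= 0 || plateau > 1) abort("`plateau` must lie in (0, 1].")
  if (archetype == "nucleated_polymer") {
    stop_if_not_number(ec50, "ec50", positive = TRUE)
    stop_if_not_number(delta, "delta")
    if (delta < 0) abort("`delta` must be >= 0.")
  }
  if (archetype == "threshold_polymer") {
    stop_if_not_number(c_star, "c_star", positive = TRUE)
  }
  if (amfret_high_mean <= amfret_low_mean) {
    abort("`amfret_high_mean` must exceed `amfret_low_mean`.")
  }
  if (is.null(saturation_onset)) {
    saturation_onset <- switch(archetype,
      nucleated_polymer = ec50 / 10,
      threshold_polymer = c_star / 10,
      c_min
    )
  }
  structure(
    list(
      n_cells = as.integer(n_cells), c_min = c_min, c_max = c_max,
      photoconversion = photoconversion, archetype = archetype,
      ec50 = ec50, delta = delta, c_star = c_star, plateau = plateau,
      amfret_low_mean = amfret_low_mean, amfret_low_sd = amfret_low_sd,
      amfret_high_mean = amfret_high_mean, amfret_high_sd = amfret_high_sd,
      noise_floor = noise_floor, detection_sdlog = detection_sdlog,
      acceptor_gain = acceptor_gain, donor_gain = donor_gain,
      donor_loss = donor_loss, seeded = isTRUE(seeded),
      saturation_onset = saturation_onset, label = label,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "damfret_params"
  )
}

#' @export
print.damfret_params <- function(x, ...) {
  cat("<damfret_params> archetype:", x$archetype,
      " n_cells:", x$n_cells,
      " range: [", x$c_min, ",", x$c_max, "] a.u.\n")
  if (x$archetype == "nucleated_polymer") {
    cat("  ec50:", x$ec50, " delta:", x$delta, " plateau:", x$plateau, "\n")
  }
  invisible(x)
}

#' Sample single-cell expression levels
#'
#' Draws `n` concentrations log-uniformly on `[c_min, c_max]`, emulating the
#' broad plasmid copy-number variation that lets one sample cover the full
#' expression axis.
#'
#' @param params A [damfret_params()] object.
#' @param n Number of draws; defaults to `params$n_cells`.
#' @return Numeric vector of concentrations (a.u.).
#' @export
sample_expression <- function(params, n = params$n_cells) {
  stopifnot(inherits(params, "damfret_params"))
  if (n == 0) return(numeric(0))
  with_seed(params$seed, {
    exp(runif(n, log(params$c_min), log(params$c_max)))
  })
}

#' Weibull concentration-response
#'
#' `plateau * (1 - 2^-(c/ec50)^delta)`: the parameterization used for both
#' generation and fitting, chosen so that the response equals `plateau / 2`
#' exactly at `c = ec50` — the median concentration at which nucleation occurs.
#'
#' @param c Concentration(s), must be > 0.
#' @param ec50 Median concentration (a.u.).
#' @param delta Dimensionless shape; larger values make nucleation less
#'   concentration-dependent (more conformationally limited).
#' @param plateau Saturating response fraction.
#' @return Probability in `[0, plateau]`, vectorized over `c`.
#' @export
weibull_response <- function(c, ec50, delta, plateau = 1) {
  plateau * (1 - 2^(-((c / ec50)^delta)))
}

#' Per-cell assembly probability under an archetype
#'
#' @param c Concentration(s), strictly positive.
#' @param params A [damfret_params()] object.
#' @return Probability vector, same length as `c`.
#' @export
assembly_probability <- function(c, params) {
  stopifnot(inherits(params, "damfret_params"))
  if (length(c) && any(!is.finite(c) | c <= 0)) {
    abort("`c` must be strictly positive and finite.")
  }
  switch(params$archetype,
    monomer = rep(0, length(c)),
    constitutive_oligomer = rep(params$plateau, length(c)),
    threshold_polymer = params$plateau * as.numeric(c > params$c_star),
    nucleated_polymer = weibull_response(c, params$ec50, params$delta,
                                         params$plateau)
  )
}

# lognormal draws parameterized by arithmetic mean / sd; degenerate cases
# (mean 0 -> all zero, sd 0 -> constant) handled exactly.
rlnorm_ms <- function(n, mean, sd) {
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

# mean-one multiplicative detection noise
detection_noise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  rlnorm(n, -sdlog^2 / 2, sdlog)
}

#' Simulate a DAmFRET event table
#'
#' Generates one flow sample. Each cell draws a concentration, assembles with
#' its archetype's probability (or deterministically above the saturation
#' onset when a seed is supplied in trans), and emits donor, acceptor and FRET
#' channel intensities: `acceptor ~ p * c * gain`,
#' `donor ~ (1 - p) * c * gain * (1 - loss * AmFRET)`,
#' `fret = AmFRET_true * acceptor`, each carrying mean-one lognormal detection
#' noise plus an additive Gaussian floor, clamped at zero. The AmFRET of
#' unassembled and assembled cells comes from well-separated low/high
#' components, so intermediate-AmFRET cells are rare by construction.
#'
#' @param params A [damfret_params()] object.
#' @return A tibble with columns `conc`, `donor`, `acceptor`, `fret`,
#'   `amfret_true`, `truth_assembled` and attribute `damfret_params`. `conc`,
#'   `amfret_true` and `truth_assembled` are synthetic ground truth that real
#'   cytometry lacks.
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "damfret_params"))
  n <- params$n_cells
  tab <- with_seed(params$seed, {
    conc <- if (n == 0) numeric(0) else {
      exp(runif(n, log(params$c_min), log(params$c_max)))
    }
    p_assemble <- assembly_probability(conc, params)
    assembled <- runif(n) < p_assemble
    if (params$seeded && params$archetype != "monomer") {
      assembled <- assembled | (conc > params$saturation_onset)
    }
    amfret_true <- ifelse(
      assembled,
      rnorm(n, params$amfret_high_mean, params$amfret_high_sd),
      rnorm(n, params$amfret_low_mean, params$amfret_low_sd)
    )
    p <- params$photoconversion
    acceptor <- pmax(0,
      p * conc * params$acceptor_gain *
        detection_noise(n, params$detection_sdlog) +
        rnorm(n, 0, params$noise_floor))
    donor <- pmax(0,
      (1 - p) * conc * params$donor_gain *
        (1 - params$donor_loss * pmax(amfret_true, 0)) *
        detection_noise(n, params$detection_sdlog) +
        rnorm(n, 0, params$noise_floor))
    fret <- pmax(0, amfret_true * acceptor + rnorm(n, 0, params$noise_floor))
    tibble::tibble(
      conc = conc, donor = donor, acceptor = acceptor, fret = fret,
      amfret_true = amfret_true, truth_assembled = assembled
    )
  })
  attr(tab, "damfret_params") <- params
  tab
}

#' Attach a binary transcriptional reporter
#'
#' Draws a reporter intensity for every event: lognormal with the ON moments
#' for assembled cells, OFF moments otherwise. The ON distribution is
#' independent of expression and of any dose covariate — stimulation changes
#' the probability, not the magnitude, of activation.
#'
#' @param events Event tibble carrying a `truth_assembled` column.
#' @param on_mean,on_sd Arithmetic mean / sd of the ON reporter distribution.
#' @param off_mean,off_sd Moments of the OFF distribution; `off_mean = 0`
#'   yields exactly zero.
#' @param seed Optional RNG seed.
#' @return `events` with a `reporter` column appended.
#' @export
attach_reporter <- function(events, on_mean = 1000, on_sd = 250,
                            off_mean = 20, off_sd = 10, seed = NULL) {
  if (!"truth_assembled" %in% names(events)) {
    abort("`events` must carry `truth_assembled` to attach a reporter.")
  }
  n <- nrow(events)
  with_seed(seed, {
    on <- rlnorm_ms(n, on_mean, on_sd)
    off <- rlnorm_ms(n, off_mean, off_sd)
    events$reporter <- ifelse(events$truth_assembled, on, off)
  })
  events
}
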