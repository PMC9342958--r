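#' Write an event table to CSV
#'
#' Canonical interchange format: columns `donor,acceptor,fret` first, then
#' `reporter` / `truth_assembled` when present, then any remaining columns.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  lead <- intersect(c("donor", "acceptor", "fret", "reporter",
                      "truth_assembled"), names(events))
  events <- events[, c(lead, setdiff(names(events), lead)), drop = FALSE]
  readr::write_csv(events, path)
  invisible(path)
}

#' Read an event table
#'
#' Reads CSV or minimal FCS (format inferred from the extension unless given)
#' and maps file columns/parameters onto the canonical channel names. A
#' missing channel raises a mapping error listing the names that are
#' available.
#'
#' @param path Input path.
#' @param format `"auto"`, `"csv"` or `"fcs"`.
#' @param channel_map Named character vector mapping canonical names to file
#'   names, e.g. `c(donor = "FL1-A", acceptor = "FL2-A", fret = "FL3-A")`.
#' @return Event tibble with at least `donor`, `acceptor`, `fret`.
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        channel_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "fcs") "fcs" else "csv"
  }
  tab <- if (format == "fcs") {
    read_fcs(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(channel_map)) {
    for (canon in names(channel_map)) {
      src <- channel_map[[canon]]
      if (!src %in% names(tab)) {
        abort(sprintf("Channel '%s' (mapped to '%s') not found; available: %s",
                      src, canon, paste(names(tab), collapse = ", ")))
      }
      names(tab)[names(tab) == src] <- canon
    }
  }
  required <- c("donor", "acceptor", "fret")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(sprintf("Missing channel(s) %s; available: %s",
                  paste(missing, collapse = ", "),
                  paste(names(tab), collapse = ", ")))
  }
  tibble::as_tibble(tab)
}

#' Write a minimal FCS 3.0 file
#'
#' List-mode, 32-bit float, little-endian; enough structure for the package's
#' own round trip and for import into standard cytometry software. No
#' compensation or analysis segments are written.
#'
#' @param events Event tibble.
#' @param path Output path.
#' @param channels Columns to export as FCS parameters.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path,
                      channels = intersect(c("donor", "acceptor", "fret",
                                             "reporter"), names(events))) {
  if (!length(channels)) abort("No channels to write.")
  dat <- as.matrix(events[, channels, drop = FALSE])
  storage.mode(dat) <- "double"
  n <- nrow(dat); p <- ncol(dat)
  data_bytes <- n * p * 4L
  pad <- function(x, w = 10) formatC(x, width = w, flag = " ")
  kw <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0",
    "$PAR", as.character(p), "$TOT", as.character(n)
  )
  for (i in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", i), channels[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(ceiling(max(dat[, i], 1)),
                                        scientific = FALSE))
  }
  # two-pass offset computation with fixed-width data offsets
  build_text <- function(begin_data, end_data) {
    all_kw <- c(kw, "$BEGINDATA", pad(begin_data), "$ENDDATA", pad(end_data))
    paste0("/", paste(all_kw, collapse = "/"), "/")
  }
  header_len <- 58L
  text0 <- build_text(0, 0)
  text_begin <- header_len
  text_end <- text_begin + nchar(text0) - 1L
  begin_data <- text_end + 1L
  end_data <- begin_data + data_bytes - 1L
  text <- build_text(begin_data, end_data)
  stopifnot(nchar(text) == nchar(text0))
  header <- paste0(
    "FCS3.0    ",
    pad(text_begin, 8), pad(text_end, 8),
    pad(begin_data, 8), pad(end_data, 8),
    pad(0, 8), pad(0, 8)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a minimal FCS file
#'
#' Supports list-mode float32 data as written by [write_fcs()] (FCS 3.0/3.1,
#' little- or big-endian). The event count is cross-checked against the
#' header-declared `$TOT`.
#'
#' @param path Path to an FCS file.
#' @return Tibble, one column per parameter.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (!startsWith(header, "FCS3")) abort("Not an FCS 3.x file.")
  off <- function(i) {
    as.integer(trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8)))
  }
  text_begin <- off(1); text_end <- off(2)
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  parts <- trimws(parts)
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kv <- setNames(vals, toupper(keys))
  if (kv[["$DATATYPE"]] != "F" || kv[["$MODE"]] != "L") {
    abort("Only list-mode float FCS data is supported.")
  }
  p <- as.integer(kv[["$PAR"]])
  n <- as.integer(kv[["$TOT"]])
  begin_data <- as.integer(kv[["$BEGINDATA"]])
  endian <- if (startsWith(kv[["$BYTEORD"]], "1")) "little" else "big"
  seek(con, begin_data)
  raw_vals <- readBin(con, "numeric", n = n * p, size = 4, endian = endian)
  if (length(raw_vals) != n * p) {
    abort(sprintf("Expected %d values (%d events x %d parameters), read %d.",
                  n * p, n, p, length(raw_vals)))
  }
  mat <- matrix(raw_vals, ncol = p, byrow = TRUE)
  nms <- vapply(seq_len(p), function(i) kv[[sprintf("$P%dN", i)]],
                character(1))
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- nms
  attr(out, "fcs_keywords") <- kv
  out
}

#' Run the simulate-analyze pipeline from a configuration
#'
#' Orchestrates the standard workflow: simulate a sample and a monomer
#' control, build the negative gate, bin the assembled fraction, fit the
#' Weibull response, classify the profile, and write every artifact plus a
#' machine-readable manifest of parameters and derived seeds. Identical
#' configurations produce byte-identical numerical outputs.
#'
#' Configuration blocks (list or YAML file): `seed` (global; every stochastic
#' stage receives a seed derived from it), `stages` (subset of
#' `c("simulate", "analyze")`), `simulate` (arguments of [damfret_params()]),
#' `control` (ditto; archetype forced to `"monomer"`), `analyze`
#' (`n_bins`, `quantile`, `min_occupancy`, `n_boot`, `fit_plateau`,
#' `background_correct`, `acceptor_min`, `acceptor_max`; the expression window
#' defaults to excluding acceptor intensities below ten times the generator's
#' additive noise floor, where intensity no longer tracks expression).
#'
#' @param config A list, or path to a YAML file.
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @return Invisibly, a list with `events`, `control`, `gate`, `bins`, `fit`,
#'   `class`, `ec50_conc` (EC50 converted back to concentration units via the
#'   generator's acceptor scaling, when simulate metadata is available),
#'   `manifest`, `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("simulate", "analyze")
  paths <- list()
  emit <- function(name, writer) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p <- file.path(out_dir, name)
      writer(p)
      paths[[name]] <<- p
    }
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  out <- list()
  sim_params <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- derive_seed(seed, 1)
      sim_params <- do.call(damfret_params, sim_args)
      out$events <- simulate_population(sim_params)
      ctl_args <- config$control %||% list()
      ctl_args$archetype <- "monomer"
      ctl_args$seed <- derive_seed(seed, 2)
      ctl_params <- do.call(damfret_params, ctl_args)
      out$control <- simulate_population(ctl_params)
      emit("events.csv", function(p) write_events(out$events, p))
      emit("control.csv", function(p) write_events(out$control, p))
    })
  }
  if ("analyze" %in% stages) {
    run_stage("analyze", {
      if (is.null(out$events)) abort("No events to analyze (run simulate or supply events).")
      az <- config$analyze %||% list()
      # default expression window: exclude the noise-floor-dominated regime
      # (10 x additive noise sd), where acceptor intensity no longer tracks
      # expression and geometric bins would be stretched far below signal
      acc_min <- az$acceptor_min %||%
        if (!is.null(sim_params)) 10 * sim_params$noise_floor else 0
      acc_max <- az$acceptor_max %||% Inf
      gated <- gate_events(out$events, acceptor_min = acc_min,
                           acceptor_max = acc_max)
      out$gate <- build_negative_gate(
        gate_events(out$control, acceptor_min = acc_min,
                    acceptor_max = acc_max),
        quantile = az$quantile %||% 0.99,
        n_bins = az$n_bins %||% 64,
        min_occupancy = az$min_occupancy %||% 50)
      out$bins <- bin_fraction_assembled(
        gated, out$gate, n_bins = az$n_bins %||% 64,
        background_correct = az$background_correct %||% TRUE)
      out$fit <- fit_weibull(
        out$bins, fit_plateau = az$fit_plateau %||% FALSE,
        events = gated, gate = out$gate, n_boot = az$n_boot %||% 0,
        seed = derive_seed(seed, 3))
      out$class <- if (out$fit$censored) "monomer" else {
        classify_profile(gated, out$gate, out$fit)
      }
      out$fit$class <- out$class
      if (!is.null(sim_params) && !out$fit$censored) {
        out$ec50_conc <- out$fit$ec50 /
          (sim_params$photoconversion * sim_params$acceptor_gain)
      }
      emit("bins.csv", function(p) readr::write_csv(out$bins, p))
      emit("fit.json", function(p) {
        jsonlite::write_json(
          list(estimates = glance(out$fit), ci = out$fit$ci,
               class = out$class, ec50_conc = out$ec50_conc),
          p, auto_unbox = TRUE, digits = NA, null = "null")
      })
    })
  }
  manifest <- list(
    package = "nucleokit",
    version = as.character(utils::packageVersion("nucleokit")),
    global_seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 1),
                       control = derive_seed(seed, 2),
                       bootstrap = derive_seed(seed, 3)),
    stages = stages,
    config = config
  )
  out$manifest <- manifest
  emit("manifest.json", function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
  })
  out$paths <- paths
  invisible(out)
}
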