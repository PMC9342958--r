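# Shared fixture builders; everything is generated in code at test time.

`%||%` <- function(x, y) if (is.null(x)) y else x

aa3_alphabet <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# minimal PDB writer for CA-only synthetic chains
write_pdb_fixture <- function(xyz, aa3, chain = "A", altloc = NULL,
                              resno = seq_along(aa3), path = NULL,
                              skip_ca = integer(0)) {
  path <- path %||% tempfile(fileext = ".pdb")
  lines <- character(0)
  serial <- 0
  for (i in seq_along(aa3)) {
    if (i %in% skip_ca) next
    alts <- altloc[[i]] %||% " "
    for (al in alts) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA %s%s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, al, aa3[i], chain, resno[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

random_chain_xyz <- function(n, sd = 5) {
  matrix(rnorm(n * 3, sd = sd), ncol = 3)
}

rotation_zyz <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

random_rotation <- function() {
  rotation_zyz(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
}

apply_rigid <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2, -trans)
}

# independent superposition oracle: refined grid search over ZYZ Euler angles
# (translation handled in closed form by centering)
grid_search_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  eval_rmsd <- function(al, be, ga) {
    r <- rotation_zyz(al, be, ga)
    sqrt(mean(rowSums((a0 - b0 %*% t(r))^2)))
  }
  best <- c(0, 0, 0)
  best_val <- Inf
  ca <- pi; cb <- pi / 2; cg <- pi
  wa <- pi; wb <- pi / 2; wg <- pi
  for (level in 1:5) {
    for (al in seq(ca - wa, ca + wa, length.out = 17))
      for (be in seq(cb - wb, cb + wb, length.out = 17))
        for (ga in seq(cg - wg, cg + wg, length.out = 17)) {
          v <- eval_rmsd(al, be, ga)
          if (v < best_val) { best_val <- v; best <- c(al, be, ga) }
        }
    ca <- best[1]; cb <- best[2]; cg <- best[3]
    wa <- wa / 7; wb <- wb / 7; wg <- wg / 7
  }
  best_val
}

# standard simulate -> gate -> bin -> fit chain used across tests; the
# expression window excludes the noise-floor regime (10 x additive sd)
analyze_sim <- function(params, control_seed, n_control = params$n_cells,
                        n_bins = 64, quantile = 0.99, fit = TRUE) {
  ev <- simulate_population(params)
  ctl <- simulate_population(damfret_params(
    n_cells = n_control, archetype = "monomer", seed = control_seed))
  acc_min <- 10 * params$noise_floor
  gated <- gate_events(ev, acceptor_min = acc_min)
  gate <- build_negative_gate(gate_events(ctl, acceptor_min = acc_min),
                              quantile = quantile, n_bins = n_bins)
  bins <- bin_fraction_assembled(gated, gate, n_bins = n_bins)
  out <- list(events = ev, gated = gated, gate = gate, bins = bins)
  if (fit) out$fit <- fit_weibull(bins)
  out
}

# noise-free bin table evaluated directly from the Weibull response
noise_free_bins <- function(ec50, delta, plateau = 1, n_bins = 64,
                            lo = 1, hi = 1e4, n_per_bin = 1000L) {
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  centers <- sqrt(edges[-(n_bins + 1)] * edges[-1])
  frac <- weibull_response(centers, ec50, delta, plateau)
  bins <- tibble::tibble(
    bin = seq_len(n_bins), lower = edges[-(n_bins + 1)], upper = edges[-1],
    center = centers, n_total = rep(n_per_bin, n_bins),
    n_assembled = round(frac * n_per_bin),
    fraction_raw = frac, fraction = frac)
  attr(bins, "background_correct") <- FALSE
  attr(bins, "false_positive_rate") <- 0
  class(bins) <- c("damfret_bins", class(bins))
  bins
}
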