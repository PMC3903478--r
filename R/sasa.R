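# Van der Waals radii (Angstrom), Bondi (1964) values for the elements that
# occur in protein structures.  Fixed table, shipped for reproducibility.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20,
  P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

# Deterministic quasi-uniform sphere lattice (golden-section spiral).
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Point-sampling SASA: each heavy atom is inflated by the probe radius,
#' covered with a fixed deterministic sphere lattice, and the fraction of
#' lattice points falling outside all neighbouring inflated spheres gives its
#' accessible area.  No randomness is involved, so results are exactly
#' reproducible for a given `n_points`.  Hydrogens are excluded.
#'
#' @param model A `structure_model`.
#' @param probe Probe (solvent) radius in Angstrom, default 1.4.
#' @param n_points Lattice points per atom, default 960.
#' @return A list of class `sasa_result`: `per_atom` (atom table with an
#'   `area` column, square Angstrom), `per_residue` (tibble `chain`,
#'   `resno`, `ins`, `resname`, `area`), `probe`, `n_points`.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960) {
  stopifnot(probe >= 0, n_points >= 12)
  atoms <- as_tibble(model)
  atoms <- atoms[!atoms$hydrogen, ]
  if (!nrow(atoms)) abort("no heavy atoms in model")
  radii <- VDW_RADII[atoms$element]
  if (any(is.na(radii))) {
    bad <- unique(atoms$element[is.na(radii)])
    abort(paste0("unknown element(s) for SASA radii: ",
                 paste(bad, collapse = ", ")))
  }
  r_inf <- unname(radii) + probe
  pts <- sphere_lattice(n_points)
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  max_r <- max(r_inf)
  # neighbour candidates within the largest possible contact distance
  nb <- grid_cross_pairs(
    tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    2 * max_r)
  nb <- nb[nb$i != nb$j, ]
  nb_list <- split(nb$j, factor(nb$i, levels = seq_len(nrow(atoms))))
  area <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    js <- nb_list[[i]]
    ri <- r_inf[i]
    if (!length(js)) {
      area[i] <- 4 * pi * ri^2
      next
    }
    js <- js[sqrt(rowSums((xyz[js, , drop = FALSE] -
                             matrix(xyz[i, ], length(js), 3,
                                    byrow = TRUE))^2)) < ri + r_inf[js]]
    if (!length(js)) {
      area[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in js) {
      if (!any(free)) break
      d2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- d2 > r_inf[j]^2
    }
    area[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  per_atom <- atoms
  per_atom$area <- area
  per_residue <- per_atom %>%
    group_by(.data$chain, .data$resno, .data$ins, .data$resname) %>%
    summarise(area = sum(.data$area), .groups = "drop")
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> ", nrow(x$per_atom), " atoms, total ",
      sprintf("%.1f", sum(x$per_atom$area)), " A^2 (probe ",
      x$probe, " A, ", x$n_points, " points)\n", sep = "")
  invisible(x)
}

#' Exposure-weighted surface-charge descriptor
#'
#' A desk-scale proxy for qualitative electrostatic-surface comparisons: it
#' sums the solvent-accessible area of exposed acidic (Asp/Glu) and basic
#' (Lys/Arg) residues and reports the balance
#' `(basic - acidic) / (basic + acidic)` in `[-1, 1]`.  Strongly negative
#' values indicate the acid-dominated surface character expected of
#' alkalophilic enzymes.  This descriptor is NOT a Poisson-Boltzmann
#' potential; it only orders structures by exposed-charge composition, and
#' all outputs label it as a proxy.
#'
#' @param model A `structure_model`.
#' @param sasa A `sasa_result` computed on the same model (default: computed
#'   here).
#' @param threshold Minimum per-residue SASA (square Angstrom) for a residue
#'   to count as exposed; default 5.
#' @return One-row tibble: `exposed_acidic_area`, `exposed_basic_area`,
#'   `surface_charge_balance` (`NA` when no charged residue is exposed),
#'   `exposure_threshold`, `descriptor` (`"exposure-weighted proxy"`).
#' @export
surface_charge_summary <- function(model, sasa = compute_sasa(model),
                                   threshold = 5) {
  pr <- sasa$per_residue
  exposed <- pr[pr$area > threshold, ]
  acid <- sum(exposed$area[exposed$resname %in% c("ASP", "GLU")])
  basic <- sum(exposed$area[exposed$resname %in% c("LYS", "ARG")])
  bal <- if (acid + basic > 0) (basic - acid) / (basic + acid) else NA_real_
  tibble(
    exposed_acidic_area = acid,
    exposed_basic_area = basic,
    surface_charge_balance = bal,
    exposure_threshold = threshold,
    descriptor = "exposure-weighted proxy"
  )
}
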