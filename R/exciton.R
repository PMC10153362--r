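## Coupled-oscillator exciton model for chromophore dimers: point-dipole
## couplings, eigenstates, absorbance and circular-dichroism spectra.

#' Wavelength (nm) to wavenumber (cm^-1)
#' @param lambda_nm wavelength, nm (> 0).
#' @export
wavelength_to_wavenumber <- function(lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  1e7 / lambda_nm
}

#' Wavenumber (cm^-1) to wavelength (nm)
#' @param nu_cm wavenumber, cm^-1 (> 0).
#' @export
wavenumber_to_wavelength <- function(nu_cm) {
  if (any(nu_cm <= 0)) stop("wavenumber must be positive")
  1e7 / nu_cm
}

EV_PER_CM1 <- 1 / 8065.544  # eV per cm^-1

#' Qy peak splitting and excitonic coupling from two band positions
#'
#' For a degenerate-site dimer the two exciton bands are split by 2V, so the
#' coupling is half the splitting.
#'
#' @param lambda1_nm,lambda2_nm band positions, nm.
#' @return list with \code{splitting_cm1} and \code{coupling_cm1}.
#' @export
coupling_from_band_positions <- function(lambda1_nm, lambda2_nm) {
  s <- abs(wavelength_to_wavenumber(lambda1_nm) -
             wavelength_to_wavenumber(lambda2_nm))
  list(splitting_cm1 = s, coupling_cm1 = s / 2)
}

#' Chromophore site for the exciton model
#'
#' @param center dipole placement point, Angstrom (3-vector).
#' @param site_energy transition energy, cm^-1 (> 0).
#' @param dipole_moment transition dipole magnitude, Debye (>= 0).
#' @param dipole_direction 3-vector (normalized internally).
#' @return object of class \code{chromophore_site}.
#' @export
chromophore_site <- function(center, site_energy, dipole_moment,
                             dipole_direction) {
  stopifnot(length(center) == 3, site_energy > 0, dipole_moment >= 0)
  structure(list(center = as.numeric(center), site_energy = site_energy,
                 dipole_moment = dipole_moment,
                 dipole_direction = unitv(dipole_direction)),
            class = "chromophore_site")
}

## V = C * s * kappa * mu1 mu2 / R^3, mu in Debye, R in nm, V in cm^-1.
## C = 1 D^2 / (4 pi eps0 hc) in cm^-1 nm^3 D^-2 = 5.04.
PD_COUPLING_CONST <- 5.04

#' Point-dipole excitonic coupling between two sites
#'
#' V = 5.04 s kappa mu1 mu2 / R^3 (cm^-1; mu in Debye, R in nm), with the
#' orientation factor kappa = u1.u2 - 3 (u1.R)(u2.R) and optional screening
#' factor s (default 1).
#'
#' @param s1,s2 \code{chromophore_site}s with distinct centers.
#' @param screening dimensionless screening factor.
#' @return coupling, cm^-1 (signed).
#' @export
point_dipole_coupling <- function(s1, s2, screening = 1) {
  rvec <- s2$center - s1$center
  R_nm <- vnorm(rvec) / 10
  if (R_nm < 1e-6) stop("site centers coincide")
  rhat <- unitv(rvec)
  u1 <- s1$dipole_direction; u2 <- s2$dipole_direction
  kappa <- sum(u1 * u2) - 3 * sum(u1 * rhat) * sum(u2 * rhat)
  PD_COUPLING_CONST * screening * kappa * s1$dipole_moment * s2$dipole_moment /
    R_nm^3
}

#' Exciton system: sites plus coupling matrix
#'
#' @param sites list of >= 2 \code{chromophore_site}.
#' @param coupling_matrix symmetric matrix of couplings, cm^-1, zero diagonal;
#'   if NULL, filled with point-dipole couplings.
#' @param screening screening factor passed to
#'   \code{\link{point_dipole_coupling}} when the matrix is computed.
#' @return object of class \code{exciton_system}.
#' @export
exciton_system <- function(sites, coupling_matrix = NULL, screening = 1) {
  n <- length(sites)
  stopifnot(n >= 2)
  if (is.null(coupling_matrix)) {
    coupling_matrix <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      coupling_matrix[i, j] <- coupling_matrix[j, i] <-
        point_dipole_coupling(sites[[i]], sites[[j]], screening)
  }
  if (max(abs(coupling_matrix - t(coupling_matrix))) > 1e-9)
    stop("coupling matrix not symmetric")
  diag(coupling_matrix) <- 0
  structure(list(sites = sites, coupling_matrix = coupling_matrix),
            class = "exciton_system")
}

#' Diagonalize the exciton Hamiltonian
#'
#' H_ii = site energies, H_ij = couplings. States are returned in increasing
#' energy with orthonormal site coefficients; electric transition dipoles,
#' dipole strengths and rotatory strengths are attached via
#' \code{\link{exciton_dipoles}}.
#'
#' @param system \code{exciton_system}.
#' @return list of exciton states: \code{energy} (cm^-1),
#'   \code{coefficients}, \code{dipole} (Debye 3-vector), \code{dipole_strength}
#'   (D^2), \code{rotatory_strength} (model units: D^2 A cm^-1).
#' @export
diagonalize <- function(system) {
  E <- vapply(system$sites, function(s) s$site_energy, numeric(1))
  H <- system$coupling_matrix
  diag(H) <- E
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  states <- lapply(ord, function(k)
    list(energy = eig$values[k], coefficients = eig$vectors[, k]))
  exciton_dipoles(system, states)
}

#' Attach electric dipoles, dipole and rotatory strengths to exciton states
#'
#' Electric dipole of state k is the coefficient-weighted sum of site dipoles;
#' dipole strength its squared norm. Rotatory strengths use the exciton
#' chirality (coupled-oscillator, length form):
#' R_k = -(pi nu_bar / 2) sum_{i<j} c_ki c_kj R_ij . (mu_i x mu_j), with R_ij
#' in Angstrom, mu in Debye and nu_bar the mean site energy. With the common
#' prefactor, coefficient orthonormality makes the rotatory strengths sum to
#' zero exactly: an identical-site dimer gives an equal and opposite
#' (conservative) couplet.
#'
#' @param system \code{exciton_system}; @param states as from the
#'   eigen-decomposition.
#' @return states with \code{dipole}, \code{dipole_strength},
#'   \code{rotatory_strength} fields added.
#' @export
exciton_dipoles <- function(system, states) {
  n <- length(system$sites)
  mu <- t(vapply(system$sites,
                 function(s) s$dipole_moment * s$dipole_direction, numeric(3)))
  cen <- t(vapply(system$sites, function(s) s$center, numeric(3)))
  nu_bar <- mean(vapply(system$sites, function(s) s$site_energy, numeric(1)))
  lapply(states, function(st) {
    cc <- st$coefficients
    d <- as.numeric(colSums(cc * mu))
    rot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      rij <- cen[j, ] - cen[i, ]
      rot <- rot + cc[i] * cc[j] * sum(rij * cross3(mu[i, ], mu[j, ]))
    }
    st$dipole <- d
    st$dipole_strength <- sum(d * d)
    st$rotatory_strength <- -(pi * nu_bar / 2) * rot
    st
  })
}

#' Spectral simulation parameters
#'
#' @param fwhm_q Gaussian FWHM for Q-band transitions, cm^-1 (default 350).
#' @param fwhm_soret FWHM for Soret-region transitions, cm^-1 (default 1150).
#' @param global_shift_ev rigid spectral shift, eV (default -0.25).
#' @param band_threshold_cm1 transitions above this energy use the Soret
#'   width (default 20000 cm^-1).
#' @param grid_nm wavelength grid, nm (monotone); ignored when
#'   \code{grid_cm1} is given.
#' @param grid_cm1 optional wavenumber grid, cm^-1 (monotone); useful for
#'   quadrature-accurate band integrals.
#' @return object of class \code{spectrum_params}.
#' @export
spectrum_params <- function(fwhm_q = 350, fwhm_soret = 1150,
                            global_shift_ev = -0.25,
                            band_threshold_cm1 = 20000,
                            grid_nm = seq(550, 750, by = 0.25),
                            grid_cm1 = NULL) {
  stopifnot(fwhm_q > 0, fwhm_soret > 0)
  grid <- if (is.null(grid_cm1)) grid_nm else grid_cm1
  if (length(grid) < 2 || !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("grid must be monotone")
  structure(list(fwhm_q = fwhm_q, fwhm_soret = fwhm_soret,
                 global_shift_ev = global_shift_ev,
                 band_threshold_cm1 = band_threshold_cm1,
                 grid_nm = grid_nm, grid_cm1 = grid_cm1),
            class = "spectrum_params")
}

#' Simulate absorbance and CD spectra from exciton states
#'
#' Each state contributes a Gaussian centered at its shifted energy with the
#' band-class FWHM; the band integral (over cm^-1) is proportional to the
#' dipole strength (absorbance) or rotatory strength (CD).
#'
#' @param states as from \code{\link{diagonalize}}.
#' @param params \code{\link{spectrum_params}}.
#' @return data.frame with \code{wavelength_nm}, \code{wavenumber_cm1},
#'   \code{absorbance}, \code{cd}.
#' @export
simulate_spectra <- function(states, params = spectrum_params()) {
  if (is.null(params$grid_cm1)) {
    grid_nm <- params$grid_nm
    if (!(all(diff(grid_nm) > 0) || all(diff(grid_nm) < 0)))
      stop("grid must be monotone")
    nu <- wavelength_to_wavenumber(grid_nm)
  } else {
    nu <- params$grid_cm1
    if (!(all(diff(nu) > 0) || all(diff(nu) < 0)))
      stop("grid must be monotone")
    grid_nm <- wavenumber_to_wavelength(nu)
  }
  absor <- numeric(length(nu)); cd <- numeric(length(nu))
  shift <- params$global_shift_ev / EV_PER_CM1
  for (st in states) {
    center <- st$energy + shift
    fwhm <- if (st$energy > params$band_threshold_cm1) params$fwhm_soret
            else params$fwhm_q
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    gauss <- exp(-(nu - center)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    absor <- absor + st$dipole_strength * gauss
    cd <- cd + st$rotatory_strength * gauss
  }
  data.frame(wavelength_nm = grid_nm, wavenumber_cm1 = nu,
             absorbance = absor, cd = cd)
}

#' Exciton system from a placed chlorin pair
#'
#' Site centers at the metals (ring centers); dipole directions along each
#' template's Qy axis; couplings from the point-dipole model.
#'
#' @param templates list of two placed \code{chlorin_template}s.
#' @param mu Qy transition dipole, Debye (default 4.6).
#' @param site_energy_nm site transition wavelength, nm (default 669).
#' @param screening dielectric screening factor.
#' @return \code{exciton_system}.
#' @export
qy_sites_from_chlorins <- function(templates, mu = 4.6, site_energy_nm = 669,
                                   screening = 1) {
  stopifnot(length(templates) >= 2)
  e <- wavelength_to_wavenumber(site_energy_nm)
  sites <- lapply(templates, function(tpl)
    chromophore_site(tpl$metal$position, e, mu, tpl$qy_axis))
  cen <- t(vapply(sites, function(s) s$center, numeric(3)))
  if (min(stats::dist(cen)) < 1e-6) stop("chromophore centers overlap")
  exciton_system(sites, screening = screening)
}

#' Write a spectrum as two-column text
#' @param spectra data.frame from \code{\link{simulate_spectra}};
#' @param prefix output path prefix (writes \code{<prefix>_abs.txt} and
#'   \code{<prefix>_cd.txt}).
#' @export
write_spectra <- function(spectra, prefix) {
  utils::write.table(spectra[, c("wavelength_nm", "absorbance")],
                     paste0(prefix, "_abs.txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(spectra[, c("wavelength_nm", "cd")],
                     paste0(prefix, "_cd.txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
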