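test_that("wavelength/wavenumber conversions and band arithmetic", {
  expect_equal(wavelength_to_wavenumber(1000), 10000)
  expect_equal(wavelength_to_wavenumber(668), 14970.06, tolerance = 1e-6)
  expect_equal(wavenumber_to_wavelength(wavelength_to_wavenumber(613.7)), 613.7)
  expect_error(wavelength_to_wavenumber(0))
  cb <- coupling_from_band_positions(668, 690)
  expect_equal(round(cb$splitting_cm1), 477)
  expect_equal(round(cb$coupling_cm1), 239)
  expect_equal(coupling_from_band_positions(650, 650),
               list(splitting_cm1 = 0, coupling_cm1 = 0))
  cb2 <- coupling_from_band_positions(650, 700)
  expect_equal(cb2$splitting_cm1, 1098.9, tolerance = 1e-4)
  expect_equal(cb2$coupling_cm1, 549.45, tolerance = 1e-4)
})

test_that("point-dipole coupling matches SI-constant oracles", {
  mk <- function(center, dir) chromophore_site(center, 14970, 5, dir)
  ## parallel side-by-side at 1 nm: kappa = 1
  expect_equal(point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, 1)),
                                     mk(c(10, 0, 0), c(0, 0, 1))),
               126.0, tolerance = 0.01)
  ## head-to-tail collinear: kappa = -2
  expect_equal(point_dipole_coupling(mk(c(0, 0, 0), c(1, 0, 0)),
                                     mk(c(10, 0, 0), c(1, 0, 0))),
               -252.0, tolerance = 0.01)
  ## mutually orthogonal, one perpendicular to R, the other perpendicular to both
  expect_equal(point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, 1)),
                                     mk(c(10, 0, 0), c(0, 1, 0))),
               0, tolerance = 1e-12)
  ## screening scales linearly; flipping one dipole negates V
  v1 <- point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, 1)),
                              mk(c(7, 2, 0), c(0, 1, 1) / sqrt(2)))
  expect_equal(point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, 1)),
                                     mk(c(7, 2, 0), c(0, 1, 1) / sqrt(2)),
                                     screening = 0.7), 0.7 * v1)
  expect_equal(point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, -1)),
                                     mk(c(7, 2, 0), c(0, 1, 1) / sqrt(2))), -v1)
  expect_error(point_dipole_coupling(mk(c(0, 0, 0), c(0, 0, 1)),
                                     mk(c(0, 0, 0), c(0, 0, 1))), "coincide")
})

test_that("degenerate dimers split to E +/- |V| with symmetric coefficients", {
  s <- lapply(list(c(0, 0, 0), c(10, 0, 0)), function(p)
    chromophore_site(p, 14970, 5, c(0, 0, 1)))
  sys <- exciton_system(s, matrix(c(0, 239, 239, 0), 2))
  st <- diagonalize(sys)
  expect_equal(st[[1]]$energy, 14731)
  expect_equal(st[[2]]$energy, 15209)
  expect_equal(abs(st[[1]]$coefficients), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  ## V = 0: localized states at the site energies
  s2 <- list(chromophore_site(c(0, 0, 0), 14000, 5, c(0, 0, 1)),
             chromophore_site(c(10, 0, 0), 15000, 5, c(0, 1, 0)))
  st0 <- diagonalize(exciton_system(s2, matrix(0, 2, 2)))
  expect_equal(vapply(st0, `[[`, 0, "energy"), c(14000, 15000))
  expect_equal(max(abs(abs(st0[[1]]$coefficients) - c(1, 0))), 0, tolerance = 1e-9)
})

test_that("2x2 closed form matches the eigensolver on random dimers", {
  set.seed(71)
  for (rep in 1:20) {
    e <- runif(2, 12000, 18000); v <- runif(1, -500, 500)
    s <- lapply(1:2, function(i)
      chromophore_site(c(10 * i, 0, 0), e[i], 4, c(0, 0, 1)))
    st <- diagonalize(exciton_system(s, matrix(c(0, v, v, 0), 2)))
    mean_e <- mean(e); half <- sqrt(((e[1] - e[2]) / 2)^2 + v^2)
    expect_equal(st[[1]]$energy, mean_e - half, tolerance = 1e-9)
    expect_equal(st[[2]]$energy, mean_e + half, tolerance = 1e-9)
    ## trace conservation
    expect_equal(sum(vapply(st, `[[`, 0, "energy")), sum(e), tolerance = 1e-6)
  }
})

test_that("dipole strengths are conserved and split as the closed form predicts", {
  set.seed(73)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    s <- lapply(1:n, function(i)
      chromophore_site(rnorm(3, sd = 8) + 15 * i, runif(1, 13000, 16000),
                       runif(1, 2, 6), rnorm(3)))
    st <- diagonalize(exciton_system(s))
    total <- sum(vapply(st, `[[`, 0, "dipole_strength"))
    expect_equal(total, sum(vapply(s, function(x) x$dipole_moment^2, 0)),
                 tolerance = 1e-9)
  }
  ## parallel side-by-side: in-phase state carries 2 mu^2, out-of-phase 0
  s <- lapply(list(c(0, 0, 0), c(10, 0, 0)), function(p)
    chromophore_site(p, 14970, 5, c(0, 0, 1)))
  st <- diagonalize(exciton_system(s))
  ds <- vapply(st, `[[`, 0, "dipole_strength")
  expect_equal(sort(ds), c(0, 50), tolerance = 1e-9)
})

test_that("identical-site dimers give a conservative rotatory couplet", {
  ## chiral arrangement: skewed dipoles
  s <- list(chromophore_site(c(0, 0, 0), 14970, 5, c(0, 0, 1)),
            chromophore_site(c(7, 0, 0), 14970, 5, unitv(c(0, 1, 1))))
  st <- diagonalize(exciton_system(s))
  r <- vapply(st, `[[`, 0, "rotatory_strength")
  expect_gt(max(abs(r)), 0)
  expect_equal(r[1] + r[2], 0,
               tolerance = 1e-9 * max(abs(r)))
  ## coplanar parallel dipoles with in-plane separation: no chirality
  s2 <- list(chromophore_site(c(0, 0, 0), 14970, 5, c(0, 0, 1)),
             chromophore_site(c(7, 0, 0), 14970, 5, c(0, 0, 1)))
  st2 <- diagonalize(exciton_system(s2))
  expect_equal(max(abs(vapply(st2, `[[`, 0, "rotatory_strength"))), 0,
               tolerance = 1e-12)
})

test_that("simulated spectra have the stated lineshape properties", {
  s <- list(chromophore_site(c(0, 0, 0), 14970, 5, c(0, 0, 1)),
            chromophore_site(c(7, 0, 0), 14970, 5, unitv(c(0, 1, 1))))
  st <- diagonalize(exciton_system(s))
  params <- spectrum_params(global_shift_ev = 0,
                            grid_nm = seq(500, 900, by = 0.1))
  ## single state: numerically measured FWHM = 350 cm^-1
  one <- st[1]
  sp1 <- simulate_spectra(one, params)
  half <- max(sp1$absorbance) / 2
  above <- sp1$wavenumber_cm1[sp1$absorbance >= half]
  expect_equal(max(above) - min(above), 350, tolerance = 0.02)
  ## global shift moves the peak by -0.25 eV
  sp_sh <- simulate_spectra(one, spectrum_params(grid_nm = seq(500, 1100, 0.1)))
  peak_sh <- sp_sh$wavenumber_cm1[which.max(sp_sh$absorbance)]
  expect_equal(peak_sh, one[[1]]$energy - 0.25 * 8065.544, tolerance = 2)
  ## CD of the C2 couplet integrates to ~0 relative to its L1 norm
  ## (uniform wavenumber grid for quadrature accuracy)
  pnu <- spectrum_params(global_shift_ev = 0,
                         grid_cm1 = seq(10000, 20000, by = 1))
  spn <- simulate_spectra(st, pnu)
  expect_lt(abs(sum(spn$cd)), 1e-6 * sum(abs(spn$cd)))
  ## linearity: doubling dipole strength doubles the absorbance integral
  w <- abs(c(diff(sp1$wavenumber_cm1), 0))
  one2 <- one
  one2[[1]]$dipole_strength <- 2 * one[[1]]$dipole_strength
  i1 <- sum(simulate_spectra(one, params)$absorbance * w)
  i2 <- sum(simulate_spectra(one2, params)$absorbance * w)
  expect_equal(i2, 2 * i1, tolerance = 1e-9)
  expect_error(simulate_spectra(st, spectrum_params(grid_nm = c(1, 3, 2))))
})

test_that("exciton systems built from placed chlorins reflect the geometry", {
  tpl1 <- build_ideal_chlorin()
  ## C2-related pair
  g <- rigid_transform(diag(3), c(3.6 / 2, 6.7 / 2, 0))
  t1 <- transform_chlorin(tpl1, g)
  t2 <- transform_chlorin(t1, rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0)))
  sys <- qy_sites_from_chlorins(list(t1, t2))
  expect_equal(sys$sites[[1]]$site_energy, sys$sites[[2]]$site_energy)
  expect_equal(abs(sys$coupling_matrix[1, 2]), abs(sys$coupling_matrix[2, 1]))
  ## antiparallel coplanar stacked pair at 0.7 nm: kappa = -1 (dipoles
  ## antiparallel, both perpendicular to R)
  ta <- transform_chlorin(tpl1, rigid_transform(diag(3), c(0, 0, 0)))
  tb <- transform_chlorin(tpl1, rigid_transform(
    rotation_about_axis(c(0, 0, 1), 180), c(0, 0, 7)))
  sysab <- qy_sites_from_chlorins(list(ta, tb), mu = 4.6)
  v_expect <- 5.04 * (-1) * 4.6^2 / 0.7^3
  expect_equal(sysab$coupling_matrix[1, 2], v_expect, tolerance = 1e-6)
  ## far-separated pair couples below 1 cm^-1
  tf <- transform_chlorin(tpl1, rigid_transform(diag(3), c(500, 0, 0)))
  sysf <- qy_sites_from_chlorins(list(t1, tf))
  expect_lt(abs(sysf$coupling_matrix[1, 2]), 1)
  expect_error(qy_sites_from_chlorins(list(t1, t1)), "overlap")
})
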