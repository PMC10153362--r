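## shared fixture builders (everything generated in code, no stored data)

random_rotation <- function() {
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
}

random_frame <- function() {
  repeat {
    a <- stats::rnorm(3); b <- stats::rnorm(3); c <- stats::rnorm(3)
    f <- tryCatch(frame_from_residue(a, b, c), error = function(e) NULL)
    if (!is.null(f)) return(f)
  }
}

## a motif geometry that reliably grafts onto the helical fixture
test_motif <- function(...) {
  build_his_chl_motif(chi1 = -60, chi2 = 90, ligation_dihedral = 0,
                      geom = dimer_geometry(3.6, 6.7, 0, 0), ...)
}

## random motif parameters drawn from realistic ranges
random_motif <- function() {
  build_his_chl_motif(
    chi1 = sample(c(-60, 60, 180), 1) + stats::runif(1, -10, 10),
    chi2 = stats::runif(1, -180, 180),
    ligation_dihedral = stats::runif(1, 0, 360),
    geom = dimer_geometry(stack = stats::runif(1, 3.4, 4.2),
                          slip = stats::runif(1, 4, 8),
                          tilt = stats::runif(1, -15, 15),
                          azimuth = stats::runif(1, 0, 360)))
}

## ZYX Euler angles back to a rotation matrix (test-side inverse)
rotation_from_euler_zyx <- function(yaw, pitch, roll) {
  rotation_about_axis(c(0, 0, 1), yaw) %*%
    rotation_about_axis(c(0, 1, 0), pitch) %*%
    rotation_about_axis(c(1, 0, 0), roll)
}
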