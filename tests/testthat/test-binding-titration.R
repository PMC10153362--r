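test_that("species solver obeys mass balance, mass action, and limits", {
  m <- sequential_binding_model(3e-7, 2.5e-6)
  ## no ligand: everything free
  s0 <- solve_species(m, 5e-6, 0)
  expect_equal(s0$P, 5e-6)
  expect_equal(s0$PL + s0$PL2 + s0$L, 0)
  set.seed(83)
  for (rep in 1:50) {
    kd1 <- 10^runif(1, -8, -5); kd2 <- 10^runif(1, -7, -4)
    pt <- 10^runif(1, -7, -4); lt <- pt * runif(1, 0.1, 6)
    mm <- sequential_binding_model(kd1, kd2)
    s <- solve_species(mm, pt, lt)
    expect_lt(abs(s$P + s$PL + s$PL2 - pt) / pt, 1e-10)
    expect_lt(abs(s$L + s$PL + 2 * s$PL2 - lt) / lt, 1e-10)
    expect_lt(abs(s$P * s$L / s$PL - kd1) / kd1, 1e-8)
    expect_lt(abs(s$PL * s$L / s$PL2 - kd2) / kd2, 1e-8)
  }
})

test_that("the sequential solver collapses to the 1:1 quadratic when kd2 is huge", {
  m <- sequential_binding_model(3e-7, 1e6)
  for (lt in c(1e-6, 4e-6, 9e-6)) {
    s <- solve_species(m, 5e-6, lt)
    expect_equal(s$PL, one_site_bound(3e-7, 5e-6, lt), tolerance = 1e-8)
    expect_lt(s$PL2 / max(s$PL, 1e-300), 1e-6)
  }
})

test_that("the solver matches a brute-force grid search over free ligand", {
  set.seed(89)
  for (rep in 1:5) {
    kd1 <- 10^runif(1, -7.5, -6); kd2 <- 10^runif(1, -6.5, -5)
    pt <- 5e-6; lt <- pt * runif(1, 0.5, 4)
    m <- sequential_binding_model(kd1, kd2)
    s <- solve_species(m, pt, lt)
    Lgrid <- seq(0, lt, length.out = 200001)
    resid <- abs(Lgrid * (1 + 0) +
                   (pt / (1 + Lgrid / kd1 + Lgrid^2 / (kd1 * kd2))) *
                   (Lgrid / kd1 + 2 * Lgrid^2 / (kd1 * kd2)) - lt)
    Lbest <- Lgrid[which.min(resid)]
    expect_lt(abs(s$L - Lbest), 2 * lt / 200000)
  }
})

test_that("titration simulation is seeded, exact at zero noise, and monotone", {
  m <- sequential_binding_model(3e-7, 2.5e-6, list(s_pl = 0.2e6, s_pl2 = 1e6))
  lt <- seq(0, 2e-5, length.out = 20)
  t0 <- simulate_titration(m, 5e-6, lt, noise_sd = 0, seed = 1)
  expect_equal(t0$observed, t0$noiseless)
  t1 <- simulate_titration(m, 5e-6, lt, noise_sd = 0.05, seed = 42)
  t2 <- simulate_titration(m, 5e-6, lt, noise_sd = 0.05, seed = 42)
  expect_identical(t1$observed, t2$observed)
  t3 <- simulate_titration(m, 5e-6, lt, noise_sd = 0.05, seed = 43)
  expect_false(identical(t1$observed, t3$observed))
  ## non-negative coefficients give a non-decreasing noiseless curve
  expect_true(all(diff(t0$noiseless) >= -1e-12))
})

test_that("noiseless sequential fits recover the generating parameters", {
  m <- sequential_binding_model(3e-7, 2.5e-6, list(s_pl = -0.1e6, s_pl2 = 1e6))
  lt <- seq(0, 25e-6, length.out = 25)
  te <- simulate_titration(m, 5e-6, lt, noise_sd = 0, seed = 1)
  ft <- fit_sequential(te)
  expect_true(ft$converged)
  expect_equal(ft$parameters$kd1, 3e-7, tolerance = 1e-3)
  expect_equal(ft$parameters$kd2, 2.5e-6, tolerance = 1e-3)
  expect_equal(ft$parameters$s_pl2, 1e6, tolerance = 1e-3)
  ## absorbance flavor
  ma <- sequential_binding_model(1.1e-7, 2e-6,
                                 list(eps_free = 30000, eps_pl = 49900,
                                      eps_pl2 = 38200), "absorbance")
  ta <- simulate_titration(ma, 5e-6, lt, noise_sd = 0, seed = 1)
  fa <- fit_sequential(ta)
  expect_true(fa$converged)
  expect_equal(fa$parameters$kd1, 1.1e-7, tolerance = 1e-3)
  expect_equal(fa$parameters$eps_pl2, 38200, tolerance = 1e-3)
})

test_that("data from a 1:1 system drives the second site empty", {
  ## generate under one-site binding (per-monomer), fit sequentially
  kd <- 4.8e-7; pt <- 5e-6
  lt <- seq(0, 25e-6, length.out = 25)
  pl <- one_site_bound(kd, pt, lt)
  ex <- structure(list(protein_total = pt, ligand_totals = lt,
                       observed = 1e6 * pl, noiseless = 1e6 * pl,
                       path_length = 1, noise_sd = 0, seed = 1,
                       signal_type = "cd"),
                  class = "titration_experiment")
  ft <- fit_sequential(ex)
  sp_end <- solve_species(sequential_binding_model(ft$parameters$kd1,
                                                   ft$parameters$kd2),
                          pt, max(lt))
  contrib_pl2 <- abs(ft$parameters$s_pl2 * sp_end$PL2)
  contrib_pl <- abs(ft$parameters$s_pl * sp_end$PL)
  expect_lt(contrib_pl2, 0.05 * (contrib_pl + contrib_pl2))
})

test_that("one-site fits recover parameters and the stoichiometric limit", {
  kd <- 4.8e-7; pt <- 5e-6
  lt <- seq(0, 25e-6, length.out = 25)
  m1 <- sequential_binding_model(1, 1)  # container only for the generator path
  ex <- structure(list(protein_total = pt, ligand_totals = lt,
                       observed = 2e5 * one_site_bound(kd, pt, lt),
                       path_length = 1, noise_sd = 0, seed = 1,
                       signal_type = "cd"),
                  class = "titration_experiment")
  ft <- fit_one_site(ex)
  expect_true(ft$converged)
  expect_equal(ft$parameters$kd, kd, tolerance = 1e-4)
  expect_equal(ft$parameters$s_bound, 2e5, tolerance = 1e-4)
  ## kd -> 0: stoichiometric break at lt = pt
  pl0 <- one_site_bound(1e-15, pt, lt)
  expect_equal(pl0[lt <= pt], lt[lt <= pt], tolerance = 1e-6)
  expect_equal(pl0[lt > pt], rep(pt, sum(lt > pt)), tolerance = 1e-6)
})

test_that("one-site recovery holds at 2 percent noise", {
  set.seed(97)
  kd <- 4.8e-7; pt <- 5e-6
  lt <- seq(0, 25e-6, length.out = 25)
  y <- 2e5 * one_site_bound(kd, pt, lt)
  kds <- vapply(1:25, function(s) {
    set.seed(s)
    ex <- structure(list(protein_total = pt, ligand_totals = lt,
                         observed = y + rnorm(25, sd = 0.02 * max(y)),
                         path_length = 1, noise_sd = NA, seed = s,
                         signal_type = "cd"),
                    class = "titration_experiment")
    fit_one_site(ex)$parameters$kd
  }, numeric(1))
  expect_lt(abs(median(kds) - kd) / kd, 0.2)
})

test_that("lifetime arithmetic matches the published example", {
  expect_equal(fret_efficiency(2058, 839), 1 - 839 / 2058)
  expect_equal(round(100 * fret_efficiency(2058, 839)), 59)
  expect_equal(fret_efficiency(1000, 1000), 0)
  expect_equal(fret_efficiency(1000, 500), 0.5)
  expect_error(fret_efficiency(800, 900), "exceeds")
  expect_equal(average_lifetime(c(1), c(1234)), 1234)
  expect_equal(average_lifetime(c(1, 1), c(1000, 3000)), 2000)
  expect_equal(average_lifetime(c(5, 5), c(1000, 3000)), 2000)
  expect_error(average_lifetime(c(0, 0), c(1, 2)), "zero")
})
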