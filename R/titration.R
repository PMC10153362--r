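## Sequential two-site and 1:1 binding models: equilibrium species solver,
## synthetic titration generator, least-squares fitting, and
## fluorescence-lifetime energy-transfer arithmetic.

#' Sequential two-site binding model
#'
#' Stepwise macroscopic dissociation constants on the protein dimer:
#' P + L <-> PL (kd1) and PL + L <-> PL2 (kd2). Signal coefficients are
#' per-species responses per unit concentration; for absorbance these are
#' per-chromophore extinction coefficients (PL2 contributes
#' 2 [PL2] eps_pl2), for CD they are per-complex.
#'
#' @param kd1,kd2 dissociation constants, M (> 0).
#' @param signal_coefficients named list; for CD: \code{s_pl}, \code{s_pl2};
#'   for absorbance: \code{eps_free}, \code{eps_pl}, \code{eps_pl2}
#'   (M^-1 cm^-1).
#' @param signal_type "cd" or "absorbance".
#' @return object of class \code{sequential_binding_model}.
#' @export
sequential_binding_model <- function(kd1, kd2,
                                     signal_coefficients = list(s_pl = -0.1e6,
                                                                s_pl2 = 1e6),
                                     signal_type = c("cd", "absorbance")) {
  stopifnot(kd1 > 0, kd2 > 0,
            all(vapply(signal_coefficients, is.finite, logical(1))))
  signal_type <- match.arg(signal_type)
  structure(list(kd1 = kd1, kd2 = kd2,
                 signal_coefficients = signal_coefficients,
                 signal_type = signal_type),
            class = "sequential_binding_model")
}

#' Equilibrium species of the sequential model
#'
#' Solves for free ligand by monotone bracketing (with Newton polish) so that
#' both mass-action laws and both mass balances hold to better than 1e-10
#' relative.
#'
#' @param model \code{sequential_binding_model}.
#' @param protein_total total protein (dimer units), M (>= 0).
#' @param ligand_total total ligand, M (>= 0).
#' @return named list: \code{P}, \code{PL}, \code{PL2}, \code{L} (M).
#' @export
solve_species <- function(model, protein_total, ligand_total) {
  stopifnot(protein_total >= 0, ligand_total >= 0)
  if (ligand_total == 0 || protein_total < 0)
    return(list(P = protein_total, PL = 0, PL2 = 0, L = ligand_total))
  k1 <- model$kd1; k2 <- model$kd2; PT <- protein_total; LT <- ligand_total
  bound <- function(L) {
    denom <- 1 + L / k1 + L^2 / (k1 * k2)
    P <- PT / denom
    PL <- P * L / k1
    PL2 <- PL * L / k2
    list(P = P, PL = PL, PL2 = PL2)
  }
  f <- function(L) { s <- bound(L); L + s$PL + 2 * s$PL2 - LT }
  ## f is strictly increasing in L, f(0) = -LT < 0, f(LT) >= 0
  r <- stats::uniroot(f, c(0, LT), tol = 1e-9 * max(LT, 1e-30), maxiter = 500)
  L <- r$root
  ## Newton polish with the analytic derivative of the conservation residual
  for (it in 1:6) {
    D <- 1 + L / k1 + L^2 / (k1 * k2)
    N <- L / k1 + 2 * L^2 / (k1 * k2)
    Dp <- 1 / k1 + 2 * L / (k1 * k2)
    Np <- 1 / k1 + 4 * L / (k1 * k2)
    fp <- 1 + PT * (Np * D - N * Dp) / D^2
    step <- (L + PT * N / D - LT) / fp
    Lnew <- L - step
    if (!is.finite(Lnew) || Lnew < 0 || Lnew > LT) break
    L <- Lnew
    if (abs(step) < 1e-15 * max(L, 1e-30)) break
  }
  s <- bound(L)
  list(P = s$P, PL = s$PL, PL2 = s$PL2, L = L)
}

## vectorized species curve: safeguarded Newton on free ligand for a whole
## titration series at once (bisection fallback keeps the bracket [0, LT])
.species_curve <- function(model, PT, LT) {
  k1 <- model$kd1; k2 <- model$kd2
  n <- length(LT)
  lo <- rep(0, n); hi <- LT
  L <- pmin(LT, pmax(LT - 2 * PT, LT / 2))
  active <- LT > 0
  for (it in 1:200) {
    if (!any(active)) break
    La <- L[active]
    D <- 1 + La / k1 + La^2 / (k1 * k2)
    N <- La / k1 + 2 * La^2 / (k1 * k2)
    fv <- La + PT * N / D - LT[active]
    Dp <- 1 / k1 + 2 * La / (k1 * k2)
    Np <- 1 / k1 + 4 * La / (k1 * k2)
    fp <- 1 + PT * (Np * D - N * Dp) / D^2
    ## tighten brackets
    lo[active] <- ifelse(fv < 0, La, lo[active])
    hi[active] <- ifelse(fv > 0, La, hi[active])
    step <- fv / fp
    Lnew <- La - step
    bad <- !is.finite(Lnew) | Lnew <= lo[active] | Lnew >= hi[active]
    Lnew[bad] <- (lo[active][bad] + hi[active][bad]) / 2
    done <- abs(Lnew - La) < 1e-15 * pmax(Lnew, 1e-30)
    L[active] <- Lnew
    active[active] <- !done
  }
  D <- 1 + L / k1 + L^2 / (k1 * k2)
  P <- PT / D
  PL <- P * L / k1
  PL2 <- PL * L / k2
  list(P = P, PL = PL, PL2 = PL2, L = L)
}

.model_signal <- function(model, protein_total, ligand_totals, path_length = 1) {
  sc <- model$signal_coefficients
  sp <- .species_curve(model, protein_total, ligand_totals)
  if (model$signal_type == "cd")
    sc$s_pl * sp$PL + sc$s_pl2 * sp$PL2
  else
    path_length * (sc$eps_free * sp$L + sc$eps_pl * sp$PL +
                     2 * sc$eps_pl2 * sp$PL2)
}

#' Simulate a binding titration
#'
#' Noiseless model curve plus Gaussian noise; deterministic per seed.
#'
#' @param model \code{sequential_binding_model}.
#' @param protein_total protein (dimer) concentration, M.
#' @param ligand_totals strictly increasing ligand concentrations, M.
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param seed integer seed.
#' @param path_length cuvette path, cm (absorbance only).
#' @return object of class \code{titration_experiment}.
#' @export
simulate_titration <- function(model, protein_total, ligand_totals,
                               noise_sd = 0, seed = 1, path_length = 1) {
  stopifnot(all(ligand_totals >= 0), !is.unsorted(ligand_totals, strictly = FALSE))
  y <- .model_signal(model, protein_total, ligand_totals, path_length)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  obs <- y + stats::rnorm(length(y), sd = noise_sd)
  structure(list(protein_total = protein_total, ligand_totals = ligand_totals,
                 observed = obs, noiseless = y, path_length = path_length,
                 noise_sd = noise_sd, seed = seed,
                 signal_type = model$signal_type),
            class = "titration_experiment")
}

#' Fit the sequential two-site model to a titration
#'
#' Trust-region least squares (Levenberg-Marquardt) on log-dissociation
#' constants; signal coefficients enter linearly but are fitted jointly. The
#' optimization is multistarted over a small deterministic grid of
#' dissociation-constant starting values (with data-driven coefficient
#' starts) and the lowest-residual solution is returned, which avoids the
#' local optima this correlated five-parameter surface supports.
#'
#' @param exp \code{titration_experiment} (>= 6 points).
#' @param init optional named list of starting values (kd1, kd2 and the
#'   signal coefficients matching the experiment's signal type); when given,
#'   only this single start is used.
#' @return object of class \code{fit_result}: \code{parameters},
#'   \code{residual_norm}, \code{converged}.
#' @export
fit_sequential <- function(exp, init = NULL) {
  stopifnot(inherits(exp, "titration_experiment"),
            length(exp$ligand_totals) >= 6)
  is_cd <- exp$signal_type == "cd"
  PT <- exp$protein_total
  cnames <- if (is_cd) c("s_pl", "s_pl2") else c("eps_free", "eps_pl", "eps_pl2")
  ex <- exp  # the argument shadows base::exp
  inits <- if (!is.null(init)) list(init) else {
    lt <- ex$ligand_totals; obs <- ex$observed
    n <- length(lt)
    ## data-driven coefficient starts: early slope reflects the first bound
    ## species, terminal slope the free ligand (absorbance only)
    slope <- function(idx) {
      if (length(idx) < 2) return(0)
      stats::coef(stats::lm(obs[idx] ~ lt[idx]))[2]
    }
    s_early <- slope(which(lt <= 1.2 * PT))
    s_late <- slope(seq(max(1, n - 4), n))
    out <- list()
    for (k1 in PT * c(0.02, 0.1, 0.5)) for (k2 in PT * c(0.2, 1)) {
      out[[length(out) + 1L]] <- if (is_cd)
        list(kd1 = k1, kd2 = k2, s_pl = 0,
             s_pl2 = max(abs(obs)) / max(PT, 1e-12))
      else
        list(kd1 = k1, kd2 = k2,
             eps_free = max(s_late, 0) / ex$path_length,
             eps_pl = max(s_early, 0) / ex$path_length,
             eps_pl2 = max(abs(obs)) / (2 * PT * ex$path_length))
    }
    out
  }
  resid_fn <- function(par) {
    m <- sequential_binding_model(base::exp(par[1]), base::exp(par[2]),
                                  as.list(stats::setNames(par[-(1:2)], cnames)),
                                  signal_type = if (is_cd) "cd" else "absorbance")
    .model_signal(m, PT, ex$ligand_totals, ex$path_length) - ex$observed
  }
  best <- NULL
  for (ini in inits) {
    par0 <- c(log(ini$kd1), log(ini$kd2), unlist(ini[cnames]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(parameters = NULL, residual_norm = Inf,
                          converged = FALSE, singular = TRUE),
                     class = "fit_result"))
  }
  pars <- unname(best$par)
  out <- c(list(kd1 = base::exp(pars[1]), kd2 = base::exp(pars[2])),
           as.list(stats::setNames(pars[-(1:2)], cnames)))
  structure(list(parameters = out,
                 residual_norm = sqrt(sum(best$fvec^2)),
                 converged = best$info %in% 1:4,
                 singular = FALSE),
            class = "fit_result")
}

#' Closed-form 1:1 bound-complex concentration
#' @param kd dissociation constant, M; @param pt protein total, M;
#' @param lt ligand total, M.
#' @return [PL], M (quadratic solution).
#' @export
one_site_bound <- function(kd, pt, lt) {
  b <- pt + lt + kd
  (b - sqrt(pmax(b * b - 4 * pt * lt, 0))) / 2
}

#' Fit a 1:1 binding model (protein monomer + ligand)
#'
#' @param exp \code{titration_experiment}; the observed signal is modeled as
#'   s_bound [PL] (+ s_free [L] for absorbance-type data).
#' @param init optional list (kd, s_bound, s_free).
#' @return \code{fit_result}.
#' @export
fit_one_site <- function(exp, init = NULL) {
  stopifnot(inherits(exp, "titration_experiment"),
            length(exp$ligand_totals) >= 6)
  PT <- exp$protein_total; LT <- exp$ligand_totals
  with_free <- exp$signal_type == "absorbance"
  if (is.null(init)) {
    scale <- max(abs(exp$observed)) / max(PT, 1e-12)
    init <- list(kd = PT / 2, s_bound = scale, s_free = if (with_free) scale / 4 else 0)
  }
  par0 <- c(log(init$kd), init$s_bound, if (with_free) init$s_free)
  ex <- exp
  resid_fn <- function(par) {
    pl <- one_site_bound(base::exp(par[1]), PT, LT)
    y <- par[2] * pl
    if (with_free) y <- y + par[3] * (LT - pl)
    y - ex$observed
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(parameters = NULL, residual_norm = Inf,
                          converged = FALSE, singular = TRUE),
                     class = "fit_result"))
  out <- list(kd = unname(base::exp(fit$par[1])), s_bound = unname(fit$par[2]),
              s_free = if (with_free) unname(fit$par[3]) else NA_real_)
  structure(list(parameters = out, residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = fit$info %in% 1:4, singular = FALSE),
            class = "fit_result")
}

#' Energy-transfer efficiency from donor lifetimes
#'
#' E = 1 - tau_DA / tau_D.
#'
#' @param tau_donor donor-only lifetime, ps (> 0).
#' @param tau_donor_acceptor donor lifetime in presence of the acceptor, ps
#'   (0 < tau_DA <= tau_D).
#' @return efficiency fraction in [0, 1).
#' @export
fret_efficiency <- function(tau_donor, tau_donor_acceptor) {
  stopifnot(tau_donor > 0, tau_donor_acceptor > 0)
  if (tau_donor_acceptor > tau_donor)
    stop("tau_DA exceeds tau_D")
  1 - tau_donor_acceptor / tau_donor
}

#' Amplitude-weighted average lifetime
#' @param amplitudes non-negative weights (positive sum).
#' @param lifetimes lifetimes, ps (same length).
#' @return sum(a * tau) / sum(a), ps.
#' @export
average_lifetime <- function(amplitudes, lifetimes) {
  stopifnot(length(amplitudes) == length(lifetimes), all(amplitudes >= 0))
  if (sum(amplitudes) <= 0) stop("amplitudes sum to zero")
  sum(amplitudes * lifetimes) / sum(amplitudes)
}
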