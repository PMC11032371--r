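# Gas constant in kcal/(mol K)
.R_KCAL <- 1.9872e-3

#' Hyperbolic (one-site equilibrium) SPR response
#'
#' Steady-state response of a 1:1 interaction at analyte concentration `C`:
#' `R = R_max * C / (K_D + C)`. Half-saturation at `C = K_D`.
#'
#' @param C Analyte concentration(s), molar (>= 0).
#' @param K_D Equilibrium dissociation constant, molar (> 0).
#' @param R_max Saturating response, response units.
#' @return Response(s) in RU.
#' @export
spr_response <- function(C, K_D, R_max) {
  stopifnot(all(C >= 0), K_D > 0)
  R_max * C / (K_D + C)
}

#' Fit a saturation equilibrium binding model to SPR plateau responses
#'
#' Nonlinear least squares of `R = R_max * C / (K_D + C)` against plateau
#' (equilibrium) responses; no kinetic model is involved, appropriate when
#' association/dissociation are too fast to resolve. A series whose maximum
#' response does not reach 60% of the fitted `R_max` is flagged as
#' non-saturating (the fitted `K_D` is then poorly constrained upward).
#'
#' @param concentrations Analyte concentrations, molar, strictly increasing.
#' @param responses Plateau responses (RU), same length.
#' @param temperature Kelvin, for the derived free energy (default 298.15,
#'   i.e. 25 C).
#' @return A `binding_fit` with `model = "spr_hyperbolic"`, estimates `K_D`
#'   (molar) and `R_max`, standard errors, `dG` (kcal/mol), warnings flags.
#' @examples
#' C <- c(0.1, 0.3, 1, 3, 10, 30, 100, 300) * 1e-6
#' fit <- fit_spr(C, spr_response(C, 1e-5, 100))
#' coef(fit)
#' @export
fit_spr <- function(concentrations, responses, temperature = 298.15) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 4L) {
    stop("need at least 4 concentrations for a saturation fit", call. = FALSE)
  }
  if (any(diff(concentrations) <= 0) || any(concentrations <= 0)) {
    stop("concentrations must be strictly positive and strictly increasing",
         call. = FALSE)
  }
  if (max(concentrations) / min(concentrations) < 10) {
    stop("concentration series must span at least one decade", call. = FALSE)
  }
  if (max(abs(responses)) < .Machine$double.eps^0.5) {
    stop("no binding detected: responses are all zero", call. = FALSE)
  }
  df <- data.frame(C = concentrations, R = responses)
  rmax0 <- max(responses) * 1.2
  # K_D start: concentration closest to half of the maximal response
  kd0 <- df$C[which.min(abs(df$R - max(df$R) / 2))]
  fit <- minpack.lm::nlsLM(R ~ Rmax * C / (KD + C), data = df,
                           start = list(Rmax = rmax0, KD = kd0),
                           lower = c(0, .Machine$double.xmin),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  warn <- character()
  if (max(responses) < 0.6 * est[["Rmax"]]) {
    warn <- c(warn, "non-saturating series: max response < 60% of fitted R_max")
  }
  new_binding_fit(
    model = "spr_hyperbolic",
    estimates = c(K_D = unname(est[["KD"]]), R_max = unname(est[["Rmax"]])),
    se = c(K_D = unname(se[[2L]]), R_max = unname(se[[1L]])),
    temperature = temperature,
    data = df,
    fitted = as.numeric(stats::fitted(fit)),
    sse = sum(stats::residuals(fit)^2),
    warnings = warn
  )
}

#' Simulate a one-site ITC titration
#'
#' Forward model for injection heats of a single-site binding isotherm with
#' displacement dilution: each injection of volume `v` into a cell of
#' working volume `V0` displaces a fraction `v/V0` of the cell content, so
#' every prior concentration is scaled by `(1 - v/V0)` per injection while
#' the titrant gains `X_s * v/V0`. The bound-complex concentration after
#' injection `i` solves the one-site quadratic
#' \deqn{[ML] = \tfrac12\left[(X_t + N M_t + K_D) -
#'   \sqrt{(X_t + N M_t + K_D)^2 - 4 N M_t X_t}\right]}
#' and the measured heat is
#' `q_i = V0 * dH * ([ML]_i - [ML]_{i-1} * (1 - v/V0))` (kcal), crediting
#' complex lost to displacement. Optional Gaussian noise is reproducible
#' under `seed`.
#'
#' @param K_D Dissociation constant, molar.
#' @param dH Binding enthalpy, kcal/mol.
#' @param N Stoichiometry (sites per macromolecule).
#' @param cell_conc Macromolecule concentration in the cell at start, molar.
#' @param syringe_conc Titrant concentration in the syringe, molar
#'   (conventionally ~10x the cell concentration).
#' @param n_injections Number of injections (default 20).
#' @param injection_volume Volume per injection, litres (default 2e-6, i.e.
#'   2 microlitres).
#' @param cell_volume Cell working volume, litres (default 200e-6).
#' @param temperature Kelvin (default 293).
#' @param noise_sd Gaussian noise sd on each heat, kcal (default 0:
#'   bit-reproducible output).
#' @param seed Optional integer seed for the noise.
#' @return An `itc_experiment`: list with the schedule, `heats` (kcal per
#'   injection), per-injection cell concentrations `M_t`/`X_t` and molar
#'   ratios, and the generating parameters.
#' @export
simulate_itc <- function(K_D, dH, N, cell_conc, syringe_conc,
                         n_injections = 20L, injection_volume = 2e-6,
                         cell_volume = 200e-6, temperature = 293,
                         noise_sd = 0, seed = NULL) {
  stopifnot(K_D > 0, N > 0, cell_conc > 0, syringe_conc > 0,
            injection_volume > 0, cell_volume > 0, n_injections >= 1L)
  f <- injection_volume / cell_volume
  M <- cell_conc
  X <- 0
  ML_prev <- 0
  heats <- numeric(n_injections)
  Mt <- Xt <- ML <- numeric(n_injections)
  for (i in seq_len(n_injections)) {
    M <- M * (1 - f)
    X <- X * (1 - f) + syringe_conc * f
    b <- X + N * M + K_D
    disc <- b^2 - 4 * N * M * X
    if (disc < 0) stop("internal error: negative discriminant in one-site quadratic")
    ml <- (b - sqrt(disc)) / 2
    heats[i] <- cell_volume * dH * (ml - ML_prev * (1 - f))
    Mt[i] <- M; Xt[i] <- X; ML[i] <- ml
    ML_prev <- ml
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    heats <- heats + rnorm(n_injections, 0, noise_sd)
  }
  structure(list(
    heats = heats, injection = seq_len(n_injections),
    molar_ratio = Xt / Mt,
    M_t = Mt, X_t = Xt, ML = ML,
    cell_conc = cell_conc, syringe_conc = syringe_conc,
    n_injections = n_injections, injection_volume = injection_volume,
    cell_volume = cell_volume, temperature = temperature,
    params = c(K_D = K_D, dH = dH, N = N), noise_sd = noise_sd
  ), class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf("<itc_experiment> %d x %.1f ul injections into %.0f ul at %.0f K; cell %.3g M, syringe %.3g M\n",
              x$n_injections, 1e6 * x$injection_volume, 1e6 * x$cell_volume,
              x$temperature, x$cell_conc, x$syringe_conc))
  cat(sprintf("  total heat %.4g kcal over molar ratio %.2f..%.2f\n",
              sum(x$heats), min(x$molar_ratio), max(x$molar_ratio)))
  invisible(x)
}

# forward heats for the fitter (no noise)
.itc_forward <- function(K_D, dH, N, expt) {
  simulate_itc(K_D, dH, N, expt$cell_conc, expt$syringe_conc,
               expt$n_injections, expt$injection_volume, expt$cell_volume,
               expt$temperature)$heats
}

#' Fit a one-site binding isotherm to ITC injection heats
#'
#' Nonlinear least squares of dilution-corrected injection heats against the
#' forward model of [simulate_itc()], estimating `K_D`, `dH` and the
#' stoichiometry `N`. The free energy `dG = R T ln K_D` and entropic term
#' `-TdS = dG - dH` are derived at the experiment temperature. Fits at a
#' Wiseman c-value (`N * M_t0 / K_D`) outside roughly 0.1-1000 are flagged:
#' below, the isotherm has no curvature; above, it is a step function, and
#' `K_D` is poorly determined either way.
#'
#' @param experiment An `itc_experiment` (from [simulate_itc()] or
#'   [read_itc_table()] plus schedule metadata).
#' @param discard_first Drop injection 1 before fitting (common practice for
#'   the diffusion-corrupted first injection; default `FALSE`).
#' @param min_heat Total-|heat| floor (kcal) below which the outcome is
#'   "no binding detected" (default 1e-9 kcal, i.e. about one microcalorie
#'   summed over the titration, well under instrument noise).
#' @return A `binding_fit` with `model = "itc_one_site"`, estimates `K_D`
#'   (molar), `dH` (kcal/mol), `N`, their standard errors, `dG`, `minus_TdS`
#'   and the c-value.
#' @export
fit_itc <- function(experiment, discard_first = FALSE, min_heat = 1e-9) {
  q <- experiment$heats
  keep <- seq_along(q)
  if (discard_first) keep <- keep[-1L]
  if (length(keep) < 10L) {
    stop("need at least 10 injections for a one-site fit", call. = FALSE)
  }
  if (sum(abs(q[keep])) < min_heat) {
    stop("no binding detected: injection heats indistinguishable from zero",
         call. = FALSE)
  }
  # starting values: dH from the first injections (near-complete binding when
  # c is high), N from the molar ratio at the heat midpoint, K_D from scale
  mol_inj <- experiment$syringe_conc * experiment$injection_volume
  dh0 <- q[keep[1L]] / mol_inj
  cum <- cumsum(abs(q[keep]))
  mid <- which.min(abs(cum - max(cum) / 2))
  n0 <- max(0.2, experiment$X_t[keep[mid]] / experiment$M_t[keep[mid]])
  kd0 <- experiment$cell_conc / 2

  obj <- function(p) {
    pred <- .itc_forward(exp(p[1L]), p[2L], exp(p[3L]), experiment)
    pred[keep] - q[keep]
  }
  start <- c(log(kd0), dh0, log(n0))
  fit <- minpack.lm::nls.lm(par = start, fn = obj,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0L, 9L)) {
    stop(sprintf("ITC fit did not converge (last iterate K_D=%.3g, dH=%.3g, N=%.3g; SSE=%.3g)",
                 exp(fit$par[1L]), fit$par[2L], exp(fit$par[3L]),
                 fit$deviance), call. = FALSE)
  }
  p <- fit$par
  est <- c(K_D = exp(p[1L]), dH = p[2L], N = exp(p[3L]))
  # standard errors on the log scale from the fit, delta method back to the
  # natural scale; NA when the information matrix is singular (e.g. exact data)
  se <- tryCatch({
    raw <- summary(fit)$coefficients[, "Std. Error"]
    c(est[["K_D"]] * raw[1L], raw[2L], est[["N"]] * raw[3L])
  }, error = function(e) rep(NA_real_, 3))
  warn <- character()
  cval <- est[["N"]] * experiment$cell_conc / est[["K_D"]]
  if (cval < 0.1 || cval > 1000) {
    warn <- c(warn, sprintf("c-value %.3g outside [0.1, 1000]: K_D poorly determined", cval))
  }
  new_binding_fit(
    model = "itc_one_site",
    estimates = est,
    se = c(K_D = se[[1L]], dH = se[[2L]], N = se[[3L]]),
    temperature = experiment$temperature,
    data = data.frame(injection = experiment$injection[keep], heat = q[keep]),
    fitted = .itc_forward(est[["K_D"]], est[["dH"]], est[["N"]], experiment)[keep],
    sse = fit$deviance,
    warnings = warn,
    extra = list(c_value = cval, experiment = experiment)
  )
}

#' Thermodynamic bookkeeping for a binding fit or a transcribed table row
#'
#' Computes `dG = R T ln(K_D)` (K_D in molar, R = 1.9872e-3 kcal/(mol K))
#' and `-TdS = dG - dH`, and, when an independent `dG` or `-TdS` is supplied
#' (e.g. transcribed from a published table), the consistency residual
#' `|dH + (-TdS) - dG|` — published rows are rounded and occasionally
#' inconsistent, so the residual is reported rather than asserted.
#'
#' @param K_D Dissociation constant, molar (or a `binding_fit`).
#' @param dH Enthalpy, kcal/mol (ignored when `K_D` is a fit).
#' @param temperature Kelvin.
#' @param dG_stated,minus_TdS_stated Optional transcribed values for the
#'   residual check.
#' @return List with `dG`, `dH`, `minus_TdS`, `temperature`, and
#'   `consistency_residual` (0 by construction when nothing is transcribed).
#' @export
thermo_table <- function(K_D, dH = NA_real_, temperature = 298.15,
                         dG_stated = NULL, minus_TdS_stated = NULL) {
  if (inherits(K_D, "binding_fit")) {
    fit <- K_D
    K_D <- fit$estimates[["K_D"]]
    dH <- if ("dH" %in% names(fit$estimates)) fit$estimates[["dH"]] else NA_real_
    temperature <- fit$temperature
  }
  stopifnot(K_D > 0)
  dG <- .R_KCAL * temperature * log(K_D)
  minus_TdS <- dG - dH
  resid <- 0
  if (!is.null(dG_stated) || !is.null(minus_TdS_stated)) {
    dGc <- if (is.null(dG_stated)) dG else dG_stated
    mts <- if (is.null(minus_TdS_stated)) minus_TdS else minus_TdS_stated
    resid <- abs(dH + mts - dGc)
  }
  list(dG = dG, dH = dH, minus_TdS = minus_TdS, temperature = temperature,
       consistency_residual = resid)
}

#' Affinity fold change between two constructs
#'
#' `K_D_reference / K_D_comparison`: values above 1 mean the comparison
#' construct binds tighter (lower K_D) than the reference.
#'
#' @param K_D_reference,K_D_comparison Dissociation constants (same units).
#' @return Dimensionless ratio.
#' @export
fold_change <- function(K_D_reference, K_D_comparison) {
  stopifnot(K_D_reference > 0, K_D_comparison > 0)
  K_D_reference / K_D_comparison
}

#' Read a two-column TSV of SPR concentrations and responses
#'
#' @param file TSV with header columns `concentration` (molar) and
#'   `response` (RU).
#' @return `data.frame` with those columns, sorted by concentration.
#' @export
read_spr_table <- function(file) {
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("concentration", "response") %in% names(df))) {
    stop("SPR table needs columns 'concentration' and 'response'", call. = FALSE)
  }
  df <- df[order(df$concentration), c("concentration", "response")]
  rownames(df) <- NULL
  df
}

#' Read a two-column TSV of ITC injection heats
#'
#' @param file TSV with header columns `injection` and `heat` (kcal),
#'   dilution-corrected.
#' @return `data.frame` with those columns.
#' @export
read_itc_table <- function(file) {
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("injection", "heat") %in% names(df))) {
    stop("ITC table needs columns 'injection' and 'heat'", call. = FALSE)
  }
  df[, c("injection", "heat")]
}
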