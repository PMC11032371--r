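#' Construct a `binding_fit`
#'
#' Container returned by [fit_spr()] and [fit_itc()]: parameter estimates
#' with standard errors, the data and fitted values, and the derived
#' thermodynamics at the stated temperature (`dG = R T ln K_D`; for ITC
#' additionally `-TdS = dG - dH`).
#'
#' @param model `"spr_hyperbolic"` or `"itc_one_site"`.
#' @param estimates,se Named numeric vectors of estimates and standard
#'   errors (`K_D` in molar).
#' @param temperature Kelvin.
#' @param data,fitted Data used and fitted values.
#' @param sse Residual sum of squares.
#' @param warnings Character vector of fit-quality flags.
#' @param extra Optional list of model-specific extras.
#' @return An object of class `binding_fit`.
#' @keywords internal
#' @export
new_binding_fit <- function(model, estimates, se, temperature, data, fitted,
                            sse, warnings = character(), extra = list()) {
  kd <- estimates[["K_D"]]
  dG <- .R_KCAL * temperature * log(kd)
  minus_TdS <- if ("dH" %in% names(estimates)) dG - estimates[["dH"]] else NA_real_
  structure(list(model = model, estimates = estimates, se = se,
                 temperature = temperature, dG = dG, minus_TdS = minus_TdS,
                 data = data, fitted = fitted, sse = sse,
                 warnings = warnings, extra = extra),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  lbl <- switch(x$model, spr_hyperbolic = "SPR saturation (hyperbolic)",
                itc_one_site = "ITC one-site isotherm", x$model)
  cat(sprintf("<binding_fit> %s at %.2f K\n", lbl, x$temperature))
  cat(sprintf("  K_D = %.4g uM", 1e6 * x$estimates[["K_D"]]))
  if (is.finite(x$se[["K_D"]])) cat(sprintf(" (+/- %.2g)", 1e6 * x$se[["K_D"]]))
  cat("\n")
  if (x$model == "itc_one_site") {
    cat(sprintf("  dH = %.3g kcal/mol, N = %.3g, dG = %.3g, -TdS = %.3g kcal/mol\n",
                x$estimates[["dH"]], x$estimates[["N"]], x$dG, x$minus_TdS))
  } else {
    cat(sprintf("  R_max = %.4g RU, dG = %.3g kcal/mol\n",
                x$estimates[["R_max"]], x$dG))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) object$estimates

#' @export
summary.binding_fit <- function(object, ...) {
  out <- list(model = object$model,
              coefficients = cbind(Estimate = object$estimates,
                                   `Std. Error` = object$se[names(object$estimates)]),
              temperature = object$temperature,
              thermo = thermo_table(object),
              sse = object$sse,
              n = nrow(object$data),
              warnings = object$warnings)
  class(out) <- "summary.binding_fit"
  out
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  cat(sprintf("Model: %s (n = %d, T = %.2f K)\n", x$model, x$n, x$temperature))
  printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("dG = %.3f kcal/mol", x$thermo$dG))
  if (is.finite(x$thermo$minus_TdS)) {
    cat(sprintf(", dH = %.3f, -TdS = %.3f kcal/mol", x$thermo$dH,
                x$thermo$minus_TdS))
  }
  cat(sprintf("\nresidual SSE = %.4g\n", x$sse))
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @importFrom stats printCoefmat
NULL

#' Predict from a binding fit
#'
#' For SPR fits, plateau responses at new concentrations; for ITC fits,
#' injection heats for a new (or the fitted) injection schedule.
#'
#' @param object A `binding_fit`.
#' @param newdata For SPR: numeric concentrations (molar) or a data.frame
#'   with column `C`/`concentration`. For ITC: an `itc_experiment` schedule.
#'   Defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  if (object$model == "spr_hyperbolic") {
    C <- if (is.null(newdata)) {
      object$data$C
    } else if (is.data.frame(newdata)) {
      newdata[[intersect(c("C", "concentration"), names(newdata))[1L]]]
    } else {
      newdata
    }
    spr_response(C, object$estimates[["K_D"]], object$estimates[["R_max"]])
  } else {
    expt <- if (is.null(newdata)) object$extra$experiment else newdata
    .itc_forward(object$estimates[["K_D"]], object$estimates[["dH"]],
                 object$estimates[["N"]], expt)
  }
}

#' @export
residuals.binding_fit <- function(object, ...) {
  obs <- if (object$model == "spr_hyperbolic") object$data$R else object$data$heat
  obs - object$fitted
}

#' Simulate data from a fitted binding model
#'
#' Draws `nsim` replicate data sets from the fitted model with Gaussian
#' noise at the residual standard deviation (or `noise_sd`).
#'
#' @param object A `binding_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param noise_sd Noise sd; default the residual sd of the fit.
#' @param ... Unused.
#' @return `data.frame` with one column per replicate.
#' @export
simulate.binding_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(object$sse / max(1, length(mu) - length(object$estimates)))
  }
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, noise_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a binding fit
#'
#' SPR: points at the measured plateaus over a log-concentration axis with
#' the fitted hyperbola and the fitted K_D marked. ITC: integrated heats per
#' injection against molar ratio with the fitted isotherm.
#'
#' @param x A `binding_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.binding_fit <- function(x, ...) {
  if (x$model == "spr_hyperbolic") {
    C <- x$data$C
    graphics::plot(C * 1e6, x$data$R, log = "x",
                   xlab = "concentration (uM)", ylab = "response (RU)",
                   pch = 19, ...)
    cc <- exp(seq(log(min(C)), log(max(C)), length.out = 200))
    graphics::lines(cc * 1e6, predict(x, cc))
    graphics::abline(v = 1e6 * x$estimates[["K_D"]], lty = 2)
  } else {
    expt <- x$extra$experiment
    mr <- expt$molar_ratio[x$data$injection]
    graphics::plot(mr, 1e9 * x$data$heat, xlab = "molar ratio (X_t/M_t)",
                   ylab = "heat per injection (ucal)", pch = 19, ...)
    graphics::lines(mr, 1e9 * x$fitted)
  }
  invisible(x)
}
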