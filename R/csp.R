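#' Nitrogen scaling factor for chemical shift perturbations
#'
#' Amide 15N shifts disperse over a much wider ppm range than 1H shifts, so
#' combined CSPs scale the nitrogen axis down by
#' \eqn{a = (\delta^N_{max}-\delta^N_{min}) / (\delta^H_{max}-\delta^H_{min})},
#' the ratio of the observed 15N and 1H shift ranges. Extrema are pooled over
#' the free and bound states of the titrated molecule, the most inclusive
#' reading and one that is stable as peaks move during the titration.
#'
#' @param pairs A `titration_pairs` table (see [read_peaklist()]).
#' @return The dimensionless scaling factor `a`. A degenerate 15N range
#'   yields `a = 0` with a warning (downstream CSPs then use the 1H axis
#'   only); a degenerate 1H range is an error.
#' @examples
#' p <- data.frame(residue = 1:2, aa = c("A", "G"),
#'                 H_free = c(7, 9), N_free = c(118, 122),
#'                 H_bound = c(7, 9), N_bound = c(118, 122))
#' scaling_factor(p)  # (122-118)/(9-7) = 2
#' @export
scaling_factor <- function(pairs) {
  h <- c(pairs$H_free, pairs$H_bound)
  n <- c(pairs$N_free, pairs$N_bound)
  h <- h[!is.na(h)]; n <- n[!is.na(n)]
  if (length(h) < 2L || length(n) < 2L) {
    stop("need at least 2 observed 1H and 15N shifts to compute the scaling factor",
         call. = FALSE)
  }
  dh <- max(h) - min(h)
  dn <- max(n) - min(n)
  if (dh == 0) stop("zero proton dispersion: 1H shift range is degenerate",
                    call. = FALSE)
  a <- dn / dh
  if (a == 0) {
    warning("zero 15N dispersion: a = 0, CSPs will use the 1H axis only",
            call. = FALSE)
  }
  a
}

#' Per-residue chemical shift perturbations
#'
#' For each residue with peaks observed in both states, the perturbation is
#' \deqn{\Delta\delta = \sqrt{(\delta^H_{bound}-\delta^H_{free})^2 +
#'   ((\delta^N_{bound}-\delta^N_{free})/a)^2}}
#' with `a` the nitrogen scaling factor. Values above `cap` are clipped to
#' `cap` and flagged; residues whose bound-state peaks are broadened beyond
#' detection are assigned the cap outright (they moved at least that far).
#' Residues unobserved in the free state are marked `missing` and excluded
#' from the per-molecule mean.
#'
#' @param pairs A `titration_pairs` table.
#' @param cap Broadening/clipping ceiling in ppm. Conventional values here:
#'   0.3 ppm when the titrated molecule is ubiquitin, 0.5 ppm for the CUE
#'   domain.
#' @param a Nitrogen scaling factor; computed via [scaling_factor()] when
#'   `NULL`. `a = 0` drops the nitrogen term.
#' @return A `csp_profile`: `data.frame` with columns `residue`, `aa`,
#'   `delta`, `capped`, `missing`, plus attributes `cap`, `scaling_a` and
#'   `mean_delta` (arithmetic mean of `delta` over non-missing residues,
#'   capped residues entering at their cap).
#' @export
compute_csp <- function(pairs, cap = 0.3, a = NULL) {
  if (!nrow(pairs)) stop("empty peak-pair list", call. = FALSE)
  stopifnot(cap > 0)
  if (is.null(a)) a <- scaling_factor(pairs)
  stopifnot(is.numeric(a), length(a) == 1L, a >= 0)

  has_free  <- !is.na(pairs$H_free) & !is.na(pairs$N_free)
  has_bound <- !is.na(pairs$H_bound) & !is.na(pairs$N_bound)

  delta <- rep(NA_real_, nrow(pairs))
  capped <- rep(FALSE, nrow(pairs))
  missing <- !has_free

  obs <- has_free & has_bound
  dh <- pairs$H_bound[obs] - pairs$H_free[obs]
  dn <- pairs$N_bound[obs] - pairs$N_free[obs]
  d <- if (a > 0) sqrt(dh^2 + (dn / a)^2) else abs(dh)
  clip <- d > cap
  delta[obs] <- pmin(d, cap)
  capped[obs] <- clip

  broad <- has_free & !has_bound
  delta[broad] <- cap
  capped[broad] <- TRUE

  out <- data.frame(residue = pairs$residue, aa = pairs$aa,
                    delta = delta, capped = capped, missing = missing,
                    stringsAsFactors = FALSE)
  structure(out,
            cap = cap, scaling_a = a,
            mean_delta = mean(delta[!missing]),
            class = c("csp_profile", "data.frame"))
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("<csp_profile> %d residues (%d broadened/capped, %d missing)\n",
              nrow(x), sum(x$capped, na.rm = TRUE), sum(x$missing)))
  cat(sprintf("  a = %.4g, cap = %.3g ppm, mean CSP = %.4g ppm, %d above mean\n",
              attr(x, "scaling_a"), attr(x, "cap"), attr(x, "mean_delta"),
              length(csp_above_mean(x))))
  invisible(x)
}

#' Residues perturbed above the per-molecule mean
#'
#' The interface-calling threshold is the arithmetic mean CSP of the titrated
#' molecule; residues strictly above it are candidate interface residues.
#' Capped (broadened) residues participate at their capped value.
#'
#' @param profile A `csp_profile`.
#' @return Integer vector of residue numbers with `delta > mean_delta`.
#' @export
csp_above_mean <- function(profile) {
  if (all(profile$missing)) stop("profile has no observed residues", call. = FALSE)
  m <- attr(profile, "mean_delta")
  keep <- !profile$missing & !is.na(profile$delta) & profile$delta > m
  profile$residue[keep]
}

#' Write a CSP profile as TSV plus a JSON summary
#'
#' @param profile A `csp_profile`.
#' @param tsv Path for the per-residue table.
#' @param json Optional path for the summary (`a`, `cap`, `mean_delta`,
#'   `n_above_mean`).
#' @return Invisibly, the summary list.
#' @export
write_csp <- function(profile, tsv, json = NULL) {
  write.table(as.data.frame(profile), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  summary <- list(a = attr(profile, "scaling_a"),
                  cap = attr(profile, "cap"),
                  mean_delta = attr(profile, "mean_delta"),
                  n_above_mean = length(csp_above_mean(profile)))
  if (!is.null(json)) {
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
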