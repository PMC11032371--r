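# Seeded generators for every input the pipeline consumes, each a pure
# function of (spec, seed), with ground-truth records for downstream scoring.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(expr)
}

#' Generate a titration peak-list pair with a planted interface
#'
#' Emulates an HSQC titration outcome: free-state amide peaks are drawn in
#' realistic windows (1H 6.5-10.5 ppm, 15N 103-133 ppm, so the nitrogen
#' scaling factor lands near its physical value of ~7), then bound-state
#' peaks are displaced so that the combined CSP of each planted interface
#' residue is near `interface_csp_mean` while background residues get small
#' |Normal(0, `background_csp_sd`)| perturbations. Displacement directions
#' are chosen inward at the spectral extremes so the pooled shift extrema —
#' and hence the scaling factor — are set by the free state, making the
#' planted CSPs exactly recoverable. Residues listed in
#' `broadened_residues` are omitted from the bound list.
#'
#' @param n_residues Number of residues.
#' @param interface_residues Integer set of planted interface residues.
#' @param interface_csp_mean Planted CSP for interface residues, ppm; must
#'   exceed 3x `background_csp_sd` so the planted set is separable.
#' @param background_csp_sd Background perturbation scale, ppm.
#' @param broadened_residues Residues whose bound peaks vanish.
#' @param interface_csp_sd Spread of planted CSPs around their mean
#'   (default 0: all planted residues at exactly the mean).
#' @param seed Integer seed; same spec + seed gives identical output.
#' @return List with `pairs` (a `titration_pairs` table), and `truth`:
#'   planted sets, per-residue planted CSPs and the realised scaling factor.
#' @export
make_titration <- function(n_residues, interface_residues = integer(),
                           interface_csp_mean = 0.4,
                           background_csp_sd = 0.02,
                           broadened_residues = integer(),
                           interface_csp_sd = 0, seed = 1L) {
  stopifnot(all(interface_residues %in% seq_len(n_residues)),
            all(broadened_residues %in% seq_len(n_residues)))
  if (length(interface_residues) &&
      interface_csp_mean <= 3 * background_csp_sd) {
    stop("interface CSP mean must exceed 3x the background sd for a separable plant",
         call. = FALSE)
  }
  .with_seed(seed, {
    res <- seq_len(n_residues)
    aa <- sample(setdiff(names(.aa_codes), "PRO"), n_residues, replace = TRUE)
    aa1 <- unname(.aa_codes[aa])
    Hf <- runif(n_residues, 6.5, 10.5)
    Nf <- runif(n_residues, 103, 133)
    a <- (max(Nf) - min(Nf)) / (max(Hf) - min(Hf))

    target <- abs(rnorm(n_residues, 0, background_csp_sd))
    if (length(interface_residues)) {
      target[interface_residues] <-
        pmax(0, rnorm(length(interface_residues), interface_csp_mean,
                      interface_csp_sd))
    }
    theta <- runif(n_residues, 0.2, pi / 2 - 0.2)
    dH <- target * cos(theta)
    dN <- target * sin(theta) * a
    # inward displacement at the extremes keeps the pooled extrema (and so
    # the scaling factor) equal to the free-state extrema
    sH <- ifelse(Hf + dH > max(Hf), -1, 1)
    sN <- ifelse(Nf + dN > max(Nf), -1, 1)
    Hb <- Hf + sH * dH
    Nb <- Nf + sN * dN

    pairs <- data.frame(residue = res, aa = aa1,
                        H_free = Hf, N_free = Nf,
                        H_bound = Hb, N_bound = Nb,
                        stringsAsFactors = FALSE)
    if (length(broadened_residues)) {
      pairs$H_bound[broadened_residues] <- NA_real_
      pairs$N_bound[broadened_residues] <- NA_real_
    }
    pairs$broadened <- !is.na(pairs$H_free) & is.na(pairs$H_bound)
    class(pairs) <- c("titration_pairs", "data.frame")
    list(pairs = pairs,
         truth = list(interface_residues = sort(interface_residues),
                      broadened_residues = sort(broadened_residues),
                      planted_csp = target, scaling_a = a))
  })
}

#' Describe a toy body for structure generation
#'
#' @param arrangement `"single"`, `"pair"`, `"helix"` or `"shell"`.
#' @param element Element symbol for every atom (default `"C"`).
#' @param chain_id Chain identifier.
#' @param resname Residue name stamped on the atoms.
#' @param d Pair separation (Angstrom), for `"pair"`.
#' @param n Atom count, for `"helix"`/`"shell"`.
#' @param rise,radius Helix rise per atom and radius (Angstrom).
#' @param r Shell radius (Angstrom).
#' @return A `toy_body` spec list.
#' @export
toy_body <- function(arrangement = c("single", "pair", "helix", "shell"),
                     element = "C", chain_id = "A", resname = "ALA",
                     d = 10, n = 12L, rise = 1.5, radius = 2.3, r = 2.5) {
  arrangement <- match.arg(arrangement)
  structure(list(arrangement = arrangement, element = element,
                 chain_id = chain_id, resname = resname, d = d, n = n,
                 rise = rise, radius = radius, r = r),
            class = "toy_body")
}

.body_coords <- function(b) {
  switch(b$arrangement,
    single = matrix(0, 1L, 3L),
    pair = rbind(c(0, 0, 0), c(b$d, 0, 0)),
    helix = {
      k <- seq_len(b$n) - 1L
      ang <- k * 100 * pi / 180
      cbind(b$radius * cos(ang), b$radius * sin(ang), k * b$rise)
    },
    shell = .sphere_points(b$n) * b$r
  )
}

#' Build a toy structure from placed bodies
#'
#' Concatenates bodies (see [toy_body()]) after applying rigid transforms,
#' one residue per atom, each body its own chain. Arrangements have closed
#' forms: a single atom has SASA `4*pi*(r_vdw+probe)^2`; a far pair is
#' additive; a tight shell around an atom buries it; a helix's centre of
#' mass lies on its axis.
#'
#' @param bodies List of `toy_body` specs with distinct `chain_id`s.
#' @param placements Optional list of `list(R = 3x3 rotation, t = 3-vector)`
#'   per body; default identity.
#' @return A `pdb_structure`.
#' @export
make_toy_structure <- function(bodies, placements = NULL) {
  if (inherits(bodies, "toy_body")) bodies <- list(bodies)
  chains <- vapply(bodies, `[[`, "", "chain_id")
  if (anyDuplicated(chains)) stop("overlapping chain ids across bodies",
                                  call. = FALSE)
  if (!is.null(placements) && length(placements) != length(bodies)) {
    stop("placements must match bodies in length", call. = FALSE)
  }
  parts <- lapply(seq_along(bodies), function(i) {
    b <- bodies[[i]]
    xyz <- .body_coords(b)
    if (!is.null(placements)) {
      p <- placements[[i]]
      if (!is.null(p$R)) xyz <- xyz %*% t(p$R)
      if (!is.null(p$t)) xyz <- sweep(xyz, 2L, p$t, "+")
    }
    data.frame(name = if (b$element == "C") "CA" else toupper(b$element),
               resname = b$resname, chain = b$chain_id,
               resno = seq_len(nrow(xyz)),
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               element = toupper(b$element), stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, source_id = "toy")
}

#' Generate synthetic binding data with known parameters
#'
#' Front end to the forward models: `"spr_hyperbolic"` produces a
#' concentration/response table from [spr_response()], `"itc_one_site"` an
#' injection/heat table from [simulate_itc()]. The truth record embeds the
#' generating parameters so fits can be scored without re-reading the
#' generator.
#'
#' @param model `"spr_hyperbolic"` or `"itc_one_site"`.
#' @param params Named list of model parameters: SPR `K_D`, `R_max`;
#'   ITC `K_D`, `dH`, `N`.
#' @param design Named list of design settings: SPR `concentrations`
#'   (molar); ITC `cell_conc`, `syringe_conc`, and optionally
#'   `n_injections`, `injection_volume`, `cell_volume`, `temperature`.
#' @param noise_sd Gaussian noise sd (RU for SPR, kcal for ITC).
#' @param seed Integer seed for the noise.
#' @param file Optional TSV output path (the dialect the fitters read).
#' @param truth_file Optional JSON sidecar path for the truth record.
#' @return List with `data` (`data.frame` for SPR, `itc_experiment` for
#'   ITC) and `truth`.
#' @export
make_binding_data <- function(model = c("spr_hyperbolic", "itc_one_site"),
                              params, design, noise_sd = 0, seed = 1L,
                              file = NULL, truth_file = NULL) {
  model <- match.arg(model)
  if (model == "spr_hyperbolic") {
    C <- sort(design$concentrations)
    R <- spr_response(C, params$K_D, params$R_max)
    if (noise_sd > 0) R <- .with_seed(seed, R + rnorm(length(R), 0, noise_sd))
    data <- data.frame(concentration = C, response = R)
    if (!is.null(file)) {
      write.table(data, file, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    d <- modifyList(list(n_injections = 20L, injection_volume = 2e-6,
                         cell_volume = 200e-6, temperature = 293), design)
    data <- simulate_itc(params$K_D, params$dH, params$N,
                         cell_conc = d$cell_conc, syringe_conc = d$syringe_conc,
                         n_injections = d$n_injections,
                         injection_volume = d$injection_volume,
                         cell_volume = d$cell_volume,
                         temperature = d$temperature,
                         noise_sd = noise_sd, seed = seed)
    if (!is.null(file)) {
      write.table(data.frame(injection = data$injection, heat = data$heats),
                  file, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  truth <- list(model = model, params = params, design = design,
                noise_sd = noise_sd, seed = seed)
  if (!is.null(truth_file)) {
    jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA)
  }
  list(data = data, truth = truth)
}
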