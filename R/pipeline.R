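#' Default pipeline configuration
#'
#' Single plain-text (JSON) configuration with units embedded in the key
#' names, since unit mistakes are the dominant hazard in this domain.
#' Unknown keys are rejected on read so typos fail loudly instead of
#' silently falling back to defaults.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    peaklist_receptor = NULL,      # TSV: titrated molecule A (e.g. CUE)
    peaklist_ligand = NULL,        # TSV: titrated molecule B (e.g. Ub)
    structure_receptor = NULL,     # PDB path
    structure_ligand = NULL,       # PDB path
    complex_structure = NULL,      # optional PDB of a pose to score
    cap_ppm_receptor = 0.5,
    cap_ppm_ligand = 0.3,
    rsasa_min = 0.30,
    probe_angstrom = 1.4,
    sphere_points = 960,
    d_max_angstrom = 2.0,
    neighbour_cutoff_angstrom = 6.5,
    com_target_angstrom = 31.0,
    com_tol_angstrom = 2.0,
    itc_temperature_K = 293,
    spr_temperature_K = 298.15,
    seed = 1,
    output_dir = "cspbind_out"
  )
}

#' Read / write a pipeline configuration
#'
#' @param file JSON config path.
#' @return `read_config()`: the merged config list (defaults overridden by
#'   the file); errors on unknown keys. `write_config()`: invisibly, `file`.
#' @export
read_config <- function(file) {
  user <- jsonlite::read_json(file, simplifyVector = TRUE)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modifyList(defaults, user)
}

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, file) {
  jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}

#' Run the interface-mapping pipeline
#'
#' Orchestrates CSP computation, SASA and relative exposure, active/passive
#' calling and restraint generation for a receptor/ligand pair, and — when a
#' complex model is supplied — pose scoring. Every intermediate statistic is
#' collected into a self-describing report (resolved config, package
#' version, input digests) written as JSON; stages log to stderr.
#'
#' @param config Config list (see [default_config()]) or a JSON path.
#' @return The report list, invisibly written to
#'   `file.path(output_dir, "report.json")` and the restraints to
#'   `restraints.tbl`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- modifyList(default_config(), config)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      stop(sprintf("missing %s input: %s", what,
                   if (is.null(path)) "(not set)" else path), call. = FALSE)
    }
    path
  }
  digest <- function(path) {
    # cheap content fingerprint: size + sum of byte values
    b <- readBin(path, "raw", file.info(path)$size)
    sprintf("size=%d;bytesum=%.0f", length(b), sum(as.integer(b)))
  }

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config,
                 version = as.character(utils::packageVersion("cspbind")),
                 inputs = list())

  one_side <- function(peak_path, pdb_path, cap, label) {
    pairs <- stage(paste0("read peak list (", label, ")"),
                   read_peaklist(need(peak_path, paste0(label, " peak list"))))
    struct <- stage(paste0("read structure (", label, ")"),
                    read_pdb(need(pdb_path, paste0(label, " structure"))))
    profile <- stage(paste0("CSP (", label, ")"),
                     compute_csp(pairs, cap = cap))
    sasa <- stage(paste0("SASA (", label, ")"),
                  relative_sasa(shrake_rupley(struct,
                                              probe = config$probe_angstrom,
                                              n_points = config$sphere_points)))
    call <- stage(paste0("interface call (", label, ")"),
                  call_active(profile, sasa, rsasa_min = config$rsasa_min,
                              molecule_id = label))
    call <- stage(paste0("passive call (", label, ")"),
                  call_passive(struct, call, sasa,
                               neighbour_cutoff = config$neighbour_cutoff_angstrom,
                               rsasa_min = config$rsasa_min))
    write_csp(profile, file.path(config$output_dir,
                                 paste0("csp_", label, ".tsv")))
    list(pairs = pairs, structure = struct, profile = profile, sasa = sasa,
         call = call,
         stats = list(scaling_a = attr(profile, "scaling_a"),
                      mean_delta = attr(profile, "mean_delta"),
                      cap_ppm = cap,
                      n_above_mean = length(csp_above_mean(profile)),
                      active = call$active, passive = call$passive,
                      buried_responders = call$buried_responders))
  }

  A <- one_side(config$peaklist_receptor, config$structure_receptor,
                config$cap_ppm_receptor, "receptor")
  B <- one_side(config$peaklist_ligand, config$structure_ligand,
                config$cap_ppm_ligand, "ligand")
  report$inputs <- lapply(
    list(peaklist_receptor = config$peaklist_receptor,
         peaklist_ligand = config$peaklist_ligand,
         structure_receptor = config$structure_receptor,
         structure_ligand = config$structure_ligand),
    digest)
  report$receptor <- A$stats
  report$ligand <- B$stats

  tbl <- stage("restraints",
               write_airs(A$call, B$call, d_max = config$d_max_angstrom,
                          file = file.path(config$output_dir, "restraints.tbl")))
  report$restraints <- list(n = length(tbl), d_max = config$d_max_angstrom)

  if (!is.null(config$complex_structure)) {
    complex <- stage("read complex", read_pdb(need(config$complex_structure,
                                                   "complex structure")))
    chain_map <- setNames(attr(complex, "chains")[1:2],
                          c("receptor", "ligand"))
    score <- stage("score pose",
                   score_pose(complex, read_airs(tbl), chain_map))
    report$pose <- list(satisfied = score$satisfied, total = score$total,
                        satisfaction = score$satisfaction,
                        violation_energy = score$violation_energy,
                        bsa = score$bsa)
  }

  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
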