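## Config-driven orchestration of the three computational experiments:
## condition comparison, exogenous-field scan, temperature scan.
##
## A run config is a plain named list (buildable in R or read from YAML):
##   seed                : integer, master seed
##   temperature         : K for single-condition runs (default 300)
##   temperatures        : K vector for the temperature scan
##                         (default 300..350 step 10)
##   field_magnitudes    : V/nm vector for the field scan
##                         (default 0.00..0.12 step 0.02, must include 0)
##   field_direction     : unit 3-vector (default +z)
##   reference_condition : name of the reference (pKa anchor) condition
##   reference_pKa       : absolute pKa of the reference (default 8.2)
##   output_dir          : optional; when set, intermediates + manifest
##                         are persisted there
##   conditions          : named list; each entry has either
##                         qc_pair = a SpeciesPair, or
##                         qc_pair = list(protonated=path, deprotonated=path,
##                                        atom_map=indices)   (qcdata JSON)
##                         and either frames = list of frame pairs per
##                         ensemble, or frames_spec = list(n_frames,
##                         mean_potential, sd_potential, mean_field,
##                         sd_field, phi, seed_offset) for the synthetic
##                         generator (two independent ensembles drawn
##                         with consecutive seeds).

.defaultConfig <- function(config) {
  defaults <- list(
    seed = 1L, temperature = 300,
    temperatures = seq(300, 350, by = 10),
    field_magnitudes = seq(0, 0.12, by = 0.02),
    field_direction = c(0, 0, 1),
    reference_pKa = 8.2,
    output_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$conditions) || !length(config$conditions))
    stop("config must declare at least one condition", call. = FALSE)
  if (is.null(config$reference_condition))
    config$reference_condition <- names(config$conditions)[1]
  if (!config$reference_condition %in% names(config$conditions))
    stop("reference condition '", config$reference_condition,
         "' not among conditions", call. = FALSE)
  config
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML config with the fields described in
#'   \code{\link{runCondition}}.
#' @return A config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  .defaultConfig(yaml::read_yaml(path))
}

.resolvePair <- function(cond, name) {
  qp <- cond$qc_pair
  if (is(qp, "SpeciesPair")) return(qp)
  if (is.list(qp) && !is.null(qp$protonated) && !is.null(qp$deprotonated)) {
    prot <- readQuantumCenter(qp$protonated)
    deprot <- readQuantumCenter(qp$deprotonated)
    am <- if (!is.null(qp$atom_map)) as.integer(qp$atom_map) else
      seq_len(nAtoms(deprot))
    return(SpeciesPair(prot, deprot, am))
  }
  stop("condition '", name, "': missing or unresolvable qc_pair input",
       call. = FALSE)
}

.resolveEnsembleFrames <- function(cond, pair, config, name) {
  if (!is.null(cond[["frames"]])) {
    fr <- cond[["frames"]]
    if (!is.null(fr$protonated) && !is.null(fr$deprotonated)) return(fr)
    return(list(protonated = fr, deprotonated = fr))
  }
  spec <- cond$frames_spec
  if (is.null(spec))
    stop("condition '", name, "': neither frames nor frames_spec supplied",
         call. = FALSE)
  base <- as.integer(config$seed) + 2L * as.integer(spec$seed_offset %||% 0L)
  args <- list(
    pair = pair,
    n_frames = spec$n_frames %||% 2000L,
    mean_potential = spec$mean_potential %||% 0,
    sd_potential = spec$sd_potential %||% 5,
    mean_field = spec$mean_field %||% c(0, 0, 0),
    sd_field = spec$sd_field %||% 20,
    phi = spec$phi %||% 0)
  list(
    protonated = do.call(genFieldFrames, c(args, seed = base)),
    deprotonated = do.call(genFieldFrames, c(args, seed = base + 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.conditionDeltaA <- function(config, name, field = c(0, 0, 0),
                             thermo = NULL) {
  cond <- config$conditions[[name]]
  if (is.null(cond))
    stop("unknown condition '", name, "'", call. = FALSE)
  if (is.null(thermo)) thermo <- ThermoConfig(config$temperature)
  pair <- .resolvePair(cond, name)
  ens <- .resolveEnsembleFrames(cond, pair, config, name)
  withField <- function(frames) {
    if (all(field == 0)) return(frames)
    lapply(frames, function(fp) list(
      protonated = applyExogenousField(fp$protonated, field,
                                       protonated(pair)),
      deprotonated = applyExogenousField(fp$deprotonated, field,
                                         deprotonated(pair))))
  }
  sProt <- perturbationEnergySeries(pair, withField(ens$protonated),
                                    "protonated")
  sDeprot <- perturbationEnergySeries(pair, withField(ens$deprotonated),
                                      "deprotonated")
  list(result = helmholtzDeltaA(sProt, sDeprot, thermo),
       series = list(protonated = sProt, deprotonated = sDeprot),
       pair = pair, thermo = thermo)
}

.persist <- function(config, name, run, extra = list()) {
  dir_ <- config$output_dir
  if (is.null(dir_)) return(invisible(NULL))
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir_, gsub("[^A-Za-z0-9._-]", "_", name))
  writeEnergySeries(run$series$protonated, paste0(stem, "_prot.csv"))
  writeEnergySeries(run$series$deprotonated, paste0(stem, "_deprot.csv"))
  writeFreeEnergyResult(run$result, paste0(stem, "_free_energy.json"))
  manifest <- c(list(
    condition = name,
    seed = config$seed,
    temperature = run$thermo@temperature,
    n_frames = list(protonated = nFrames(run$series$protonated),
                    deprotonated = nFrames(run$series$deprotonated)),
    package_version = as.character(utils::packageVersion("PMMpKa"))),
    extra)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE),
             paste0(stem, "_manifest.json"))
  invisible(NULL)
}

#' Run one condition end-to-end
#'
#' Frames (optionally with an exogenous field superposed) are turned into
#' perturbed Hamiltonians, per-frame ground-state energy gaps, a
#' free-energy estimate, and pKa quantities relative to the configured
#' reference condition. When an output directory is configured, the
#' energy series, free-energy result and a run manifest are persisted.
#'
#' @param config Run configuration list (see file-level format notes, or
#'   \code{\link{readRunConfig}}).
#' @param condition_name Name of the condition to run.
#' @param field Exogenous field vector, V/nm (default none).
#' @return A list with \code{free_energy}
#'   (\code{\link{FreeEnergyResult}}), \code{delta_pKa}, \code{pKa}
#'   (absolute, via calibration on the reference), \code{reference_delta_A}
#'   and \code{thermo}.
#' @export
runCondition <- function(config, condition_name, field = c(0, 0, 0)) {
  config <- .defaultConfig(config)
  thermo <- ThermoConfig(config$temperature)
  run <- .conditionDeltaA(config, condition_name, field, thermo)
  refName <- config$reference_condition
  refA <- if (identical(condition_name, refName) && all(field == 0))
    deltaA(run$result)
  else
    deltaA(.conditionDeltaA(config, refName, thermo = thermo)$result)
  C <- calibrateLumpedConstant(refA, config$reference_pKa, thermo)
  out <- list(
    free_energy = run$result,
    delta_pKa = deltaPKa(deltaA(run$result), refA, thermo),
    pKa = pKaFromDeltaA(deltaA(run$result), C, thermo),
    reference_delta_A = refA,
    thermo = thermo)
  .persist(config, condition_name, run,
           list(field_V_per_nm = field, reference_condition = refName,
                reference_delta_A = refA))
  out
}

#' Exogenous-field scan
#'
#' Runs the scan condition once per configured field magnitude (direction
#' from the config, default +z), the field injected additively into the
#' per-frame electrostatics before matrix construction; frames are not
#' re-sampled under the field. Shifts are reported against the reference
#' condition, and the change of shift against the zero-field row. When
#' per-magnitude mean dipole moments are supplied
#' (\code{config$field_scan_dipoles}), the Pearson correlation between
#' dipoles and free energies is attached as attribute \code{"pearson"}.
#'
#' @param config Run configuration; \code{config$field_scan_condition}
#'   names the scanned condition (default: the reference condition).
#' @return A \code{data.frame} with columns \code{field},
#'   \code{delta_A}, \code{error}, \code{delta_pKa},
#'   \code{delta_delta_pKa}, \code{mean_dipole}.
#' @export
runFieldScan <- function(config) {
  config <- .defaultConfig(config)
  mags <- config$field_magnitudes
  if (!any(mags == 0))
    stop("field scan requires a zero-field magnitude", call. = FALSE)
  dir_ <- config$field_direction / sqrt(sum(config$field_direction^2))
  thermo <- ThermoConfig(config$temperature)
  scanName <- config$field_scan_condition %||% config$reference_condition
  refA <- deltaA(.conditionDeltaA(config, config$reference_condition,
                                  thermo = thermo)$result)
  rows <- lapply(mags, function(m) {
    run <- .conditionDeltaA(config, scanName, field = m * dir_,
                            thermo = thermo)
    data.frame(field = m, delta_A = deltaA(run$result),
               error = uncertainty(run$result),
               delta_pKa = deltaPKa(deltaA(run$result), refA, thermo))
  })
  tab <- do.call(rbind, rows)
  tab$delta_delta_pKa <- deltaDeltaPKa(tab$delta_pKa,
                                       tab$delta_pKa[tab$field == 0][1])
  tab$mean_dipole <- if (!is.null(config$field_scan_dipoles))
    rep_len(config$field_scan_dipoles, nrow(tab)) else NA_real_
  if (!is.null(config$field_scan_dipoles))
    attr(tab, "pearson") <- pearsonCorrelation(tab$mean_dipole, tab$delta_A)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$output_dir, "field_scan.csv"),
                     row.names = FALSE)
  }
  tab
}

#' Temperature scan
#'
#' Re-evaluates the free-energy estimators and pKa formulas at each
#' configured temperature (both beta and the ln(10) kB T denominator are
#' temperature-dependent). The per-temperature reference free energy is
#' taken from \code{config$reference_delta_A} (a single value or one per
#' temperature) when supplied, otherwise computed from the reference
#' condition at that temperature.
#'
#' @param config Run configuration; \code{config$temperature_scan_condition}
#'   names the scanned condition (default: the reference condition).
#' @return A \code{data.frame} with columns \code{temperature},
#'   \code{delta_A}, \code{error}, \code{delta_pKa},
#'   \code{delta_delta_pKa}.
#' @export
runTemperatureScan <- function(config) {
  config <- .defaultConfig(config)
  temps <- config$temperatures
  scanName <- config$temperature_scan_condition %||%
    config$reference_condition
  refGiven <- config$reference_delta_A
  rows <- lapply(seq_along(temps), function(i) {
    thermo <- ThermoConfig(temps[i])
    run <- .conditionDeltaA(config, scanName, thermo = thermo)
    refA <- if (!is.null(refGiven)) rep_len(refGiven, length(temps))[i] else
      deltaA(.conditionDeltaA(config, config$reference_condition,
                              thermo = thermo)$result)
    data.frame(temperature = temps[i], delta_A = deltaA(run$result),
               error = uncertainty(run$result),
               delta_pKa = deltaPKa(deltaA(run$result), refA, thermo))
  })
  tab <- do.call(rbind, rows)
  tab$delta_delta_pKa <- deltaDeltaPKa(tab$delta_pKa, tab$delta_pKa[1])
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$output_dir,
                                    "temperature_scan.csv"),
                     row.names = FALSE)
  }
  tab
}
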