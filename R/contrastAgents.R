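#' Construct a contrast agent description
#'
#' Builds a [ContrastAgent-class] from its molarity and the molecular weight
#' of the active component. When the per-ml masses are not supplied they are
#' derived from the molarity: `gdMassPerMl = molarity x 157.25` (one Gd ion
#' per complex, Gd molar mass 157.25 g/mol) and
#' `activeMassPerMl = molarity x activeMW`. Product datasheets occasionally
#' print a mass that does not obey the molarity x MW identity (the Magnevist
#' entry quotes the dimeglumine salt mass against the free-acid MW); such
#' values can be stored as printed and audited with
#' [tableConsistencyReport()].
#'
#' @param name agent name.
#' @param molarity mmol of Gd complex per ml of parent solution.
#' @param activeMW molecular weight of the active component, g/mol.
#' @param activeMassPerMl mass of active component per ml, mg/ml
#'   (default `molarity * activeMW`).
#' @param gdMassPerMl mass of Gd per ml, mg/ml (default `molarity * 157.25`).
#' @param parentDensity parent solution density, g/ml. Not a datasheet
#'   composition value; defaults to the DOTAREM product density 1.1753.
#' @return A [ContrastAgent-class] object.
#' @examples
#' contrastAgent("DOTAREM", 0.5, 558.64)
#' @export
contrastAgent <- function(name, molarity, activeMW,
                          activeMassPerMl = molarity * activeMW,
                          gdMassPerMl = molarity * GD_MOLAR_MASS,
                          parentDensity = 1.1753) {
  checkScalar(molarity, "molarity", min = 0)
  checkScalar(activeMW, "activeMW", min = 0, strict = TRUE)
  new("ContrastAgent", name = name, molarity = molarity, activeMW = activeMW,
      activeMassPerMl = activeMassPerMl, gdMassPerMl = gdMassPerMl,
      parentDensity = parentDensity)
}

#' @describeIn contrastAgent Agent name accessor.
#' @param object,agent a [ContrastAgent-class].
#' @export
agentName <- function(agent) agent@name

#' @describeIn contrastAgent Molarity accessor (mmol/ml).
#' @export
agentMolarity <- function(agent) agent@molarity

#' @describeIn contrastAgent Parent-solution density accessor (g/ml).
#' @export
parentDensity <- function(agent) agent@parentDensity

setMethod("show", "ContrastAgent", function(object) {
  cat(sprintf(paste0("ContrastAgent '%s': %.3g mmol/ml, active MW %.2f",
                     " g/mol\n  active %.2f mg/ml, Gd %.3f mg/ml,",
                     " parent density %.4f g/ml\n"),
              object@name, object@molarity, object@activeMW,
              object@activeMassPerMl, object@gdMassPerMl,
              object@parentDensity))
})

#' Mass of gadolinium per ml of parent solution
#'
#' Computes the elemental Gd mass in 1 ml of parent solution as
#' `molarity x 157.25` mg (Gd molar mass 157.25 g/mol, one Gd per complex).
#' The value is recomputed from the molarity, not read from the stored slot,
#' so it can be checked against datasheet figures.
#'
#' @param agent a [ContrastAgent-class], or a numeric molarity in mmol/ml.
#' @return Gd mass, mg per ml of parent solution.
#' @examples
#' gdMassPerMl(getAgent("DOTAREM"))  # 78.625
#' gdMassPerMl(1)                    # Gadovist-strength: 157.25
#' @export
setGeneric("gdMassPerMl", function(agent) standardGeneric("gdMassPerMl"))

#' @rdname gdMassPerMl
#' @export
setMethod("gdMassPerMl", "ContrastAgent", function(agent)
  gdMassPerMl(agent@molarity))

#' @rdname gdMassPerMl
#' @export
setMethod("gdMassPerMl", "numeric", function(agent) {
  checkScalar(agent, "molarity", min = 0)
  agent * GD_MOLAR_MASS
})

#' Mass of active component per ml of parent solution
#'
#' Computes the active-compound mass in 1 ml of parent solution as
#' `molarity x activeMW` mg.
#'
#' @param agent a [ContrastAgent-class].
#' @param molarity,activeMW used instead of `agent` when it is missing.
#' @return active component mass, mg per ml of parent solution.
#' @examples
#' activeMassPerMl(getAgent("DOTAREM"))  # 0.5 x 558.64 = 279.32
#' @export
activeMassPerMl <- function(agent, molarity = agent@molarity,
                            activeMW = agent@activeMW) {
  checkScalar(molarity, "molarity", min = 0)
  checkScalar(activeMW, "activeMW", min = 0, strict = TRUE)
  molarity * activeMW
}

#' Audit a stored agent composition against the molarity identities
#'
#' Compares the stored per-ml masses of a [ContrastAgent-class] with the
#' values implied by its molarity (`molarity x activeMW` and
#' `molarity x 157.25`). Rows whose stored and computed values differ by more
#' than `tolerance` (relative) are reported; a consistent datasheet row
#' yields a zero-row data frame.
#'
#' @param agent a [ContrastAgent-class].
#' @param tolerance relative mismatch above which a field is flagged
#'   (default 0.001, i.e. 0.1 percent).
#' @return data.frame with columns `field`, `stored`, `computed`,
#'   `relative_error`; one row per mismatched field.
#' @examples
#' tableConsistencyReport(getAgent("DOTAREM"))    # empty
#' tableConsistencyReport(getAgent("Magnevist"))  # flags active mass
#' @export
tableConsistencyReport <- function(agent, tolerance = 0.001) {
  stopifnot(is(agent, "ContrastAgent"))
  stored <- c(active_mass_per_ml = agent@activeMassPerMl,
              gd_mass_per_ml = agent@gdMassPerMl)
  computed <- c(active_mass_per_ml = agent@molarity * agent@activeMW,
                gd_mass_per_ml = agent@molarity * GD_MOLAR_MASS)
  rel <- abs(stored - computed) / pmax(abs(computed), .Machine$double.eps)
  bad <- rel > tolerance
  data.frame(field = names(stored)[bad], stored = unname(stored[bad]),
             computed = unname(computed[bad]),
             relative_error = unname(rel[bad]), stringsAsFactors = FALSE)
}

#' Worst-case chamber concentration of a contrast bolus
#'
#' Millimolar Gd concentration reached when an entire contrast bolus mixes
#' into a cardiac chamber: `1000 x bolusVolume x bolusMolarity /
#' chamberVolume`. The bolus volume is not added to the chamber volume; the
#' scenario is the full bolus present in the end-diastolic volume. A 20 ml
#' bolus of a 0.5 mmol/ml agent in a 150 ml left ventricle gives 66.67 mM,
#' i.e. approximately 70 mM.
#'
#' @param bolusVolume bolus volume, ml (>= 0).
#' @param bolusMolarity agent molarity, mmol/ml (>= 0).
#' @param chamberVolume chamber (end-diastolic) volume, ml (> 0).
#' @return concentration, mM.
#' @examples
#' maxChamberConcentration(20, 0.5, 150)  # 66.67 mM
#' @export
maxChamberConcentration <- function(bolusVolume, bolusMolarity,
                                    chamberVolume) {
  checkScalar(bolusVolume, "bolusVolume", min = 0)
  checkScalar(bolusMolarity, "bolusMolarity", min = 0)
  checkScalar(chamberVolume, "chamberVolume", min = 0, strict = TRUE)
  1000 * bolusVolume * bolusMolarity / chamberVolume
}

#' Built-in registry of common contrast agents
#'
#' The four agents shipped with the package, with per-ml masses as printed on
#' the product datasheets. Note that the Magnevist active mass (469.01 mg/ml)
#' is the dimeglumine salt mass and does not equal molarity x free-acid MW;
#' it is stored as printed and flagged by [tableConsistencyReport()].
#'
#' @return named list of [ContrastAgent-class] objects.
#' @examples
#' names(agentRegistry())
#' @export
agentRegistry <- function() {
  agents <- list(
    contrastAgent("DOTAREM", 0.5, 558.64, 279.32, 78.625),
    contrastAgent("Gadovist", 1.0, 604.71, 604.71, 157.25),
    contrastAgent("Magnevist", 0.5, 545.56, 469.01, 78.625),
    contrastAgent("MultiHance", 0.5, 667.72, 529.00, 78.625))
  names(agents) <- vapply(agents, agentName, character(1))
  agents
}

#' @describeIn agentRegistry Fetch one agent by name (case-insensitive).
#' @param name agent name.
#' @param registry registry to search (default the built-in one).
#' @export
getAgent <- function(name, registry = agentRegistry()) {
  hit <- match(tolower(name), tolower(names(registry)))
  if (is.na(hit))
    stop(sprintf("unknown agent '%s'; registry has: %s", name,
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  registry[[hit]]
}

#' Read or write an agent registry as a YAML config block
#'
#' The on-disk format is a YAML list of records with keys `name`,
#' `molarity_mmol_per_ml`, `active_mw_g_per_mol`, `active_mass_mg_per_ml`,
#' `gd_mass_mg_per_ml`, `parent_density_g_per_ml`, so user-defined agents can
#' be added alongside the built-in ones.
#'
#' @param path file path.
#' @param registry named list of [ContrastAgent-class] objects.
#' @return `readAgentRegistry` returns a named list of agents;
#'   `writeAgentRegistry` returns `path` invisibly.
#' @export
readAgentRegistry <- function(path) {
  recs <- yaml::read_yaml(path)
  agents <- lapply(recs, function(r)
    contrastAgent(r$name, r$molarity_mmol_per_ml, r$active_mw_g_per_mol,
                  r$active_mass_mg_per_ml, r$gd_mass_mg_per_ml,
                  r$parent_density_g_per_ml))
  names(agents) <- vapply(agents, agentName, character(1))
  agents
}

#' @rdname readAgentRegistry
#' @export
writeAgentRegistry <- function(registry, path) {
  recs <- lapply(unname(registry), function(a)
    list(name = a@name, molarity_mmol_per_ml = a@molarity,
         active_mw_g_per_mol = a@activeMW,
         active_mass_mg_per_ml = a@activeMassPerMl,
         gd_mass_mg_per_ml = a@gdMassPerMl,
         parent_density_g_per_ml = a@parentDensity))
  yaml::write_yaml(recs, path)
  invisible(path)
}
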