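## Treatment conditions: the mechanical / pharmacological state of a cell.

#' Construct a treatment condition
#'
#' Describes the mechanical and pharmacological environment of a cell:
#' substrate stiffness (glass is encoded as 1e7 kPa, i.e. 10 GPa), contact
#' area relative to the control area `A_0` stored in the parameter table,
#' qualitative cell density, inhibitor concentrations and mutation status.
#'
#' @param stiffness_kpa substrate stiffness in kPa (> 0); default glass.
#' @param area_um2 cell-substrate contact area in um^2, or `NA` to use the
#'   control area `area_a0` from the parameter table.
#' @param density `"low"` (control) or `"high"`; high density reduces FAK
#'   phosphorylation and raises LATS-dependent YAP/TAZ phosphorylation.
#' @param cytd_um cytochalasin D concentration (uM).
#' @param lat_um latrunculin A/B concentration (uM).
#' @param jas_um jasplakinolide concentration (uM).
#' @param y27_um Y-27632 (ROCK inhibitor) concentration (uM).
#' @param bleb_um blebbistatin concentration (uM).
#' @param mutation `"none"`, `"YAP_5SA"` or `"LMNA"`.
#' @return An object of class `treatment_condition`.
#' @export
treatment_condition <- function(stiffness_kpa = 1e7,
                                area_um2 = NA_real_,
                                density = c("low", "high"),
                                cytd_um = 0, lat_um = 0, jas_um = 0,
                                y27_um = 0, bleb_um = 0,
                                mutation = c("none", "YAP_5SA", "LMNA")) {
  density <- match.arg(density)
  mutation <- match.arg(mutation)
  if (is.null(area_um2)) area_um2 <- NA_real_
  stopifnot(is.numeric(stiffness_kpa), length(stiffness_kpa) == 1L)
  if (!is.finite(stiffness_kpa) || stiffness_kpa <= 0)
    stop("stiffness_kpa must be > 0", call. = FALSE)
  if (!is.na(area_um2) && area_um2 <= 0)
    stop("area_um2 must be > 0", call. = FALSE)
  conc <- c(cytd_um = cytd_um, lat_um = lat_um, jas_um = jas_um,
            y27_um = y27_um, bleb_um = bleb_um)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("inhibitor concentrations must be finite and >= 0", call. = FALSE)
  structure(list(stiffness_kpa = stiffness_kpa, area_um2 = area_um2,
                 density = density, cytd_um = cytd_um, lat_um = lat_um,
                 jas_um = jas_um, y27_um = y27_um, bleb_um = bleb_um,
                 mutation = mutation),
            class = "treatment_condition")
}

#' @export
print.treatment_condition <- function(x, ...) {
  cat("<treatment_condition>\n")
  cat(sprintf("  stiffness: %g kPa%s\n", x$stiffness_kpa,
              if (x$stiffness_kpa >= 1e7) " (glass)" else ""))
  if (!is.na(x$area_um2)) cat(sprintf("  contact area: %g um^2\n", x$area_um2))
  if (x$density != "low") cat("  density: high\n")
  for (d in c("cytd_um", "lat_um", "jas_um", "y27_um", "bleb_um"))
    if (x[[d]] > 0) cat(sprintf("  %s: %g uM\n", sub("_um$", "", d), x[[d]]))
  if (x$mutation != "none") cat("  mutation:", x$mutation, "\n")
  invisible(x)
}

#' Read a treatment condition from a JSON config file
#'
#' The file is a flat JSON object whose keys are the arguments of
#' [treatment_condition()]; unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return A `treatment_condition`.
#' @export
load_condition <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- names(formals(treatment_condition))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown condition key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(treatment_condition, cfg)
}

#' Write a treatment condition to a JSON config file
#' @param condition a `treatment_condition`.
#' @param path output path.
#' @export
write_condition <- function(condition, path) {
  stopifnot(inherits(condition, "treatment_condition"))
  jsonlite::write_json(unclass(condition), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
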