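#' Analysis configuration
#'
#' Bundles the dietary and trial constants used throughout the pipeline:
#' daily recommended intakes (DRI), the dehulling correction for hulled
#' wheats, the lowest acceptable limits (LAL) for Elston's multiplicative
#' index and the desired gains for the Pesek-Baker index.
#'
#' Defaults are the constants of the Swedish organic winter-wheat trial the
#' package ships reference tables for: DRI of 12 (Fe), 8 (Zn), 0.9 (Cu) and
#' 315 (Mg) mg per day (adult averages), yields of spelt and primitive
#' wheats scaled by 0.75 to a naked-grain basis, LALs of 28/40/50/25 and
#' desired gains of 11/4/0/6 adults per hectare per year for Fe/Zn/Cu/Mg.
#'
#' @param dri named numeric, mg per day required of each mineral; all > 0.
#' @param year_days days per year used to convert daily intakes to yearly
#'   requirements (default 365).
#' @param dehulling_factor fraction of hulled grain mass remaining after
#'   dehulling, in (0, 1].
#' @param hulled_groups genotype groups whose yields are recorded with hulls
#'   on and must be dehull-corrected.
#' @param lal named numeric, lowest acceptable limit per mineral nutritional
#'   yield (adults ha-1 year-1) for Elston's index.
#' @param desired_gains named numeric, desired gain per mineral nutritional
#'   yield (adults ha-1 year-1) for the desired-gains index.
#' @param ridge nonnegative ridge added to the genotypic covariance matrix
#'   when solving for desired-gains coefficients (default 0).
#' @return An object of class `analysis_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$dri[["Fe"]]
analysis_config <- function(dri = c(Fe = 12, Zn = 8, Cu = 0.9, Mg = 315),
                            year_days = 365,
                            dehulling_factor = 0.75,
                            hulled_groups = c("Spelt", "Primitive"),
                            lal = c(Fe = 28, Zn = 40, Cu = 50, Mg = 25),
                            desired_gains = c(Fe = 11, Zn = 4, Cu = 0, Mg = 6),
                            ridge = 0) {
  dri <- unlist(dri)
  lal <- unlist(lal)
  desired_gains <- unlist(desired_gains)
  if (length(dri) == 0 || is.null(names(dri)) || any(!nzchar(names(dri))))
    stop("`dri` must be a named numeric vector with one entry per mineral")
  if (any(dri <= 0)) stop("all DRI values must be > 0")
  if (!(dehulling_factor > 0 && dehulling_factor <= 1))
    stop("`dehulling_factor` must be in (0, 1]")
  if (year_days <= 0) stop("`year_days` must be > 0")
  if (ridge < 0) stop("`ridge` must be >= 0")
  structure(
    list(dri = dri, year_days = year_days,
         dehulling_factor = dehulling_factor,
         hulled_groups = as.character(hulled_groups),
         lal = lal, desired_gains = desired_gains, ridge = ridge),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' The file mirrors the fields of [analysis_config()]; fields not present
#' keep their defaults. YAML is a superset of JSON, so plain JSON configs
#' are accepted too.
#'
#' @param path path to a YAML/JSON config file.
#' @param ... field overrides applied after reading (e.g. from CLI flags).
#' @return An `analysis_config` object.
#' @export
read_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(analysis_config)))
  args <- lapply(raw[keep], function(x) if (is.list(x)) unlist(x) else x)
  over <- list(...)
  args[names(over)] <- over
  do.call(analysis_config, args)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat("  minerals:        ", paste(names(x$dri), collapse = ", "), "\n")
  cat("  DRI (mg/day):    ", paste(format(x$dri), collapse = ", "), "\n")
  cat("  year days:       ", x$year_days, "\n")
  cat("  dehulling:       ", x$dehulling_factor, "for groups",
      paste(x$hulled_groups, collapse = ", "), "\n")
  cat("  LAL:             ", paste(format(x$lal), collapse = ", "), "\n")
  cat("  desired gains:   ", paste(format(x$desired_gains), collapse = ", "), "\n")
  invisible(x)
}

# Report-scale rounding: nearest integer, halves away from zero, matching the
# convention of the published tables. Internal computation stays full
# precision; this is applied only when emitting report tables.
round_half_away <- function(x) trunc(x + 0.5 * sign(x))
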