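#' Dose-group PK summary of the emulated Phase 2 trial
#'
#' Published per-group summary statistics (arithmetic mean/SD; median and
#' range for tmax) of the non-compartmental PK parameters, by BSA dosing
#' threshold (2500 IU/m^2 for BSA >= 0.6 m^2, n = 22; 82.5 IU/kg for
#' BSA < 0.6 m^2, n = 4). Used as calibration guides for the synthetic
#' cohort generator and for internal-consistency checks such as the
#' approximately 2.7-fold CL and Vss ratio between dosing groups; these
#' are aggregate statistics, not patient-level data.
#'
#' @return data frame with columns `parameter`, `stat`, `bsa_ge_0.6`,
#'   `bsa_lt_0.6`.
#' @export
trial_pk_summary <- function() {
  utils::read.csv(system.file("extdata", "pk_group_summary.csv",
                              package = "pegaspk"))
}
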