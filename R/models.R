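# Canonical hypothesis models for the two-group, two-scanner cohort.
#
# Model "amplitude": dependent mPerAF; cells age group x scanner; group-wise
#   mean-centered, group-split hippocampal volume, TIV and WMLV; collapsed
#   (but group-wise centered) age; GMV as a cell-expanded voxel-wise
#   covariate. 15 columns.
# Model "sme": identical design with the SME map as dependent.
# Model "coupling": dependent SME; cells; group-wise centered age; mPerAF
#   and GMV as cell-expanded voxel-wise covariates. 13 columns.

scalar_block_default <- function() {
  list(
    hc_vol = list(center = "groupwise_mean_center", split = TRUE,
                  label = "HCvol"),
    tiv = list(center = "groupwise_mean_center", split = TRUE, label = "TIV"),
    wmlv = list(center = "groupwise_mean_center", split = TRUE,
                label = "WMLV"),
    age = list(center = "groupwise_mean_center", split = FALSE, label = "age"))
}

#' Default hypothesis models
#'
#' Build the three standard [group_model_spec()]s for the cohort design:
#' `"amplitude"` (does resting amplitude depend on group / hippocampal
#' volume?), `"sme"` (same design on the encoding map), and `"coupling"`
#' (does the encoding map depend on resting amplitude, by group?). Column
#' names follow the field convention, e.g. `young_Skyra, young_Verio,
#' older_Skyra, older_Verio, HCvol_young, HCvol_old, TIV_young, TIV_old,
#' WMLV_young, WMLV_old, age, GMV_young_Skyra, GMV_young_Verio,
#' GMV_old_Skyra, GMV_old_Verio` for `"amplitude"`.
#'
#' @param model One of `"amplitude"`, `"sme"`, `"coupling"`.
#' @param analysis_mask Logical 3D array or vector of analyzed voxels.
#' @return A [group_model_spec()].
#' @export
default_model <- function(model = c("amplitude", "sme", "coupling"),
                          analysis_mask = NULL) {
  model <- match.arg(model)
  if (model == "amplitude" || model == "sme") {
    group_model_spec(
      dependent = if (model == "amplitude") "mperaf" else "sme",
      cell_factors = c("age_group", "scanner"),
      scalar_covariates = scalar_block_default(),
      voxelwise_covariates = list(
        gmv = list(split = "cell", label = "GMV")),
      analysis_mask = analysis_mask)
  } else {
    group_model_spec(
      dependent = "sme",
      cell_factors = c("age_group", "scanner"),
      scalar_covariates = list(
        age = list(center = "groupwise_mean_center", split = FALSE,
                   label = "age")),
      voxelwise_covariates = list(
        mperaf = list(split = "cell", label = "mPerAF"),
        gmv = list(split = "cell", label = "GMV")),
      analysis_mask = analysis_mask)
  }
}

#' Standard contrasts for the default models
#'
#' Named contrast weight vectors over the columns of a [default_model()]
#' design: group differences averaged over scanners, and positive/negative
#' effects of a (possibly cell-expanded) covariate per group or collapsed.
#'
#' @param name One of `"young_gt_old"`, `"old_gt_young"`,
#'   `"mperaf_neg_young"`, `"mperaf_pos_young"`, `"mperaf_neg_old"`,
#'   `"mperaf_pos_old"`, `"mperaf_pos_all"`, `"mperaf_neg_all"`,
#'   `"hcvol_pos_young"`, `"hcvol_neg_young"`, `"hcvol_pos_old"`,
#'   `"hcvol_neg_old"`.
#' @return A named numeric contrast (to be passed to [t_contrast()] /
#'   [fwe_threshold()]).
#' @export
default_contrast <- function(name) {
  half <- 0.5
  switch(
    name,
    young_gt_old = c(young_Skyra = half, young_Verio = half,
                     older_Skyra = -half, older_Verio = -half),
    old_gt_young = c(young_Skyra = -half, young_Verio = -half,
                     older_Skyra = half, older_Verio = half),
    mperaf_neg_young = c(mPerAF_young_Skyra = -half, mPerAF_young_Verio = -half),
    mperaf_pos_young = c(mPerAF_young_Skyra = half, mPerAF_young_Verio = half),
    mperaf_neg_old = c(mPerAF_old_Skyra = -half, mPerAF_old_Verio = -half),
    mperaf_pos_old = c(mPerAF_old_Skyra = half, mPerAF_old_Verio = half),
    mperaf_pos_all = c(mPerAF_young_Skyra = 0.25, mPerAF_young_Verio = 0.25,
                       mPerAF_old_Skyra = 0.25, mPerAF_old_Verio = 0.25),
    mperaf_neg_all = c(mPerAF_young_Skyra = -0.25, mPerAF_young_Verio = -0.25,
                       mPerAF_old_Skyra = -0.25, mPerAF_old_Verio = -0.25),
    hcvol_pos_young = c(HCvol_young = 1),
    hcvol_neg_young = c(HCvol_young = -1),
    hcvol_pos_old = c(HCvol_old = 1),
    hcvol_neg_old = c(HCvol_old = -1),
    stop("unknown contrast: ", name, call. = FALSE))
}
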