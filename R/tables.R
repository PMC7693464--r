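# Bundled reference values from the motivating 15-subject prefrontal fNIRS
# tooth-clench experiment (22-channel probe, 10 Hz). These serve two roles:
# (i) default task-effect magnitudes for the synthetic cohort generator, and
# (ii) published summary numbers against which the package's metric and
# aggregation arithmetic is regression-checked.

#' Anatomical region label for each fNIRS channel
#'
#' The 22-channel prefrontal probe maps onto the superior (SFG), middle (MFG)
#' and inferior (IFG) frontal gyri via virtual registration to the 10-20
#' system.
#'
#' @return character vector of length 22 with values `"SFG"`, `"MFG"`, `"IFG"`.
#' @export
channel_regions <- function() {
  reg <- rep("MFG", 22L)
  reg[c(2, 3, 7, 12, 16, 21)] <- "SFG"
  reg[c(14, 18, 19)] <- "IFG"
  reg
}

#' Reference per-channel hemoglobin changes during tooth clenching
#'
#' Mean clench-minus-rest concentration changes (and across-subject SDs, in
#' m(mol/L)*mm) for each of the 22 prefrontal channels, with the
#' Bonferroni-adjusted paired-t p-values as published (adjusted p = raw p x 22,
#' uncapped, hence values above 1). These are the default task-effect
#' amplitudes used by [effect_profile()].
#'
#' @param species `"oxy"` or `"deoxy"`.
#' @return data.frame with columns `channel`, `change_mean`, `change_sd`,
#'   `p_adj`, `region`.
#' @export
hb_effect_table <- function(species = c("oxy", "deoxy")) {
  species <- match.arg(species)
  if (species == "oxy") {
    change_mean <- c(0.038, -0.021, -0.006, 0.027, 0.057, -0.006, -0.044,
                     -0.033, 0.097, 0.128, -0.032, -0.043, 0.092, 0.084,
                     0.080, -0.040, -0.098, 0.179, 0.305, 0.093, 0.061, 0.132)
    change_sd <- c(0.134, 0.151, 0.125, 0.104, 0.200, 0.124, 0.229, 0.242,
                   0.095, 0.158, 0.221, 0.360, 0.252, 0.553, 0.182, 0.306,
                   0.540, 0.196, 0.247, 0.356, 0.293, 0.320)
    p_adj <- c(6.83, 13.27, 19.14, 7.54, 6.67, 18.71, 10.67, 13.58, 0.04,
               0.20, 13.00, 14.46, 4.22, 12.69, 2.68, 12.20, 11.19, 0.09,
               0.01, 7.63, 9.88, 3.20)
  } else {
    change_mean <- c(-0.029, -0.025, -0.027, -0.042, 0.043, -0.030, -0.045,
                     -0.036, -0.021, 0.016, -0.028, -0.023, -0.013, 0.240,
                     -0.041, -0.074, -0.119, 0.078, 0.068, -0.037, -0.028,
                     -0.068)
    change_sd <- c(0.041, 0.053, 0.047, 0.087, 0.190, 0.052, 0.039, 0.048,
                   0.112, 0.108, 0.051, 0.054, 0.059, 0.515, 0.079, 0.108,
                   0.288, 0.180, 0.126, 0.123, 0.093, 0.240)
    p_adj <- c(0.42, 2.09, 1.08, 2.03, 9.13, 1.09, 0.02, 0.30, 10.95, 12.79,
               1.32, 3.03, 9.23, 2.27, 1.52, 0.47, 3.19, 2.78, 1.40, 6.40,
               6.34, 6.78)
  }
  data.frame(channel = 1:22, change_mean = change_mean,
             change_sd = change_sd, p_adj = p_adj,
             region = channel_regions())
}

#' Reference per-group identification rates of the three trained networks
#'
#' Published per-fold (subject groups A-E) identification rates for the
#' networks trained on oxy, deoxy and mixed (OD) frames. Percentages are as
#' printed (1 decimal), F-values to 3 decimals. Used to regression-check the
#' package's metric/aggregation formulas.
#'
#' @return data.frame with columns `modality`, `group`, `accuracy`, `recall`,
#'   `specificity`, `precision` (percent) and `f_value`.
#' @export
reference_metrics <- function() {
  grp <- rep(LETTERS[1:5], 3)
  mod <- rep(c("oxy", "deoxy", "od"), each = 5)
  acc <- c(78.0, 84.4, 88.1, 98.4, 85.3,
           56.2, 86.2, 90.2, 84.1, 64.0,
           83.3, 85.3, 94.8, 98.8, 89.2)
  rec <- c(75.1, 86.0, 97.9, 97.3, 77.2,
           62.8, 90.8, 88.7, 73.7, 67.9,
           70.0, 87.5, 92.0, 97.6, 93.5)
  spc <- c(80.9, 82.9, 78.4, 99.5, 93.5,
           49.7, 81.6, 91.6, 94.5, 60.2,
           96.5, 83.1, 97.6, 100.0, 85.0)
  prc <- c(79.7, 83.4, 81.9, 99.5, 92.2,
           55.5, 83.2, 91.3, 93.0, 63.0,
           95.3, 83.8, 97.5, 100.0, 86.1)
  f <- c(0.773, 0.847, 0.892, 0.984, 0.840,
         0.590, 0.868, 0.900, 0.822, 0.654,
         0.807, 0.856, 0.946, 0.988, 0.897)
  data.frame(modality = mod, group = grp, accuracy = acc, recall = rec,
             specificity = spc, precision = prc, f_value = f)
}

#' Reference macro-averaged identification rates
#'
#' Published fold-averaged mean and SD per metric and modality.
#'
#' @return data.frame with columns `modality`, `metric`, `mean`, `sd`
#'   (percent scale except `f_value`).
#' @export
reference_macro <- function() {
  data.frame(
    modality = rep(c("oxy", "deoxy", "od"), each = 5),
    metric = rep(c("accuracy", "recall", "specificity", "precision",
                   "f_value"), 3),
    mean = c(86.8, 86.7, 87.0, 87.3, 0.867,
             76.1, 76.8, 75.5, 77.2, 0.767,
             90.3, 88.1, 92.4, 92.5, 0.899),
    sd = c(7.4, 10.8, 9.0, 8.3, 0.078,
           15.1, 12.5, 19.7, 17.0, 0.137,
           6.5, 10.8, 7.8, 7.1, 0.071)
  )
}

#' Reference pooled test-image counts per network
#'
#' Published pooled counts of correctly identified test images per modality,
#' the inputs to the stepwise multiple-proportion comparison.
#'
#' @return data.frame with columns `modality`, `correct`, `total`.
#' @export
reference_counts <- function() {
  data.frame(modality = c("od", "oxy", "deoxy"),
             correct = c(8502L, 11170L, 8052L),
             total = c(9442L, 12878L, 10602L))
}

#' Reference pooled AUCs with 95 percent confidence intervals
#'
#' @return data.frame with columns `modality`, `auc`, `ci_lo`, `ci_hi`.
#' @export
reference_auc <- function() {
  data.frame(modality = c("oxy", "deoxy", "od"),
             auc = c(0.867, 0.759, 0.900),
             ci_lo = c(0.861, 0.750, 0.893),
             ci_hi = c(0.874, 0.769, 0.907))
}
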