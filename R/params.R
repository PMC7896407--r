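# Default baseline phenotype distributions per group x subtype.
# Means and SDs emulate published amyloid-positive ADNI cohort
# characteristics; composite cognitive scores are on the ADNI composite
# scale, CSF markers in pg/ml, AV45 in SUVR, volumes in TIV-scaled units
# (x1000), WMH in ml. The prodromal cortical-predominant row has no
# published counterpart (too few observed cases) and is a package default.
baseline_params <- function() {
  cols <- c("age_m", "age_sd", "female", "edu_m", "edu_sd", "mmse_m",
            "mmse_sd", "mem_m", "mem_sd", "ef_m", "ef_sd", "vs_m", "vs_sd",
            "lan_m", "lan_sd", "apoe4", "av45_m", "av45_sd", "abeta_m",
            "abeta_sd", "ttau_m", "ttau_sd", "ptau_m", "ptau_sd", "hv_m",
            "hv_sd", "ctv_m", "ctv_sd", "wmh_m", "wmh_sd")
  rows <- list(
    `CN.none` = c(73.8, 6.5, 0.50, 16.6, 2.5, 29.1, 1.2, 1.04, 0.62, 0.92,
                  0.83, 0.23, 0.59, 0.89, 0.71, 0.28, 1.11, 0.18, 1392, 663,
                  236, 92, 22, 9, 4.97, 0.38, 87.39, 6.28, 6.1, 10.4),
    `AD.limbic_predominant` = c(75.4, 6.9, 0.49, 15.4, 3.1, 23.4, 1.9,
                  -0.85, 0.55, -0.65, 0.86, -0.42, 0.80, -0.63, 0.95, 0.81,
                  1.43, 0.14, 598, 163, 374, 143, 38, 16, 4.05, 0.51, 75.84,
                  6.95, 8.0, 10.0),
    `AD.typical` = c(73.2, 5.7, 0.38, 15.5, 2.6, 23.2, 2.2, -0.90, 0.49,
                  -1.11, 0.89, -0.67, 1.01, -0.83, 0.88, 0.79, 1.47, 0.17,
                  585, 225, 374, 154, 37, 16, 4.10, 0.38, 73.99, 6.23,
                  5.8, 7.9),
    `AD.cortical_predominant` = c(68.0, 7.7, 0.50, 16.3, 2.6, 22.0, 2.2,
                  -1.31, 0.44, -1.73, 0.81, -1.15, 1.08, -1.11, 0.78, 0.58,
                  1.40, 0.17, 629, 169, 402, 124, 39, 14, 4.46, 0.46, 70.04,
                  5.88, 8.1, 12.7),
    `MCI.no_hypometabolism` = c(68.4, 6.6, 0.60, 16.2, 2.8, 28.2, 1.8, 0.57,
                  0.63, 0.76, 0.91, 0.08, 0.65, 0.60, 0.70, 0.68, 1.31,
                  0.17, 921, 437, 315, 134, 31, 15, 4.86, 0.45, 89.87, 5.45,
                  4.9, 5.0),
    `MCI.limbic_predominant` = c(76.1, 5.7, 0.35, 15.7, 3.0, 27.6, 1.8,
                  0.05, 0.61, 0.00, 0.77, -0.06, 0.76, -0.05, 0.74, 0.62,
                  1.39, 0.17, 736, 237, 337, 137, 34, 16, 4.53, 0.51, 83.19,
                  6.48, 11.3, 12.8),
    `MCI.typical` = c(71.7, 6.2, 0.41, 16.4, 2.6, 27.3, 1.8, -0.06, 0.65,
                  0.15, 1.01, -0.21, 0.67, 0.29, 0.79, 0.77, 1.43, 0.15,
                  672, 214, 357, 144, 37, 16, 4.57, 0.41, 82.93, 5.35,
                  6.8, 6.5),
    `MCI.cortical_predominant` = c(69.0, 6.5, 0.50, 16.3, 2.6, 27.2, 1.8,
                  -0.05, 0.65, -0.35, 0.95, -0.30, 0.70, 0.10, 0.80, 0.58,
                  1.40, 0.16, 680, 210, 360, 140, 37, 16, 4.80, 0.45, 80.50,
                  5.50, 7.0, 7.0))
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  as.data.frame(m)
}
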