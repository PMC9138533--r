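# Synthetic cohort generator.
#
# Emulates the measured study conditions: a treated cohort split into
# low/high lung-inflammation groups by CD45 infiltration, six informative
# biomarkers with group-specific normal moments (NLR, GM-CSF, CT average
# gray, CT histogram kurtosis, CT co-occurrence entropy, MR histogram
# kurtosis), the remaining CBC and cytokine panels drawn uniformly within
# their published cohort ranges identically in both groups, and
# non-informative nuisance features filling each modality's radiomics
# vector up to 92 entries.

# CBC panel ranges (units as printed: counts 10^3/uL, RBC 10^6/uL, HGB g/dL,
# percentages %, MCV/MPV fL, MCH pg, MCHC g/dL).
cbc_ranges <- function() {
  data.frame(
    name = c("WBC", "Neu", "Lym", "Mon", "Eos", "Bas",
             "Neu_pct", "Lym_pct", "Mon_pct", "Eos_pct", "Bas_pct",
             "RBC", "HGB", "HCT", "MCV", "MCH", "MCHC", "RDW_CV",
             "PLT", "MPV"),
    min = c(0.98, 0.37, 0.53, 0.05, 0.02, 0.01,
            26.4, 48.1, 2.2, 0.8, 0.5,
            1.79, 4, 8.8, 48.5, 15.6, 29.9, 12.9, 184, 5.1),
    max = c(7.95, 3.09, 4.43, 0.42, 0.28, 0.12,
            42.2, 65.5, 8, 5.7, 1.8,
            8.43, 13.4, 42.4, 52.7, 22.6, 45.5, 23.3, 1137, 5.9),
    stringsAsFactors = FALSE
  )
}

# Serum cytokine ranges (pg/mL). RANTES is constant at its detection-limit
# value in the source panel; downstream screening discards it as degenerate.
cytokine_ranges <- function() {
  data.frame(
    name = c("KC", "TNF_a", "MCP_1", "RANTES", "IL_1b", "IP_10", "GM_CSF"),
    min = c(33.345, 3.77, 232.235, 41.355, 4.87, 82.44, 8.54),
    max = c(380.18, 29.59, 2362.09, 41.355, 29.22, 512.41, 15.54),
    stringsAsFactors = FALSE
  )
}

# Group-specific normal moments for the informative biomarkers.  Floors are
# applied only where the printed moments leave them far out in the tail
# (NLR > 0, non-negative cytokine/gray/entropy); the histogram-kurtosis
# columns are drawn untruncated because their printed moments put
# non-negligible normal mass below the mathematical floor and moment
# fidelity takes precedence in a tabular emulation.
default_biomarker_params <- function() {
  data.frame(
    feature = c("NLR", "GM_CSF", "ct_average_gray", "ct_hist_kurtosis",
                "ct_cooc_entropy", "mr_hist_kurtosis"),
    mean_low  = c(0.7, 8.8, 278.4, 2.6, 12.1, 6.1),
    sd_low    = c(0.1, 0.6, 9.0, 0.4, 0.1, 3.3),
    mean_high = c(0.6, 11.7, 289.9, 3.8, 12.3, 3.7),
    sd_high   = c(0.1, 2.2, 15.3, 1.7, 0.1, 1.6),
    floor     = c(0.01, 0, 0, -Inf, 0, -Inf),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults reproduce the study conditions: 7 low- / 8 high-inflammation
#' subjects, CD45 group moments 0.176 (sd 0.041) and 0.324 (sd 0.055), the
#' six informative biomarkers at their published group means/SDs, and enough
#' standard-normal nuisance features that each imaging modality carries 92
#' radiomics columns (3 informative CT + 89 nuisance; 1 informative MR + 91
#' nuisance).
#'
#' @param n_low,n_high Subjects per group (each >= 1, total >= 4).
#' @param cd45_params List with `low = c(mean, sd)` and `high = c(mean, sd)`.
#' @param biomarker_params Data frame with columns `feature`, `mean_low`,
#'   `sd_low`, `mean_high`, `sd_high`, `floor`.
#' @param n_nuisance_ct,n_nuisance_mr Count of non-informative features per
#'   modality, drawn N(0,1) identically in both groups.
#' @param seed Integer RNG seed or `NULL`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_low = 7, n_high = 8,
                        cd45_params = list(low = c(0.176, 0.041),
                                           high = c(0.324, 0.055)),
                        biomarker_params = default_biomarker_params(),
                        n_nuisance_ct = 89, n_nuisance_mr = 91,
                        seed = NULL) {
  assert_that(n_low >= 1 && n_high >= 1, "subject counts must be positive")
  assert_that(n_low + n_high >= 4, "cohort must have at least 4 subjects")
  assert_that(all(c("feature", "mean_low", "sd_low", "mean_high",
                    "sd_high", "floor") %in% names(biomarker_params)),
              "biomarker_params is missing required columns")
  assert_that(all(biomarker_params$sd_low >= 0) &&
              all(biomarker_params$sd_high >= 0) &&
              all(cd45_params$low[2] >= 0, cd45_params$high[2] >= 0),
              "standard deviations must be non-negative")
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 cd45_params = cd45_params,
                 biomarker_params = biomarker_params,
                 n_nuisance_ct = as.integer(n_nuisance_ct),
                 n_nuisance_mr = as.integer(n_nuisance_mr),
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic tabular cohort
#'
#' Draws one record per subject: a group label, a CD45 inflammation score
#' from its group's normal distribution (truncated at 0 by resampling),
#' the informative biomarkers from group-specific normals, the remaining
#' CBC/cytokine columns uniformly within their published ranges identically
#' in both groups, and N(0,1) nuisance radiomics columns. Neutrophil counts
#' are set to `NLR x Lym` so that the derived neutrophil-to-lymphocyte ratio
#' carries the planted group effect. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec].
#' @return A data frame with columns `subject_id`, `group`, `cd45`, the CBC
#'   panel, the cytokine panel, the CT/MR biomarkers and nuisance features.
#' @export
generate_tabular_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  with_seed(spec$seed, {
    n <- spec$n_low + spec$n_high
    group <- rep(c("low", "high"), c(spec$n_low, spec$n_high))
    draw_group <- function(mean_low, sd_low, mean_high, sd_high, floor = -Inf) {
      c(rnorm_floor(spec$n_low, mean_low, sd_low, floor),
        rnorm_floor(spec$n_high, mean_high, sd_high, floor))
    }
    cd45 <- draw_group(spec$cd45_params$low[1], spec$cd45_params$low[2],
                       spec$cd45_params$high[1], spec$cd45_params$high[2],
                       floor = 0)
    bp <- spec$biomarker_params
    bio <- lapply(seq_len(nrow(bp)), function(i)
      draw_group(bp$mean_low[i], bp$sd_low[i], bp$mean_high[i], bp$sd_high[i],
                 floor = bp$floor[i]))
    names(bio) <- bp$feature

    cbc <- cbc_ranges()
    panel <- lapply(seq_len(nrow(cbc)), function(i)
      runif(n, cbc$min[i], cbc$max[i]))
    names(panel) <- cbc$name
    if (!is.null(bio$NLR)) panel$Neu <- bio$NLR * panel$Lym

    cyt <- cytokine_ranges()
    serum <- lapply(seq_len(nrow(cyt)), function(i)
      runif(n, cyt$min[i], cyt$max[i]))
    names(serum) <- cyt$name
    if (!is.null(bio$GM_CSF)) serum$GM_CSF <- bio$GM_CSF

    nuis <- c(
      setNames(lapply(seq_len(spec$n_nuisance_ct), function(i) rnorm(n)),
               sprintf("ct_nuis_%02d", seq_len(spec$n_nuisance_ct))),
      setNames(lapply(seq_len(spec$n_nuisance_mr), function(i) rnorm(n)),
               sprintf("mr_nuis_%02d", seq_len(spec$n_nuisance_mr)))
    )

    out <- data.frame(subject_id = sprintf("s%04d", seq_len(n)),
                      group = group, cd45 = cd45,
                      stringsAsFactors = FALSE)
    extra <- bio[setdiff(names(bio), c("NLR", "GM_CSF"))]
    cbind(out, as.data.frame(panel), as.data.frame(serum),
          as.data.frame(extra), as.data.frame(nuis))
  })
}
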