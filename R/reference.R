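#' Published reference values for the 17-site bipolar disorder cohort
#'
#' Summary statistics printed by a 17-site mega-analysis of subcortical
#' volumes in bipolar disorder (1601 controls, 1134 cases), which this
#' package's default generator configuration emulates. These are inputs
#' for worked examples and calibration checks — demographic summaries,
#' region-level model coefficients (with the group contrast in the
#' original control-positive print coding), and the mediation summary for
#' the lateral ventricles — not quantities the package computes.
#'
#' @return A list with elements:
#' * `age`, `bmi`: per-group `mean`, `sd`, `n`;
#' * `weight_counts`, `sex_counts`: 2-row contingency tables
#'   (control/case);
#' * `table2`: data.frame of per-region coefficients `b`, `se`, `df` for
#'   each model family (`group_only`, `bmi_only`, `joint`) and term;
#' * `mediation`: `indirect`, `indirect_ci`, `total` (magnitude of the
#'   group-only coefficient), `prop_mediated_pct`, `prop_ci`, `sobel_z`;
#' * `n1`, `n2`: control and case sample sizes.
#' @export
study_reference <- function() {
  t2 <- rbind(
    data.frame(family = "group_only", term = "group",
               roi = c("accumbens", "amygdala", "hippocampus", "pallidum",
                       "putamen", "caudate", "thalamus", "lateral_ventricles"),
               b = c(4.66, 21.70, 44.49, 34.21, -9.52, 57.37, 82.77, -613.65),
               se = c(4.09, 8.62, 17.68, 10.35, 24.89, 18.61, 29.78, 187.28),
               df = c(2372, 2380, 2386, 2274, 2351, 2388, 2382, 2414)),
    data.frame(family = "bmi_only", term = "bmi",
               roi = c("accumbens", "amygdala", "hippocampus", "pallidum",
                       "putamen", "caudate", "thalamus", "lateral_ventricles"),
               b = c(0.23, 2.96, 0.03, -2.60, 3.48, -2.75, 3.49, 61.22),
               se = c(0.39, 0.81, 1.66, 0.97, 2.36, 1.75, 2.80, 17.61),
               df = c(2372, 2380, 2386, 2274, 2351, 2388, 2382, 2414)),
    data.frame(family = "joint", term = "group",
               roi = c("accumbens", "amygdala", "hippocampus", "pallidum",
                       "putamen", "caudate", "thalamus", "lateral_ventricles"),
               b = c(5.38, 29.70, 46.59, 29.76, -2.26, 53.62, 94.66, -500.84),
               se = c(4.17, 8.78, 18.08, 10.58, 25.40, 19.02, 30.44, 191.11),
               df = c(2371, 2379, 2385, 2273, 2350, 2387, 2381, 2413)),
    data.frame(family = "joint", term = "bmi",
               roi = c("accumbens", "amygdala", "hippocampus", "pallidum",
                       "putamen", "caudate", "thalamus", "lateral_ventricles"),
               b = c(0.33, 3.55, 0.95, -2.02, 3.43, -1.71, 5.35, 51.54),
               se = c(0.40, 0.82, 1.69, 0.99, 2.41, 1.78, 2.86, 17.98),
               df = c(2371, 2379, 2385, 2273, 2350, 2387, 2381, 2413)))
  list(
    age = list(control = c(mean = 35.47, sd = 12.63, n = 1601),
               case = c(mean = 41.72, sd = 12.66, n = 1134)),
    bmi = list(control = c(mean = 24.43, sd = 4.12, n = 1601),
               case = c(mean = 26.80, sd = 5.22, n = 1134)),
    weight_counts = rbind(control = c(normal = 1014, overweight = 437,
                                      obese = 150),
                          case = c(normal = 470, overweight = 399,
                                   obese = 265)),
    sex_counts = rbind(control = c(female = 916, male = 685),
                       case = c(female = 684, male = 450)),
    table2 = t2,
    mediation = list(indirect = 112.97, indirect_ci = c(50.33, 174.12),
                     total = 613.65, prop_mediated_pct = 18.41,
                     prop_ci = c(5.71, 46.64), sobel_z = 2.73),
    n1 = 1601, n2 = 1134)
}
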