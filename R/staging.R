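# Rule-based staging of oncosis progression from per-cell morphological
# features and annexin V / PI status.

ONCOSIS_STAGES <- c("not_oncotic", "transition", "early", "late",
                    "necrosis_transition")

#' Build an oncosis feature record
#'
#' @param bleb_count number of membrane blebs.
#' @param max_bleb_area largest bleb area, pixels.
#' @param spindle_shape_lost loss of spindle cell shape.
#' @param nucleus_swollen significant nuclear swelling (membrane still
#'   distinguishable).
#' @param karyolysis_or_membrane_rupture karyolysis or plasma-membrane
#'   rupture (necrotic morphology). Not detectable from phase images alone;
#'   supplied from fluorescence/ultrastructure annotation or generator truth.
#' @param rel_mass dry mass relative to the cohort mean.
#' @param annexin_pos,pi_pos staining status.
#' @return data.frame with one row per feature record (vectorised inputs
#'   are recycled to the longest).
#' @export
oncosis_features <- function(bleb_count = 0L, max_bleb_area = 0,
                             spindle_shape_lost = FALSE,
                             nucleus_swollen = FALSE,
                             karyolysis_or_membrane_rupture = FALSE,
                             rel_mass = 1, annexin_pos = FALSE,
                             pi_pos = FALSE) {
  f <- data.frame(bleb_count = as.integer(bleb_count),
                  max_bleb_area = max_bleb_area,
                  spindle_shape_lost = spindle_shape_lost,
                  nucleus_swollen = nucleus_swollen,
                  karyolysis_or_membrane_rupture =
                    karyolysis_or_membrane_rupture,
                  rel_mass = rel_mass, annexin_pos = annexin_pos,
                  pi_pos = pi_pos)
  if (any(f$bleb_count < 0)) stop("bleb_count must be nonnegative")
  if (any(f$rel_mass <= 0)) stop("rel_mass must be positive")
  f
}

#' Assign the oncosis progression stage of one cell
#'
#' First matching rule wins, evaluated from the most advanced stage down
#' (later stages subsume earlier criteria):
#' \enumerate{
#'   \item annexin+ and PI+ with karyolysis/membrane rupture ->
#'     `necrosis_transition`;
#'   \item annexin+ and PI+ with nuclear swelling -> `late`;
#'   \item annexin+ and PI- with at least one bleb -> `early`;
#'   \item annexin- and PI- with blebs and above-average mass ->
#'     `transition` (the stage only native morphology can reveal);
#'   \item otherwise `not_oncotic`.
#' }
#'
#' @param f a single-row feature record from [oncosis_features()] (or any
#'   list with the same fields).
#' @return one of `"not_oncotic"`, `"transition"`, `"early"`, `"late"`,
#'   `"necrosis_transition"`.
#' @export
stage_oncosis <- function(f) {
  if (isTRUE(f$annexin_pos) && isTRUE(f$pi_pos) &&
      isTRUE(f$karyolysis_or_membrane_rupture)) return("necrosis_transition")
  if (isTRUE(f$annexin_pos) && isTRUE(f$pi_pos) &&
      (isTRUE(f$nucleus_swollen) || f$bleb_count >= 1)) return("late")
  if (isTRUE(f$annexin_pos) && !isTRUE(f$pi_pos) && f$bleb_count >= 1)
    return("early")
  if (!isTRUE(f$annexin_pos) && !isTRUE(f$pi_pos) && f$bleb_count >= 1 &&
      f$rel_mass > 1) return("transition")
  "not_oncotic"
}

#' Stage a cohort of feature records
#'
#' @param features data.frame of feature records ([oncosis_features()]).
#' @return list with `stages` (character, input order preserved) and
#'   `histogram` (named counts over all five stages).
#' @export
stage_cohort <- function(features) {
  if (NROW(features) == 0) stop("empty feature table")
  stages <- vapply(seq_len(nrow(features)),
                   function(i) stage_oncosis(features[i, , drop = FALSE]),
                   character(1))
  hist <- table(factor(stages, levels = ONCOSIS_STAGES))
  list(stages = stages, histogram = setNames(as.integer(hist),
                                             ONCOSIS_STAGES))
}
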