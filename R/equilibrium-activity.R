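#' Normalize autophosphorylation blot intensities to protein loading
#'
#' Kinase activity is read from the pY551 (activation-loop
#' autophosphorylation) band, and total protein from the anti-His band of
#' the same lane. Each lane's activity is `py551 / his`, rescaled so the
#' reference lane equals exactly 1; loading differences cancel.
#'
#' @param measurements Tibble with columns `label`, `py551`, `his`.
#' @param reference_label Label whose normalized activity is set to 1.
#'
#' @return Tibble with columns `label`, `value`. Records with
#'   non-positive `his` are dropped with a warning (the reference record
#'   must be valid).
#' @export
#' @examples
#' normalize_blot(
#'   tibble::tibble(label = c("WT", "T316A"),
#'                  py551 = c(100, 200), his = c(50, 50)),
#'   reference_label = "WT")
normalize_blot <- function(measurements, reference_label) {
  stopifnot(all(c("label", "py551", "his") %in% names(measurements)))
  bad <- measurements$his <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive anti-His intensity ",
            "rejected", call. = FALSE)
    measurements <- measurements[!bad, ]
  }
  if (!reference_label %in% measurements$label) {
    stop("reference label '", reference_label, "' not present (or rejected)",
         call. = FALSE)
  }
  ratio <- measurements$py551 / measurements$his
  ref <- ratio[match(reference_label, measurements$label)]
  tibble::tibble(label = measurements$label, value = ratio / ref)
}

#' Fold change in active-state population between two estimates
#'
#' @param est_a Reference population estimate (one-row tibble with
#'   `f_active`, `f_inactive`), e.g. wild type.
#' @param est_b Comparison estimate, e.g. a mutant.
#'
#' @return `est_b$f_active / est_a$f_active`.
#' @export
#' @examples
#' wt <- tibble::tibble(f_active = 0.28, f_inactive = 0.72)
#' mut <- tibble::tibble(f_active = 0.40, f_inactive = 0.60)
#' population_fold_change(wt, mut)  # ~1.43
population_fold_change <- function(est_a, est_b) {
  stopifnot(all(c("f_active", "f_inactive") %in% names(est_a)),
            all(c("f_active", "f_inactive") %in% names(est_b)))
  if (est_a$f_active <= 0) {
    stop("reference active population is zero; fold change undefined",
         call. = FALSE)
  }
  est_b$f_active / est_a$f_active
}

#' Predicted activity fold change under linear population-activity coupling
#'
#' The simplest coupling between conformational equilibrium and catalysis
#' is proportionality: activity scales with the active-state (alphaC-in)
#' population, with no basal offset. The predicted activity fold change
#' between two states then equals their active-population fold change.
#' The prediction is reported for comparison with a measured fold change,
#' never forced to match it: deviations indicate coupling beyond the
#' two-state linear model.
#'
#' @inheritParams population_fold_change
#'
#' @return Predicted activity fold change (dimensionless).
#' @export
predict_activity_fold <- function(est_a, est_b) {
  population_fold_change(est_a, est_b)
}

#' Compare predicted and observed activity fold changes
#'
#' @inheritParams population_fold_change
#' @param observed_fold Measured activity fold change (e.g. from
#'   [normalize_blot()]), same orientation (b relative to a).
#'
#' @return One-row tibble with `predicted_fold`, `observed_fold`,
#'   `same_direction` (both on the same side of 1) and `ratio`
#'   (observed / predicted).
#' @export
activity_consistency <- function(est_a, est_b, observed_fold) {
  pred <- predict_activity_fold(est_a, est_b)
  tibble::tibble(
    predicted_fold = pred,
    observed_fold = observed_fold,
    same_direction = (pred - 1) * (observed_fold - 1) >= 0,
    ratio = observed_fold / pred
  )
}
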