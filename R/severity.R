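#' Severity levels for vitamin D deficiency
#'
#' The four clinical grades of vitamin D status used throughout the package,
#' ordered from best (level 1) to worst (level 4). Serum 25-hydroxyvitamin D
#' bands: Optimal above 30 ng/mL, Suboptimal 20-30 ng/mL, Inadequate
#' 10-20 ng/mL, Extremely Inadequate below 10 ng/mL.
#'
#' @return A tibble with columns `level` (integer 1-4), `label`, and the
#'   serum band bounds `lower`/`upper` in ng/mL (`upper` is `Inf` for
#'   Optimal).
#' @export
#' @examples
#' severity_levels()
severity_levels <- function() {
  tibble::tibble(
    level = 1:4,
    label = c("Optimal", "Suboptimal", "Inadequate", "ExtremelyInadequate"),
    lower = c(30, 20, 10, 0),
    upper = c(Inf, 30, 20, 10)
  )
}

severity_labels <- function() severity_levels()$label

#' Assign a severity grade from serum 25-OH-D
#'
#' Maps serum 25-hydroxyvitamin D concentrations (ng/mL) to the four-level
#' severity grade. Band boundaries follow a single consistent convention:
#' Optimal is strictly above 30 ng/mL; the remaining bands are closed at
#' their lower bound and open at the upper, so 30 and 20 are Suboptimal and
#' 10 is Inadequate.
#'
#' @param serum Numeric vector of serum 25-OH-D values in ng/mL. Must be
#'   non-negative and non-missing.
#' @return A factor with levels `Optimal`, `Suboptimal`, `Inadequate`,
#'   `ExtremelyInadequate` (in severity order), same length as `serum`.
#' @export
#' @examples
#' assign_severity(c(35, 30, 20, 10, 5))
assign_severity <- function(serum) {
  if (!is.numeric(serum)) abort("`serum` must be numeric (ng/mL).")
  if (length(serum) && any(is.na(serum))) {
    abort("`serum` contains missing values; severity is undefined.")
  }
  if (length(serum) && any(serum < 0)) {
    abort("`serum` must be non-negative (ng/mL).")
  }
  labs <- severity_labels()
  out <- ifelse(serum > 30, labs[1],
    ifelse(serum >= 20, labs[2],
      ifelse(serum >= 10, labs[3], labs[4])
    )
  )
  factor(out, levels = labs)
}
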