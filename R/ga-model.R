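# Fixed-coefficient gestational-age predictor and Hittner grade lookup.
#
# The shipped coefficients are kept in a versioned JSON file (not hard-coded)
# so that refitted models are drop-in replacements. The file also declares
# the mapping from model term names to biomarker export names, making the
# width-vs-thickness terminology ambiguity explicit and auditable: "thickness"
# terms map to the distance-transform width, "width" terms to the
# chord-perpendicular extent.

#' Load a gestational-age model from a coefficients file
#'
#' @param path JSON file with fields `version`, `feature_units`, `mapping`,
#'   `intercept`, `coefficients`. The mapping must cover every coefficient and
#'   point at exported biomarker names; this is validated at load.
#' @return A `ga_model`: list with `intercept` (weeks), `coefficients`
#'   (named, weeks per feature unit), `mapping`, `feature_units`, `version`.
#' @export
load_ga_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("version", "feature_units", "mapping", "intercept", "coefficients")
  miss <- setdiff(need, names(j))
  if (length(miss) > 0) {
    stop(
      "load_ga_model: coefficients file lacks field(s): ",
      paste(miss, collapse = ", ")
    )
  }
  coefs <- unlist(j$coefficients)
  mapping <- unlist(j$mapping)
  if (any(!is.finite(c(j$intercept, coefs)))) {
    stop("load_ga_model: non-finite intercept or coefficient")
  }
  unmapped <- setdiff(names(coefs), names(mapping))
  if (length(unmapped) > 0) {
    stop(
      "load_ga_model: no feature mapping for term(s): ",
      paste(unmapped, collapse = ", ")
    )
  }
  bad <- setdiff(mapping[names(coefs)], feature_names())
  if (length(bad) > 0) {
    stop(
      "load_ga_model: mapping targets unknown biomarker(s): ",
      paste(bad, collapse = ", ")
    )
  }
  structure(
    list(
      intercept = as.numeric(j$intercept), coefficients = coefs,
      mapping = mapping, feature_units = j$feature_units,
      version = j$version
    ),
    class = "ga_model"
  )
}

#' The shipped fixed-coefficient model
#'
#' Loads the published final-model coefficients bundled with the package
#' (intercept 34.406 weeks; terms for maximal branch length, maximal/minimal
#' branch width and thickness, and density). Predictions with these
#' coefficients are unit-convention dependent: the pixel/percent scale of the
#' features behind them was never published.
#'
#' @return A `ga_model`.
#' @export
default_ga_model <- function() {
  load_ga_model(system.file("extdata", "ga_coefficients.json",
    package = "alcv", mustWork = TRUE
  ))
}

#' Predict gestational age from ALCV biomarkers
#'
#' Computes `intercept + sum(coef_j * feature_j)` over the model's terms,
#' resolving each term through the model's declared feature mapping. No
#' clamping is applied; values outside the 27--37 week validity range trigger
#' a warning.
#'
#' @param model a `ga_model`.
#' @param features an `alcv_features`, or any named list/vector containing the
#'   mapped feature names.
#' @return Predicted gestational age, weeks.
#' @export
predict_ga <- function(model, features) {
  ga <- model$intercept
  for (term in names(model$coefficients)) {
    fname <- model$mapping[[term]]
    val <- features[[fname]]
    if (is.null(val) || !is.finite(as.numeric(val))) {
      stop("predict_ga: missing or non-finite feature '", fname,
        "' (model term '", term, "')")
    }
    ga <- ga + model$coefficients[[term]] * as.numeric(val)
  }
  if (ga < 27 || ga > 37) {
    warning(sprintf(
      "predict_ga: %.2f weeks is outside the 27-37 week validity range", ga
    ))
  }
  ga
}

#' @export
print.ga_model <- function(x, ...) {
  cat(sprintf(
    "<ga_model '%s' (%s)>\n  intercept: %.3f weeks\n",
    x$version, x$feature_units, x$intercept
  ))
  for (term in names(x$coefficients)) {
    cat(sprintf(
      "  %-22s %+8.3f  -> %s\n", term, x$coefficients[[term]],
      x$mapping[[term]]
    ))
  }
  invisible(x)
}

hittner_table <- function() {
  data.frame(
    grade = c("I", "II", "III", "IV"),
    ga_low = c(33, 31, 29, 27),
    ga_high = c(34, 32, 30, 28),
    stringsAsFactors = FALSE
  )
}

#' Gestational-age range of a Hittner grade
#'
#' The four-level ordinal staging of lens-vessel regression: Grade I, 33--34
#' weeks; Grade II, 31--32; Grade III, 29--30; Grade IV, 27--28.
#'
#' @param grade one of `"I"`, `"II"`, `"III"`, `"IV"` (or 1--4).
#' @return Named numeric `c(ga_low, ga_high)` in weeks.
#' @export
hittner_grade_range <- function(grade) {
  tab <- hittner_table()
  if (is.numeric(grade)) grade <- c("I", "II", "III", "IV")[grade]
  i <- match(grade, tab$grade)
  if (is.na(i)) {
    stop("hittner_grade_range: unknown grade '", grade, "'")
  }
  c(ga_low = tab$ga_low[i], ga_high = tab$ga_high[i])
}

#' Classify a gestational age into a Hittner grade
#'
#' The printed grade ranges leave 1-week gaps (e.g. 30--31 weeks); this
#' inverse classifier uses contiguous half-open bins covering 27--35 weeks:
#' IV `[27, 29)`, III `[29, 31)`, II `[31, 33)`, I `[33, 35)`. The bins are a
#' package convention, chosen so the midpoint of every printed range maps back
#' to its own grade.
#'
#' @param ga gestational age, weeks.
#' @return Grade token, or `NA` (with a warning) outside `[27, 35)`.
#' @export
hittner_grade <- function(ga) {
  if (!is.finite(ga) || ga < 27 || ga >= 35) {
    warning("hittner_grade: ", ga, " weeks is outside the graded 27-35 range")
    return(NA_character_)
  }
  c("IV", "III", "II", "I")[findInterval(ga, c(27, 29, 31, 33))]
}
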