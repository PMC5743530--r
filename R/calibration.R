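#' Summary of paired estimate differences
#'
#' Mean and sample standard deviation of the pairwise differences `a - b`,
#' the mean relative value `100 * a / b` (over pairs with positive `b`),
#' and a paired t-test on the differences.
#'
#' @param a,b Equal-length numeric vectors of paired estimates (e.g.
#'   smartphone vs circular values at the same points), `n >= 2`.
#' @return A list with `mean_diff`, `sd_diff`, `mean_ratio_percent`, `n`,
#'   and `p_value` from the paired t-test (NA when the differences are
#'   constant).
#' @export
paired_difference_summary <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("insufficient data: at least 2 complete pairs needed")
  d <- a - b
  ratio <- if (any(b > 0)) mean(100 * a[b > 0] / b[b > 0]) else NA_real_
  p <- if (stats::sd(d) > 0) stats::t.test(a, b, paired = TRUE)$p.value
       else NA_real_
  list(mean_diff = mean(d), sd_diff = stats::sd(d),
       mean_ratio_percent = ratio, n = length(a), p_value = p)
}

# The six fixed-effects model structures compared by AIC, from the simplest
# straight-line transformation up to overstory-specific slopes and
# intercepts plus camera/height covariates.
calibration_structures <- c(
  "y~x",
  "y~x+OV",
  "y~x+x:OV",
  "y~x+x:OV+OV",
  "y~x+x:OV+OV+camera",
  "y~x+x:OV+OV+camera+HFG")

# Translate a structure id into an R formula for the given column names.
structure_formula <- function(structure_id, response, predictor) {
  if (!structure_id %in% calibration_structures) {
    stop("unknown structure id: ", structure_id)
  }
  rhs <- sub("^y~", "", structure_id)
  rhs <- gsub("x", predictor, rhs, fixed = TRUE)
  rhs <- gsub("camera", "camera_type", rhs, fixed = TRUE)
  rhs <- gsub("HFG", "height_from_ground", rhs, fixed = TRUE)
  stats::as.formula(paste(response, "~", gsub("\\+", " + ", rhs)))
}

# Columns a structure needs beyond response/predictor.
structure_covariates <- function(structure_id) {
  out <- character(0)
  if (grepl("OV", structure_id)) out <- c(out, "OV")
  if (grepl("camera", structure_id)) out <- c(out, "camera_type")
  if (grepl("HFG", structure_id)) out <- c(out, "height_from_ground")
  out
}

#' Fit one calibration model structure
#'
#' Ordinary least-squares fit of a fixed-effects transformation model of a
#' circular-camera estimate on its smartphone counterpart, optionally with
#' overstory-type (OV) slope and intercept terms and camera/height
#' covariates. The AIC is computed as `n * ln(RSS / n) + 2 * (k + 1)` with
#' `k` fitted coefficients (the `+ 1` counts the residual variance).
#'
#' @param records Data frame of paired records; must contain `response`,
#'   `predictor`, and any covariate columns the structure requires (`OV`,
#'   `camera_type`, `height_from_ground`).
#' @param response,predictor Column names (e.g. `"CO"` and `"COsm"`).
#' @param structure_id One of `"y~x"`, `"y~x+OV"`, `"y~x+x:OV"`,
#'   `"y~x+x:OV+OV"`, `"y~x+x:OV+OV+camera"`, `"y~x+x:OV+OV+camera+HFG"`.
#' @return An object of class `calibration_model` with the fitted `lm`,
#'   `coefficients`, `n`, `RSS`, `AIC`, `sigma` and factor levels.
#' @export
fit_linear_structure <- function(records, response, predictor,
                                 structure_id = "y~x") {
  stopifnot(is.data.frame(records))
  for (col in c(response, predictor, structure_covariates(structure_id))) {
    if (!col %in% names(records)) {
      stop("degenerate design: required column '", col, "' is missing")
    }
  }
  df <- records
  for (col in structure_covariates(structure_id)) {
    df[[col]] <- factor(df[[col]])
    if (nlevels(df[[col]]) < 2) {
      stop("degenerate design: '", col, "' has fewer than 2 observed levels")
    }
  }
  form <- structure_formula(structure_id, response, predictor)
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("degenerate design: rank-deficient model matrix for ", structure_id)
  }
  k <- length(stats::coef(fit))
  n <- stats::nobs(fit)
  if (n < k + 2) stop("insufficient data: need at least 2 more records than coefficients")
  rss <- max(sum(stats::residuals(fit)^2), .Machine$double.xmin)
  structure(list(structure_id = structure_id, formula = form, fit = fit,
                 coefficients = stats::coef(fit), n = n, RSS = rss,
                 AIC = n * log(rss / n) + 2 * (k + 1),
                 sigma = sqrt(rss / stats::df.residual(fit)),
                 response = response, predictor = predictor,
                 ov_levels = if ("OV" %in% structure_covariates(structure_id))
                   levels(df$OV) else NULL),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: %s on %s; n = %d, AIC = %.1f\n",
              x$structure_id, x$response, x$predictor, x$n, x$AIC))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Compare calibration structures by AIC
#'
#' Fits all applicable model structures (see [fit_linear_structure()]) and
#' ranks them by ascending AIC. Structures whose covariates are missing
#' from `records` or degenerate (single observed level) are skipped and
#' reported in the `skipped` attribute; the base `y~x` structure must
#' always be fittable.
#'
#' @inheritParams fit_linear_structure
#' @param structures Character vector of structure ids to compare.
#' @return A data frame (`structure`, `k`, `RSS`, `AIC`, `dAIC`) sorted by
#'   AIC, with attributes `models` (named list of fits) and `skipped`.
#' @export
compare_structures_aic <- function(records, response, predictor,
                                   structures = calibration_structures) {
  fits <- list(); skipped <- character(0)
  for (s in structures) {
    f <- tryCatch(fit_linear_structure(records, response, predictor, s),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "calibration_model")) fits[[s]] <- f
    else skipped[s] <- f
  }
  if (length(fits) == 0) stop("no structure could be fitted")
  tab <- data.frame(
    structure = names(fits),
    k = vapply(fits, function(f) length(f$coefficients), numeric(1)),
    RSS = vapply(fits, `[[`, numeric(1), "RSS"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    row.names = NULL)
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  attr(tab, "models") <- fits
  attr(tab, "skipped") <- skipped
  tab
}

#' Predict circular-equivalent values from a calibration model
#'
#' Applies a fitted transformation model to smartphone estimates, yielding
#' circular-camera-equivalent values clipped to `[0, 1]`. Clipping is
#' flagged in the `"clipped"` attribute.
#'
#' @param model A [fit_linear_structure()] result.
#' @param smartphone_value Numeric vector of smartphone estimates.
#' @param OV Overstory type (required, and must be a level seen during
#'   fitting, when the structure includes OV terms).
#' @param camera_type,height_from_ground Covariate values for structures
#'   that include them.
#' @return Numeric vector of calibrated values with attribute `clipped`.
#' @export
predict_circular_equivalent <- function(model, smartphone_value, OV = NULL,
                                        camera_type = NULL,
                                        height_from_ground = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  newdata <- data.frame(x = as.numeric(smartphone_value))
  names(newdata) <- model$predictor
  covs <- structure_covariates(model$structure_id)
  if ("OV" %in% covs) {
    if (is.null(OV)) stop("this structure requires 'OV'")
    if (!all(OV %in% model$ov_levels)) {
      stop("missing level: unknown OV value for this model")
    }
    newdata$OV <- factor(OV, levels = model$ov_levels)
  }
  if ("camera_type" %in% covs) {
    if (is.null(camera_type)) stop("this structure requires 'camera_type'")
    newdata$camera_type <- factor(camera_type,
                                  levels = levels(model$fit$model$camera_type))
  }
  if ("height_from_ground" %in% covs) {
    if (is.null(height_from_ground)) {
      stop("this structure requires 'height_from_ground'")
    }
    newdata$height_from_ground <- factor(
      height_from_ground,
      levels = levels(model$fit$model$height_from_ground))
  }
  raw <- as.numeric(stats::predict(model$fit, newdata = newdata))
  out <- pmin(1, pmax(0, raw))
  attr(out, "clipped") <- raw < 0 | raw > 1
  out
}

#' Serialize calibration model coefficients to JSON
#'
#' Writes structure id, coefficient estimates, residual SD, sample size and
#' AIC for interoperability.
#'
#' @param model A [fit_linear_structure()] result.
#' @param path Output JSON path.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(
    list(structure = model$structure_id,
         response = model$response, predictor = model$predictor,
         coefficients = as.list(model$coefficients),
         ov_levels = model$ov_levels,
         n = model$n, RSS = model$RSS, AIC = model$AIC, sigma = model$sigma),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read paired estimate records from CSV
#'
#' Expects a header with `point_id`, optional `forest`, `stand`, `OV`,
#' followed by estimate columns; estimate columns present among the known
#' parameter names are validated to lie in `[0, 1]`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_paired_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"point_id" %in% names(df)) stop("'point_id' column is required")
  est_cols <- intersect(names(df),
                        c("CO", "ISF", "DSF", "GSF", "TG", "COsm", "ISFsm",
                          "DSFsm", "GSFsm", "TGsm",
                          "CO150", "ISF150", "DSF150", "GSF150"))
  for (col in est_cols) {
    v <- df[[col]]
    if (any(is.finite(v) & (v < 0 | v > 1))) {
      stop("estimate column '", col, "' has values outside [0, 1]")
    }
  }
  df
}
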