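#' Standardization run configuration
#'
#' Bundles the tunable parameters of calibration. Defaults follow the method's
#' published operating point: the upper-percentile search interval is
#' \[90, 100\] with a 0.1 grid step (beta is meaningful to one decimal), and
#' the standard-scale ceiling s_max is 5.00 for SUV volumes and 50,000 Bq/mL
#' for AC volumes — values chosen so that clinically distinct SUVs (0.01
#' apart) never collapse onto the same standardized value.
#'
#' @param modality `"AC"` or `"SUV"` — the modality being calibrated.
#' @param s_max Standard-scale ceiling. `NULL` selects the modality default
#'   (5.00 SUV, 50000 Bq/mL AC).
#' @param b_low,b_high Bounds of the upper-percentile search interval.
#' @param b_step Grid step for the percentile search.
#' @param sd_convention `"population"` (divide by n, default) or `"sample"`
#'   (divide by n-1); used for every standard deviation in calibration and
#'   evaluation.
#' @param reference_organ Name recorded in the calibration product.
#' @return A list of class `std_config`.
#' @export
std_config <- function(modality = c("SUV", "AC"), s_max = NULL,
                       b_low = 90, b_high = 100, b_step = 0.1,
                       sd_convention = c("population", "sample"),
                       reference_organ = "liver") {
  modality <- match.arg(modality)
  sd_convention <- match.arg(sd_convention)
  if (is.null(s_max))
    s_max <- if (modality == "SUV") 5.00 else 50000
  if (!is.numeric(s_max) || s_max <= 0)
    stop("s_max must be positive")
  if (b_low > b_high)
    stop("b_low must be <= b_high")
  if (b_low < 0 || b_high > 100)
    stop("percentile bounds must lie in [0, 100]")
  if (b_step <= 0)
    stop("b_step must be positive")
  structure(
    list(modality = modality, s_max = s_max, b_low = b_low, b_high = b_high,
         b_step = b_step, sd_convention = sd_convention,
         reference_organ = reference_organ),
    class = "std_config"
  )
}

# standard deviation under the configured convention
sd_conv <- function(x, convention = "population") {
  n <- length(x)
  if (n < 1L) stop("empty input to sd_conv")
  if (convention == "population") {
    m <- mean(x)
    sqrt(sum((x - m)^2) / n)
  } else {
    if (n < 2L) stop("sample SD needs at least 2 values")
    stats::sd(x)
  }
}
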