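# Closed-form bench calculations.

#' Specific cytotoxicity percentage
#'
#' `100 * (experimental - spontaneous) / (1 - spontaneous)`, with the dead
#' fractions given on the 0-1 scale. The result can be negative when the
#' experimental dead fraction falls below the spontaneous one; it is
#' returned as-is with a warning.
#'
#' @param experimental Experimental dead target-cell fraction in \[0, 1\].
#' @param spontaneous Spontaneous dead target-cell fraction in \[0, 1).
#' @return Cytotoxicity in percent.
#' @examples
#' cytotoxicity_percent(0.55, 0.10) # 50
#' @export
cytotoxicity_percent <- function(experimental, spontaneous) {
  if (any(experimental < 0 | experimental > 1))
    stop("experimental dead fraction must be in [0, 1]", call. = FALSE)
  if (any(spontaneous < 0 | spontaneous >= 1))
    stop("spontaneous dead fraction must be in [0, 1)", call. = FALSE)
  out <- 100 * (experimental - spontaneous) / (1 - spontaneous)
  if (any(out < 0))
    warning("experimental dead fraction below spontaneous: ",
            "negative cytotoxicity reported", call. = FALSE)
  out
}

#' Caliper tumor volume
#'
#' `V = L * W * H / 2` in mm³.
#'
#' @param length,width,height Caliper dimensions in mm, each > 0.
#' @return Volume in mm³.
#' @examples
#' tumor_volume(4, 3, 2) # 12 mm^3
#' @export
tumor_volume <- function(length, width, height) {
  if (any(c(length, width, height) <= 0) ||
      any(!is.finite(c(length, width, height))))
    stop("tumor dimensions must be finite and > 0 (mm)", call. = FALSE)
  length * width * height / 2
}
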