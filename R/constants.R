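#' Physical constants (SI)
#'
#' Speed of light, vacuum permittivity and permeability used throughout.
#' @keywords internal
#' @name constants
NULL

C0 <- 299792458
EPS0 <- 8.8541878128e-12
MU0 <- 1.25663706212e-6

mwt_stop <- function(msg, class = "mwtomo_error", ...) {
  stop(errorCondition(msg, class = c(class, "mwtomo_error"), ...))
}
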