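#' Molecular clock parameters
#'
#' Bundles the point mutation rate, its 95% highest-posterior-density (HPD)
#' interval, and the normalization length used when expressing mutation
#' counts "per 10 Mb". The defaults are the ancient-DNA-calibrated
#' Y-chromosome single-nucleotide rate of 0.76e-9 mutations/site/year with
#' HPD 0.67e-9 to 0.86e-9, the rate most widely used for calibrating the
#' human Y phylogeny.
#'
#' @param mu_point point mutation rate, mutations per site per year.
#' @param mu_hpd_low,mu_hpd_high bounds of the 95% HPD interval on the rate,
#'   same units. Must satisfy `mu_hpd_low <= mu_point <= mu_hpd_high`.
#' @param norm_length length (bp) that normalized mutation counts refer to.
#' @return an object of class `clock_params`.
#' @examples
#' clock_params()
#' clock_params(mu_point = 1e-9, mu_hpd_low = 1e-9, mu_hpd_high = 1e-9)
#' @export
clock_params <- function(mu_point = 0.76e-9,
                         mu_hpd_low = 0.67e-9,
                         mu_hpd_high = 0.86e-9,
                         norm_length = 1e7) {
  assert_scalar_num(mu_point, "mu_point", lower = .Machine$double.xmin)
  assert_scalar_num(mu_hpd_low, "mu_hpd_low", lower = .Machine$double.xmin)
  assert_scalar_num(mu_hpd_high, "mu_hpd_high", lower = .Machine$double.xmin)
  assert_scalar_num(norm_length, "norm_length", lower = 1)
  if (!(mu_hpd_low <= mu_point && mu_point <= mu_hpd_high)) {
    stop("clock rates must satisfy mu_hpd_low <= mu_point <= mu_hpd_high",
         call. = FALSE)
  }
  structure(
    list(mu_point = mu_point, mu_hpd_low = mu_hpd_low,
         mu_hpd_high = mu_hpd_high, norm_length = norm_length),
    class = "clock_params"
  )
}

#' @export
print.clock_params <- function(x, ...) {
  cat(sprintf("<clock_params> mu = %.3g /site/yr (95%% HPD %.3g-%.3g), norm length %g bp\n",
              x$mu_point, x$mu_hpd_low, x$mu_hpd_high, x$norm_length))
  invisible(x)
}

as_clock_params <- function(x) {
  if (inherits(x, "clock_params")) return(x)
  if (is.list(x)) return(do.call(clock_params, x))
  stop("cannot interpret `clock` argument as clock parameters", call. = FALSE)
}
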