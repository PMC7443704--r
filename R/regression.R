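#' Cable length versus receptor-neuron input regression
#'
#' For multiglomerular PNs the question is whether synaptic input from a
#' glomerulus simply tracks the amount of dendritic cable the PN places in
#' it. This fits an ordinary least squares line of RN input count on cable
#' length across (PN, glomerulus) samples, via [stats::lm()]; the R-squared
#' and the F-test p-value (1 and n−2 degrees of freedom) summarise the fit.
#'
#' @param samples tibble with columns `cable_nm` (dendritic cable inside the
#'   glomerulus, nanometres) and `rn_count` (synaptic connections received
#'   from that glomerulus's RNs); at least 3 rows, `cable_nm` not constant.
#' @return object of class `consat_cable_fit` wrapping the `lm` fit, with
#'   [generics::tidy()] / [generics::glance()] methods.
#' @examples
#' fit <- fit_cable_vs_input(
#'   tibble::tibble(cable_nm = c(0, 1, 2, 3), rn_count = c(0, 2, 4, 6)))
#' glance(fit)$r.squared
#' @export
fit_cable_vs_input <- function(samples) {
  check_that(all(c("cable_nm", "rn_count") %in% names(samples)),
    "samples need columns cable_nm, rn_count", "config")
  check_that(nrow(samples) >= 3, "need at least 3 samples", "config")
  check_that(all(samples$cable_nm >= 0) && all(samples$rn_count >= 0),
    "negative cable length or input count", "config")
  check_that(stats::sd(samples$cable_nm) > 0,
    "cable length is constant: degenerate predictor", "config")
  fit <- stats::lm(rn_count ~ cable_nm, data = samples)
  structure(list(lm = fit, samples = as_tibble(samples)),
    class = "consat_cable_fit")
}

#' @export
print.consat_cable_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cable-vs-input fit: slope %.4g per nm, intercept %.4g, R^2 %.3f, p %.3g, n %d>\n",
    stats::coef(x$lm)[2], stats::coef(x$lm)[1], g$r.squared, g$p.value, g$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname fit_cable_vs_input
#' @param x a `consat_cable_fit`.
#' @param ... unused.
#' @export
tidy.consat_cable_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(
    term = c("(Intercept)", "cable_nm"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @rdname fit_cable_vs_input
#' @export
glance.consat_cable_fit <- function(x, ...) {
  s <- summary(x$lm)
  f <- s$fstatistic
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    df = unname(f[2]), df.residual = unname(f[3]),
    n = nrow(x$samples)
  )
}

#' @rdname fit_cable_vs_input
#' @param object a `consat_cable_fit` (for `autoplot`).
#' @export
autoplot.consat_cable_fit <- function(object, ...) {
  ggplot2::ggplot(object$samples,
    ggplot2::aes(x = .data$cable_nm / 1000, y = .data$rn_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "firebrick") +
    ggplot2::labs(x = "cable in glomerulus (µm)", y = "RN inputs") +
    ggplot2::theme_minimal()
}
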