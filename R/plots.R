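# ggplot2 front-ends for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col labs
#'   scale_x_log10 geom_hline geom_vline
NULL

#' @export
ggplot2::autoplot

#' Plot a radial profile
#'
#' @param object a `radial_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  kind <- attr(object, "kind")
  ylab <- c(mass_density = "density (amu/nm³)", count = "count per bin",
            rdf = "g(r)", charge = "net charge per bin (e)",
            cumulative_charge = "cumulative charge Q(r) (e)")[kind]
  p <- ggplot(object, aes(x = .data$r, y = .data$value)) +
    geom_line() +
    labs(x = "r (nm)", y = ylab %||% "value", title = paste0("radial profile: ", kind))
  if (identical(kind, "rdf")) p <- p + geom_hline(yintercept = 1, linetype = 2)
  p
}

#' Plot an autocorrelation function
#'
#' @param object a `dendri_acf`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dendri_acf <- function(object, ...) {
  ggplot(object, aes(x = .data$lag, y = .data$value)) +
    geom_line() +
    geom_hline(yintercept = exp(-1), linetype = 2) +
    labs(x = "lag", y = paste0(attr(object, "order"), "(t)"),
         title = sprintf("%s ACF (%d vectors)", attr(object, "order"),
                         attr(object, "n_vectors")))
}

#' Plot a reduced relaxation curve
#'
#' @param object a `t1_curve`.
#' @param ... unused.
#' @return a ggplot (log-frequency axis, maximum marked).
#' @export
autoplot.t1_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$omega, y = .data$invT1_reduced)) +
    geom_line() +
    scale_x_log10() +
    geom_vline(xintercept = attr(object, "omega_max"), linetype = 2) +
    labs(x = expression(omega ~ "(rad/s)"), y = expression(1 / T[1 * H]),
         title = "reduced spin-lattice relaxation (susceptibility representation)")
}

#' Plot an electrostatic potential field
#'
#' @param object an `electro_field`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.electro_field <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$Psi_mV)) +
    geom_line() +
    labs(x = "r (nm)", y = expression(Psi ~ "(mV)"),
         title = sprintf("electrostatic potential (T = %g K)", attr(object, "T")))
}

#' Plot a hydrogen-bond count distribution
#'
#' @param object an `hbond_dist`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hbond_dist <- function(object, ...) {
  ggplot(object, aes(x = .data$n_bonds, y = .data$p)) +
    geom_col() +
    labs(x = "bonds per frame", y = "probability",
         title = sprintf("H-bond count distribution (mean %.2f)", attr(object, "mean")))
}
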