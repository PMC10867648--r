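#' Plot the order parameters of a stiffness sweep
#'
#' Shows, against the bending stiffness, the ensemble means of the
#' normalized radius of gyration, the end-to-end correlation parameter,
#' and the interchain motif sum (the L2 + T3 + I4 order parameter), with
#' one-standard-deviation ribbons.
#'
#' @param sweep a [run_sweep()] result.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  m <- sweep$summary$mean
  s <- sweep$summary$sd
  vars <- c("Rg_tilde", "CR", "inter_sum")
  df <- do.call(rbind, lapply(vars, function(v)
    data.frame(kappa = m$kappa, value = m[[v]], sd = s[[v]], what = v)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kappa, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sd,
                                      ymax = .data$value + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = expression(kappa), y = NULL,
                  title = "Stiffness sweep order parameters")
}

#' Plot ensemble-mean motif fractions against stiffness
#'
#' @param sweep a [run_sweep()] result.
#' @return A ggplot object.
#' @export
plot_motif_fractions <- function(sweep) {
  m <- sweep$summary$mean
  df <- do.call(rbind, lapply(motif_classes, function(cl)
    data.frame(kappa = m$kappa, fraction = m[[cl]], motif = cl)))
  df$motif <- factor(df$motif, levels = motif_classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kappa, y = .data$fraction,
                                   colour = .data$motif)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(kappa), y = "motif fraction",
                  colour = "motif")
}
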