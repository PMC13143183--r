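#' Plot a bifurcation diagram
#'
#' Larval equilibrium density against release rate; stable branches drawn
#' as solid points, unstable as open points, with the eradication threshold
#' marked.
#'
#' @param x A \code{sit_bifurcation}.
#' @param ... Passed to \code{plot}.
#' @export
plot.sit_bifurcation <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$sigma, df$L_star,
                 pch = ifelse(df$stability == "stable", 16, 1),
                 col = ifelse(df$kind == "pest-free", "grey40", "orange3"),
                 xlab = expression(sigma ~ "(sterilized males/day)"),
                 ylab = expression(L^"*"), ...)
  graphics::abline(v = attr(x, "sigma_bar"), lty = 3)
  invisible(x)
}

#' Plot an eradication-threshold heatmap
#'
#' @param x A \code{sit_heatmap}.
#' @param ... Passed to \code{image}.
#' @export
plot.sit_heatmap <- function(x, ...) {
  a1 <- attr(x, "axis1"); a2 <- attr(x, "axis2")
  graphics::image(a1$grid, a2$grid, unclass(x),
                  xlab = a1$name, ylab = a2$name,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
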