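#' Plot a hallucination trajectory
#'
#' Total, restraint and confidence loss against iteration, as a ggplot when
#' ggplot2 is installed, otherwise base graphics.
#' @param run a `hallucination_run`.
#' @return a ggplot object, or `NULL` (base plot drawn) without ggplot2.
#' @export
plot_trajectory <- function(run) {
  tr <- run$trajectory
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    long <- data.frame(
      iteration = rep(tr$iteration, 3),
      component = rep(c("total", "restraint", "confidence"), each = nrow(tr)),
      loss = c(tr$total, tr$restraint, tr$confidence))
    return(ggplot2::ggplot(long,
                           ggplot2::aes(x = .data$iteration, y = .data$loss,
                                        colour = .data$component)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "iteration", y = "loss (nats)",
                           title = sprintf("hallucination trajectory (seed %d)",
                                           run$seed)) +
             ggplot2::theme_minimal())
  }
  graphics::plot(tr$iteration, tr$total, type = "l", xlab = "iteration",
                 ylab = "loss (nats)")
  graphics::lines(tr$iteration, tr$restraint, lty = 2)
  graphics::lines(tr$iteration, tr$confidence, lty = 3)
  invisible(NULL)
}

#' Plot a profile's expected distance map
#'
#' Expected inter-residue distance per conserved-column pair under the family
#' restraints (no-contact bin shown at the cutoff), as an image.
#' @param profile a `family_profile`.
#' @return the distance matrix, invisibly.
#' @export
plot_profile_distances <- function(profile) {
  spec <- profile$spec
  e <- spec$edges$d
  mids <- c((e[-length(e)] + e[-1]) / 2, spec$cutoff)
  cc <- profile$annotation$conserved_cols
  n <- max(cc)
  M <- matrix(NA_real_, n, n)
  ed <- as.vector(profile$restraints$d %*% mids)
  M[cbind(profile$pairs[, 1], profile$pairs[, 2])] <- ed
  M[cbind(profile$pairs[, 2], profile$pairs[, 1])] <- ed
  graphics::image(seq_len(n), seq_len(n), M, xlab = "alignment column",
                  ylab = "alignment column", main = "expected distance (A)")
  invisible(M)
}
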