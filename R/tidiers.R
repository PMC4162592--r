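# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fold result
#'
#' One row per base pair with nonzero probability.
#'
#' @param x a `vfold_fold` object.
#' @param min_prob floor below which pairs are dropped.
#' @param ... ignored.
#' @return tibble with `i`, `j`, `prob`, `in_dominant`.
#' @export
tidy.vfold_fold <- function(x, min_prob = 1e-6, ...) {
  idx <- which(upper.tri(x$bpp) & x$bpp >= min_prob, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  domkey <- paste(x$dominant$pairs[, 1], x$dominant$pairs[, 2])
  tibble(i = idx[, 1], j = idx[, 2], prob = x$bpp[idx],
         in_dominant = paste(idx[, 1], idx[, 2]) %in% domkey)
}

#' @rdname tidy.vfold_fold
#' @export
glance.vfold_fold <- function(x, ...) {
  tibble(n = x$n, temperature = x$temperature, dialect = x$dialect,
         pseudoknot = x$pseudoknot, Q = x$Q, lnQ = x$lnQ,
         n_helices = nrow(x$helices),
         dominant_prob = x$dominant$probability,
         n_alternatives = length(x$alternatives))
}

#' Tidy a melting curve
#'
#' @param x a `vfold_melt` object.
#' @param ... ignored.
#' @return the curve tibble (`temperature`, `lnQ`, `C`).
#' @export
tidy.vfold_melt <- function(x, ...) x$curve

#' @rdname tidy.vfold_melt
#' @export
glance.vfold_melt <- function(x, ...) {
  tibble(n = attr(x$seq, "n"), dialect = x$dialect,
         pseudoknot = x$pseudoknot,
         n_peaks = nrow(x$peaks),
         t_peak_main = if (nrow(x$peaks)) x$peaks$t_peak[which.max(x$peaks$C_peak)]
         else NA_real_)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Base-pair probability dot plot
#'
#' @param object a `vfold_fold` object.
#' @param min_prob smallest probability drawn.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vfold_fold <- function(object, min_prob = 1e-3, ...) {
  d <- tidy(object, min_prob = min_prob)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i,
                                  size = .data$prob, colour = .data$in_dominant)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse(limits = c(object$n, 1)) +
    ggplot2::scale_x_continuous(limits = c(1, object$n), position = "top") +
    ggplot2::scale_size_area(max_size = 3, limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "j", y = "i", size = expression(P[ij]),
                  colour = expression(P[ij] > 0.5)) +
    ggplot2::theme_minimal()
}

#' Melting-curve plot
#'
#' @param object a `vfold_melt` object.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.vfold_melt <- function(object, ...) {
  d <- object$curve[is.finite(object$curve$C), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)",
                  y = "heat capacity (kcal mol⁻¹ K⁻¹)") +
    ggplot2::theme_minimal()
  if (nrow(object$peaks))
    p <- p + ggplot2::geom_vline(xintercept = object$peaks$t_peak,
                                 linetype = "dashed", colour = "grey50")
  p
}
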