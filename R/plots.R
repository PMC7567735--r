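# ggplot2 displays for the package's result types.

#' @method autoplot klse_connectome
#' @export
autoplot.klse_connectome <- function(object, ...) {
  df <- tidyr::expand_grid(
    region_a = factor(object$region_labels, levels = object$region_labels),
    region_b = factor(object$region_labels, levels = object$region_labels)
  )
  df$weight <- as.vector(t(object$weights))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_b, y = .data$region_a,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s connectivity matrix", object$kind)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @method autoplot klse_diff
#' @export
autoplot.klse_diff <- function(object, ...) {
  labs <- object$region_labels
  df <- tidyr::expand_grid(
    region_a = factor(labs, levels = labs),
    region_b = factor(labs, levels = labs)
  )
  df$significant <- as.vector(t(object$significant))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_b, y = .data$region_a,
                                   fill = .data$significant)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92", `TRUE` = "#6a3d9a"),
                               name = sprintf("q < %.2g", object$alpha)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Edge-wise difference pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @method autoplot klse_dissimilarity
#' @export
autoplot.klse_dissimilarity <- function(object, ...) {
  df <- object$map
  df$region <- factor(df$region, levels = df$region[order(df$z)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$region)) +
    ggplot2::geom_col(fill = "#1f78b4") +
    ggplot2::labs(x = "inter-individual dissimilarity (z)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot klse_km
#' @export
autoplot.klse_km <- function(object, ...) {
  sf <- object$survfit
  strata <- rep(names(sf$strata), sf$strata)
  df <- bind_rows(
    tibble(time = 0, surv = 1, risk = unique(strata)),
    tibble(time = sf$time, surv = sf$surv, risk = strata)
  )
  df$risk <- sub("^risk=", "", df$risk)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$risk)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "months since baseline", y = "conversion-free survival",
      color = "risk group",
      subtitle = sprintf("log-rank p = %.3g, HR = %.2f",
                         object$logrank_p, object$hazard_ratio)
    ) +
    ggplot2::theme_minimal()
}
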