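#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Manhattan-style plot of a ROH genome scan
#'
#' `-log10` p-values of the ROH effect along the genome, coloured by
#' chromosome, with the significance threshold drawn as a dashed line.
#'
#' @param object A `roh_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.roh_scan <- function(object, ...) {
  cfg <- attr(object, "config")
  dat <- object[object$tested, ]
  dat$chr <- factor(dat$chr, levels = unique(object$chr))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos_bp / 1e6,
                                    y = .data$neglog10_p4,
                                    colour = .data$chr)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(cfg$p_threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)",
                  y = expression(-log[10](italic(p))~"(ROH effect)")) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of an animal-model fit
#'
#' Point estimates with ±2 standard-error bars for the inbreeding-measure
#' covariates (all estimable terms with `all_terms = TRUE`).
#'
#' @param object An `ibd_fit`.
#' @param all_terms Plot every fixed-effect term instead of only the
#'   measure covariates.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ibd_fit <- function(object, all_terms = FALSE, ...) {
  co <- object$coefficients
  if (!all_terms && length(object$measure_terms)) {
    co <- co[co$term %in% object$measure_terms, ]
  }
  co <- co[!is.na(co$estimate), ]
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 2 * .data$std_error,
      xmax = .data$estimate + 2 * .data$std_error), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Estimate (trait units per unit measure)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Mean ROH-based inbreeding against minimum run length
#'
#' The population mean of `roh_f(n)` declines as the minimum run length
#' `n` grows; this plots that curve from an [inbreeding_measures()] table.
#'
#' @param measures Table from [inbreeding_measures()].
#' @return A ggplot object.
#' @export
plot_roh_f_curve <- function(measures) {
  roh_cols <- grep("^roh_f_", names(measures), value = TRUE)
  long <- tidyr::pivot_longer(measures[c("animal", roh_cols)],
                              dplyr::all_of(roh_cols),
                              names_to = "n", values_to = "roh_f")
  long$n <- as.integer(sub("^roh_f_", "", long$n))
  avg <- dplyr::summarise(dplyr::group_by(long, .data$n),
                          mean_roh_f = mean(.data$roh_f), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$n, y = .data$mean_roh_f)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Minimum run length (SNPs)",
                  y = "Mean proportion of genome in ROH") +
    ggplot2::theme_minimal()
}

#' Pedigree inbreeding trend by birth year
#'
#' Mean pedigree inbreeding coefficient per birth year with the OLS trend
#' line from [inbreeding_trend()].
#'
#' @param f Inbreeding table (`animal`, `F`).
#' @param ped A [pedigree].
#' @return A ggplot object.
#' @export
plot_inbreeding_trend <- function(f, ped) {
  dat <- dplyr::inner_join(f, ped[, c("animal", "birth_year")], by = "animal")
  dat <- dat[!is.na(dat$birth_year), ]
  avg <- dplyr::summarise(dplyr::group_by(dat, .data$birth_year),
                          mean_f = mean(.data$F), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$birth_year, y = .data$mean_f)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(data = dat,
                         ggplot2::aes(x = .data$birth_year, y = .data$F),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40") +
    ggplot2::labs(x = "Birth year", y = "Mean pedigree inbreeding (F)") +
    ggplot2::theme_minimal()
}
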