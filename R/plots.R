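region_palette <- function(greyscale) {
  if (greyscale)
    c("D" = "grey20", "S\\D" = "grey65", "Sc" = "grey90")
  else
    c("D" = "#1b9e77", "S\\D" = "#e6c200", "Sc" = "#d95f02")
}

# pick the age slices closest to the requested quantiles of the grid axis
age_slices <- function(grid, probs = c(0.25, 0.5, 0.75)) {
  ax <- grid$axes$age
  unique(ax[pmin(length(ax), pmax(1L, round(probs * (length(ax) - 1L)) + 1L))])
}

save_png <- function(p, file, width = 9, height = 5) {
  grDevices::png(file, width = width, height = height, units = "in",
                 res = 150, type = "cairo")
  on.exit(grDevices::dev.off())
  print(p)
  invisible(file)
}

#' Trichotomy plot of the covariate space
#'
#' Tiles the SF-36 general health x HbA1c plane with the region colouring of
#' a credible subgroup pair, faceted by sex and by age slices taken at fixed
#' quantiles of the grid's age axis.  The plotted table is attached to the
#' returned path as attribute `"table"` so the figure has a machine-readable
#' twin.
#'
#' @param pair a [classify()] object.
#' @param grid the `covariate_grid` it was built on.
#' @param greyscale logical; colour-blind-safe greyscale fill.
#' @param file output PNG path.
#' @param ages raw age values to slice at; default quantile slices.
#' @return `file`, invisibly, with the plotted `data.frame` as attribute
#'   `"table"`.
#' @export
plot_trichotomy <- function(pair, grid, greyscale = FALSE, file,
                            ages = age_slices(grid)) {
  stopifnot(inherits(pair, "credible_subgroup_pair"),
            inherits(grid, "covariate_grid"))
  if (!all(ages %in% grid$axes$age))
    stop("unknown age slice; must be values of the grid's age axis")
  tab <- data.frame(sf36_gh = grid$raw$sf36_gh, age = grid$raw$age,
                    sex = grid$raw$sex, hba1c = grid$raw$hba1c,
                    region = as.character(pair$region))
  tab <- tab[tab$age %in% ages, , drop = FALSE]
  tab$sex_label <- factor(ifelse(tab$sex == 1, "Male", "Female"))
  tab$age_label <- factor(sprintf("Age %.0f", tab$age))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$sf36_gh, y = .data$hba1c,
                                         fill = .data$region)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(ggplot2::vars(.data$sex_label),
                        ggplot2::vars(.data$age_label)) +
    ggplot2::scale_fill_manual(values = region_palette(greyscale),
                               drop = FALSE, name = "Region") +
    ggplot2::labs(x = "SF-36 general health", y = "HbA1c (%)",
                  title = sprintf("Credible subgroup trichotomy (level %.0f%%)",
                                  100 * pair$level)) +
    ggplot2::theme_minimal()
  save_png(p, file)
  invisible(structure(file, table = tab))
}

#' Funnel plot of predicted treatment effects
#'
#' Posterior mean personalised treatment effect against its pointwise
#' posterior sd for every grid point, coloured by region.  The plotted table
#' accompanies the figure as attribute `"table"`.
#'
#' @param band a [simultaneous_band()] object.
#' @param pair the matching [classify()] object.
#' @param file output PNG path.
#' @param greyscale logical.
#' @return `file`, invisibly, with the plotted `data.frame` as attribute
#'   `"table"`.
#' @export
plot_funnel <- function(band, pair, file, greyscale = FALSE) {
  stopifnot(inherits(band, "simultaneous_band"),
            inherits(pair, "credible_subgroup_pair"))
  tab <- data.frame(mean_effect = band$mean, sd_effect = band$sd,
                    region = as.character(pair$region))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_effect,
                                         y = .data$sd_effect,
                                         colour = .data$region)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = pair$threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = region_palette(greyscale),
                                 drop = FALSE, name = "Region") +
    ggplot2::labs(x = "Posterior mean treatment effect (benefit-positive)",
                  y = "Pointwise posterior sd",
                  title = sprintf("Funnel plot (level %.0f%%)",
                                  100 * pair$level)) +
    ggplot2::theme_minimal()
  save_png(p, file, width = 7, height = 5)
  invisible(structure(file, table = tab))
}

#' Maximum-credible-level contour plot
#'
#' Signed maximum credible level over the SF-36 x HbA1c plane, faceted by
#' sex and age slices; positive contours mark entry into the exclusive
#' subgroup D, negative ones entry into the no-benefit region.  The plotted
#' table accompanies the figure as attribute `"table"`.
#'
#' @param surface a [max_credible_level()] object.
#' @param grid the `covariate_grid` it was computed on.
#' @param file output PNG path.
#' @param ages raw age values to slice at; default quantile slices.
#' @return `file`, invisibly, with the plotted `data.frame` as attribute
#'   `"table"`.
#' @export
plot_level_contours <- function(surface, grid, file, ages = age_slices(grid)) {
  stopifnot(inherits(surface, "max_level_surface"),
            inherits(grid, "covariate_grid"))
  tab <- data.frame(sf36_gh = grid$raw$sf36_gh, age = grid$raw$age,
                    sex = grid$raw$sex, hba1c = grid$raw$hba1c,
                    max_level = surface$level)
  tab <- tab[tab$age %in% ages, , drop = FALSE]
  tab$sex_label <- factor(ifelse(tab$sex == 1, "Male", "Female"))
  tab$age_label <- factor(sprintf("Age %.0f", tab$age))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$sf36_gh, y = .data$hba1c,
                                         z = .data$max_level)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$max_level)) +
    ggplot2::geom_contour(colour = "black",
                          breaks = c(-0.8, -0.5, 0, 0.5, 0.8)) +
    ggplot2::facet_grid(ggplot2::vars(.data$sex_label),
                        ggplot2::vars(.data$age_label)) +
    ggplot2::scale_fill_gradient2(low = "#d95f02", mid = "white",
                                  high = "#1b9e77", limits = c(-1, 1),
                                  name = "Max level") +
    ggplot2::labs(x = "SF-36 general health", y = "HbA1c (%)",
                  title = "Signed maximum credible level") +
    ggplot2::theme_minimal()
  save_png(p, file)
  invisible(structure(file, table = tab))
}
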