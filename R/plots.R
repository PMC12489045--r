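#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_area
#'   geom_segment geom_text labs scale_x_continuous scale_y_continuous
#'   coord_fixed theme_minimal arrow unit
NULL

#' Plot a homopolymer prevalence spectrum
#'
#' One line per base: percentage of reads carrying a qualifying run versus
#' the run-length threshold. A poly(dA)-product library shows a dominant,
#' slowly decaying A line with the other bases near zero.
#'
#' @param object An `hp_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hp_spectrum <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$threshold, y = .data$percent, colour = .data$base)) +
    geom_line() +
    geom_point() +
    scale_x_continuous(breaks = unique(d$threshold)) +
    labs(x = "Minimum run length (nt)", y = "Reads with a run (%)",
         colour = "Base",
         title = "Homopolymer prevalence spectrum") +
    theme_minimal()
}

#' Plot per-position base composition
#'
#' Stacked per-position base frequencies from the 5' end of the reads.
#'
#' @param object A `positional_freq`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.positional_freq <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$coverage > 0, ]
  ggplot(d, aes(x = .data$position, y = .data$freq, fill = .data$base)) +
    geom_area(position = "stack") +
    labs(x = "Read position (nt from 5')", y = "Base frequency",
         fill = "Base", title = "Positional base composition") +
    theme_minimal()
}

#' Plot a conservation profile as an information-content logo
#'
#' Per-column stacked bars whose total height is the column information
#' content (bits) and whose segments are the base frequencies scaled by IC —
#' the quantity a sequence logo draws.
#'
#' @param object A `conservation_profile`.
#' @param rna Display T as U.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conservation_profile <- function(object, rna = FALSE, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(
    d[, c("column", "ic", "p_a", "p_c", "p_g", "p_t")],
    cols = c("p_a", "p_c", "p_g", "p_t"),
    names_to = "base", values_to = "p"
  )
  long$base <- toupper(sub("^p_", "", long$base))
  if (rna) long$base[long$base == "T"] <- "U"
  long$height <- ifelse(is.na(long$p), 0, long$p * long$ic)
  ggplot(long, aes(x = .data$column, y = .data$height, fill = .data$base)) +
    geom_col(position = "stack", width = 1) +
    labs(x = "Alignment column (reference position)",
         y = "Information content (bits)", fill = "Base",
         title = "Conservation profile") +
    theme_minimal()
}

#' Plot an assembly angle report (top view)
#'
#' Draws each unit's directed axis (arrow through its centroid) projected
#' into the assembly plane, annotated with the adjacent projected angles.
#'
#' @param object An `assembly_angles` report.
#' @param axis_length Arrow half-length in plot units.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_angles <- function(object, axis_length = 15, ...) {
  normal <- object$normal
  centroids <- do.call(rbind, lapply(object$frames, `[[`, "centroid"))
  center <- colMeans(centroids)
  e1 <- project_axis(centroids[1, ] - center, normal)
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  to2d <- function(v) c(sum(v * e1), sum(v * e2))
  d <- purrr::map_dfr(names(object$frames), function(nm) {
    fr <- object$frames[[nm]]
    c2 <- to2d(fr$centroid - center)
    a2 <- to2d(project_axis(fr$axis, normal))
    tibble(unit = nm,
           x = c2[1] - axis_length * a2[1], y = c2[2] - axis_length * a2[2],
           xend = c2[1] + axis_length * a2[1], yend = c2[2] + axis_length * a2[2],
           cx = c2[1], cy = c2[2])
  })
  ggplot(d) +
    geom_segment(aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$unit),
                 arrow = arrow(length = unit(0.25, "cm"))) +
    geom_text(aes(x = .data$cx, y = .data$cy, label = .data$unit),
              nudge_y = 3) +
    coord_fixed() +
    labs(title = sprintf("Inter-unit angles (median %.1f deg, %s)",
                         object$median_angle, object$classification),
         x = "In-plane axis 1 (A)", y = "In-plane axis 2 (A)",
         colour = "Unit") +
    theme_minimal()
}
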