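# Dot-plots, block-plots (dot-plot + block rectangles) and scaled
# block-plots (non-repetitive regions removed, rectangles squared onto the
# fitting-alignment core).

#' Dot-plot match points
#'
#' All positions (x, y) where the `window`-mer of `a` at x equals the
#' `window`-mer of `b` at y on either strand (reverse-strand matches are
#' flagged).
#'
#' @param a,b DNA strings.
#' @param window match window (default 30 bp).
#' @return tibble `x`, `y` (0-based), `forward`.
#' @export
dotplot_points <- function(a, b, window = 30L) {
  stopifnot(window >= 1)
  tibble::as_tibble(cpp_dotplot(a, b, as.integer(window)))
}

# block-rectangles of a decomposition restricted to one chromosome pair:
# one rectangle per unordered pair of instances of the same block
# (self-pairs included)
block_rectangles <- function(decomp, chrom_x, chrom_y = chrom_x) {
  ix <- decomp$instances |> filter(paste(.data$genome, .data$chrom) == chrom_x)
  iy <- decomp$instances |> filter(paste(.data$genome, .data$chrom) == chrom_y)
  same <- identical(chrom_x, chrom_y)
  out <- list()
  for (b in unique(ix$block_id)) {
    bx <- ix |> filter(.data$block_id == b)
    by <- iy |> filter(.data$block_id == b)
    for (i in seq_len(nrow(bx))) {
      for (j in seq_len(nrow(by))) {
        if (same && j < i) next
        out[[length(out) + 1L]] <- tibble::tibble(
          block_id = b,
          x0 = bx$start[i], x1 = bx$end[i],
          y0 = by$start[j], y1 = by$end[j],
          xi = i, yi = j)
      }
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(block_id = character(), x0 = integer(),
                          x1 = integer(), y0 = integer(), y1 = integer(),
                          xi = integer(), yi = integer()))
  bind_rows(out)
}

#' Block-plot: dot-plot with superimposed block rectangles
#'
#' Every unordered pair of instances of the same block (including
#' self-pairs) is drawn as a rectangle spanning the two instances, coloured
#' by block, over the dot-plot of the sequence against itself (mirrored
#' pairs are drawn on both sides of the diagonal).
#'
#' @param decomp an `sd_decomposition`.
#' @param ss the string-set the decomposition describes (same coordinate
#'   space).
#' @param chrom which chromosome (`"genome chrom"`; default first).
#' @param window dot-plot window.
#' @return a ggplot object.
#' @export
plot_blocks <- function(decomp, ss, chrom = NULL, window = 30L) {
  key <- paste(ss$genome, ss$chrom)
  if (is.null(chrom)) chrom <- key[1]
  s <- ss$seq[key == chrom]
  dots <- dotplot_points(s, s, window)
  rect <- block_rectangles(decomp, chrom)
  rect2 <- rect |> filter(.data$x0 != .data$y0) |>
    rename(x0 = "y0", y0 = "x0", x1 = "y1", y1 = "x1")
  rect <- bind_rows(rect, rect2)
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = rect,
                       ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1,
                                    fill = .data$block_id),
                       alpha = 0.35, colour = NA) +
    ggplot2::geom_point(data = dots,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$forward), size = 0.1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "red"),
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = chrom, y = chrom, fill = "block") +
    ggplot2::theme_minimal()
}

#' Scaled block-plot
#'
#' Non-repetitive regions are removed from both axes (instances are laid
#' end to end) and each rectangle is replaced by the square over the
#' fitting-alignment core of its two instances: the shorter instance is
#' fitted inside the longer one with free end gaps on the longer, and the
#' unaligned overhangs are trimmed.
#'
#' @inheritParams plot_blocks
#' @return a ggplot object.
#' @export
plot_blocks_scaled <- function(decomp, ss, chrom = NULL, window = 30L) {
  key <- paste(ss$genome, ss$chrom)
  if (is.null(chrom)) chrom <- key[1]
  s <- ss$seq[key == chrom]
  ckey <- chrom
  ins <- decomp$instances |>
    filter(paste(.data$genome, .data$chrom) == ckey) |>
    arrange(.data$start) |>
    mutate(len = .data$end - .data$start,
           scaled_start = cumsum(dplyr::lag(.data$len, default = 0L)))
  if (nrow(ins) == 0) return(plot_blocks(decomp, ss, chrom, window))
  itext <- vapply(seq_len(nrow(ins)), function(i)
    substring(s, ins$start[i] + 1L, ins$end[i]), "")
  sq <- list()
  for (b in unique(ins$block_id)) {
    idx <- which(ins$block_id == b)
    for (ii in idx) {
      for (jj in idx[idx >= ii]) {
        core <- fitting_core(itext[ii], itext[jj])
        sq[[length(sq) + 1L]] <- tibble::tibble(
          block_id = b,
          x0 = ins$scaled_start[ii] + core$q[1],
          x1 = ins$scaled_start[ii] + core$q[2],
          y0 = ins$scaled_start[jj] + core$t[1],
          y1 = ins$scaled_start[jj] + core$t[2])
      }
    }
  }
  sq <- bind_rows(sq)
  sq2 <- sq |> filter(.data$x0 != .data$y0) |>
    rename(x0 = "y0", y0 = "x0", x1 = "y1", y1 = "x1")
  sq <- bind_rows(sq, sq2)
  # dot-plot in scaled coordinates: concatenate instance texts
  scat <- paste(itext, collapse = "")
  dots <- dotplot_points(scat, scat, window)
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = sq,
                       ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1,
                                    fill = .data$block_id),
                       alpha = 0.35, colour = NA) +
    ggplot2::geom_point(data = dots,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$forward), size = 0.1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "red"),
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste(chrom, "(repeats only)"),
                  y = paste(chrom, "(repeats only)"), fill = "block") +
    ggplot2::theme_minimal()
}

# fitting-alignment core of an instance pair: intervals (within each
# instance) covered by fitting the shorter inside the longer
fitting_core <- function(a, b) {
  la <- str_len(a); lb <- str_len(b)
  if (la <= lb) {
    f <- cpp_fitting_align(a, b)
    list(q = c(0L, la), t = c(f$start, f$end))
  } else {
    f <- cpp_fitting_align(b, a)
    list(q = c(f$start, f$end), t = c(0L, lb))
  }
}

#' @export
#' @importFrom ggplot2 autoplot
#' @method autoplot sd_decomposition
#' @rdname autoplot_sd
#' @title Block diagram of a decomposition
#' @param object an `sd_decomposition`.
#' @param ... unused.
#' @description One horizontal bar per chromosome with coloured block
#'   instances (reverse-strand instances drawn below the midline).
autoplot.sd_decomposition <- function(object, ...) {
  ins <- object$instances |>
    mutate(track = paste(.data$genome, .data$chrom),
           ymin = ifelse(.data$strand == "+", 0, -1),
           ymax = ifelse(.data$strand == "+", 1, 0))
  chr <- object$chroms |> mutate(track = paste(.data$genome, .data$chrom))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = chr,
                          ggplot2::aes(x = 0, xend = .data$length,
                                       y = 0, yend = 0), colour = "grey60") +
    ggplot2::geom_rect(data = ins,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$block_id)) +
    ggplot2::facet_wrap(~track, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "block") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
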