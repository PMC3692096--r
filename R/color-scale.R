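#' Color scales for ring cells
#'
#' A continuous scale maps a value through piecewise-linear interpolation
#' low-color to mid-color to high-color, clipping at `min`/`max`; a binary
#' scale is the two-color special case on \[0, 1\], which also colors
#' aggregated mutation frequencies (the group mean of 0/1 calls) on a
#' white-to-dark ramp; a categorical scale maps discrete codes through a
#' fixed table. Missing values are colored by the scene's missing color at
#' render time, never by the scale.
#'
#' @param min,mid,max breakpoints of the continuous ramp; `min < max` and
#'   `min <= mid <= max` are required.
#' @param low,midcol,high hex colors at the breakpoints.
#' @return an object of class `color_scale`.
#' @export
color_scale_continuous <- function(min, mid = (min + max) / 2, max,
                                   low = "#2166AC", midcol = "#F7F7F7",
                                   high = "#B2182B") {
  if (!is.finite(min) || !is.finite(max) || min >= max)
    stop("color scale requires min < max", call. = FALSE)
  if (mid < min || mid > max)
    stop("color scale requires min <= mid <= max", call. = FALSE)
  structure(list(kind = "continuous", min = min, mid = mid, max = max,
                 low = low, midcol = midcol, high = high),
            class = "color_scale")
}

#' @rdname color_scale_continuous
#' @export
color_scale_binary <- function(low = "#FFFFFF", high = "#54278F") {
  structure(list(kind = "binary", min = 0, mid = 0.5, max = 1,
                 low = low, midcol = .mix_color(low, high, 0.5), high = high),
            class = "color_scale")
}

#' @rdname color_scale_continuous
#' @param categories named character vector mapping category code
#'   (as character) to color.
#' @export
color_scale_categorical <- function(categories) {
  if (is.null(names(categories)))
    stop("categorical scale needs a named color vector", call. = FALSE)
  structure(list(kind = "categorical", categories = categories),
            class = "color_scale")
}

# channel-wise linear mix of two colors, t in [0, 1]
.mix_color <- function(a, b, t) {
  ca <- grDevices::col2rgb(a)
  cb <- grDevices::col2rgb(b)
  m <- round(ca + t * (cb - ca))
  sprintf("#%02X%02X%02X", m[1L], m[2L], m[3L])
}

#' Map a value to a color under a scale
#'
#' Continuous (and binary) scales interpolate linearly in RGB between the
#' low, mid and high colors, clipping outside `[min, max]`; the midpoint
#' value maps exactly to the mid color. Missing values map to
#' `missing_color`.
#'
#' @param value numeric (or `NA`) scalar or vector.
#' @param scale a `color_scale`.
#' @param missing_color color used for `NA`.
#' @return character vector of hex colors.
#' @export
colorize <- function(value, scale, missing_color = "#BBBBBB") {
  stopifnot(inherits(scale, "color_scale"))
  vapply(value, function(v) {
    if (is.na(v)) return(missing_color)
    if (scale$kind == "categorical") {
      col <- scale$categories[as.character(v)]
      return(if (is.na(col)) missing_color else unname(col))
    }
    v <- max(scale$min, min(scale$max, v))
    if (v <= scale$mid) {
      span <- scale$mid - scale$min
      t <- if (span > 0) (v - scale$min) / span else 1
      .mix_color(scale$low, scale$midcol, t)
    } else {
      span <- scale$max - scale$mid
      t <- if (span > 0) (v - scale$mid) / span else 1
      .mix_color(scale$midcol, scale$high, t)
    }
  }, character(1L), USE.NAMES = FALSE)
}

#' Default scale for a matrix
#'
#' Binary matrices get the white-to-dark two-color ramp; continuous
#' matrices get a diverging scale symmetric around 0 clipped at the 95th
#' percentile of absolute non-missing values (outlier-robust, the
#' convention for omics heatmaps); discrete matrices get a categorical
#' palette over the observed codes.
#'
#' @param x an [omics_matrix].
#' @return a `color_scale`.
#' @export
default_scale <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$value_kind == "binary") return(color_scale_binary())
  v <- x$values[!is.na(x$values)]
  if (x$value_kind == "discrete") {
    codes <- sort(unique(v))
    pal <- rep_len(c("#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3",
                     "#A6D854", "#FFD92F", "#E5C494", "#B3B3B3"), length(codes))
    return(color_scale_categorical(stats::setNames(pal, as.character(codes))))
  }
  m <- if (length(v)) stats::quantile(abs(v), 0.95, names = FALSE) else 1
  if (m <= 0) m <- 1
  color_scale_continuous(min = -m, mid = 0, max = m)
}
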