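## Prediction grids clipped to district polygons, conditional deficiency
## probabilities, IPCC calibrated verbal labels, and prevalence tables.

#' Plasma selenium deficiency thresholds
#'
#' Default thresholds (ug/L): 70 (conventional plasma Se deficiency cut-off),
#' and the concentrations above which selenoprotein activities are optimal -
#' 100 for selenoprotein P (SELENOP), 84.9 for glutathione peroxidase 3
#' (GPX3), 64.8 for iodothyronine deiodinase (IDI).
#'
#' @param generic,selenop,gpx3,idi thresholds in ug/L
#' @return named numeric vector of class \code{threshold_set}
#' @export
threshold_set <- function(generic = 70, selenop = 100, gpx3 = 84.9,
                          idi = 64.8) {
  th <- c(generic = generic, selenop = selenop, gpx3 = gpx3, idi = idi)
  if (any(th <= 0)) stop("thresholds must be positive")
  if (!(idi < generic && generic < gpx3 && gpx3 < selenop)) {
    stop("expected threshold ordering idi < generic < gpx3 < selenop")
  }
  structure(th, class = c("threshold_set", "numeric"))
}

#' Build a square prediction grid clipped to a polygon
#'
#' Axis-aligned lattice anchored at the polygon bounding-box lower-left
#' corner (so output is reproducible bit-for-bit), keeping nodes inside the
#' polygon or on its boundary (even-odd rule). Spacing is given in metres,
#' matching survey-mapping convention; coordinates are km.
#'
#' @param polygon boundary polygon (km)
#' @param spacing_m node spacing in metres (default 250)
#' @return data frame of class \code{grid_surface} with columns \code{x},
#'   \code{y}; attribute \code{spacing_km}
#' @export
build_grid <- function(polygon, spacing_m = 250) {
  if (spacing_m <= 0) stop("spacing must be positive")
  sp <- spacing_m / 1000
  bb <- polygon_bbox(polygon)
  xs <- seq(bb["xmin"], bb["xmax"], by = sp)
  ys <- seq(bb["ymin"], bb["ymax"], by = sp)
  nodes <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  keep <- point_in_polygon(nodes$x, nodes$y, polygon)
  nodes <- nodes[keep, , drop = FALSE]
  strictly_inside <- nrow(nodes) > 0 &&
    any(dist_to_boundary(nodes$x, nodes$y, polygon) > 1e-9)
  if (!strictly_inside) {
    stop("no grid nodes fall inside the polygon (spacing too large?)")
  }
  rownames(nodes) <- NULL
  structure(nodes, spacing_km = sp, class = c("grid_surface", "data.frame"))
}

#' Kriged prediction and variance surfaces on a grid
#'
#' @param model fitted \code{\link{variogram_model}}
#' @param records survey data frame
#' @param grid a \code{\link{build_grid}} result (or any x/y data frame)
#' @return list of two \code{grid_surface} data frames, \code{prediction}
#'   (columns x, y, value in ug/L) and \code{variance} (value in (ug/L)^2)
#' @export
predict_surface <- function(model, records, grid) {
  kr <- krige(model, records, as.matrix(grid[, c("x", "y")]))
  mk <- function(value) {
    out <- data.frame(x = kr$x, y = kr$y, value = value)
    attr(out, "spacing_km") <- attr(grid, "spacing_km")
    class(out) <- c("grid_surface", "data.frame")
    out
  }
  list(prediction = mk(kr$prediction), variance = mk(kr$variance))
}

#' Conditional probability of falling below a threshold
#'
#' Under the Gaussian kriging model the unknown value at a node is normal
#' with the kriging prediction as mean and the kriging variance as variance,
#' so \eqn{P(Z < T) = \Phi((T - \hat z)/\sigma_K)}. A zero-variance node
#' degenerates to the indicator \code{1\{z < T\}}, with probability 0.5 when
#' prediction and threshold tie.
#'
#' @param prediction kriging predictions (ug/L), vector or
#'   \code{grid_surface}
#' @param variance kriging variances ((ug/L)^2), same shape
#' @param threshold threshold (ug/L)
#' @return probabilities in [0, 1] (a \code{grid_surface} when the inputs
#'   were surfaces)
#' @export
deficiency_probability <- function(prediction, variance, threshold) {
  as_surface <- inherits(prediction, "grid_surface")
  pred <- if (as_surface) prediction$value else prediction
  v <- if (inherits(variance, "grid_surface")) variance$value else variance
  if (any(v < -1e-8)) stop("negative kriging variance")
  v <- pmax(v, 0)
  p <- ifelse(v > 0, pnorm((threshold - pred) / sqrt(v)),
              ifelse(pred < threshold, 1, ifelse(pred > threshold, 0, 0.5)))
  if (as_surface) {
    out <- data.frame(x = prediction$x, y = prediction$y, value = p)
    attr(out, "spacing_km") <- attr(prediction, "spacing_km")
    class(out) <- c("grid_surface", "data.frame")
    return(out)
  }
  p
}

#' IPCC calibrated likelihood scale
#'
#' Probability bands and verbal phrases of the calibrated-uncertainty
#' language used to communicate likelihoods: virtually certain (> 0.99),
#' very likely (> 0.90), likely (> 0.66), about as likely as not
#' (0.33-0.66), unlikely (< 0.33), very unlikely (< 0.10), exceptionally
#' unlikely (< 0.01).
#'
#' @return data frame with \code{label}, \code{p_low}, \code{p_high};
#'   bands partition [0, 1], each covering (p_low, p_high] except the first
#'   which includes 0
#' @export
ipcc_scale <- function() {
  data.frame(
    label = c("exceptionally unlikely", "very unlikely", "unlikely",
              "about as likely as not", "likely", "very likely",
              "virtually certain"),
    p_low = c(0, 0.01, 0.10, 0.33, 0.66, 0.90, 0.99),
    p_high = c(0.01, 0.10, 0.33, 0.66, 0.90, 0.99, 1),
    stringsAsFactors = FALSE
  )
}

#' Verbal likelihood label for a probability
#'
#' Maps probabilities to the IPCC calibrated phrases; band boundaries are
#' configurable via a custom \code{scale} data frame in the
#' \code{\link{ipcc_scale}} layout.
#'
#' @param probability numeric in [0, 1]
#' @param scale band definition (default \code{\link{ipcc_scale}})
#' @return character vector of labels (factor levels ordered by probability)
#' @export
verbal_classify <- function(probability, scale = ipcc_scale()) {
  p <- if (inherits(probability, "grid_surface")) probability$value else probability
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  breaks <- c(scale$p_low[1L], scale$p_high)
  idx <- cut(p, breaks, labels = FALSE, include.lowest = TRUE)
  factor(scale$label[idx], levels = scale$label, ordered = TRUE)
}

#' Average probability over a surface
#'
#' Unweighted mean over grid nodes; on an equal-area lattice this is the
#' area-weighted district average. Supply \code{at} (a data frame of
#' locations with columns x, y) to average instead over nearest-node values
#' at those locations, e.g. household positions.
#'
#' @param surface probability \code{grid_surface}
#' @param at optional locations over which to average
#' @return scalar average probability
#' @export
average_surface <- function(surface, at = NULL) {
  if (!nrow(surface)) stop("empty surface")
  if (is.null(at)) return(mean(surface$value))
  # nearest grid node per query location
  idx <- vapply(seq_len(nrow(at)), function(i) {
    which.min((surface$x - at$x[i])^2 + (surface$y - at$y[i])^2)
  }, integer(1))
  mean(surface$value[idx])
}

#' Prevalence of deficiency by district and group
#'
#' Per-stratum percentage of records strictly below each threshold, with
#' summary statistics, plus an \code{Overall} row per group pooling the
#' districts. Values exactly at a threshold are not deficient.
#'
#' @param records survey data frame
#' @param thresholds a \code{\link{threshold_set}}
#' @return data frame: district, group, n, median, mean, sd, min, max and
#'   one \code{pct_below_*} column per threshold
#' @export
prevalence_table <- function(records, thresholds = threshold_set()) {
  one <- function(vals, district, group) {
    if (!length(vals)) return(NULL)
    row <- data.frame(district = district, group = group, n = length(vals),
                      median = median(vals), mean = mean(vals),
                      sd = if (length(vals) > 1) sd(vals) else NA_real_,
                      min = min(vals), max = max(vals))
    for (nm in names(thresholds)) {
      row[[paste0("pct_below_", nm)]] <- 100 * mean(vals < thresholds[[nm]])
    }
    row
  }
  rows <- list()
  for (g in unique(records$group)) {
    for (d in unique(records$district[records$group == g])) {
      vals <- records$se[records$group == g & records$district == d]
      vals <- vals[is.finite(vals)]
      if (!length(vals)) {
        warning("empty stratum ", d, "/", g, " omitted")
        next
      }
      rows[[paste(d, g)]] <- one(vals, d, g)
    }
    pooled <- records$se[records$group == g]
    pooled <- pooled[is.finite(pooled)]
    rows[[paste("Overall", g)]] <- one(pooled, "Overall", g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
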