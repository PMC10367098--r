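## Synthetic biomarker survey generator: stationary Gaussian random field
## (nugget + exponential/spherical correlation) sampled at cluster
## (enumeration-area) locations, with known ground-truth parameters so the
## estimation stages can be verified by parameter recovery.

#' Specify a stationary Gaussian field
#'
#' The field is \eqn{Z(x) = \mu + \eta(x) + \epsilon}, with \eqn{\eta} a
#' zero-mean Gaussian process with variance \code{c1} and correlation
#' \code{family} with distance parameter \code{a}, and \eqn{\epsilon} white
#' noise with variance \code{c0} (the nugget: measurement error plus
#' sub-sampling-scale variation).
#'
#' @param mean field mean (ug/L)
#' @param family \code{"exponential"}, \code{"spherical"} or \code{"nugget"}
#' @param c0 nugget variance ((ug/L)^2), >= 0
#' @param c1 partial sill ((ug/L)^2), >= 0
#' @param a distance parameter (km), > 0 for spatial families. For the
#'   exponential family the effective range (95% decorrelation) is about 3a;
#'   for the spherical family correlation is exactly 0 beyond a.
#' @return object of class \code{field_spec}
#' @export
field_spec <- function(mean, family = c("exponential", "spherical", "nugget"),
                       c0, c1, a = NA_real_) {
  family <- match.arg(family)
  stopifnot(is.finite(mean), is.finite(c0), c0 >= 0, is.finite(c1), c1 >= 0)
  if (family != "nugget" && !(is.finite(a) && a > 0)) {
    stop("distance parameter `a` must be > 0 for family '", family, "'")
  }
  if (family == "nugget") a <- NA_real_
  structure(list(mean = mean, family = family, c0 = c0, c1 = c1, a = a),
            class = "field_spec")
}

#' Specify the cluster sampling design
#'
#' Mirrors a two-stage household survey: cluster (enumeration-area) centres
#' uniform in the study polygon, then households Gaussian-scattered around
#' each centre.
#'
#' @param polygon study-area boundary, planar km (vertex matrix)
#' @param n_clusters number of enumeration areas
#' @param per_cluster households sampled per enumeration area
#' @param cluster_sd within-cluster location spread (km)
#' @return object of class \code{sampling_spec}
#' @export
sampling_spec <- function(polygon, n_clusters = 30, per_cluster = 10,
                          cluster_sd = 0.5) {
  polygon <- as_ring(polygon)
  stopifnot(n_clusters >= 1, per_cluster >= 1, cluster_sd >= 0)
  structure(list(polygon = polygon, n_clusters = n_clusters,
                 per_cluster = per_cluster, cluster_sd = cluster_sd),
            class = "sampling_spec")
}

#' Derive a child RNG seed from a parent seed
#'
#' Counter-based fan-out so each pipeline stage draws from its own stream:
#' \code{child = (parent + 1000003 * counter) mod (2^31 - 1)}. Keeps every
#' derived seed a valid 32-bit integer.
#'
#' @param seed parent seed (integer)
#' @param counter stage counter (integer >= 0)
#' @return integer seed
#' @export
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(counter)) %% 2147483647)
}

## Correlogram of a spatial family at distance h (vectorised)
correlogram <- function(h, family, a) {
  switch(family,
    exponential = exp(-h / a),
    spherical = ifelse(h < a, 1 - 1.5 * (h / a) + 0.5 * (h / a)^3, 0),
    nugget = (h == 0) + 0  # keeps matrix dimensions
  )
}

#' Simulate a Gaussian random field at given locations
#'
#' One exact draw from the multivariate Gaussian implied by
#' \code{\link{field_spec}}, by dense Cholesky factorisation of the
#' covariance matrix. Distinct records at coincident locations get
#' independent nugget components (covariance \code{c1} between them); with
#' \code{c0 = 0} coincident points therefore receive identical values.
#'
#' @param locations matrix or data frame with columns \code{x}, \code{y} (km)
#' @param spec a \code{\link{field_spec}}
#' @param seed integer seed (optional; if supplied the draw is reproducible)
#' @return numeric vector of simulated biomarker values (ug/L)
#' @export
simulate_grf <- function(locations, spec, seed = NULL) {
  loc <- as.matrix(locations)[, 1:2, drop = FALSE]
  n <- nrow(loc)
  if (n == 0L) stop("empty location list")
  if (!is.null(seed)) set.seed(seed)
  if (spec$c1 == 0) {
    # white noise: no covariance matrix needed, any n
    return(spec$mean + sqrt(spec$c0) * rnorm(n))
  }
  D <- as.matrix(dist(loc))
  C <- spec$c1 * correlogram(D, spec$family, spec$a)
  diag(C) <- spec$c0 + spec$c1
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(L)) {
    return(unname(drop(spec$mean + crossprod(L, rnorm(n)))))
  }
  # rank-deficient covariance (e.g. duplicated locations with no nugget):
  # exact PSD square root via the eigendecomposition, eigenvalues clamped
  e <- tryCatch(eigen(C, symmetric = TRUE), error = function(e2) {
    stop("covariance factorization failed for c0=", spec$c0, ", c1=", spec$c1,
         ", a=", spec$a, " (", conditionMessage(e2), ")")
  })
  S <- e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(n))
  unname(drop(spec$mean + S))
}

#' Sample cluster survey locations inside a polygon
#'
#' Cluster centres are uniform in the polygon (rejection sampling from the
#' bounding box); each cluster's points are Gaussian offsets from its centre,
#' rejection-resampled until inside the polygon.
#'
#' @param spec a \code{\link{sampling_spec}}
#' @param seed integer seed (optional)
#' @param max_tries rejection bound per point before erroring
#' @return data frame with columns \code{x}, \code{y} (km) and \code{cluster}
#' @export
sample_locations <- function(spec, seed = NULL, max_tries = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  poly <- spec$polygon
  bb <- polygon_bbox(poly)
  draw_in_poly <- function(k) {
    pts <- matrix(NA_real_, k, 2)
    got <- 0L
    for (i in seq_len(max_tries)) {
      cand_x <- runif(k - got, bb["xmin"], bb["xmax"])
      cand_y <- runif(k - got, bb["ymin"], bb["ymax"])
      ok <- point_in_polygon(cand_x, cand_y, poly)
      keep <- which(ok)
      if (length(keep)) {
        take <- keep[seq_len(min(length(keep), k - got))]
        pts[(got + 1L):(got + length(take)), ] <- cbind(cand_x[take], cand_y[take])
        got <- got + length(take)
      }
      if (got == k) return(pts)
    }
    stop("rejection sampling failed to place points inside the polygon")
  }
  centres <- draw_in_poly(spec$n_clusters)
  out <- vector("list", spec$n_clusters)
  for (cl in seq_len(spec$n_clusters)) {
    m <- spec$per_cluster
    if (spec$cluster_sd == 0) {
      pts <- cbind(rep(centres[cl, 1L], m), rep(centres[cl, 2L], m))
    } else {
      pts <- matrix(NA_real_, m, 2)
      got <- 0L
      tries <- 0L
      while (got < m) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("cluster ", cl, ": could not place points inside the polygon ",
               "(cluster_sd too large for the boundary?)")
        }
        cx <- centres[cl, 1L] + rnorm(m - got, sd = spec$cluster_sd)
        cy <- centres[cl, 2L] + rnorm(m - got, sd = spec$cluster_sd)
        ok <- point_in_polygon(cx, cy, poly)
        keep <- which(ok)
        if (length(keep)) {
          pts[(got + 1L):(got + length(keep)), ] <- cbind(cx[keep], cy[keep])
          got <- got + length(keep)
        }
      }
    }
    out[[cl]] <- data.frame(x = pts[, 1L], y = pts[, 2L], cluster = cl)
  }
  do.call(rbind, out)
}

#' Generate one synthetic district stratum
#'
#' Joins sampled locations with a simulated field draw, producing a survey
#' data frame with optional inflammation markers. CRP and AGP are lognormal;
#' in \code{"correlated"} mode CRP is given a target Spearman rank
#' correlation with Se through a Gaussian copula (latent Pearson correlation
#' \code{2*sin(pi*rho/6)}), to exercise the inflammation decision rule. The
#' \code{"independent"} mode matches an analysis in which no inflammation
#' adjustment is warranted.
#'
#' @param field a \code{\link{field_spec}}
#' @param sampling a \code{\link{sampling_spec}}
#' @param group \code{"child"} or \code{"wra"}
#' @param district district name
#' @param seed integer seed; fans out to location/field/marker child seeds
#' @param inflammation \code{"none"}, \code{"independent"} or \code{"correlated"}
#' @param rho target Spearman correlation between Se and CRP in
#'   \code{"correlated"} mode (negative values emulate the
#'   inflammation-suppression scenario)
#' @param truncate_at optional lower truncation for realism demos; by default
#'   negative simulated concentrations are retained so estimator tests see an
#'   exactly Gaussian field
#' @return survey data frame (columns \code{id}, \code{group},
#'   \code{district}, \code{x}, \code{y}, \code{se}, \code{crp}, \code{agp})
#' @export
make_district_dataset <- function(field, sampling, group = "child",
                                  district = "district", seed = 1L,
                                  inflammation = c("none", "independent", "correlated"),
                                  rho = -0.5, truncate_at = NULL) {
  inflammation <- match.arg(inflammation)
  loc <- sample_locations(sampling, seed = child_seed(seed, 1L))
  se <- simulate_grf(loc[, c("x", "y")], field, seed = child_seed(seed, 2L))
  n <- nrow(loc)
  crp <- agp <- rep(NA_real_, n)
  if (inflammation != "none") {
    set.seed(child_seed(seed, 3L))
    if (inflammation == "independent") {
      z_crp <- rnorm(n)
    } else {
      r_latent <- 2 * sin(pi * rho / 6)  # copula inversion for Spearman rho
      z_se <- (se - mean(se)) / sd(se)
      z_crp <- r_latent * z_se + sqrt(1 - r_latent^2) * rnorm(n)
    }
    crp <- exp(0 + 1.0 * z_crp)          # median 1 mg/L, right-skewed
    agp <- exp(log(0.8) + 0.3 * rnorm(n))
  }
  if (!is.null(truncate_at)) se <- pmax(se, truncate_at)
  data.frame(
    id = sprintf("%s-%s-%04d", district, group, seq_len(n)),
    group = group, district = district,
    x = loc$x, y = loc$y, se = se, crp = crp, agp = agp,
    stringsAsFactors = FALSE
  )
}

#' Default synthetic study conditions per district and demographic group
#'
#' One row per stratum of the three-district pilot the generator emulates
#' (Murewa, Shamva, Mutasa; children 6-59 months and women of reproductive
#' age). Means, total variances and sample sizes follow the exploratory
#' summary of the field survey; the split of variance into nugget and
#' spatially correlated components and the correlation ranges follow its
#' variogram narrative: strongest spatial structure in Murewa, weakest in
#' Shamva (short range for women, ~12 km effective for children), Mutasa
#' intermediate. Exponential correlation throughout, \code{a} = effective
#' range / 3.
#'
#' @return data frame with columns \code{district}, \code{group}, \code{n},
#'   \code{mean}, \code{variance}, \code{spatial_share}, \code{a},
#'   \code{family}
#' @export
district_defaults <- function() {
  d <- rbind(
    data.frame(district = "Murewa", group = "child", n = 208, mean = 37.0,
               variance = 156.9, spatial_share = 0.60, a = 2.0),
    data.frame(district = "Shamva", group = "child", n = 223, mean = 40.1,
               variance = 129.3, spatial_share = 0.35, a = 4.0),
    data.frame(district = "Mutasa", group = "child", n = 201, mean = 48.5,
               variance = 342.1, spatial_share = 0.50, a = 2.0),
    data.frame(district = "Murewa", group = "wra", n = 258, mean = 53.9,
               variance = 279, spatial_share = 0.60, a = 2.0),
    data.frame(district = "Shamva", group = "wra", n = 260, mean = 59.1,
               variance = 290, spatial_share = 0.35, a = 1.5),
    data.frame(district = "Mutasa", group = "wra", n = 239, mean = 74.7,
               variance = 470, spatial_share = 0.50, a = 2.0)
  )
  d$family <- "exponential"
  d
}

#' Generate the full three-district synthetic survey
#'
#' Builds every stratum of \code{\link{district_defaults}} inside its own
#' square polygon, using 30 enumeration areas per district and rounding
#' households per cluster to hit the stratum sample size.
#'
#' @param seed integer master seed
#' @param size_km district polygon side (km)
#' @param cluster_sd within-cluster spread (km)
#' @param inflammation passed to \code{\link{make_district_dataset}}
#' @return list with \code{survey} (row-bound data frame), \code{polygons}
#'   (named list of vertex matrices) and \code{truth} (named list of
#'   \code{field_spec} per stratum, the recovery ground truth)
#' @export
simulate_survey <- function(seed = 1L, size_km = 50, cluster_sd = 0.5,
                            inflammation = "independent") {
  defs <- district_defaults()
  polys <- list()
  truth <- list()
  rows <- vector("list", nrow(defs))
  for (i in seq_len(nrow(defs))) {
    def <- defs[i, ]
    if (is.null(polys[[def$district]])) polys[[def$district]] <- square_polygon(size_km)
    fs <- field_spec(def$mean, def$family,
                     c0 = (1 - def$spatial_share) * def$variance,
                     c1 = def$spatial_share * def$variance, a = def$a)
    n_clusters <- 30L
    per <- max(1L, as.integer(round(def$n / n_clusters)))
    ss <- sampling_spec(polys[[def$district]], n_clusters = n_clusters,
                        per_cluster = per, cluster_sd = cluster_sd)
    key <- paste(def$district, def$group, sep = ".")
    truth[[key]] <- fs
    rows[[i]] <- make_district_dataset(fs, ss, group = def$group,
                                       district = def$district,
                                       seed = child_seed(seed, 100L + i),
                                       inflammation = inflammation)
  }
  list(survey = do.call(rbind, rows), polygons = polys, truth = truth)
}

#' Write a survey data frame and its ground truth to disk
#'
#' CSV columns follow the interchange layout \code{id, group, district,
#' x_km, y_km, se_ugL, crp_mgL, agp_gL}; the ground-truth sidecar (JSON)
#' records the generating \code{field_spec}s for recovery tests.
#'
#' @param survey survey data frame
#' @param path CSV output path
#' @param truth optional named list of \code{\link{field_spec}}
#' @param truth_path sidecar path (default: \code{path} with
#'   \code{.truth.json})
#' @return invisibly, the CSV path
#' @export
write_survey <- function(survey, path, truth = NULL, truth_path = NULL) {
  out <- data.frame(id = survey$id, group = survey$group,
                    district = survey$district,
                    x_km = survey$x, y_km = survey$y, se_ugL = survey$se,
                    crp_mgL = survey$crp, agp_gL = survey$agp)
  write.csv(out, path, row.names = FALSE)
  if (!is.null(truth)) {
    if (is.null(truth_path)) truth_path <- sub("\\.csv$", ".truth.json", path)
    jsonlite::write_json(lapply(truth, unclass), truth_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
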