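## Exploratory stage: summary statistics with octile skewness, the normality
## gate, GPS exclusion rules, quantile post-plot classes and the
## inflammation-correlation screen. Quantiles throughout use linear
## interpolation of order statistics (stats::quantile type 7), one convention
## for the whole package.

#' Octile skewness
#'
#' Robust skewness from the 1st, 4th and 7th octiles (12.5/50/87.5%
#' quantiles): \code{((O7 - O4) - (O4 - O1)) / (O7 - O1)}. Bounded in
#' [-1, 1]; values with \code{|skew| < 0.2} are conventionally treated as
#' compatible with a symmetric (Gaussian) distribution.
#'
#' @param values numeric vector (n >= 8 for the octiles to be defined)
#' @return octile skewness, or \code{NA} if undefined (n < 8 or zero
#'   inter-octile range)
#' @export
octile_skewness <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8L) return(NA_real_)
  o <- quantile(values, c(0.125, 0.5, 0.875), names = FALSE, type = 7)
  denom <- o[3L] - o[1L]
  if (denom == 0) return(NA_real_)
  ((o[3L] - o[2L]) - (o[2L] - o[1L])) / denom
}

#' Summary statistics for a biomarker vector
#'
#' @param values numeric vector of concentrations (ug/L)
#' @return object of class \code{se_summary}: n, mean, median, q1, q3, min,
#'   max, variance, sd, octile_skew
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("no finite values to summarize")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(
    n = n, mean = mean(values), median = q[2L], q1 = q[1L], q3 = q[3L],
    min = min(values), max = max(values),
    variance = if (n > 1L) var(values) else NA_real_,
    sd = if (n > 1L) sd(values) else NA_real_,
    octile_skew = octile_skewness(values)
  ), class = "se_summary")
}

#' @export
print.se_summary <- function(x, ...) {
  cat(sprintf(
    "n=%d  mean=%.1f  median=%.1f (Q1 %.1f, Q3 %.1f)  range [%.1f, %.1f]\n",
    x$n, x$mean, x$median, x$q1, x$q3, x$min, x$max))
  cat(sprintf("variance=%.1f  sd=%.1f  octile skewness=%s\n",
              x$variance, x$sd,
              if (is.na(x$octile_skew)) "undefined" else sprintf("%.2f", x$octile_skew)))
  invisible(x)
}

#' Octile-skewness normality gate
#'
#' Data pass when \code{|octile skewness| < threshold} (default 0.2), the
#' symmetry check used before assuming stationary Gaussian variation about a
#' constant mean. Failing strata should be transformed before variogram
#' estimation; this package only flags them.
#'
#' @param stats an \code{se_summary} (or a bare skewness value)
#' @param threshold gate on \code{|octile skewness|}
#' @return list: \code{decision} (\code{"pass"}, \code{"fail"} or
#'   \code{"indeterminate"}), \code{octile_skew}, \code{threshold},
#'   \code{rationale}
#' @export
normality_gate <- function(stats, threshold = 0.2) {
  skew <- if (inherits(stats, "se_summary")) stats$octile_skew else as.numeric(stats)
  if (is.na(skew)) {
    return(list(decision = "indeterminate", octile_skew = NA_real_,
                threshold = threshold,
                rationale = "octile skewness undefined (n < 8 or constant data)"))
  }
  pass <- abs(skew) < threshold
  list(decision = if (pass) "pass" else "fail", octile_skew = skew,
       threshold = threshold,
       rationale = sprintf("|octile skewness| = %.3f %s %.2f", abs(skew),
                           if (pass) "<" else ">=", threshold))
}

#' Exclude records with unusable GPS coordinates
#'
#' Drops records whose coordinates are missing/non-finite, or which fall
#' outside the district polygon by more than \code{buffer_km}. Retained
#' records are returned unmodified (filtering only). A warning is raised if
#' fewer than \code{min_n} records remain, the conventional minimum for
#' variogram estimation.
#'
#' @param records survey data frame (columns \code{x}, \code{y}, \code{se})
#' @param polygon optional boundary polygon (km); omit to skip the
#'   containment check
#' @param buffer_km tolerance outside the boundary (km)
#' @param min_n warning threshold on retained records
#' @return list: \code{records} (retained rows), \code{report} with
#'   \code{n_input}, \code{n_retained}, \code{n_excluded_gps},
#'   \code{n_excluded_boundary} and per-record \code{reasons}
#' @export
exclude_bad_gps <- function(records, polygon = NULL, buffer_km = 1,
                            min_n = 100L) {
  n <- nrow(records)
  reasons <- rep(NA_character_, n)
  bad_coord <- !is.finite(records$x) | !is.finite(records$y)
  reasons[bad_coord] <- "missing_gps"
  if (!is.null(polygon)) {
    idx <- which(!bad_coord)
    if (length(idx)) {
      inside <- point_in_polygon(records$x[idx], records$y[idx], polygon)
      near <- inside
      if (any(!inside)) {
        off <- idx[!inside]
        near[!inside] <- dist_to_boundary(records$x[off], records$y[off],
                                          polygon) <= buffer_km
      }
      reasons[idx[!near]] <- "outside_boundary"
    }
  }
  keep <- is.na(reasons)
  retained <- records[keep, , drop = FALSE]
  report <- list(
    n_input = n,
    n_retained = sum(keep),
    n_excluded_gps = sum(reasons == "missing_gps", na.rm = TRUE),
    n_excluded_boundary = sum(reasons == "outside_boundary", na.rm = TRUE),
    reasons = reasons
  )
  if (report$n_retained == 0L) stop("all records excluded by GPS screening")
  if (report$n_retained < min_n) {
    warning("only ", report$n_retained, " records retained; variogram ",
            "estimation conventionally needs at least ", min_n, " points")
  }
  list(records = retained, report = report)
}

#' Quartile classes for post plots
#'
#' Assigns each record its sample-quartile bin (1 = lowest). Values exactly
#' on a quartile boundary go to the lower bin. A constant vector puts every
#' record in bin 1 with a warning.
#'
#' @param records survey data frame with column \code{se} (or a numeric
#'   vector)
#' @return integer vector of bins in 1..4
#' @export
quantile_post_classes <- function(records) {
  values <- if (is.data.frame(records)) records$se else as.numeric(records)
  if (length(values) < 4L) stop("need at least 4 values for quartile classes")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (q[1L] == q[3L]) {
    warning("degenerate quartiles (constant data); all records in bin 1")
    return(rep(1L, length(values)))
  }
  1L + (values > q[1L]) + (values > q[2L]) + (values > q[3L])
}

#' Screen for inflammation-suppressed biomarker values
#'
#' Spearman rank correlation of plasma Se with CRP and with AGP, each with a
#' two-sided significance probability. The decision is
#' \code{"flag_for_adjustment"} only when some correlation is negative with
#' p < \code{alpha}; otherwise \code{"no_adjustment"}. The pipeline itself
#' never adjusts concentrations - inflammation correction is a separate
#' modelling exercise - it only records the decision.
#'
#' @param records survey data frame with columns \code{se} and optionally
#'   \code{crp}, \code{agp}
#' @param alpha significance level
#' @param min_pairs minimum complete pairs per marker
#' @return list: \code{decision} (\code{"no_adjustment"},
#'   \code{"flag_for_adjustment"} or \code{"not_assessed"}) and
#'   \code{correlations} (data frame marker/n/rho/p_value)
#' @export
inflammation_check <- function(records, alpha = 0.05, min_pairs = 10L) {
  rows <- list()
  for (marker in c("crp", "agp")) {
    if (!marker %in% names(records)) next
    ok <- is.finite(records$se) & is.finite(records[[marker]])
    if (sum(ok) < min_pairs) next
    ct <- suppressWarnings(cor.test(records$se[ok], records[[marker]][ok],
                                    method = "spearman", exact = FALSE))
    rows[[marker]] <- data.frame(marker = marker, n = sum(ok),
                                 rho = unname(ct$estimate),
                                 p_value = ct$p.value)
  }
  if (!length(rows)) {
    return(list(decision = "not_assessed",
                correlations = data.frame(marker = character(), n = integer(),
                                          rho = numeric(), p_value = numeric())))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  flag <- any(tab$rho < 0 & tab$p_value < alpha)
  list(decision = if (flag) "flag_for_adjustment" else "no_adjustment",
       correlations = tab)
}

#' Exploratory summary table by district and group
#'
#' One row per stratum in the layout of a survey exploratory table:
#' n, mean, median, quartiles, variance, SD and octile skewness.
#'
#' @param survey survey data frame
#' @return data frame, one row per district x group
#' @export
exploratory_table <- function(survey) {
  strata <- unique(survey[, c("district", "group")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- survey$district == strata$district[i] & survey$group == strata$group[i]
    s <- summarize_values(survey$se[sel])
    data.frame(district = strata$district[i], group = strata$group[i],
               n = s$n, mean = s$mean, median = s$median, q1 = s$q1,
               q3 = s$q3, variance = s$variance, sd = s$sd,
               octile_skew = s$octile_skew)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
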