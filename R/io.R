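## Survey reading/validation, configuration, and the end-to-end pipeline:
## exclusions -> exploratory summaries + gates -> empirical variograms ->
## REML fits -> LOOCV model selection -> prediction/variance/probability
## surfaces -> prevalence tables, with a machine-readable run manifest.

#' Read a survey CSV into the internal record layout
#'
#' Required columns: \code{id}, \code{group}, \code{district},
#' \code{se_ugL}, and either planar \code{x_km}/\code{y_km} or geographic
#' \code{lon}/\code{lat} (projected to planar km via
#' \code{\link{project_lonlat}}, transverse Mercator centred on the data).
#' Optional: \code{crp_mgL}, \code{agp_gL}. Rows whose Se value is missing
#' or non-positive are dropped with a tag; the read fails if more than
#' \code{max_bad_fraction} of rows are unusable. Missing coordinates are
#' retained (flagged later by \code{\link{exclude_bad_gps}}).
#'
#' @param path CSV file
#' @param max_bad_fraction error if more than this fraction of rows drop
#' @return list: \code{records} (survey data frame), \code{dropped}
#'   (data frame of row/reason), and the projection centre when geographic
#'   input was projected
#' @export
read_survey <- function(path, max_bad_fraction = 0.2) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group", "district", "se_ugL")
  missing_cols <- setdiff(required, names(raw))
  has_planar <- all(c("x_km", "y_km") %in% names(raw))
  has_geo <- all(c("lon", "lat") %in% names(raw))
  if (!has_planar && !has_geo) {
    missing_cols <- c(missing_cols, "x_km/y_km or lon/lat")
  }
  if (length(missing_cols)) {
    stop("survey CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  se <- suppressWarnings(as.numeric(raw$se_ugL))
  bad <- !is.finite(se) | se <= 0
  reason <- ifelse(!is.finite(se), "unparseable_se", "nonpositive_se")
  dropped <- data.frame(row = which(bad), reason = reason[bad])
  if (nrow(dropped) > max_bad_fraction * nrow(raw)) {
    stop(nrow(dropped), " of ", nrow(raw),
         " rows unusable (> ", 100 * max_bad_fraction, "%)")
  }
  keep <- !bad
  lon0 <- lat0 <- NULL
  if (has_planar) {
    x <- suppressWarnings(as.numeric(raw$x_km))
    y <- suppressWarnings(as.numeric(raw$y_km))
  } else {
    lon <- suppressWarnings(as.numeric(raw$lon))
    lat <- suppressWarnings(as.numeric(raw$lat))
    xy <- project_lonlat(lon, lat)
    x <- xy$x; y <- xy$y
    lon0 <- attr(xy, "lon0"); lat0 <- attr(xy, "lat0")
  }
  num_or_na <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]])) else NA_real_
  }
  records <- data.frame(
    id = as.character(raw$id), group = as.character(raw$group),
    district = as.character(raw$district),
    x = x, y = y, se = se,
    crp = num_or_na("crp_mgL"), agp = num_or_na("agp_gL"),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, dropped = dropped, lon0 = lon0, lat0 = lat0)
}

#' Pipeline configuration
#'
#' @param families candidate variogram families for model selection
#' @param estimators empirical-variogram estimators to compute
#' @param spacing_m prediction grid spacing, metres
#' @param thresholds a \code{\link{threshold_set}}
#' @param group_thresholds named list mapping demographic group to the
#'   threshold (by name) used for its probability surface: IDI for children
#'   (growth and thyroid function), GPX3 for women of reproductive age
#'   (oxidative-stress protection in pregnancy)
#' @param alpha significance level for the inflammation screen
#' @param buffer_km GPS exclusion buffer outside the district boundary
#' @param bin_width empirical variogram bin width (km)
#' @param seed integer seed recorded in the manifest
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(families = c("exponential", "spherical"),
                            estimators = c("matheron", "cressie_hawkins"),
                            spacing_m = 250,
                            thresholds = threshold_set(),
                            group_thresholds = list(child = "idi", wra = "gpx3"),
                            alpha = 0.05, buffer_km = 1, bin_width = 1,
                            seed = 1L) {
  stopifnot(spacing_m > 0, bin_width > 0)
  structure(list(families = families, estimators = estimators,
                 spacing_m = spacing_m, thresholds = thresholds,
                 group_thresholds = group_thresholds, alpha = alpha,
                 buffer_km = buffer_km, bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of \code{\link{pipeline_config}};
#' \code{thresholds} may be a mapping with keys generic/selenop/gpx3/idi.
#'
#' @param path YAML file
#' @return \code{pipeline_config}
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- if (!is.null(y$thresholds)) do.call(threshold_set, y$thresholds) else threshold_set()
  args <- y[intersect(names(y), c("families", "estimators", "spacing_m",
                                  "group_thresholds", "alpha", "buffer_km",
                                  "bin_width", "seed"))]
  args$thresholds <- th
  do.call(pipeline_config, args)
}

## Write a grid surface as long-format CSV (x_km, y_km, value).
write_surface <- function(surface, path, value_name = "value") {
  out <- data.frame(x_km = surface$x, y_km = surface$y, value = surface$value)
  names(out)[3L] <- value_name
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full geostatistical pipeline
#'
#' Processes each district x group stratum independently: GPS exclusions,
#' exploratory summary with the octile-skewness gate, the inflammation
#' screen, empirical variograms (both estimators), REML fits for every
#' candidate family plus the pure-nugget reference, leave-one-out
#' cross-validation, median-SSPE model selection, kriged prediction and
#' variance surfaces on a polygon-clipped grid, the group-specific
#' deficiency-probability surface with IPCC verbal labels, and a prevalence
#' table over all strata. Strata failing the normality gate are marked
#' \code{needs_transformation} and skipped for kriging. A stage failure
#' aborts the stratum, not the run; the manifest records it.
#'
#' @param survey survey data frame (or a \code{\link{read_survey}} result)
#' @param polygons named list of district boundary polygons (km)
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir output directory (created if needed); \code{NULL} for no
#'   file output
#' @return list of class \code{pipeline_result}: per-stratum results,
#'   prevalence table, manifest
#' @export
run_pipeline <- function(survey, polygons, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.list(survey) && !is.data.frame(survey) && !is.null(survey$records)) {
    survey <- survey$records
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit_csv <- function(obj, name) {
    if (!is.null(out_dir)) write.csv(obj, file.path(out_dir, name), row.names = FALSE)
  }
  emit_json <- function(obj, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(obj, file.path(out_dir, name), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
    }
  }
  strata <- unique(survey[, c("district", "group")])
  results <- list()
  manifest <- list(seed = config$seed, spacing_m = config$spacing_m,
                   families = config$families, strata = list())
  for (i in seq_len(nrow(strata))) {
    district <- strata$district[i]; group <- strata$group[i]
    key <- paste(district, group, sep = ".")
    poly <- polygons[[district]]
    process_stratum <- function() {
      recs <- survey[survey$district == district & survey$group == group, ]
      excl <- suppressWarnings(
        exclude_bad_gps(recs, polygon = poly, buffer_km = config$buffer_km))
      recs <- excl$records
      stats <- summarize_values(recs$se)
      gate <- normality_gate(stats)
      infl <- inflammation_check(recs, alpha = config$alpha)
      emp <- lapply(setNames(config$estimators, config$estimators), function(est) {
        empirical_variogram(recs, estimator = est, bin_width = config$bin_width)
      })
      out <- list(district = district, group = group, n = stats$n,
                  exclusions = excl$report, summary = stats, gate = gate,
                  inflammation = infl, empirical = emp)
      emit_json(excl$report[c("n_input", "n_retained", "n_excluded_gps",
                              "n_excluded_boundary")],
                paste0(key, ".exclusions.json"))
      emit_csv(data.frame(id = recs$id, x = recs$x, y = recs$y, se = recs$se,
                          quartile_bin = quantile_post_classes(recs)),
               paste0(key, ".postplot.csv"))
      if (gate$decision == "fail") {
        out$status <- "needs_transformation"
        return(out)
      }
      fits <- lapply(setNames(config$families, config$families), function(f) {
        suppressWarnings(reml_fit(recs, family = f))
      })
      cvs <- lapply(fits, function(m) loo_cross_validate(m, recs))
      sel <- select_model(cvs)
      cv_best <- cvs[[sel$index]]
      emit_csv(cv_best$folds, paste0(key, ".crossval.csv"))
      emit_json(list(median_sspe = cv_best$median_sspe, ci95 = cv_best$ci95,
                     rationale = sel$rationale,
                     model = unclass(sel$model)),
                paste0(key, ".model.json"))
      if (!is.null(poly)) {
        grid <- build_grid(poly, spacing_m = config$spacing_m)
        surf <- predict_surface(sel$model, recs, grid)
        th_name <- config$group_thresholds[[group]]
        th <- config$thresholds[[th_name]]
        prob <- deficiency_probability(surf$prediction, surf$variance, th)
        labels <- verbal_classify(prob)
        out$surfaces <- list(prediction = surf$prediction,
                             variance = surf$variance, probability = prob)
        out$threshold <- setNames(th, th_name)
        out$avg_probability <- average_surface(prob)
        out$verbal <- labels
        if (!is.null(out_dir)) {
          write_surface(surf$prediction, file.path(out_dir, paste0(key, ".prediction.csv")),
                        "se_ugL")
          write_surface(surf$variance, file.path(out_dir, paste0(key, ".variance.csv")),
                        "kriging_variance")
          pl <- data.frame(x_km = prob$x, y_km = prob$y, probability = prob$value,
                           verbal = as.character(labels))
          write.csv(pl, file.path(out_dir, paste0(key, ".probability.csv")),
                    row.names = FALSE)
        }
      }
      out$model <- sel$model
      out$selection <- sel
      out$cv <- cvs
      out$status <- "ok"
      out
    }
    res <- tryCatch(process_stratum(), error = function(e) {
      list(district = district, group = group, status = "failed",
           error = conditionMessage(e))
    })
    results[[key]] <- res
    manifest$strata[[key]] <- list(
      status = res$status,
      n = if (!is.null(res$n)) res$n else NA,
      selected_family = if (!is.null(res$model)) res$model$family else NA,
      median_sspe = if (!is.null(res$selection)) {
        res$cv[[res$selection$index]]$median_sspe
      } else NA,
      avg_probability = if (!is.null(res$avg_probability)) res$avg_probability else NA,
      error = if (!is.null(res$error)) res$error else NULL
    )
  }
  prev <- prevalence_table(survey, config$thresholds)
  emit_csv(prev, "prevalence.csv")
  emit_json(manifest, "manifest.json")
  structure(list(strata = results, prevalence = prev, manifest = manifest,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("geostatistical pipeline:", length(x$strata), "strata\n")
  for (key in names(x$strata)) {
    s <- x$strata[[key]]
    if (identical(s$status, "ok")) {
      cat(sprintf("  %-18s n=%-4d %s model, median SSPE %.3f, avg P(deficient) %.2f\n",
                  key, s$n, s$model$family,
                  s$cv[[s$selection$index]]$median_sspe,
                  if (!is.null(s$avg_probability)) s$avg_probability else NA))
    } else {
      cat(sprintf("  %-18s %s\n", key, s$status))
    }
  }
  invisible(x)
}
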