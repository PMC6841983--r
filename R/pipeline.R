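#' Pipeline configuration
#'
#' Bundles every tunable of the analysis. The defaults reproduce the
#' standard regional protocol: 1000-px square ROIs on the optic disc and
#' macula, box counting and lacunarity with 12 deterministic grid origins
#' and box sides up to 45% of the window, Student t-tests and alpha = 0.05.
#'
#' @param manifest Path to a manifest CSV ([read_manifest()]).
#' @param out_dir Output directory for result tables.
#' @param roi_shape `"square"` or `"circle"`.
#' @param roi_size ROI side/diameter in px (default 1000).
#' @param origins,max_size_frac,n_sizes Grid settings shared by
#'   [box_count()] and [lacunarity()].
#' @param t_variant `"student"` or `"welch"` for the regional t-tests.
#' @param alpha Significance level for post-hoc letters.
#' @param seed Integer seed (used only by synthetic generation verbs).
#' @param clamp_roi Shift edge-overrunning ROI windows inside bounds
#'   instead of failing (see [crop_roi()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = NULL,
                            roi_shape = c("square", "circle"), roi_size = 1000,
                            origins = 12, max_size_frac = 0.45, n_sizes = 20,
                            t_variant = c("student", "welch"), alpha = 0.05,
                            seed = 1, clamp_roi = FALSE) {
  structure(list(manifest = manifest, out_dir = out_dir,
                 roi_shape = match.arg(roi_shape), roi_size = as.integer(roi_size),
                 origins = as.integer(origins), max_size_frac = max_size_frac,
                 n_sizes = as.integer(n_sizes), t_variant = match.arg(t_variant),
                 alpha = alpha, seed = as.integer(seed), clamp_roi = clamp_roi),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj[!vapply(obj, is.null, TRUE)])
}

#' Analyze one mask: whole retina plus the two ROIs
#'
#' For each region the analysis window is cropped first and then
#' skeletonized (whole-retina analysis skeletonizes the full mask);
#' box-counting dimension, lacunarity and skeleton vessel density are all
#' measured on the skeleton of that window. Boundary-touching vessels are
#' thinned as-is, without padding.
#'
#' @param mask A [binary_mask].
#' @param od_roi,mac_roi [roi_spec]s for the optic-disc and macula windows;
#'   `NULL` skips that region.
#' @param config A [pipeline_config()] supplying grid settings.
#' @param image Identifier for the output rows.
#' @param group Group label for the output rows.
#' @return Data frame with one row per region: `image`, `group`, `region`,
#'   `db`, `db_sd`, `lambda_mean`, `density_pct`, `skeleton_px`.
#' @export
analyze_mask <- function(mask, od_roi = NULL, mac_roi = NULL,
                         config = pipeline_config(), image = mask$name,
                         group = NA_character_) {
  windows <- list(whole = mask)
  if (!is.null(mac_roi)) windows$macula <- crop_roi(mask, mac_roi, clamp = config$clamp_roi)
  if (!is.null(od_roi)) windows$optic_disc <- crop_roi(mask, od_roi, clamp = config$clamp_roi)
  rows <- lapply(names(windows), function(region) {
    sk <- skeletonize(windows[[region]])
    bc <- box_count(sk, origins = config$origins,
                    max_size_frac = config$max_size_frac, n_sizes = config$n_sizes)
    lac <- lacunarity(sk, origins = config$origins,
                      max_size_frac = config$max_size_frac, n_sizes = config$n_sizes)
    den <- vessel_density(sk)
    data.frame(image = image, group = group, region = region,
               db = bc$db, db_sd = bc$db_sd, lambda_mean = lac$lambda_mean,
               density_pct = den$density_pct, skeleton_px = den$foreground_px)
  })
  do.call(rbind, rows)
}

#' Run the full regional morphometry pipeline
#'
#' Reads the manifest, computes per-image metrics for the whole retina and
#' the two ROIs, then reproduces the standard statistical battery:
#' (i) macula vs optic disc t-tests per metric within the healthy group,
#' (ii) one-way ANOVA + Tukey across groups on whole-retina metrics,
#' (iii) two-way (region x group) ANOVA + Tukey over cell means on ROI
#' metrics. Unreadable masks are recorded as per-image errors and the run
#' continues. If `config$out_dir` is set, writes `metrics.csv`,
#' `stats_global.csv`, `stats_regional.csv` and `run_report.txt`.
#'
#' @param config A [pipeline_config()] with `manifest` set (or a
#'   `dataset_manifest` passed directly via `manifest`).
#' @param manifest Optional pre-loaded [read_manifest()] result, overriding
#'   `config$manifest`.
#' @return List with `metrics` (data frame), `healthy_region` (named list of
#'   `comparison_result` per metric), `global` (idem), `regional` (idem),
#'   `errors` (per-image failures), `config`.
#' @export
run_pipeline <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(manifest)) {
    manifest <- read_manifest(config$manifest, roi_size = config$roi_size,
                              roi_shape = config$roi_shape)
  }
  attr(manifest, "roi_size") <- config$roi_size
  attr(manifest, "roi_shape") <- config$roi_shape
  rows <- list(); errors <- list(); timings <- numeric()
  for (i in seq_len(nrow(manifest))) {
    ti <- Sys.time()
    res <- tryCatch({
      mask <- read_mask(manifest$mask[i])
      analyze_mask(mask,
                   od_roi = manifest_roi(manifest, i, "optic_disc"),
                   mac_roi = manifest_roi(manifest, i, "macula"),
                   config = config,
                   image = basename(manifest$mask[i]),
                   group = manifest$group[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[basename(manifest$mask[i])]] <- conditionMessage(res)
    } else {
      rows[[i]] <- res
    }
    timings <- c(timings, as.numeric(difftime(Sys.time(), ti, units = "secs")))
  }
  metrics <- metrics_record(do.call(rbind, rows))
  stats_for <- function(fun, data) {
    out <- list()
    for (m in c("db", "lambda_mean", "density_pct")) {
      out[[m]] <- tryCatch(fun(data, m), error = function(e) e)
    }
    out
  }
  healthy <- metrics[metrics$group == "H" & metrics$region != "whole", ]
  healthy_region <- if (nrow(healthy)) {
    stats_for(function(d, m) region_ttest(d, m, variant = config$t_variant), healthy)
  }
  whole <- metrics[metrics$region == "whole", ]
  global <- if (length(unique(whole$group)) >= 2) {
    stats_for(function(d, m) anova_oneway(d, m, alpha = config$alpha), whole)
  }
  rois <- metrics[metrics$region != "whole", ]
  regional <- if (length(unique(rois$group)) >= 2) {
    stats_for(function(d, m) anova_twoway(d, m, alpha = config$alpha), rois)
  }
  result <- list(metrics = metrics, healthy_region = healthy_region,
                 global = global, regional = regional, errors = errors,
                 config = config)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, timings, t0)
  }
  result
}

comparison_rows <- function(comps) {
  rows <- lapply(names(comps), function(m) {
    x <- comps[[m]]
    if (inherits(x, "error")) {
      return(data.frame(metric = m, design = NA, statistic = NA, p_value = NA,
                        letters = conditionMessage(x)))
    }
    data.frame(metric = m, design = x$design, statistic = x$statistic,
               p_value = x$p_value,
               letters = if (is.null(x$letters)) "" else
                 paste(names(x$letters), x$letters, sep = "=", collapse = ";"))
  })
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(result, timings, t0) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- result$config$out_dir
  utils::write.csv(result$metrics, file.path(od, "metrics.csv"), row.names = FALSE)
  if (!is.null(result$global)) {
    utils::write.csv(comparison_rows(result$global),
                     file.path(od, "stats_global.csv"), row.names = FALSE)
  }
  if (!is.null(result$regional)) {
    utils::write.csv(comparison_rows(result$regional),
                     file.path(od, "stats_regional.csv"), row.names = FALSE)
  }
  rpt <- c(sprintf("retmorph %s run report", as.character(utils::packageVersion("retmorph"))),
           sprintf("started: %s", format(t0)),
           sprintf("R: %s", R.version.string),
           sprintf("config: %s", jsonlite::toJSON(unclass(result$config),
                                                  auto_unbox = TRUE, null = "null")),
           sprintf("images analyzed: %d, failed: %d",
                   length(unique(result$metrics$image)), length(result$errors)),
           sprintf("per-image time [s]: %s", paste(round(timings, 2), collapse = " ")),
           if (length(result$errors)) {
             paste("errors:", paste(names(result$errors), unlist(result$errors),
                                    sep = ": ", collapse = "; "))
           })
  writeLines(rpt, file.path(od, "run_report.txt"))
  invisible(NULL)
}

#' Compare square and circular ROI shapes image by image
#'
#' For every image and region, measures Db and lacunarity under both the
#' square ROI and the inscribed-circle ROI of the same centre and size, and
#' summarises the per-image paired differences. Corner removal deletes
#' foreground, so circular windows can only lower the occupied-box counts.
#'
#' @inheritParams run_pipeline
#' @return List with `paired` (per image/region/shape metrics) and
#'   `summary` (median square-minus-circle differences and sign counts).
#' @export
compare_roi_shapes <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(manifest)) {
    manifest <- read_manifest(config$manifest, roi_size = config$roi_size)
  }
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    mask <- read_mask(manifest$mask[i])
    for (region in c("macula", "optic_disc")) {
      for (shape in c("square", "circle")) {
        attr(manifest, "roi_shape") <- shape
        attr(manifest, "roi_size") <- config$roi_size
        roi <- manifest_roi(manifest, i, region)
        sk <- skeletonize(crop_roi(mask, roi, clamp = config$clamp_roi))
        bc <- box_count(sk, origins = config$origins,
                        max_size_frac = config$max_size_frac,
                        n_sizes = config$n_sizes)
        lac <- lacunarity(sk, origins = config$origins,
                          max_size_frac = config$max_size_frac,
                          n_sizes = config$n_sizes)
        rows[[length(rows) + 1L]] <- data.frame(
          image = basename(manifest$mask[i]), group = manifest$group[i],
          region = region, shape = shape, db = bc$db,
          lambda_mean = lac$lambda_mean)
      }
    }
  }
  paired <- do.call(rbind, rows)
  sq <- paired[paired$shape == "square", ]
  ci <- paired[paired$shape == "circle", ]
  key <- paste(sq$image, sq$region)
  ci <- ci[match(key, paste(ci$image, ci$region)), ]
  d_db <- sq$db - ci$db
  d_lam <- sq$lambda_mean - ci$lambda_mean
  list(paired = paired,
       summary = data.frame(
         metric = c("db", "lambda_mean"),
         median_square_minus_circle = c(stats::median(d_db), stats::median(d_lam)),
         n_positive = c(sum(d_db > 0), sum(d_lam > 0)),
         n = length(d_db)))
}
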