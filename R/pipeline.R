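#' Screen a video for visible drug dynamics
#'
#' Computes the ROI percent-variation signal, smooths it with a 1-s moving
#' average and applies the inclusion rule (strictly above `threshold_pct`).
#' Optionally writes the trace CSV and decision JSON.
#'
#' @param video An [ebus_video()] or a TIFF path.
#' @param annotation An [injection_annotation()] or a JSON path.
#' @param threshold_pct Inclusion threshold, percent (default 20).
#' @param side_cm ROI side, cm.
#' @param out_dir Optional output directory for artifacts.
#' @return A list with `included`, `max_pct`, `trace` (raw) and `smoothed`.
#' @export
run_screening <- function(video, annotation, threshold_pct = 20,
                          side_cm = 1, out_dir = NULL) {
  if (is.character(video)) video <- read_video(video)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  raw <- intensity_variation(video, annotation, side_cm)
  sm <- moving_average(raw, 1)
  verdict <- passes_inclusion(sm, threshold_pct)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trace(sm, file.path(out_dir, "screening_trace.csv"))
    jsonlite::write_json(
      list(injection_id = annotation$injection_id,
           included = verdict$included,
           max_pct = verdict$max_pct, threshold_pct = threshold_pct),
      file.path(out_dir, "screening.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(included = verdict$included, max_pct = verdict$max_pct,
       trace = raw, smoothed = sm)
}

#' Full per-injection analysis
#'
#' Runs the whole pipeline on one injection video: screening, background
#' model, depot segmentation, uptake kinetics (background-subtracted mean
#' cone intensity), constant flow rate, needle-frame shape metrics,
#' rotation-volume retention, and the physical-mechanism report driven by
#' the fitted flow rate and the measured depot size. Videos failing the
#' screening rule stop after screening with `included = FALSE` and no
#' downstream fields.
#'
#' @param video An [ebus_video()] or TIFF path.
#' @param annotation An [injection_annotation()] or JSON path.
#' @param threshold_pct Screening threshold, percent.
#' @param segmentation Named list of overrides for [segment_depot()].
#' @param mechanisms Named list of overrides for [mechanism_report()]
#'   inputs: `p_i`, `k_lit`, `p_ref_kpa`, `q_ref_ml_per_s`,
#'   `sigma_injection_kpa`.
#' @param out_dir Optional directory; when given every intermediate
#'   artifact (background, masks, traces, fits, report) is written.
#' @return An object of class `injection_result` with fields
#'   `injection_id`, `included`, `uptake`, `flow`, `shape`, `retention`,
#'   `mechanism`, `provenance`.
#' @export
run_full <- function(video, annotation, threshold_pct = 20,
                     segmentation = list(), mechanisms = list(),
                     out_dir = NULL) {
  if (is.character(video)) video <- read_video(video)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  stage <- "screening"
  result <- tryCatch({
    scr <- run_screening(video, annotation, threshold_pct,
                         out_dir = out_dir)
    prov <- list(
      package_version = as.character(utils::packageVersion("ebusdepot")),
      config_hash = rlang::hash(list(
        annotation = unclass(annotation), threshold_pct = threshold_pct,
        segmentation = segmentation, mechanisms = mechanisms
      ))
    )
    if (!scr$included) {
      excluded <- structure(
        list(injection_id = annotation$injection_id, included = FALSE,
             screening = scr[c("included", "max_pct")],
             uptake = NULL, flow = NULL, shape = NULL, retention = NULL,
             mechanism = NULL, provenance = prov),
        class = "injection_result"
      )
      if (!is.null(out_dir)) write_injection_result(excluded, out_dir)
      return(excluded)
    }

    stage <- "background"
    bg <- compute_background(video, annotation$t0)

    stage <- "kinetics"
    mu <- mean_cone_trace(video, bg, annotation$t0)
    fit <- fit_uptake(mu)
    flow <- flow_rate(annotation$injected_volume, fit)

    stage <- "segmentation"
    seg <- do.call(segment_depot,
                   c(list(video = video, background = bg,
                          annotation = annotation), segmentation))

    stage <- "shape"
    nf <- needle_frame(annotation)
    shp <- shape_trace(seg, nf)
    ret <- retention(seg, nf, annotation$injected_volume)

    stage <- "mechanisms"
    fer_final <- shp[nrow(shp), ]
    r_range <- sort(c(fer_final$feret_min, fer_final$feret_max)) / 2
    r_range <- pmax(r_range, 0.05)
    p_ref <- mechanisms$p_ref_kpa %||% 30
    q_ref <- mechanisms$q_ref_ml_per_s %||% 0.05
    sigma <- mechanisms$sigma_injection_kpa %||%
      (pressure_from_flow(p_ref, q_ref, flow$q_ml_per_s) * c(1, 1.25))
    dar <- darcy_params(
      q_inj = flow$q_ml_per_s,
      p_i = mechanisms$p_i %||% 10,
      r_depot_cm = r_range,
      k_lit = mechanisms$k_lit %||% 3.1831e-7
    )
    mech <- mechanism_report(darcy = dar, sigma_injection_kpa = sigma)

    structure(
      list(injection_id = annotation$injection_id, included = TRUE,
           screening = scr[c("included", "max_pct")],
           uptake = fit, flow = flow, shape = shp, retention = ret,
           mechanism = mech, provenance = prov),
      class = "injection_result"
    )
  }, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
          parent = e)
  })

  if (!is.null(out_dir)) write_injection_result(result, out_dir)
  result
}

#' @export
print.injection_result <- function(x, ...) {
  cat(sprintf("<injection_result> %s: %s\n", x$injection_id,
              if (x$included) "included" else "excluded by screening"))
  if (x$included) {
    cat(sprintf("  delta_t %.2f s, Q %.3f mL/s, R^2 %.3f, retention %.1f%%\n",
                x$uptake$delta_t, x$flow$q_ml_per_s, x$uptake$r_squared,
                x$retention$retention_pct))
  }
  invisible(x)
}

write_injection_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    injection_id = result$injection_id,
    included = result$included,
    provenance = result$provenance
  )
  if (result$included) {
    summary <- c(summary, list(
      a = result$uptake$a, b = result$uptake$b, c = result$uptake$c,
      r_squared = result$uptake$r_squared,
      delta_t_s = result$uptake$delta_t,
      q_ml_per_s = result$flow$q_ml_per_s,
      retention_pct = result$retention$retention_pct,
      rotation_volume_ml = result$retention$rotation_volume_ml,
      porous_flow_plausible = result$mechanism$porous_flow_plausible,
      fracture_plausible = result$mechanism$fracture_plausible
    ))
    utils::write.csv(as.data.frame(result$shape),
                     file.path(out_dir, "shape_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(result$retention$trace),
                     file.path(out_dir, "retention_trace.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Cohort summary across injections
#'
#' Runs [run_full()] for each injection and assembles one row per
#' injection with the headline quantities. Per-injection failures are
#' recorded as error rows; the run continues.
#'
#' @param inputs A list of lists, each with elements `video`,
#'   `annotation` and optionally any [run_full()] argument.
#' @param out_dir Optional directory; the summary CSV is written there.
#' @return A tibble with columns `injection_id`, `included`, `delta_t_s`,
#'   `q_ml_per_s`, `r_squared`, `retention_pct`, `error`.
#' @export
run_cohort <- function(inputs, out_dir = NULL) {
  stopifnot(length(inputs) >= 1)
  rows <- purrr::map(inputs, function(inp) {
    res <- tryCatch(do.call(run_full, inp), error = function(e) e)
    if (inherits(res, "error")) {
      ann <- inp$annotation
      id <- if (inherits(ann, "injection_annotation")) ann$injection_id else NA_character_
      return(tibble::tibble(
        injection_id = id, included = NA,
        delta_t_s = NA_real_, q_ml_per_s = NA_real_,
        r_squared = NA_real_, retention_pct = NA_real_,
        error = conditionMessage(res)
      ))
    }
    tibble::tibble(
      injection_id = res$injection_id,
      included = res$included,
      delta_t_s = if (res$included) res$uptake$delta_t else NA_real_,
      q_ml_per_s = if (res$included) res$flow$q_ml_per_s else NA_real_,
      r_squared = if (res$included) res$uptake$r_squared else NA_real_,
      retention_pct = if (res$included) res$retention$retention_pct else NA_real_,
      error = NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
  }
  out
}
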