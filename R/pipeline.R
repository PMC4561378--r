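# End-to-end composition: smoothing -> iso-level search band -> proposed
# initial contour -> level-set evolution -> mask, plus the cohort
# initialization-sensitivity experiment.

#' Propose an initial level-set contour for a mass image
#'
#' Runs the full initialization chain on an already TV-smoothed image:
#' threshold set, iso-level contour map, dense nested search band, radial
#' maximum-gradient profile, statistical clipping, contour assembly.
#'
#' @param smoothed TV-smoothed image matrix.
#' @param n_levels number of iso-levels.
#' @param min_run minimum contours in the search band.
#' @param m number of radial rays.
#' @param n_sigma clipping multiplier (1 or 2).
#' @return list with `contour` (closed polyline), `band`, `profile`,
#'   `clipped`, `map`.
#' @export
propose_initial_contour <- function(smoothed, n_levels = 24, min_run = 4,
                                    m = 360, n_sigma = 1) {
  thr <- compute_thresholds(smoothed, n_levels)
  map <- iso_level_map(smoothed, thr)
  band <- extract_search_band(map, min_run)
  gm <- gradient_magnitude(smoothed)
  prof <- radial_profile(band, gm, m)
  clip <- clip_profile(prof, n_sigma)
  list(contour = profile_to_contour(clip), band = band, profile = prof,
       clipped = clip, map = map)
}

#' Evolve an initial contour to a final mask
#'
#' @param img image matrix in \[0, 1\] (typically the smoothed image).
#' @param contour closed initial `polyline`.
#' @param model `"chanvese"` or `"spf"`.
#' @param params optional [chan_vese_params()] / [spf_params()] bundle.
#' @param fill_holes passed to [mask_from_levelset()].
#' @return list with `mask`, `result` (the `levelset_result`).
#' @export
segment_from_contour <- function(img, contour,
                                 model = c("chanvese", "spf"),
                                 params = NULL, fill_holes = FALSE) {
  model <- match.arg(model)
  phi0 <- init_levelset(contour, dim(img))
  res <- if (model == "chanvese") {
    evolve_chan_vese(img, phi0, params %||% chan_vese_params())
  } else {
    evolve_sbgfrls(img, phi0, params %||% spf_params())
  }
  list(mask = mask_from_levelset(res$phi, fill_holes), result = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialization-sensitivity experiment on a phantom cohort
#'
#' For each phantom specification: generate the phantom, smooth it, build
#' the proposed initial contour and a loose manual-style enclosing
#' contour, propagate both with each requested model, and compare the two
#' final segmentations. The smoothing and initialization chain is shared
#' across models. Per-phantom failures are logged and skipped.
#'
#' @param specs list of [phantom_spec()] objects (length >= 2).
#' @param models subset of `c("chanvese", "spf")`.
#' @param params optional named list of evolution parameter bundles, e.g.
#'   `list(chanvese = chan_vese_params(...), spf = spf_params(...))`.
#' @param tv_lam smoothing scale for the proposed-contour chain.
#' @param dilation manual-ROI outward offset in pixels.
#' @param n_levels,min_run,m,n_sigma initialization-chain settings.
#' @return a `sensitivity_experiment`: `table` (one row per phantom and
#'   model with JSC, DF, percentage differences and paired descriptors),
#'   `agreement` (per-model [agreement_report()]), `failures` (character
#'   vector of messages).
#' @export
sensitivity_experiment <- function(specs, models = c("chanvese", "spf"),
                                   params = NULL, tv_lam = 0.05,
                                   dilation = 10, n_levels = 24,
                                   min_run = 4, m = 360, n_sigma = 1) {
  models <- match.arg(models, several.ok = TRUE)
  if (length(specs) < 2)
    stop("need at least 2 phantom specs", call. = FALSE)
  rows <- list()
  failures <- character(0)
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    prep <- tryCatch({
      ph <- make_phantom(spec)
      sm <- weighted_tv_flow(ph$image, tv_params(lam = tv_lam))
      prop <- propose_initial_contour(sm, n_levels, min_run, m, n_sigma)
      man <- make_manual_init(ph$truth_contour, dilation, spec$size)
      list(ph = ph, sm = sm, prop = prop, man = man)
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("phantom %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(prep)) next
    for (model in models) {
      row <- tryCatch({
        segY <- segment_from_contour(prep$sm, prep$prop$contour, model,
                                     params[[model]])
        segX <- segment_from_contour(prep$sm, prep$man, model,
                                     params[[model]])
        cmp <- compare_pair(segX$mask, segY$mask)
        data.frame(id = i, model = model, margin = spec$margin,
                   seed = spec$seed, jsc = cmp$jsc, df = cmp$df,
                   pdF1 = cmp$pdF1, pdF2 = cmp$pdF2, pdF3 = cmp$pdF3,
                   pdSC = cmp$pdSC, pdSR = cmp$pdSR,
                   jsc_truth_manual = jaccard(segX$mask, prep$ph$truth_mask),
                   jsc_truth_proposed = jaccard(segY$mask, prep$ph$truth_mask),
                   F1_x = cmp$descX$F1, F1_y = cmp$descY$F1,
                   F2_x = cmp$descX$F2, F2_y = cmp$descY$F2,
                   F3_x = cmp$descX$F3, F3_y = cmp$descY$F3,
                   SC_x = cmp$descX$SC, SC_y = cmp$descY$SC,
                   SR_x = cmp$descX$SR, SR_y = cmp$descY$SR)
      }, error = function(e) {
        failures <<- c(failures, sprintf("phantom %d (%s): %s", i, model,
                                         conditionMessage(e)))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  table <- do.call(rbind, rows)
  agreement <- NULL
  if (!is.null(table)) {
    agreement <- do.call(rbind, lapply(unique(table$model), function(mm) {
      sub <- table[table$model == mm, ]
      if (nrow(sub) < 3) return(NULL)
      cbind(model = mm, agreement_report(sub))
    }))
  }
  structure(list(table = table, agreement = agreement, failures = failures,
                 models = models),
            class = "sensitivity_experiment")
}

#' @export
print.sensitivity_experiment <- function(x, ...) {
  cat(sprintf("initialization-sensitivity experiment: %d rows, %d failures\n",
              if (is.null(x$table)) 0 else nrow(x$table),
              length(x$failures)))
  if (!is.null(x$table)) {
    for (mm in unique(x$table$model)) {
      for (mg in unique(x$table$margin)) {
        sub <- x$table[x$table$model == mm & x$table$margin == mg, ]
        if (!nrow(sub)) next
        cat(sprintf("  %s / %s: mean JSC(proposed vs manual) = %.3f (n = %d)\n",
                    mm, mg, mean(sub$jsc), nrow(sub)))
      }
    }
  }
  invisible(x)
}

#' Run the full pipeline on an image file and write artifacts
#'
#' Stages: read, smooth, band, init, segment, describe (and compare when a
#' manual contour is supplied). Every artifact is written under
#' `config$out_dir`; errors name the failing stage.
#'
#' @param config a list (see [run_config()]): `input`, `out_dir`, `model`,
#'   `tv_lam`, `n_levels`, `min_run`, `m`, `n_sigma`, optional
#'   `manual_contour` CSV path, optional parameter bundles.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- stage("read", load_gray_image(cfg$input))
  sm <- stage("smooth", weighted_tv_flow(img, tv_params(lam = cfg$tv_lam)))
  paths <- list(smoothed = file.path(cfg$out_dir, "smoothed.png"))
  write_gray_image(sm, paths$smoothed)
  prop <- stage("init", propose_initial_contour(sm, cfg$n_levels,
                                                cfg$min_run, cfg$m,
                                                cfg$n_sigma))
  paths$band_overlay <- file.path(cfg$out_dir, "band_overlay.png")
  overlay <- pmin(sm + 0.5 * prop$band$band_mask, 1)
  write_gray_image(overlay, paths$band_overlay)
  paths$init <- file.path(cfg$out_dir, "init_contour.csv")
  write_contour_csv(prop$contour, paths$init)
  seg <- stage("segment",
               segment_from_contour(sm, prop$contour, cfg$model))
  paths$mask <- file.path(cfg$out_dir, "mask.png")
  write_mask_png(seg$mask, paths$mask)
  paths$log <- file.path(cfg$out_dir, "iterations.csv")
  utils::write.csv(seg$result$log, paths$log, row.names = FALSE)
  desc <- stage("describe", describe_mask(seg$mask))
  paths$descriptors <- file.path(cfg$out_dir, "descriptors.csv")
  write_descriptors_csv(desc, paths$descriptors)
  if (!is.null(cfg$manual_contour)) {
    man <- stage("manual", read_contour_csv(cfg$manual_contour))
    segX <- stage("segment", segment_from_contour(sm, man, cfg$model))
    cmp <- stage("compare", compare_pair(segX$mask, seg$mask))
    paths$pair <- file.path(cfg$out_dir, "pair_comparison.json")
    jsonlite::write_json(
      list(jsc = cmp$jsc, df = cmp$df, pdF1 = cmp$pdF1, pdF2 = cmp$pdF2,
           pdF3 = cmp$pdF3, pdSC = cmp$pdSC, pdSR = cmp$pdSR),
      paths$pair, auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
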