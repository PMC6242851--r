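#' Movement steps and turning angles of a regular track
#'
#' @param track data.frame with `x`, `y` (km), regular time spacing.
#' @return data.frame `step` (km) and `angle` (radians; `NA` for the first
#'   two positions), length `nrow(track) - 1`.
#' @export
track_steps <- function(track) {
  dx <- diff(track$x); dy <- diff(track$y)
  step <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  angle <- c(NA, diff(bearing))
  angle <- atan2(sin(angle), cos(angle))
  data.frame(step = step, angle = angle)
}

# Proportion of each [t, t+dt) interval spent hauled out / diving, from the
# haul-out events and dive records overlapping the interval.
interval_activity <- function(times, dt_h, dives, haulouts) {
  n <- length(times)
  t0 <- as.numeric(times); t1 <- t0 + dt_h * 3600
  hauled <- numeric(n); diving <- numeric(n)
  if (!is.null(haulouts) && nrow(haulouts)) {
    hs <- as.numeric(haulouts$start_time); he <- as.numeric(haulouts$end_time)
    for (i in seq_len(nrow(haulouts))) {
      ov <- pmax(0, pmin(t1, he[i]) - pmax(t0, hs[i]))
      hauled <- hauled + ov
    }
  }
  if (!is.null(dives) && nrow(dives)) {
    ds <- as.numeric(dives$start_time)
    de <- ds + dives$duration_min * 60
    for (i in seq_len(nrow(dives))) {
      ov <- pmax(0, pmin(t1, de[i]) - pmax(t0, ds[i]))
      diving <- diving + ov
    }
  }
  data.frame(prop_diving = pmin(1, diving / (dt_h * 3600)),
             prop_hauled = pmin(1, hauled / (dt_h * 3600)))
}

#' Two-hourly interpolated track for one seal
#'
#' Projects the seal's GPS fixes to the planar system, fits the CTCRW model
#' with the haul-out stopping constraint and predicts positions on a
#' regular grid.
#'
#' @param dataset a dataset list.
#' @param seal_id seal to process.
#' @param every_h grid spacing in hours (2 for the behavioural analysis,
#'   1 for home ranges).
#' @param error_sd_m GPS error sd.
#' @param seed fitting seed.
#' @return list: `track` (interpolated positions), `fit`, `fixes`
#'   (planar), `haulouts`.
#' @export
seal_track <- function(dataset, seal_id, every_h = 2, error_sd_m = 36, seed = 1) {
  fx <- dataset$fixes[dataset$fixes$seal_id == seal_id, ]
  ho <- dataset$haulouts[dataset$haulouts$seal_id == seal_id, ]
  ctr <- dataset$env$center
  p <- project_aeqd(fx$lat, fx$lon, ctr)
  fx$x <- p$x; fx$y <- p$y
  fit <- fit_ctcrw(fx, ho, error_sd_m = error_sd_m, seed = seed)
  tt <- seq(min(fx$time), max(fx$time), by = every_h * 3600)
  track <- predict_positions(fit, fx, ho, tt)
  list(track = track, fit = fit, fixes = fx, haulouts = ho)
}

#' Foraging areas and specialization indices for a population
#'
#' The full behavioural specialization chain: per seal, a two-hourly CTCRW
#' track, an HMM with diving and haul-out covariates, Viterbi decoding with
#' behavioural labels, density-cluster foraging-area selection per 3-day
#' interval, habitat covariates at the selected areas, and pairwise
#' similarity indices per environmental variable.
#'
#' @param dataset dataset with `env`.
#' @param variables environmental variables to compare.
#' @param min_pts DBSCAN minimum points.
#' @param seed seed driving CTCRW and HMM restarts.
#' @param hmm_restarts HMM restarts per seal.
#' @return list: `areas` (one row per seal x interval), `indices` (one
#'   [similarity_indices()] result per variable), `states` per seal.
#' @export
specialization_pipeline <- function(dataset, variables = c("dist_glacier",
                                                           "dist_coast",
                                                           "bathy_depth"),
                                    min_pts = 5, seed = 1, hmm_restarts = 2) {
  ids <- unique(dataset$metadata$id)
  areas <- NULL
  states_by_seal <- list()
  for (s in seq_along(ids)) {
    id <- ids[s]
    st <- seal_track(dataset, id, every_h = 2, seed = seed + s)
    tr <- st$track
    mv <- track_steps(tr)
    act <- interval_activity(tr$time[-nrow(tr)], 2,
                             dataset$dives[dataset$dives$seal_id == id, ],
                             st$haulouts)
    model <- fit_hmm(mv$step, mv$angle, act, n_restarts = hmm_restarts,
                     seed = seed + 100 * s)
    dec <- viterbi_states(model, mv$step, mv$angle, act)
    labels <- label_states(dec, mv$step, act$prop_hauled)
    states_by_seal[[id]] <- labels[dec]
    forage <- which(labels[dec] == "foraging")
    if (!length(forage)) next
    ft <- tr[forage, ]
    bin <- floor(as.numeric(ft$time - min(tr$time), units = "days") / 3)
    for (b in unique(bin)) {
      sel <- bin == b
      fa <- select_foraging_area(cbind(ft$x[sel], ft$y[sel]), min_pts = min_pts)
      if (is.null(fa)) next
      areas <- rbind(areas, data.frame(seal_id = id, interval = b,
                                       time = ft$time[sel][fa$index],
                                       x = fa$x, y = fa$y,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(areas) || length(unique(areas$seal_id)) < 2)
    stop("too few foraging areas to compare seals")
  cv <- extract_covariates(areas[, c("time", "x", "y")], dataset$env)
  areas$dist_coast <- cv$dist_coast
  areas$dist_glacier <- cv$dist_glacier
  areas$bathy_depth <- cv$bathy_depth
  idx <- lapply(variables, function(v) similarity_indices(areas, v))
  list(areas = areas, indices = setNames(idx, variables),
       states = states_by_seal)
}

#' Pipeline run configuration
#'
#' @param mode "synthetic" (generate a population) or "files" (read a
#'   dataset directory).
#' @param input_dir dataset directory for `mode = "files"`.
#' @param out_dir output directory.
#' @param seed master seed; per-stage and per-seal seeds are derived from
#'   it.
#' @param sim a [sim_config()] for synthetic mode.
#' @param ... module parameter overrides: `error_sd_m`, `cell_m`,
#'   `hr_error_sd_m`, `window`, `margin`, `min_days`, `boot_reps`,
#'   `min_pts`, `benthic_margin_m`, `tau_h`, `rho_km`, `zeta_m`, `K`.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), input_dir = NULL,
                       out_dir = tempfile("pinnitrack_run_"), seed = 1,
                       sim = sim_config(seed = seed), ...) {
  mode <- match.arg(mode)
  params <- list(error_sd_m = 36, cell_m = 500, hr_error_sd_m = 50,
                 window = 35, margin = 11, min_days = 20, boot_reps = 10000,
                 min_pts = 5, benthic_margin_m = 25,
                 tau_h = 48, rho_km = 25, zeta_m = 10, K = 10)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(params))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params[names(extra)] <- extra
  structure(c(list(mode = mode, input_dir = input_dir, out_dir = out_dir,
                   seed = seed, sim = sim), params),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — load or simulate, track
#' fitting and hourly interpolation, home ranges, habitat summaries and
#' trends, specialization, dive metrics and PCA, water masses — writing
#' tidy CSV outputs to `config$out_dir` and a run manifest (config hash,
#' file checksums, wall time per stage) last. Any stage failure halts with
#' an error naming the stage.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every stage's in-memory result plus the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("pinnitrack")),
                   seed = config$seed, stages = list())
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(wall_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  ds <- stage("input", function() {
    if (config$mode == "synthetic") simulate_population(config$sim)
    else read_dataset(config$input_dir)
  })
  results$dataset <- ds
  ids <- unique(ds$metadata$id)

  tracks <- stage("track", function() {
    out <- list()
    for (s in seq_along(ids))
      out[[ids[s]]] <- seal_track(ds, ids[s], every_h = 1,
                                  error_sd_m = config$error_sd_m,
                                  seed = config$seed + s)
    out
  })
  results$tracks <- tracks
  tr_csv <- do.call(rbind, lapply(ids, function(id)
    cbind(seal_id = id, as.data.frame(tracks[[id]]$track))))
  write.csv(tr_csv, file.path(config$out_dir, "hourly_tracks.csv"), row.names = FALSE)

  results$home_ranges <- stage("home_range", function() {
    hr <- do.call(rbind, lapply(ids, function(id)
      monthly_home_ranges(tracks[[id]]$track, seal_id = id,
                          window = config$window, margin = config$margin,
                          cell_m = config$cell_m,
                          error_sd_m = config$hr_error_sd_m,
                          min_days = config$min_days)))
    write.csv(hr, file.path(config$out_dir, "home_ranges.csv"), row.names = FALSE)
    hr
  })

  results$habitat <- stage("habitat", function() {
    out <- list()
    summaries <- NULL; trends <- NULL
    for (s in seq_along(ids)) {
      id <- ids[s]
      cv <- extract_covariates(tracks[[id]]$track, ds$env)
      out[[id]] <- list(covariates = cv)
      summaries <- rbind(summaries,
                         habitat_summaries(cv, seal_id = id,
                                           reps = config$boot_reps,
                                           seed = config$seed + 10 * s))
      day <- as.numeric(cv$time - min(cv$time), units = "days") + 1
      for (v in c("dist_coast", "dist_glacier", "bathy_depth")) {
        tr <- tryCatch(seasonal_trend(cv[[v]][cv$valid], day[cv$valid]),
                       error = function(e) NULL)
        if (!is.null(tr))
          trends <- rbind(trends, data.frame(seal_id = id, variable = v,
                                             slope = tr$slope,
                                             p_value = tr$p_value,
                                             transform = tr$transform))
      }
      out[[id]]$env_ud <- tryCatch(env_space_ud(cv), error = function(e) NULL)
    }
    write.csv(summaries, file.path(config$out_dir, "habitat_summaries.csv"),
              row.names = FALSE)
    write.csv(trends, file.path(config$out_dir, "habitat_trends.csv"),
              row.names = FALSE)
    c(out, list(summaries = summaries, trends = trends))
  })

  results$specialization <- stage("specialization", function() {
    sp <- specialization_pipeline(ds, min_pts = config$min_pts,
                                  seed = config$seed)
    write.csv(sp$areas, file.path(config$out_dir, "foraging_areas.csv"),
              row.names = FALSE)
    idx <- do.call(rbind, lapply(sp$indices, `[[`, "summary"))
    write.csv(idx, file.path(config$out_dir, "similarity_indices.csv"),
              row.names = FALSE)
    sp
  })

  results$dives <- stage("dives", function() {
    dm <- dive_metrics(ds$dives, ds$env, margin_m = config$benthic_margin_m)
    write.csv(dm, file.path(config$out_dir, "dive_metrics.csv"), row.names = FALSE)
    budgets <- lapply(ids, function(id)
      activity_budget(ds$summaries[ds$summaries$seal_id == id, ],
                      ds$haulouts[ds$haulouts$seal_id == id, ]))
    names(budgets) <- ids
    mon <- format(dm$start_time, "%Y-%m")
    tab <- aggregate(cbind(duration_min, max_depth, surface_after_s, bottom,
                           ascent, descent) ~ seal_id + mon, data = dm, FUN = mean)
    benth <- aggregate((dive_class == "benthic") ~ seal_id + mon, data = dm,
                       FUN = function(z) 100 * mean(z))
    names(benth)[3] <- "pct_benthic"
    tab <- merge(tab, benth)
    pca <- tryCatch(monthly_pca(tab[, setdiff(names(tab), c("seal_id", "mon"))]),
                    error = function(e) NULL)
    list(metrics = dm, budgets = budgets, monthly = tab, pca = pca)
  })

  results$water_mass <- stage("water_mass", function() {
    wm <- dive_water_masses(ds$dives, ds$ctd, ds$env, tau_h = config$tau_h,
                            rho_km = config$rho_km, zeta_m = config$zeta_m,
                            K = config$K)
    write.csv(wm, file.path(config$out_dir, "dive_water_masses.csv"),
              row.names = FALSE)
    list(assignments = wm, same_mass = same_mass_fraction(wm, by = "seal_id"))
  })

  manifest <- stage("manifest", function() {
    files <- list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    cfg <- config; cfg$out_dir <- NULL
    manifest$config_hash <- config_hash(cfg)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest
  })
  results$manifest <- manifest
  invisible(results)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}
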