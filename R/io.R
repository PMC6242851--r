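#' Read and write telemetry datasets
#'
#' A dataset on disk is a directory of plain-text files: one CSV per
#' observation stream (`metadata.csv`, `fixes.csv`, `dives.csv` +
#' `dive_profiles.csv`, `summaries.csv`, `haulouts.csv`, `ctd_casts.csv` +
#' `ctd_samples.csv`), GeoJSON polylines for the coastline and tidal glacier
#' fronts, ESRI ASCII grids for bathymetry and dated sea-ice fields, and a
#' small `projection.json` holding the planar projection centre. Missing
#' stream files yield empty streams; missing mandatory columns are a format
#' error naming the column. All timestamps are UTC.
#'
#' @param dir dataset directory.
#' @param validate run [validate_dataset()] after reading.
#' @return a list with elements `metadata`, `fixes`, `dives`, `summaries`,
#'   `haulouts`, `ctd`, `env` (an `environment_stack` or `NULL`).
#' @export
read_dataset <- function(dir, validate = TRUE) {
  rd <- function(file, cols, time_cols = character()) {
    path <- file.path(dir, file)
    if (!file.exists(path))
      return(empty_stream(cols, time_cols))
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop("format error in ", file, ": missing column(s) ",
           paste(missing, collapse = ", "))
    for (tc in time_cols) df[[tc]] <- as_utc(df[[tc]])
    df
  }
  meta <- rd("metadata.csv",
             c("id", "sex", "standard_length", "girth", "body_mass",
               "tag_start", "tag_end", "start_lat", "start_lon"),
             c("tag_start", "tag_end"))
  fixes <- rd("fixes.csv", c("seal_id", "time", "lat", "lon", "source"), "time")
  dives <- rd("dives.csv",
              c("dive_id", "seal_id", "start_time", "duration_min", "max_depth",
                "surface_after_s", "lat", "lon"), "start_time")
  prof <- rd("dive_profiles.csv", c("dive_id", "elapsed_fraction", "depth"))
  dives$profile <- if (nrow(dives)) {
    lapply(dives$dive_id, function(id) {
      p <- prof[prof$dive_id == id, c("elapsed_fraction", "depth")]
      rownames(p) <- NULL
      if (nrow(p)) p else NULL
    })
  } else list()
  summaries <- rd("summaries.csv",
                  c("seal_id", "period_start", "period_hours",
                    "pct_diving", "pct_surface", "pct_hauled"), "period_start")
  haulouts <- rd("haulouts.csv", c("seal_id", "start_time", "end_time"),
                 c("start_time", "end_time"))
  ctd <- rd("ctd_casts.csv", c("cast_id", "seal_id", "time", "lat", "lon"), "time")
  samp <- rd("ctd_samples.csv", c("cast_id", "depth", "temperature", "salinity"))
  ctd$samples <- if (nrow(ctd)) {
    lapply(ctd$cast_id, function(id) {
      s <- samp[samp$cast_id == id, c("depth", "temperature", "salinity")]
      rownames(s) <- NULL
      s
    })
  } else list()

  env <- NULL
  if (file.exists(file.path(dir, "bathymetry.asc"))) {
    center <- jsonlite::read_json(file.path(dir, "projection.json"))
    env <- list(bathymetry = read_ascii_grid(file.path(dir, "bathymetry.asc")),
                coastline = read_geojson_lines(file.path(dir, "coastline.geojson")),
                glacier_fronts = read_geojson_lines(file.path(dir, "glacier_fronts.geojson")),
                center = list(lat = center$lat, lon = center$lon))
    idx_path <- file.path(dir, "ice_fields.csv")
    if (file.exists(idx_path)) {
      idx <- read.csv(idx_path, stringsAsFactors = FALSE)
      env$ice <- list(
        dates = as_utc(idx$date),
        fields = lapply(idx$file, function(f) read_ascii_grid(file.path(dir, f))),
        landfast = lapply(idx$landfast_file, function(f) {
          g <- read_ascii_grid(file.path(dir, f)); g$values <- g$values > 0.5; g
        }))
    }
    class(env) <- "environment_stack"
  }

  ds <- list(metadata = meta,
             fixes = canonicalise_stream(fixes, "time", "fix"),
             dives = canonicalise_stream(dives, "start_time", "dive"),
             summaries = canonicalise_stream(summaries, "period_start", "summary"),
             haulouts = canonicalise_stream(haulouts, "start_time", "haul-out"),
             ctd = canonicalise_stream(ctd, "time", "CTD"),
             env = env)
  if (validate) validate_dataset(ds)
  ds
}

empty_stream <- function(cols, time_cols = character()) {
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  for (tc in time_cols) df[[tc]] <- as_utc(numeric(0))
  df
}

fmt_time <- function(x) format(as_utc(x), "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' @rdname read_dataset
#' @param dataset a dataset list (see [read_dataset()] for structure).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file, time_cols = character()) {
    df <- as.data.frame(df)
    df$profile <- NULL; df$samples <- NULL
    for (tc in intersect(time_cols, names(df))) df[[tc]] <- fmt_time(df[[tc]])
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  wr(dataset$metadata, "metadata.csv", c("tag_start", "tag_end"))
  wr(dataset$fixes, "fixes.csv", "time")
  wr(dataset$dives, "dives.csv", "start_time")
  if (nrow(dataset$dives)) {
    prof <- do.call(rbind, lapply(seq_len(nrow(dataset$dives)), function(i) {
      p <- dataset$dives$profile[[i]]
      if (is.null(p)) return(NULL)
      cbind(dive_id = dataset$dives$dive_id[i], p)
    }))
    if (is.null(prof))
      prof <- data.frame(dive_id = character(0), elapsed_fraction = numeric(0),
                         depth = numeric(0))
    write.csv(prof, file.path(dir, "dive_profiles.csv"), row.names = FALSE, quote = FALSE)
  }
  wr(dataset$summaries, "summaries.csv", "period_start")
  wr(dataset$haulouts, "haulouts.csv", c("start_time", "end_time"))
  wr(dataset$ctd, "ctd_casts.csv", "time")
  if (nrow(dataset$ctd)) {
    samp <- do.call(rbind, lapply(seq_len(nrow(dataset$ctd)), function(i)
      cbind(cast_id = dataset$ctd$cast_id[i], dataset$ctd$samples[[i]])))
    write.csv(samp, file.path(dir, "ctd_samples.csv"), row.names = FALSE, quote = FALSE)
  }
  env <- dataset$env
  if (!is.null(env)) {
    write_ascii_grid(env$bathymetry, file.path(dir, "bathymetry.asc"))
    write_geojson_lines(env$coastline, file.path(dir, "coastline.geojson"))
    write_geojson_lines(env$glacier_fronts, file.path(dir, "glacier_fronts.geojson"))
    jsonlite::write_json(env$center, file.path(dir, "projection.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(env$ice)) {
      files <- sprintf("ice_%03d.asc", seq_along(env$ice$dates))
      lf <- sprintf("landfast_%03d.asc", seq_along(env$ice$dates))
      for (i in seq_along(files)) {
        write_ascii_grid(env$ice$fields[[i]], file.path(dir, files[i]))
        g <- env$ice$landfast[[i]]; g$values <- g$values * 1
        write_ascii_grid(g, file.path(dir, lf[i]))
      }
      write.csv(data.frame(date = fmt_time(env$ice$dates), file = files,
                           landfast_file = lf),
                file.path(dir, "ice_fields.csv"), row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' ESRI ASCII grid I/O
#'
#' Minimal reader/writer for the `.asc` raster dialect (cell-centre
#' registration via `xllcenter`/`yllcenter`; `xllcorner` is shifted by half
#' a cell on read). Row 1 of the file is the northernmost row.
#'
#' @param path file path.
#' @return a [planar_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nx <- hdr$ncols; ny <- hdr$nrows; cell <- hdr$cellsize
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  m <- m[ny:1, , drop = FALSE]  # file stores north row first; we store south first
  xmin <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cell / 2
  ymin <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cell / 2
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  planar_grid(m, xmin, ymin, cell)
}

#' @rdname read_ascii_grid
#' @param grid a [planar_grid()].
#' @export
write_ascii_grid <- function(grid, path) {
  hdr <- c(sprintf("ncols %d", grid$nx), sprintf("nrows %d", grid$ny),
           sprintf("xllcenter %.10g", grid$xmin), sprintf("yllcenter %.10g", grid$ymin),
           sprintf("cellsize %.10g", grid$cell), "NODATA_value -9999")
  m <- grid$values[grid$ny:1, , drop = FALSE]
  m[is.na(m)] <- -9999
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' GeoJSON polyline I/O
#'
#' Reads LineString / MultiLineString features into a list of polylines
#' (data.frames with `x`, `y` in planar km). Coordinates are stored as-is:
#' for this package's datasets they are already planar km.
#'
#' @param path file path.
#' @return list of polylines.
#' @export
read_geojson_lines <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- list()
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    coords <- geom$coordinates
    ll <- if (identical(geom$type, "LineString")) list(coords) else coords
    for (cl in ll) {
      m <- do.call(rbind, lapply(cl, function(p) c(p[[1]], p[[2]])))
      out[[length(out) + 1]] <- data.frame(x = m[, 1], y = m[, 2])
    }
  }
  out
}

#' @rdname read_geojson_lines
#' @param lines list of polylines (`x`, `y` data.frames).
#' @export
write_geojson_lines <- function(lines, path) {
  feats <- lapply(lines, function(ln) {
    list(type = "Feature", properties = NULL,
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(ln)),
                                              function(i) c(ln$x[i], ln$y[i]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
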