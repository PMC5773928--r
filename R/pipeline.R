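#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks every invariant, and injects the
#' regulatory defaults (base 12.39 degC, 345.56 DDc/generation, 3
#' generations, 95% elimination quantile, 7-day run spacing). Each violated
#' invariant is reported with its config key.
#'
#' A minimal config needs a `sites:` list; each site carries `callsign`,
#' `latitude`, `longitude` and a `weather:` block with either `file:` (an
#' hourly CSV path) or `synthetic:` (fields of [synthetic_climate_params()]
#' plus `n_years`, `start_year`).
#'
#' @param path Path to a YAML file.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  fail <- function(key, msg) stop("config error at '", key, "': ", msg, call. = FALSE)

  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "medpql-out"
  cfg$log_level <- cfg$log_level %||% "info"

  dd <- cfg$degree_day %||% list()
  dd$base_c <- dd$base_c %||% 12.39
  dd$dd_per_generation <- dd$dd_per_generation %||% 345.56
  dd$n_generations <- dd$n_generations %||% 3L
  if (dd$dd_per_generation <= 0) fail("degree_day.dd_per_generation", "must be > 0")
  if (dd$n_generations < 1) fail("degree_day.n_generations", "must be >= 1")
  cfg$degree_day <- dd

  ps <- cfg$popsim %||% list()
  ps$n_sims <- ps$n_sims %||% 250L
  ps$every_days <- ps$every_days %||% 7L
  ps$quantile <- ps$quantile %||% 0.95
  ps$max_days <- ps$max_days %||% 730L
  if (ps$n_sims < 20) fail("popsim.n_sims", "must be >= 20")
  if (ps$quantile <= 0 || ps$quantile > 1) fail("popsim.quantile", "must be in (0, 1]")
  rng_over <- ps$ranges %||% list()
  ps$ranges <- tryCatch(do.call(bio_param_ranges, lapply(rng_over, as.numeric)),
                        error = function(e) fail("popsim.ranges", conditionMessage(e)))
  cfg$popsim <- ps

  if (is.null(cfg$sites) || !length(cfg$sites)) fail("sites", "at least one site required")
  for (i in seq_along(cfg$sites)) {
    s <- cfg$sites[[i]]
    key <- sprintf("sites[%d]", i)
    if (is.null(s$callsign)) fail(paste0(key, ".callsign"), "required")
    meta <- tryCatch(
      site_meta(s$callsign, s$name %||% s$callsign, s$latitude, s$longitude,
                s$elevation %||% NA_real_, s$start_year %||% NA_integer_),
      error = function(e) fail(key, conditionMessage(e))
    )
    w <- s$weather
    if (is.null(w) || (is.null(w$file) && is.null(w$synthetic))) {
      fail(paste0(key, ".weather"), "needs either 'file' or 'synthetic'")
    }
    if (!is.null(w$file) && !file.exists(w$file)) {
      fail(paste0(key, ".weather.file"), paste0("path not resolvable: ", w$file))
    }
    if (!is.null(w$synthetic)) {
      syn <- w$synthetic
      n_years <- syn$n_years %||% 5L
      start_year <- syn$start_year %||% 2000L
      syn$n_years <- syn$start_year <- NULL
      sp <- tryCatch(do.call(synthetic_climate_params,
                             c(syn, list(seed = cfg$seed + i))),
                     error = function(e) fail(paste0(key, ".weather.synthetic"),
                                              conditionMessage(e)))
      cfg$sites[[i]]$weather$synthetic_params <- sp
      cfg$sites[[i]]$weather$n_years <- n_years
      cfg$sites[[i]]$weather$start_year <- start_year
    }
    cfg$sites[[i]]$meta <- meta
  }

  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  semantic <- cfg[setdiff(names(cfg), c("log_level"))]
  canon <- jsonlite::toJSON(semantic, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canon, f)
  unname(tools::md5sum(f))
}

pipeline_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet")) message("[medpql] ", ...)
}

#' Run the full quarantine-length pipeline
#'
#' For every configured site: obtain hourly temperatures (read + clean a CSV,
#' or generate synthetic weather and clean it if defects were injected),
#' write the cleaned series, compute degree-day PQLs by both methods, run the
#' agent-based ensemble, aggregate day-of-year normals of each PQL series and
#' of daily mean temperature, and write a DD-vs-ABS comparison report. A
#' cross-site latitude regression is added when three or more sites are
#' configured. Every output is listed in `manifest.json` together with the
#' master seed and a hash of the semantic config.
#'
#' @param config A `pipeline_config` from [validate_config()], or a path to a
#'   YAML file.
#' @param make_plots Also write summary plot PNGs (advisory artifacts; the
#'   CSV/JSON outputs are canonical). Default TRUE.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, make_plots = TRUE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   files = character())
  add_file <- function(p) manifest$files <<- c(manifest$files, basename(p))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ddm <- config$degree_day
  model_ss <- degree_day_model(ddm$base_c, ddm$dd_per_generation,
                               ddm$n_generations, "single_sine")
  model_hs <- degree_day_model(ddm$base_c, ddm$dd_per_generation,
                               ddm$n_generations, "hourly_sum")
  ps <- config$popsim

  site_rows <- list()
  for (i in seq_along(config$sites)) {
    s <- config$sites[[i]]
    cs <- s$callsign
    pipeline_log(config, "site ", cs, ": weather")

    series <- stage(paste0(cs, "/weather"), {
      if (!is.null(s$weather$file)) {
        raw <- read_hourly_csv(s$weather$file)
        raw <- remove_outliers(raw)
        resample_and_fill(raw, site = s$meta)
      } else {
        syn <- generate_synthetic_weather(s$weather$synthetic_params,
                                          s$weather$n_years,
                                          s$weather$start_year, site = s$meta)
        if (nrow(syn$log[syn$log$type != "coldsnap", ]) > 0) {
          raw <- remove_outliers(syn$raw)
          resample_and_fill(raw, site = s$meta)
        } else {
          syn$clean
        }
      }
    })
    f_temps <- file.path(out_dir, paste0(cs, "_temps.csv"))
    write_hourly_csv(series, f_temps); add_file(f_temps)

    pipeline_log(config, "site ", cs, ": degree-day PQL")
    dd_ss <- stage(paste0(cs, "/dd_pql"), dd_pql_series(series, model_ss))
    dd_hs <- dd_pql_series(series, model_hs)
    f_dd <- file.path(out_dir, paste0(cs, "_dd_pql.csv"))
    write_pql_csv(dplyr::bind_rows(dd_ss, dd_hs), f_dd); add_file(f_dd)

    pipeline_log(config, "site ", cs, ": agent-based ensemble (",
                 ps$n_sims, " sims every ", ps$every_days, " d)")
    rs <- stage(paste0(cs, "/abs_pql"),
                run_runset(series, every_days = ps$every_days, n_sims = ps$n_sims,
                           ranges = ps$ranges, seed = config$seed + 1000L * i,
                           quantile = ps$quantile, max_days = ps$max_days))
    f_abs <- file.path(out_dir, paste0(cs, "_abs_pql.csv"))
    write_pql_csv(rs$runs, f_abs); add_file(f_abs)

    pipeline_log(config, "site ", cs, ": normals & comparison")
    dd_daily <- tibble::tibble(date = dd_ss$start_date,
                               value = as.numeric(dd_ss$pql_days))
    abs_daily <- tibble::tibble(date = rs$daily_pql$date,
                                value = rs$daily_pql$pql_days)
    dd_norm <- compute_normals(dd_daily)
    abs_norm <- compute_normals(abs_daily)
    tmean <- series |>
      dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
      dplyr::group_by(.data$date) |>
      dplyr::summarise(value = mean(.data$temp_c), n = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n == 24L) |>
      dplyr::select("date", "value")
    temp_norm <- compute_normals(tmean)
    for (nm in c("dd", "abs", "temp")) {
      f <- file.path(out_dir, paste0(cs, "_normals_", nm, ".csv"))
      write_normals_csv(switch(nm, dd = dd_norm, abs = abs_norm, temp = temp_norm), f)
      add_file(f)
    }

    # paired DD vs ABS comparison at uncensored run dates
    paired <- dplyr::inner_join(
      dplyr::filter(dd_daily, !is.na(.data$value)),
      dplyr::filter(abs_daily, !is.na(.data$value)),
      by = "date", suffix = c("_dd", "_abs")
    ) |> dplyr::semi_join(dplyr::filter(rs$runs, !.data$censored),
                          by = c(date = "start_date"))
    cmp <- NULL
    if (nrow(paired) >= 2L) {
      cmp <- tryCatch(
        paired_comparison(
          tibble::tibble(date = paired$date, value = paired$value_dd),
          tibble::tibble(date = paired$date, value = paired$value_abs),
          dd_norm, abs_norm),
        error = function(e) NULL)
    }
    report <- list(
      site = cs,
      n_dd_starts = nrow(dd_daily),
      n_abs_runs = nrow(rs$runs),
      dd_r2_pct = tryCatch(normal_r2(dd_daily, dd_norm), error = function(e) NA),
      abs_r2_pct = tryCatch(normal_r2(abs_daily, abs_norm), error = function(e) NA),
      paired = unclass(cmp)
    )
    f_cmp <- file.path(out_dir, paste0(cs, "_comparison.json"))
    jsonlite::write_json(report, f_cmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    add_file(f_cmp)

    if (make_plots) {
      f_plot <- file.path(out_dir, paste0(cs, "_normals.png"))
      p <- plot_pql_normals(dd_norm, abs_norm, title = cs)
      grDevices::png(f_plot, width = 900, height = 600)
      print(p)
      grDevices::dev.off()
      add_file(f_plot)
    }

    site_rows[[i]] <- tibble::tibble(
      callsign = cs, latitude = s$meta$latitude,
      dd_median = median(dd_daily$value, na.rm = TRUE),
      abs_median = median(abs_daily$value, na.rm = TRUE)
    )
  }

  site_tbl <- dplyr::bind_rows(site_rows)
  if (nrow(site_tbl) >= 3L && length(unique(site_tbl$latitude)) > 1L) {
    fit_dd <- latitude_ols(dplyr::transmute(site_tbl, latitude = .data$latitude,
                                            median_pql = .data$dd_median))
    fit_abs <- latitude_ols(dplyr::transmute(site_tbl, latitude = .data$latitude,
                                             median_pql = .data$abs_median))
    f_lat <- file.path(out_dir, "latitude_fit.json")
    jsonlite::write_json(list(dd = unclass(fit_dd), abs = unclass(fit_abs)),
                         f_lat, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_file(f_lat)
  }
  f_sites <- file.path(out_dir, "site_medians.csv")
  readr::write_csv(site_tbl, f_sites, progress = FALSE); add_file(f_sites)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeline_log(config, "done: ", length(manifest$files), " artifacts in ", out_dir)
  invisible(out_dir)
}

#' Plot mean and spread of PQL normals for one site
#'
#' @param dd_normals,abs_normals [compute_normals()] tables of the two PQL
#'   methods.
#' @param title Plot title.
#' @return A ggplot object: mean normal PQL by day of year with an
#'   inter-quartile ribbon, one panel per method.
#' @export
plot_pql_normals <- function(dd_normals, abs_normals, title = NULL) {
  both <- dplyr::bind_rows(
    dplyr::mutate(dd_normals, method = "degree-day"),
    dplyr::mutate(abs_normals, method = "agent-based")
  ) |>
    dplyr::mutate(doy = as.integer(format(
      as.Date(sprintf("2001-%02d-%02d", .data$month, pmin(.data$day, 28L))), "%j")))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$doy, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "start day of year", y = "predicted quarantine length (days)",
                  title = title) +
    ggplot2::theme_minimal()
}
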