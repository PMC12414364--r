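# Configuration parsing and validation, trajectory CSV output, comparison
# report rendering, and the helpers behind the command-line wrapper.

#' Load a run configuration from YAML
#'
#' A configuration file describes 1 to 4 scenarios under a top-level
#' `scenarios:` key. Each scenario entry carries the animal/environment
#' fields (`initial_bw`, `temperature`, `weaning_age`, `horizon`), a
#' `liquid:` mapping (`kind`, `dm_fraction`, `me_density`,
#' `cost_per_litre`, and `mixing_rate_g_l` or `solids_per_litre` for milk
#' replacer), a `starter:` mapping (`cp`, `ndf`, `fat`, `ash`, `dm`,
#' `form`, `cost_per_kg`), and an `allowance` that is either a single L/d
#' value or a list of `{day, litres}` steps. Optional keys `k_g`,
#' `fp_unit`, `first_starter_offer_day` and `label` override the defaults.
#'
#' Validation is collective: every violated bound in the file is reported
#' in one error, each message naming the offending scenario and field with
#' its acceptable range.
#'
#' @param path Path to the YAML configuration.
#' @return A list of class `calf_run_config` with element `scenarios`, a
#'   list of [calf_scenario()] objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scenarios) || length(raw$scenarios) == 0) {
    stop("config must contain a non-empty `scenarios:` list.", call. = FALSE)
  }
  if (length(raw$scenarios) > 4) {
    stop("at most 4 scenarios can be simulated (maximum of 4); found ",
         length(raw$scenarios), ".", call. = FALSE)
  }
  problems <- character()
  scenarios <- vector("list", length(raw$scenarios))
  for (i in seq_along(raw$scenarios)) {
    entry <- raw$scenarios[[i]]
    label <- entry$label %||% paste0("scenario_", i)
    built <- tryCatch(scenario_from_config_entry(entry, label),
                      error = function(e) conditionMessage(e))
    if (is.character(built)) {
      problems <- c(problems, paste0("[", label, "] ", built))
    } else {
      scenarios[[i]] <- built
    }
  }
  if (length(problems) > 0) {
    stop("invalid configuration:\n", paste(problems, collapse = "\n"),
         call. = FALSE)
  }
  structure(list(scenarios = scenarios), class = "calf_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_from_config_entry <- function(entry, label) {
  lq <- entry$liquid %||% list()
  st <- entry$starter %||% list()
  kind <- lq$kind %||% "whole_milk"
  liquid_args <- list(
    kind = kind,
    me_density = lq$me_density %||% 4.6,
    cost_per_litre = lq$cost_per_litre %||% 0.5
  )
  if (!is.null(lq$dm_fraction)) liquid_args$dm_fraction <- lq$dm_fraction
  if (!is.null(lq$mixing_rate_g_l)) liquid_args$mixing_rate_g_l <- lq$mixing_rate_g_l
  if (!is.null(lq$solids_per_litre)) liquid_args$solids_per_litre <- lq$solids_per_litre
  liquid <- do.call(liquid_diet, liquid_args)
  starter <- starter_composition(
    cp_fraction = st$cp %||% 0.22, ndf_fraction = st$ndf %||% 0.15,
    fat_fraction = st$fat %||% 0.04, ash_fraction = st$ash %||% 0.07,
    dm_fraction = st$dm %||% 0.90, form = st$form %||% "texturized",
    cost_per_kg = st$cost_per_kg %||% 0.5
  )
  allowance <- entry$allowance %||% 6
  if (is.list(allowance)) {
    allowance <- data.frame(
      day = vapply(allowance, function(s) as.numeric(s$day), numeric(1)),
      litres = vapply(allowance, function(s) as.numeric(s$litres), numeric(1))
    )
  }
  calf_scenario(
    initial_bw = entry$initial_bw %||% stop("missing `initial_bw`"),
    temperature = entry$temperature %||% stop("missing `temperature`"),
    weaning_age = entry$weaning_age %||% stop("missing `weaning_age`"),
    liquid = liquid, starter = starter, allowance = allowance,
    horizon = entry$horizon %||% 100,
    k_g = entry$k_g %||% 0.60,
    fp_unit = entry$fp_unit %||% "weeks",
    first_starter_offer_day = entry$first_starter_offer_day %||% 3,
    label = label
  )
}

#' Write a run configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces an equivalent configuration.
#'
#' @param config A `calf_run_config` from [load_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "calf_run_config"))
  entries <- lapply(config$scenarios, function(s) {
    list(
      label = s$label,
      initial_bw = s$initial_bw, temperature = s$temperature,
      weaning_age = s$weaning_age, horizon = s$horizon,
      k_g = s$k_g, fp_unit = s$fp_unit,
      first_starter_offer_day = s$first_starter_offer_day,
      liquid = list(kind = s$liquid$kind,
                    dm_fraction = s$liquid$dm_fraction,
                    me_density = s$liquid$me_density,
                    cost_per_litre = s$liquid$cost_per_litre,
                    solids_per_litre = s$liquid$solids_per_litre),
      starter = list(cp = s$starter$cp_fraction, ndf = s$starter$ndf_fraction,
                     fat = s$starter$fat_fraction, ash = s$starter$ash_fraction,
                     dm = s$starter$dm_fraction, form = s$starter$form,
                     cost_per_kg = s$starter$cost_per_kg),
      allowance = as.list(s$plan$offered_l)
    )
  })
  yaml::write_yaml(list(scenarios = entries), path)
  invisible(path)
}

#' Effective settings of a scenario
#'
#' Returns the configuration parameters the model equations do not pin
#' down -- the gain efficiency `k_g`, the starter-exposure clock unit, and
#' the first starter offer day -- so runs can log every default in force.
#'
#' @param scenario A [calf_scenario()].
#' @return A named list.
#' @export
scenario_settings <- function(scenario) {
  stopifnot(inherits(scenario, "calf_scenario"))
  list(k_g = scenario$k_g, fp_unit = scenario$fp_unit,
       first_starter_offer_day = scenario$first_starter_offer_day,
       liquid_cap_l = LIQUID_CAP_L)
}

#' Write trajectories and KPI tables as delimited text
#'
#' Trajectories are written as RFC-4180 CSV, one row per day (and per
#' scenario for comparisons), with the daily-record fields as columns.
#' KPI tables are written as CSV or JSON depending on the file extension.
#'
#' @param x A trajectory, comparison, or KPI tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  if (inherits(x, "calf_comparison")) x <- x$trajectories
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_kpis <- function(x, path) {
  if (inherits(x, "calf_comparison")) x <- x$kpis
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}

#' Render a side-by-side comparison report
#'
#' Produces a single markdown document with the four dashboard KPI metrics
#' per scenario (final BW, ADG, feeding cost, cost per kg of gain), the
#' weaning-window/full-horizon KPI table, and day-by-day time series of BW,
#' starter intake and ME intake in compact tabular form. The body contains
#' no timestamps, so re-rendering identical inputs is byte-identical.
#'
#' @param comparison A [compare_scenarios()] result.
#' @param path Output path for the markdown report.
#' @param series_days Days at which the time-series tables are sampled
#'   (default every 7 days plus the final day).
#' @return `path`, invisibly.
#' @export
render_report <- function(comparison, path, series_days = NULL) {
  stopifnot(inherits(comparison, "calf_comparison"))
  k <- comparison$kpis
  tr <- comparison$trajectories
  if (is.null(series_days)) {
    series_days <- sort(unique(c(seq(7, max(tr$day), by = 7), max(tr$day))))
  }
  fmt <- function(x, d = 2) ifelse(is.na(x), "-", formatC(x, format = "f", digits = d))
  lines <- c(
    "# Feeding-plan comparison report", "",
    "## KPIs until weaning", "",
    "| Scenario | Final BW (kg) | ADG (kg/d) | Age at 15 kg NFC (d) | Feeding cost | Cost per kg gain |",
    "|---|---|---|---|---|---|"
  )
  kw <- k[k$window == "until_weaning", ]
  for (i in seq_len(nrow(kw))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s |",
      kw$label[i], fmt(kw$final_bw[i]), fmt(kw$adg[i], 3),
      fmt(kw$age_at_15kg_nfc[i], 0), fmt(kw$total_cost[i]),
      fmt(kw$cost_per_kg_gain[i])
    ))
  }
  lines <- c(lines, "", "## KPIs over the full horizon", "",
             "| Scenario | Final BW (kg) | ADG (kg/d) | Age at 15 kg NFC (d) | Feeding cost | Cost per kg gain |",
             "|---|---|---|---|---|---|")
  kh <- k[k$window == "full_horizon", ]
  for (i in seq_len(nrow(kh))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s |",
      kh$label[i], fmt(kh$final_bw[i]), fmt(kh$adg[i], 3),
      fmt(kh$age_at_15kg_nfc[i], 0), fmt(kh$total_cost[i]),
      fmt(kh$cost_per_kg_gain[i])
    ))
  }
  series <- function(var, title, digits = 2) {
    out <- c("", paste0("## ", title), "",
             paste0("| Day | ", paste(comparison$labels, collapse = " | "), " |"),
             paste0("|---|", paste(rep("---", length(comparison$labels)),
                                   collapse = "|"), "|"))
    for (d in series_days) {
      vals <- vapply(comparison$labels, function(lab) {
        v <- tr[[var]][tr$label == lab & tr$day == d]
        if (length(v) == 0) "-" else fmt(v, digits)
      }, character(1))
      out <- c(out, paste0("| ", d, " | ", paste(vals, collapse = " | "), " |"))
    }
    out
  }
  lines <- c(lines,
             series("bw_end", "Body weight (kg) over time"),
             series("starter_dm", "Starter intake (kg DM/d) over time", 3),
             series("me_total", "ME intake (Mcal/d) over time"))
  writeLines(lines, path)
  invisible(path)
}

#' Plot a comparison time series
#'
#' Returns a ggplot of one daily-record variable over time, one line per
#' scenario. Requires the ggplot2 package.
#'
#' @param comparison A [compare_scenarios()] result.
#' @param var Daily-record column to plot (default `"bw_end"`).
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison, var = "bw_end") {
  stopifnot(inherits(comparison, "calf_comparison"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_comparison() requires the ggplot2 package.", call. = FALSE)
  }
  tr <- comparison$trajectories
  tr$.value <- tr[[var]]
  ggplot2::ggplot(tr, ggplot2::aes(x = day, y = .value, colour = label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day of life", y = var, colour = "scenario") +
    ggplot2::theme_minimal()
}
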