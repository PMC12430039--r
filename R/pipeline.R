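#' Pipeline run configuration
#'
#' A reproducible description of a simulate / fit / contrast / report run.
#' The seed threads through every stage and is recorded in each output
#' artifact; the configuration round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param mode One of `"simulate"`, `"fit"`, `"contrast"`, `"report"`,
#'   `"full"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_subjects,n_days Generator size (simulate/full modes).
#' @param subsamples Subsample labels to process.
#' @param chains,warmup,iter MCMC geometry.
#' @param n_rep Monte-Carlo replicates per contrast policy evaluation.
#' @param n_contrast_draws Posterior draws used in the contrast stage
#'   (evenly thinned from the posterior).
#' @param panel_path Optional existing panel CSV (fit/contrast modes
#'   default to `<out_dir>/panel.csv`).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = "full", out_dir = tempfile("sleepdmpm-run-"),
                       seed = 1, n_subjects = 48, n_days = 4,
                       subsamples = subsample_levels(),
                       chains = 2, warmup = 250, iter = 250,
                       n_rep = 20, n_contrast_draws = 25,
                       panel_path = NULL) {
  mode <- match.arg(mode, c("simulate", "fit", "contrast", "report", "full"))
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days), subsamples = subsamples,
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), n_rep = as.integer(n_rep),
                 n_contrast_draws = as.integer(n_contrast_draws),
                 panel_path = panel_path),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

fit_from_draws <- function(draws, channels = channel_spec(),
                           spec = sleep_covariates()) {
  structure(list(draws = draws, channels = channels, spec = spec,
                 param_index = param_index(channels, spec)),
            class = "dmpm_fit")
}

sub_slug <- function(x) gsub("-", "_", x)

#' Run the analysis pipeline
#'
#' Executes the requested stages per subsample and writes all artifacts
#' under `config$out_dir`:
#'
#' * `panel.csv`, `true_params.yaml` — synthetic panel plus ground truth;
#' * `draws_<subsample>.csv`, `diagnostics_<subsample>.json` — posterior;
#' * `contrast_<subsample>.csv`, `contrast.json` — tidy category/item
#'   effects (outcome, category, item, posterior mean, 90% interval);
#' * `report.csv` — the rendered summary table;
#' * `manifest.json` — seed, configuration, per-file MD5 hashes, and any
#'   stage error.
#'
#' Reruns with an identical configuration reproduce every CSV byte for
#' byte.
#'
#' @param config A [run_config()].
#' @return The manifest (invisibly a list), written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sleepdmpm",
                   version = as.character(utils::packageVersion("sleepdmpm")),
                   seed = config$seed, config = unclass(config),
                   stages = list(), files = list())
  spec <- sleep_covariates()
  channels <- channel_spec()
  out <- function(...) file.path(config$out_dir, paste0(...))
  finish <- function() {
    files <- unlist(manifest$files, use.names = FALSE)
    if (length(files) > 0) {
      manifest$hashes <<- as.list(tools::md5sum(files))
    }
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- paste("error:", conditionMessage(err))
    finish()
    abort_sleepdmpm(sprintf("Stage `%s` failed: %s", stage,
                            conditionMessage(err)),
                    "sleepdmpm_pipeline_error")
  }
  modes <- if (config$mode == "full") c("simulate", "fit", "contrast", "report")
           else config$mode

  if ("simulate" %in% modes) {
    tryCatch({
      sim <- generate_panel(generator_config(
        n_subjects = config$n_subjects, n_days = config$n_days,
        seed = config$seed, subsamples = config$subsamples))
      write_sleep_panel(sim$panel, out("panel.csv"), spec)
      yaml::write_yaml(
        list(seed = config$seed,
             params = as.list(params_to_draw(sim$params)),
             feedback = as.list(as.data.frame(sim$params$feedback))),
        out("true_params.yaml"))
      manifest$files$panel <- out("panel.csv")
      manifest$files$true_params <- out("true_params.yaml")
      manifest$stages$simulate <- "ok"
    }, error = function(e) fail("simulate", e))
  }

  panel_path <- config$panel_path %||% out("panel.csv")
  need_panel <- any(c("fit", "contrast") %in% modes)
  if (need_panel && !file.exists(panel_path)) {
    fail(modes[1], simpleError(paste0("missing input panel: ", panel_path)))
  }
  panel <- if (need_panel) {
    tryCatch(read_sleep_panel(panel_path, spec),
             error = function(e) fail("load_panel", e))
  }

  if ("fit" %in% modes) {
    tryCatch({
      for (ss in config$subsamples) {
        sub <- panel[panel$subsample == ss, ]
        fit <- fit_dmpm(sub, spec, channels, chains = config$chains,
                        warmup = config$warmup, iter = config$iter,
                        seed = config$seed + match(ss, subsample_levels()))
        readr::write_csv(fit$draws, out("draws_", sub_slug(ss), ".csv"),
                         progress = FALSE)
        jsonlite::write_json(
          list(seed = fit$mcmc$seed, subsample = ss,
               glance = as.list(glance(fit)),
               parameters = fit$diagnostics),
          out("diagnostics_", sub_slug(ss), ".json"),
          auto_unbox = TRUE, digits = NA)
        manifest$files[[paste0("draws_", sub_slug(ss))]] <-
          out("draws_", sub_slug(ss), ".csv")
        manifest$files[[paste0("diagnostics_", sub_slug(ss))]] <-
          out("diagnostics_", sub_slug(ss), ".json")
      }
      manifest$stages$fit <- "ok"
    }, error = function(e) fail("fit", e))
  }

  if ("contrast" %in% modes) {
    tryCatch({
      summaries <- list()
      for (ss in config$subsamples) {
        dpath <- out("draws_", sub_slug(ss), ".csv")
        if (!file.exists(dpath)) {
          stop("missing input draws: ", dpath, call. = FALSE)
        }
        draws <- readr::read_csv(dpath, show_col_types = FALSE,
                                 progress = FALSE)
        fit <- fit_from_draws(draws, channels, spec)
        ids <- unique(round(seq(1, nrow(draws),
                                length.out = min(config$n_contrast_draws,
                                                 nrow(draws)))))
        sub <- panel[panel$subsample == ss, ]
        res <- sleep_contrast(fit, sub, n_rep = config$n_rep,
                              seed = config$seed +
                                10L * match(ss, subsample_levels()),
                              draw_ids = ids, spec = spec,
                              channels = channels)
        item_summary <- res$items |>
          dplyr::group_by(.data$item, .data$outcome) |>
          dplyr::summarise(
            posterior_mean = mean(.data$delta),
            ci_low = stats::quantile(.data$delta, ci_probs[1], names = FALSE),
            ci_high = stats::quantile(.data$delta, ci_probs[2], names = FALSE),
            .groups = "drop") |>
          dplyr::mutate(
            category = as.character(stats::setNames(
              as.character(spec$category), spec$name)[.data$item]))
        cat_summary <- res$summary |>
          dplyr::transmute(outcome = .data$outcome,
                           category = as.character(.data$category),
                           item = NA_character_,
                           posterior_mean = .data$mean,
                           ci_low = .data$ci_low, ci_high = .data$ci_high)
        tidy_csv <- dplyr::bind_rows(
          cat_summary,
          item_summary[c("outcome", "category", "item", "posterior_mean",
                         "ci_low", "ci_high")]) |>
          dplyr::arrange(.data$outcome, .data$category, .data$item)
        readr::write_csv(tidy_csv, out("contrast_", sub_slug(ss), ".csv"),
                         progress = FALSE)
        manifest$files[[paste0("contrast_", sub_slug(ss))]] <-
          out("contrast_", sub_slug(ss), ".csv")
        summaries[[ss]] <- res$summary
      }
      jsonlite::write_json(
        list(seed = config$seed, summaries = summaries),
        out("contrast.json"), auto_unbox = TRUE, digits = NA)
      manifest$files$contrast_json <- out("contrast.json")
      manifest$stages$contrast <- "ok"
    }, error = function(e) fail("contrast", e))
  }

  if ("report" %in% modes) {
    tryCatch({
      results <- list()
      for (ss in config$subsamples) {
        cpath <- out("contrast_", sub_slug(ss), ".csv")
        if (!file.exists(cpath)) {
          stop("missing input contrast: ", cpath, call. = FALSE)
        }
        tab <- readr::read_csv(cpath, show_col_types = FALSE,
                               progress = FALSE)
        summary <- tab[is.na(tab$item), ] |>
          dplyr::transmute(category = .data$category,
                           outcome = .data$outcome,
                           mean = .data$posterior_mean,
                           ci_low = .data$ci_low, ci_high = .data$ci_high)
        results[[ss]] <- structure(list(summary = summary),
                                   class = "dmpm_contrast")
      }
      readr::write_csv(render_summary(results), out("report.csv"),
                       progress = FALSE)
      manifest$files$report <- out("report.csv")
      manifest$stages$report <- "ok"
    }, error = function(e) fail("report", e))
  }

  finish()
  invisible(manifest)
}
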