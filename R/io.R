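# CSV reading with validation, summary writers, and the
# simulate -> fit -> describe pipeline.

#' Read and validate a clustered survival dataset
#'
#' Reads a CSV with header and checks the survival-data invariants:
#' `time`, `event` and `cluster` columns present, times positive finite
#' numbers, events in \{0, 1\}. Violations are reported with row numbers.
#' If a covariate schema is supplied, covariate columns must exist and
#' contain only schema categories (offenders listed); covariates are
#' returned as factors in schema order.
#'
#' @param path CSV file path.
#' @param schema optional covariate schema as [default_marriage_schema()].
#' @param time_field,event_field,cluster_field column names.
#' @return The validated data.frame, with per-column category tallies in
#'   the `"tallies"` attribute.
#' @export
read_marriage_data <- function(path, schema = NULL, time_field = "time",
                               event_field = "event",
                               cluster_field = "cluster") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty dataset: ", path)
  need <- c(time_field, event_field, cluster_field)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  tm <- suppressWarnings(as.numeric(df[[time_field]]))
  bad <- which(!is.finite(tm) | tm <= 0)
  if (length(bad))
    stop("invalid times (must be positive numbers) at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  df[[time_field]] <- tm
  ev <- df[[event_field]]
  bad <- which(!ev %in% c(0, 1))
  if (length(bad))
    stop("invalid event indicators (must be 0/1) at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!is.null(schema)) {
    for (nm in names(schema)) {
      if (!nm %in% names(df)) stop("missing covariate column: ", nm)
      offenders <- setdiff(unique(df[[nm]]), schema[[nm]]$categories)
      if (length(offenders))
        stop("covariate '", nm, "' has categories outside the schema: ",
             paste(offenders, collapse = ", "))
      df[[nm]] <- factor(df[[nm]], levels = schema[[nm]]$categories)
    }
  }
  covcols <- setdiff(names(df), c("id", need))
  attr(df, "tallies") <- lapply(df[covcols], function(x) table(as.character(x)))
  df
}

#' Write a dataset or a regression summary to disk
#'
#' `write_dataset` writes the CSV the reader round-trips;
#' `write_summary` writes the regression table as full-precision CSV
#' and, optionally, as an aligned text table with the `<= 0.001`
#' p-value display floor and the random-effects footer (gamma, theta,
#' tau, boundary LR p) when the fit includes frailty.
#'
#' @param data data.frame to write.
#' @param path output CSV path.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param tab a [summary_table()] result.
#' @param txt_path optional path for the aligned text rendering.
#' @export
write_summary <- function(tab, path, txt_path = NULL) {
  stopifnot(inherits(tab, "frailty_summary"))
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    df <- as.data.frame(tab)
    df$p <- ifelse(is.na(df$p), "NA",
                   ifelse(df$p <= 0.001, "<=0.001", format(round(df$p, 3))))
    for (col in c("coef", "se", "phi")) df[[col]] <- signif(df[[col]], 7)
    writeLines(capture.output(print(df, row.names = FALSE)), con)
    re <- attr(tab, "random_effects")
    if (!is.null(re$theta))
      writeLines(sprintf(
        "Random effects: gamma = %.4f, theta = %.4f, tau = %.1f%%, LR test p = %.4g",
        re$gamma, re$theta, 100 * re$tau, re$lr_p), con)
  }
  invisible(path)
}

#' Read a regression summary back from CSV
#'
#' @param path CSV written by [write_summary()].
#' @return data.frame with `term`, `coef`, `se`, `p`, `phi`.
#' @export
read_summary <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Run the simulate - fit - describe pipeline
#'
#' Either simulates a dataset from `sim_config` or reads one from
#' `data_path`, fits the model, and writes all artifacts under
#' `out_dir`: `dataset.csv`, `truth.json` (simulated runs),
#' `fit_summary.csv` / `fit_summary.txt`, `fit_meta.json` (log-lik,
#' theta, tau, convergence, seed, package version) and
#' `descriptives.csv` (overall row plus one block per covariate). A
#' plain-text log records event fraction, cluster sizes and the
#' optimizer iteration count.
#'
#' @param out_dir output directory (created if needed).
#' @param sim_config a [synthetic_config()] to simulate from, or `NULL`
#'   to read `data_path`.
#' @param data_path CSV read when `sim_config` is `NULL`.
#' @param spec a [model_spec()]; default derives covariates from the
#'   simulation schema.
#' @param seed integer seed used for simulation.
#' @return Invisible named list of artifact paths plus the fit.
#' @export
run_pipeline <- function(out_dir, sim_config = synthetic_config(),
                         data_path = NULL, spec = NULL, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (!is.null(sim_config)) {
    pop <- generate_population(sim_config, seed = seed)
    data <- pop$data
    paths$dataset <- write_dataset(data, file.path(out_dir, "dataset.csv"))
    truth <- pop$truth
    truth$beta <- lapply(truth$beta, as.list)
    truth$frailties <- as.list(truth$frailties)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$truth <- file.path(out_dir, "truth.json")
    schema <- sim_config$covariate_schema
  } else {
    if (is.null(data_path)) stop("need 'sim_config' or 'data_path'")
    schema <- NULL
    data <- read_marriage_data(data_path, schema = schema)
    paths$dataset <- data_path
  }
  if (is.null(spec)) {
    if (is.null(schema)) stop("supply 'spec' when fitting external data")
    spec <- model_spec_from_schema(schema)
  }

  fit <- fit_model(data, spec)
  tab <- summary_table(fit)
  paths$summary_csv <- write_summary(
    tab, file.path(out_dir, "fit_summary.csv"),
    txt_path = file.path(out_dir, "fit_summary.txt"))
  paths$summary_txt <- file.path(out_dir, "fit_summary.txt")

  meta <- list(loglik = fit$loglik, loglik_nofrailty = fit$loglik_nofrailty,
               gamma = fit$gamma_reported, converged = fit$converged,
               n = fit$n, n_events = fit$n_events, G = fit$G, seed = seed,
               mode = fit$mode, frailty = spec$frailty,
               package_version = as.character(packageVersion("frailtyLL")))
  if (spec$frailty) {
    meta$theta <- fit$theta
    meta$tau <- fit$tau
    meta$lr_theta_p <- fit$lr_theta$p.value
  }
  jsonlite::write_json(meta, file.path(out_dir, "fit_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$meta <- file.path(out_dir, "fit_meta.json")

  desc <- rbind(
    cbind(covariate = "(overall)", group = "(all)",
          overall_summary(data)[c("n_total", "n_married", "pct_married",
                                  "mean_age", "median_age")],
          stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(spec$covariates), function(nm) {
      d <- describe_by_group(data, nm)
      data.frame(covariate = d$covariate, group = d$group,
                 n_total = d$n_total, n_married = d$n_married,
                 pct_married = d$pct_married_of_total,
                 mean_age = d$mean_age, median_age = d$median_age,
                 stringsAsFactors = FALSE)
    })))
  write.csv(desc, file.path(out_dir, "descriptives.csv"), row.names = FALSE)
  paths$descriptives <- file.path(out_dir, "descriptives.csv")

  log_lines <- c(
    sprintf("seed: %d", seed),
    sprintf("n: %d, events: %d (%.2f%%)", fit$n, fit$n_events,
            100 * fit$n_events / fit$n),
    sprintf("clusters: %d (sizes %s)", fit$G,
            paste(table(data[[spec$cluster_field]]), collapse = ", ")),
    sprintf("optimizer: %d function evaluations, converged = %s",
            fit$n_iter, fit$converged),
    sprintf("loglik = %.6f (no frailty %.6f)", fit$loglik,
            fit$loglik_nofrailty))
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  paths$log <- file.path(out_dir, "pipeline_log.txt")

  invisible(c(paths, list(fit = fit)))
}
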