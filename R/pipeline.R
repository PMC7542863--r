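#' Per-variable summary statistics
#'
#' Mean, median and sample standard deviation (n - 1 denominator) for every
#' numeric column.
#'
#' @param data data.frame of numeric columns.
#' @return data.frame with columns `variable`, `n`, `mean`, `median`, `sd`.
#' @export
summarize_variables <- function(data) {
  if (ncol(data) == 0) stop("no columns to summarize")
  rows <- lapply(names(data), function(nm) {
    v <- data[[nm]]
    if (!is.numeric(v)) stop("column '", nm, "' is not numeric")
    if (length(v) == 0 || all(is.na(v))) stop("column '", nm, "' is empty")
    data.frame(variable = nm, n = sum(!is.na(v)), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a pipeline configuration
#'
#' @param geometry_path GeoJSON polygon file.
#' @param attribute_path CSV attribute table.
#' @param id_field unit-id column/property name.
#' @param outcome outcome variable name.
#' @param covariates character vector of covariate names.
#' @param weight_style `"row_standardized"` or `"binary"` (statistics only;
#'   models always use row-standardized weights).
#' @param snap queen-contiguity snap distance.
#' @param n_perm permutations for Moran/LISA inference.
#' @param alpha significance level for LISA labels.
#' @param seed integer seed for all randomized stages.
#' @param models subset of `c("ols", "sem", "slm")`.
#' @param output_dir directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry_path, attribute_path,
                            id_field = "unit_id", outcome, covariates,
                            weight_style = "row_standardized", snap = 1e-7,
                            n_perm = 999, alpha = 0.05, seed = 1L,
                            models = c("ols", "sem", "slm"),
                            output_dir = "spareal_output") {
  if (outcome %in% covariates) stop("outcome cannot also be a covariate")
  bad <- setdiff(models, c("ols", "sem", "slm"))
  if (length(bad) > 0) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (!weight_style %in% c("row_standardized", "binary")) {
    stop("weight_style must be 'row_standardized' or 'binary'")
  }
  structure(list(geometry_path = geometry_path,
                 attribute_path = attribute_path, id_field = id_field,
                 outcome = outcome, covariates = covariates,
                 weight_style = weight_style, snap = snap, n_perm = n_perm,
                 alpha = alpha, seed = as.integer(seed), models = models,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One `key = value` (or `key: value`) pair per line; `covariates` and
#' `models` are comma-separated lists. Lines starting with `#` are ignored.
#' `overrides` (a named list, e.g. from command-line flags) take precedence
#' over the file.
#'
#' @param path config file path.
#' @param overrides named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*[=:]\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: '", ln, "'")
    kv[[m[2]]] <- trimws(m[3])
  }
  for (nm in names(overrides)) kv[[nm]] <- overrides[[nm]]
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  lst <- function(x) if (is.null(x)) NULL else trimws(strsplit(x, ",")[[1]])
  args <- list(geometry_path = kv$geometry_path,
               attribute_path = kv$attribute_path,
               outcome = kv$outcome, covariates = lst(kv$covariates))
  if (!is.null(kv$id_field)) args$id_field <- kv$id_field
  if (!is.null(kv$weight_style)) args$weight_style <- kv$weight_style
  if (!is.null(kv$snap)) args$snap <- num(kv$snap)
  if (!is.null(kv$n_perm)) args$n_perm <- as.integer(kv$n_perm)
  if (!is.null(kv$alpha)) args$alpha <- num(kv$alpha)
  if (!is.null(kv$seed)) args$seed <- as.integer(kv$seed)
  if (!is.null(kv$models)) args$models <- lst(kv$models)
  if (!is.null(kv$output_dir)) args$output_dir <- kv$output_dir
  do.call(pipeline_config, args)
}

.write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full spatial-analysis pipeline
#'
#' Orchestrates the complete workflow: read and join inputs, build queen
#' weights, summary statistics, per-variable global Moran tests, LISA cluster
#' map for the outcome, OLS with VIF and residual Moran, LM spatial
#' diagnostics, maximum-likelihood SEM and SLM with model comparison, and
#' residual maps. Everything is written under `config$output_dir`
#' (summary.csv, moran_global.csv, lisa.csv, lisa_clusters.geojson, the model
#' JSONs, residual GeoJSONs) plus a single machine-readable `report.json`
#' that embeds all numbers, the seed and a software stamp. Outputs are pure
#' functions of (inputs, config): identical reruns are byte-identical. On any
#' stage failure the partially written output directory is removed.
#'
#' @param config a [pipeline_config].
#' @param quiet suppress progress messages.
#' @return The report, invisibly (a nested list mirroring report.json).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[spareal] ", ...)
  out_dir <- config$output_dir
  fresh <- !dir.exists(out_dir)
  ok <- FALSE
  if (fresh) dir.create(out_dir, recursive = TRUE)
  on.exit(if (!ok && fresh) unlink(out_dir, recursive = TRUE), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("reading inputs")
  areas <- stage("read", read_areas(config$geometry_path,
                                    config$attribute_path, config$id_field))
  vars <- c(config$outcome, config$covariates)
  missing_vars <- setdiff(vars, names(areas$attributes))
  if (length(missing_vars) > 0) {
    stop("pipeline stage 'config' failed: variable(s) not in attribute table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }

  say("building queen weights (snap = ", format(config$snap), ")")
  Wb <- stage("weights", queen_weights(areas, snap = config$snap))
  W <- if (config$weight_style == "binary") Wb else row_standardize(Wb)
  W <- cache_spectrum(W)
  if (length(W$islands) > 0) {
    say("WARNING: ", length(W$islands), " island unit(s): ",
        paste(W$ids[W$islands], collapse = ", "))
  }
  write_gal(W, file.path(out_dir, "weights.gal"))

  say("summary statistics")
  summ <- stage("summary", summarize_variables(areas$attributes[, vars, drop = FALSE]))
  utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)

  say("global Moran per variable (", config$n_perm, " permutations)")
  glob <- stage("moran", do.call(rbind, lapply(vars, function(v) {
    mt <- moran_mc(areas$attributes[[v]], W, n_perm = config$n_perm,
                   seed = config$seed)
    data.frame(variable = v, I = mt$I, expected_I = mt$expected_I,
               z_score = mt$z_score, p_sim = mt$p_sim,
               stringsAsFactors = FALSE)
  })))
  utils::write.csv(glob, file.path(out_dir, "moran_global.csv"), row.names = FALSE)

  say("LISA for ", config$outcome)
  lisa <- stage("lisa", lisa_mc(areas$attributes[[config$outcome]], W,
                                n_perm = config$n_perm, alpha = config$alpha,
                                seed = config$seed))
  ltab <- lisa_table(lisa, areas$unit_id)
  utils::write.csv(ltab, file.path(out_dir, "lisa.csv"), row.names = FALSE)
  write_cluster_geojson(areas, lisa$label, lisa$local_i, lisa$p_sim,
                        file.path(out_dir, "lisa_clusters.geojson"))

  design <- stage("design", regression_design(areas$attributes, config$outcome,
                                              config$covariates))
  Wrow <- if (W$style == "row_standardized") W else cache_spectrum(row_standardize(Wb))

  report_models <- list()
  fits <- list()
  if ("ols" %in% config$models) {
    say("OLS")
    ols <- stage("ols", fit_ols(design))
    ols_rm <- stage("ols", residual_moran(ols, Wrow, n_perm = config$n_perm,
                                          seed = config$seed))
    diag_tab <- stage("lm_diagnostics", lm_diagnostics(ols, Wrow))
    report_models$ols <- list(
      beta = as.list(ols$beta), se = as.list(ols$se),
      p_values = as.list(ols$p_values), r2 = ols$r2, adj_r2 = ols$adj_r2,
      logL = ols$logL, aic = ols$aic, vif = as.list(ols$vif),
      residual_moran = list(I = ols_rm$I, p_sim = ols_rm$p_sim),
      lm_diagnostics = list(statistics = as.list(diag_tab$statistics),
                            p_values = as.list(diag_tab$p_values)))
    .write_json_stable(report_models$ols, file.path(out_dir, "ols.json"))
    write_geojson(areal_table(areas$unit_id, areas$geometry),
                  file.path(out_dir, "residuals_ols.geojson"),
                  properties = data.frame(residual = ols$residuals))
    fits$ols <- ols
  }
  for (kind in intersect(config$models, c("sem", "slm"))) {
    say(toupper(kind))
    fitter <- if (kind == "sem") fit_sem else fit_slm
    fit <- stage(kind, fitter(design, Wrow, n_perm = config$n_perm,
                              seed = config$seed))
    report_models[[kind]] <- list(
      spatial_param = fit$spatial_param, se_spatial = fit$se_spatial,
      p_value_spatial = fit$p_value_spatial,
      beta = as.list(fit$beta), se = as.list(fit$se),
      p_values = as.list(fit$p_values), sigma2 = fit$sigma2,
      logL = fit$logL, aic = fit$aic,
      lr_test = fit$lr_test, bp_studentized = fit$bp_studentized,
      residual_moran = list(I = fit$residual_moran$I,
                            p_sim = fit$residual_moran$p_sim),
      converged = fit$converged)
    .write_json_stable(report_models[[kind]],
                       file.path(out_dir, paste0(kind, ".json")))
    write_geojson(areal_table(areas$unit_id, areas$geometry),
                  file.path(out_dir, paste0("residuals_", kind, ".geojson")),
                  properties = data.frame(residual = fit$residuals))
    fits[[kind]] <- fit
  }
  comparison <- NULL
  if (length(fits) > 1) {
    cmp <- do.call(compare_models, fits)
    comparison <- list(preferred = cmp$preferred,
                       table = lapply(seq_len(nrow(cmp$table)), function(i)
                         as.list(cmp$table[i, ])))
  }

  report <- list(
    software = list(package = "spareal",
                    version = as.character(utils::packageVersion("spareal"))),
    seed = config$seed,
    config = unclass(config),
    n_units = areas$n,
    weights = list(style = W$style, S0 = W$S0,
                   islands = as.list(W$ids[W$islands]),
                   links = sum(lengths(W$neighbors))),
    summary = lapply(seq_len(nrow(summ)), function(i) as.list(summ[i, ])),
    global_moran = lapply(seq_len(nrow(glob)), function(i) as.list(glob[i, ])),
    lisa = list(alpha = config$alpha, n_perm = config$n_perm,
                labels = table_to_list(table(factor(lisa$label,
                  levels = c("HH", "LL", "HL", "LH", "NS"))))),
    models = report_models,
    comparison = comparison
  )
  .write_json_stable(report, file.path(out_dir, "report.json"))
  say("report written to ", file.path(out_dir, "report.json"))
  ok <- TRUE
  invisible(report)
}

# named list from a 1-d table (jsonlite-friendly)
table_to_list <- function(tb) {
  out <- as.list(as.integer(tb))
  names(out) <- names(tb)
  out
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the three files a pipeline run consumes plus the ground truth:
#' `geometry.geojson`, `attributes.csv`, and `truth.json` (the generating
#' process, coefficients, spatial parameter, noise SD, seed).
#'
#' @param fixture result of [district_fixture].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geom_only <- areal_table(fixture$areas$unit_id, fixture$areas$geometry)
  write_geojson(geom_only, file.path(dir, "geometry.geojson"))
  tab <- cbind(unit_id = fixture$areas$unit_id, fixture$areas$attributes)
  utils::write.csv(tab, file.path(dir, "attributes.csv"), row.names = FALSE)
  .write_json_stable(fixture$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
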