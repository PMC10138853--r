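# Config-driven orchestration: one call runs ranking, concentration
# indices, curves and decompositions for every outcome-by-domain pair,
# with per-survey weight rescaling, per-domain survey filters, and
# reproducible file outputs.

#' Assemble a pipeline run configuration
#'
#' @param data a pooled woman-level data frame, a path to a CSV file, or
#'   `NULL` when `generator` is given.
#' @param generator optional [synth_config()]; when supplied the data are
#'   generated (with ground truth attached to the run for validation).
#' @param outcomes character vector of binary outcome columns.
#' @param domains character vector of ordinal stratifier columns; each must
#'   order as `domain_levels`.
#' @param domain_levels category labels, ascending (default
#'   low/medium/high).
#' @param covariates covariate columns entering each decomposition model
#'   (the ranked domain itself is always added, as in the source tables).
#' @param reference optional named list covariate -> reference category.
#' @param domain_filters optional named list domain -> survey-year labels
#'   to KEEP for that domain (e.g. a domain unavailable in the earliest
#'   round).
#' @param recode_map optional named list for [recode_missing()].
#' @param survey_col,weight_col,stratum_col,cluster_col design column
#'   names in `data`.
#' @param target_total per-survey rescaled weight total (default 1).
#' @param se_method,boot_reps passed to [erreygers_index()].
#' @param seed integer master seed recorded in the manifest and used for
#'   any bootstrap.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @param digits decimal places used in written tables (default 3).
#' @param write_plots write concentration-curve PNGs under `output_dir`?
#' @return Object of class `run_config`.
#' @export
run_config <- function(data = NULL, generator = NULL,
                       outcomes, domains,
                       domain_levels = c("low", "medium", "high"),
                       covariates = character(), reference = NULL,
                       domain_filters = NULL, recode_map = NULL,
                       survey_col = "survey_year", weight_col = "weight",
                       stratum_col = "stratum", cluster_col = "cluster",
                       target_total = 1,
                       se_method = c("linearized", "bootstrap"),
                       boot_reps = 1000, seed = 1L,
                       output_dir = NULL, digits = 3, write_plots = FALSE) {
  if (is.null(data) && is.null(generator)) {
    stop("supply `data` (frame or CSV path) or a `generator` config", call. = FALSE)
  }
  structure(list(data = data, generator = generator,
                 outcomes = outcomes, domains = domains,
                 domain_levels = domain_levels,
                 covariates = covariates, reference = reference,
                 domain_filters = domain_filters, recode_map = recode_map,
                 survey_col = survey_col, weight_col = weight_col,
                 stratum_col = stratum_col, cluster_col = cluster_col,
                 target_total = target_total,
                 se_method = match.arg(se_method), boot_reps = boot_reps,
                 seed = as.integer(seed), output_dir = output_dir,
                 digits = digits, write_plots = write_plots),
            class = "run_config")
}

resolve_data <- function(config) {
  if (!is.null(config$generator)) {
    gen <- generate_pooled_survey(config$generator, truth = FALSE)
    return(list(data = gen$data, generated = TRUE))
  }
  d <- config$data
  if (is.character(d)) d <- read_woman_table(d)
  list(data = d, generated = FALSE)
}

#' Validate a run configuration against its data
#'
#' Collects configuration problems without stopping: missing columns,
#' undefined reference categories, degenerate (single-category)
#' stratifiers, and strata with fewer than two clusters (fatal under the
#' bootstrap, otherwise collapsed with a warning at run time).
#'
#' @param config a [run_config()].
#' @return A list of class `config_report` with `errors` and `warnings`
#'   character vectors; an empty `errors` element means the run can
#'   proceed.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  errors <- character()
  warnings <- character()
  dat <- tryCatch(resolve_data(config)$data, error = function(e) {
    errors <<- c(errors, paste("data unavailable:", conditionMessage(e)))
    NULL
  })
  if (!is.null(dat)) {
    need <- c(config$outcomes, config$domains, config$covariates,
              config$survey_col, config$weight_col, config$stratum_col,
              config$cluster_col)
    absent <- setdiff(need, names(dat))
    if (length(absent)) {
      errors <- c(errors, paste("missing columns:", paste(absent, collapse = ", ")))
    }
    for (cv in names(config$reference %||% list())) {
      if (!cv %in% names(dat)) next
      if (!config$reference[[cv]] %in% unique(as.character(dat[[cv]]))) {
        errors <- c(errors, paste0("reference category `", config$reference[[cv]],
                                   "` not observed in `", cv, "`"))
      }
    }
    for (dom in intersect(config$domains, names(dat))) {
      obs <- unique(stats::na.omit(as.character(dat[[dom]])))
      if (length(obs) < 2) {
        errors <- c(errors, paste0("degenerate ranking: stratifier `", dom,
                                   "` has a single observed category"))
      }
      stray <- setdiff(obs, c(config$domain_levels, "dont_know"))
      if (length(stray)) {
        errors <- c(errors, paste0("stratifier `", dom, "` has values outside ",
                                   "domain_levels: ", paste(stray, collapse = ", ")))
      }
    }
    if (all(c(config$stratum_col, config$cluster_col) %in% names(dat))) {
      st <- paste(dat[[config$survey_col]], dat[[config$stratum_col]])
      cl <- paste(dat[[config$survey_col]], dat[[config$cluster_col]])
      n_cl <- tapply(cl, st, function(z) length(unique(z)))
      single <- sum(n_cl < 2)
      if (single > 0) {
        msg <- paste0(single, " stratum(s) contain a single cluster")
        if (config$se_method == "bootstrap") {
          errors <- c(errors, paste0(msg, ": the stratified cluster bootstrap needs ",
                                     ">= 2 clusters per stratum; collapse these strata"))
        } else {
          warnings <- c(warnings, paste0(msg, "; they will be collapsed for ",
                                         "variance estimation"))
        }
      }
    }
  }
  structure(list(errors = errors, warnings = warnings), class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  if (!length(x$errors) && !length(x$warnings)) {
    cat("configuration OK\n")
  } else {
    for (e in x$errors) cat("ERROR:", e, "\n")
    for (w in x$warnings) cat("warning:", w, "\n")
  }
  invisible(x)
}

#' Run the full inequality analysis
#'
#' For every outcome-by-domain pair: restricts to rows where the outcome
#' applies and the domain is observed (honouring per-domain survey
#' filters), rescales weights so each survey counts equally, builds
#' pooled-unique design IDs, computes fractional ranks, the Erreygers
#' index with design-based uncertainty, the concentration curve, the
#' survey-weighted logit fit and the decomposition. Optionally writes all
#' results plus a reproducibility manifest under `output_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a named list (keys `"outcome.domain"`) of lists with
#'   elements `concentration` ([erreygers_index()] result), `curve`,
#'   `fit`, `decomposition`, and `n`; plus attribute `"log"`, a data frame
#'   of per-stage record counts.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- validate_config(config)
  if (length(report$errors)) {
    stop("invalid configuration:\n  ", paste(report$errors, collapse = "\n  "),
         call. = FALSE)
  }
  src <- resolve_data(config)
  dat <- src$data
  if (!is.null(config$recode_map)) dat <- recode_missing(dat, config$recode_map)
  dat <- pool_and_rescale(dat, survey_col = config$survey_col,
                          weight_col = config$weight_col,
                          stratum_col = config$stratum_col,
                          cluster_col = config$cluster_col,
                          target_total = config$target_total)

  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  log_rows <- list()
  for (outcome in config$outcomes) {
    for (dom in config$domains) {
      key <- paste(outcome, dom, sep = ".")
      sub <- dat[!is.na(dat[[outcome]]) & !is.na(dat[[dom]]), , drop = FALSE]
      filt <- config$domain_filters[[dom]]
      if (!is.null(filt)) {
        sub <- sub[as.character(sub[[config$survey_col]]) %in% as.character(filt), ,
                   drop = FALSE]
      }
      log_rows[[key]] <- data.frame(outcome = outcome, domain = dom,
                                    rows_in = nrow(dat), rows_used = nrow(sub))
      res <- tryCatch({
        rs <- fractional_rank(as.character(sub[[dom]]),
                              weights = sub$rescaled_weight,
                              levels = config$domain_levels)
        design <- list(cluster = sub$unique_cluster, strata = sub$unique_stratum)
        conc <- erreygers_index(sub[[outcome]], rs, design = design,
                                se_method = config$se_method,
                                boot_reps = config$boot_reps,
                                boot_seed = derive_seed(config$seed, match(key, names(log_rows))))
        curve <- concentration_curve(sub[[outcome]], rs)
        fit <- fit_outcome_model(sub, outcome,
                                 covariates = unique(c(config$covariates, dom)),
                                 weights = sub$rescaled_weight,
                                 reference = config$reference)
        dec <- interpret_signs(decompose_inequality(fit, rs, conc))
        list(concentration = conc, curve = curve, fit = fit,
             decomposition = dec, n = nrow(sub))
      }, error = function(e) {
        stop("stage failure for (", outcome, ", ", dom, "): ",
             conditionMessage(e), call. = FALSE)
      })
      results[[key]] <- res

      if (!is.null(out_dir)) {
        base <- file.path(out_dir, key)
        conc <- res$concentration
        utils::write.csv(data.frame(outcome = outcome, domain = dom, n = res$n,
                                    prevalence = conc$prevalence,
                                    ci_standard = conc$ci_standard,
                                    eci = conc$eci, se = conc$se,
                                    ci95_low = conc$ci95[1], ci95_high = conc$ci95[2],
                                    method = conc$method),
                         paste0(base, "_index.csv"), row.names = FALSE)
        utils::write.csv(as.data.frame(res$curve), paste0(base, "_curve.csv"),
                         row.names = FALSE)
        write_decomposition(res$decomposition, paste0(base, "_decomposition.csv"),
                            digits = config$digits)
        if (isTRUE(config$write_plots)) {
          grDevices::png(paste0(base, "_curve.png"), width = 640, height = 640)
          plot(res$curve, main = paste("Concentration curve:", outcome, "by", dom))
          grDevices::dev.off()
        }
      }
    }
  }

  log_df <- do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    cfg_json <- file.path(out_dir, "config.json")
    cfg_out <- config
    cfg_out$data <- if (is.character(config$data)) config$data else "(in-memory data frame)"
    jsonlite::write_json(unclass(cfg_out), cfg_json, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    manifest <- list(config_file = "config.json",
                     config_md5 = unname(tools::md5sum(cfg_json)),
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("svyconc")),
                     r_version = R.version.string,
                     combinations = names(results))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(log_df, file.path(out_dir, "stage_log.csv"), row.names = FALSE)
  }
  attr(results, "log") <- log_df
  invisible(results)
}
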