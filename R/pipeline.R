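# End-to-end orchestration: phantom/manifest -> preprocessing -> bands ->
# habitats -> features -> heterogeneity -> selection -> models -> survival.

#' Pipeline configuration
#'
#' Collects every stage parameter with the framework defaults: 1 x 1 x 3 mm
#' resampling, 3/5/7 mm bands, 50 habitats, ICC threshold 0.800, univariate
#' alpha 0.05, top-20 tree selection, 7:3 stratified split, RMST taus 36 and
#' 60 months. Round-trips losslessly through YAML.
#'
#' @param manifest Path to a case manifest YAML (or `NULL` to simulate).
#' @param phantom_n Number of phantom cases when simulating, default 20.
#' @param target_spacing,distances,K,compactness,bin_width,icc_threshold,alpha,top_k,split_ratio,algorithms,taus,seed
#'   Stage parameters (see module functions for semantics).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, phantom_n = 20,
                            target_spacing = c(1, 1, 3),
                            distances = c(3, 5, 7), K = 50,
                            compactness = 0.1, bin_width = 0.1,
                            icc_threshold = 0.800, alpha = 0.05, top_k = 20,
                            split_ratio = 0.7, algorithms = ALGORITHMS,
                            taus = c(36, 60), seed = 20406) {
  cfg <- list(manifest = manifest, phantom_n = phantom_n,
              target_spacing = target_spacing, distances = distances, K = K,
              compactness = compactness, bin_width = bin_width,
              icc_threshold = icc_threshold, alpha = alpha, top_k = top_k,
              split_ratio = split_ratio, algorithms = algorithms, taus = taus,
              seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Stages: load or simulate the cohort; resample + normalize; peritumoral
#' bands; habitat encoding; per-habitat feature extraction; heterogeneity
#' vectors (TH features) and whole-tumor features (Rad baseline); train-only
#' median imputation; three-step selection; seven-model suites on TH and Rad
#' subsets; evaluation on train/test; survival analysis of actual and
#' predicted labels. Stage outputs are written under `out_dir` and reused on
#' rerun when present (cache keyed on the configuration hash).
#'
#' @param config A [pipeline_config].
#' @param out_dir Output/run directory.
#' @param quiet Suppress stage messages.
#' @return List: `heterogeneity` (cases x 1712 tibble), `rad` (cases x 428),
#'   `selection` (TH and Rad reports), `metrics` (model x split tibble),
#'   `survival` (per-endpoint summaries), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("habrun"),
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_hash <- rlang::hash(unclass(config))
  hash_path <- file.path(out_dir, "config_hash.txt")
  cache_ok <- file.exists(hash_path) &&
    identical(readLines(hash_path, warn = FALSE)[1], cfg_hash)
  writeLines(cfg_hash, hash_path)
  write_config(config, file.path(out_dir, "config.yaml"))

  het_path <- file.path(out_dir, "heterogeneity.csv")
  rad_path <- file.path(out_dir, "rad_features.csv")
  cohort_path <- file.path(out_dir, "cohort.csv")

  if (cache_ok && file.exists(het_path) && file.exists(rad_path) &&
      file.exists(cohort_path)) {
    say("feature stage: cache hit")
    het <- tibble::as_tibble(read.csv(het_path, check.names = FALSE))
    rad <- tibble::as_tibble(read.csv(rad_path, check.names = FALSE))
    cohort <- tibble::as_tibble(read.csv(cohort_path, check.names = FALSE))
  } else {
    if (is.null(config$manifest)) {
      say("stage simulate: %d phantom cases", config$phantom_n)
      gen <- generate_cohort(phantom_spec(seed = config$seed), config$phantom_n)
      cases <- gen$cases
      cohort <- gen$cohort
    } else {
      say("stage load: manifest %s", config$manifest)
      man <- read_manifest(config$manifest)
      cases <- lapply(seq_len(nrow(man)), function(i) {
        lc <- load_case(as.list(man[i, SEQ_NAMES]), man$mask[i],
                        case_id = man$case_id[i],
                        target_spacing = config$target_spacing)
        list(stack = lc$stack, mask = lc$mask)
      })
      cohort <- tibble::tibble(case_id = man$case_id)
    }
    say("stages bands/habitats/features/heterogeneity: %d cases", length(cases))
    settings <- extraction_settings(bin_width = config$bin_width)
    het <- cohort_heterogeneity(cases, K = config$K,
                                distances = config$distances,
                                settings = settings,
                                compactness = config$compactness,
                                seed = config$seed, progress = !quiet)
    rad_rows <- lapply(cases, function(cs) {
      v <- extract_whole_tumor(cs$stack, cs$mask, settings)
      tibble::as_tibble(c(list(case_id = cs$stack$case_id), as.list(v)))
    })
    rad <- dplyr::bind_rows(rad_rows)
    write.csv(het, het_path, row.names = FALSE)
    write.csv(rad, rad_path, row.names = FALSE)
    write.csv(cohort, cohort_path, row.names = FALSE)
  }

  if (!"label" %in% names(cohort)) {
    say("no labels available; stopping after feature stages")
    return(list(heterogeneity = het, rad = rad, selection = NULL,
                metrics = NULL, survival = NULL, config = config,
                out_dir = out_dir))
  }

  say("stage select/train/evaluate")
  labels <- cohort$label
  split <- stratified_split(labels, ratio = config$split_ratio,
                            seed = config$seed)
  modeled <- lapply(list(TH = het, Rad = rad), function(tab) {
    feats <- tab[setdiff(names(tab), "case_id")]
    imp <- impute_train_median(feats, split == "train")
    train <- imp$data[split == "train", ]
    sel <- select_features(train, labels[split == "train"],
                           icc_threshold = config$icc_threshold,
                           alpha = config$alpha, k = config$top_k,
                           seed = config$seed %% 1000)
    if (length(sel$selected) == 0) return(list(selection = sel, metrics = NULL))
    suite <- fit_models(train[sel$selected], labels[split == "train"],
                        algorithms = config$algorithms,
                        seed = config$seed %% 1000)
    splits <- list(
      train = list(data = imp$data[split == "train", sel$selected],
                   labels = labels[split == "train"]),
      test = list(data = imp$data[split == "test", sel$selected],
                  labels = labels[split == "test"]))
    metrics <- evaluate_suite(suite, splits)
    pred <- as.integer(predict(suite, imp$data[sel$selected])[[
      utils::tail(config$algorithms, 1)]] >=
        metrics$threshold[metrics$split == "train"][
          length(config$algorithms)])
    list(selection = sel, suite = suite, metrics = metrics, pred = pred)
  })
  metrics <- dplyr::bind_rows(
    dplyr::mutate(modeled$TH$metrics %||% tibble::tibble(), subset = "TH"),
    dplyr::mutate(modeled$Rad$metrics %||% tibble::tibble(), subset = "Rad"))
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  sel_report <- list(TH = modeled$TH$selection$counts,
                     Rad = modeled$Rad$selection$counts,
                     TH_selected = modeled$TH$selection$selected,
                     Rad_selected = modeled$Rad$selection$selected)
  jsonlite::write_json(sel_report, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  surv_out <- NULL
  if (all(c("time_os", "event_os") %in% names(cohort))) {
    say("stage survival")
    rec <- dplyr::mutate(cohort, group = factor(labels))
    surv_out <- list(
      os = list(km = km_estimate(rec, "time_os", "event_os", "group"),
                logrank = logrank(rec, "time_os", "event_os", "group"),
                rmst = lapply(config$taus, function(tau)
                  rmst(rec, tau, "time_os", "event_os", "group")),
                cox = cox_hr(dplyr::mutate(rec, grp = as.integer(labels)),
                             "grp", "time_os", "event_os")),
      rfs = list(km = km_estimate(rec, "time_rfs", "event_rfs", "group"),
                 logrank = logrank(rec, "time_rfs", "event_rfs", "group"),
                 rmst = lapply(config$taus, function(tau)
                   rmst(rec, tau, "time_rfs", "event_rfs", "group")),
                 cox = cox_hr(dplyr::mutate(rec, grp = as.integer(labels)),
                              "grp", "time_rfs", "event_rfs")))
    surv_json <- list(
      os_median = surv_out$os$km$median,
      os_logrank_p = surv_out$os$logrank$p,
      os_hr = surv_out$os$cox$hr,
      rfs_median = surv_out$rfs$km$median,
      rfs_logrank_p = surv_out$rfs$logrank$p,
      rfs_hr = surv_out$rfs$cox$hr)
    jsonlite::write_json(surv_json, file.path(out_dir, "survival.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  list(heterogeneity = het, rad = rad,
       selection = sel_report, metrics = metrics, survival = surv_out,
       split = split, config = config, out_dir = out_dir)
}
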