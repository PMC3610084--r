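# Orchestration: config -> cohort (synthetic or audio manifest) ->
# features -> statistics -> report files.

#' Default pipeline configuration
#'
#' @param mode `"synthetic"` (bundled cohort generator) or
#'   `"audio-dir"` (user recordings listed in a manifest CSV).
#' @param seed Integer seed (mandatory in synthetic mode).
#' @param out_dir Output directory for report files (`NULL`: no files
#'   written, results only returned).
#' @param manifest Path to a manifest CSV in `audio-dir` mode; columns
#'   `id`, `wav`, optional `annotation` (exclusion-interval CSV),
#'   `group`, plus any behavioral-score columns.
#' @param cohort Synthetic-cohort options: `n` (named group sizes),
#'   `recording_duration` (s), `sample_rate`, `burst_base`.
#' @param spectrogram,contour,bands,detector,stats Stage parameter
#'   lists; see [spectrogram_config()], [extract_contour()],
#'   [default_bands()], [detect_vocalizations()].
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = "synthetic", seed = 1, out_dir = NULL,
                            manifest = NULL,
                            cohort = list(), spectrogram = list(),
                            contour = list(), bands = NULL,
                            detector = list(), stats = list()) {
  cfg <- list(
    mode = mode, seed = seed, out_dir = out_dir, manifest = manifest,
    cohort = utils::modifyList(
      list(n = NULL, recording_duration = 150, sample_rate = 22050,
           burst_base = 0.06), cohort),
    spectrogram = utils::modifyList(
      list(window_length = 25, hop = 2, window_shape = "gaussian",
           amplitude_scale = "log", log_floor = 80, max_frequency = 8000),
      spectrogram),
    contour = utils::modifyList(
      list(energy_fraction = 0.999, wt_max = 100, wf_max = 20,
           chunk_duration = 1, chunk_overlap = 0.5), contour),
    bands = if (is.null(bands)) list(sr = c(0, 10), ft = c(10, 50),
                                     poa = c(50, 100)) else bands,
    detector = utils::modifyList(
      list(pause_ms = 300, frame = 10, threshold_db = 15), detector),
    stats = utils::modifyList(list(alpha = 0.05), stats)
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of
#' [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file did not parse to a list", call. = FALSE)
  args <- raw[intersect(names(raw),
                        names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problems; empty when the config is
#'   runnable. Each entry names the offending field and constraint.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!config$mode %in% c("synthetic", "audio-dir")) {
    add(sprintf("mode: must be 'synthetic' or 'audio-dir' (got '%s')",
                config$mode))
  }
  if (identical(config$mode, "synthetic") &&
      (is.null(config$seed) || !is.finite(config$seed))) {
    add("seed: mandatory in synthetic mode")
  }
  sp <- config$spectrogram
  if (sp$hop > sp$window_length) {
    add("spectrogram.hop: must be <= spectrogram.window_length")
  }
  if (1000 / (2 * sp$hop) < 100) {
    add("spectrogram.hop: temporal-modulation Nyquist 1/(2 hop) must be >= 100 Hz")
  }
  if (!sp$amplitude_scale %in% c("log", "linear")) {
    add("spectrogram.amplitude_scale: must be 'log' or 'linear'")
  }
  ct <- config$contour
  if (ct$energy_fraction <= 0 || ct$energy_fraction >= 1) {
    add("contour.energy_fraction: must be in (0, 1)")
  }
  bands_df <- tryCatch(config_bands(config), error = function(e) e)
  if (inherits(bands_df, "error")) {
    add(paste0("bands: ", conditionMessage(bands_df)))
  } else if (max(bands_df$hi) > ct$wt_max + 1e-9) {
    add("bands: upper edge exceeds contour.wt_max")
  }
  if (config$detector$pause_ms <= 0) add("detector.pause_ms: must be > 0")
  if (identical(config$mode, "audio-dir")) {
    if (is.null(config$manifest)) {
      add("manifest: required in audio-dir mode")
    } else if (!file.exists(config$manifest)) {
      add(sprintf("manifest: file '%s' does not exist", config$manifest))
    } else {
      mf <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
      if (!all(c("id", "wav", "group") %in% names(mf))) {
        add("manifest: needs columns id, wav, group")
      } else {
        miss <- mf$wav[!file.exists(mf$wav)]
        if (length(miss)) {
          add(paste0("manifest: missing wav files: ",
                     paste(miss, collapse = ", ")))
        }
      }
    }
  }
  problems
}

config_bands <- function(config) {
  b <- config$bands
  df <- data.frame(name = names(b),
                   lo = vapply(b, function(x) x[1], 0),
                   hi = vapply(b, function(x) x[2], 0),
                   stringsAsFactors = FALSE)
  validate_bands(df)
  df[order(df$lo), ]
}

config_feature_config <- function(config) {
  sp <- config$spectrogram
  ct <- config$contour
  feature_config(
    spectrogram = spectrogram_config(
      window_length = sp$window_length, hop = sp$hop,
      window_shape = sp$window_shape, amplitude_scale = sp$amplitude_scale,
      log_floor = sp$log_floor, max_frequency = sp$max_frequency),
    chunk_duration = ct$chunk_duration, chunk_overlap = ct$chunk_overlap,
    energy_fraction = ct$energy_fraction, wt_max = ct$wt_max,
    wf_max = ct$wf_max, bands = config_bands(config)
  )
}

stat_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(test = x$test, statistic = x$statistic, df = x$df,
       p_value = x$p_value, note = x$note)
}

load_manifest_cohort <- function(config) {
  mf <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
  audio <- list()
  for (i in seq_len(nrow(mf))) {
    s <- read_wav(mf$wav[i])
    s <- resample(s, config$cohort$sample_rate)
    ann <- NULL
    if ("annotation" %in% names(mf) && nzchar(mf$annotation[i] %||% "")) {
      ann <- list(read_annotation_csv(mf$annotation[i]))
    }
    audio[[mf$id[i]]] <- excise_and_concatenate(list(s), ann,
                                                min_duration_s = 120)
  }
  participants <- mf[, setdiff(names(mf), c("wav", "annotation")),
                     drop = FALSE]
  if (all(c("mullen_rl", "mullen_el") %in% names(participants)) &&
      !"viq" %in% names(participants)) {
    participants$viq <- (participants$mullen_rl + participants$mullen_el) / 2
  }
  structure(list(participants = participants, audio = audio,
                 specs = NULL, spec = NULL), class = "cohort")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, extracts articulatory features and
#' vocalization rates for every participant, runs the statistical
#' battery, and - when `out_dir` is set - writes the report files:
#' `features.csv`, `presence.csv`, `descriptives_poa.csv`,
#' `correlations_<group>.csv`, `stats.json` and `run_manifest.json`.
#' All outputs are fully determined by `(config, seed)`. Participants
#' whose extraction fails are listed in the failure log, never silently
#' dropped.
#'
#' @param config A `pipeline_config` (or path to a YAML/JSON file).
#' @return A list: `participants` (feature table), `stats` (list of
#'   test results), `presence`, `descriptives`, `correlations`,
#'   `failures`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  cohort <- if (identical(config$mode, "synthetic")) {
    sizes <- config$cohort$n
    profiles <- if (is.null(sizes)) default_profiles()
                else default_profiles(n = unlist(sizes))
    generate_cohort(cohort_spec(
      profiles = profiles,
      sample_rate = config$cohort$sample_rate,
      recording_duration = config$cohort$recording_duration,
      seed = config$seed,
      burst_base = config$cohort$burst_base))
  } else {
    load_manifest_cohort(config)
  }

  fc <- config_feature_config(config)
  feats <- extract_cohort_features(
    cohort, fc, vocalizations = TRUE,
    pause_ms = config$detector$pause_ms,
    threshold_db = config$detector$threshold_db)
  failures <- attr(feats, "failures")
  ok <- !is.na(feats$total_area)
  tab <- feats[ok, , drop = FALSE]

  alpha <- config$stats$alpha
  stats_out <- list()

  # timescale comparison collapsed across participants
  by_band <- list(sr = tab$sr_area, ft = tab$ft_area, poa = tab$poa_area)
  stats_out$timescale_kw <- tryCatch(kruskal_wallis(by_band),
                                     error = function(e) NULL)
  stats_out$timescale_tukey <- tryCatch(
    tukey_posthoc(by_band, alpha, rank_transform = TRUE),
    error = function(e) NULL)

  # per-band group comparisons (all groups)
  split_groups <- function(d, col) split(d[[col]], d$group)
  for (band in c("sr_area", "ft_area", "poa_area")) {
    stats_out[[paste0("group_kw_", band)]] <- tryCatch(
      kruskal_wallis(split_groups(tab, band)), error = function(e) NULL)
  }

  # VIQ-split comparisons (ASD vs TD vs DD with ASD halved by VIQ)
  if ("viq" %in% names(tab) && any(tab$group == "ASD")) {
    asd <- tab[tab$group == "ASD", , drop = FALSE]
    sp <- split_by_viq(asd)
    for (half in c("lviq", "hviq")) {
      sub <- sp[[half]]
      if (nrow(sub) < 2) next
      for (band in c("sr_area", "ft_area", "poa_area")) {
        groups <- c(stats::setNames(list(sub[[band]]),
                                    paste0(toupper(half), "-ASD")),
                    list(TD = tab[[band]][tab$group == "TD"],
                         DD = tab[[band]][tab$group == "DD"]))
        groups <- Filter(function(v) length(v) >= 2, groups)
        key <- paste0(half, "_anova_", band)
        stats_out[[key]] <- tryCatch(one_way_anova(groups),
                                     error = function(e) NULL)
        if (band == "poa_area") {
          stats_out[[paste0(half, "_lsd_poa")]] <- tryCatch(
            fisher_lsd_posthoc(groups, alpha), error = function(e) NULL)
        }
      }
    }
    stats_out$viq_cutoff <- sp$cutoff
  }

  # vocalization rate comparison
  if ("voc_rate" %in% names(tab)) {
    vr <- split_groups(tab, "voc_rate")
    stats_out$voc_anova <- tryCatch(one_way_anova(vr), error = function(e) NULL)
    stats_out$voc_tukey <- tryCatch(tukey_posthoc(vr, alpha),
                                    error = function(e) NULL)
  }

  presence <- presence_percentages(tab)
  desc_by_group <- lapply(split(tab$poa_area, tab$group), function(v) {
    if (sum(is.finite(v)) < 2) return(NULL)
    as.data.frame(descriptive_stats(v))
  })
  desc_by_group <- Filter(Negate(is.null), desc_by_group)
  descriptives <- if (length(desc_by_group)) {
    out <- do.call(rbind, desc_by_group)
    out <- cbind(group = names(desc_by_group), out)
    rownames(out) <- NULL
    out
  } else NULL

  score_cols <- intersect(c("mullen_rl", "mullen_el", "mullen_fm",
                            "vabs_rl", "vabs_el"), names(tab))
  feat_cols <- intersect(c("sr_area", "ft_area", "poa_area", "total_area",
                           "voc_rate"), names(tab))
  correlations <- if (length(score_cols)) {
    pearson_correlations(tab, feat_cols, score_cols)
  } else NULL

  result <- list(participants = feats, stats = stats_out,
                 presence = presence, descriptives = descriptives,
                 correlations = correlations, failures = failures,
                 config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(f) file.path(config$out_dir, f)
    utils::write.csv(feats, wp("features.csv"), row.names = FALSE)
    utils::write.csv(presence, wp("presence.csv"), row.names = FALSE)
    if (!is.null(descriptives)) {
      utils::write.csv(descriptives, wp("descriptives_poa.csv"),
                       row.names = FALSE)
    }
    if (!is.null(correlations)) {
      for (gr in names(correlations)) {
        utils::write.csv(correlations[[gr]],
                         wp(sprintf("correlations_%s.csv", gr)),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(
      lapply(stats_out, function(x) {
        if (inherits(x, "stat_result")) stat_to_list(x) else x
      }),
      wp("stats.json"), auto_unbox = TRUE, digits = NA, null = "null",
      force = TRUE)
    jsonlite::write_json(
      list(config = unclass(config), seed = config$seed,
           package_version = as.character(utils::packageVersion("speechmod")),
           n_participants = nrow(feats),
           failures = as.list(failures)),
      wp("run_manifest.json"), auto_unbox = TRUE, digits = NA,
      null = "null", force = TRUE)
  }
  invisible(result)
}
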