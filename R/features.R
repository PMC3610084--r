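#' Timescale band definitions
#'
#' The operational partition of the temporal-modulation axis into the
#' three articulatory-feature bands: syllabic rhythm (SR, slow
#' supra-segmental modulations), formant transitions (FT, intermediate
#' modulations of consonant blends and vowel transitions) and place of
#' articulation (POA, fast plosive-like modulations). Bands are
#' half-open `[lo, hi)` except the last, which closes at its upper
#' edge, so together they tile `[0, 100]` Hz.
#'
#' @param sr,ft,poa Numeric `c(lo, hi)` edges in Hz.
#' @return A data.frame with columns `name`, `lo`, `hi`.
#' @export
default_bands <- function(sr = c(0, 10), ft = c(10, 50), poa = c(50, 100)) {
  bands <- data.frame(
    name = c("sr", "ft", "poa"),
    lo = c(sr[1], ft[1], poa[1]),
    hi = c(sr[2], ft[2], poa[2]),
    stringsAsFactors = FALSE
  )
  validate_bands(bands)
  bands
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "lo", "hi") %in% names(bands)))
  b <- bands[order(bands$lo), ]
  if (any(b$hi <= b$lo)) stop("band edges must satisfy lo < hi", call. = FALSE)
  if (b$lo[1] != 0) stop("bands must start at 0 Hz", call. = FALSE)
  if (nrow(b) > 1 && any(abs(b$lo[-1] - b$hi[-nrow(b)]) > 1e-9)) {
    stop("bands must be contiguous (no gaps or overlaps)", call. = FALSE)
  }
  invisible(bands)
}

#' Extract the minimal-area energy contour
#'
#' Finds the smallest set of modulation bins whose cumulative power
#' reaches `energy_fraction` (default 99.9%) of the total modulation
#' energy within the analysis domain. The analysis domain is the
#' non-negative temporal-modulation half plane restricted to
#' `wt <= wt_max` and `|wf| <= wf_max`, with the DC bin
#' (`wt = 0, wf = 0`, overall level) excluded. Bins are accumulated in
#' decreasing order of power; ties are broken deterministically toward
#' lower `|wt|`, then lower `|wf|`. The "contour area" of downstream
#' analyses is the number of bins in this set.
#'
#' @param ms A [modulation_spectrum].
#' @param energy_fraction Fraction of domain energy to cover, in (0, 1).
#' @param wt_max Upper temporal-modulation limit of the domain, Hz.
#' @param wf_max Spectral-modulation limit, cycles/kHz.
#' @return An object of class `contour_mask`: `inside` (logical matrix
#'   over the domain grid), `power` (the domain power matrix), `wf`,
#'   `wt` axes, `total_area` (bin count), `energy_fraction_covered`.
#' @export
extract_contour <- function(ms, energy_fraction = 0.999, wt_max = 100,
                            wf_max = 20) {
  stopifnot(inherits(ms, "modulation_spectrum"),
            energy_fraction > 0, energy_fraction < 1)
  keep_f <- abs(ms$wf) <= wf_max + 1e-9
  keep_t <- ms$wt >= -1e-9 & ms$wt <= wt_max + 1e-9
  P <- ms$power[keep_f, keep_t, drop = FALSE]
  wf <- ms$wf[keep_f]
  wt <- ms$wt[keep_t]
  dc <- outer(abs(wf) < 1e-9, abs(wt) < 1e-9, FUN = "&")
  P[dc] <- 0
  total <- sum(P)
  if (total <= 0) {
    stop("degenerate input: no modulation energy in the analysis domain",
         call. = FALSE)
  }
  wt_grid <- matrix(rep(abs(wt), each = length(wf)), nrow = length(wf))
  wf_grid <- matrix(rep(abs(wf), times = length(wt)), nrow = length(wf))
  ord <- order(-P, wt_grid, wf_grid)
  csum <- cumsum(P[ord])
  k <- which(csum >= energy_fraction * total - 1e-12)[1]
  inside <- matrix(FALSE, length(wf), length(wt))
  inside[ord[seq_len(k)]] <- TRUE
  structure(
    list(inside = inside, power = P, wf = wf, wt = wt,
         total_area = as.integer(k),
         energy_fraction_covered = csum[k] / total,
         energy_fraction = energy_fraction),
    class = "contour_mask"
  )
}

#' @export
print.contour_mask <- function(x, ...) {
  cat(sprintf("<contour_mask: %d bins covering %.4f%% of modulation energy>\n",
              x$total_area, 100 * x$energy_fraction_covered))
  invisible(x)
}

#' Band-wise contour areas
#'
#' Counts the contour bins falling in each timescale band of the
#' temporal-modulation axis. Bands are applied as `[lo, hi)` with the
#' last band closed at its upper edge, so the band areas always sum to
#' the total contour area.
#'
#' @param mask A [contour_mask].
#' @param bands Band definitions, see [default_bands()].
#' @param min_presence_area Minimum band area (bins) to count the band
#'   as present (default 0: any bin counts).
#' @return An object of class `articulatory_features`: `sr_area`,
#'   `ft_area`, `poa_area`, `total_area` (bin counts) and `presence`
#'   (named logical vector).
#' @export
band_areas <- function(mask, bands = default_bands(), min_presence_area = 0) {
  stopifnot(inherits(mask, "contour_mask"))
  validate_bands(bands)
  bands <- bands[order(bands$lo), ]
  wt_of_bin <- matrix(rep(abs(mask$wt), each = length(mask$wf)),
                      nrow = length(mask$wf))
  areas <- integer(nrow(bands))
  names(areas) <- bands$name
  for (i in seq_len(nrow(bands))) {
    hi_closed <- i == nrow(bands)
    inb <- wt_of_bin >= bands$lo[i] - 1e-9 &
      (if (hi_closed) wt_of_bin <= bands$hi[i] + 1e-9
       else wt_of_bin < bands$hi[i] - 1e-9)
    areas[i] <- sum(mask$inside & inb)
  }
  presence <- areas > min_presence_area
  out <- list(total_area = mask$total_area, areas = areas,
              presence = presence, bands = bands)
  for (nm in names(areas)) out[[paste0(nm, "_area")]] <- unname(areas[[nm]])
  structure(out, class = "articulatory_features")
}

#' @export
print.articulatory_features <- function(x, ...) {
  cat(sprintf("<articulatory_features: total %d bins | %s>\n", x$total_area,
              paste(sprintf("%s=%d%s", names(x$areas), x$areas,
                            ifelse(x$presence, "", " (absent)")),
                    collapse = ", ")))
  invisible(x)
}

#' Feature-extraction configuration
#'
#' Bundles the spectrogram, chunking, contour and band parameters used
#' by [extract_features()].
#'
#' @param spectrogram A [spectrogram_config].
#' @param chunk_duration,chunk_overlap Chunking of the spectrogram for
#'   the 2-D transform (see [compute_modulation_spectrum()]).
#' @param energy_fraction Contour energy fraction (default 0.999).
#' @param wt_max,wf_max Contour analysis domain limits.
#' @param bands Timescale bands (see [default_bands()]).
#' @param min_presence_area Presence threshold in bins.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(spectrogram = spectrogram_config(),
                           chunk_duration = 1, chunk_overlap = 0.5,
                           energy_fraction = 0.999, wt_max = 100,
                           wf_max = 20, bands = default_bands(),
                           min_presence_area = 0) {
  stopifnot(inherits(spectrogram, "spectrogram_config"),
            energy_fraction > 0, energy_fraction < 1)
  validate_bands(bands)
  if (max(bands$hi) > wt_max + 1e-9) {
    stop("band upper edges must lie within `wt_max`", call. = FALSE)
  }
  structure(
    list(spectrogram = spectrogram, chunk_duration = chunk_duration,
         chunk_overlap = chunk_overlap, energy_fraction = energy_fraction,
         wt_max = wt_max, wf_max = wf_max, bands = bands,
         min_presence_area = min_presence_area),
    class = "feature_config"
  )
}

#' Extract articulatory features from audio
#'
#' End-to-end composition: spectrogram, chunked 2-D Fourier transform,
#' 99.9%-energy contour, band areas. Deterministic for a fixed input
#' and configuration.
#'
#' @param sample An [audio_sample].
#' @param config A [feature_config].
#' @return An `articulatory_features` object (see [band_areas()]).
#' @export
extract_features <- function(sample, config = feature_config()) {
  stopifnot(inherits(sample, "audio_sample"), inherits(config, "feature_config"))
  if (length(sample$samples) == 0 || all(sample$samples == 0)) {
    stop("degenerate input: silent or empty sample", call. = FALSE)
  }
  spgm <- compute_spectrogram(sample, config$spectrogram)
  ms <- compute_modulation_spectrum(spgm, config$chunk_duration,
                                    config$chunk_overlap)
  mask <- extract_contour(ms, config$energy_fraction, config$wt_max,
                          config$wf_max)
  band_areas(mask, config$bands, config$min_presence_area)
}

#' Extract features and vocalization rates for a whole cohort
#'
#' Runs [extract_features()] (and optionally [detect_vocalizations()])
#' on every participant of a synthetic cohort and appends the results
#' to the participant table. Per-participant failures are recorded in
#' the `failures` attribute rather than aborting the run.
#'
#' @param cohort A `cohort` from [generate_cohort()] (with audio).
#' @param config A [feature_config].
#' @param vocalizations If `TRUE`, also run the pause-based
#'   vocalization counter on each recording.
#' @param pause_ms,threshold_db Detector parameters, see
#'   [detect_vocalizations()].
#' @return The participant data.frame with columns `sr_area`,
#'   `ft_area`, `poa_area`, `total_area`, `presence_sr`, `presence_ft`,
#'   `presence_poa` (and `voc_count`, `voc_rate` when requested);
#'   attribute `failures` holds a named character vector of errors.
#' @export
extract_cohort_features <- function(cohort, config = feature_config(),
                                    vocalizations = TRUE,
                                    pause_ms = 300, threshold_db = 15) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$audio)) {
    stop("cohort was generated with `audio = FALSE`", call. = FALSE)
  }
  df <- cohort$participants
  cols <- c("sr_area", "ft_area", "poa_area", "total_area")
  for (cl in cols) df[[cl]] <- NA_integer_
  for (cl in c("presence_sr", "presence_ft", "presence_poa")) df[[cl]] <- NA
  if (vocalizations) {
    df$voc_count <- NA_integer_
    df$voc_rate <- NA_real_
  }
  failures <- character(0)
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    res <- tryCatch({
      feats <- extract_features(cohort$audio[[id]], config)
      df[i, cols] <- as.list(feats[c("sr_area", "ft_area", "poa_area",
                                     "total_area")])
      df$presence_sr[i] <- feats$presence[["sr"]]
      df$presence_ft[i] <- feats$presence[["ft"]]
      df$presence_poa[i] <- feats$presence[["poa"]]
      if (vocalizations) {
        v <- detect_vocalizations(cohort$audio[[id]], pause_ms = pause_ms,
                                  threshold_db = threshold_db)
        df$voc_count[i] <- v$count
        df$voc_rate[i] <- v$rate
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures[id] <- res
  }
  attr(df, "failures") <- failures
  df
}
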