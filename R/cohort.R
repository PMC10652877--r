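#' Describe a synthetic seizure cohort
#'
#' A cohort specification is a tibble with one row per (patient, label)
#' combination: columns `patient_id`, `label`, `n_clips` and `split`
#' (`"train"` or `"test"`). [generate_cohort()] turns it into labelled clips
#' with per-patient parameter offsets and per-clip jitter.
#'
#' @param patient_id Character vector of patient identifiers.
#' @param label Seizure label per row.
#' @param n_clips Number of clips per row (>= 1).
#' @param split `"train"` or `"test"` per row.
#' @return A tibble usable as `spec` in [generate_cohort()].
#' @export
cohort_spec <- function(patient_id, label, n_clips, split = "train") {
  spec <- tibble::tibble(patient_id = as.character(patient_id),
                         label = as.character(label),
                         n_clips = as.integer(n_clips),
                         split = as.character(split))
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (nrow(spec) == 0) stop("empty cohort spec", call. = FALSE)
  stopifnot(all(c("patient_id", "label", "n_clips", "split") %in% names(spec)))
  if (!all(spec$label %in% SEIZURE_LABELS)) {
    stop("labels must be one of: ", paste(SEIZURE_LABELS, collapse = ", "),
         call. = FALSE)
  }
  if (any(spec$n_clips < 1)) stop("n_clips must be >= 1", call. = FALSE)
  if (!all(spec$split %in% c("train", "test"))) {
    stop("split must be 'train' or 'test'", call. = FALSE)
  }
  both <- tapply(spec$split, spec$patient_id, function(s) length(unique(s)))
  if (any(both > 1)) {
    stop("each patient must appear in exactly one split: ",
         paste(names(both)[both > 1], collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

#' Cohort specification mirroring a realistic clinical class imbalance
#'
#' Default cohort layout for a drug-resistant-epilepsy video-monitoring study:
#' the training arm holds 73 hyperkinetic (5 patients), 44 tonic (3) and 12
#' tonic-clonic (4) seizures; the testing arm 41/51/6 over 7/7/3 different
#' patients. Tonic-clonic seizures are deliberately scarce — class imbalance
#' is part of the study conditions, not an artefact.
#'
#' @param split `"train"`, `"test"` or `"both"`.
#' @return A cohort spec tibble.
#' @export
clinical_cohort_spec <- function(split = c("train", "test", "both")) {
  split <- match.arg(split)
  spread <- function(total, k) {
    base <- rep(total %/% k, k)
    if (total %% k > 0) base[seq_len(total %% k)] <- base[seq_len(total %% k)] + 1
    base
  }
  mk <- function(prefix, counts, phase) {
    rows <- list()
    pid <- 0
    for (lab in names(counts)) {
      cc <- counts[[lab]]
      for (i in seq_along(cc)) {
        pid <- pid + 1
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = sprintf("%s%02d", prefix, pid),
          label = lab, n_clips = cc[i], split = phase)
      }
    }
    dplyr::bind_rows(rows)
  }
  train <- mk("tr", list(hyperkinetic = spread(73, 5), tonic = spread(44, 3),
                         tonic_clonic = spread(12, 4)), "train")
  test <- mk("te", list(hyperkinetic = spread(41, 7), tonic = spread(51, 7),
                        tonic_clonic = spread(6, 3)), "test")
  out <- switch(split, train = train, test = test,
                both = dplyr::bind_rows(train, test))
  validate_cohort_spec(out)
  out
}

#' Generate a labelled synthetic seizure cohort
#'
#' Draws one multiplicative parameter offset per patient (inter-patient
#' variability) and additional jitter per clip, then renders every clip with
#' [generate_clip()]. Fully deterministic for a given `(spec, seed)` pair.
#'
#' @param spec Cohort spec tibble, see [cohort_spec()].
#' @param seed Integer seed controlling every random draw.
#' @param duration_range Clip durations are drawn uniformly (in seconds) from
#'   this range.
#' @param fps,frame_size,noise_sigma Shared rendering parameters, see
#'   [archetype_params()].
#' @param clonic_freq_hz Clonic frequency for tonic-clonic clips (Hz).
#' @param patient_sd,clip_sd Log-normal standard deviations of the per-patient
#'   offset and per-clip jitter applied to amplitude (and, halved, body size).
#' @param out_dir If non-`NULL`, clips and the manifest CSV are written there
#'   and the manifest's `path` column points at the frame-stack files.
#' @return A list with `manifest` (tibble: `clip_id`, `patient_id`, `label`,
#'   `duration_s`, `split`, `path`) and `clips` (named list of `seizure_clip`).
#' @export
generate_cohort <- function(spec, seed,
                            duration_range = c(10, 120),
                            fps = 30,
                            frame_size = c(240L, 320L),
                            noise_sigma = 2,
                            clonic_freq_hz = 3,
                            patient_sd = 0.15,
                            clip_sd = 0.08,
                            out_dir = NULL) {
  validate_cohort_spec(spec)
  stopifnot(length(duration_range) == 2, duration_range[1] > 0,
            duration_range[2] >= duration_range[1])
  with_seed(seed, {
    patients <- unique(spec$patient_id)
    offsets <- setNames(exp(rnorm(length(patients), 0, patient_sd)), patients)
    rows <- list(); clips <- list()
    for (i in seq_len(nrow(spec))) {
      row <- spec[i, ]
      for (j in seq_len(row$n_clips)) {
        dur <- runif(1, duration_range[1], duration_range[2])
        amp_mult <- offsets[[row$patient_id]] * exp(rnorm(1, 0, clip_sd))
        body_mult <- sqrt(offsets[[row$patient_id]])
        clip_seed <- sample.int(2147483646L, 1)
        sc <- frame_size[1] / 240
        base_amp <- switch(row$label, hyperkinetic = 45 * sc,
                           tonic = 20 * sc, tonic_clonic = 12 * sc)
        body <- round(c(80, 50) * sc * body_mult)
        # keep the jittered body inside the frame at all displacements
        room <- min(frame_size / 2 - body / 2 - 2)
        drift <- switch(row$label, hyperkinetic = 0, 0.5 * sc)
        amp_max <- switch(row$label,
          hyperkinetic = room,
          tonic = room - drift * dur,
          tonic_clonic = (room - drift * dur * 0.5) / 2)
        params <- archetype_params(
          label = row$label, duration_s = dur, fps = fps,
          frame_size = frame_size,
          body_size = body,
          amplitude_px = min(base_amp * amp_mult, 0.95 * amp_max),
          clonic_freq_hz = clonic_freq_hz,
          noise_sigma = noise_sigma,
          seed = clip_seed)
        clip_id <- sprintf("%s_%s_%02d", row$patient_id, row$label, j)
        clip <- generate_clip(params, clip_id = clip_id)
        path <- NA_character_
        if (!is.null(out_dir)) path <- write_clip(clip, out_dir)
        rows[[length(rows) + 1]] <- tibble::tibble(
          clip_id = clip_id, patient_id = row$patient_id, label = row$label,
          duration_s = dur, split = row$split, path = path)
        clips[[clip_id]] <- clip
      }
    }
    manifest <- dplyr::bind_rows(rows)
    stopifnot(!anyDuplicated(manifest$clip_id))
    if (!is.null(out_dir)) {
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
    }
    list(manifest = manifest, clips = clips)
  })
}

#' Read a cohort manifest CSV
#' @param path Path to a `manifest.csv` written by [generate_cohort()].
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("clip_id", "patient_id", "label", "duration_s", "split")
                %in% names(m)))
  m
}
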