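# Study design and token-level simulator.
#
# The simulated study mirrors a three-speaker consonant experiment: 12
# target consonants spanning five laryngeal classes (voiceless ejectives,
# voiceless pulmonics, voiced implosives, voiced pulmonics, nasals), each
# produced at two prosodic positions (phrase-initial, phrase-internal) with
# 7 repetitions, i.e. 168 tokens per speaker. Implosives are written with a
# leading apostrophe ('b, 'd), the Hausa orthographic convention for
# glottalized stops; ejectives carry a trailing apostrophe.

#' The default consonant inventory
#'
#' @return data frame with columns `consonant` and `class`.
#' @export
consonant_inventory <- function() {
  data.frame(
    consonant = c("b", "d", "'b", "'d", "k", "kw", "s",
                  "k'", "kw'", "s'", "m", "n"),
    class = c("voiced_pulmonic", "voiced_pulmonic",
              "voiced_implosive", "voiced_implosive",
              "voiceless_pulmonic", "voiceless_pulmonic", "voiceless_pulmonic",
              "voiceless_ejective", "voiceless_ejective", "voiceless_ejective",
              "nasal", "nasal"),
    stringsAsFactors = FALSE
  )
}

#' Define a multi-speaker study design
#'
#' @param speakers character vector of speaker labels.
#' @param consonants data frame with columns `consonant`, `class` (defaults
#'   to [consonant_inventory()]).
#' @param conditions prosodic conditions.
#' @param repetitions repetitions per consonant x condition.
#' @return a `study_design` object; `tokens_per_speaker` is derived.
#' @export
study_design <- function(speakers = c("S1", "S2", "S3"),
                         consonants = consonant_inventory(),
                         conditions = c("phrase_initial", "phrase_internal"),
                         repetitions = 7) {
  stopifnot(is.data.frame(consonants),
            all(c("consonant", "class") %in% names(consonants)))
  if (!is_count(repetitions)) stopf("repetitions must be a positive integer")
  if (anyDuplicated(consonants$consonant)) stopf("duplicate consonant labels")
  structure(list(speakers = speakers, consonants = consonants,
                 conditions = conditions, repetitions = as.integer(repetitions),
                 tokens_per_speaker =
                   nrow(consonants) * length(conditions) * repetitions),
            class = "study_design")
}

measure_names <- function() {
  c("lx_displacement_mm", "lx_extremum_mm", "onset_lag_ms",
    "target_lag_ms", "lx_duration_ms")
}

#' Default per-speaker, per-class distributional parameters
#'
#' Means and SDs for LX displacement and extremum (mm) and the two
#' intergestural lags (ms), per speaker and laryngeal class, as observed in
#' the three-speaker study the simulator emulates; lag parameters exist only
#' for the classes with an active laryngeal timing target (ejectives,
#' implosives, voiced pulmonics). LX duration has no published per-class
#' summary; defaults sit inside the reported 200-600 ms range for larynx
#' raising/lowering. `r_onset`/`r_target` couple the lags to LX duration
#' (correlation of the underlying normals); by default only voiced pulmonics
#' are coupled, emulating their duration-dependent lags.
#'
#' `omission_counts` gives, per speaker, the number of tokens (out of
#' `2 * repetitions` per consonant) without a quantifiable vertical larynx
#' movement, which the simulator marks as omitted.
#'
#' @return a `class_params` object: a list with data frame `cells`
#'   (speaker, class, and mean/sd per measure) and data frame
#'   `omission_counts` (speaker, consonant, n_omit).
#' @export
default_class_params <- function() {
  cells <- rbind(
    data.frame(speaker = c("S1", "S2", "S3"), class = "voiceless_ejective",
               disp_mean = c(5.33, 6.81, 3.33), disp_sd = c(4.5, 4.2, 2.1),
               ext_mean = c(25.87, 25.9, 30.54), ext_sd = c(4.6, 4.4, 2.9),
               onset_mean = c(70.55, 43.63, 78.63), onset_sd = c(90.2, 81.5, 92.5),
               target_mean = c(-43.53, -66.48, -31.44), target_sd = c(67.3, 71.4, 82.7),
               dur_mean = 350, dur_sd = 70, r_onset = 0, r_target = 0),
    data.frame(speaker = c("S1", "S2", "S3"), class = "voiceless_pulmonic",
               disp_mean = c(2.89, 6.65, 2.29), disp_sd = c(3.7, 3.3, 1.8),
               ext_mean = c(25.52, 23.43, 29.61), ext_sd = c(5.8, 2.3, 2.9),
               onset_mean = NA, onset_sd = NA, target_mean = NA, target_sd = NA,
               dur_mean = 350, dur_sd = 80, r_onset = 0, r_target = 0),
    data.frame(speaker = c("S1", "S2", "S3"), class = "voiced_implosive",
               disp_mean = c(-1.92, -4.79, -1.64), disp_sd = c(3.5, 4.4, 1.5),
               ext_mean = c(21.84, 18.12, 26.94), ext_sd = c(3.8, 4.9, 3.2),
               onset_mean = c(22.69, 102.50, 77.62), onset_sd = c(95.7, 53.2, 115.0),
               target_mean = c(-75.16, 0.85, -15.01), target_sd = c(101.6, 48.6, 121.3),
               dur_mean = 400, dur_sd = 80, r_onset = 0, r_target = 0),
    data.frame(speaker = c("S1", "S2", "S3"), class = "voiced_pulmonic",
               disp_mean = c(-0.62, -3.62, -1.91), disp_sd = c(4.5, 5.6, 2.8),
               ext_mean = c(20.68, 18.24, 26.27), ext_sd = c(5.2, 6.1, 4.1),
               onset_mean = c(-20.87, -11.53, -35.16), onset_sd = c(160.3, 119.0, 136.3),
               target_mean = c(-132.62, -122.0, -145.82), target_sd = c(136.8, 114.3, 140.0),
               dur_mean = 420, dur_sd = 90, r_onset = -0.54, r_target = 0.54),
    data.frame(speaker = c("S1", "S2", "S3"), class = "nasal",
               disp_mean = c(-1.5, -2.0, -1.0), disp_sd = c(3.0, 3.5, 2.0),
               ext_mean = c(22.0, 19.0, 27.0), ext_sd = c(4.5, 5.0, 3.5),
               onset_mean = NA, onset_sd = NA, target_mean = NA, target_sd = NA,
               dur_mean = 400, dur_sd = 90, r_onset = 0, r_target = 0)
  )
  omission_counts <- rbind(
    data.frame(speaker = "S1",
               consonant = c("m", "n", "'d", "b", "d", "k", "kw", "s", "kw'"),
               n_omit = c(8, 7, 1, 3, 2, 3, 1, 1, 2)),
    data.frame(speaker = "S2",
               consonant = c("m", "n", "b", "k", "kw", "kw'"),
               n_omit = c(2, 2, 3, 1, 2, 1))
  )
  structure(list(cells = cells, omission_counts = omission_counts),
            class = "class_params")
}

#' Simulate a token-level measure table
#'
#' Draws one row per token of the design. Measures come from normal
#' distributions with the speaker x class cell's mean and SD; the two lags
#' may be correlated with LX duration through the cell's `r_onset` /
#' `r_target` coefficients (`lag = mu + sd * (r * z_dur +
#' sqrt(1 - r^2) * z)`, with `z_dur` the standardised duration draw).
#' Classes without lag parameters get `NA` lags.
#'
#' Token omission (no quantifiable larynx movement) is marked in the
#' `omitted` column: with `omission = "counts"` exactly `n_omit` randomly
#' placed tokens per speaker x consonant are flagged; with
#' `omission = "bernoulli"` each token is flagged independently with
#' probability `n_omit / tokens-per-consonant`.
#'
#' @param design a [study_design()].
#' @param params a `class_params` object (see [default_class_params()]).
#' @param seed integer seed; identical seeds give identical tables.
#' @param omission omission model, `"counts"` or `"bernoulli"`.
#' @return a data frame (`measure_table`) with one row per token: speaker,
#'   consonant, class, condition, rep, the five kinematic measures, and
#'   `omitted`.
#' @export
generate_study_tokens <- function(design = study_design(),
                                  params = default_class_params(),
                                  seed = NULL,
                                  omission = c("counts", "bernoulli")) {
  stopifnot(inherits(design, "study_design"), inherits(params, "class_params"))
  omission <- match.arg(omission)
  cells <- params$cells
  need <- unique(expand.grid(speaker = design$speakers,
                             class = unique(design$consonants$class),
                             stringsAsFactors = FALSE))
  key <- paste(cells$speaker, cells$class)
  miss <- !(paste(need$speaker, need$class) %in% key)
  if (any(miss))
    stopf("missing cell parameters for: %s",
          paste(paste(need$speaker[miss], need$class[miss]), collapse = ", "))

  grid <- expand.grid(rep = seq_len(design$repetitions),
                      condition = design$conditions,
                      consonant = design$consonants$consonant,
                      speaker = design$speakers,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("speaker", "consonant", "condition", "rep")]
  grid$class <- design$consonants$class[match(grid$consonant,
                                              design$consonants$consonant)]
  n <- nrow(grid)
  idx <- match(paste(grid$speaker, grid$class), key)

  with_seed(seed, {
    z_dur <- stats::rnorm(n)
    grid$lx_displacement_mm <- stats::rnorm(n, cells$disp_mean[idx], cells$disp_sd[idx])
    grid$lx_extremum_mm <- stats::rnorm(n, cells$ext_mean[idx], cells$ext_sd[idx])
    grid$lx_duration_ms <- cells$dur_mean[idx] + cells$dur_sd[idx] * z_dur
    r1 <- cells$r_onset[idx]; r2 <- cells$r_target[idx]
    grid$onset_lag_ms <- cells$onset_mean[idx] + cells$onset_sd[idx] *
      (r1 * z_dur + sqrt(1 - r1^2) * stats::rnorm(n))
    grid$target_lag_ms <- cells$target_mean[idx] + cells$target_sd[idx] *
      (r2 * z_dur + sqrt(1 - r2^2) * stats::rnorm(n))

    grid$omitted <- FALSE
    oc <- params$omission_counts
    per_cons <- length(design$conditions) * design$repetitions
    for (j in seq_len(nrow(oc))) {
      rows <- which(grid$speaker == oc$speaker[j] &
                    grid$consonant == oc$consonant[j])
      if (!length(rows)) next
      if (omission == "counts") {
        k <- min(oc$n_omit[j], length(rows))
        grid$omitted[sample(rows, k)] <- TRUE
      } else {
        grid$omitted[rows] <- stats::runif(length(rows)) < oc$n_omit[j] / per_cons
      }
    }
    grid
  }) -> out
  out <- out[, c("speaker", "consonant", "class", "condition", "rep",
                 measure_names(), "omitted")]
  out$token_id <- sprintf("%s_%s_%s_r%d", out$speaker, out$consonant,
                          ifelse(out$condition == "phrase_initial", "PI", "PM"),
                          out$rep)
  rownames(out) <- NULL
  class(out) <- c("measure_table", "data.frame")
  out
}
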