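#' Channel vocabulary
#'
#' Automated expression coders in the CERT/FACET family emit, per video frame,
#' proportion codes for seven emotion categories plus neutral (constrained to
#' sum to 1) and unconstrained nonnegative intensities for individual facial
#' action units (AUs). These constants fix the canonical channel vocabulary
#' used throughout the package.
#'
#' @format Character vectors of channel labels.
#' @name channels
NULL

#' @rdname channels
#' @export
EMOTION_CHANNELS <- c("anger", "contempt", "disgust", "fear",
                      "happiness", "sadness", "surprise")

#' @rdname channels
#' @export
NEUTRAL_CHANNEL <- "neutral"

#' @rdname channels
#' @export
SIMPLEX_CHANNELS <- c(EMOTION_CHANNELS, NEUTRAL_CHANNEL)

#' Six basic emotions scored in the production task (contempt is coded by the
#' software but never a production target).
#' @rdname channels
#' @export
BASIC_EMOTIONS <- c("anger", "disgust", "fear", "happiness", "sadness",
                    "surprise")

#' Calibration movement types and the action unit each one isolates.
#'
#' Movement 1 pulls the eyebrows together (brow lowerer, AU4); 2 raises the
#' eyebrows (outer brow raiser, AU2); 3 wrinkles the nose (nose wrinkler,
#' AU9); 5 raises the mouth corners (lip corner puller, AU12); 6 lowers them
#' (lip corner depressor, AU15). Movement 4 (nostril widening) has no single
#' associated AU and is excluded from the plasticity composite.
#'
#' @return Named character vector mapping movement kind to AU label.
#' @export
#' @examples
#' au_calibration_map()
au_calibration_map <- function() {
  c(movement_1 = "AU4", movement_2 = "AU2", movement_3 = "AU9",
    movement_5 = "AU12", movement_6 = "AU15")
}

#' @rdname channels
#' @export
AU_CHANNELS <- c("AU4", "AU2", "AU9", "AU12", "AU15")

TASKS <- c("calibration_pre", "production", "calibration_post")
MOVEMENT_KINDS <- paste0("movement_", 1:6)
TRIAL_KINDS <- c("baseline", MOVEMENT_KINDS, BASIC_EMOTIONS)
SCORE_METHODS <- c("arith", "geom", "avg_auc", "max")
TREATMENTS <- c("untreated", "loess", "loess_base", "loess_base_plast")
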