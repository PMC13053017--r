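#' Prominence cue weights
#'
#' Weights of the composite prominence score
#' `S_i = W_F * zF_i + W_I * zI_i + W_D * zD_i`. The default weighs peak f0,
#' peak envelope amplitude and duration equally at 0.33 each; since the
#' nominated syllable is an argmax, any common positive rescaling of equal
#' weights (0.33 vs 1/3) leaves the nomination unchanged.
#'
#' @param w_f,w_i,w_d Non-negative weights for peak f0, peak amplitude and
#'   duration; not all zero.
#' @return A `prominence_weights` object.
#' @export
prominence_weights <- function(w_f = 0.33, w_i = 0.33, w_d = 0.33) {
  w <- c(f0 = w_f, intensity = w_i, duration = w_d)
  if (any(w < 0)) stop("prominence weights must be non-negative")
  if (all(w == 0)) stop("prominence weights must not all be zero")
  structure(as.list(w), class = "prominence_weights")
}

#' z-normalize a cue across the syllables of one utterance
#'
#' Centers to mean 0 and scales to unit sample standard deviation (n-1
#' denominator). A zero-variance cue returns all zeros: it is neutral for
#' the composite score rather than undefined.
#'
#' @param values Numeric vector, length >= 2.
#' @return z-scores of the same length.
#' @export
z_normalize <- function(values) {
  if (length(values) < 2) stop("insufficient data: z-normalization needs >= 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(values)))
  (values - mean(values)) / s
}

#' Composite prominence scores from z-scored cues
#'
#' @param z_f,z_i,z_d Per-syllable z-scores of peak f0, peak envelope
#'   amplitude and duration (missing-f0 policy already applied, so `z_f`
#'   contains no `NA`).
#' @param weights A [prominence_weights()] object.
#' @return Numeric vector of scores `S_i`.
#' @export
score_syllables <- function(z_f, z_i, z_d, weights = prominence_weights()) {
  stopifnot(inherits(weights, "prominence_weights"))
  n <- length(z_d)
  if (n < 2) stop("insufficient data: need >= 2 syllables")
  stopifnot(length(z_f) == n, length(z_i) == n)
  if (anyNA(z_f) || anyNA(z_i) || anyNA(z_d))
    stop("z-scores contain NA; apply the missing-f0 policy first")
  weights$f0 * z_f + weights$intensity * z_i + weights$duration * z_d
}

#' Nominate the acoustically most prominent syllable
#'
#' Index of the highest composite score; exact ties resolve to the earliest
#' syllable (deterministic).
#'
#' @param scores Numeric score vector, length >= 2.
#' @return 1-based index of the nominated syllable.
#' @export
nominate <- function(scores) {
  if (length(scores) < 2) stop("insufficient data: need >= 2 syllables")
  which.max(scores)
}

#' Score an utterance's syllables and nominate the most prominent one
#'
#' z-normalizes the three cues within the utterance, applies the missing-f0
#' policy, computes the weighted composite scores and the envelope-peak time
#' of the nominated syllable.
#'
#' The missing-f0 policy: a syllable with no voiced frame receives the
#' minimum f0 z-score among the utterance's voiced syllables, so absent
#' voicing can never win prominence through the f0 cue; the utterance is
#' flagged. If fewer than two syllables are voiced, the f0 cue is neutral
#' (all zeros).
#'
#' @param env An `envelope_track`.
#' @param pitch A `pitch_track`.
#' @param syllables Syllable interval tibble.
#' @param weights A [prominence_weights()].
#' @return A `prominence_result`: list with `cues` (the cue tibble augmented
#'   with `z_f`, `z_i`, `z_d`, `score`), `nominated` (1-based), `peak_env_time`
#'   (s) and `flags` (character vector).
#' @export
analyze_prominence <- function(env, pitch, syllables,
                               weights = prominence_weights()) {
  cues <- extract_syllable_cues(env, pitch, syllables)
  if (nrow(cues) < 2) stop("insufficient data: need >= 2 syllables")
  flags <- character()

  z_d <- z_normalize(cues$duration)
  z_i <- z_normalize(cues$env_peak)
  voiced <- !cues$f0_missing
  z_f <- rep(0, nrow(cues))
  if (sum(voiced) >= 2) {
    zv <- z_normalize(cues$f0_peak[voiced])
    z_f[voiced] <- zv
    if (any(!voiced)) {
      z_f[!voiced] <- min(zv)
      flags <- c(flags, "f0_missing")
    }
  } else if (any(!voiced)) {
    flags <- c(flags, "f0_mostly_unvoiced")
  }

  s <- score_syllables(z_f, z_i, z_d, weights)
  nom <- nominate(s)
  cues$z_f <- z_f; cues$z_i <- z_i; cues$z_d <- z_d; cues$score <- s
  structure(list(
    cues = cues,
    nominated = nom,
    peak_env_time = envelope_peak_time(env, syllables[nom, ]),
    flags = flags
  ), class = "prominence_result")
}

#' @export
print.prominence_result <- function(x, ...) {
  cat(sprintf("<prominence_result> nominated syllable %d ('%s'), envelope peak at %.3f s\n",
              x$nominated, x$cues$label[x$nominated], x$peak_env_time))
  print(x$cues)
  invisible(x)
}
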