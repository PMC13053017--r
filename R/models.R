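#' @importFrom stats as.formula pnorm qnorm
NULL

# Fit a (generalized) linear mixed model with random intercepts for speaker
# and item, falling back to a fixed-effects-only fit if lme4 errors (e.g. on
# degenerate zero-variance data). Returns a promkin_fit.
fit_mixed <- function(fixed, data, family = NULL, alpha = 0.016,
                      random = c("speaker_id", "item_id")) {
  re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  form <- as.formula(paste(fixed, "+", re))
  fallback <- FALSE
  messages <- character()
  fit <- withCallingHandlers(
    tryCatch({
      if (is.null(family)) {
        lme4::lmer(form, data = data,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      } else {
        lme4::glmer(form, data = data, family = family,
                    control = lme4::glmerControl(check.conv.singular = "ignore"))
      }
    }, error = function(e) {
      fallback <<- TRUE
      messages <<- c(messages, conditionMessage(e))
      if (is.null(family)) stats::lm(as.formula(fixed), data = data)
      else stats::glm(as.formula(fixed), data = data, family = family)
    }),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  co <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  vc <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(vc))
  z <- co / se
  p <- 2 * pnorm(-abs(z))
  conv_msgs <- if (inherits(fit, "merMod")) unlist(fit@optinfo$conv$lme4$messages) else NULL
  structure(list(
    terms = tibble::tibble(
      term = names(co), estimate = unname(co), se = unname(se),
      z = unname(z), p = unname(p),
      conf_low = unname(co - qnorm(0.975) * se),
      conf_high = unname(co + qnorm(0.975) * se),
      significant = unname(p < alpha)
    ),
    alpha = alpha,
    n = nrow(data),
    converged = !fallback && is.null(conv_msgs),
    notes = unique(c(messages, conv_msgs)),
    model = fit
  ), class = "promkin_fit")
}

#' @export
print.promkin_fit <- function(x, ...) {
  cat(sprintf("<promkin_fit> n = %d, alpha = %g%s\n", x$n, x$alpha,
              if (!x$converged) " [convergence flagged]" else ""))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Tidy the terms of a model fit
#' @param fit A `promkin_fit`.
#' @return The `terms` tibble (term, estimate, se, z, p, CI, significance).
#' @export
tidy_fit <- function(fit) {
  stopifnot(inherits(fit, "promkin_fit"))
  fit$terms
}

prepare_timing_trials <- function(records) {
  d <- records[records$movement & !is.na(records$asynchrony_ms) &
                 records$condition %in% condition_levels, , drop = FALSE]
  d$condition <- factor(d$condition, levels = condition_levels)
  d$condition <- droplevels(d$condition)
  d
}

#' Mixed model of asynchrony on condition
#'
#' Linear mixed model (identity link: the outcome is in ms) of gesture-speech
#' asynchrony on the five-level timing condition, without intercept so each
#' condition gets its own estimate, with random intercepts for speaker and
#' item. p-values use the large-sample normal approximation on
#' estimate/standard-error ratios; significance is judged against `alpha`
#' (default 0.016, a three-test-adjusted level).
#'
#' @param records Trial table (see [trial_table]); only movement trials with
#'   a defined asynchrony in a modeled condition enter the fit.
#' @param alpha Significance level.
#' @param random Grouping columns receiving random intercepts.
#' @return A `promkin_fit`; term names are the condition labels.
#' @export
fit_condition_model <- function(records, alpha = 0.016,
                                random = c("speaker_id", "item_id")) {
  d <- prepare_timing_trials(records)
  if (length(unique(d$speaker_id)) < 2 || length(unique(d$item_id)) < 2)
    stop("insufficient data: need >= 2 speakers and >= 2 items")
  fit <- fit_mixed("asynchrony_ms ~ 0 + condition", d, alpha = alpha, random = random)
  fit$terms$term <- sub("^condition", "", fit$terms$term)
  fit
}

#' Mixed model of asynchrony on signed stress distance (gradient attraction)
#'
#' Fits asynchrony on the signed syllable distance between the L1 competitor
#' and the L2 target (`competitor - target`; negative = competitor precedes)
#' over correctly produced mismatching movement trials, with random
#' intercepts for speaker and item. The slope measures how strongly the
#' competitor syllable pulls the hand apex per syllable of separation.
#'
#' @inheritParams fit_condition_model
#' @return A `promkin_fit`; the slope term is named `distance`.
#' @export
fit_gradient_model <- function(records, alpha = 0.016,
                               random = c("speaker_id", "item_id")) {
  d <- records[records$movement & !is.na(records$asynchrony_ms) &
                 records$condition %in% c("precede_correct", "follow_correct"), ,
               drop = FALSE]
  if (nrow(d) < 4) stop("insufficient data: too few mismatching correct movement trials")
  if (length(unique(d$distance)) < 2)
    stop("parameter error: stress distance is constant; gradient model is unidentified")
  fit_mixed("asynchrony_ms ~ distance", d, alpha = alpha, random = random)
}

#' Does producing a hand movement boost peak intensity?
#'
#' Linear mixed model of the prominent syllable's peak envelope amplitude on
#' the movement flag, with random intercepts for speaker and item. A positive
#' significant movement term indicates biomechanical intensity coupling.
#'
#' @inheritParams fit_condition_model
#' @return A `promkin_fit`; the effect term is `movementTRUE`.
#' @export
movement_boost_test <- function(records, alpha = 0.016,
                                random = c("speaker_id", "item_id")) {
  d <- records[!is.na(records$peak_intensity), , drop = FALSE]
  if (length(unique(d$movement)) < 2)
    stop("parameter error: need both movement and no-movement trials")
  fit_mixed("peak_intensity ~ movement", d, alpha = alpha, random = random)
}

#' Does producing a hand movement change production accuracy?
#'
#' Logistic mixed model of correct L2 prominence placement (binary) on the
#' movement flag, random intercepts for speaker and item.
#'
#' @inheritParams fit_condition_model
#' @return A `promkin_fit` on the log-odds scale.
#' @export
accuracy_by_movement_test <- function(records, alpha = 0.016,
                                      random = c("speaker_id", "item_id")) {
  d <- records[!is.na(records$production_class), , drop = FALSE]
  if (length(unique(d$movement)) < 2)
    stop("parameter error: need both movement and no-movement trials")
  d$correct <- as.integer(d$production_class == "correct_L2")
  fit_mixed("correct ~ movement", d, family = stats::binomial(), alpha = alpha,
            random = random)
}

#' Agreement between nominated prominence and annotated lexical stress
#'
#' Fraction of trials in which the acoustically nominated syllable equals an
#' independently annotated phonologically stressed syllable (used to verify
#' the metric on native productions).
#'
#' @param records Trial table with `item_id` and `nominated`.
#' @param stress_annotation Tibble with `item_id` and `stress_syll` (1-based)
#'   covering every item in `records`.
#' @return Proportion in `[0, 1]`.
#' @export
verification_agreement <- function(records, stress_annotation) {
  need <- c("item_id", "stress_syll")
  if (!all(need %in% names(stress_annotation)))
    stop("stress_annotation needs columns item_id and stress_syll")
  m <- match(records$item_id, stress_annotation$item_id)
  if (anyNA(m)) stop("data error: missing stress annotation for some items")
  mean(records$nominated == stress_annotation$stress_syll[m])
}

#' Asynchrony anchored to the phonological target syllable
#'
#' Recomputes per-trial asynchrony against the envelope peak inside the L2
#' target syllable's interval, irrespective of which syllable the acoustic
#' metric nominated. This makes the timing analysis independent of the
#' produced prominence cues.
#'
#' @param records Trial table carrying `t_ext` and `t_peak_env_target`.
#' @return Numeric vector of asynchronies (ms), `NA` on no-movement trials.
#' @export
phonological_anchor_asynchrony <- function(records) {
  if (!all(c("t_ext", "t_peak_env_target") %in% names(records)))
    stop("records lack t_ext / t_peak_env_target columns")
  compute_asynchrony(records$t_ext, records$t_peak_env_target)
}

#' Drop items with word-initial or word-final L2 stress
#'
#' Robustness filter: restricting the trial set to items whose target
#' syllable is word-internal checks that condition estimates are not driven
#' by edge-of-word stress positions.
#'
#' @param records Trial table.
#' @param items Item table with `item_id`, `target_syll`, `n_syll`.
#' @return The filtered trial table.
#' @export
filter_interior_stress <- function(records, items) {
  keep <- items$item_id[items$target_syll > 1 & items$target_syll < items$n_syll]
  records[records$item_id %in% keep, , drop = FALSE]
}
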