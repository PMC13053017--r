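#' Default cognate item table
#'
#' 96 two-language cognate items: 48 *matching* (L1 and L2 stress on the
#' same syllable) and 48 *mismatching* (24 with the L1 competitor syllable
#' preceding the L2 target, 24 following), half of each group carrying an
#' orthographic accent mark. Word lengths span 2-5 syllables and every
#' condition class contains items whose target syllable is word-internal, so
#' the robustness filter that drops initial/final-stress items leaves all
#' conditions populated. Words are synthetic pseudo-cognates built from a
#' fixed syllable inventory.
#'
#' @return Tibble with columns `item_id`, `word`, `n_syll`, `target_syll`
#'   (1-based L2 stressed syllable), `competitor_syll` (1-based L1 stressed
#'   syllable), `matching`, `accent_mark` and `distance`
#'   (`competitor_syll - target_syll`).
#' @export
default_item_table <- function() {
  if (!is.null(.promkin_cache$items)) return(.promkin_cache$items)
  # (n_syll, target) patterns for matching items
  match_pat <- list(c(2, 1), c(2, 2), c(3, 1), c(3, 2), c(3, 3), c(4, 1),
                    c(4, 2), c(4, 3), c(4, 4), c(5, 2), c(5, 3), c(5, 4))
  # (n_syll, target, competitor) with competitor preceding the target
  # mismatching items are >= 3 syllables so that all three production
  # classes (target / competitor / other syllable) exist for every item
  pre_pat <- list(c(3, 3, 2), c(3, 2, 1), c(3, 3, 1), c(4, 3, 2), c(4, 4, 2),
                  c(4, 3, 1), c(4, 2, 1), c(5, 3, 2), c(5, 4, 2), c(5, 3, 1),
                  c(5, 4, 1), c(4, 4, 3))
  # competitor following the target (mirror of pre_pat)
  fol_pat <- lapply(pre_pat, function(p) c(p[1], p[1] + 1 - p[2], p[1] + 1 - p[3]))

  inv <- c("ba", "ca", "de", "fo", "gu", "la", "me", "ni", "po", "ra",
           "so", "te", "vi", "mu", "do", "ri")
  make_word <- function(n, i) paste(inv[((i * 5 + seq_len(n) * 3) %% length(inv)) + 1L],
                                    collapse = "")
  rows <- list()
  add <- function(pat, matching, k) {
    n <- pat[1]; tg <- pat[2]
    cp <- if (matching) pat[2] else pat[3]
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      n_syll = n, target_syll = tg, competitor_syll = cp, matching = matching)
  }
  for (k in 1:48) add(match_pat[[(k - 1) %% 12 + 1]], TRUE, k)
  for (k in 1:24) add(pre_pat[[(k - 1) %% 12 + 1]], FALSE, k)
  for (k in 1:24) add(fol_pat[[(k - 1) %% 12 + 1]], FALSE, k)
  items <- dplyr::bind_rows(rows)
  items$item_id <- sprintf("item%03d", seq_len(nrow(items)))
  items$word <- vapply(seq_len(nrow(items)),
                       function(i) make_word(items$n_syll[i], i), character(1))
  items$accent_mark <- rep(c(TRUE, FALSE), length.out = nrow(items))
  items$distance <- items$competitor_syll - items$target_syll
  items <- items[, c("item_id", "word", "n_syll", "target_syll", "competitor_syll",
                     "matching", "accent_mark", "distance")]
  .promkin_cache$items <- items
  items
}

.promkin_cache <- new.env(parent = emptyenv())

#' Read / write an item table
#'
#' Comma-delimited with the columns of [default_item_table()] (`matching`
#' and `distance` are recomputed if absent).
#'
#' @param path File path.
#' @return A tibble of items.
#' @export
read_item_table <- function(path) {
  if (!file.exists(path)) stop("item table not found: ", path)
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("item_id", "word", "n_syll", "target_syll", "competitor_syll")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("item table is missing columns: ", paste(miss, collapse = ", "))
  if (any(d$target_syll > d$n_syll | d$competitor_syll > d$n_syll |
          d$target_syll < 1 | d$competitor_syll < 1))
    stop("item table has stress positions outside 1..n_syll")
  d$matching <- d$target_syll == d$competitor_syll
  d$distance <- d$competitor_syll - d$target_syll
  d
}

#' @rdname read_item_table
#' @param items Item tibble.
#' @export
write_item_table <- function(items, path) {
  utils::write.csv(as.data.frame(items), path, row.names = FALSE)
  invisible(path)
}

#' Classify a produced prominence pattern
#'
#' `correct_L2` when the nominated syllable is the L2 target, `incorrect_L1`
#' when it is the (distinct) L1 competitor, `other` otherwise. Vectorized.
#'
#' @param nominated 1-based nominated syllable index (vector).
#' @param target_syll,competitor_syll 1-based stress positions (vectors
#'   recycled to `nominated`).
#' @return Character vector of production classes.
#' @export
classify_production <- function(nominated, target_syll, competitor_syll) {
  dplyr::case_when(
    nominated == target_syll ~ "correct_L2",
    nominated == competitor_syll ~ "incorrect_L1",
    TRUE ~ "other"
  )
}

#' Gesture-speech asynchrony in milliseconds
#'
#' `(t_ext - t_peak_env) * 1000`: positive values mean the hand apex
#' followed the speech envelope peak, negative that it preceded it.
#'
#' @param t_ext Apex (maximum extension) time, seconds.
#' @param t_peak_env Envelope-peak time of the prominent syllable, seconds.
#' @return Signed asynchrony in ms.
#' @export
compute_asynchrony <- function(t_ext, t_peak_env) {
  (t_ext - t_peak_env) * 1000
}

#' Label the timing-analysis condition of a trial
#'
#' Conditions encode where the cross-linguistic attractor syllable lies
#' relative to the produced (anchor) syllable:
#' \itemize{
#'   \item matching item, correct production: `matching_correct` (baseline);
#'   \item mismatching, correct: the attractor is the L1 competitor, so
#'     `precede_correct` when the competitor precedes the target, else
#'     `follow_correct`;
#'   \item mismatching, competitor-stressed (`incorrect_L1`): the attractor
#'     is the L2 target, so `precede_incorrect` when the target precedes the
#'     competitor, else `follow_incorrect`;
#'   \item everything else (`other` productions, matching items produced
#'     off-target): `excluded`.
#' }
#' Vectorized over trials.
#'
#' @param matching Logical: L1 and L2 stress coincide.
#' @param target_syll,competitor_syll 1-based stress positions.
#' @param production_class From [classify_production()].
#' @return Character vector of condition labels.
#' @export
label_condition <- function(matching, target_syll, competitor_syll,
                            production_class) {
  dplyr::case_when(
    matching & production_class == "correct_L2" ~ "matching_correct",
    !matching & production_class == "correct_L2" &
      competitor_syll < target_syll ~ "precede_correct",
    !matching & production_class == "correct_L2" ~ "follow_correct",
    !matching & production_class == "incorrect_L1" &
      target_syll < competitor_syll ~ "precede_incorrect",
    !matching & production_class == "incorrect_L1" ~ "follow_incorrect",
    TRUE ~ "excluded"
  )
}

condition_levels <- c("matching_correct", "precede_correct", "follow_correct",
                      "precede_incorrect", "follow_incorrect")
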