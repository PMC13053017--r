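#' Trial-table column schema
#'
#' One row per produced word (trial). Columns:
#' \describe{
#'   \item{speaker_id, item_id}{identifiers.}
#'   \item{movement}{logical; was the trial produced with the biphasic hand
#'     movement?}
#'   \item{block}{block index within the speaker's session.}
#'   \item{n_syll}{syllable count of the item.}
#'   \item{nominated}{1-based index of the acoustically most prominent
#'     syllable.}
#'   \item{production_class}{`correct_L2`, `incorrect_L1` or `other`.}
#'   \item{condition}{`matching_correct`, `precede_correct`, `follow_correct`,
#'     `precede_incorrect`, `follow_incorrect` or `excluded`.}
#'   \item{distance}{signed syllable distance, competitor minus target.}
#'   \item{t_peak_env}{envelope-peak time (s) within the nominated syllable.}
#'   \item{t_peak_env_target}{envelope-peak time (s) within the phonological
#'     L2 target syllable, regardless of nomination.}
#'   \item{t_ext}{apex (maximum extension) time in seconds; `NA` on
#'     no-movement trials.}
#'   \item{asynchrony_ms}{`(t_ext - t_peak_env) * 1000`; negative = hand
#'     leads speech.}
#'   \item{asynchrony_anchor_ms}{asynchrony against the target-syllable
#'     envelope peak.}
#'   \item{peak_intensity}{peak envelope amplitude (arbitrary units) of the
#'     nominated syllable.}
#'   \item{flags}{semicolon-separated quality flags, empty when clean.}
#' }
#' @name trial_table
NULL

trial_table_columns <- c(
  "speaker_id", "item_id", "movement", "block", "n_syll", "nominated",
  "production_class", "condition", "distance", "t_peak_env",
  "t_peak_env_target", "t_ext", "asynchrony_ms", "asynchrony_anchor_ms",
  "peak_intensity", "flags"
)

#' Write a trial table to a comma-delimited file
#'
#' Missing values are written as empty fields and restored as `NA` by
#' [read_trial_table()]. See [trial_table] for the column schema.
#'
#' @param records Tibble of trial records sharing one schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(records, path) {
  keep <- intersect(trial_table_columns, names(records))
  extra <- setdiff(names(records), keep)
  out <- as.data.frame(records[, c(keep, extra), drop = FALSE])
  status <- try(utils::write.csv(out, path, row.names = FALSE, na = ""),
                silent = TRUE)
  if (inherits(status, "try-error")) stop("cannot write trial table to ", path)
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#'
#' @param path Path to the comma-delimited trial table.
#' @return A tibble of trial records.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("trial table not found: ", path)
  d <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  for (col in c("movement")) if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  if ("flags" %in% names(d)) d$flags[is.na(d$flags)] <- ""
  tibble::as_tibble(d)
}
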