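#' @importFrom tibble tibble
NULL

# Parse all interval tiers of a Praat TextGrid (long or short text format).
# Returns a named list of tibbles (start, end, label), one per interval tier.
parse_textgrid <- function(path) {
  if (!file.exists(path)) stop("TextGrid file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))])))
    stop("not a Praat TextGrid (missing ooTextFile header): ", path)
  long <- any(grepl("item\\s*\\[", lines))
  if (long) parse_textgrid_long(lines) else parse_textgrid_short(lines)
}

tg_unquote <- function(x) {
  x <- sub('^\\s*"', "", x)
  x <- sub('"\\s*$', "", x)
  gsub('""', '"', x)
}

parse_textgrid_long <- function(lines) {
  tiers <- list()
  item_at <- grep("^\\s*item\\s*\\[\\d+\\]", lines)
  bounds <- c(item_at, length(lines) + 1L)
  for (k in seq_along(item_at)) {
    block <- lines[item_at[k]:(bounds[k + 1L] - 1L)]
    cls <- tg_unquote(sub(".*class\\s*=\\s*", "", grep("class\\s*=", block, value = TRUE)[1]))
    nm <- tg_unquote(sub(".*name\\s*=\\s*", "", grep("name\\s*=", block, value = TRUE)[1]))
    if (!identical(cls, "IntervalTier")) next
    iv_at <- grep("^\\s*intervals\\s*\\[\\d+\\]", block)
    starts <- ends <- numeric(length(iv_at))
    labels <- character(length(iv_at))
    iv_bounds <- c(iv_at, length(block) + 1L)
    for (j in seq_along(iv_at)) {
      b <- block[iv_at[j]:(iv_bounds[j + 1L] - 1L)]
      starts[j] <- as.numeric(sub(".*xmin\\s*=\\s*", "", grep("xmin\\s*=", b, value = TRUE)[1]))
      ends[j] <- as.numeric(sub(".*xmax\\s*=\\s*", "", grep("xmax\\s*=", b, value = TRUE)[1]))
      labels[j] <- tg_unquote(sub(".*text\\s*=\\s*", "", grep("text\\s*=", b, value = TRUE)[1]))
    }
    tiers[[nm]] <- tibble::tibble(start = starts, end = ends, label = labels)
  }
  tiers
}

parse_textgrid_short <- function(lines) {
  # short format: after the 2 header lines and blank, a flat token stream
  toks <- trimws(lines)
  toks <- toks[nzchar(toks)]
  toks <- toks[-(1:2)]                     # File type, Object class
  pos <- 1L
  nxt <- function() { v <- toks[pos]; pos <<- pos + 1L; v }
  nxt(); nxt()                             # global xmin, xmax
  nxt()                                    # <exists>
  n_tiers <- as.integer(nxt())
  tiers <- list()
  for (k in seq_len(n_tiers)) {
    cls <- tg_unquote(nxt())
    nm <- tg_unquote(nxt())
    nxt(); nxt()                           # tier xmin, xmax
    n <- as.integer(nxt())
    if (identical(cls, "IntervalTier")) {
      starts <- ends <- numeric(n)
      labels <- character(n)
      for (j in seq_len(n)) {
        starts[j] <- as.numeric(nxt())
        ends[j] <- as.numeric(nxt())
        labels[j] <- tg_unquote(nxt())
      }
      tiers[[nm]] <- tibble::tibble(start = starts, end = ends, label = labels)
    } else {
      for (j in seq_len(n)) { nxt(); nxt() }   # point tier: time, mark
    }
  }
  tiers
}

#' Read a syllable interval tier from a Praat TextGrid
#'
#' Parses either the long or the short TextGrid text format, selects the
#' named interval tier, and returns its non-empty intervals time-ordered.
#' Intervals whose label is empty or whitespace-only (silences, as emitted by
#' forced aligners) are dropped.
#'
#' @param path Path to a `.TextGrid` file.
#' @param tier_name Name of the interval tier holding syllable boundaries.
#' @return A tibble with columns `start`, `end` (seconds) and `label`.
#' @export
read_syllable_tier <- function(path, tier_name = "syllables") {
  tiers <- parse_textgrid(path)
  if (!tier_name %in% names(tiers))
    stop("TextGrid has no interval tier named '", tier_name, "' (found: ",
         paste(names(tiers), collapse = ", "), ")")
  iv <- tiers[[tier_name]]
  iv <- iv[!grepl("^\\s*$", iv$label), , drop = FALSE]
  iv <- iv[order(iv$start), , drop = FALSE]
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  if (nrow(iv) == 0) return(invisible(iv))
  if (any(iv$end <= iv$start)) stop("malformed syllable tier: interval with end <= start")
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-9))
    stop("malformed syllable tier: overlapping intervals")
  invisible(iv)
}

#' Write a single-tier Praat TextGrid (long text format)
#'
#' Gaps between consecutive labelled intervals (and any lead-in/lead-out)
#' are filled with empty-label intervals so the tier tiles `[0, xmax]`, as
#' Praat requires.
#'
#' @param intervals Tibble/data.frame with `start`, `end`, `label`.
#' @param path Output path.
#' @param tier_name Tier name to write.
#' @param xmax Total duration of the annotated object (defaults to the last
#'   interval end).
#' @return `path`, invisibly.
#' @export
write_syllable_tier <- function(intervals, path, tier_name = "syllables",
                                xmax = NULL) {
  iv <- intervals[order(intervals$start), , drop = FALSE]
  validate_intervals(iv)
  if (is.null(xmax)) xmax <- if (nrow(iv)) max(iv$end) else 1
  # fill gaps with empty intervals
  full <- list()
  cur <- 0
  for (j in seq_len(nrow(iv))) {
    if (iv$start[j] > cur + 1e-9)
      full[[length(full) + 1L]] <- c(cur, iv$start[j], "")
    full[[length(full) + 1L]] <- c(iv$start[j], iv$end[j], iv$label[j])
    cur <- iv$end[j]
  }
  if (xmax > cur + 1e-9) full[[length(full) + 1L]] <- c(cur, xmax, "")
  if (!length(full)) full[[1L]] <- c(0, xmax, "")

  num <- function(x) format(as.numeric(x), digits = 12, scientific = FALSE, trim = TRUE)
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    paste0("xmax = ", num(xmax)),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    paste0('        name = "', tier_name, '"'),
    "        xmin = 0",
    paste0("        xmax = ", num(xmax)),
    paste0("        intervals: size = ", length(full))
  )
  for (j in seq_along(full)) {
    f <- full[[j]]
    out <- c(out,
             paste0("        intervals [", j, "]:"),
             paste0("            xmin = ", num(f[1])),
             paste0("            xmax = ", num(f[2])),
             paste0('            text = "', gsub('"', '""', f[3]), '"'))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
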