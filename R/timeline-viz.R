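#' Specify a patient attribution timeline
#'
#' One row of colored squares per model (LSTM above BiLSTM, when both
#' are given), one square per visit, with an optional highlighted
#' most-predictive subset.
#'
#' @param record a [patient_record()].
#' @param scores named list of numeric per-visit score vectors, e.g.
#'   `list(lstm = ..., bilstm = ...)`; each of length `T`.
#' @param subset optional integer vector of visit ordinals to outline
#'   (the most predictive subset `X_S`).
#' @return a `timeline_spec`.
#' @export
timeline_spec <- function(record, scores, subset = NULL) {
  stopifnot(is.list(scores), length(scores) >= 1L, !is.null(names(scores)))
  T_p <- n_visits(record)
  for (nm in names(scores)) {
    if (length(scores[[nm]]) != T_p)
      stop("score row '", nm, "' has length ", length(scores[[nm]]),
           ", expected ", T_p)
    if (!all(is.finite(scores[[nm]]))) stop("non-finite scores in row '", nm, "'")
  }
  if (!is.null(subset) && (min(subset) < 1L || max(subset) > T_p))
    stop("highlighted subset outside 1..", T_p)
  structure(list(record = record, scores = scores,
                 subset = as.integer(subset)), class = "timeline_spec")
}

#' Map a score to a diverging hex color
#'
#' Symmetric blue-white-red scale anchored at zero: zero is white,
#' positive scores warm toward red and negative scores cool toward
#' blue, linearly in `score / max_abs`. Monotone in the score.
#'
#' @param score numeric vector.
#' @param max_abs positive normalization constant (row maximum absolute
#'   score); if 0, everything is neutral.
#' @return character vector of `#RRGGBB` colors.
#' @export
score_to_color <- function(score, max_abs) {
  v <- if (max_abs > 0) pmax(pmin(score / max_abs, 1), -1) else rep(0, length(score))
  ch <- function(x) as.integer(round(255 * x))
  ifelse(v >= 0,
         sprintf("#FF%02X%02X", ch(1 - v), ch(1 - v)),
         sprintf("#%02X%02XFF", ch(1 + v), ch(1 + v)))
}

#' Render a patient attribution timeline as static HTML
#'
#' Writes a self-contained HTML file (no network resources): one row of
#' squares per model, each square labeled with the visit ordinal and
#' age, colored on a diverging scale anchored at zero and normalized by
#' the row's maximum absolute score, with the visit's diagnosis codes
#' in a `title` tooltip. Squares of the highlighted subset get a yellow
#' outline. Rendering is deterministic: the same spec yields
#' byte-identical output.
#'
#' @param spec a [timeline_spec()].
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
render_timeline <- function(spec, path) {
  stopifnot(inherits(spec, "timeline_spec"))
  r <- spec$record
  T_p <- n_visits(r)
  if (T_p == 0L) stop("cannot render an empty timeline")
  ages <- visit_ages(r)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  row_html <- vapply(names(spec$scores), function(nm) {
    s <- spec$scores[[nm]]
    cols <- score_to_color(s, max(abs(s)))
    squares <- vapply(seq_len(T_p), function(t) {
      hl <- if (t %in% spec$subset) " highlight" else ""
      sprintf(paste0("<div class=\"sq%s\" style=\"background:%s\" ",
                     "title=\"%s\"><span>%d</span><small>%.1fy</small></div>"),
              hl, cols[t],
              esc(paste(sort(r$visits[[t]]$codes), collapse = "; ")),
              t, ages[t])
    }, character(1))
    sprintf("<div class=\"row\"><span class=\"label\">%s</span>%s</div>",
            esc(nm), paste(squares, collapse = ""))
  }, character(1))
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>Visit attribution timeline: %s</title>", esc(r$patient_id)),
    "<style>",
    "body{font-family:sans-serif;margin:2em}",
    ".row{margin:6px 0;white-space:nowrap}",
    ".label{display:inline-block;width:70px;font-weight:bold}",
    paste0(".sq{display:inline-block;width:44px;height:44px;margin:1px;",
           "border:1px solid #888;text-align:center;vertical-align:middle}"),
    ".sq span{display:block;margin-top:4px;font-size:13px}",
    ".sq small{font-size:9px;color:#333}",
    ".highlight{border:3px solid #FFD700;margin:-1px}",
    "</style></head><body>",
    sprintf("<h3>Patient %s &mdash; per-visit CD attributions</h3>", esc(r$patient_id)),
    "<p>Red: positive contribution to the scored class; white: neutral;",
    "blue: negative. Hover a square for the visit's diagnosis codes.</p>",
    row_html,
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
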