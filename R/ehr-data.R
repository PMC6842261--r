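#' Truncate a diagnosis code to a coding level
#'
#' ICD-9-style codes have a 3-character category followed by an optional
#' dot-suffix (e.g. `"493.9"`). At the `"3-digit"` level everything after
#' the first three characters of the pre-dot part is dropped; at
#' `"4-digit"` the raw code is kept. Truncation is idempotent.
#'
#' @param code character vector of raw codes.
#' @param level `"3-digit"` or `"4-digit"`.
#' @return character vector of codes at the requested level.
#' @export
#' @examples
#' truncate_code(c("493.9", "786.2"), "3-digit")
truncate_code <- function(code, level = c("4-digit", "3-digit")) {
  level <- match.arg(level)
  if (level == "4-digit") return(code)
  substr(sub("\\..*$", "", code), 1L, 3L)
}

#' Construct a single visit
#'
#' @param age_years non-negative patient age at the visit, in years.
#' @param codes non-empty character vector of diagnosis codes; duplicates
#'   within a visit are an error.
#' @return a `visit` object (list with `age_years`, `codes`).
#' @export
visit <- function(age_years, codes) {
  if (length(codes) == 0L) stop("a visit must carry at least one diagnosis code")
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("duplicate codes within one visit: ",
                                 paste(codes[duplicated(codes)], collapse = ", "))
  if (!is.finite(age_years) || age_years < 0) stop("age_years must be a non-negative number")
  structure(list(age_years = as.numeric(age_years), codes = codes), class = "visit")
}

#' Construct a patient record
#'
#' The unit of analysis: an ordered sequence of visits (sorted by age) with
#' an outcome label. Visit ordinals are implicit: visit `t` is
#' `visits[[t]]`, `t = 1..T`.
#'
#' @param patient_id character scalar.
#' @param visits list of [visit()] objects; re-sorted by age if needed
#'   (stable, so ties keep their given order).
#' @param label `"case"`, `"control"` or `"unlabeled"`.
#' @param artificial_ordinal optional integer: position of an injected
#'   artificial visit (see [inject_artificial_visit()]).
#' @param signal_ordinals optional integer vector: positions of planted
#'   signal visits (see [generate_cohort()]).
#' @return a `patient_record`.
#' @export
patient_record <- function(patient_id, visits, label = "unlabeled",
                           artificial_ordinal = NULL, signal_ordinals = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  label <- match.arg(label, c("case", "control", "unlabeled"))
  if (length(visits) == 0L) stop("a patient record needs at least one visit")
  visits <- lapply(visits, function(v) {
    if (inherits(v, "visit")) v else visit(v$age_years, v$codes)
  })
  ages <- vapply(visits, function(v) v$age_years, numeric(1))
  if (is.unsorted(ages)) visits <- visits[order(ages)]
  structure(list(patient_id = patient_id, visits = visits, label = label,
                 artificial_ordinal = artificial_ordinal,
                 signal_ordinals = signal_ordinals),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %d visits, label=%s>\n",
              x$patient_id, length(x$visits), x$label))
  invisible(x)
}

n_visits <- function(record) length(record$visits)

visit_ages <- function(record) vapply(record$visits, `[[`, numeric(1), "age_years")

#' Save a cohort as JSON Lines
#'
#' One JSON object per line:
#' `{"patient_id": ..., "label": ..., "visits": [{"age_years": ..., "codes": [...]}, ...]}`.
#' Optional annotation fields (`artificial_ordinal`, `signal_ordinals`) are
#' written when present so that the round-trip is lossless.
#'
#' @param records list of [patient_record()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_cohort()]
#' @export
save_cohort <- function(records, path) {
  lines <- vapply(records, function(r) {
    obj <- list(patient_id = r$patient_id, label = r$label,
                visits = lapply(r$visits, function(v)
                  list(age_years = v$age_years, codes = as.list(v$codes))))
    if (!is.null(r$artificial_ordinal)) obj$artificial_ordinal <- r$artificial_ordinal
    if (!is.null(r$signal_ordinals)) obj$signal_ordinals <- as.list(r$signal_ordinals)
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a cohort from JSON Lines
#'
#' Inverse of [save_cohort()]. Malformed lines raise an error naming the
#' line number; a visit with an empty code list is an error.
#'
#' @param path file path, one JSON object per line.
#' @return list of [patient_record()] objects, in file order.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) stop("malformed cohort line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    for (key in c("patient_id", "visits")) {
      if (is.null(obj[[key]])) stop("cohort line ", i, ": missing \"", key, "\" field",
                                    call. = FALSE)
    }
    visits <- lapply(obj$visits, function(v) {
      if (is.null(v$codes) || length(v$codes) == 0L)
        stop("cohort line ", i, ": visit with empty code list", call. = FALSE)
      visit(v$age_years, unlist(v$codes, use.names = FALSE))
    })
    patient_record(obj$patient_id, visits, obj$label %||% "unlabeled",
                   artificial_ordinal = obj$artificial_ordinal,
                   signal_ordinals = if (!is.null(obj$signal_ordinals))
                     as.integer(unlist(obj$signal_ordinals)))
  })
}

#' Build a code vocabulary from a cohort
#'
#' Collects the distinct diagnosis codes across all visits, truncated to
#' the requested level, sorted lexicographically (so the index is
#' reproducible across runs and platforms).
#'
#' @param records list of patient records.
#' @inheritParams truncate_code
#' @return a `code_vocabulary`: list with `codes` (character vector; the
#'   0-based design index of code `codes[i]` is `i - 1`) and `level`.
#' @export
build_vocabulary <- function(records, level = c("4-digit", "3-digit")) {
  level <- match.arg(level)
  raw <- unlist(lapply(records, function(r)
    unlist(lapply(r$visits, `[[`, "codes"), use.names = FALSE)), use.names = FALSE)
  if (length(raw) == 0L) stop("cannot build a vocabulary from a cohort with no visits")
  codes <- sort(unique(truncate_code(raw, level)), method = "radix")
  structure(list(codes = codes, level = level), class = "code_vocabulary")
}

#' @export
print.code_vocabulary <- function(x, ...) {
  cat(sprintf("<code_vocabulary: %d codes at %s level>\n", length(x$codes), x$level))
  invisible(x)
}

#' Number of codes in a vocabulary
#' @param vocab a `code_vocabulary`.
#' @return integer |D|.
#' @export
vocab_size <- function(vocab) length(vocab$codes)

#' Write / read a vocabulary as plain text (one code per line)
#' @param vocab a `code_vocabulary`.
#' @param path file path.
#' @param level coding level to record on read.
#' @return `path` / a `code_vocabulary`.
#' @export
save_vocabulary <- function(vocab, path) {
  writeLines(vocab$codes, path)
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path, level = c("4-digit", "3-digit")) {
  structure(list(codes = readLines(path, warn = FALSE), level = match.arg(level)),
            class = "code_vocabulary")
}

#' Encode a patient record as a multi-hot visit matrix
#'
#' Row `t` of the matrix is the binary indicator vector of the codes in
#' visit `t` against the vocabulary (after truncation to the vocabulary's
#' level). Unknown codes are an error, never silently dropped.
#'
#' @param record a [patient_record()].
#' @param vocab a `code_vocabulary` from [build_vocabulary()].
#' @return an `encoded_sequence`: list with `matrix` (T x |D| 0/1),
#'   `true_length` (T) and `patient_id`.
#' @export
encode_patient <- function(record, vocab) {
  T_p <- n_visits(record)
  m <- matrix(0, nrow = T_p, ncol = vocab_size(vocab))
  for (t in seq_len(T_p)) {
    codes <- truncate_code(record$visits[[t]]$codes, vocab$level)
    idx <- match(unique(codes), vocab$codes)
    if (anyNA(idx)) {
      stop("codes not in vocabulary: ",
           paste(unique(codes)[is.na(idx)], collapse = ", "))
    }
    m[t, idx] <- 1
  }
  structure(list(matrix = m, true_length = T_p, patient_id = record$patient_id),
            class = "encoded_sequence")
}

#' Pad encoded sequences into a batch tensor
#'
#' Sequences are post-padded: all-zero rows are appended after the real
#' visits up to the longest sequence in the batch, and the true lengths
#' are returned so downstream computation reads hidden states at the true
#' final step (padding is inert by construction).
#'
#' @param sequences list of `encoded_sequence` objects sharing |D|.
#' @return list with `tensor` (N x T_max x |D| array), `lengths`
#'   (integer vector) and `patient_ids`.
#' @export
pad_batch <- function(sequences) {
  d <- unique(vapply(sequences, function(s) ncol(s$matrix), integer(1)))
  if (length(d) != 1L) stop("sequences encoded against different vocabulary sizes: ",
                            paste(d, collapse = ", "))
  lens <- vapply(sequences, `[[`, integer(1), "true_length")
  t_max <- max(lens)
  n <- length(sequences)
  arr <- array(0, dim = c(n, t_max, d))
  for (i in seq_len(n)) arr[i, seq_len(lens[i]), ] <- sequences[[i]]$matrix
  list(tensor = arr, lengths = lens,
       patient_ids = vapply(sequences, `[[`, character(1), "patient_id"))
}

#' Label a patient for the school-age asthma outcome
#'
#' Cohort rule for predicting school-age asthma from pre-school
#' respiratory symptoms. Inclusion requires at least one visit bearing a
#' respiratory-symptom code (prefix `786`, excluding the `786.3`
#' hemoptysis category) before age 5, and more than two visits before
#' age 5. An included child is a **case** if any visit after age 6
#' carries an asthma code (prefix `493`); a **control** if no visit
#' between age 6 and age 9 carries an asthma code and follow-up extends
#' to at least age 9; anything else is **excluded**. Age bounds are
#' strict (`< 5`, `> 6`).
#'
#' @param record a [patient_record()] (visits age-ordered).
#' @return `"case"`, `"control"` or `"excluded"`.
#' @export
label_asthma_outcome <- function(record) {
  ages <- visit_ages(record)
  has_resp <- vapply(record$visits, function(v)
    any(startsWith(v$codes, "786") & !startsWith(v$codes, "786.3")), logical(1))
  has_asthma <- vapply(record$visits, function(v)
    any(startsWith(v$codes, "493")), logical(1))

  included <- any(has_resp & ages < 5) && sum(ages < 5) > 2L
  if (!included) return("excluded")
  if (any(has_asthma & ages > 6)) return("case")
  asthma_free_window <- !any(has_asthma & ages > 6 & ages < 9)
  if (asthma_free_window && max(ages) >= 9) return("control")
  "excluded"
}

#' Stratified train/validation/test split
#'
#' Shuffles each class with the seed, then allocates the requested
#' fractions per class, so class proportions are preserved up to
#' rounding. Deterministic given the seed.
#'
#' @param records list of patient records, each labeled `"case"` or
#'   `"control"`.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer RNG seed.
#' @return a `cohort_split`: list with `train`, `validation`, `test`,
#'   `seed`.
#' @export
stratified_split <- function(records, fractions = c(0.55, 0.15, 0.30), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("split fractions must sum to 1")
  labels <- vapply(records, `[[`, character(1), "label")
  if (!all(labels %in% c("case", "control")))
    stop("stratified_split requires every record labeled case or control")
  parts <- list(train = list(), validation = list(), test = list())
  with_seed(seed, {
    for (cls in c("case", "control")) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n1 <- round(fractions[1] * n)
      n2 <- round(fractions[2] * n)
      take <- list(train = idx[seq_len(n1)],
                   validation = idx[n1 + seq_len(n2)],
                   test = idx[if (n1 + n2 < n) (n1 + n2 + 1L):n else integer(0)])
      for (p in names(parts)) parts[[p]] <- c(parts[[p]], records[take[[p]]])
    }
  })
  structure(list(train = parts$train, validation = parts$validation,
                 test = parts$test, seed = seed), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split: train=%d validation=%d test=%d (seed %d)>\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}
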