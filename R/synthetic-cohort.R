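#' Describe a plantable class-discriminative visit signal
#'
#' A planted signal is one or more consecutive "signal visits" whose code
#' sets are fixed in advance. When a generated patient carries the signal
#' (with probability `penetrance_case` for cases, `penetrance_control`
#' for controls), a block of `block_size` consecutive visits is
#' overwritten with the signal codes, split evenly across the block.
#'
#' @param signal_codes integer vector of 1-based vocabulary indices used
#'   by the signal.
#' @param carrier_position where the signal block sits: `"random"`
#'   (uniform over admissible starts), `"late"` (ends at the last visit)
#'   or `"early"` (starts at visit 1).
#' @param penetrance_case,penetrance_control probabilities that a
#'   case/control carries the signal; must satisfy
#'   `0 <= penetrance_control <= penetrance_case <= 1`.
#' @param block_size number of consecutive signal visits (default 1).
#' @return a `planted_signal` object.
#' @export
planted_signal <- function(signal_codes, carrier_position = c("random", "late", "early"),
                           penetrance_case = 1, penetrance_control = 0,
                           block_size = 1L) {
  carrier_position <- match.arg(carrier_position)
  if (!(penetrance_control >= 0 && penetrance_control <= penetrance_case &&
        penetrance_case <= 1))
    stop("need 0 <= penetrance_control <= penetrance_case <= 1")
  signal_codes <- as.integer(signal_codes)
  block_size <- as.integer(block_size)
  if (block_size < 1L || length(signal_codes) < block_size)
    stop("block_size must be >= 1 and <= length(signal_codes)")
  structure(list(signal_codes = signal_codes, carrier_position = carrier_position,
                 penetrance_case = penetrance_case,
                 penetrance_control = penetrance_control,
                 block_size = block_size), class = "planted_signal")
}

#' Configure a synthetic EHR cohort
#'
#' The defaults emulate the scale of a pediatric diagnosis-code cohort:
#' around ten visits per patient, about two codes per visit, and a
#' heavy-tailed (Zipf-like) marginal code distribution, so a few codes
#' are common and most are rare.
#'
#' @param n_patients number of patients.
#' @param vocab_size number of distinct background diagnosis codes |D|.
#' @param visit_count_range inclusive (min, max) visits per patient.
#' @param codes_per_visit_range inclusive (min, max) codes per visit.
#' @param zipf_exponent exponent `a` of the background code distribution
#'   `P(rank r) proportional to r^-a`.
#' @param case_fraction probability a generated patient is a case.
#' @param signal a [planted_signal()], or `NULL` for a label-free cohort.
#' @param seed integer RNG seed; generation is deterministic given it.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2000L, vocab_size = 100L,
                          visit_count_range = c(5L, 12L),
                          codes_per_visit_range = c(1L, 3L),
                          zipf_exponent = 1.2, case_fraction = 0.5,
                          signal = NULL, seed = 1L) {
  stopifnot(visit_count_range[1] <= visit_count_range[2],
            codes_per_visit_range[1] <= codes_per_visit_range[2],
            case_fraction > 0, case_fraction < 1)
  if (codes_per_visit_range[2] > vocab_size)
    stop("vocabulary smaller than the maximum number of codes per visit")
  if (!is.null(signal) && max(signal$signal_codes) > vocab_size)
    stop("vocabulary smaller than the planted signal's code indices")
  structure(list(n_patients = as.integer(n_patients),
                 vocab_size = as.integer(vocab_size),
                 visit_count_range = as.integer(visit_count_range),
                 codes_per_visit_range = as.integer(codes_per_visit_range),
                 zipf_exponent = zipf_exponent, case_fraction = case_fraction,
                 signal = signal, seed = as.integer(seed)),
            class = "cohort_config")
}

# Synthetic ICD-9-style code strings "100.0", "100.1", ..., ten 4-digit
# codes per 3-digit category, so level truncation stays meaningful.
synthetic_code_names <- function(n) {
  sprintf("%d.%d", 100L + (seq_len(n) - 1L) %/% 10L, (seq_len(n) - 1L) %% 10L)
}

#' Generate a labeled synthetic EHR cohort
#'
#' Each patient receives a visit count uniform in the configured range,
#' strictly increasing ages, and per-visit background codes sampled
#' without within-visit repeats from a Zipf-like distribution. With the
#' configured penetrances, a case/control additionally carries the
#' planted signal block (which overwrites the codes of the chosen
#' visits); carriers are annotated via `signal_ordinals`.
#'
#' @param config a [cohort_config()].
#' @return list of [patient_record()] objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  codes <- synthetic_code_names(config$vocab_size)
  zipf_p <- (seq_len(config$vocab_size))^(-config$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)
  sig <- config$signal
  with_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(i) {
      is_case <- runif(1) < config$case_fraction
      T_p <- sample(config$visit_count_range[1]:config$visit_count_range[2], 1L)
      ages <- round(cumsum(runif(T_p, 0.3, 0.8)) + runif(1, 0.1, 0.6), 3)
      code_sets <- lapply(seq_len(T_p), function(t) {
        k <- sample(config$codes_per_visit_range[1]:config$codes_per_visit_range[2], 1L)
        codes[sort(sample.int(config$vocab_size, k, prob = zipf_p))]
      })
      signal_ordinals <- NULL
      if (!is.null(sig)) {
        pen <- if (is_case) sig$penetrance_case else sig$penetrance_control
        if (runif(1) < pen && T_p >= sig$block_size) {
          start <- switch(sig$carrier_position,
                          random = sample.int(T_p - sig$block_size + 1L, 1L),
                          late = T_p - sig$block_size + 1L,
                          early = 1L)
          signal_ordinals <- start + seq_len(sig$block_size) - 1L
          split_codes <- split(sig$signal_codes,
                               ceiling(seq_along(sig$signal_codes) *
                                         sig$block_size / length(sig$signal_codes)))
          for (b in seq_len(sig$block_size))
            code_sets[[signal_ordinals[b]]] <- codes[sort(split_codes[[b]])]
        }
      }
      patient_record(sprintf("P%05d", i),
                     mapply(visit, ages, code_sets, SIMPLIFY = FALSE),
                     label = if (is_case) "case" else "control",
                     signal_ordinals = signal_ordinals)
    })
  })
}

#' Configure artificial-visit injection
#'
#' @param p_art probability in `[0, 1]` that a **case** receives the
#'   artificial visit; controls receive it with probability `1 - p_art`.
#' @param position `"random"` (seeded uniform insertion ordinal) or
#'   `"append"` (after the last real visit).
#' @param seed integer RNG seed.
#' @param code the artificial diagnosis code; must lie outside the real
#'   vocabulary (the default `"ART"` cannot collide with numeric
#'   ICD-9-style codes).
#' @return an `artificial_visit_config`.
#' @export
artificial_visit_config <- function(p_art, position = c("random", "append"),
                                    seed = 1L, code = "ART") {
  stopifnot(p_art >= 0, p_art <= 1)
  structure(list(p_art = p_art, position = match.arg(position),
                 seed = as.integer(seed), code = code),
            class = "artificial_visit_config")
}

#' Inject an artificial visit into a labeled cohort
#'
#' Adds at most one extra visit carrying a single out-of-vocabulary code
#' to each patient: cases receive it with probability `p_art`, controls
#' with probability `1 - p_art`. At `p_art = 1` the artificial visit is a
#' perfect class-1 marker; at `p_art = 0.5` it carries no label
#' information. Existing visits are never altered; injected records are
#' annotated with the insertion ordinal (`artificial_ordinal`).
#'
#' @param records labeled patient records.
#' @param cfg an [artificial_visit_config()].
#' @return list of patient records (same order and length as `records`).
#' @export
inject_artificial_visit <- function(records, cfg) {
  stopifnot(inherits(cfg, "artificial_visit_config"))
  labels <- vapply(records, `[[`, character(1), "label")
  if (!all(labels %in% c("case", "control")))
    stop("inject_artificial_visit requires a labeled cohort")
  with_seed(cfg$seed, {
    lapply(records, function(r) {
      prob <- if (r$label == "case") cfg$p_art else 1 - cfg$p_art
      if (runif(1) >= prob) return(r)
      T_p <- n_visits(r)
      ages <- visit_ages(r)
      pos <- if (cfg$position == "append") T_p + 1L else sample.int(T_p + 1L, 1L)
      age <- if (pos > T_p) ages[T_p] + 0.5
             else if (pos == 1L) ages[1] / 2
             else (ages[pos - 1L] + ages[pos]) / 2
      new_visits <- append(r$visits, list(visit(age, cfg$code)), after = pos - 1L)
      patient_record(r$patient_id, new_visits, r$label,
                     artificial_ordinal = pos,
                     signal_ordinals = if (!is.null(r$signal_ordinals))
                       as.integer(r$signal_ordinals + (r$signal_ordinals >= pos)))
    })
  })
}
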