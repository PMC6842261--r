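#' Shapley linearization of a gate activation
#'
#' Splits a nonlinear activation of a sum of 1-3 summands (relevant,
#' irrelevant, bias — in that order, as present) into per-summand
#' contributions: each summand's contribution is its marginal effect
#' `activation(prefix + summand) - activation(prefix)`, averaged over
#' every ordering of the summands. The contributions then sum to
#' `activation(total) - activation(0)`; the `activation(0)` offset is
#' assigned to the last summand (the bias when present, otherwise the
#' irrelevant part) so that the contributions sum to
#' `activation(total)` exactly.
#'
#' @param summands ordered list of 1-3 conformable numeric vectors or
#'   matrices.
#' @param activation `"sigmoid"` or `"tanh"`.
#' @return list of per-summand contributions, same shapes as the input.
#' @export
shapley_linearize <- function(summands, activation = c("sigmoid", "tanh")) {
  activation <- match.arg(activation)
  act <- if (activation == "sigmoid") sigmoid else tanh
  k <- length(summands)
  if (k < 1L || k > 3L) stop("shapley_linearize supports 1 to 3 summands, got ", k)
  perms <- switch(k,
                  list(1L),
                  list(c(1L, 2L), c(2L, 1L)),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  contrib <- lapply(summands, function(s) s * 0)
  for (perm in perms) {
    run <- summands[[1]] * 0
    a_run <- act(run)
    for (j in perm) {
      run <- run + summands[[j]]
      a_new <- act(run)
      contrib[[j]] <- contrib[[j]] + (a_new - a_run)
      a_run <- a_new
    }
  }
  contrib <- lapply(contrib, function(x) x / length(perms))
  contrib[[k]] <- contrib[[k]] + act(0)
  contrib
}

# Contextual-decomposition recursion over one LSTM direction, evaluated
# for K visit subsets simultaneously (one column per subset).
#
# mat:  T x |D| input rows (true visits only)
# smat: T x K logical membership matrix, smat[t, k] == TRUE iff visit t
#       belongs to subset k
#
# At each step the gate pre-activation W x_t + U h_{t-1} + b is split
# into relevant (= U beta_{t-1}, plus W x_t when t is in S), irrelevant
# (= U gamma_{t-1}, plus W x_t when t is not in S), and bias summands;
# the sigmoid i/f gates and tanh candidate g are linearized by
# shapley_linearize. The cell beta keeps the products that involve only
# relevant (and bias) factors — the bias x bias cross-term is credited
# to beta only at in-subset steps — and gamma is the exact remainder
# against the true cell state. The output gate is left undecomposed.
cd_direction <- function(params, mat, smat) {
  states <- run_direction(params, mat)
  H <- params$hidden
  K <- ncol(smat)
  Bh <- matrix(0, H, K); Gh <- matrix(0, H, K); Bc <- matrix(0, H, K)
  for (t in seq_len(nrow(mat))) {
    x <- mat[t, ]
    M <- matrix(as.numeric(smat[t, ]), H, K, byrow = TRUE)
    lin <- list()
    for (gate in c("i", "f", "g")) {
      wx <- drop(params$W[[gate]] %*% x)
      rel <- params$U[[gate]] %*% Bh + wx * M
      irr <- params$U[[gate]] %*% Gh + wx * (1 - M)
      bias <- matrix(params$b[[gate]], H, K)
      lin[[gate]] <- shapley_linearize(list(rel, irr, bias),
                                       if (gate == "g") "tanh" else "sigmoid")
    }
    Bc <- (lin$f[[1]] + lin$f[[3]]) * Bc +
      (lin$i[[1]] + lin$i[[3]]) * lin$g[[1]] +
      lin$i[[1]] * lin$g[[3]] +
      M * (lin$i[[3]] * lin$g[[3]])
    Gc <- states[[t]]$c - Bc
    tanh_split <- shapley_linearize(list(Bc, Gc), "tanh")
    Bh <- states[[t]]$o * tanh_split[[1]]
    Gh <- states[[t]]$h - Bh
  }
  list(beta = Bh, gamma = Gh, states = states)
}

subset_membership <- function(subsets, T_p) {
  smat <- matrix(FALSE, T_p, length(subsets))
  for (k in seq_along(subsets)) {
    s <- as.integer(subsets[[k]])
    if (length(s) > 0L && (min(s) < 1L || max(s) > T_p))
      stop("visit subset outside 1..", T_p, " (padding is out of bounds)")
    smat[s, k] <- TRUE
  }
  smat
}

output_row <- function(out, class_index) {
  if (identical(class_index, "contrast")) {
    list(w = out$weights[2, ] - out$weights[1, ], b = out$bias[2] - out$bias[1])
  } else {
    j <- as.integer(class_index) + 1L
    stopifnot(j >= 1L, j <= nrow(out$weights))
    list(w = out$weights[j, ], b = out$bias[j])
  }
}

new_cd_result <- function(subset, class_index, rel, irr, logit, components) {
  structure(list(subset = sort(as.integer(subset)), class_index = class_index,
                 score_relevant = rel, score_irrelevant = irr, logit = logit,
                 components = components), class = "cd_result")
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("<cd_result S={%s} class=%s: relevant=%.4f irrelevant=%.4f logit=%.4f>\n",
              paste(x$subset, collapse = ","), format(x$class_index),
              x$score_relevant, x$score_irrelevant, x$logit))
  invisible(x)
}

#' Contextual decomposition of an LSTM for a subset of visits
#'
#' Decomposes the final hidden state into `beta` (driven by the visits
#' in `S`) and `gamma` (everything else), and reports the subset's
#' contribution `W_j . beta` to the pre-softmax logit of class `j`. The
#' split is exactly additive:
#' `score_relevant + score_irrelevant + b_j = logit`.
#'
#' @param params [lstm_params()] of the (forward) layer.
#' @param out [output_params()] of the classifier.
#' @param seq an `encoded_sequence`.
#' @param S integer vector of visit ordinals in `1..true_length`
#'   (need not be contiguous; empty means the empty-set probe, whose
#'   relevant score is exactly 0).
#' @param class_index class to score: `1` (default, cases), `0`, or
#'   `"contrast"` for the class-1 minus class-0 logit difference.
#' @return a `cd_result`.
#' @export
cd_lstm <- function(params, out, seq, S, class_index = 1) {
  T_p <- seq$true_length
  mat <- seq$matrix[seq_len(T_p), , drop = FALSE]
  dec <- cd_direction(params, mat, subset_membership(list(S), T_p))
  row <- output_row(out, class_index)
  h_T <- dec$states[[T_p]]$h
  new_cd_result(S, class_index,
                rel = sum(row$w * dec$beta[, 1]),
                irr = sum(row$w * dec$gamma[, 1]),
                logit = sum(row$w * h_T) + row$b,
                components = list(beta = dec$beta[, 1], gamma = dec$gamma[, 1]))
}

#' Contextual decomposition of a BiLSTM for a subset of visits
#'
#' Runs the CD recursion over the forward layer and, with the subset
#' mapped through the sequence reversal, over the backward layer; the
#' relevant score is `W_j . [beta_fwd, beta_bwd]` against the
#' classifier's concatenated feature layout.
#'
#' @param model a bidirectional [bilstm_model()].
#' @inheritParams cd_lstm
#' @return a `cd_result` with per-direction components.
#' @export
cd_bilstm <- function(model, seq, S, class_index = 1) {
  if (model$direction != "bidirectional")
    stop("cd_bilstm requires a bidirectional model; use cd_lstm for forward-only")
  T_p <- seq$true_length
  mat <- seq$matrix[seq_len(T_p), , drop = FALSE]
  smat <- subset_membership(list(S), T_p)
  dec_f <- cd_direction(model$forward, mat, smat)
  dec_b <- cd_direction(model$backward, mat[rev(seq_len(T_p)), , drop = FALSE],
                        smat[rev(seq_len(T_p)), , drop = FALSE])
  row <- output_row(model$output, class_index)
  beta <- c(dec_f$beta[, 1], dec_b$beta[, 1])
  gamma <- c(dec_f$gamma[, 1], dec_b$gamma[, 1])
  h_feat <- c(dec_f$states[[T_p]]$h, dec_b$states[[T_p]]$h)
  new_cd_result(S, class_index,
                rel = sum(row$w * beta), irr = sum(row$w * gamma),
                logit = sum(row$w * h_feat) + row$b,
                components = list(beta_forward = dec_f$beta[, 1],
                                  beta_backward = dec_b$beta[, 1],
                                  gamma_forward = dec_f$gamma[, 1],
                                  gamma_backward = dec_b$gamma[, 1]))
}

#' Contextual decomposition dispatched on model direction
#'
#' @param model a [bilstm_model()] (either direction).
#' @inheritParams cd_lstm
#' @return a `cd_result`.
#' @export
cd_subset <- function(model, seq, S, class_index = 1) {
  if (model$direction == "bidirectional") cd_bilstm(model, seq, S, class_index)
  else cd_lstm(model$forward, model$output, seq, S, class_index)
}

# Relevant scores for many subsets of the same sequence in one pass
# (columns of the recursion are subsets; forward states are shared).
cd_scores_multi <- function(model, seq, subsets, class_index = 1) {
  T_p <- seq$true_length
  mat <- seq$matrix[seq_len(T_p), , drop = FALSE]
  smat <- subset_membership(subsets, T_p)
  row <- output_row(model$output, class_index)
  H <- model$hidden
  dec_f <- cd_direction(model$forward, mat, smat)
  scores <- drop(crossprod(dec_f$beta, row$w[seq_len(H)]))
  if (model$direction == "bidirectional") {
    dec_b <- cd_direction(model$backward, mat[rev(seq_len(T_p)), , drop = FALSE],
                          smat[rev(seq_len(T_p)), , drop = FALSE])
    scores <- scores + drop(crossprod(dec_b$beta, row$w[H + seq_len(H)]))
  }
  as.numeric(scores)
}

#' Per-visit CD attribution scores
#'
#' The attribution of visit `t` is the relevant score of the singleton
#' subset `S = {t}`; scores are returned in visit order. A deterministic
#' function of the model weights and the sequence.
#'
#' @param model a trained [bilstm_model()].
#' @param seq an `encoded_sequence`.
#' @param class_index class to score (default 1, cases).
#' @return numeric vector of length `true_length`.
#' @export
visit_attributions <- function(model, seq, class_index = 1) {
  cd_scores_multi(model, seq, as.list(seq_len(seq$true_length)), class_index)
}

#' Export per-visit attributions for a set of patients
#'
#' @param model a trained [bilstm_model()].
#' @param records list of patient records.
#' @param path optional CSV output path.
#' @param class_index class to score.
#' @return data.frame with columns `patient_id`, `visit_ordinal`,
#'   `age_years`, `codes` (semicolon-joined) and `cd_score_lstm` or
#'   `cd_score_bilstm` depending on the model direction.
#' @export
export_attributions <- function(model, records, path = NULL, class_index = 1) {
  score_col <- if (model$direction == "bidirectional") "cd_score_bilstm" else "cd_score_lstm"
  rows <- lapply(records, function(r) {
    seq <- encode_patient(r, model$vocab)
    data.frame(patient_id = r$patient_id,
               visit_ordinal = seq_len(n_visits(r)),
               age_years = visit_ages(r),
               codes = vapply(r$visits, function(v)
                 paste(sort(v$codes), collapse = ";"), character(1)),
               score = visit_attributions(model, seq, class_index))
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "score"] <- score_col
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
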