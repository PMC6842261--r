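#' Training configuration
#'
#' Defaults are desk-scale standard practice for this model family:
#' Adam with learning rate 0.0005 and early stopping on validation loss.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of passes over the training set.
#' @param patience epochs without validation-loss improvement tolerated
#'   before stopping (0 = stop at the first non-improving epoch).
#' @param batch_size minibatch size.
#' @param hidden_size LSTM hidden state width.
#' @param seed RNG seed for initialization and shuffling; training is
#'   deterministic given it.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, max_epochs = 50L, patience = 5L,
                         batch_size = 32L, hidden_size = 64L, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1, patience >= 0,
            batch_size >= 1, hidden_size >= 1)
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), batch_size = as.integer(batch_size),
                 hidden_size = as.integer(hidden_size), seed = as.integer(seed)),
            class = "train_config")
}

# ---- internal stacked-parameter representation (fast path) ----
# The four gate weight matrices are stacked row-wise (i, f, o, g) so each
# time step costs two matrix products instead of eight.

as_plain <- function(p) list(W = rbind(p$W$i, p$W$f, p$W$o, p$W$g),
                             U = rbind(p$U$i, p$U$f, p$U$o, p$U$g),
                             b = c(p$b$i, p$b$f, p$b$o, p$b$g))

from_plain <- function(p) {
  H <- nrow(p$W) / 4L
  rws <- function(k) (k - 1L) * H + seq_len(H)
  lstm_params(W = list(i = p$W[rws(1), , drop = FALSE], f = p$W[rws(2), , drop = FALSE],
                       o = p$W[rws(3), , drop = FALSE], g = p$W[rws(4), , drop = FALSE]),
              U = list(i = p$U[rws(1), , drop = FALSE], f = p$U[rws(2), , drop = FALSE],
                       o = p$U[rws(3), , drop = FALSE], g = p$U[rws(4), , drop = FALSE]),
              b = list(i = p$b[rws(1)], f = p$b[rws(2)], o = p$b[rws(3)],
                       g = p$b[rws(4)]))
}

# Recursively map f over parallel nested lists of arrays.
nmap <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(i)
      do.call(nmap, c(list(f), lapply(args, `[[`, i))))
    names(out) <- names(args[[1]])
    out
  } else {
    do.call(f, args)
  }
}

# Stack encoded sequences into a |D| x N x T tensor (post-padded), and the
# same tensor with each patient's true visits reversed (for the backward
# layer of a BiLSTM).
stack_sequences <- function(seqs, reverse = FALSE) {
  d <- ncol(seqs[[1]]$matrix)
  lens <- vapply(seqs, `[[`, integer(1), "true_length")
  X <- array(0, dim = c(d, length(seqs), max(lens)))
  for (n in seq_along(seqs)) {
    m <- seqs[[n]]$matrix[seq_len(lens[n]), , drop = FALSE]
    if (reverse) m <- m[rev(seq_len(lens[n])), , drop = FALSE]
    X[, n, seq_len(lens[n])] <- t(m)
  }
  list(X = X, lengths = lens)
}

# Batched forward over one direction with length freezing: past a
# patient's true length the state is carried forward unchanged, so the
# final slice holds every patient's state at its true last step.
fwd_dir <- function(p, X, lengths, keep_cache = TRUE) {
  D <- dim(X)[1]; N <- dim(X)[2]; Tb <- dim(X)[3]
  H <- length(p$b) %/% 4L
  ri <- seq_len(H); rf <- H + ri; ro <- 2L * H + ri; rg <- 3L * H + ri
  h <- matrix(0, H, N); cc <- matrix(0, H, N)
  cache <- if (keep_cache) vector("list", Tb)
  for (t in seq_len(Tb)) {
    xt <- matrix(X[, , t], D, N)
    M <- matrix(as.numeric(lengths >= t), H, N, byrow = TRUE)
    A <- p$W %*% xt + p$U %*% h + p$b
    i <- sigmoid(A[ri, , drop = FALSE])
    f <- sigmoid(A[rf, , drop = FALSE])
    o <- sigmoid(A[ro, , drop = FALSE])
    g <- tanh(A[rg, , drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f, o = o,
                         g = g, tc = tc, M = M)
    h <- M * h_new + (1 - M) * h
    cc <- M * c_new + (1 - M) * cc
  }
  list(h = h, cache = cache)
}

# Backpropagation through time for one direction, given the gradient of
# the loss with respect to the (frozen) final hidden state.
bptt_dir <- function(p, cache, dh_final) {
  Tb <- length(cache)
  g0 <- lapply(p, function(x) x * 0)
  H <- nrow(dh_final); N <- ncol(dh_final)
  dh <- dh_final; dc <- dh_final * 0
  dA <- matrix(0, 4L * H, N)
  ri <- seq_len(H); rf <- H + ri; ro <- 2L * H + ri; rg <- 3L * H + ri
  for (t in rev(seq_len(Tb))) {
    cs <- cache[[t]]
    M <- cs$M
    dh_new <- M * dh
    dc_new <- M * dc + dh_new * cs$o * (1 - cs$tc^2)
    do_ <- dh_new * cs$tc
    dc_prev <- (1 - M) * dc + dc_new * cs$f
    dA[ri, ] <- dc_new * cs$g * cs$i * (1 - cs$i)
    dA[rf, ] <- dc_new * cs$c_prev * cs$f * (1 - cs$f)
    dA[ro, ] <- do_ * cs$o * (1 - cs$o)
    dA[rg, ] <- dc_new * cs$i * (1 - cs$g^2)
    g0$W <- g0$W + tcrossprod(dA, cs$xt)
    g0$U <- g0$U + tcrossprod(dA, cs$h_prev)
    g0$b <- g0$b + rowSums(dA)
    dh <- (1 - M) * dh + crossprod(p$U, dA)
    dc <- dc_prev
  }
  g0
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Loss (mean cross-entropy) and parameter gradients on one minibatch.
batch_loss_grad <- function(params, Xf, Xb, lengths, y, want_grads = TRUE) {
  ff <- fwd_dir(params$f, Xf, lengths, keep_cache = want_grads)
  fb <- if (!is.null(params$b)) fwd_dir(params$b, Xb, lengths, keep_cache = want_grads)
  feat <- if (is.null(fb)) ff$h else rbind(ff$h, fb$h)
  N <- ncol(feat)
  Z <- params$out$W %*% feat + params$out$b
  P <- softmax_cols(Z)
  picked <- P[cbind(y + 1L, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  if (!want_grads) return(list(loss = loss, probs = P))
  dZ <- P
  dZ[cbind(y + 1L, seq_len(N))] <- dZ[cbind(y + 1L, seq_len(N))] - 1
  dZ <- dZ / N
  dF <- crossprod(params$out$W, dZ)
  H <- length(params$f$b) %/% 4L
  grads <- list(f = bptt_dir(params$f, ff$cache, dF[seq_len(H), , drop = FALSE]),
                b = if (!is.null(fb))
                  bptt_dir(params$b, fb$cache, dF[H + seq_len(H), , drop = FALSE]),
                out = list(W = tcrossprod(dZ, feat), b = rowSums(dZ)))
  if (is.null(grads$b)) grads$b <- NULL
  list(loss = loss, grads = grads)
}

#' Train an LSTM or BiLSTM classifier
#'
#' Minimizes cross-entropy with Adam (learning rate from `config`),
#' evaluating validation loss after every epoch and stopping once the
#' loss has not improved for more than `patience` epochs; the weights
#' from the best validation epoch are returned. Deterministic given
#' `config$seed`.
#'
#' @param split a [stratified_split()] result with labeled records.
#' @param config a [train_config()].
#' @param direction `"forward-only"` (LSTM) or `"bidirectional"`
#'   (BiLSTM).
#' @param vocab optional `code_vocabulary`; by default built from all
#'   records in the split at the 4-digit level.
#' @return a [bilstm_model()] carrying a `history` attribute
#'   (per-epoch train/validation loss) and `best_epoch`.
#' @export
train <- function(split, config = train_config(),
                  direction = c("forward-only", "bidirectional"), vocab = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(split, "cohort_split"))
  if (is.null(vocab))
    vocab <- build_vocabulary(c(split$train, split$validation, split$test))
  enc <- function(recs) lapply(recs, encode_patient, vocab = vocab)
  lab01 <- function(recs)
    as.integer(vapply(recs, `[[`, character(1), "label") == "case")

  tr_seqs <- enc(split$train); va_seqs <- enc(split$validation)
  y_tr <- lab01(split$train); y_va <- lab01(split$validation)
  bidir <- direction == "bidirectional"
  tr_f <- stack_sequences(tr_seqs); va_f <- stack_sequences(va_seqs)
  tr_b <- if (bidir) stack_sequences(tr_seqs, reverse = TRUE)
  va_b <- if (bidir) stack_sequences(va_seqs, reverse = TRUE)

  H <- config$hidden_size
  D <- vocab_size(vocab)
  feat_w <- H * if (bidir) 2L else 1L
  n_tr <- length(tr_seqs)

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = NULL, epoch = 0L)

  with_seed(config$seed, {
    s <- 1 / sqrt(H)
    params <- list(f = as_plain(init_lstm_params(H, D)),
                   b = if (bidir) as_plain(init_lstm_params(H, D)),
                   out = list(W = matrix(runif(2 * feat_w, -s, s), 2, feat_w),
                              b = numeric(2)))
    if (!bidir) params$b <- NULL
    m_st <- nmap(function(x) x * 0, params)
    v_st <- nmap(function(x) x * 0, params)
    step <- 0L
    since_best <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        Tb <- max(tr_f$lengths[idx])
        Xf <- tr_f$X[, idx, seq_len(Tb), drop = FALSE]
        Xb <- if (bidir) tr_b$X[, idx, seq_len(Tb), drop = FALSE]
        res <- batch_loss_grad(params, Xf, Xb, tr_f$lengths[idx], y_tr[idx])
        if (!is.finite(res$loss)) stop("training diverged: non-finite loss")
        ep_loss <- ep_loss + res$loss * length(idx); ep_n <- ep_n + length(idx)
        step <- step + 1L
        lr_t <- config$learning_rate * sqrt(1 - 0.999^step) / (1 - 0.9^step)
        m_st <- nmap(function(m, g) 0.9 * m + 0.1 * g, m_st, res$grads)
        v_st <- nmap(function(v, g) 0.999 * v + 0.001 * g^2, v_st, res$grads)
        params <- nmap(function(x, m, v) x - lr_t * m / (sqrt(v) + 1e-8),
                       params, m_st, v_st)
      }
      val <- batch_loss_grad(params, va_f$X, if (bidir) va_b$X, va_f$lengths,
                             y_va, want_grads = FALSE)$loss
      if (!is.finite(val)) stop("training diverged: non-finite validation loss")
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss / ep_n, val)
      if (val < best$loss) {
        best <- list(loss = val, params = params, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best > config$patience) break
      }
    }
  })

  model <- bilstm_model(direction = direction,
                        forward = from_plain(best$params$f),
                        backward = if (bidir) from_plain(best$params$b),
                        output = output_params(best$params$out$W, best$params$out$b),
                        vocab = vocab)
  attr(model, "history") <- history
  attr(model, "best_epoch") <- best$epoch
  model
}

#' Predict class probabilities for a set of patients
#'
#' @param model a trained [bilstm_model()].
#' @param records list of patient records (encoded against the model's
#'   vocabulary internally).
#' @return N x 2 matrix of class probabilities, columns
#'   `(control, case)`.
#' @export
predict_proba <- function(model, records) {
  seqs <- lapply(records, encode_patient, vocab = model$vocab)
  bidir <- model$direction == "bidirectional"
  sf <- stack_sequences(seqs)
  params <- list(f = as_plain(model$forward),
                 b = if (bidir) as_plain(model$backward),
                 out = list(W = model$output$weights, b = model$output$bias))
  ff <- fwd_dir(params$f, sf$X, sf$lengths, keep_cache = FALSE)
  feat <- ff$h
  if (bidir) {
    sb <- stack_sequences(seqs, reverse = TRUE)
    feat <- rbind(feat, fwd_dir(params$b, sb$X, sb$lengths, keep_cache = FALSE)$h)
  }
  P <- t(softmax_cols(params$out$W %*% feat + params$out$b))
  colnames(P) <- c("control", "case")
  P
}

#' Predicted class labels
#' @inheritParams predict_proba
#' @return character vector `"case"`/`"control"`.
#' @export
predict_class <- function(model, records) {
  p <- predict_proba(model, records)
  ifelse(p[, "case"] >= p[, "control"], "case", "control")
}

#' Rank-statistic AUC
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted as 1/2 (the Mann-Whitney form).
#'
#' @param scores numeric risk scores.
#' @param labels `"case"`/`"control"` (or 1/0) per score.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- if (is.numeric(labels)) labels == 1 else labels == "case"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: test set contains a single class")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean AUC with a 95% confidence interval over repeated runs
#'
#' Scores the test set with each model, computes the rank AUC per run,
#' and summarizes as mean plus/minus 1.96 standard errors.
#'
#' @param models list of at least two trained models (e.g. seeded
#'   training replicates).
#' @param test_records labeled test set.
#' @return list with `per_run` (data.frame `run`, `auc`), `mean_auc`,
#'   `ci_low`, `ci_high`, and `formatted` (e.g. `"0.831 (0.824-0.838)"`).
#' @export
evaluate_auc_ci <- function(models, test_records) {
  if (length(models) < 2L) stop("evaluate_auc_ci needs at least two runs")
  labels <- vapply(test_records, `[[`, character(1), "label")
  aucs <- vapply(models, function(m)
    auc_rank(predict_proba(m, test_records)[, "case"], labels), numeric(1))
  mu <- mean(aucs)
  half <- 1.96 * sd(aucs) / sqrt(length(aucs))
  list(per_run = data.frame(run = seq_along(aucs), auc = aucs),
       mean_auc = mu, ci_low = mu - half, ci_high = mu + half,
       formatted = format_auc_ci(mu, mu - half, mu + half))
}

#' Render an AUC summary as `"0.831 (0.824-0.838)"`
#' @param mean_auc,ci_low,ci_high numeric scalars.
#' @return character scalar.
#' @export
format_auc_ci <- function(mean_auc, ci_low, ci_high) {
  sprintf("%.3f (%.3f-%.3f)", mean_auc, ci_low, ci_high)
}

#' Write the per-run AUC metrics report
#'
#' CSV with columns `run_seed`, `auc`, followed by a summary row holding
#' the mean and the 95% CI bounds.
#'
#' @param result output of [evaluate_auc_ci()].
#' @param run_seeds integer seeds of the runs (defaults to run index).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(result, path, run_seeds = result$per_run$run) {
  df <- data.frame(run_seed = as.character(run_seeds),
                   auc = sprintf("%.6f", result$per_run$auc))
  df[nrow(df) + 1L, ] <- c("summary",
                           sprintf("mean=%.6f ci_low=%.6f ci_high=%.6f",
                                   result$mean_auc, result$ci_low, result$ci_high))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
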