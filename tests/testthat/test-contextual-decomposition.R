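test_that("shapley_linearize matches permutation enumeration and its closed forms", {
  set.seed(20)
  # single summand, tanh: contribution is tanh(y)
  y <- rnorm(4)
  expect_equal(shapley_linearize(list(y), "tanh")[[1]], tanh(y))
  # two equal summands, tanh: each gets half of tanh(2y) by symmetry
  two <- shapley_linearize(list(y, y), "tanh")
  expect_equal(two[[1]], 0.5 * tanh(2 * y))
  expect_equal(two[[1]] + two[[2]], tanh(2 * y))
  # sigmoid with bias: contributions complete to sigmoid(a + bias)
  a <- rnorm(4); b <- rnorm(4)
  sg <- shapley_linearize(list(a, b), "sigmoid")
  expect_equal(sg[[1]] + sg[[2]], 1 / (1 + exp(-(a + b))), tolerance = 1e-12)
  # random 1-3 summand cases against the independent enumerator
  for (k in 1:3) {
    for (act_name in c("sigmoid", "tanh")) {
      summands <- lapply(seq_len(k), function(i) rnorm(5))
      got <- shapley_linearize(summands, act_name)
      act <- if (act_name == "sigmoid") sig_ else tanh
      want <- shapley_oracle(summands, act)
      for (i in seq_len(k)) expect_equal(got[[i]], want[[i]], tolerance = 1e-12)
    }
  }
  expect_error(shapley_linearize(list(1, 2, 3, 4), "tanh"), "1 to 3")
})

test_that("CD is exactly additive for random models, sequences and subsets", {
  set.seed(21)
  for (rep in 1:40) {
    dir <- sample(c("forward-only", "bidirectional"), 1)
    H <- sample(2:6, 1); D <- sample(4:10, 1)
    m <- rand_model(dir, H = H, D = D)
    T_p <- sample(1:7, 1)
    seq <- rand_sequence(T_p, D)
    S <- sort(sample(seq_len(T_p), sample(0:T_p, 1)))
    res <- cd_subset(m, seq, S)
    b_j <- m$output$bias[2]
    expect_lt(abs(res$score_relevant + res$score_irrelevant + b_j - res$logit) /
                (1 + abs(res$logit)), 1e-10)
    # the logit matches an independent forward pass + softmax pre-activation
    feat <- sequence_forward(m, seq)$features
    expect_equal(res$logit, sum(m$output$weights[2, ] * feat) + b_j,
                 tolerance = 1e-10)
  }
})

test_that("the empty subset carries exactly zero relevant score", {
  set.seed(22)
  for (dir in c("forward-only", "bidirectional")) {
    m <- rand_model(dir, H = 4, D = 8)
    seq <- rand_sequence(5, 8)
    res <- cd_subset(m, seq, integer(0))
    expect_identical(res$score_relevant, 0)
  }
})

test_that("with all visits in S and zero biases the irrelevant stream vanishes", {
  set.seed(23)
  H <- 4; D <- 8
  for (dir in c("forward-only", "bidirectional")) {
    m <- rand_model(dir, H = H, D = D)
    zero_b <- function(p) { p$b <- lapply(p$b, function(x) x * 0); p }
    m$forward <- zero_b(m$forward)
    if (dir == "bidirectional") m$backward <- zero_b(m$backward)
    seq <- rand_sequence(4, D)
    res <- cd_subset(m, seq, 1:4)
    expect_equal(res$score_irrelevant, 0, tolerance = 1e-10)
    expect_equal(res$score_relevant + m$output$bias[2], res$logit,
                 tolerance = 1e-10)
  }
})

test_that("the CD recursion matches the scalar oracle (hidden size 1, T <= 2)", {
  set.seed(24)
  for (rep in 1:25) {
    D <- sample(2:5, 1)
    T_p <- sample(1:2, 1)
    p <- rand_lstm_params(1, D, scale = 1)
    out <- output_params(matrix(rnorm(2), 2, 1), rnorm(2))
    seq <- rand_sequence(T_p, D, max_codes = 2)
    for (S in list(integer(0), 1L, seq_len(T_p))) {
      got <- cd_lstm(p, out, seq, S)
      want <- scalar_cd_direction(p, seq$matrix, S)
      expect_equal(got$score_relevant, sum(out$weights[2, ] * want$beta),
                   tolerance = 1e-10)
      expect_equal(got$score_irrelevant, sum(out$weights[2, ] * want$gamma),
                   tolerance = 1e-10)
    }
  }
})

test_that("the CD recursion matches the scalar oracle at larger sizes too", {
  set.seed(25)
  for (rep in 1:5) {
    D <- 6; H <- 3; T_p <- 4
    p <- rand_lstm_params(H, D)
    out <- output_params(matrix(rnorm(2 * H), 2, H), rnorm(2))
    seq <- rand_sequence(T_p, D)
    S <- c(2L, 4L)
    got <- cd_lstm(p, out, seq, S)
    want <- scalar_cd_direction(p, seq$matrix, S)
    expect_equal(got$components$beta, want$beta, tolerance = 1e-10)
    expect_equal(got$components$gamma, want$gamma, tolerance = 1e-10)
  }
})

test_that("BiLSTM decomposition with zero backward weights reduces to the LSTM one", {
  set.seed(26)
  H <- 4; D <- 8
  fp <- rand_lstm_params(H, D)
  bp <- zero_lstm_params(H, D)
  W <- matrix(rnorm(4 * H), 2, 2 * H)
  m <- bilstm_model("bidirectional", fp, bp, output_params(W, c(0.1, -0.2)),
                    toy_vocab(D))
  uni_out <- output_params(W[, 1:H, drop = FALSE], c(0.1, -0.2))
  seq <- rand_sequence(5, D)
  bi <- cd_bilstm(m, seq, c(2, 3))
  uni <- cd_lstm(fp, uni_out, seq, c(2, 3))
  # the backward layer contributes nothing relevant (its states are 0)
  expect_equal(bi$score_relevant, uni$score_relevant, tolerance = 1e-10)
  expect_equal(bi$components$beta_backward, rep(0, H))
  # additivity of the concatenated decomposition
  expect_equal(bi$score_relevant + bi$score_irrelevant + m$output$bias[2],
               bi$logit, tolerance = 1e-10)
})

test_that("palindromic sequences with shared weights give symmetric direction scores", {
  set.seed(27)
  H <- 3; D <- 6
  p <- rand_lstm_params(H, D)
  m <- bilstm_model("bidirectional", p, p,
                    output_params(matrix(rnorm(4 * H), 2, 2 * H), c(0, 0)),
                    toy_vocab(D))
  seq <- rand_sequence(3, D)
  seq$matrix[3, ] <- seq$matrix[1, ]   # palindrome around visit 2
  res <- cd_bilstm(m, seq, 2L)
  expect_equal(res$components$beta_forward, res$components$beta_backward,
               tolerance = 1e-10)
})

test_that("cd_bilstm refuses forward-only models and padding subsets error", {
  set.seed(28)
  m1 <- rand_model("forward-only", H = 3, D = 6)
  seq <- rand_sequence(3, 6)
  expect_error(cd_bilstm(m1, seq, 1L), "bidirectional")
  m2 <- rand_model("bidirectional", H = 3, D = 6)
  expect_error(cd_subset(m2, seq, 4L), "padding|bounds")
})

test_that("visit attributions are singleton CD scores, in order, and pure", {
  set.seed(29)
  for (dir in c("forward-only", "bidirectional")) {
    m <- rand_model(dir, H = 4, D = 8)
    seq <- rand_sequence(6, 8)
    va <- visit_attributions(m, seq)
    expect_length(va, 6L)
    for (t in c(1L, 4L, 6L))
      expect_equal(va[t], cd_subset(m, seq, t)$score_relevant, tolerance = 1e-12)
    expect_identical(va, visit_attributions(m, seq))
    one <- rand_sequence(1, 8)
    expect_equal(visit_attributions(m, one),
                 cd_subset(m, one, 1L)$score_relevant)
  }
})

test_that("attribution export has the documented columns", {
  set.seed(30)
  m <- rand_model("bidirectional", H = 3, D = 12)
  cfg <- cohort_config(n_patients = 3, vocab_size = 12, seed = 4)
  recs <- generate_cohort(cfg)
  df <- export_attributions(m, recs)
  expect_equal(names(df), c("patient_id", "visit_ordinal", "age_years",
                            "codes", "cd_score_bilstm"))
  expect_equal(nrow(df), sum(vapply(recs, function(r) length(r$visits), integer(1))))
  path <- withr::local_tempfile(fileext = ".csv")
  export_attributions(m, recs, path)
  expect_true(file.exists(path))
})
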