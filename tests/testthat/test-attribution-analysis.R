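test_that("window enumeration matches the closed-form count", {
  set.seed(40)
  m <- rand_model("forward-only", H = 3, D = 8)
  # 50 random (T, W, s) configurations
  for (rep in 1:50) {
    T_p <- sample(3:14, 1)
    sizes <- sort(sample(1:6, sample(1:3, 1)))
    s <- sample(1:3, 1)
    seq <- rand_sequence(T_p, 8)
    fits <- sizes[sizes <= T_p]
    if (length(fits) == 0L) {
      expect_error(find_predictive_subset(m, seq, window_spec(sizes, s)),
                   "no window")
      next
    }
    res <- find_predictive_subset(m, seq, window_spec(sizes, s))
    want <- sum(vapply(fits, function(w) floor((T_p - w) / s) + 1L, numeric(1)))
    expect_equal(nrow(res$candidates), want)
    expect_equal(res$best_score, max(res$candidates$score))
  }
  # worked example: T=14, W={2,3}, s=1 -> 13 + 12 candidates
  seq14 <- rand_sequence(14, 8)
  expect_equal(nrow(find_predictive_subset(m, seq14,
                                           window_spec(c(2, 3), 1))$candidates),
               25L)
})

test_that("a whole-sequence window scores like the full subset; ties break small/early", {
  set.seed(41)
  m <- rand_model("bidirectional", H = 3, D = 8)
  seq <- rand_sequence(3, 8)
  res <- find_predictive_subset(m, seq, window_spec(3L, 1L))
  expect_equal(nrow(res$candidates), 1L)
  expect_equal(res$best, 1:3)
  expect_equal(res$best_score, cd_subset(m, seq, 1:3)$score_relevant)
  # tie-break: an all-zero model scores every window exactly 0, so the
  # smaller, earlier window must win
  H <- 3; D <- 8
  m0 <- bilstm_model("forward-only", zero_lstm_params(H, D), NULL,
                     output_params(matrix(1, 2, H), c(0, 0)), toy_vocab(D))
  res2 <- find_predictive_subset(m0, rand_sequence(5, D), window_spec(c(3L, 1L, 2L), 1L))
  expect_true(all(res2$candidates$score == 0))
  expect_equal(res2$best, 1L)
})

test_that("LR importance groups sorted codes into quartile scores", {
  # synthetic cohort where codes 1..8 discriminate with graded strength
  set.seed(42)
  n <- 1500
  probs_case <- c(0.9, 0.85, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55, rep(0.3, 4))
  probs_ctrl <- c(rep(0.3, 8), rep(0.3, 4))
  codes <- visitCD:::synthetic_code_names(12)
  recs <- lapply(seq_len(n), function(i) {
    is_case <- i <= n / 2
    pr <- if (is_case) probs_case else probs_ctrl
    present <- which(runif(12) < pr)
    if (length(present) == 0L) present <- 12L
    chunks <- split(present, ceiling(seq_along(present) / 2))
    visits <- lapply(seq_along(chunks),
                     function(t) visit(t + runif(1), codes[chunks[[t]]]))
    patient_record(paste0("p", i), visits, if (is_case) "case" else "control")
  })
  imp <- lr_code_importance(recs)
  sig <- imp[imp$score > 0, ]
  expect_equal(imp$odds_ratio[!is.na(imp$coefficient)],
               exp(imp$coefficient[!is.na(imp$coefficient)]))
  expect_true(all(sig$p_value <= 0.05 & sig$odds_ratio > 1))
  # 8 filtered codes -> groups of two, scores 4,4,3,3,2,2,1,1
  if (nrow(sig) == 8L) {
    expect_equal(sig$score, c(4L, 4L, 3L, 3L, 2L, 2L, 1L, 1L))
    expect_true(all(diff(sig$odds_ratio) <= 0))
  }
  expect_true(all(imp$score[is.na(imp$p_value) | imp$p_value > 0.05 |
                              imp$odds_ratio <= 1] == 0L))
})

test_that("perfectly separating codes raise the separation error", {
  codes <- visitCD:::synthetic_code_names(5)
  recs <- lapply(1:60, function(i) {
    is_case <- i <= 30
    present <- c(if (is_case) 1L, 1L + sample.int(4, 2))
    patient_record(paste0("p", i),
                   list(visit(1, codes[unique(present)])),
                   if (is_case) "case" else "control")
  })
  set.seed(43)
  expect_error(lr_code_importance(recs), "separation.*100\\.0")
})

test_that("ground-truth top visits rank by score with recency tie-break", {
  imp <- data.frame(code = c("A", "B", "C"), coefficient = 1, p_value = 0.01,
                    odds_ratio = 2, group = 1L, score = c(4L, 3L, 0L))
  attr(imp, "level") <- "4-digit"
  r <- patient_record("p", list(visit(1, "C"), visit(2, c("A", "B")),
                                visit(3, "B"), visit(4, c("A", "B"))))
  # visit scores (0, 7, 3, 7): recency breaks the 7-7 tie toward visit 4
  gt <- ground_truth_top_visits(r, imp)
  expect_equal(gt$ordinals, c(4L, 2L, 3L))
  expect_equal(gt$scores, c(7, 7, 3))
  expect_true(gt$complete)
  # all-zero scores: the last three visits win by recency
  imp0 <- imp; imp0$score <- 0L; attr(imp0, "level") <- "4-digit"
  expect_equal(ground_truth_top_visits(r, imp0)$ordinals, c(4L, 3L, 2L))
  # short records are flagged incomplete
  short <- patient_record("q", list(visit(1, "A"), visit(2, "B")))
  gs <- ground_truth_top_visits(short, imp)
  expect_false(gs$complete)
  expect_length(gs$ordinals, 2L)
})

test_that("matching accuracy is monotone in k and hits the degenerate limits", {
  set.seed(44)
  m <- rand_model("forward-only", H = 3, D = 12)
  cfg <- cohort_config(n_patients = 12, vocab_size = 12, seed = 6,
                       visit_count_range = c(3L, 6L))
  recs <- generate_cohort(cfg)
  imp <- data.frame(code = visitCD:::synthetic_code_names(12), coefficient = NA,
                    p_value = NA, odds_ratio = NA, group = NA, score = 0L)
  attr(imp, "level") <- "4-digit"
  acc <- cd_lr_matching_accuracy(m, recs, imp)
  expect_equal(acc$k, 1:3)
  expect_true(all(diff(acc$accuracy) >= 0))
  # if CD argmax always equals the LR top visit, accuracy is 1 at every k
  top_cd <- vapply(recs, function(r)
    which.max(visit_attributions(m, encode_patient(r, m$vocab))), integer(1))
  imp_perfect <- imp
  gt_match <- all(vapply(seq_along(recs), function(i) {
    gt <- ground_truth_top_visits(recs[[i]], imp_perfect)
    top_cd[i] == gt$ordinals[1]
  }, logical(1)))
  if (gt_match) expect_equal(acc$accuracy, rep(1, 3))
})

test_that("pattern mining aggregates identical winning visits", {
  set.seed(45)
  # model whose case logit loads on one code: winning visit is predictable
  D <- 8; H <- 4
  vocab <- toy_vocab(D)
  fp <- zero_lstm_params(H, D)
  fp$W$i <- matrix(0, H, D); fp$W$i[, 1] <- 2   # code 1 opens the input gate
  fp$W$g <- matrix(0, H, D); fp$W$g[, 1] <- 2
  out <- output_params(rbind(rep(-1, H), rep(1, H)), c(0, 0))
  m <- bilstm_model("forward-only", fp, NULL, out, vocab)
  codes <- visitCD:::synthetic_code_names(D)
  mk <- function(id, idx_list) patient_record(id, lapply(seq_along(idx_list),
    function(t) visit(t, codes[idx_list[[t]]])), "case")
  recs <- list(mk("a", list(2, 1, 3)), mk("b", list(1, 4)), mk("c", list(5, 1)))
  pt <- mine_top_patterns(m, recs, length = 1)
  expect_equal(pt$pattern[1], codes[1])
  expect_equal(pt$count[1], 3L)
  expect_equal(pt$percent[1], 100)
  pt2 <- mine_top_patterns(m, recs, length = 2)
  expect_true(all(grepl("^\\[.*\\],\\[.*\\]$", pt2$pattern)))
  expect_equal(sum(pt2$count), attr(pt2, "n_contributing"))
})

test_that("attribution accuracy never exceeds its prediction upper bound", {
  # forced by the eligibility rule: only predicted-class-1 patients count
  df <- data.frame(p_art = c(1, 0.8), model = "lstm", seed = 1,
                   attribution_accuracy = c(100, 60),
                   class1_prediction_accuracy = c(100, 80), n_eligible = 10)
  expect_true(all(df$attribution_accuracy <= df$class1_prediction_accuracy))
  s <- summarize_artificial_visit(df)
  expect_equal(nrow(s), 2L)
  expect_equal(s$p_art, c(1, 0.8))
})
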