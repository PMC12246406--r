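test_that("target transforms invert exactly", {
  for (x in c(0, 1, 7)) expect_equal(nlnm_inverse(nlnm_transform(x)), x)
  for (x in c(0, 12.5, 50)) expect_equal(tsize_inverse(tsize_transform(x)), x)
})

test_that("scope ties the default block count; code path is shared", {
  expect_equal(neck_config(scope = "roi")$n_blocks, 1L)
  expect_equal(neck_config(scope = "full")$n_blocks, 2L)
  # identical settings except scope: configs differ only in scope/n_blocks
  a <- neck_config(scope = "roi"); b <- neck_config(scope = "full")
  a$scope <- NULL; a$n_blocks <- NULL
  b$scope <- NULL; b$n_blocks <- NULL
  expect_identical(unclass(a), unclass(b))
  expect_error(neck_config(task_weights = rep(0, 5)), "not all 0")
})

test_that("resblock neck with zero blocks reduces to global average pooling", {
  set.seed(41)
  fm <- array(runif(6 * 5 * 8), c(6, 5, 8))
  cfg <- neck_config(neck_type = "resblock", scope = "roi")
  params <- mammonode:::neck_init(cfg, 8, 6, 5, seed = 1)
  for (k in grep("^nb", names(params), value = TRUE))
    params[[k]][] <- 0
  out <- resblock_neck_forward(fm, cfg, params)
  expect_equal(out, apply(fm, 3, mean), tolerance = 1e-12)
  expect_length(out, 8)
  # depthwise parameter count: 3x3 per channel
  expect_equal(length(params$nb1_dw), 9 * ncol(params$nb1_w1))
})

test_that("shifted patch tokenization: shapes, zero rule, shift oracle", {
  set.seed(42)
  fm <- array(runif(4 * 4 * 3), c(4, 4, 3))
  toks <- spt_tokenize(fm, embed_dim = 8)
  expect_equal(dim(toks), c(17, 8))    # 16 tokens + class token
  # zero input with zero-initialized class/positional/bias parameters
  cfg <- neck_config(neck_type = "transformer", tf_dim = 8, tf_heads = 1)
  params <- mammonode:::neck_init(cfg, 3, 4, 4, seed = 2)
  params$cls[] <- 0; params$posemb[] <- 0; params$spt_pb[] <- 0
  params$spt_b[] <- 0
  toks0 <- spt_tokenize(array(0, c(4, 4, 3)), 8, params)
  expect_equal(max(abs(toks0)), 0)
  # diagonal shift oracle on a horizontal ramp
  ramp <- array(rep(1:6, each = 5), c(5, 6, 1))
  tape <- mammonode:::tp_new()
  x <- mammonode:::tp_leaf(tape, array(ramp, c(1, 5, 6, 1)))
  sh <- mammonode:::op_shift2d(x, 0, 1, tape)$v[1, , , 1]
  expect_equal(sh[, 2:6], ramp[, 1:5, 1])
  expect_true(all(sh[, 1] == 0))
})

test_that("locality self-attention masks the self token", {
  # two tokens attend to each other with weight exactly one
  two <- matrix(c(1, 0, 0, 1), 2, 2)
  a <- lsa_attention(two, temperature = 1)
  expect_equal(a$attention, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(a$tokens, two[2:1, ])
  # attention rows sum to one on random tokens
  set.seed(43)
  toks <- matrix(rnorm(8 * 4), 8, 4)
  a8 <- lsa_attention(toks)
  expect_equal(rowSums(a8$attention), rep(1, 8), tolerance = 1e-6)
  expect_true(all(diag(a8$attention) == 0))
  # infinite-temperature limit: uniform over the 7 non-self tokens
  a_inf <- lsa_attention(toks, temperature = 1e9)
  off <- a_inf$attention[row(a_inf$attention) != col(a_inf$attention)]
  expect_equal(off, rep(1 / 7, length(off)), tolerance = 1e-6)
  expect_error(lsa_attention(matrix(1, 1, 4)), "two tokens")
})

test_that("transformer neck output contract and position sensitivity", {
  set.seed(44)
  fm <- array(runif(4 * 3 * 6), c(4, 3, 6))
  cfg <- neck_config(neck_type = "transformer", scope = "full", tf_depth = 1,
                     tf_heads = 2, tf_dim = 8)
  params <- mammonode:::neck_init(cfg, 6, 4, 3, seed = 3)
  out1 <- transformer_neck_forward(fm, cfg, params)
  out2 <- transformer_neck_forward(fm, cfg, params)
  expect_identical(out1, out2)
  expect_length(out1, 6)
  # permuting spatial positions changes the output (positional embeddings)
  fm_perm <- fm[c(2, 1, 3, 4), , , drop = FALSE]
  out3 <- transformer_neck_forward(fm_perm, cfg, params)
  expect_false(isTRUE(all.equal(out1, out3)))
})

test_that("multitask heads: zero-representation defaults and bundle ranges", {
  b <- multitask_heads(rep(0, 16))
  expect_equal(b$lnm_prob, 0.5)
  expect_equal(b$lvi_prob, 0.5)
  expect_equal(b$multifoc_prob, 0.5)
  expect_equal(b$n_lnm_pred, 0)    # expm1(0)
  expect_equal(b$tsize_pred, 0)    # 0 * 50
  set.seed(45)
  cfg <- neck_config()
  params <- mammonode:::neck_init(cfg, 8, 2, 2, seed = 9)
  b2 <- multitask_heads(matrix(rnorm(5 * 8, 0, 3), 5, 8), params)
  expect_true(all(b2$lnm_prob >= 0 & b2$lnm_prob <= 1))
  expect_true(all(b2$lvi_prob >= 0 & b2$lvi_prob <= 1))
})

test_that("masked multitask loss: reductions and hand-computed case", {
  preds <- cbind(c(0.8, 0.3), c(0.5, 0.1), c(0.6, 0.2), c(0.3, 0.4),
                 c(0.7, 0.9))
  labels <- cbind(c(1, 0), c(0.7, 0), c(1, 0), c(0.25, 0.5), c(1, 1))
  mask <- matrix(1, 2, 5)
  # all labels missing: error
  expect_error(multitask_loss(preds, labels, matrix(0, 2, 5)), "missing")
  # only the LNM task: plain binary cross-entropy of that head
  m_lnm <- matrix(0, 2, 5); m_lnm[, 1] <- 1
  expect_equal(multitask_loss(preds, labels, m_lnm),
               -mean(log(c(0.8, 0.7))))
  # hand-computed full batch with one missing LVI label
  mask2 <- mask; mask2[2, 3] <- 0
  hand <- -mean(log(c(0.8, 1 - 0.3))) +                       # lnm BCE
    mean((preds[, 2] - labels[, 2])^2) +                       # n_lnm MSE
    (-log(0.6)) / 1 +                                          # lvi, 1 obs
    mean((preds[, 4] - labels[, 4])^2) +                       # tsize MSE
    -mean(log(c(0.7, 0.9)))                                    # multifoc
  expect_equal(multitask_loss(preds, labels, mask2), hand, tolerance = 1e-12)
  # weights scale task contributions
  w <- c(2, 0, 0, 0, 0)
  expect_equal(multitask_loss(preds, labels, mask, task_weights = w),
               2 * multitask_loss(preds, labels, m_lnm))
})

test_that("an all-missing sample leaves training gradients unchanged", {
  set.seed(46)
  imgs <- lapply(1:4, function(i) matrix(runif(16 * 16), 16, 16))
  cfg <- neck_config(neck_type = "resblock", scope = "roi",
                     backbone = backbone_config(c(4)), seed = 1)
  bcfg <- cfg$backbone
  params <- c(backbone_init(bcfg, seed = 2),
              mammonode:::neck_init(cfg, 4, 8, 8, seed = 3))
  attr(params, "config") <- NULL
  y <- cbind(c(1, 0, 1), log1p(c(2, 0, 1)), c(0, 1, 0), c(0.3, 0.2, 0.5),
             c(0, 0, 1))
  mk <- matrix(1, 3, 5)
  x3 <- mammonode:::images_to_array(imgs[1:3])
  x4 <- mammonode:::images_to_array(imgs)
  g3 <- mammonode:::nn_grad_step(params, function(tape, lv)
    mammonode:::model_loss_node(tape, lv, x3, y, mk, bcfg, cfg))
  g4 <- mammonode:::nn_grad_step(params, function(tape, lv)
    mammonode:::model_loss_node(tape, lv, x4, rbind(y, 0),
                                rbind(mk, 0), bcfg, cfg))
  expect_equal(g3$loss, g4$loss, tolerance = 1e-12)
  for (k in names(params))
    expect_equal(g3$grads[[k]], g4$grads[[k]], tolerance = 1e-9)
})

test_that("neck training is seeded, early-stops, and predicts every image", {
  set.seed(47)
  n <- 24
  cfg0 <- cohort_config(n_patients = n, image_height = 32, image_width = 24,
                        px_per_mm = 0.5, seed = 8)
  cohort <- generate_cohort(cfg0)
  imgs <- lapply(seq_len(n), function(i)
    render_mammogram(cohort[i, ], 0, cfg0)$image)
  names(imgs) <- cohort$patient_id
  labels <- cohort[, c("outcome_lnm", "outcome_n_lnm", "outcome_lvi",
                       "outcome_tsize", "outcome_multifoc")]
  cfg <- neck_config(neck_type = "resblock", scope = "full",
                     backbone = backbone_config(c(4, 8)), epochs = 3,
                     batch_size = 8, patience = 2, seed = 5)
  fold <- list(train = 1:16, val = 17:24)
  m1 <- train_neck(NULL, imgs, labels, fold, cfg)
  m2 <- train_neck(NULL, imgs, labels, fold, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$predictions, m2$predictions)
  expect_equal(nrow(m1$predictions), n)
  expect_true(all(m1$predictions$lnm_prob >= 0 &
                  m1$predictions$lnm_prob <= 1))
  # early stopping: training never continues more than patience epochs
  # beyond the inner-validation minimum
  expect_lte(nrow(m1$log), m1$best_epoch + cfg$patience)
  # single-class folds for every classification task are rejected
  labels_bad <- labels
  labels_bad$outcome_lnm <- 1
  labels_bad$outcome_lvi <- NA
  labels_bad$outcome_multifoc <- 0
  expect_error(train_neck(NULL, imgs, labels_bad, fold, cfg),
               "single class")
})
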