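test_that("focal balanced CE matches closed-form values and reduces to CE", {
  expect_equal(focal_balanced_ce(1, 1, 2), 0)
  ## gamma = 0, alpha = 1 equals standard cross entropy over a grid
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(focal_balanced_ce(p, 1, 0), -log(p))
  ## direct arithmetic: p = .9, alpha = .25, gamma = 2
  expect_equal(focal_balanced_ce(0.9, 0.25, 2), 0.25 * 0.01 * -log(0.9),
               tolerance = 1e-12)
  expect_equal(focal_balanced_ce(0.9, 0.25, 2), 2.634e-4, tolerance = 1e-3)
  ## monotone decreasing in p, nonnegative
  l <- focal_balanced_ce(p, 0.5, 2)
  expect_true(all(diff(l) < 0))
  expect_true(all(l >= 0))
  ## larger gamma vanishes faster near p = 1
  eps <- 1e-3
  g2 <- focal_balanced_ce(1 - eps, 1, 2) / focal_balanced_ce(1 - 2 * eps, 1, 2)
  g4 <- focal_balanced_ce(1 - eps, 1, 4) / focal_balanced_ce(1 - 2 * eps, 1, 4)
  expect_lt(g4, g2)
  ## p = 0 is clamped, not an error
  expect_true(is.finite(focal_balanced_ce(0, 1, 2)))
})

test_that("rebalancing reaches the 1:5 ratio and is deterministic", {
  labels <- c(rep(1L, 100), rep(0L, 10000))
  sel <- rebalance(labels, 5, seed = 1)
  expect_equal(sum(labels[sel] == 1), 100)
  expect_equal(sum(labels[sel] == 0), 500)
  expect_identical(sel, rebalance(labels, 5, seed = 1))
  expect_false(identical(sel, rebalance(labels, 5, seed = 2)))
  ## insufficient negatives: keep all with a warning
  labels2 <- c(rep(1L, 100), rep(0L, 300))
  expect_warning(sel2 <- rebalance(labels2, 5, seed = 1), "1:3")
  expect_equal(sum(labels2[sel2] == 0), 300)
  expect_error(rebalance(rep(1L, 10)), class = "spikeloop_degenerate_training")
})

test_that("decision rule applies the >= threshold inclusively", {
  rule <- decision_rule(0.99)
  expect_equal(decide(c(0.99, 0.989, 1, 0), rule), c(1L, 0L, 1L, 0L))
  expect_equal(decide(0.7, decision_rule(0.5)), 1L)
  ## threshold monotonicity: raising the threshold never adds positives
  set.seed(7)
  p <- runif(500)
  ths <- sort(runif(20, 0.01, 0.99))
  counts <- vapply(ths, function(t) sum(decide(p, decision_rule(t))), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(decision_rule(1), class = "spikeloop_invalid_configuration")
})

test_that("network gradients match finite differences", {
  net <- spikeloop:::build_resnet(8, c(2L, 3L), 1L, seed = 5)
  set.seed(9)
  B <- 4
  X <- matrix(runif(B * 64), ncol = 1)
  y <- c(1, 0, 1, 0)
  ## training-mode forward (batch statistics) to match the backward pass
  loss_of <- function(net) {
    fw <- spikeloop:::net_forward(net, X, B, keep_cache = TRUE)
    p <- 1 / (1 + exp(-fw$logits))
    q <- pmin(pmax(ifelse(y == 1, p, 1 - p), 1e-7), 1 - 1e-15)
    mean(-0.5 * (1 - q)^2 * log(q))
  }
  fw <- spikeloop:::net_forward(net, X, B, keep_cache = TRUE)
  p <- 1 / (1 + exp(-fw$logits))
  q <- pmin(pmax(ifelse(y == 1, p, 1 - p), 1e-7), 1 - 1e-15)
  dldq <- 0.5 * (1 - q) * (2 * log(q) - (1 - q) / q)
  dlogit <- dldq * (2 * y - 1) * q * (1 - q) / B
  grads <- spikeloop:::net_backward(net, fw$caches, dlogit, B)
  eps <- 1e-5
  ## probe a few scalar parameters in different layer types
  probes <- list(c(1, 1), c(2, 2))  # (layer, conv-k) pairs for conv layers
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    if (ly$type == "conv") {
      for (k in c(1L, 5L)) {
        g_analytic <- grads[[li]]$W[[k]][1, 1]
        net2 <- net
        net2$layers[[li]]$W[[k]][1, 1] <- ly$W[[k]][1, 1] + eps
        net3 <- net
        net3$layers[[li]]$W[[k]][1, 1] <- ly$W[[k]][1, 1] - eps
        g_num <- (loss_of(net2) - loss_of(net3)) / (2 * eps)
        expect_equal(g_analytic, g_num, tolerance = 1e-4)
      }
      ## batch-norm scale and shift gradients
      for (fld in c("gamma", "beta")) {
        g_analytic <- grads[[li]][[fld]][1]
        net2 <- net
        net2$layers[[li]][[fld]][1] <- ly[[fld]][1] + eps
        net3 <- net
        net3$layers[[li]][[fld]][1] <- ly[[fld]][1] - eps
        g_num <- (loss_of(net2) - loss_of(net3)) / (2 * eps)
        expect_equal(g_analytic, g_num, tolerance = 1e-4)
      }
    }
    if (ly$type == "resblock") {
      g_analytic <- grads[[li]]$conv2$W[[3]][1, 1]
      net2 <- net
      net2$layers[[li]]$conv2$W[[3]][1, 1] <- ly$conv2$W[[3]][1, 1] + eps
      net3 <- net
      net3$layers[[li]]$conv2$W[[3]][1, 1] <- ly$conv2$W[[3]][1, 1] - eps
      g_num <- (loss_of(net2) - loss_of(net3)) / (2 * eps)
      expect_equal(g_analytic, g_num, tolerance = 1e-4)
    }
    if (ly$type == "dense") {
      g_analytic <- grads[[li]]$W[1, 1]
      net2 <- net
      net2$layers[[li]]$W[1, 1] <- ly$W[1, 1] + eps
      net3 <- net
      net3$layers[[li]]$W[1, 1] <- ly$W[1, 1] - eps
      g_num <- (loss_of(net2) - loss_of(net3)) / (2 * eps)
      expect_equal(g_analytic, g_num, tolerance = 1e-4)
    }
  }
})

test_that("batched and single-image predictions agree", {
  net <- spikeloop:::build_resnet(8, c(2L, 3L), 1L, seed = 5)
  set.seed(10)
  feats <- matrix(runif(20 * 64), 20)
  p_batch <- spikeloop:::net_predict(net, feats, batch_size = 20)
  p_single <- vapply(seq_len(20), function(i)
    spikeloop:::net_predict(net, feats[i, , drop = FALSE]), 0)
  expect_lt(max(abs(p_batch - p_single)), 1e-6)
  expect_true(all(p_batch >= 0 & p_batch <= 1))
  ## duplicated image in one batch gets identical probabilities
  dup <- rbind(feats[1, ], feats[1, ])
  pd <- spikeloop:::net_predict(net, dup)
  expect_equal(pd[1], pd[2])
})

test_that("a briefly trained detector outranks the band-power baseline and is seed-stable", {
  co <- generate_cohort(fix_config(duration_s = 150, seed = 23), 5)
  cfg <- training_config(epochs = 6, learning_rate = 3e-3,
                         channels = c(8L, 16L), seed = 23)
  m <- train_detector(co[1:3], co[4:5], cfg)
  expect_s3_class(m, "ied_detector")
  expect_true(all(m$history$loss >= 0))
  expect_equal(nrow(m$history), 6)
  ## learnability at this reduced scale: the trained model ranks burst
  ## windows far above chance (the baseline-relative F1 comparison runs at
  ## full scale in the end-to-end experiment)
  ws_va <- lapply(co[4:5], frame_windows)
  va_truth <- unlist(lapply(ws_va, `[[`, "label"))
  cnn_p <- unlist(lapply(co[4:5], function(r)
    classify_recording(m, r)$probabilities))
  auc <- as.numeric(pROC::auc(pROC::roc(va_truth, cnn_p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_gt(auc, 0.9)
  ## same seed reproduces the training curve exactly
  m2 <- train_detector(co[1:3], co[4:5], cfg)
  expect_equal(m$history$loss, m2$history$loss)
  expect_equal(m$calibration, m2$calibration)
})

test_that("training on misaligned labels yields chance-level validation MCC", {
  co <- generate_cohort(fix_config(duration_s = 150, seed = 29), 4)
  ## rotate the label track by half the recording: burst-shaped label blocks
  ## survive but no longer coincide with the waveforms (no-signal control)
  shuffled <- lapply(co[1:2], function(r) {
    n <- length(r$labels)
    r$labels <- r$labels[c((n %/% 2 + 1):n, 1:(n %/% 2))]
    r
  })
  cfg <- training_config(epochs = 2, learning_rate = 3e-3, seed = 29)
  m <- suppressWarnings(train_detector(shuffled, co[3:4], cfg))
  cr <- classify_recording(m, co[[3]], decision_rule(0.5))
  dm <- detection_metrics(cr$predicted, cr$truth)
  mcc <- if (is.na(dm$mcc)) 0 else dm$mcc
  expect_lt(abs(mcc), 0.15)
})

test_that("fine-tuning with zero epochs is the identity and guards F1", {
  co <- generate_cohort(fix_config(duration_s = 150, seed = 23), 5)
  cfg <- training_config(epochs = 2, learning_rate = 3e-3, seed = 23)
  m <- train_detector(co[1:3], co[4:5], cfg)
  expect_identical(finetune(m, co[1:2], epochs = 0), m)
  expect_error(finetune(m, list()), class = "spikeloop_invalid_configuration")
  hi <- select_high_snr(co[1:3])
  expect_true(length(hi) >= 1)
  m_ft <- suppressWarnings(finetune(m, co[hi], val_recordings = co[4:5],
                                    epochs = 1))
  expect_s3_class(m_ft, "ied_detector")
  ## guard: validation F1 at 0.5 does not drop by more than 0.05
  f1_at <- function(model) {
    mean(vapply(co[4:5], function(r) {
      cr <- classify_recording(model, r, decision_rule(0.5))
      spikeloop:::f1_score(cr$predicted, cr$truth)
    }, 0), na.rm = TRUE)
  }
  expect_gte(f1_at(m_ft), f1_at(m) - 0.05 - 1e-9)
})

test_that("detector bundles round-trip through disk with provenance", {
  co <- generate_cohort(fix_config(duration_s = 120, seed = 31), 3)
  cfg <- training_config(epochs = 1, seed = 31)
  m <- train_detector(co[1:2], co[3], cfg)
  expect_true(nzchar(m$provenance$config_hash))
  path <- file.path(tempdir(), "model.rds")
  save_detector(m, path)
  m2 <- load_detector(path)
  feats <- matrix(runif(3 * 1024), 3)
  expect_equal(predict_proba(m, feats), predict_proba(m2, feats))
  unlink(path)
})
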