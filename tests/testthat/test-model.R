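test_that("protein-level splits use floor(0.15 n) test/validate and the rest train", {
  sp20 <- split_proteins(sprintf("P%02d", 1:20), seed = 1)
  expect_equal(as.integer(table(sp20$assignment)[c("train", "test", "validate")]),
               c(14L, 3L, 3L))
  sp100 <- split_proteins(sprintf("P%03d", 1:100), seed = 2)
  expect_equal(as.integer(table(sp100$assignment)[c("train", "test", "validate")]),
               c(70L, 15L, 15L))
  expect_error(split_proteins(c("a", "b"), seed = 1), "at least 3")
  # same seed, same assignment; partitions disjoint and exhaustive
  again <- split_proteins(sprintf("P%02d", 1:20), seed = 1)
  expect_identical(sp20$assignment, again$assignment)
  expect_setequal(c(partition_ids(sp20, "train"), partition_ids(sp20, "test"),
                    partition_ids(sp20, "validate")), sprintf("P%02d", 1:20))
})

test_that("no protein contributes windows to two partitions", {
  setup <- tiny_training_setup(n = 12)
  part_by_window <- setup$split$assignment[setup$windows$protein_id]
  per_protein <- tapply(part_by_window, setup$windows$protein_id,
                        function(x) length(unique(x)))
  expect_true(all(per_protein == 1L))
})

test_that("balanced class weights are N/(2 Nc) and flag absent classes", {
  w <- class_weights(rep(c(1L, 0L), c(100L, 900L)))
  expect_equal(w[["positive"]], 5.0)
  expect_equal(w[["negative"]], 1000 / 1800)
  expect_equal(unname(class_weights(c(0L, 1L))), c(1, 1))
  expect_equal(unname(class_weights(rep(0:1, 10), scheme = "none")), c(1, 1))
  expect_error(class_weights(rep(0L, 5)), "positive")
  expect_error(class_weights(rep(1L, 5)), "negative")
})

test_that("training returns best-epoch weights, respects patience, and is seeded", {
  setup <- tiny_training_setup(n = 16)
  cfg <- tiny_config(max_epochs = 30L, patience = 3L)
  m <- train_brnn(setup$windows, setup$split, cfg, protease = "trypsin")
  log <- m$training_log
  # returned weights correspond to the maximum logged validation F1
  expect_equal(m$best_val_f1, max(log$val_f1))
  expect_equal(log$val_f1[m$best_epoch], m$best_val_f1)
  # stopping epoch is at most best epoch + patience (or the epoch ceiling)
  expect_lte(nrow(log), max(m$best_epoch + cfg$patience, 1L))
  # determinism: identical seeds give identical training logs
  m2 <- train_brnn(setup$windows, setup$split, cfg, protease = "trypsin")
  expect_identical(m$training_log, m2$training_log)
  expect_identical(m$params, m2$params)
})

test_that("training requires both classes and both partitions", {
  setup <- tiny_training_setup(n = 10)
  empty_truth <- setup$windows
  empty_truth$label <- rep(0L, length(empty_truth$label))
  expect_error(train_brnn(empty_truth, setup$split, tiny_config()),
               "one class")
  sp_bad <- setup$split
  sp_bad$assignment[] <- "train"
  expect_error(train_brnn(setup$windows, sp_bad, tiny_config()),
               "validate")
})

test_that("analytic BPTT gradients match finite differences", {
  set.seed(42)
  cfg <- model_config(n_bilstm_layers = 2, hidden_units = 3, dense_units = 4,
                      seed = 9)
  params <- protcleave:::init_params(cfg, input_dim = 5)
  n <- 6
  x <- array(rnorm(n * 5 * 8), dim = c(n, 5, 8))
  y <- rep(c(1, 0), 3)
  w <- rep(c(2, 0.6), 3)
  g <- protcleave:::.lstm_loss_grad(params, x, y, w)
  getp <- function(obj, pth) { for (k in pth) obj <- obj[[k]]; obj }
  setp <- function(obj, pth, val) {
    if (length(pth) == 1) { obj[[pth[[1]]]] <- val; return(obj) }
    obj[[pth[[1]]]] <- setp(obj[[pth[[1]]]], pth[-1], val)
    obj
  }
  eps <- 1e-6
  paths <- list(list("layers", 1, "fw", "W"), list("layers", 1, "bw", "U"),
                list("layers", 2, "fw", "b"), list("layers", 2, "bw", "W"),
                list("dense", "W"), list("out", "W"))
  for (pth in paths) {
    pm <- getp(params, pth)
    gm <- getp(g$grad, pth)
    for (i in sample(length(pm), min(4, length(pm)))) {
      m2 <- pm
      m2[i] <- pm[i] + eps
      lp <- protcleave:::.lstm_loss_grad(setp(params, pth, m2), x, y, w)$loss
      m2[i] <- pm[i] - eps
      lm <- protcleave:::.lstm_loss_grad(setp(params, pth, m2), x, y, w)$loss
      expect_equal(gm[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("transfer learning freezes the bottom layer bit-identically", {
  setup <- tiny_training_setup(n = 16)
  cfg <- tiny_config(max_epochs = 4L)
  generic <- pretrain_generic(setup$windows, setup$split, cfg, group = "other")
  fine <- transfer_model(generic, setup$windows, setup$split,
                         tiny_config(max_epochs = 3L, seed = 8L),
                         freeze_layers = 1L, protease = "trypsin")
  expect_identical(fine$params$layers[[1]], generic$params$layers[[1]])
  # the unfrozen layers did move
  expect_false(identical(fine$params$layers[[2]], generic$params$layers[[2]]))
  expect_equal(fine$provenance, "transferred")
  # zero fine-tuning epochs: output identical to the generic model
  frozen <- transfer_model(generic, setup$windows, setup$split,
                           tiny_config(max_epochs = 0L), protease = "trypsin")
  expect_identical(frozen$params, generic$params)
  sub <- windows_subset(setup$windows, 1:20)
  expect_equal(predict_windows(frozen, sub), predict_windows(generic, sub))
})

test_that("transfer rejects input-dimensionality mismatches", {
  setup <- tiny_training_setup(n = 12)
  generic <- pretrain_generic(setup$windows, setup$split,
                              tiny_config(max_epochs = 1L))
  bad <- setup$windows
  bad$x <- bad$x[, , 1:20, drop = FALSE]
  expect_error(transfer_model(generic, bad, setup$split, tiny_config()),
               "mismatch")
})

test_that("ensembles average member scores and differ only by member seed", {
  setup <- tiny_training_setup(n = 14)
  ens <- train_ensemble(setup$windows, setup$split, tiny_config(max_epochs = 2L),
                        k = 3L, protease = "trypsin")
  expect_equal(ens$k, 3L)
  sub <- windows_subset(setup$windows, 1:25)
  member_scores <- vapply(ens$members, predict_windows, numeric(25),
                          windows = sub)
  expect_equal(predict_windows(ens, sub), rowMeans(member_scores))
  # k = 1 ensemble equals its single member
  e1 <- train_ensemble(setup$windows, setup$split, tiny_config(max_epochs = 2L),
                       k = 1L)
  expect_equal(predict_windows(e1, sub), predict_windows(e1$members[[1]], sub))
  # member seeds are offset, so training logs generally differ
  expect_false(identical(ens$members[[1]]$training_log,
                         ens$members[[2]]$training_log))
})

test_that("per-protein site prediction scores every candidate bond in [0, 1]", {
  setup <- tiny_training_setup(n = 14)
  ens <- train_ensemble(setup$windows, setup$split, tiny_config(max_epochs = 2L),
                        k = 2L, protease = "trypsin")
  p <- setup$dataset$proteins[[1]]
  pred <- predict_sites(ens, p)
  expect_equal(nrow(pred), p$length - 1L)
  expect_equal(pred$p1, candidate_sites(p))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(unique(pred$source), "prediction")
})

test_that("models and ensembles round-trip through their on-disk directory format", {
  setup <- tiny_training_setup(n = 12)
  m <- train_brnn(setup$windows, setup$split, tiny_config(max_epochs = 2L),
                  protease = "trypsin")
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "weights.json")))
  back <- load_model(dir)
  expect_equal(back$params, m$params)
  expect_equal(back$best_epoch, m$best_epoch)
  sub <- windows_subset(setup$windows, 1:10)
  expect_equal(predict_windows(back, sub), predict_windows(m, sub))

  ens <- train_ensemble(setup$windows, setup$split, tiny_config(max_epochs = 1L),
                        k = 2L, protease = "trypsin")
  edir <- withr::local_tempdir()
  save_model(ens, edir)
  eback <- load_ensemble(edir)
  expect_equal(predict_windows(eback, sub), predict_windows(ens, sub))
})

test_that("the classifier recovers a cleavage rule from modest data", {
  # small-scale rule recovery; the full-size fixture is exercised in the
  # acceptance suite
  setup <- tiny_training_setup(n = 60, seed = 5)
  cfg <- tiny_config(n_bilstm_layers = 4L, hidden_units = 12L,
                     dense_units = 12L, max_epochs = 10L, seed = 7L)
  m <- train_brnn(setup$windows, setup$split, cfg, protease = "trypsin")
  truth <- rule_truth(setup$dataset$proteins, trypsin_rule())
  expect_gt(heldout_auc(m, setup$windows, setup$split, truth), 0.95)
})
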