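test_that("training on the separable fixture fits each member", {
  m <- small_model()
  expect_length(m$members, 6)
  # defaults carry the published hyperparameters through to every member
  expect_equal(m$config$n_estimators, 150L) # overridden in this fixture
  d <- rf_config()
  expect_equal(d$n_estimators, 500L)
  expect_true(d$oob_score)
  expect_equal(d$max_features, 6L)
  expect_equal(d$min_samples_split, 6L)

  p <- predict(m, small_fx()$split$train)
  y <- small_fx()$split$train$label[match(p$id, small_fx()$split$train$id)] == "ACTIVE"
  acc <- vapply(fp_types(), function(t) {
    mean((p[[paste0("prob_", t)]] >= 0.5) == y)
  }, numeric(1))
  # topological/structural-key members separate the scaffold exactly;
  # FP4's sparse functional-group keys leave a narrower margin
  expect_true(all(acc[c("FP2", "MACCS", "Morgan", "Layered", "RDKit")] == 1))
  expect_gte(acc[["FP4"]], 0.7)
  expect_error(
    train_ensemble(list(train = small_fx()$split$train[
      small_fx()$split$train$label == "ACTIVE", ], test = NULL)),
    "both"
  )
})

test_that("training and prediction are reproducible under a fixed seed", {
  fx <- small_fx()
  sub <- list(train = fx$split$train[1:60, ], test = fx$split$test[1:20, ],
              decoys_per_active = NA)
  class(sub) <- c("corpus_split", "list")
  m1 <- train_ensemble(sub, rf_config(n_estimators = 60, seed = 99))
  m2 <- train_ensemble(sub, rf_config(n_estimators = 60, seed = 99))
  p1 <- predict(m1, fx$library[1:30, ])
  p2 <- predict(m2, fx$library[1:30, ])
  expect_identical(p1, p2)
})

test_that("point-biserial evaluation behaves at its limits", {
  perfect <- evaluate_member(c(1, 1, 0, 0), c("ACTIVE", "ACTIVE", "DECOY", "DECOY"))
  expect_equal(perfect$R, 1)
  expect_equal(perfect$R2, 1)

  set.seed(42)
  n <- 4000
  prob <- runif(n)
  labels <- ifelse(runif(n) < 0.5, "ACTIVE", "DECOY")
  indep <- evaluate_member(prob, labels)
  expect_lt(abs(indep$R), 3 / sqrt(n))

  expect_warning(z <- evaluate_member(rep(0.5, 4), c("ACTIVE", "DECOY",
                                                     "ACTIVE", "DECOY")),
                 "zero-variance")
  expect_true(is.na(z$R))
})

test_that("consensus votes agree with a brute-force recount and nest by k", {
  m <- small_model()
  lib <- small_fx()$library
  scr <- consensus_screen(m, lib, k = 1, all = TRUE)
  prob_cols <- paste0("prob_", fp_types())
  recount <- rowSums(as.matrix(scr[, prob_cols]) >= m$config$active_threshold)
  expect_equal(scr$votes, as.integer(recount))
  expect_equal(scr$mean_probability, rowMeans(as.matrix(scr[, prob_cols])))

  hit_sets <- lapply(1:6, function(k) consensus_screen(m, lib, k = k)$id)
  for (k in 1:5) {
    expect_true(all(hit_sets[[k + 1]] %in% hit_sets[[k]]))
  }
  # a molecule with zero votes is never a hit
  zero <- scr$id[scr$votes == 0]
  expect_gt(length(zero), 0)
  expect_false(any(zero %in% hit_sets[[1]]))
  # ranking: votes desc, then mean probability desc, then id
  hits <- consensus_screen(m, lib, k = 1)
  expect_identical(
    hits$id,
    hits[order(-hits$votes, -hits$mean_probability, hits$id), ]$id
  )
})

test_that("screening recovers planted actives with low background rate", {
  fx <- small_fx()
  hits <- consensus_screen(small_model(), fx$library, k = 1)
  expect_gte(sum(fx$planted_ids %in% hits$id) / length(fx$planted_ids), 0.95)
  background <- setdiff(fx$library$id, fx$planted_ids)
  expect_lt(sum(hits$id %in% background) / length(background), 0.2)
})

test_that("model report exposes R/R2 per member and tidy methods work", {
  m <- small_model()
  rep <- model_report(m, small_fx()$split)
  expect_equal(rep$fp_type, fp_types())
  expect_true(all(rep$R2_train >= 0 & rep$R2_train <= 1, na.rm = TRUE))
  expect_equal(rep$R2_test, rep$R_test^2)
  td <- tidy(m, small_fx()$split)
  expect_identical(td, rep)
  gl <- glance(m)
  expect_equal(gl$n_members, 6)
  expect_s3_class(plot_model_report(rep), "ggplot")
})

test_that("OOB accuracy tracks held-out accuracy at n >= 500", {
  tr <- big_fx()$split$train
  idx <- pdlscreen:::with_seed(7, sample(nrow(tr), round(0.8 * nrow(tr))))
  sp <- list(train = tr[idx, ], test = tr[-idx, ], decoys_per_active = NA)
  class(sp) <- c("corpus_split", "list")
  m <- train_ensemble(sp)
  p <- predict(m, sp$test)
  y <- sp$test$label[match(p$id, sp$test$id)] == "ACTIVE"
  for (t in fp_types()) {
    held <- mean((p[[paste0("prob_", t)]] >= 0.5) == y)
    expect_lt(abs(m$oob_accuracy[[t]] - held), 0.1)
  }
})

test_that("funnel reduction reproduces the screening-stage arithmetic", {
  expect_equal(funnel_reduction(100, 50), 50)
  expect_equal(funnel_reduction(10, 10), 0)
  expect_error(funnel_reduction(0, 0))
})
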