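# Random Forest ensemble: one probability forest per fingerprint type,
# point-biserial R/R2 evaluation, and at-least-k-of-6 consensus screening.

#' Random Forest configuration
#'
#' Defaults are the screening campaign's published hyperparameters:
#' 500 trees, OOB scoring on, 6 features tried per split (an absolute
#' count, deliberately small for 2048-bit inputs), minimum node size 6.
#'
#' @param n_estimators Number of trees.
#' @param oob_score Keep out-of-bag probability predictions.
#' @param max_features Features tried at each split (absolute count).
#' @param min_samples_split Minimal node size eligible for splitting.
#' @param seed RNG seed used for training and fold assignment.
#' @param active_threshold Per-member probability at or above which a
#'   molecule is voted ACTIVE.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_estimators = 500, oob_score = TRUE, max_features = 6,
                      min_samples_split = 6, seed = 20220516,
                      active_threshold = 0.5) {
  structure(list(
    n_estimators = as.integer(n_estimators),
    oob_score = isTRUE(oob_score),
    max_features = as.integer(max_features),
    min_samples_split = as.integer(min_samples_split),
    seed = as.integer(seed),
    active_threshold = active_threshold
  ), class = "rf_config")
}

#' Train the six-fingerprint Random Forest ensemble
#'
#' Fits one probability Random Forest per fingerprint type on the training
#' molecules of a [split_corpus()] object (ACTIVE vs non-ACTIVE as the
#' binary target). The returned model carries a training manifest (class
#' counts, seed, fingerprint parameters) for reproducibility; training is
#' deterministic given the seed.
#'
#' @param split A `corpus_split` (train must contain both classes).
#' @param config An [rf_config()].
#' @param params Fingerprint parameters, [fp_params()].
#' @param types Fingerprint types (default all six).
#' @return An object of class `pdl1_ensemble`.
#' @export
train_ensemble <- function(split, config = rf_config(), params = fp_params(),
                           types = fp_types()) {
  train <- split$train
  y <- factor(ifelse(train$label == "ACTIVE", "ACTIVE", "INACTIVE"),
              levels = c("ACTIVE", "INACTIVE"))
  if (length(unique(y)) < 2) {
    abort("training set must contain both ACTIVE and non-ACTIVE molecules")
  }
  feats <- featurize_all(train, types, params)
  ids <- rownames(feats[[1]])
  ylab <- y[match(ids, train$id)]
  members <- list()
  oob <- numeric(0)
  for (t in types) {
    x <- feats[[t]]
    colnames(x) <- paste0("b", seq_len(ncol(x)))
    fit <- ranger::ranger(
      x = x, y = ylab,
      num.trees = config$n_estimators,
      mtry = min(config$max_features, ncol(x)),
      min.node.size = config$min_samples_split,
      probability = TRUE,
      seed = config$seed,
      oob.error = config$oob_score,
      num.threads = 1
    )
    members[[t]] <- fit
    oob[t] <- if (config$oob_score) {
      oobp <- fit$predictions[, "ACTIVE"]
      mean((oobp >= config$active_threshold) == (ylab == "ACTIVE"), na.rm = TRUE)
    } else NA_real_
  }
  structure(list(
    members = members,
    consensus_k = 1L,
    config = config,
    fp_params = params,
    types = types,
    oob_accuracy = oob,
    manifest = list(
      n_train = nrow(train),
      n_train_active = sum(ylab == "ACTIVE"),
      n_train_inactive = sum(ylab == "INACTIVE"),
      n_test = nrow(split$test),
      seed = config$seed,
      fp_params = params$hash,
      trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
  ), class = "pdl1_ensemble")
}

#' @export
print.pdl1_ensemble <- function(x, ...) {
  cat("<pdl1_ensemble> ", length(x$members), " members (",
      paste(x$types, collapse = ", "), ")\n", sep = "")
  cat("  trained on", x$manifest$n_train_active, "ACTIVE /",
      x$manifest$n_train_inactive, "non-ACTIVE; seed",
      x$manifest$seed, "\n")
  invisible(x)
}

#' Per-member ACTIVE probabilities for a molecule table
#'
#' @param object A `pdl1_ensemble`.
#' @param mols Molecule tibble (`id`, `smiles`).
#' @param ... Unused.
#' @return Tibble with `id`, one `prob_<type>` column per member, `votes`
#'   (members voting ACTIVE at the configured threshold) and
#'   `mean_probability`.
#' @export
predict.pdl1_ensemble <- function(object, mols, ...) {
  feats <- featurize_all(mols, object$types, object$fp_params)
  ids <- rownames(feats[[1]])
  probs <- map(object$types, function(t) {
    x <- feats[[t]]
    colnames(x) <- paste0("b", seq_len(ncol(x)))
    predict(object$members[[t]], data = x,
            num.threads = 1)$predictions[, "ACTIVE"]
  })
  names(probs) <- paste0("prob_", object$types)
  out <- tibble(id = ids, !!!probs)
  pm <- as.matrix(out[, -1])
  out$votes <- as.integer(rowSums(pm >= object$config$active_threshold))
  out$mean_probability <- rowMeans(pm)
  out
}

#' Point-biserial correlation between predictions and labels
#'
#' Quality metric for one ensemble member: Pearson correlation R between
#' the predicted ACTIVE-class probability and the 0/1 true label, plus
#' R^2 = R*R. With zero variance in either vector R is undefined and is
#' returned as `NA` with a warning (never silently 0). Hard-label variants
#' are reported alongside.
#'
#' @param prob Predicted ACTIVE probabilities.
#' @param labels Character labels (`ACTIVE` = positive class) or 0/1.
#' @param threshold Vote threshold for the hard-label variant.
#' @return One-row tibble: `R`, `R2`, `R_hard`, `R2_hard`, `n`.
#' @export
evaluate_member <- function(prob, labels, threshold = 0.5) {
  y <- if (is.numeric(labels)) as.numeric(labels)
       else as.numeric(labels == "ACTIVE")
  stopifnot(length(prob) == length(y))
  safe_cor <- function(a, b, quiet = FALSE) {
    if (sd(a) == 0 || sd(b) == 0) {
      if (!quiet) warn("zero-variance predictions or labels; R undefined (NA)")
      return(NA_real_)
    }
    cor(a, b)
  }
  r <- safe_cor(prob, y)
  # hard-label variant is auxiliary; degenerate cases stay quiet
  rh <- safe_cor(as.numeric(prob >= threshold), y, quiet = TRUE)
  tibble(R = r, R2 = r^2, R_hard = rh, R2_hard = rh^2, n = length(y))
}

#' Train/test model report for every ensemble member
#'
#' @param model A `pdl1_ensemble`.
#' @param split The `corpus_split` it was trained on (or any labeled split).
#' @return Tibble with one row per fingerprint type: `R_train`, `R2_train`,
#'   `R_test`, `R2_test`, `oob_accuracy`.
#' @export
model_report <- function(model, split) {
  ptr <- predict(model, split$train)
  pte <- predict(model, split$test)
  ytr <- split$train$label[match(ptr$id, split$train$id)]
  yte <- split$test$label[match(pte$id, split$test$id)]
  rows <- map(model$types, function(t) {
    col <- paste0("prob_", t)
    etr <- evaluate_member(ptr[[col]], ytr, model$config$active_threshold)
    ete <- evaluate_member(pte[[col]], yte, model$config$active_threshold)
    tibble(
      fp_type = t,
      R_train = etr$R, R2_train = etr$R2,
      R_test = ete$R, R2_test = ete$R2,
      oob_accuracy = unname(model$oob_accuracy[t])
    )
  })
  bind_rows(rows)
}

#' @export
tidy.pdl1_ensemble <- function(x, split = NULL, ...) {
  if (is.null(split)) {
    tibble(fp_type = x$types,
           oob_accuracy = unname(x$oob_accuracy[x$types]))
  } else {
    model_report(x, split)
  }
}

#' @export
glance.pdl1_ensemble <- function(x, ...) {
  tibble(
    n_members = length(x$members),
    consensus_k = x$consensus_k,
    n_train = x$manifest$n_train,
    n_train_active = x$manifest$n_train_active,
    seed = x$manifest$seed,
    mean_oob_accuracy = mean(x$oob_accuracy, na.rm = TRUE)
  )
}

#' Consensus screening of a molecule library
#'
#' A molecule is a hit iff at least `k` of the six members predict ACTIVE
#' (probability at or above the configured threshold). Hits are ranked by
#' vote count (descending), mean ACTIVE probability (descending) and id
#' (ascending). Per-member probabilities are kept for audit.
#'
#' @param model A `pdl1_ensemble`.
#' @param library Molecule tibble to screen.
#' @param k Consensus threshold in 1..6 (default 1).
#' @param all Return all molecules with a logical `hit` column instead of
#'   hits only.
#' @return Ranked tibble of hits (`id`, `smiles`, `votes`,
#'   `mean_probability`, per-member `prob_*`).
#' @export
consensus_screen <- function(model, library, k = 1, all = FALSE) {
  stopifnot(k >= 1, k <= length(model$members))
  pred <- predict(model, library)
  pred <- left_join(pred, library[, c("id", "smiles")], by = "id")
  pred$hit <- pred$votes >= k
  pred <- pred %>%
    arrange(desc(.data$votes), desc(.data$mean_probability), .data$id) %>%
    select("id", "smiles", "votes", "mean_probability", dplyr::everything())
  if (all) pred else pred %>% filter(.data$hit) %>% select(-"hit")
}

#' Screening-funnel size reduction
#'
#' Percent reduction of a screened library achieved by a screening stage,
#' `100 * (n_in - n_out) / n_in`.
#'
#' @param n_in Library size entering the stage.
#' @param n_out Number of molecules passing the stage.
#' @return Percent reduction (0-100).
#' @examples
#' funnel_reduction(16191, 361) # ~98
#' @export
funnel_reduction <- function(n_in, n_out) {
  stopifnot(n_in > 0, n_out >= 0, n_out <= n_in)
  100 * (n_in - n_out) / n_in
}

#' @rdname plot_model_report
#' @export
autoplot.pdl1_ensemble <- function(object, split = NULL, ...) {
  if (is.null(split)) abort("autoplot needs the corpus_split for evaluation")
  plot_model_report(model_report(object, split))
}

#' Plot train/test R-squared per ensemble member
#'
#' @param report Output of [model_report()].
#' @param object,split Ensemble and corpus split (autoplot method).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_model_report <- function(report, ...) {
  long <- tidyr::pivot_longer(
    report[, c("fp_type", "R2_train", "R2_test")],
    cols = c("R2_train", "R2_test"),
    names_to = "set", values_to = "R2"
  )
  long$set <- ifelse(long$set == "R2_train", "training", "test")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fp_type, y = .data$R2,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fingerprint", y = expression(R^2), fill = NULL) +
    ggplot2::theme_minimal()
}
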