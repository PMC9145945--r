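# HTRF plate normalization to percent inhibition and 4PL (variable-slope)
# IC50 fitting.

#' Normalize HTRF plate signals to percent inhibition
#'
#' `%I = 100 * (S_control - S_sample) / (S_control - S_negative)` where
#' `S_control` is the mean untreated (full PD1-PDL1 interaction) signal and
#' `S_negative` the mean no-PD1 signal defining 0% interaction, i.e. 100%
#' inhibition. Control signals are averaged over replicates; replicate
#' sample wells are summarized as mean and SD.
#'
#' @param plate Tibble with columns `compound_id`, `concentration_uM`,
#'   `signal` and `role` (`SAMPLE`, `CONTROL_UNTREATED`, `NEGATIVE_NO_PD1`).
#' @return Tibble `compound_id`, `concentration_uM`, `pct_inhibition`,
#'   `dispersion_sd`, `n_replicates`, `flagged` (outside `[-20, 120]`).
#' @export
percent_inhibition <- function(plate) {
  need <- c("compound_id", "concentration_uM", "signal", "role")
  stopifnot(all(need %in% names(plate)))
  if (any(plate$signal < 0, na.rm = TRUE)) abort("negative signals in plate")
  s_ctrl <- mean(plate$signal[plate$role == "CONTROL_UNTREATED"])
  s_neg <- mean(plate$signal[plate$role == "NEGATIVE_NO_PD1"])
  if (!is.finite(s_ctrl) || !is.finite(s_neg)) {
    abort("plate must contain CONTROL_UNTREATED and NEGATIVE_NO_PD1 wells")
  }
  if (s_ctrl == s_neg) abort("degenerate assay window: control equals negative")
  out <- plate %>%
    filter(.data$role == "SAMPLE") %>%
    mutate(pi_well = 100 * (s_ctrl - .data$signal) / (s_ctrl - s_neg)) %>%
    group_by(.data$compound_id, .data$concentration_uM) %>%
    summarise(
      pct_inhibition = mean(.data$pi_well),
      dispersion_sd = if (n() > 1) sd(.data$pi_well) else NA_real_,
      n_replicates = n(),
      .groups = "drop"
    )
  out$flagged <- out$pct_inhibition < -20 | out$pct_inhibition > 120
  if (any(out$flagged)) {
    warn(paste0(sum(out$flagged),
                " point(s) outside the typical [-20, 120]% range flagged"))
  }
  out
}

# Variable-slope (4-parameter logistic) inhibition model.
fourpl <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Variable-slope model `%I(c) = bottom + (top - bottom) /
#' (1 + (IC50/c)^hill)` fitted by Levenberg-Marquardt least squares.
#' Initialization: `top = max(%I)`, `bottom = min(%I)` (padded slightly off
#' the data extremes for numerical stability), `IC50 =` geometric mid-dose,
#' `hill = 1`; bounds `IC50 in [min dose/10, max dose*10]`,
#' `hill in [0.1, 10]`, `top`/`bottom` in the plausible inhibition range
#' `[-20, 120]`. Zero-concentration points anchor the starting `bottom` but
#' are excluded from the fitted dose axis. Flat responses and optimizer
#' failures are reported as `converged = FALSE`, never silently.
#'
#' @param points Tibble with `concentration_uM` and `pct_inhibition`
#'   (e.g. one compound's rows from [percent_inhibition()]).
#' @param compound_id Optional label carried into the result.
#' @return Object of class `ic50_fit` with elements `params` (ic50_uM,
#'   hill, top, bottom), `converged`, `rss`, `points`.
#' @export
fit_ic50 <- function(points, compound_id = NULL) {
  stopifnot(all(c("concentration_uM", "pct_inhibition") %in% names(points)))
  zero <- points[points$concentration_uM == 0, , drop = FALSE]
  pts <- points[points$concentration_uM > 0, , drop = FALSE]
  if (length(unique(pts$concentration_uM)) < 4) {
    abort("need at least 4 distinct nonzero concentrations for a 4PL fit")
  }
  resp <- pts$pct_inhibition
  conc <- pts$concentration_uM
  flat <- sd(resp) < 1e-8
  span <- max(max(resp) - min(resp), 1)
  # A start sitting exactly on the data extremes can make the initial
  # Jacobian numerically singular; pad it slightly, and keep a short
  # deterministic ladder of fallback starts.
  start_bottom <- if (nrow(zero) > 0) mean(zero$pct_inhibition)
                  else min(resp) - 0.02 * span
  geo_mid <- exp(mean(log(range(conc))))
  starts <- list(
    list(bottom = start_bottom, top = max(resp) + 0.02 * span,
         ic50 = geo_mid, hill = 1),
    list(bottom = min(resp) - 0.1 * span, top = max(resp) + 0.1 * span,
         ic50 = median(conc), hill = 1.5),
    list(bottom = 0, top = 100, ic50 = geo_mid, hill = 1)
  )
  # top/bottom bounded to the plausible percent-inhibition range; an
  # unbounded top is weakly identified when the IC50 sits near the top
  # tested dose and biases the IC50 low
  lower <- c(bottom = -20, top = -20, ic50 = min(conc) / 10, hill = 0.1)
  upper <- c(bottom = 120, top = 120, ic50 = max(conc) * 10, hill = 10)
  starts <- lapply(starts, function(s) {
    s$bottom <- min(max(s$bottom, -20), 120)
    s$top <- min(max(s$top, -20), 120)
    s
  })
  fit <- NULL
  if (!isTRUE(flat)) {
    for (start in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          pct_inhibition ~ fourpl(concentration_uM, bottom, top, ic50, hill),
          data = pts, start = start, lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit) && isTRUE(fit$convInfo$isConv)) break
    }
  }
  converged <- !is.null(fit) && isTRUE(fit$convInfo$isConv)
  # A fit that pegs IC50 at the bounds with a near-zero amplitude is flat.
  params <- if (converged) {
    cf <- coef(fit)
    if (abs(cf["top"] - cf["bottom"]) < 1e-6) converged <- FALSE
    tibble(ic50_uM = unname(cf["ic50"]), hill = unname(cf["hill"]),
           top = unname(cf["top"]), bottom = unname(cf["bottom"]))
  } else {
    tibble(ic50_uM = NA_real_, hill = NA_real_,
           top = NA_real_, bottom = NA_real_)
  }
  if (!converged) warn("dose-response fit did not converge; flagged")
  structure(list(
    compound_id = compound_id %||%
      (if ("compound_id" %in% names(points)) points$compound_id[1]
       else NA_character_),
    params = params,
    converged = converged,
    rss = if (converged) sum(stats::residuals(fit)^2) else NA_real_,
    fit = fit,
    points = points
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("<ic50_fit>", x$compound_id %||% "", "\n")
  if (x$converged) {
    cat(sprintf("  IC50 = %.4g uM, hill = %.3g, top = %.3g%%, bottom = %.3g%% (RSS %.3g)\n",
                x$params$ic50_uM, x$params$hill, x$params$top,
                x$params$bottom, x$rss))
  } else {
    cat("  not converged\n")
  }
  invisible(x)
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble(
    compound_id = x$compound_id,
    ic50_uM = x$params$ic50_uM,
    hill = x$params$hill,
    top = x$params$top,
    bottom = x$params$bottom,
    rss = x$rss,
    n_points = nrow(x$points),
    converged = x$converged
  )
}

#' @export
autoplot.ic50_fit <- function(object, ...) {
  pts <- object$points[object$points$concentration_uM > 0, ]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$concentration_uM,
                                         y = .data$pct_inhibition)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)", y = "% inhibition",
                  title = object$compound_id) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(concentration_uM = 10^seq(log10(min(pts$concentration_uM)),
                                             log10(max(pts$concentration_uM)),
                                             length.out = 200))
    grid$pct_inhibition <- fourpl(grid$concentration_uM,
                                  object$params$bottom, object$params$top,
                                  object$params$ic50_uM, object$params$hill)
    p <- p + ggplot2::geom_line(data = grid, color = "steelblue")
  }
  p
}

#' Fit dose-response curves for every compound on a plate
#'
#' @param plate Raw plate tibble (see [percent_inhibition()]).
#' @return Tibble with one row per compound ([glance()] of each fit), plus
#'   a `fit` list-column of `ic50_fit` objects.
#' @export
fit_plate <- function(plate) {
  norm <- percent_inhibition(plate)
  ids <- unique(norm$compound_id)
  fits <- map(ids, function(cid) {
    pts <- norm[norm$compound_id == cid, , drop = FALSE]
    tryCatch(fit_ic50(pts, compound_id = cid), error = function(e) NULL)
  })
  keepers <- !vapply(fits, is.null, logical(1))
  out <- bind_rows(map(fits[keepers], glance))
  out$fit <- fits[keepers]
  out
}
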