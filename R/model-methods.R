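#' @export
print.cw_model <- function(x, ...) {
  cat("Correlation-weight QSAR model\n")
  cat(sprintf("  target: %s, T = %d, N = %d epochs, seed = %d\n",
              x$control$target, x$control$threshold, x$control$epochs,
              x$control$seed))
  cat(sprintf("  attributes: %d active, %d blocked\n",
              length(x$weights), length(x$blocked)))
  cat(sprintf("  calibration line: endpoint = %.4f + %.4f * DCW\n",
              x$c0, x$c1))
  v <- x$stats$V
  if (!is.null(v))
    cat(sprintf("  validation: n = %d, R2 = %.4f, RMSE = %.3f\n",
                v$n, v$r2, v$rmse))
  invisible(x)
}

#' Per-set statistics table of a fitted model
#'
#' Builds the standard report: one row per set (active training, passive
#' training, calibration, validation) with n, R2, CCC, IIC, Q2, RMSE, MAE
#' and the F-ratio.
#'
#' @param object A fitted [cw_fit()] model.
#' @param ... Unused.
#' @return An object of class `"summary.cw_model"`: data frame with one row
#'   per set.
#' @export
summary.cw_model <- function(object, ...) {
  rows <- lapply(names(object$stats), function(s) {
    b <- object$stats[[s]]
    if (is.null(b)) return(NULL)
    data.frame(set = s, n = b$n, r2 = b$r2, ccc = b$ccc, iic = b$iic,
               q2 = b$q2, rmse = b$rmse, mae = b$mae, f = b$f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("summary.cw_model", "data.frame"),
            target = object$control$target,
            outliers = cw_outliers(object)$total)
}

#' @export
print.summary.cw_model <- function(x, ...) {
  cat("Model statistics per set (target", attr(x, "target"), "):\n")
  disp <- as.data.frame(x)
  disp$r2 <- round(disp$r2, 4); disp$ccc <- round(disp$ccc, 4)
  disp$iic <- round(disp$iic, 4); disp$q2 <- round(disp$q2, 4)
  disp$rmse <- signif(disp$rmse, 3); disp$mae <- signif(disp$mae, 3)
  disp$f <- round(disp$f)
  print(disp, row.names = FALSE)
  cat("Compounds outside the applicability domain:", attr(x, "outliers"), "\n")
  invisible(x)
}

#' @export
coef.cw_model <- function(object, which = c("line", "weights"), ...) {
  which <- match.arg(which)
  if (which == "line") c(c0 = object$c0, c1 = object$c1) else object$weights
}

#' Predict endpoints for new SMILES
#'
#' Applies the fitted model `endpoint = C0 + C1 * DCW` to new compounds.
#' Attributes unseen during training contribute zero to the descriptor but
#' raise the compound's statistical defect, so the `domain = TRUE` report
#' flags such compounds as outside the applicability domain when warranted.
#'
#' @param object A fitted [cw_fit()] model.
#' @param newdata Character vector of SMILES, or a data frame with a
#'   `smiles` column (and optionally `id`).  `NULL` returns fitted values.
#' @param domain If `TRUE`, return a data frame with descriptor, prediction,
#'   statistical defect and in-domain flag; otherwise a numeric vector.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a data frame when
#'   `domain = TRUE`.
#' @export
predict.cw_model <- function(object, newdata = NULL, domain = FALSE, ...) {
  if (is.null(newdata)) {
    if (!domain) return(object$fitted)
    dj <- object$domain$dj
    return(data.frame(id = names(object$fitted), dcw = unname(object$dcw),
                      predicted = unname(object$fitted), dj = unname(dj),
                      in_domain = unname(in_domain(dj, object$domain$dbar)),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(newdata)) {
    smiles <- newdata$smiles
    ids <- if (!is.null(newdata$id)) as.character(newdata$id)
    else as.character(seq_along(smiles))
  } else {
    smiles <- as.character(newdata)
    ids <- as.character(seq_along(smiles))
  }
  profiles <- lapply(smiles, attribute_profile)
  d <- vapply(profiles, dcw, numeric(1L), weights = object$weights,
              blocked = object$blocked)
  pred <- object$c0 + object$c1 * d
  if (!domain) return(stats::setNames(pred, ids))
  dj <- vapply(profiles, compound_defect, numeric(1L),
               domain = object$domain, blocked = object$blocked)
  data.frame(id = ids, dcw = d, predicted = pred, dj = dj,
             in_domain = in_domain(dj, object$domain$dbar),
             stringsAsFactors = FALSE)
}

#' @export
fitted.cw_model <- function(object, ...) object$fitted

#' @export
residuals.cw_model <- function(object, ...) {
  stats::setNames(object$data$endpoint, object$data$id) - object$fitted
}

#' Diagnostic plots for a correlation-weight model
#'
#' `which = "history"` draws the per-epoch trajectories of the target
#' function components (R2 on the active and passive training sets and on
#' the calibration set), the plot on which overtraining is diagnosed;
#' `which = "clusters"` draws observed versus predicted values colored by
#' residual sign.
#'
#' @param x A fitted [cw_fit()] model.
#' @param which `"history"` or `"clusters"`.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.cw_model <- function(x, which = c("history", "clusters"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    graphics::matplot(h$epoch, h[, c("r2_active", "r2_passive",
                                     "r2_calibration")],
                      type = "b", pch = 1:3, lty = 1, xlab = "epoch",
                      ylab = expression(R^2), ...)
    graphics::legend("bottomright", c("active", "passive", "calibration"),
                     pch = 1:3, col = 1:3, lty = 1, bty = "n")
  } else {
    obs <- x$data$endpoint
    pred <- unname(x$fitted)
    low <- obs < pred
    graphics::plot(pred, obs, col = ifelse(low, "blue", "orange"),
                   xlab = "predicted", ylab = "observed", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Simulate endpoints from a fitted model
#'
#' Draws new endpoint vectors as `fitted + Normal(0, rmse_A)` where
#' `rmse_A` is the active-training root mean squared error, the model's
#' native noise scale.
#'
#' @param object A fitted [cw_fit()] model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated endpoints.
#' @export
simulate.cw_model <- function(object, nsim = 1, seed = NULL, ...) {
  sim <- function() object$fitted +
    stats::rnorm(length(object$fitted), 0, object$stats$A$rmse)
  draw <- function() as.data.frame(replicate(nsim, sim()))
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(object$fitted)
  out
}
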