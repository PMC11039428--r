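#' Cook's distances for a fitted meta-analytic model
#'
#' For each record i the model is re-estimated without it and the displacement
#' of the fixed-effect vector is scaled by the full-data coefficient
#' covariance:
#' \deqn{D_i = (\beta_{(-i)} - \beta)^\top \, \Sigma_\beta^{-1} \,
#'       (\beta_{(-i)} - \beta).}
#' With `refit_components = TRUE` (the default) the variance components are
#' re-optimized for every deletion; otherwise they are held at the full-data
#' optimum and only the GLS step is redone (fast mode for large simulations).
#'
#' If deleting a record empties a moderator level, that record's distance is
#' computed on the reduced design (the estimable coefficients only), with a
#' note.
#'
#' @param spec a [model_spec()].
#' @param fit the full-data `meta_fit` for `spec`.
#' @param refit_components re-optimize variance components per deletion?
#' @return numeric vector of Cook's distances, one per record.
#' @export
cooks_distances <- function(spec, fit, refit_components = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(fit, "meta_fit"))
  n <- length(spec$y)
  p <- ncol(spec$X)
  if (n < p + 2) stop("too few records for leave-one-out influence (need n >= p + 2)")
  covb_inv <- solve(fit$cov_beta)
  D <- numeric(n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    spec_i <- spec_subset(spec, idx)
    est <- rep(TRUE, p)
    # columns that become constant zero after deletion are inestimable
    rank_ok <- qr(spec_i$X)$rank == p
    if (!rank_ok) {
      est <- apply(spec_i$X, 2, function(col) length(unique(col)) > 1)
      est[1] <- TRUE
      message("cooks_distances: record ", i,
              " deletion empties a design column; D computed on the reduced design")
      spec_i$X <- spec_i$X[, est, drop = FALSE]
      spec_i$block <- integer(0)
    }
    beta_i <- if (refit_components) {
      suppressWarnings(fit_reml(spec_i)$beta)
    } else {
      reml_core(fit$vc, spec_i)$beta
    }
    d <- beta_i - fit$beta[est]
    Vinv <- if (all(est)) covb_inv else solve(fit$cov_beta[est, est, drop = FALSE])
    D[i] <- drop(t(d) %*% Vinv %*% d)
  }
  D
}

#' Apply the outlier removal rule
#'
#' Flags records whose Cook's distance strictly exceeds three times the mean
#' distance, refits the model once on the retained records (a single pass, no
#' iteration), and reports both fits side by side.
#'
#' @param spec a [model_spec()].
#' @param fit the full-data `meta_fit`.
#' @param D optional precomputed Cook's distances (else computed here).
#' @param refit_components passed to [cooks_distances()].
#' @return an `influence_report`: `D`, `mean_D`, `threshold`, `flagged`
#'   (indices), `fit_full`, `fit_reduced` (equal to `fit_full` when nothing is
#'   flagged), `n_full`, `n_reduced`.
#' @export
apply_outlier_rule <- function(spec, fit, D = NULL, refit_components = TRUE) {
  if (is.null(D)) D <- cooks_distances(spec, fit, refit_components)
  if (any(!is.finite(D))) stop("non-finite Cook's distance(s)")
  mean_D <- mean(D)
  threshold <- 3 * mean_D
  flagged <- which(D > threshold)
  if (length(flagged) == length(D)) {
    stop("outlier rule flagged every record (degenerate application)")
  }
  fit_reduced <- if (length(flagged)) {
    fit_reml(spec_subset(spec, setdiff(seq_along(D), flagged)))
  } else {
    fit
  }
  structure(
    list(D = D, mean_D = mean_D, threshold = threshold, flagged = flagged,
         fit_full = fit, fit_reduced = fit_reduced,
         n_full = length(D), n_reduced = length(D) - length(flagged)),
    class = "influence_report"
  )
}

#' @export
print.influence_report <- function(x, ...) {
  cat("Cook's distance screen: mean D =", signif(x$mean_D, 4),
      "threshold (3x mean) =", signif(x$threshold, 4), "\n")
  cat(length(x$flagged), "of", x$n_full, "record(s) flagged",
      if (length(x$flagged)) paste0("(", paste(x$flagged, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Serialize an influence report
#'
#' Writes the per-record distances and flags as CSV and, optionally, the full
#' report (distances, threshold, both fits' coefficients) as JSON.
#'
#' @param report an `influence_report`.
#' @param csv,json output paths (either may be `NULL`).
#' @param ids optional record identifiers for the CSV.
#' @export
write_influence_report <- function(report, csv = NULL, json = NULL, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(report$D)
  tab <- data.frame(record = ids, D = report$D,
                    flagged = seq_along(report$D) %in% report$flagged)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(D = report$D, mean_D = report$mean_D, threshold = report$threshold,
           flagged = ids[report$flagged],
           beta_full = as.list(report$fit_full$beta),
           beta_reduced = as.list(report$fit_reduced$beta)),
      json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(tab)
}
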