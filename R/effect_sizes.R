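#' Percent change in symbiont fitness between two conditions
#'
#' Computes the ratio-of-means effect size
#' \deqn{100 \cdot (\bar{x}_c - \bar{x}_a) / \bar{x}_c}
#' where \eqn{\bar{x}_c} is the mean fitness in the control (reference)
#' condition — in symbiosis, ambient environment, or younger host — and
#' \eqn{\bar{x}_a} the mean in the alternative condition. Positive values mean
#' fitness is greater in the control condition; negative values mean it is
#' greater in the alternative condition.
#'
#' @param control_mean,alt_mean group mean fitness on the study's own scale
#'   (CFU, counts, density, ...). Vectorized.
#' @param scale `"percent"` (default, x100) or `"fraction"`.
#' @param id optional record identifiers used in error messages.
#' @return numeric vector of percent changes.
#' @export
percent_change <- function(control_mean, alt_mean, scale = c("percent", "fraction"),
                           id = NULL) {
  scale <- match.arg(scale)
  stopifnot(length(control_mean) == length(alt_mean))
  if (is.null(id)) id <- seq_along(control_mean)
  bad <- !is.na(control_mean) & control_mean == 0
  if (any(bad)) {
    stop("control mean is zero for record(s): ", paste(id[bad], collapse = ", "),
         " (percent change undefined)")
  }
  neg <- (!is.na(control_mean) & control_mean < 0) |
    (!is.na(alt_mean) & alt_mean < 0)
  if (any(neg)) {
    warning("negative fitness mean(s) for record(s): ",
            paste(id[neg], collapse = ", "),
            " (fitness measures are expected to be non-negative)")
  }
  k <- if (scale == "percent") 100 else 1
  k * (control_mean - alt_mean) / control_mean
}

#' Delta-method sampling variance of the percent change
#'
#' First-order delta-method variance of the ratio-of-means percent change.
#' With \eqn{r = \bar{x}_a/\bar{x}_c} and squared standard errors of the two
#' means \eqn{SE_c^2, SE_a^2} (SE = sd/sqrt(n) when dispersions are standard
#' deviations),
#' \deqn{v = 100^2 \, r^2 \left( SE_c^2/\bar{x}_c^2 + SE_a^2/\bar{x}_a^2 \right).}
#' The two group means are treated as independent.
#'
#' @param control_mean,alt_mean group means (both nonzero).
#' @param control_disp,alt_disp group dispersions.
#' @param control_n,alt_n group sample sizes.
#' @param disp_kind `"sd"` (dispersion is a standard deviation) or `"se"`
#'   (already a standard error). Recycled.
#' @param scale `"percent"` or `"fraction"`.
#' @param id optional record identifiers for error messages.
#' @return numeric vector of sampling variances (percent squared).
#' @export
delta_method_variance <- function(control_mean, alt_mean,
                                  control_disp, alt_disp,
                                  control_n, alt_n,
                                  disp_kind = "sd",
                                  scale = c("percent", "fraction"),
                                  id = NULL) {
  scale <- match.arg(scale)
  n_rec <- length(control_mean)
  disp_kind <- rep_len(disp_kind, n_rec)
  if (is.null(id)) id <- seq_len(n_rec)
  if (!all(disp_kind %in% c("sd", "se"))) {
    stop("disp_kind must be 'sd' or 'se'")
  }
  bad <- (!is.na(control_mean) & control_mean == 0) |
    (!is.na(alt_mean) & alt_mean == 0)
  if (any(bad)) {
    stop("zero mean for record(s): ", paste(id[bad], collapse = ", "),
         " (delta-method variance undefined)")
  }
  if (any(control_disp < 0, na.rm = TRUE) || any(alt_disp < 0, na.rm = TRUE)) {
    stop("dispersions must be non-negative")
  }
  deg <- disp_kind == "sd" & (control_n < 2 | alt_n < 2) &
    (control_disp > 0 | alt_disp > 0)
  if (any(deg, na.rm = TRUE)) {
    stop("n = 1 with dispersion_kind = sd for record(s): ",
         paste(id[which(deg)], collapse = ", "), " (standard error undefined)")
  }
  se_c <- ifelse(disp_kind == "sd", control_disp / sqrt(control_n), control_disp)
  se_a <- ifelse(disp_kind == "sd", alt_disp / sqrt(alt_n), alt_disp)
  k <- if (scale == "percent") 100 else 1
  r <- alt_mean / control_mean
  k^2 * r^2 * (se_c^2 / control_mean^2 + se_a^2 / alt_mean^2)
}

#' Sign-preserving cube root
#'
#' `sign(x) * |x|^(1/3)`: odd, strictly increasing, a bijection on the reals.
#' Used to pull in the very large percent changes while preserving their sign.
#'
#' @param x numeric vector.
#' @return numeric vector, same length.
#' @export
signed_cube_root <- function(x) {
  sign(x) * abs(x)^(1 / 3)
}

#' Cube-root transform of an effect size and its variance
#'
#' Applies the sign-preserving cube root to the percent change and, in the
#' default literal mode, a plain cube root to the sampling variance (the
#' variance is non-negative, so signed and plain cube roots coincide). The
#' transformed variance `v` is used downstream as the known sampling variance
#' of `y`. The alternative `"delta"` mode cube-roots only the effect and
#' propagates the variance to the transformed scale by the delta method,
#' \eqn{v' = v / (9 |pc|^{4/3})}, for sensitivity analysis; it is guarded
#' against `pc -> 0` by flooring `|pc|` at `pc_floor`.
#'
#' @param percent_change numeric vector of percent changes.
#' @param variance numeric vector of non-negative sampling variances.
#' @param variance_mode `"literal"` (default) or `"delta"`.
#' @param pc_floor floor on `|percent_change|` in the delta mode.
#' @return list with components `y` and `v`.
#' @export
transform_effect <- function(percent_change, variance,
                             variance_mode = c("literal", "delta"),
                             pc_floor = 1e-8) {
  variance_mode <- match.arg(variance_mode)
  if (any(variance < 0, na.rm = TRUE)) {
    stop("negative sampling variance(s): cube-root transform undefined")
  }
  y <- signed_cube_root(percent_change)
  v <- switch(variance_mode,
    literal = variance^(1 / 3),
    delta = variance / (9 * pmax(abs(percent_change), pc_floor)^(4 / 3))
  )
  list(y = y, v = v)
}

#' Compute effect sizes for a whole dataset
#'
#' Takes a data frame in the project schema (one row per effect size, columns
#' `control_mean`, `control_disp`, `control_n`, `alt_mean`, `alt_disp`,
#' `alt_n`, `disp_kind`, plus identifiers and moderators) and appends
#' `percent_change`, `variance`, `y` and `v`. Rows that already carry
#' `percent_change`/`variance` keep their precomputed values; only missing
#' entries are filled from the raw summaries.
#'
#' @param records data frame of effect-size records.
#' @param scale,variance_mode passed to [percent_change()],
#'   [delta_method_variance()] and [transform_effect()].
#' @return the input data frame augmented with `percent_change`, `variance`,
#'   `y`, `v`.
#' @export
compute_effect_sizes <- function(records, scale = "percent",
                                 variance_mode = "literal") {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  id <- if ("effect_id" %in% names(records)) records$effect_id else seq_len(n)
  pc <- if ("percent_change" %in% names(records)) records$percent_change
        else rep(NA_real_, n)
  vr <- if ("variance" %in% names(records)) records$variance
        else rep(NA_real_, n)
  need <- is.na(pc) | is.na(vr)
  if (any(need)) {
    raw_cols <- c("control_mean", "control_disp", "control_n",
                  "alt_mean", "alt_disp", "alt_n")
    missing_cols <- setdiff(raw_cols, names(records))
    if (length(missing_cols)) {
      stop("records lack precomputed effect sizes and raw summary column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    dk <- if ("disp_kind" %in% names(records)) records$disp_kind else "sd"
    sub <- records[need, , drop = FALSE]
    pc[need] <- percent_change(sub$control_mean, sub$alt_mean,
                               scale = scale, id = id[need])
    vr[need] <- delta_method_variance(
      sub$control_mean, sub$alt_mean,
      sub$control_disp, sub$alt_disp,
      sub$control_n, sub$alt_n,
      disp_kind = rep_len(dk, n)[need], scale = scale, id = id[need]
    )
  }
  tr <- transform_effect(pc, vr, variance_mode = variance_mode)
  records$percent_change <- pc
  records$variance <- vr
  records$y <- tr$y
  records$v <- tr$v
  records
}
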