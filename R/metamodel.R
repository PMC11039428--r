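#' Specify a multilevel meta-analytic model
#'
#' Bundles the aligned ingredients of the model: transformed effects `y`,
#' their known sampling variances `v`, a fixed-effect design matrix `X`
#' (default: intercept only), an optional study grouping factor for the
#' between-study component, and an optional phylogenetic correlation matrix
#' `R` with a record-to-tip mapping for the phylogenetic component. The
#' within-record component always uses the identity structure.
#'
#' Sampling variances must be positive; exact zeros arise from degenerate
#' source data and are floored at `v_floor` with a warning so the marginal
#' covariance stays invertible.
#'
#' @param y numeric vector of transformed effect sizes.
#' @param v numeric vector of known sampling variances, same length.
#' @param X design matrix (rows aligned with `y`); default intercept only.
#' @param study optional study identifiers (vector, length of `y`).
#' @param tip optional tip labels mapping each record to a row/column of `R`.
#' @param R optional tip-by-tip correlation matrix (unit diagonal, PSD) with
#'   dimnames covering all values of `tip`.
#' @param block integer indices of the moderator coefficient block in `X`
#'   (excluding the intercept); empty for intercept-only models.
#' @param v_floor floor applied to non-positive sampling variances.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(y, v, X = NULL, study = NULL, tip = NULL, R = NULL,
                       block = integer(0), v_floor = 1e-10) {
  n <- length(y)
  stopifnot(length(v) == n)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intrcpt"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (!is.null(study)) stopifnot(length(study) == n)
  if (!is.null(R)) {
    if (is.null(tip)) stop("a correlation matrix requires a record-to-tip mapping")
    stopifnot(length(tip) == n)
    tip <- as.character(tip)
    if (is.null(rownames(R))) stop("R must carry tip labels as dimnames")
    missing_tips <- setdiff(unique(tip), rownames(R))
    if (length(missing_tips)) {
      stop("record tip(s) absent from correlation matrix: ",
           paste(missing_tips, collapse = ", "))
    }
    if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix is not symmetric")
    ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) {
      stop("correlation matrix is not positive semidefinite (min eigenvalue ",
           format(ev_min), ")")
    }
  }
  if (any(v <= 0)) {
    warning(sum(v <= 0), " non-positive sampling variance(s) floored at ",
            v_floor)
    v[v <= 0] <- v_floor
  }
  structure(
    list(y = as.numeric(y), v = as.numeric(v), X = X,
         study = study, tip = tip, R = R, block = as.integer(block)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", length(x$y), "records,", ncol(x$X), "fixed effect(s);",
      "components:", paste(spec_components(x), collapse = " + "), "\n")
  invisible(x)
}

spec_components <- function(spec) {
  comps <- "within"
  if (!is.null(spec$study)) comps <- c("study", comps)
  if (!is.null(spec$R)) comps <- c(comps, "phylo")
  comps
}

spec_subset <- function(spec, idx) {
  model_spec(spec$y[idx], spec$v[idx], spec$X[idx, , drop = FALSE],
             study = if (!is.null(spec$study)) spec$study[idx],
             tip = if (!is.null(spec$tip)) spec$tip[idx],
             R = spec$R, block = spec$block)
}

#' Marginal covariance matrix of the observed effects
#'
#' \deqn{M = diag(v) + \sigma^2_{study} S + \sigma^2_{within} I +
#'       \sigma^2_{phylo} R_{exp}}
#' where `S[i,j] = 1` iff records i and j share a study and `R_exp` is the
#' tip-level Brownian-motion correlation lifted to records.
#'
#' @param vc named numeric: any of `study`, `within`, `phylo` (missing
#'   components are taken as 0).
#' @param spec a [model_spec()].
#' @return symmetric n-by-n matrix.
#' @export
marginal_covariance <- function(vc, spec) {
  n <- length(spec$y)
  M <- diag(spec$v, n)
  s_study <- vc_get(vc, "study")
  s_within <- vc_get(vc, "within")
  s_phylo <- vc_get(vc, "phylo")
  if (s_within != 0) M <- M + diag(s_within, n)
  if (s_study != 0) {
    if (is.null(spec$study)) stop("sigma2_study > 0 but no study factor in spec")
    S <- outer(spec$study, spec$study, `==`) * 1
    M <- M + s_study * S
  }
  if (s_phylo != 0) {
    if (is.null(spec$R)) stop("sigma2_phylo > 0 but no correlation matrix in spec")
    Rexp <- spec$R[spec$tip, spec$tip, drop = FALSE]
    M <- M + s_phylo * Rexp
  }
  dimnames(M) <- NULL
  M
}

vc_get <- function(vc, name) {
  if (is.null(vc) || !name %in% names(vc)) 0 else unname(vc[[name]])
}

#' Restricted log-likelihood of the variance components
#'
#' \deqn{\ell_R = -\tfrac12 \left[ \log|M| + \log|X^\top M^{-1} X| + y^\top P y
#'   + (n - p)\log 2\pi \right]}
#' with \eqn{P = M^{-1} - M^{-1}X(X^\top M^{-1}X)^{-1}X^\top M^{-1}}.
#'
#' @param vc named variance components (see [marginal_covariance()]).
#' @param spec a [model_spec()].
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(vc, spec) {
  reml_core(vc, spec)$ll
}

# One pass over the dense algebra shared by reml_loglik and the GLS step:
# Cholesky of M, GLS beta, covariance, residual quadratic form.
reml_core <- function(vc, spec) {
  M <- marginal_covariance(vc, spec)
  L <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(L)) return(list(ll = -Inf))
  X <- spec$X
  y <- spec$y
  n <- length(y)
  p <- ncol(X)
  Minv_X <- backsolve(L, forwardsolve(t(L), X))
  Minv_y <- backsolve(L, forwardsolve(t(L), y))
  XtMinvX <- crossprod(X, Minv_X)
  XtMinvy <- crossprod(X, Minv_y)
  cf <- tryCatch(chol(XtMinvX), error = function(e) NULL)
  if (is.null(cf)) stop("X'M^-1X is singular (rank-deficient design)")
  cov_beta <- chol2inv(cf)
  beta <- drop(cov_beta %*% XtMinvy)
  resid <- y - drop(X %*% beta)
  Minv_r <- backsolve(L, forwardsolve(t(L), resid))
  quad <- drop(crossprod(resid, Minv_r))
  logdet_M <- 2 * sum(log(diag(L)))
  logdet_XtMinvX <- 2 * sum(log(diag(cf)))
  ll <- -0.5 * (logdet_M + logdet_XtMinvX + quad + (n - p) * log(2 * pi))
  list(ll = ll, beta = beta, cov_beta = cov_beta)
}

#' Fit the multilevel meta-analytic model by REML
#'
#' Maximizes the restricted log-likelihood over the non-negative variance
#' components present in the spec (between-study if a study factor is given,
#' within-record always, phylogenetic if a correlation matrix is given), then
#' computes the GLS fixed effects, their covariance, Wald z statistics and
#' two-sided normal p values at the optimum. The optimizer is bound-
#' constrained quasi-Newton (`L-BFGS-B`) launched from three starting points —
#' all zeros, a method-of-moments point, and an equal split of the excess
#' residual variance — keeping the best converged solution.
#'
#' @param spec a [model_spec()].
#' @param fixed optional named numeric of components held fixed (not
#'   optimized), e.g. `c(study = 0, within = 0, phylo = 0)` for the
#'   fixed-effect (inverse-variance) limit.
#' @param reltol relative convergence tolerance of the optimizer.
#' @return an object of class `meta_fit`: `beta`, `se`, `zval`, `pval`,
#'   `cov_beta`, `vc` (named variance components), `reml_loglik`, `n`, `p`,
#'   `block`, `QM`/`QM_df`/`QM_p` when a moderator block is present, and a
#'   `convergence` record (per-start status and the retained start).
#' @export
fit_reml <- function(spec, fixed = NULL, reltol = 1e-8) {
  stopifnot(inherits(spec, "model_spec"))
  n <- length(spec$y)
  p <- ncol(spec$X)
  if (n <= p) stop("need more records than fixed effects (n > p)")
  if (qr(spec$X)$rank < p) stop("X'M^-1X is singular (rank-deficient design)")
  comps <- spec_components(spec)
  free <- setdiff(comps, names(fixed))
  fixed_vec <- if (is.null(fixed)) numeric(0) else unlist(fixed)

  make_vc <- function(theta) c(theta, fixed_vec)[comps]
  negll <- function(theta) {
    names(theta) <- free
    -reml_core(make_vc(theta), spec)$ll
  }

  if (length(free) == 0L) {
    vc <- fixed_vec[comps]
    core <- reml_core(vc, spec)
    conv <- list(status = "no free components", start = NA_integer_)
  } else {
    # method-of-moments scale: excess of weighted residual variance over
    # the mean sampling variance
    w <- 1 / spec$v
    bw <- tryCatch(
      stats::lm.wfit(spec$X, spec$y, w)$coefficients,
      error = function(e) rep(0, p)
    )
    bw[is.na(bw)] <- 0
    r <- spec$y - drop(spec$X %*% bw)
    s2_excess <- max(stats::var(r) - mean(spec$v), mean(spec$v) * 1e-3)
    starts <- list(
      rep(1e-4, length(free)),
      stats::setNames(ifelse(free == "within", s2_excess, 1e-4), free),
      rep(s2_excess / length(free), length(free))
    )
    # L-BFGS-B first; its line search can abort on flat boundary likelihoods,
    # in which case nlminb (PORT) is retried from the same start
    optimize_one <- function(s0) {
      run <- tryCatch(
        stats::optim(s0, negll, method = "L-BFGS-B",
                     lower = rep(0, length(free)),
                     control = list(factr = reltol / .Machine$double.eps,
                                    maxit = 500)),
        error = function(e) list(value = Inf, convergence = 99L,
                                 message = conditionMessage(e))
      )
      if (run$convergence != 0L) {
        alt <- tryCatch(
          stats::nlminb(s0, negll, lower = rep(0, length(free)),
                        control = list(rel.tol = reltol, iter.max = 500)),
          error = function(e) NULL
        )
        if (!is.null(alt) && alt$convergence == 0L) {
          run <- list(par = alt$par, value = alt$objective, convergence = 0L)
        }
      }
      run
    }
    runs <- lapply(starts, optimize_one)
    vals <- vapply(runs, function(r) r$value, numeric(1))
    conv_ok <- vapply(runs, function(r) identical(r$convergence, 0L), logical(1))
    if (all(!is.finite(vals))) {
      stop("REML optimization failed from all starting points")
    }
    best <- if (any(conv_ok)) which(conv_ok)[which.min(vals[conv_ok])]
            else which.min(vals)
    opt <- runs[[best]]
    theta <- opt$par
    names(theta) <- free
    vc <- make_vc(theta)
    core <- reml_core(vc, spec)
    conv <- list(status = opt$convergence, start = best,
                 value = opt$value,
                 per_start = vals,
                 message = if (!is.null(opt$message)) opt$message else "")
    if (opt$convergence != 0L) {
      stop("REML optimizer did not converge (status ", opt$convergence,
           "): best nll ", format(opt$value), "; ", conv$message)
    }
  }

  se <- sqrt(diag(core$cov_beta))
  zval <- core$beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  fit <- structure(
    list(beta = stats::setNames(core$beta, colnames(spec$X)),
         se = se, zval = zval, pval = pval,
         cov_beta = core$cov_beta,
         vc = vc, reml_loglik = core$ll,
         n = n, p = p, block = spec$block,
         convergence = conv, spec = spec),
    class = "meta_fit"
  )
  if (length(spec$block)) {
    qm <- wald_tests(fit, spec$block)
    fit$QM <- qm$QM
    fit$QM_df <- qm$df
    fit$QM_p <- qm$p
  }
  fit
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic model (REML), n =", x$n, "\n")
  cat("Variance components:\n")
  print(round(x$vc, digits))
  tab <- data.frame(estimate = x$beta, se = x$se, zval = x$zval, pval = x$pval)
  print(round(tab, digits))
  if (!is.null(x$QM)) {
    cat(sprintf("QM = %.*f, df = %d, p = %.*f\n",
                digits, x$QM, x$QM_df, digits, x$QM_p))
  }
  invisible(x)
}

#' Wald z and omnibus QM moderator test
#'
#' For the coefficient block indexed by `block`,
#' \deqn{Q_M = \beta_b^\top \, (\Sigma_{bb})^{-1} \, \beta_b}
#' compared to a chi-square distribution with `length(block)` degrees of
#' freedom. Per-coefficient z statistics with two-sided normal p values are
#' returned for the whole coefficient vector.
#'
#' @param fit a `meta_fit`.
#' @param block integer indices of the moderator coefficients; defaults to
#'   the block stored in the spec.
#' @return list with `z`, `p` (per coefficient), and `QM`, `df`, `p` for the
#'   block.
#' @export
wald_tests <- function(fit, block = fit$block) {
  stopifnot(inherits(fit, "meta_fit"))
  if (length(block) == 0L) {
    stop("empty moderator block: use the intercept z test for overall models")
  }
  b <- fit$beta[block]
  Vb <- fit$cov_beta[block, block, drop = FALSE]
  QM <- drop(t(b) %*% solve(Vb) %*% b)
  df <- length(block)
  list(z = fit$zval, p_z = fit$pval,
       QM = QM, df = df, p = stats::pchisq(QM, df, lower.tail = FALSE))
}

#' Build a fixed-effect design matrix for a moderator analysis
#'
#' Intercept plus, for a categorical moderator, `levels - 1` dummy columns
#' against the alphabetically first reference level (so a k-level factor
#' yields a df = k-1 omnibus QM test), or, for a numeric moderator, one
#' centered continuous column (df = 1). Records with a missing moderator
#' value are dropped, with the count reported.
#'
#' @param records data frame of effect-size records.
#' @param moderator column name, or `NULL` for an intercept-only design.
#' @return list: `X` (design matrix), `block` (moderator coefficient
#'   indices), `df`, `keep` (logical row filter applied), `reference`
#'   (reference level, categorical only), `n_dropped`.
#' @export
build_design <- function(records, moderator = NULL) {
  n <- nrow(records)
  if (is.null(moderator)) {
    return(list(X = matrix(1, n, 1, dimnames = list(NULL, "intrcpt")),
                block = integer(0), df = 0L,
                keep = rep(TRUE, n), reference = NULL, n_dropped = 0L))
  }
  if (!moderator %in% names(records)) {
    stop("moderator column not found: ", moderator)
  }
  x <- records[[moderator]]
  keep <- !is.na(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("build_design: dropping ", n_dropped,
            " record(s) with missing '", moderator, "'")
  }
  x <- x[keep]
  if (is.numeric(x)) {
    X <- cbind(intrcpt = 1, scale(x, center = TRUE, scale = FALSE)[, 1])
    colnames(X)[2] <- moderator
    block <- 2L
    reference <- NULL
  } else {
    lev <- sort(unique(as.character(x)))
    if (length(lev) < 2L) {
      stop("moderator '", moderator, "' has a single observed level: ", lev)
    }
    f <- factor(x, levels = lev)
    X <- stats::model.matrix(~f)
    colnames(X) <- c("intrcpt", paste0(moderator, lev[-1]))
    attr(X, "assign") <- NULL
    attr(X, "contrasts") <- NULL
    block <- seq(2L, ncol(X))
    reference <- lev[1]
  }
  list(X = X, block = as.integer(block), df = length(block),
       keep = keep, reference = reference, n_dropped = n_dropped)
}
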