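test_that("design builder encodes moderators with the right omnibus df", {
  rec <- data.frame(kingdom = c("animal", "plant", "protist",
                                "animal", "plant", "protist"),
                    gen_time = c(0.1, 1, 2, 5, 10, 0.5))
  d <- build_design(rec, "kingdom")
  expect_equal(dim(d$X), c(6, 3))
  expect_equal(d$block, c(2L, 3L))
  expect_equal(d$df, 2L)
  expect_equal(d$reference, "animal")  # alphabetically first level
  expect_equal(unname(d$X[, 1]), rep(1, 6))

  d0 <- build_design(rec, NULL)
  expect_equal(unname(d0$X), matrix(1, 6, 1))
  expect_length(d0$block, 0)

  dc <- build_design(rec, "gen_time")
  expect_equal(dc$df, 1L)
  expect_equal(mean(dc$X[, 2]), 0)  # centered continuous covariate

  rec$mono <- "same"
  expect_error(build_design(rec, "mono"), "single observed level")
  rec$kingdom[1] <- NA
  expect_message(d2 <- build_design(rec, "kingdom"), "dropping 1")
  expect_equal(sum(d2$keep), 5)
})

test_that("marginal covariance assembles the three structures correctly", {
  spec <- model_spec(y = c(0, 0), v = c(1, 1), study = c("s1", "s1"))
  expect_equal(marginal_covariance(c(study = 0, within = 0), spec),
               diag(c(1, 1)))
  expect_equal(marginal_covariance(c(study = 2), spec),
               matrix(c(3, 2, 2, 3), 2))

  tr <- random_fixture_tree(8, seed = 2)
  R <- bm_correlation(tr)
  set.seed(30)
  for (k in 1:5) {
    n <- 12
    spec <- model_spec(rnorm(n), runif(n, 0.2, 1),
                       study = sample(letters[1:4], n, replace = TRUE),
                       tip = sample(rownames(R), n, replace = TRUE), R = R)
    M <- marginal_covariance(c(study = runif(1), within = runif(1),
                               phylo = runif(1)), spec)
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_silent(chol(M))
  }
})

test_that("restricted likelihood matches closed form and the dense oracle", {
  # n = 2, intercept only, unit variances, zero components:
  # -1/2 [ log|I| + log|X'X| + 0 + (n-p) log 2pi ] with |X'X| = 2
  spec <- model_spec(y = c(0, 0), v = c(1, 1))
  expect_equal(reml_loglik(c(within = 0), spec),
               -0.5 * (log(2) + log(2 * pi)))

  # shift invariance with an intercept present
  set.seed(41)
  y <- rnorm(10); v <- runif(10, 0.3, 1)
  s1 <- model_spec(y, v, study = rep(letters[1:5], 2))
  s2 <- model_spec(y + 17.3, v, study = rep(letters[1:5], 2))
  vc <- c(study = 0.3, within = 0.2)
  expect_equal(reml_loglik(vc, s1), reml_loglik(vc, s2), tolerance = 1e-10)

  # dense-algebra oracle on random small specs
  tr <- random_fixture_tree(6, seed = 8)
  R <- bm_correlation(tr)
  set.seed(55)
  for (k in 1:10) {
    n <- 9
    X <- cbind(1, rnorm(n))
    spec <- model_spec(rnorm(n), runif(n, 0.2, 2), X,
                       study = sample(letters[1:3], n, replace = TRUE),
                       tip = sample(rownames(R), n, replace = TRUE), R = R,
                       block = 2L)
    vc <- c(study = runif(1), within = runif(1), phylo = runif(1))
    expect_equal(reml_loglik(vc, spec), reml_loglik_dense(vc, spec),
                 tolerance = 1e-8)
  }
})

test_that("REML fit reduces to the closed-form limits", {
  set.seed(61)
  y <- rnorm(20, 1, 1); v <- runif(20, 0.3, 2)
  # all components pinned at zero: inverse-variance fixed-effect estimate
  spec <- model_spec(y, v)
  f0 <- fit_reml(spec, fixed = c(within = 0))
  w <- 1 / v
  expect_equal(unname(f0$beta), sum(w * y) / sum(w), tolerance = 1e-10)
  expect_equal(f0$se, sqrt(1 / sum(w)), tolerance = 1e-10)

  # equal sampling variances, intercept only: REML within-variance equals
  # max(0, sample variance - v) and beta is the plain mean
  v_eq <- rep(0.4, 20)
  f1 <- fit_reml(model_spec(y, v_eq))
  expect_equal(unname(f1$beta), mean(y), tolerance = 1e-8)
  expect_equal(unname(f1$vc["within"]), max(0, var(y) - 0.4), tolerance = 1e-6)

  # same but truncated at the bound: huge v forces the component to zero
  f2 <- fit_reml(model_spec(y, rep(50, 20)))
  expect_equal(unname(f2$vc["within"]), 0, tolerance = 1e-8)
})

test_that("REML fit is permutation-equivariant and ignores an inert correlation matrix", {
  tr <- random_fixture_tree(10, seed = 14)
  R <- bm_correlation(tr)
  set.seed(71)
  n <- 30
  study <- sample(paste0("s", 1:10), n, replace = TRUE)
  tip <- sample(rownames(R), n, replace = TRUE)
  y <- rnorm(n); v <- runif(n, 0.3, 1)

  spec <- model_spec(y, v, study = study, tip = tip, R = R)
  fit <- fit_reml(spec)
  perm <- sample(n)
  fitp <- fit_reml(model_spec(y[perm], v[perm], study = study[perm],
                              tip = tip[perm], R = R))
  expect_equal(fitp$beta, fit$beta, tolerance = 1e-6)
  expect_equal(fitp$vc, fit$vc, tolerance = 1e-4)

  # with sigma2_phylo pinned at 0 the matrix is inert
  f_r <- fit_reml(spec, fixed = c(phylo = 0))
  f_nor <- fit_reml(model_spec(y, v, study = study))
  expect_equal(f_r$beta, f_nor$beta, tolerance = 1e-8)
  expect_equal(f_r$vc[c("study", "within")], f_nor$vc[c("study", "within")],
               tolerance = 1e-6)
})

test_that("Wald z and QM behave as a coherent pair", {
  # scalar block: QM = z^2 and the chi-square(1) p equals the normal p
  set.seed(81)
  n <- 40
  x <- rnorm(n)
  y <- 0.2 + 0.3 * x + rnorm(n, 0, 1)
  spec <- model_spec(y, runif(n, 0.5, 1), cbind(intrcpt = 1, x = x), block = 2L)
  fit <- fit_reml(spec)
  wt <- wald_tests(fit)
  expect_equal(wt$QM, fit$zval[2]^2, tolerance = 1e-10)
  expect_equal(wt$p, fit$pval[2], tolerance = 1e-12)

  # brute-force quadratic form with an explicit inverse
  f3 <- fit_reml(model_spec(y, runif(n, 0.5, 1),
                            cbind(1, x, x^2), block = c(2L, 3L)))
  b <- f3$beta[2:3]
  Vb <- f3$cov_beta[2:3, 2:3]
  expect_equal(f3$QM, drop(t(b) %*% solve(Vb) %*% b), tolerance = 1e-10)
  expect_equal(f3$QM_df, 2L)

  # an exactly-zero block gives QM = 0, p = 1
  fz <- fit_reml(spec)
  fz$beta[2] <- 0
  expect_equal(wald_tests(fz, 2L)$QM, 0)
  expect_equal(wald_tests(fz, 2L)$p, 1)

  expect_error(wald_tests(fit, integer(0)), "empty")
})

test_that("fit agrees with metafor's rma.mv on all reported quantities", {
  skip_if_not_installed("metafor")
  tr <- simulation_truth(beta0 = 0.3, n_studies = 25, n_tips = 15, seed = 7,
                         sigma2_phylo = 0.8,
                         moderators = list(kingdom = list(
                           type = "categorical",
                           levels = c("animal", "plant", "protist"),
                           effects = c(animal = 0, plant = 0.6, protist = -0.4))))
  sim <- simulate_dataset(tr)
  rec <- sim$records
  R <- bm_correlation(sim$tree)

  spec <- model_spec(rec$y, rec$v, study = rec$study_id,
                     tip = rec$symbiont_species, R = R)
  fit <- fit_reml(spec)
  mf <- suppressWarnings(metafor::rma.mv(
    rec$y, rec$v,
    random = list(~ 1 | study_id, ~ 1 | effect_id, ~ 1 | symbiont_species),
    R = list(symbiont_species = R), data = rec, method = "REML",
    control = list(optimizer = "optim", optmethod = "L-BFGS-B")))
  expect_equal(unname(fit$beta), unname(coef(mf)), tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(mf$se), tolerance = 1e-3)
  expect_equal(unname(fit$vc), unname(mf$sigma2), tolerance = 1e-2)
  # same REML criterion up to the +0.5 log|X'X| constant metafor includes
  expect_equal(fit$reml_loglik + 0.5 * determinant(crossprod(spec$X))$modulus[1],
               as.numeric(logLik(mf)), tolerance = 1e-4)

  d <- build_design(rec, "kingdom")
  fitm <- fit_reml(model_spec(rec$y, rec$v, d$X, study = rec$study_id,
                              tip = rec$symbiont_species, R = R,
                              block = d$block))
  mfm <- suppressWarnings(metafor::rma.mv(
    rec$y, rec$v, mods = ~ kingdom,
    random = list(~ 1 | study_id, ~ 1 | effect_id, ~ 1 | symbiont_species),
    R = list(symbiont_species = R), data = rec, method = "REML",
    control = list(optimizer = "optim", optmethod = "L-BFGS-B")))
  expect_equal(fitm$QM, mfm$QM, tolerance = 1e-3)
  expect_equal(fitm$QM_p, mfm$QMp, tolerance = 1e-3)
})

test_that("degenerate inputs are rejected or repaired as documented", {
  expect_error(fit_reml(model_spec(1:2, c(1, 1), cbind(1, c(1, 2)))), "n > p")
  expect_warning(model_spec(c(1, 2), c(0, 1)), "floored")
  sp <- suppressWarnings(model_spec(c(1, 2), c(0, 1)))
  expect_equal(sp$v[1], 1e-10)
  # rank-deficient design
  expect_error(
    fit_reml(model_spec(rnorm(6), rep(1, 6), cbind(rep(1, 6), rep(1, 6)))),
    "rank-deficient"
  )
  # R without labels, or records mapping to unknown tips
  R <- diag(2)
  expect_error(model_spec(1:3, rep(1, 3), tip = c("a", "b", "a"), R = R),
               "dimnames")
  dimnames(R) <- list(c("a", "b"), c("a", "b"))
  expect_error(model_spec(1:3, rep(1, 3), tip = c("a", "c", "a"), R = R), "c")
})
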