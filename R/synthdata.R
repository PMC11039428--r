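# Seeded RNG scope: run code under a given seed, then restore the caller's
# RNG state so generators are deterministic per seed without side effects.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate an ultrametric pure-birth tree
#'
#' Pure-birth (Yule) tree with exponential branching times, rescaled to unit
#' root-to-tip depth. Deterministic per seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param tip_prefix prefix for tip labels (`sym_1`, `sym_2`, ...).
#' @return an ultrametric `phylo` object of depth 1.
#' @export
simulate_tree <- function(n_tips, seed = 1, tip_prefix = "sym") {
  if (n_tips < 2) stop("n_tips must be at least 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0(tip_prefix, "_", seq_len(n_tips))
  tree
}

#' Generating parameters for a synthetic meta-analytic dataset
#'
#' Defaults emulate the statistical structure of a symbiont-fitness corpus of
#' moderate size on the cube-root-transformed scale: ~50 studies contributing
#' 1–5 effect sizes each, 60 symbiont species, comparable between-study and
#' within-study heterogeneity, a weaker phylogenetic component, and
#' heteroscedastic known sampling variances.
#'
#' @param beta0 true overall (intercept) transformed effect.
#' @param sigma2_study,sigma2_within,sigma2_phylo true variance components
#'   (non-negative, transformed scale).
#' @param v_range range of the known sampling variances (drawn uniformly).
#' @param n_studies number of studies.
#' @param effects_per_study integer range `c(min, max)`; each study's record
#'   count is drawn uniformly from it.
#' @param n_tips number of symbiont species (tree tips).
#' @param moderators named list of moderator descriptions. A categorical
#'   moderator is `list(type = "categorical", levels = ..., probs = ...,
#'   effects = ...)` with `effects` named per level (reference effect 0); a
#'   continuous one is `list(type = "continuous", mean = , sd = , slope = )`.
#' @param analysis analysis label stamped on every record.
#' @param seed integer seed.
#' @return an object of class `simulation_truth`.
#' @export
simulation_truth <- function(beta0 = 0,
                             sigma2_study = 1, sigma2_within = 1,
                             sigma2_phylo = 0.5,
                             v_range = c(0.5, 2),
                             n_studies = 50,
                             effects_per_study = c(1, 5),
                             n_tips = 60,
                             moderators = list(),
                             analysis = "environment",
                             seed = 1) {
  stopifnot(sigma2_study >= 0, sigma2_within >= 0, sigma2_phylo >= 0,
            length(v_range) == 2, all(v_range >= 0),
            n_studies >= 1, n_tips >= 2,
            length(effects_per_study) == 2,
            effects_per_study[1] >= 1,
            effects_per_study[2] >= effects_per_study[1])
  structure(
    list(beta0 = beta0, sigma2_study = sigma2_study,
         sigma2_within = sigma2_within, sigma2_phylo = sigma2_phylo,
         v_range = v_range, n_studies = n_studies,
         effects_per_study = effects_per_study, n_tips = n_tips,
         moderators = moderators, analysis = analysis, seed = seed),
    class = "simulation_truth"
  )
}

#' Simulate an effect-size dataset with known truth
#'
#' Draws study effects ~ N(0, sigma2_study), record effects ~
#' N(0, sigma2_within), species-level phylogenetic effects ~
#' MVN(0, sigma2_phylo * R) via the Cholesky factor of the tree's
#' Brownian-motion correlation, and sampling errors ~ N(0, v_i), and sums
#' them with the fixed part to give the transformed effect
#' `y_i = beta0 + x_i' b + u_study + u_record + u_phylo + e_i`.
#'
#' Each record also carries back-transformed raw two-group summaries
#' (`control_mean = 100`, and an alternative mean, SDs and n = 5 chosen so
#' that the percent change and delta-method variance reproduce `y_i`, `v_i`
#' exactly after the cube-root transform), so the effect-size module can be
#' exercised end to end. Records whose implied percent change reaches 100
#' (alternative mean would be non-positive) are emitted on the transformed
#' scale only, with `raw_ok = FALSE`.
#'
#' @param truth a [simulation_truth()].
#' @param tree optional `phylo`; default a [simulate_tree()] with
#'   `truth$n_tips` tips under `truth$seed`.
#' @return list: `records` (data frame in the project schema, plus `y`, `v`,
#'   `percent_change`, `variance`, `raw_ok` and the true random-effect draws
#'   are echoed in `truth`), `tree`, `truth`.
#' @export
simulate_dataset <- function(truth, tree = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(tree)) tree <- simulate_tree(truth$n_tips, seed = truth$seed)
  R <- bm_correlation(tree)
  tips <- tree$tip.label
  with_seed(truth$seed + 1L, {
    eps <- truth$effects_per_study
    k_vals <- seq(eps[1], eps[2])
    k_per_study <- k_vals[sample.int(length(k_vals), truth$n_studies,
                                     replace = TRUE)]
    n <- sum(k_per_study)
    study <- rep(paste0("study_", seq_len(truth$n_studies)), k_per_study)
    species <- sample(tips, n, replace = TRUE)
    host <- paste0("host_", (match(species, tips) - 1L) %% 20L + 1L)

    X_part <- numeric(n)
    mod_cols <- list()
    mod_truth <- list()
    for (nm in names(truth$moderators)) {
      m <- truth$moderators[[nm]]
      if (m$type == "categorical") {
        probs <- if (!is.null(m$probs)) m$probs else rep(1, length(m$levels))
        val <- sample(m$levels, n, replace = TRUE, prob = probs)
        eff <- m$effects[val]
        eff[is.na(eff)] <- 0
        X_part <- X_part + unname(eff)
        mod_cols[[nm]] <- val
      } else {
        val <- stats::rnorm(n, m$mean, m$sd)
        X_part <- X_part + m$slope * (val - mean(val))
        mod_cols[[nm]] <- val
      }
      mod_truth[[nm]] <- m
    }

    u_study <- stats::rnorm(truth$n_studies, 0, sqrt(truth$sigma2_study))
    u_record <- stats::rnorm(n, 0, sqrt(truth$sigma2_within))
    Lr <- chol(R + diag(1e-10, nrow(R)))
    u_phylo_sp <- sqrt(truth$sigma2_phylo) * drop(crossprod(Lr, stats::rnorm(length(tips))))
    names(u_phylo_sp) <- tips
    v <- stats::runif(n, truth$v_range[1], truth$v_range[2])
    e <- stats::rnorm(n, 0, sqrt(v))
    y <- truth$beta0 + X_part + rep(u_study, k_per_study) + u_record +
      u_phylo_sp[species] + e
  })

  pc <- y^3
  V <- v^3
  raw <- backtransform_raw(pc, V)
  records <- data.frame(
    study_id = study,
    effect_id = paste0("es_", seq_len(n)),
    host_species = host,
    symbiont_species = species,
    analysis = truth$analysis,
    control_mean = raw$control_mean, control_disp = raw$control_disp,
    control_n = raw$n, alt_mean = raw$alt_mean, alt_disp = raw$alt_disp,
    alt_n = raw$n, disp_kind = "sd",
    percent_change = pc, variance = V, y = y, v = v,
    raw_ok = raw$ok,
    stringsAsFactors = FALSE
  )
  for (nm in names(mod_cols)) records[[nm]] <- mod_cols[[nm]]
  truth$draws <- list(u_study = u_study, u_record = u_record,
                      u_phylo = u_phylo_sp, v = v)
  list(records = records, tree = tree, truth = truth)
}

# Choose two-group summaries (control mean 100, n = 5 replicates per group,
# equal relative SEs) whose percent change and delta-method variance equal
# (pc, V). Infeasible when pc >= 100 (alternative mean would be <= 0).
backtransform_raw <- function(pc, V, control_mean = 100, n_rep = 5) {
  k <- length(pc)
  ok <- pc < 100
  cm <- rep(control_mean, k)
  am <- cm * (1 - pc / 100)
  r <- am / cm
  # V = 100^2 r^2 (se_c^2/cm^2 + se_a^2/am^2); split the two terms equally
  se_c <- cm * sqrt(V / 2) / (100 * abs(r))
  se_a <- am * sqrt(V / 2) / (100 * abs(r))
  out <- list(control_mean = cm, alt_mean = am,
              control_disp = se_c * sqrt(n_rep),
              alt_disp = abs(se_a) * sqrt(n_rep),
              n = rep(n_rep, k), ok = ok)
  for (f in c("control_mean", "alt_mean", "control_disp", "alt_disp")) {
    out[[f]][!ok] <- NA_real_
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the records CSV, the newick tree and a JSON echo of the generating
#' parameters, mirroring the schema the pipeline reads.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "records.csv")
  nwk <- file.path(dir, "tree.nwk")
  js <- file.path(dir, "truth.json")
  utils::write.csv(sim$records, csv, row.names = FALSE)
  write_newick(sim$tree, nwk)
  tr <- sim$truth
  tr$draws <- NULL
  jsonlite::write_json(unclass(tr), js, auto_unbox = TRUE, digits = NA)
  invisible(c(records = csv, tree = nwk, truth = js))
}
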