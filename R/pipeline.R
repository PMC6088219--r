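#' Cochran sample size for estimating a prevalence
#'
#' `n0 = z_{1 - alpha/2}^2 p (1 - p) / d^2`, rounded up to the next
#' multiple of `round_to`. With prevalence 0.1, type-one error 0.05 and
#' sampling error 0.01 the raw value is 3457.3, giving 3500 at
#' `round_to = 100`.
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param alpha Type-one error rate, in (0, 1).
#' @param d Absolute sampling error (margin), in (0, 1).
#' @param round_to Round the raw size up to this multiple; default 1.
#' @return Integer sample size.
#' @export
cochran_sample_size <- function(p, alpha = 0.05, d = 0.01, round_to = 1L) {
  for (v in list(p = p, alpha = alpha, d = d)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop("p, alpha and d must be single numbers in (0, 1)", call. = FALSE)
    }
  }
  if (!is.numeric(round_to) || round_to < 1) {
    stop("round_to must be a positive integer", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  n0 <- z^2 * p * (1 - p) / d^2
  as.integer(ceiling(n0 / round_to) * round_to)
}

#' Run the full analysis pipeline
#'
#' Executes the stages score -> factors -> fit -> eval -> report in fixed
#' order on either a raw questionnaire CSV (scored via a codebook) or a
#' synthetic cohort generated from a ground truth. Each enabled stage
#' writes its tables under `config$out_dir` together with the
#' configuration hash; rerunning with an unchanged configuration reuses
#' stage outputs already on disk.
#'
#' @param config List with entries: `out_dir`; `seed`; either `raw_csv` +
#'   `codebook` (paths) or `truth` (a [synthetic_truth()]; default one is
#'   built with `n = config$n`); `quantiles`; `mcmc` (list passed to
#'   [qsem_spec()]); `stages` (character subset of
#'   `c("score", "factors", "fit", "eval", "report")`).
#' @return List with the per-stage results (`scored`, `factors`, `fit`,
#'   `eval`, `report`) and the provenance block.
#' @export
run_pipeline <- function(config) {
  stages_all <- c("score", "factors", "fit", "eval", "report")
  config <- utils::modifyList(list(
    seed = 1L, n = 1000L, quantiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
    mcmc = list(chains = 2L, iter = 3000L, burnin = 1000L, thin = 1L),
    stages = stages_all
  ), config)
  stopifnot(!is.null(config$out_dir))
  stages <- intersect(stages_all, config$stages)  # fixed execution order
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  res <- list(provenance = list(
    config_hash = cfg_hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("quantsem")),
    timestamp = format(Sys.time(), tz = "UTC")
  ))

  stage_path <- function(s) file.path(config$out_dir, paste0(s, ".rds.json"))
  stage_done <- function(s) {
    f <- stage_path(s)
    file.exists(f) &&
      identical(jsonlite::read_json(f)$config_hash, cfg_hash)
  }
  mark_done <- function(s, summary) {
    jsonlite::write_json(list(config_hash = cfg_hash, stage = s,
                              summary = summary),
                         stage_path(s), auto_unbox = TRUE)
  }

  # --- score (or simulate) ---
  if (!is.null(config$raw_csv)) {
    raw <- utils::read.csv(config$raw_csv, check.names = FALSE)
    cb <- read_codebook(config$codebook)
    scored_all <- score_participants(raw, cb)
    scored <- scored_all[!scored_all$excluded, , drop = FALSE]
    X <- as.matrix(scored[intersect(design_columns(), names(scored))])
  } else {
    truth <- config$truth
    if (is.null(truth)) {
      truth <- synthetic_truth(n = config$n, seed = config$seed)
    }
    sim <- generate_dataset(truth)
    scored <- cbind(sim$indicators, sim$covariates)
    X <- sim$X
  }
  if ("score" %in% stages) {
    utils::write.csv(cbind(scored, as.data.frame(X)),
                     file.path(config$out_dir, "scored.csv"),
                     row.names = FALSE)
    mark_done("score", list(n = nrow(scored)))
  }
  res$scored <- scored
  res$X <- X
  if (!any(c("factors", "fit", "eval", "report") %in% stages)) return(res)

  # --- factors ---
  psych_cols <- c("ghq12_distress", "hads_anxiety", "hads_depression")
  domain_cols <- c(stressor_domains()$socioeconomic,
                   stressor_domains()$personal)
  if ("factors" %in% stages) {
    profile <- extract_profile(scored[psych_cols])
    efa <- efa_stressors(scored[domain_cols])
    desc_vars <- setdiff(names(scored), c(psych_cols, domain_cols))
    desc <- quartile_descriptives(scored[desc_vars],
                                  profile$factor_scores[, 1])
    utils::write.csv(as.data.frame(efa$loadings),
                     file.path(config$out_dir, "stressor_loadings.csv"))
    utils::write.csv(desc$table,
                     file.path(config$out_dir, "quartile_descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(efa$scree, file.path(config$out_dir, "scree.csv"),
                     row.names = FALSE)
    mark_done("factors", list(
      profile_variance_pct = profile$variance_explained,
      efa_variance_pct = efa$variance_explained))
    res$factors <- list(profile = profile, efa = efa, descriptives = desc)
  }

  spec <- default_qsem_spec(quantiles = config$quantiles,
                            mcmc = config$mcmc)
  fit_data <- cbind(scored[c(psych_cols, domain_cols)], as.data.frame(X))

  # --- fit ---
  if ("fit" %in% stages) {
    grid <- fit_all_quantiles(fit_data, spec, seed = config$seed)
    utils::write.csv(grid$table,
                     file.path(config$out_dir, "coefficients_by_quantile.csv"),
                     row.names = FALSE)
    mark_done("fit", list(quantiles = config$quantiles,
                          crossing = grid$crossing))
    res$fit <- grid
  }

  # --- eval ---
  if ("eval" %in% stages) {
    msem <- fit_mean_sem(fit_data, spec)
    idx <- fit_indices(msem)
    med_fit <- if (!is.null(res$fit) && "tau_0.5" %in% names(res$fit$fits)) {
      res$fit$fits$tau_0.5
    } else {
      gibbs_fit(fit_data, spec, tau = 0.5, seed = config$seed)
    }
    ppc <- posterior_predictive_pvalue(med_fit, seed = config$seed,
                                       min_draws = min(500L,
                                                       length(med_fit$latent)))
    eval_out <- list(
      mean_sem = list(gamma = as.list(msem$estimates$gamma),
                      chisq = msem$chisq, df = msem$df),
      fit_indices = idx,
      ppc = list(p_value = ppc$p_value, discrepancy = ppc$discrepancy,
                 n_draws = ppc$n_draws)
    )
    jsonlite::write_json(c(eval_out, list(config_hash = cfg_hash)),
                         file.path(config$out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA)
    mark_done("eval", list(ppc = ppc$p_value))
    res$eval <- list(mean_sem = msem, fit_indices = idx, ppc = ppc)
  }

  # --- report ---
  if ("report" %in% stages) {
    report <- list(provenance = res$provenance)
    if (!is.null(res$factors)) {
      report$profile_variance_pct <- res$factors$profile$variance_explained
      report$efa_variance_pct <- res$factors$efa$variance_explained
    }
    if (!is.null(res$fit)) report$coefficients <- res$fit$table
    if (!is.null(res$eval)) {
      report$fit_indices <- res$eval$fit_indices
      report$ppc_p_value <- res$eval$ppc$p_value
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    md <- c("# Quantile SEM pipeline report",
            sprintf("- seed: %s; config hash: %s", config$seed, cfg_hash),
            if (!is.null(report$profile_variance_pct))
              sprintf("- profile variance explained: %.2f%%",
                      report$profile_variance_pct),
            if (!is.null(report$efa_variance_pct))
              sprintf("- stressor EFA variance explained: %.2f%%",
                      report$efa_variance_pct),
            if (!is.null(report$ppc_p_value))
              sprintf("- posterior predictive p-value: %.3f",
                      report$ppc_p_value))
    writeLines(md, file.path(config$out_dir, "report.md"))
    mark_done("report", list(ok = TRUE))
    res$report <- report
  }
  res
}
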