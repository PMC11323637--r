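#' Fit one PRS method on a simulated study
#'
#' Thin per-method pipelines used by [run_benchmark()]: posterior effects
#' from the summary statistics, group/bin scores on the test panel,
#' cross-validated combination weights, per-fold AUC and R2 (AUC on the
#' top-decile binarization of the quantitative phenotype).
#'
#' @param study A list from [simulate_study()].
#' @param method One of `"bils"`, `"prscs"`, `"hybrid"`, `"ldpred_funct"`.
#' @param cfg Sampler configuration ([prsbils_config()]); the mode is set
#'   per method. Ignored by `"ldpred_funct"`.
#' @param prscs_post Optional precomputed single-group posterior (reused by
#'   `"hybrid"` to avoid a second chain).
#' @param bils_post Optional precomputed bilevel posterior.
#' @param L Bin count for `"ldpred_funct"`.
#' @param cv_seed Fold-assignment seed.
#' @return List with `per_fold` (data.frame fold/AUC/R2), `overall`,
#'   and the posterior object (`post`) where applicable.
#' @export
fit_method <- function(study, method = c("bils", "prscs", "hybrid", "ldpred_funct"),
                       cfg = prsbils_config(), prscs_post = NULL,
                       bils_post = NULL, L = 40L, cv_seed = 1L) {
  method <- match.arg(method)
  y <- study$test_phenotype
  if (method == "ldpred_funct") {
    if (study$annot$M_prime != study$annot$M)
      stop("the ranked-bin comparator supports non-overlapping annotations only")
    prior <- funct_prior(study$truth$per_snp_h2, study$setting$h2)
    eff <- funct_posterior_mean(study$ss, study$ld, prior)
    bins <- bin_by_posterior(eff, L = L)
    res <- funct_prs(study$test_panel, eff, bins, y, kind = "quantitative",
                     seed = cv_seed)
    return(list(per_fold = res$per_fold, overall = res$metrics, post = NULL))
  }

  if (method %in% c("bils", "hybrid")) {
    if (is.null(bils_post)) {
      cfg_b <- cfg; cfg_b$mode <- "bils"
      bils_post <- run_gibbs(study$ss, study$ld, study$annot, cfg_b)
    }
  }
  if (method %in% c("prscs", "hybrid")) {
    if (is.null(prscs_post)) {
      cfg_p <- cfg; cfg_p$mode <- "prscs_auto"
      prscs_post <- run_gibbs(study$ss, study$ld, study$annot, cfg_p)
    }
  }

  if (method == "prscs") {
    scores <- group_prs(study$test_panel, prscs_post)
    fit <- fit_alpha_cv(scores, y, seed = cv_seed)
    post <- prscs_post
  } else {
    scores <- group_prs(study$test_panel, bils_post)
    extra <- if (method == "hybrid") {
      cs <- group_prs(study$test_panel, prscs_post)
      as.numeric(rowSums(cs))
    } else NULL
    fit <- fit_alpha_cv(scores, y, extra = extra, seed = cv_seed)
    post <- bils_post
  }
  per_fold <- evaluate_by_fold(fit$pred, y, fit$fold, kind = "quantitative")
  overall <- evaluate(fit$pred, y, kind = "quantitative")
  list(per_fold = per_fold, overall = overall, post = post, fit = fit)
}

#' Run the simulation benchmark
#'
#' For each setting and replicate: simulate a study, run the bilevel
#' sampler, the single-group sampler, the hybrid combination and (for
#' non-overlapping settings) the ranked-bin comparator on the same data,
#' score the disjoint test panel with tenfold cross-validated weights, and
#' collect per-fold AUC/R2.
#'
#' @param settings Integer vector of setting ids (1..7).
#' @param n_replicates Replicates per setting.
#' @param scale `"desk"` or `"full"` (passed to [sim_setting()]).
#' @param methods Methods to run (default all four where applicable).
#' @param cfg Sampler configuration shared by the sampler-based methods.
#' @param seed Base seed; replicate r of setting s uses
#'   `seed + 1000*s + r` for the data and derived seeds downstream.
#' @param out_dir Optional directory for `results.tsv` / `summary.tsv`.
#' @return List with `results` (setting x method x replicate x fold) and
#'   `summary` (per setting/method mean AUC and R2 with 95% CIs across
#'   replicates, plus absolute and relative AUC gain of the bilevel model
#'   over the single-group benchmark).
#' @export
run_benchmark <- function(settings = c(1L, 5L), n_replicates = 10L,
                          scale = "desk",
                          methods = c("bils", "prscs", "hybrid", "ldpred_funct"),
                          cfg = prsbils_config(), seed = 1L, out_dir = NULL) {
  rows <- list()
  for (s in settings) {
    st <- sim_setting(s, scale = scale)
    meths <- methods
    if (st$overlap != "none") meths <- setdiff(meths, "ldpred_funct")
    for (r in seq_len(n_replicates)) {
      rseed <- seed + 1000L * s + r
      study <- tryCatch(simulate_study(st, seed = rseed), error = identity)
      if (inherits(study, "error")) {
        warning("setting ", s, " replicate ", r, " failed in simulation: ",
                conditionMessage(study))
        next
      }
      bils_post <- NULL; prscs_post <- NULL
      for (m in meths) {
        res <- tryCatch(
          fit_method(study, m, cfg = cfg, bils_post = bils_post,
                     prscs_post = prscs_post, cv_seed = rseed),
          error = identity)
        if (inherits(res, "error")) {
          warning("setting ", s, " replicate ", r, " method ", m,
                  " failed: ", conditionMessage(res))
          next
        }
        if (m == "bils") bils_post <- res$post
        if (m == "prscs") prscs_post <- res$post
        pf <- res$per_fold
        rows[[length(rows) + 1L]] <-
          data.frame(setting = s, method = m, replicate = r,
                     fold = pf$fold, AUC = pf$AUC, R2 = pf$R2)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- summarize_benchmark(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(results, file.path(out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(results = results, summary = summary)
}

#' Summarize benchmark results
#'
#' Per setting and method: replicate-level means (folds averaged first),
#' their across-replicate mean, a normal-theory 95% CI, and — for the
#' sampler methods — the gain in AUC over the single-group benchmark, both
#' absolute (difference) and relative
#' (\eqn{100 (AUC_m - AUC_{cs}) / AUC_{cs}} percent).
#'
#' @param results The `results` data.frame from [run_benchmark()].
#' @return A summary `data.frame`.
#' @export
summarize_benchmark <- function(results) {
  if (is.null(results) || nrow(results) == 0L) return(NULL)
  rep_means <- stats::aggregate(cbind(AUC, R2) ~ setting + method + replicate,
                                data = results, FUN = mean, na.rm = TRUE)
  out <- list()
  for (s in unique(rep_means$setting)) {
    sub <- rep_means[rep_means$setting == s, ]
    base <- sub$AUC[sub$method == "prscs"]
    base_mean <- if (length(base)) mean(base) else NA_real_
    for (m in unique(sub$method)) {
      a <- sub$AUC[sub$method == m]
      r2 <- sub$R2[sub$method == m]
      ci <- function(x) {
        if (length(x) < 2) return(c(NA_real_, NA_real_))
        mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
      }
      ca <- ci(a)
      out[[length(out) + 1L]] <- data.frame(
        setting = s, method = m, n_replicates = length(a),
        AUC_mean = mean(a), AUC_lo = ca[1], AUC_hi = ca[2],
        R2_mean = mean(r2),
        AUC_gain_abs = mean(a) - base_mean,
        AUC_gain_rel_pct = 100 * (mean(a) - base_mean) / base_mean)
    }
  }
  do.call(rbind, out)
}
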