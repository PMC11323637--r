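#' Annotation-informed normal prior for posterior-mean effects
#'
#' Bundles per-SNP heritabilities \eqn{\sigma_j^2} (e.g. from stratified LD
#' score regression, or the simulator's true per-variant variances) with the
#' normalizing constant \eqn{c} calibrated so that
#' \eqn{c \sum_j \sigma_j^2 = h^2}, the target total heritability.
#'
#' @param per_snp_h2 Non-negative per-variant heritability contributions.
#' @param h2_total Target total heritability.
#' @return List of class `funct_prior` with `sigma2_j` and `c`.
#' @export
funct_prior <- function(per_snp_h2, h2_total) {
  stopifnot(all(per_snp_h2 >= 0), sum(per_snp_h2) > 0, h2_total > 0)
  structure(list(sigma2_j = per_snp_h2, c = h2_total / sum(per_snp_h2)),
            class = "funct_prior")
}

#' Posterior-mean effect sizes under a per-SNP normal prior
#'
#' Computes \eqn{E[\beta | \cdot] = W^{-1} N \hat\beta} with
#' \eqn{W = N D + \tfrac{1}{c}\,diag(1/\sigma_j^2)}, block-wise over the LD
#' partition. Variants with \eqn{\sigma_j^2 = 0} have prior (and posterior)
#' mass at zero and are removed from each block's solve.
#'
#' @param ss A `prsbils_sumstats` aligned to `ld`.
#' @param ld An `ld_blocks` object.
#' @param prior A [funct_prior()] with one `sigma2_j` per variant.
#' @return Numeric vector of per-variant posterior means.
#' @export
funct_posterior_mean <- function(ss, ld, prior) {
  stopifnot(inherits(prior, "funct_prior"),
            length(prior$sigma2_j) == nrow(ss))
  if (!identical(as.character(ss$variant_id), as.character(ld$variant_ids)))
    stop("summary statistics and LD blocks must be aligned")
  n <- ss$n_gwas[1]
  out <- numeric(nrow(ss))
  for (b in ld$blocks) {
    s2 <- prior$sigma2_j[b$idx]
    nz <- s2 > 0
    if (!any(nz)) next
    W <- n * b$D[nz, nz, drop = FALSE]
    diag(W) <- diag(W) + 1 / (prior$c * s2[nz])
    R <- chol_jitter(W)
    out[b$idx[nz]] <- backsolve(R, backsolve(R, n * ss$beta_hat[b$idx][nz],
                                             transpose = TRUE))
  }
  out
}

#' Rank effects into bins of approximately equal sum of squares
#'
#' Variants are sorted by absolute posterior-mean effect (descending, ties
#' by original order) and cut greedily into `L` bins: a bin closes as soon
#' as the running sum of squared effects reaches the next multiple of
#' `total/L`. Every variant lands in exactly one bin.
#'
#' @param effects Per-variant posterior-mean effects.
#' @param L Number of bins (default 40). Reduced (with a message) when there
#'   are fewer nonzero effects than bins.
#' @return Integer bin assignment (1 = largest effects); all-zero effects
#'   give a single bin.
#' @export
bin_by_posterior <- function(effects, L = 40L) {
  m <- length(effects)
  total <- sum(effects^2)
  if (total == 0) return(rep(1L, m))
  n_nonzero <- sum(effects != 0)
  if (n_nonzero < L) {
    message("only ", n_nonzero, " nonzero effects; reducing L from ", L)
    L <- max(1L, n_nonzero)
  }
  ord <- order(-abs(effects))  # ties broken by original variant order
  sq <- effects[ord]^2
  cs <- cumsum(sq)
  # bin index = how many cut points the running sum had reached before this
  # variant was added (tolerance guards exact-boundary float error)
  tol <- total * 1e-12
  bin_sorted <- pmin(1L + findInterval(cs - sq + tol,
                                       total / L * seq_len(L - 1)), L)
  # a variant whose own square crosses a cut still belongs to the bin it
  # started in; the NEXT variant starts the new bin
  bins <- integer(m)
  bins[ord] <- bin_sorted
  bins
}

#' Binned PRS with cross-validated bin weights
#'
#' Scores each bin separately (\eqn{PRS(l) = \sum_{j \in l} G_j E[\beta_j]}),
#' fits the bin weights \eqn{\alpha_l} by tenfold cross-validation on the
#' phenotype and evaluates the held-out predictions — the ranked-bin
#' comparator pipeline.
#'
#' @param panel Standardized `genotype_panel` (validation/test individuals).
#' @param effects Per-variant posterior-mean effects, aligned to the panel.
#' @param bins Bin assignment from [bin_by_posterior()].
#' @param phenotype Outcome vector for the panel's samples.
#' @param kind Passed to [evaluate()].
#' @param folds,seed Cross-validation controls.
#' @param top_fraction,binarize_threshold Passed to [evaluate()].
#' @return List with `fit` (from [fit_alpha_cv()]), `metrics` (overall
#'   held-out AUC/R2), and `per_fold`.
#' @export
funct_prs <- function(panel, effects, bins, phenotype,
                      kind = c("quantitative", "binary"), folds = 10L,
                      seed = 1L, top_fraction = 0.1, binarize_threshold = NULL) {
  kind <- match.arg(kind)
  panel <- standardize_panel(panel)
  stopifnot(length(effects) == ncol(panel$X), length(bins) == length(effects))
  L <- max(bins)
  scores <- sapply(seq_len(L), function(l) {
    w <- ifelse(bins == l, effects, 0)
    as.numeric(panel$X %*% w)
  })
  colnames(scores) <- paste0("bin", seq_len(L))
  fit <- fit_alpha_cv(scores, phenotype, folds = folds, seed = seed)
  metrics <- evaluate(fit$pred, phenotype, kind,
                      binarize_threshold = binarize_threshold,
                      top_fraction = top_fraction)
  per_fold <- evaluate_by_fold(fit$pred, phenotype, fit$fold, kind,
                               binarize_threshold = binarize_threshold,
                               top_fraction = top_fraction)
  list(fit = fit, metrics = metrics, per_fold = per_fold)
}
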