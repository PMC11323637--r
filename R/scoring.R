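#' Group-wise polygenic risk scores
#'
#' Computes the K group-wise scores
#' \eqn{PRS_k(i) = \sum_{(j,k)} G_{ij} \tilde\beta_{j,k}} from the per-copy
#' posterior mean effects, on the standardized genotype scale. Summing the
#' columns (weights all 1) recovers the plain weighted sum over all copies.
#'
#' @param panel A standardized `genotype_panel` allele-aligned to the
#'   posterior weights.
#' @param post A `prsbils_posterior` (or a `data.frame` with `variant_id`,
#'   `group`, `effect`).
#' @param annot Optional `annotation_map`; defaults to the one stored in
#'   `post`.
#' @return Numeric matrix, samples x groups, with group labels as column
#'   names; variants absent from the panel are excluded (count in attribute
#'   `n_missing`).
#' @export
group_prs <- function(panel, post, annot = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  panel <- standardize_panel(panel)
  if (inherits(post, "prsbils_posterior")) {
    tab <- data.frame(variant_id = post$variant_id,
                      group = post$groups[post$copy_group],
                      effect = post$beta_mean, stringsAsFactors = FALSE)
    groups <- post$groups
  } else {
    tab <- post
    if (is.null(tab$group)) tab$group <- "all"
    groups <- if (!is.null(annot)) annot$groups else unique(tab$group)
  }
  col <- match(tab$variant_id, panel$variants$variant_id)
  n_missing <- sum(is.na(col))
  if (n_missing > 0)
    message(n_missing, " weight entr(ies) for variants absent from the panel excluded")
  tab <- tab[!is.na(col), , drop = FALSE]
  col <- col[!is.na(col)]
  scores <- matrix(0, nrow(panel$X), length(groups),
                   dimnames = list(panel$sample_id, groups))
  for (k in seq_along(groups)) {
    sel <- tab$group == groups[k]
    if (any(sel)) {
      w <- numeric(ncol(panel$X))
      w[col[sel]] <- w[col[sel]] + tab$effect[sel]
      scores[, k] <- panel$X %*% w
    }
  }
  attr(scores, "n_missing") <- n_missing
  scores
}

#' Fit group combination weights by tenfold cross-validation
#'
#' Within each fold, regresses the phenotype on the K group scores (plus an
#' optional conventional-PRS column for the hybrid score, and an intercept)
#' by least squares on the 9/10 training part, and predicts the held-out
#' 1/10. Binary phenotypes use the same linear working model (the scores are
#' used for ranking only). Reported `alpha`/`gamma` are across-fold
#' averages. Rank-deficient columns (e.g. an empty group) get weight 0.
#'
#' @param scores Matrix of group scores (samples x K) from [group_prs()].
#' @param phenotype Numeric (or 0/1) vector, one value per row of `scores`.
#' @param extra Optional conventional PRS vector; its fitted weight is the
#'   hybrid coefficient `gamma`.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `alpha` (length K), `gamma` (0 when `extra` is `NULL`),
#'   `pred` (held-out predictions, one per sample), `fold` (fold ids,
#'   sizes differing by at most 1), and `per_fold` (coefficients by fold).
#' @export
fit_alpha_cv <- function(scores, phenotype, extra = NULL, folds = 10L, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  K <- ncol(scores)
  stopifnot(length(phenotype) == n)
  X <- cbind(scores, if (!is.null(extra)) matrix(extra, ncol = 1))
  p <- ncol(X)
  if (n < folds * (p + 2))
    stop("need at least ", folds * (p + 2), " individuals for ", folds,
         "-fold fitting of ", p, " weights")
  old <- .Random.seed_save()
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  .Random.seed_restore(old)

  pred <- numeric(n)
  coefs <- matrix(0, folds, p + 1)
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- cbind(1, X[tr, , drop = FALSE])
    ok <- qr(Xtr)$rank == ncol(Xtr)
    use <- rep(TRUE, p)
    if (!ok) {
      # drop offending columns (zero variance / collinear), weight 0
      piv <- qr(Xtr, LAPACK = FALSE)
      rank <- piv$rank
      keep <- sort(piv$pivot[seq_len(rank)])
      use <- (seq_len(p) + 1L) %in% keep
      message("rank-deficient fold ", f, ": ", sum(!use), " column(s) dropped")
      Xtr <- cbind(1, X[tr, use, drop = FALSE])
    }
    fit <- stats::lm.fit(Xtr, phenotype[tr])
    b <- fit$coefficients
    b[is.na(b)] <- 0
    cf <- numeric(p + 1)
    cf[c(TRUE, use)] <- b
    coefs[f, ] <- cf
    pred[!tr] <- cbind(1, X[!tr, , drop = FALSE]) %*% cf
  }
  cm <- colMeans(coefs)
  alpha <- cm[2:(K + 1)]
  names(alpha) <- colnames(scores)
  list(alpha = alpha,
       gamma = if (is.null(extra)) 0 else cm[p + 1],
       intercept = cm[1],
       pred = pred, fold = fold, per_fold = coefs)
}

# save/restore the global RNG state so fold assignment does not perturb
# caller-controlled sampling streams
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Midrank (tie-aware) Mann-Whitney statistic: the probability that a random
#' case outranks a random control. Invariant under strictly increasing
#' transforms of `pred`.
#'
#' @param pred Numeric predictions.
#' @param labels 0/1 (or logical) outcome labels.
#' @return AUC in \[0, 1\], or an error if only one class is present.
#' @export
auc_mann_whitney <- function(pred, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: labels contain a single class")
  r <- rank(pred)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate prediction accuracy
#'
#' For quantitative phenotypes: \eqn{R^2} is the squared Pearson correlation
#' of prediction and phenotype, and AUC is computed on labels induced by
#' `binarize_threshold` (or, by default, the top-`top_fraction` of phenotype
#' values as the at-risk class). For binary phenotypes: AUC on the labels and
#' Efron's pseudo-\eqn{R^2 = 1 - \sum(y_i-\hat p_i)^2 / \sum(y_i-\bar y)^2}.
#'
#' @param pred Numeric predictions.
#' @param phenotype Outcome vector (numeric, or 0/1 for `kind = "binary"`).
#' @param kind `"quantitative"` or `"binary"`.
#' @param binarize_threshold Optional absolute threshold for binarizing a
#'   quantitative phenotype.
#' @param top_fraction Fraction labelled at-risk when no threshold is given
#'   (default 0.1, the top decile).
#' @return List with elements `AUC` and `R2`.
#' @export
evaluate <- function(pred, phenotype, kind = c("quantitative", "binary"),
                     binarize_threshold = NULL, top_fraction = 0.1) {
  kind <- match.arg(kind)
  stopifnot(length(pred) == length(phenotype), length(pred) >= 10)
  if (kind == "binary") {
    y <- as.integer(as.logical(phenotype))
    auc <- auc_mann_whitney(pred, y)
    r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  } else {
    thr <- if (is.null(binarize_threshold))
      stats::quantile(phenotype, 1 - top_fraction) else binarize_threshold
    labels <- phenotype > thr
    auc <- auc_mann_whitney(pred, labels)
    r2 <- stats::cor(pred, phenotype)^2
  }
  list(AUC = auc, R2 = r2)
}

#' Per-fold evaluation of cross-validated predictions
#'
#' Applies [evaluate()] separately to each held-out fold, the way boxplots of
#' tenfold results are built.
#'
#' @inheritParams evaluate
#' @param fold Fold ids from [fit_alpha_cv()].
#' @return `data.frame` with one row per fold: `fold`, `AUC`, `R2`.
#' @export
evaluate_by_fold <- function(pred, phenotype, fold,
                             kind = c("quantitative", "binary"),
                             binarize_threshold = NULL, top_fraction = 0.1) {
  kind <- match.arg(kind)
  # labels induced on the full sample so every fold sees both classes
  thr <- if (kind == "quantitative" && is.null(binarize_threshold))
    stats::quantile(phenotype, 1 - top_fraction) else binarize_threshold
  out <- lapply(sort(unique(fold)), function(f) {
    i <- fold == f
    m <- tryCatch(
      evaluate(pred[i], phenotype[i], kind, binarize_threshold = thr,
               top_fraction = top_fraction),
      error = function(e) list(AUC = NA_real_, R2 = NA_real_))
    data.frame(fold = f, AUC = m$AUC, R2 = m$R2)
  })
  do.call(rbind, out)
}
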