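# Core blocked Gibbs sampler for the bilevel continuous shrinkage model.
#
# Model (standardized genotypes/phenotype, GWAS sample size N):
#   y = G beta + eps,              eps ~ MVN(0, sigma2 I),  p(sigma2) ~ 1/sigma2
#   beta | . ~ MVN(0, sigma2/N * Psi),   Psi = diag(delta2[g(j)] * lambda2_j * tau2)
#   delta_k ~ C+(0,1) (group scales), lambda_j ~ C+(0,1) (per-copy local scales),
#   tau ~ C+(0,1) only in the single-group (PRS-CS-auto style) mode.
# Half-Cauchy scales are updated through their inverse-gamma scale-mixture
# representation; summary-statistic form uses beta_hat = G'y/N and the
# block-diagonal LD matrix D = G'G/N.

#' Sampler configuration
#'
#' @param n_iter Total Gibbs iterations.
#' @param n_burnin Burn-in iterations discarded before averaging.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer RNG seed; a run is fully determined by it.
#' @param mode `"bils"` (bilevel, annotation groups), `"bils_overlap"`
#'   (same sampler, names the overlapping-annotation use), or
#'   `"prscs_auto"` (annotations collapsed to one group; an extra global
#'   scale `tau2` with a half-Cauchy prior is sampled unless `fix_tau`).
#' @param a0,b0 Gamma-gamma shape parameters for the local shrinkage prior
#'   in `prscs_auto` mode. The defaults (0.5, 1) are the half-Cauchy case
#'   and share the bilevel sampler's exact inverse-gamma code path; other
#'   values use generalized-inverse-Gaussian updates.
#' @param clip_psi Upper cap on the per-copy shrinkage product
#'   \eqn{\psi_j = \delta^2\lambda^2\tau^2} (floored at 1e-12). The default 1
#'   bounds every effect's prior variance by \eqn{\sigma^2/N}; without that
#'   bound the sampler has an absorbing degenerate mode (shrinkage vanishes,
#'   the \eqn{\sigma^2} scale turns negative, \eqn{\sigma^2} collapses)
#'   whenever the variant count approaches the GWAS sample size.
#' @param fix_sigma2,fix_delta2,fix_lambda2,fix_tau Freeze the corresponding
#'   updates at their initial values (used for conjugate-limit checks).
#' @param keep_draws Store the retained beta draws (rows = kept iterations).
#' @param init Optional named list of initial values (`beta`, `sigma2`,
#'   `delta2`, `lambda2`, `tau2`).
#' @return A `prsbils_config` list.
#' @export
prsbils_config <- function(n_iter = 1000L, n_burnin = 500L, thin = 5L,
                           seed = 42L,
                           mode = c("bils", "bils_overlap", "prscs_auto"),
                           a0 = 0.5, b0 = 1, clip_psi = 1,
                           fix_sigma2 = FALSE, fix_delta2 = FALSE,
                           fix_lambda2 = FALSE, fix_tau = FALSE,
                           keep_draws = FALSE, init = list()) {
  mode <- match.arg(mode)
  stopifnot(n_burnin < n_iter, thin >= 1, a0 > 0, b0 > 0, clip_psi > 0)
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed), mode = mode,
                 a0 = a0, b0 = b0, clip_psi = clip_psi,
                 fix_sigma2 = fix_sigma2, fix_delta2 = fix_delta2,
                 fix_lambda2 = fix_lambda2, fix_tau = fix_tau,
                 keep_draws = keep_draws, init = init),
            class = "prsbils_config")
}

# clip the shrinkage product into [1e-12, clip]; the cap bounds each prior
# variance by clip * sigma2/N (heavy half-Cauchy tails overflow otherwise)
clip_product <- function(x, clip) pmin(pmax(x, 1e-12), clip)

#' Draw the effect sizes of one LD block
#'
#' Samples \eqn{\beta_b} from its multivariate-normal full conditional
#' \eqn{MVN(A^{-1}\hat\beta_b, \sigma^2/N\, A^{-1})} with
#' \eqn{A = D_b + \Psi_b^{-1}}, \eqn{\Psi_b = diag(\psi)} the per-copy
#' shrinkage products. Uses a Cholesky factorization with escalating jitter
#' (1e-10 up to 1e-6) if \eqn{A} is numerically indefinite.
#'
#' @param beta_hat_block Standardized marginal effects of the block.
#' @param D_block Block LD correlation matrix.
#' @param psi_block Per-copy shrinkage products \eqn{\delta^2\lambda^2\tau^2}.
#' @param sigma2 Current residual variance.
#' @param n_gwas GWAS sample size N.
#' @return List with `beta` (the draw) and `quad`
#'   (\eqn{\beta^T A \beta}, accumulated by the \eqn{\sigma^2} update).
#' @export
sample_beta_block <- function(beta_hat_block, D_block, psi_block, sigma2, n_gwas) {
  A <- D_block
  diag(A) <- diag(A) + 1 / psi_block
  R <- chol_jitter(A)
  mu <- backsolve(R, backsolve(R, beta_hat_block, transpose = TRUE))
  z <- stats::rnorm(length(beta_hat_block))
  beta <- mu + sqrt(sigma2 / n_gwas) * backsolve(R, z)
  v <- A %*% beta
  list(beta = as.numeric(beta), quad = sum(beta * v))
}

chol_jitter <- function(A) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  jit <- 1e-10
  while (is.null(R) && jit <= 1e-6) {
    Aj <- A
    diag(Aj) <- diag(Aj) + jit
    R <- tryCatch(chol(Aj), error = function(e) NULL)
    jit <- jit * 10
  }
  if (is.null(R)) stop("Cholesky factorization failed even with 1e-6 jitter")
  R
}

#' Draw the residual variance
#'
#' \eqn{\sigma^2 | \cdot \sim IG\big(\tfrac{N+M'}{2},
#' \tfrac{N}{2}\{1 - 2\beta^T\hat\beta + \beta^T[D + \Psi^{-1}]\beta\}\big)}.
#' The quadratic form is accumulated block-wise (`quad`). Because the
#' summary-statistic approximation combines marginal effects and reference
#' LD estimated on different samples, the data part of the scale can turn
#' non-positive; the draw then falls back to the prior quadratic form
#' \eqn{\tfrac{N}{2}\beta^T\Psi^{-1}\beta} (floored at
#' \eqn{\epsilon N/2, \epsilon = 10^{-8}}) and the event is counted as a
#' clamp.
#'
#' @param beta Current effect vector (all copies).
#' @param beta_hat Standardized marginal effects (all copies).
#' @param quad \eqn{\beta^T [D + \Psi^{-1}] \beta} summed over blocks.
#' @param n_gwas GWAS sample size N.
#' @param m_prime Number of effect copies M'.
#' @param prior_quad Optional \eqn{\beta^T \Psi^{-1} \beta} (guard term).
#' @return List with `sigma2`, `shape`, `scale`, and logical `clamped`.
#' @export
sample_sigma2 <- function(beta, beta_hat, quad, n_gwas, m_prime = length(beta),
                          prior_quad = 0) {
  shape <- (n_gwas + m_prime) / 2
  scale <- n_gwas / 2 * (1 - 2 * sum(beta * beta_hat) + quad)
  clamped <- scale <= 0
  scale <- max(scale, n_gwas / 2 * prior_quad, 1e-8 * n_gwas / 2)
  list(sigma2 = rinvgamma(1L, shape, scale), shape = shape, scale = scale,
       clamped = clamped)
}

#' Draw the group-level shrinkage scales and their hyper-scales
#'
#' For each annotation group k,
#' \eqn{\delta_k^2 | \cdot \sim IG\big(\tfrac{M_k+1}{2},
#' \sum_{(j,k)} \tfrac{N\beta_{j,k}^2}{2\sigma^2\lambda_{j,k}^2}
#' + \tfrac{1}{t_k}\big)} and
#' \eqn{t_k | \delta_k^2 \sim IG(1, \delta_k^{-2} + 1)}
#' (the half-Cauchy inverse-gamma mixture). An empty group draws from the
#' prior-only conditional \eqn{IG(1/2, 1/t_k)}. Draws are floored at 1e-12.
#'
#' @param beta,lambda2 Per-copy current values.
#' @param copy_group Integer group index per copy.
#' @param sigma2,n_gwas Scalars.
#' @param t Current hyper-scales (length K).
#' @param K Number of groups.
#' @return List with `delta2` and the updated `t` (each length K).
#' @export
sample_delta2 <- function(beta, lambda2, copy_group, sigma2, n_gwas, t, K) {
  contrib <- n_gwas * beta^2 / lambda2 / (2 * sigma2)
  ssum <- vapply(seq_len(K), function(k) sum(contrib[copy_group == k]), numeric(1))
  M_k <- tabulate(copy_group, nbins = K)
  delta2 <- pmax(rinvgamma(K, (M_k + 1) / 2, ssum + 1 / t), 1e-12)
  t_new <- rinvgamma(K, 1, 1 / delta2 + 1)
  list(delta2 = delta2, t = t_new)
}

#' Draw the local shrinkage scales and their hyper-scales
#'
#' Half-Cauchy mixture route (the bilevel model, and the single-group mode
#' at its default hyper-parameters):
#' \eqn{\lambda_j^2 | \cdot \sim IG\big(1,
#' \tfrac{N\beta_j^2}{2\sigma^2} + \tfrac{1}{c_j}\big)},
#' \eqn{c_j | \lambda_j^2 \sim IG(1, \lambda_j^{-2} + 1)}. With
#' `gamma_gamma = TRUE` (single-group mode, general `a0`/`b0`) the prior
#' \eqn{\lambda_j^2 \sim G(a_0, rate\,c_j)}, \eqn{c_j \sim G(b_0, 1)} gives
#' \eqn{\lambda_j^2 | \cdot \sim GIG\big(a_0 - \tfrac12,\, 2c_j,\,
#' \tfrac{N\beta_j^2}{\sigma^2}\big)} and
#' \eqn{c_j | \cdot \sim G(a_0 + b_0, rate\,\lambda_j^2 + 1)}.
#'
#' As in the lineage tools, the group/global scales enter the local update
#' through the hierarchy rather than the conditional's quadratic term, which
#' keeps the local scale a function of the absolute marginal signal.
#'
#' @param beta Per-copy effects.
#' @param sigma2,n_gwas Scalars.
#' @param c Current hyper-scales (per copy).
#' @param gamma_gamma Use the gamma-gamma conditionals.
#' @param a0,b0 Gamma-gamma shapes (used when `gamma_gamma`).
#' @return List with `lambda2` and updated `c`.
#' @export
sample_lambda2 <- function(beta, sigma2, c, n_gwas,
                           gamma_gamma = FALSE, a0 = 0.5, b0 = 1) {
  m <- length(beta)
  if (!gamma_gamma) {
    scale <- n_gwas * beta^2 / (2 * sigma2) + 1 / c
    lambda2 <- rinvgamma(m, 1, scale)
    c_new <- rinvgamma(m, 1, 1 / lambda2 + 1)
  } else {
    bq <- n_gwas * beta^2 / sigma2
    lambda2 <- rgig(m, a0 - 0.5, 2 * c, bq)
    c_new <- stats::rgamma(m, shape = a0 + b0, rate = lambda2 + 1)
  }
  list(lambda2 = pmax(lambda2, 1e-12), c = c_new)
}

#' Draw the extra global shrinkage scale (single-group mode)
#'
#' \eqn{\tau^2 | \cdot \sim IG\big(\tfrac{M'+1}{2},
#' \sum_j \tfrac{N\beta_j^2}{2\sigma^2\delta_{g(j)}^2\lambda_j^2} +
#' \tfrac{1}{w}\big)}, \eqn{w | \tau^2 \sim IG(1, \tau^{-2} + 1)} — the same
#' half-Cauchy mixture as the group scales, over all copies.
#'
#' @param beta,lambda2,delta2_copy Per-copy values.
#' @param sigma2,n_gwas Scalars.
#' @param w Current hyper-scale.
#' @return List with `tau2` and updated `w`.
#' @export
sample_tau2 <- function(beta, lambda2, delta2_copy, sigma2, n_gwas, w) {
  ssum <- sum(n_gwas * beta^2 / (lambda2 * delta2_copy)) / (2 * sigma2)
  tau2 <- pmax(rinvgamma(1L, (length(beta) + 1) / 2, ssum + 1 / w), 1e-12)
  w_new <- rinvgamma(1L, 1, 1 / tau2 + 1)
  list(tau2 = tau2, w = w_new)
}

#' Run the blocked Gibbs sampler
#'
#' Fits the bilevel continuous shrinkage model to GWAS summary statistics
#' given block-diagonal LD and an annotation map, and returns posterior-mean
#' effect sizes per (variant, group) copy. Update order per sweep:
#' beta (block-wise) -> sigma2 -> \{delta2, t\} -> \{lambda2, c\}
#' (-> tau2 in `prscs_auto` mode). Deterministic given `cfg$seed`.
#'
#' @param ss A `prsbils_sumstats` aligned to `ld`/`annot` (same variants,
#'   same order).
#' @param ld An `ld_blocks` object.
#' @param annot An `annotation_map` on the same variants. Ignored (collapsed
#'   to one group) in `prscs_auto` mode.
#' @param cfg A [prsbils_config()].
#' @return An object of class `prsbils_posterior`: per-copy posterior mean
#'   `beta_mean`, per-group `delta2_mean`, `sigma2_mean`, `tau2_mean`, the
#'   annotation map used, kept-draw count, clamp/floor event counts, and
#'   (optionally) the retained `draws` matrix.
#' @export
run_gibbs <- function(ss, ld, annot, cfg = prsbils_config()) {
  stopifnot(inherits(cfg, "prsbils_config"), inherits(annot, "annotation_map"))
  if (!identical(as.character(ss$variant_id), as.character(ld$variant_ids)) ||
      !identical(as.character(ss$variant_id), as.character(annot$variant_ids)))
    stop("summary statistics, LD blocks and annotations must be aligned on ",
         "the same variants in the same order")
  prscs <- cfg$mode == "prscs_auto"
  if (prscs) annot <- collapse_annotations(annot)
  half_cauchy_local <- !prscs || (cfg$a0 == 0.5 && cfg$b0 == 1)

  n_gwas <- ss$n_gwas[1]
  beta_hat <- ss$beta_hat
  bh_copy <- beta_hat[annot$copy_variant]
  Mp <- annot$M_prime
  K <- annot$K
  g <- annot$copy_group

  # expand LD blocks to annotation copies (variant-major copy order keeps
  # each block's copies contiguous)
  blocks <- lapply(ld$blocks, function(b) {
    cidx <- which(annot$copy_variant %in% b$idx)
    local <- match(annot$copy_variant[cidx], b$idx)
    list(cidx = cidx, D = b$D[local, local, drop = FALSE],
         bh = beta_hat[annot$copy_variant[cidx]])
  })

  ini <- function(name, default) if (!is.null(cfg$init[[name]])) cfg$init[[name]] else default
  beta <- rep_len(ini("beta", 0), Mp)
  sigma2 <- ini("sigma2", 1)
  delta2 <- rep_len(ini("delta2", 1), K)
  lambda2 <- rep_len(ini("lambda2", 1), Mp)
  tau2 <- ini("tau2", 1)
  t_hyper <- rep(1, K)
  c_hyper <- rep(1, Mp)
  w_hyper <- 1

  keep <- (seq_len(cfg$n_iter) > cfg$n_burnin) &
    ((seq_len(cfg$n_iter) - cfg$n_burnin - 1L) %% cfg$thin == 0L)
  n_keep <- sum(keep)
  beta_sum <- numeric(Mp); delta2_sum <- numeric(K)
  sigma2_sum <- 0; tau2_sum <- 0
  draws <- if (cfg$keep_draws) matrix(NA_real_, n_keep, Mp) else NULL
  kept <- 0L
  n_clamped <- 0L

  set.seed(cfg$seed)
  for (it in seq_len(cfg$n_iter)) {
    psi <- clip_product(delta2[g] * lambda2 * tau2, cfg$clip_psi)
    quad <- 0
    for (b in blocks) {
      res <- sample_beta_block(b$bh, b$D, psi[b$cidx], sigma2, n_gwas)
      beta[b$cidx] <- res$beta
      quad <- quad + res$quad
    }
    if (!is.finite(quad) || anyNA(beta))
      stop("non-finite sampler state at iteration ", it)

    if (!cfg$fix_sigma2) {
      s2 <- sample_sigma2(beta, bh_copy, quad, n_gwas, Mp,
                          prior_quad = sum(beta^2 / psi))
      sigma2 <- s2$sigma2
      n_clamped <- n_clamped + s2$clamped
    }
    if (!cfg$fix_delta2) {
      d <- sample_delta2(beta, lambda2, g, sigma2, n_gwas, t_hyper, K)
      delta2 <- d$delta2
      t_hyper <- d$t
    }
    if (!cfg$fix_lambda2) {
      l <- sample_lambda2(beta, sigma2, c_hyper, n_gwas,
                          gamma_gamma = !half_cauchy_local,
                          a0 = cfg$a0, b0 = cfg$b0)
      lambda2 <- l$lambda2
      c_hyper <- l$c
    }
    if (prscs && !cfg$fix_tau) {
      tu <- sample_tau2(beta, lambda2, delta2[g], sigma2, n_gwas, w_hyper)
      tau2 <- tu$tau2
      w_hyper <- tu$w
    }

    if (keep[it]) {
      kept <- kept + 1L
      beta_sum <- beta_sum + beta
      delta2_sum <- delta2_sum + delta2
      sigma2_sum <- sigma2_sum + sigma2
      tau2_sum <- tau2_sum + tau2
      if (cfg$keep_draws) draws[kept, ] <- beta
    }
  }
  if (n_clamped > 0.01 * cfg$n_iter)
    warning("sigma2 scale clamped in ", n_clamped, " of ", cfg$n_iter,
            " iterations; check LD/summary-statistic consistency")

  structure(list(beta_mean = beta_sum / n_keep,
                 variant_id = annot$variant_ids[annot$copy_variant],
                 copy_variant = annot$copy_variant,
                 copy_group = annot$copy_group,
                 groups = annot$groups,
                 annot = annot,
                 delta2_mean = delta2_sum / n_keep,
                 sigma2_mean = sigma2_sum / n_keep,
                 tau2_mean = tau2_sum / n_keep,
                 n_kept = n_keep, n_clamped = n_clamped,
                 draws = draws, config = cfg, n_gwas = n_gwas),
            class = "prsbils_posterior")
}

#' @export
print.prsbils_posterior <- function(x, ...) {
  cat("prsbils_posterior:", length(x$beta_mean), "effect copies,",
      length(x$groups), "groups; mode", x$config$mode, ";",
      x$n_kept, "kept draws\n")
  invisible(x)
}

#' Extract posterior effect sizes as a table
#'
#' @param post A `prsbils_posterior`.
#' @param ss The matching summary statistics (for the effect allele).
#' @param per_copy Keep one row per (variant, group) copy (`TRUE`) or sum
#'   copies per variant into a single weight (`FALSE`).
#' @return `data.frame` with `variant_id`, `a1`, `group` (per-copy only),
#'   `effect`; suitable for [write_posterior()].
#' @export
posterior_effects <- function(post, ss, per_copy = TRUE) {
  a1 <- ss$a1[match(post$variant_id, ss$variant_id)]
  if (per_copy) {
    data.frame(variant_id = post$variant_id, a1 = a1,
               group = post$groups[post$copy_group],
               effect = post$beta_mean, stringsAsFactors = FALSE)
  } else {
    eff <- tapply(post$beta_mean, post$copy_variant, sum)
    i <- as.integer(names(eff))
    data.frame(variant_id = post$annot$variant_ids[i],
               a1 = ss$a1[match(post$annot$variant_ids[i], ss$variant_id)],
               effect = as.numeric(eff), stringsAsFactors = FALSE)
  }
}
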