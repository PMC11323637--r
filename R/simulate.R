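# Synthetic-data engine: block-LD genotypes, point-Normal genetic effects
# stratified by annotation group, phenotypes with fixed heritability, and
# marginal GWAS summary statistics.

#' Simulation setting presets
#'
#' Packaged parameter grids for the seven study settings: four-group designs
#' with causal proportions (0.5, 1, 1.5, 2)% and heritability shares ranging
#' from highly group-sparse (0, 0, 10, 90)% to uniform (25, 25, 25, 25)%, a
#' ten-group design with shares (0 x 8, 10, 90)%, and two overlapping-group
#' variants of the sparse design (patterns I and II). Total heritability is
#' 0.7 throughout. The `"desk"` scale keeps the group-size proportions of
#' the full design at M = 2,000 variants with N_sumstat = 2,000 and
#' N_test = 1,000; `"full"` is the original scale (M = 125,000,
#' N_sumstat = 50,000, N_test = 24,000).
#'
#' @param setting Integer 1..7.
#' @param scale `"desk"` (default) or `"full"`.
#' @param h2 Total heritability (default 0.7).
#' @param iou_high,iou_low Target pairwise IOU for the overlapping settings
#'   (6: pattern I, high IOU among the zero-heritability groups;
#'   7: pattern II, high IOU between the 10% and 90% groups).
#' @param p_k Optional override of the per-group causal proportions. The
#'   presets keep the full design's causal *fractions*; group-scale recovery
#'   experiments at reduced M should instead preserve the order of causal
#'   *counts* (e.g. tenfold the fractions at M = 2,000), since a handful of
#'   causal variants cannot identify a group-level scale.
#' @return A list of class `sim_setting`: `setting`, `K`, `M`, `M_k`, `p_k`,
#'   `q_k`, `h2`, `overlap` (`"none"`, `"pattern_I"`, `"pattern_II"`),
#'   `iou_high`, `iou_low`, `N_sumstat`, `N_test`, `N_ref`, `block_size`,
#'   `rho`, `maf_range`.
#' @export
sim_setting <- function(setting, scale = c("desk", "full"), h2 = 0.7,
                        iou_high = 0.5, iou_low = 0, p_k = NULL) {
  scale <- match.arg(scale)
  stopifnot(setting %in% 1:7)
  M_k4 <- c(49750, 37500, 25125, 12625)
  grid <- list(
    list(K = 4L, M_k = M_k4, p_k = c(0.5, 1, 1.5, 2) / 100,
         q_k = c(0, 0, 10, 90) / 100, overlap = "none"),
    list(K = 4L, M_k = M_k4, p_k = c(0.5, 1, 1.5, 2) / 100,
         q_k = c(0, 0, 50, 50) / 100, overlap = "none"),
    list(K = 4L, M_k = M_k4, p_k = c(0.5, 1, 1.5, 2) / 100,
         q_k = c(10, 20, 30, 40) / 100, overlap = "none"),
    list(K = 4L, M_k = M_k4, p_k = c(0.5, 1, 1.5, 2) / 100,
         q_k = c(25, 25, 25, 25) / 100, overlap = "none"),
    list(K = 10L, M_k = c(rep(12375, 6), 12625, 12625, 12750, 12750),
         p_k = c(rep(0, 6), 2, 2, 3, 3) / 100,
         q_k = c(rep(0, 8), 10, 90) / 100, overlap = "none"),
    list(K = 4L, M_k = M_k4, p_k = c(0.5, 1, 1.5, 2) / 100,
         q_k = c(0, 0, 10, 90) / 100, overlap = "pattern_I"),
    list(K = 4L, M_k = M_k4, p_k = c(0.5, 1, 1.5, 2) / 100,
         q_k = c(0, 0, 10, 90) / 100, overlap = "pattern_II"))[[setting]]
  M_full <- 125000L
  if (scale == "desk") {
    M <- 2000L
    M_k <- round(grid$M_k / M_full * M)
    M_k[1] <- M_k[1] + (M - sum(M_k))  # absorb rounding
    dims <- list(M = M, M_k = as.integer(M_k), N_sumstat = 2000L,
                 N_test = 1000L, N_ref = 500L, block_size = 50L)
  } else {
    dims <- list(M = M_full, M_k = as.integer(grid$M_k), N_sumstat = 50000L,
                 N_test = 24000L, N_ref = 500L, block_size = 500L)
  }
  if (!is.null(p_k)) {
    stopifnot(length(p_k) == grid$K)
    grid$p_k <- p_k
  }
  stopifnot(sum(dims$M_k) == dims$M, abs(sum(grid$q_k) - 1) < 1e-12,
            all(grid$p_k >= 0 & grid$p_k <= 1))
  structure(c(list(setting = as.integer(setting), scale = scale, K = grid$K,
                   p_k = grid$p_k, q_k = grid$q_k, h2 = h2,
                   overlap = grid$overlap, iou_high = iou_high,
                   iou_low = iou_low),
              dims, list(rho = 0.5, maf_range = c(0.05, 0.5))),
            class = "sim_setting")
}

#' Write / read a simulation setting as a key=value config file
#'
#' @param setting A `sim_setting`.
#' @param path File path.
#' @return `path` invisibly (`write_sim_setting`); a `sim_setting`
#'   (`read_sim_setting`).
#' @export
write_sim_setting <- function(setting, path) {
  fmt <- function(x) paste(format(x, digits = 15, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  lines <- vapply(names(setting), function(nm) paste0(nm, "=", fmt(setting[[nm]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_setting
#' @export
read_sim_setting <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  out <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1, FUN.VALUE = ""))
  num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  res <- sim_setting(as.integer(out$setting), out$scale,
                     h2 = num(out$h2), iou_high = num(out$iou_high),
                     iou_low = num(out$iou_low))
  res
}

#' Simulate genotypes with block-autoregressive LD
#'
#' Within each block of `block_size` variants, two latent AR(1) Gaussian
#' haplotypes per individual (correlation `rho` between adjacent variants)
#' are thresholded at each variant's minor-allele-frequency quantile and
#' summed to Hardy-Weinberg dosages in \{0, 1, 2\}. Blocks are independent;
#' variants are placed on one chromosome at 1 kb spacing.
#'
#' @param M Number of variants.
#' @param N Number of individuals.
#' @param block_size Variants per LD block.
#' @param maf Either a range `c(lo, hi)` in (0.01, 0.5] to draw per-variant
#'   MAFs from, or a length-M vector of fixed MAFs (use a shared vector to
#'   make several panels draw from the same population).
#' @param rho AR(1) latent correlation in \[0, 0.95\].
#' @param seed RNG seed.
#' @param standardize Standardize the dosages (default `TRUE`).
#' @return A `genotype_panel`; the drawn MAF vector is in attribute `maf`.
#' @export
simulate_genotypes <- function(M, N, block_size = 50L, maf = c(0.05, 0.5),
                               rho = 0.5, seed = 1L, standardize = TRUE) {
  stopifnot(rho >= 0, rho <= 0.95)
  set.seed(seed)
  maf <- if (length(maf) == 2L && M != 2L) stats::runif(M, maf[1], maf[2]) else rep_len(maf, M)
  stopifnot(all(maf > 0.01 - 1e-9), all(maf <= 0.5))
  thr <- stats::qnorm(maf)
  X <- matrix(0L, N, M)
  n_blocks <- ceiling(M / block_size)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_size + 1L):min(b * block_size, M)
    m <- length(idx)
    for (hap in 1:2) {
      Z <- matrix(stats::rnorm(N * m), N, m)
      if (rho > 0 && m > 1) {
        for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
      }
      X[, idx] <- X[, idx] + (Z < matrix(thr[idx], N, m, byrow = TRUE))
    }
  }
  vars <- data.frame(variant_id = sprintf("sv%05d", seq_len(M)),
                     chrom = "1", pos = 1000L * seq_len(M),
                     a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  panel <- genotype_panel(X, vars)
  if (standardize) panel <- standardize_panel(panel)
  attr(panel, "maf") <- maf
  panel
}

#' Draw true genetic effects from the stratified point-Normal model
#'
#' Each variant in annotation group k is causal with probability `p_k`;
#' causal effects are \eqn{N(0, q_k h^2 / (p_k M_k))} on the standardized
#' scale, so group k's expected total effect variance is its stated
#' heritability share \eqn{q_k h^2}. Groups with `q_k = 0` get all-zero
#' effects regardless of `p_k`; `p_k = 0` with `q_k > 0` is a configuration
#' error. Group labels are assigned by a seeded random permutation of the
#' per-group counts `M_k`.
#'
#' @param setting A [sim_setting()].
#' @param seed RNG seed.
#' @return A list of class `truth_set`: `beta` (length M), `causal`
#'   (logical), `group` (integer true assignment), `per_snp_h2` (true
#'   per-variant variance contributions, exported for the ranked-bin
#'   comparator), `groups` (labels `g1..gK`).
#' @export
draw_effects <- function(setting, seed = 1L) {
  stopifnot(inherits(setting, "sim_setting"))
  bad <- setting$p_k == 0 & setting$q_k > 0
  if (any(bad))
    stop("group(s) ", paste(which(bad), collapse = ", "),
         " have q_k > 0 but p_k = 0: heritability unassignable")
  set.seed(seed)
  group <- sample(rep.int(seq_len(setting$K), setting$M_k))
  beta <- numeric(setting$M)
  causal <- logical(setting$M)
  for (k in seq_len(setting$K)) {
    if (setting$q_k[k] == 0) next
    jk <- which(group == k)
    is_causal <- stats::runif(length(jk)) < setting$p_k[k]
    v <- setting$q_k[k] * setting$h2 / (setting$p_k[k] * setting$M_k[k])
    beta[jk[is_causal]] <- stats::rnorm(sum(is_causal), 0, sqrt(v))
    causal[jk[is_causal]] <- TRUE
  }
  structure(list(beta = beta, causal = causal, group = group,
                 per_snp_h2 = beta^2,
                 groups = paste0("g", seq_len(setting$K)),
                 setting = setting),
            class = "truth_set")
}

#' Simulate a phenotype with fixed in-sample heritability
#'
#' \eqn{y = G\beta + \epsilon} with the normal error orthogonalized against
#' the genetic value and rescaled so that the in-sample genetic variance
#' share \eqn{Var(G\beta)/Var(y)} equals `h2` exactly; `y` is then
#' re-standardized.
#'
#' @param panel Standardized `genotype_panel`.
#' @param truth A `truth_set` (or a plain numeric effect vector).
#' @param h2 Target heritability (default 0.7).
#' @param seed RNG seed.
#' @return Numeric phenotype vector (mean 0, variance 1).
#' @export
simulate_phenotype <- function(panel, truth, h2 = 0.7, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  panel <- standardize_panel(panel)
  beta <- if (inherits(truth, "truth_set")) truth$beta else truth
  stopifnot(length(beta) == ncol(panel$X))
  gv <- as.numeric(panel$X %*% beta)
  vg <- stats::var(gv)
  if (vg == 0) stop("degenerate genetic value: all effects zero")
  set.seed(seed)
  eps <- stats::rnorm(nrow(panel$X))
  eps <- eps - mean(eps)
  eps <- eps - gv * stats::cov(eps, gv) / vg  # orthogonal to the genetic value
  eps <- eps * sqrt(vg * (1 - h2) / h2 / stats::var(eps))
  y <- gv + eps
  (y - mean(y)) / stats::sd(y)
}

#' Marginal GWAS on standardized data
#'
#' Per-variant marginal least-squares effects
#' \eqn{\hat\beta_j = \tfrac{1}{N}\sum_i g_{ij} y_i} (equal to the OLS slope
#' of `y` on each standardized variant), packaged as summary statistics.
#'
#' @param panel Standardized `genotype_panel`.
#' @param phenotype Standardized phenotype vector.
#' @return A `prsbils_sumstats` with `n_gwas = N`.
#' @export
marginal_gwas <- function(panel, phenotype) {
  panel <- standardize_panel(panel)
  N <- nrow(panel$X)
  stopifnot(length(phenotype) == N)
  beta_hat <- as.numeric(crossprod(panel$X, phenotype)) / N
  out <- data.frame(variant_id = panel$variants$variant_id,
                    chrom = panel$variants$chrom, pos = panel$variants$pos,
                    a1 = panel$variants$a1, a2 = panel$variants$a2,
                    beta_hat = beta_hat, n_gwas = N, stringsAsFactors = FALSE)
  class(out) <- c("prsbils_sumstats", "data.frame")
  out
}

#' Overlay an overlapping-group pattern on a non-overlapping assignment
#'
#' Adds secondary group memberships so that selected group pairs reach a
#' target pairwise intersection-over-union. Pattern I targets `iou_high`
#' among the zero-heritability groups (`iou_low` elsewhere); pattern II
#' targets `iou_high` between the two heritability-carrying groups (the two
#' largest `q_k`). For a pair (k1, k2) the construction moves
#' \eqn{x = \lceil \theta (M_{k_1} + M_{k_2}) \rceil} members of k2 into k1
#' as shared members, which requires \eqn{\theta \le M_{k_2}/(M_{k_1}+M_{k_2})}.
#'
#' @param annot Non-overlapping `annotation_map` (the true assignment).
#' @param setting The [sim_setting()] providing `q_k` and the pattern.
#' @param pattern `"I"` or `"II"`; defaults to the setting's own pattern.
#' @param iou_high,iou_low Target IOUs; default from the setting.
#' @param seed Seed for sampling which variants become shared.
#' @return An overlapping `annotation_map`; achieved pairwise IOUs in
#'   attribute `achieved_iou`.
#' @export
make_overlap <- function(annot, setting, pattern = NULL, iou_high = NULL,
                         iou_low = NULL, seed = 1L) {
  stopifnot(inherits(annot, "annotation_map"), annot$M_prime == annot$M)
  if (is.null(pattern))
    pattern <- switch(setting$overlap, pattern_I = "I", pattern_II = "II",
                      stop("setting has no overlap pattern; pass `pattern`"))
  if (is.null(iou_high)) iou_high <- setting$iou_high
  if (is.null(iou_low)) iou_low <- setting$iou_low
  stopifnot(iou_low >= 0, iou_low <= iou_high, iou_high < 1)
  K <- annot$K
  stopifnot(K == setting$K)
  pairs <- t(utils::combn(K, 2))
  hi <- if (pattern == "I") {
    z <- which(setting$q_k == 0)
    pairs[, 1] %in% z & pairs[, 2] %in% z
  } else {
    top2 <- order(setting$q_k, decreasing = TRUE)[1:2]
    pairs[, 1] %in% top2 & pairs[, 2] %in% top2
  }
  target <- ifelse(hi, iou_high, iou_low)
  membership <- lapply(annot$membership, identity)
  set.seed(seed)
  for (i in seq_len(nrow(pairs))) {
    if (target[i] <= 0) next
    k1 <- pairs[i, 1]; k2 <- pairs[i, 2]
    m1 <- sum(annot$copy_group == k1); m2 <- sum(annot$copy_group == k2)
    x <- ceiling(target[i] * (m1 + m2))
    feas <- m2 / (m1 + m2)
    if (x > m2)
      stop(sprintf("IOU %.2f infeasible for groups %d,%d (max %.3f)",
                   target[i], k1, k2, feas))
    donors <- which(annot$copy_group == k2)
    shared <- annot$copy_variant[sample(donors, x)]
    for (j in shared) membership[[j]] <- union(membership[[j]], k1)
  }
  labels <- paste0("g", seq_len(K))
  out <- annotation_map(annot$variant_ids,
                        lapply(membership, function(ix) labels[ix]))
  iou <- apply(pairs, 1, function(pr) group_iou(out, pr[1], pr[2]))
  attr(out, "achieved_iou") <- data.frame(k1 = pairs[, 1], k2 = pairs[, 2],
                                          target = target, achieved = iou)
  out
}

#' Randomly misclassify annotation groups
#'
#' Replaces each variant's observed group with a uniform draw over the K
#' groups, independent of the true assignment (the misclassification
#' robustness experiment).
#'
#' @param annot Non-overlapping `annotation_map`.
#' @param seed RNG seed.
#' @return An `annotation_map` with the same groups, reshuffled assignment.
#' @export
misclassify_annotations <- function(annot, seed = 1L) {
  stopifnot(inherits(annot, "annotation_map"), annot$M_prime == annot$M)
  if (annot$K == 1L) return(annot)
  set.seed(seed)
  obs <- sample.int(annot$K, annot$M, replace = TRUE)
  annotation_map(annot$variant_ids, lapply(obs, function(k) annot$groups[k]))
}

#' Simulate a complete study
#'
#' End-to-end generator for one replicate of a simulation setting: a shared
#' variant model (MAFs, block structure), disjoint GWAS / test / LD-reference
#' panels, true effects, phenotypes, marginal summary statistics, the
#' annotation map (with overlap or misclassification applied when asked),
#' and LD blocks estimated from the reference panel.
#'
#' @param setting A [sim_setting()].
#' @param seed Replicate seed; all panel/effect/phenotype seeds derive
#'   from it.
#' @param misclassify Replace the analysis annotation with uniformly random
#'   groups (truth is kept for effect generation).
#' @return List with `ss` (summary statistics), `ld` (`ld_blocks` from the
#'   reference panel), `annot` (analysis annotation map), `truth`,
#'   `test_panel`, `test_phenotype`, `setting`.
#' @export
simulate_study <- function(setting, seed = 1L, misclassify = FALSE) {
  stopifnot(inherits(setting, "sim_setting"))
  seeds <- seed * 101L + 0:5
  set.seed(seeds[1])
  maf <- stats::runif(setting$M, setting$maf_range[1], setting$maf_range[2])

  truth <- draw_effects(setting, seed = seeds[2])
  gwas_panel <- simulate_genotypes(setting$M, setting$N_sumstat,
                                   setting$block_size, maf, setting$rho,
                                   seed = seeds[3])
  y_gwas <- simulate_phenotype(gwas_panel, truth, setting$h2, seed = seeds[3])
  ss <- marginal_gwas(gwas_panel, y_gwas)

  test_panel <- simulate_genotypes(setting$M, setting$N_test,
                                   setting$block_size, maf, setting$rho,
                                   seed = seeds[4])
  y_test <- simulate_phenotype(test_panel, truth, setting$h2, seed = seeds[4])

  ref_panel <- simulate_genotypes(setting$M, setting$N_ref, setting$block_size,
                                  maf, setting$rho, seed = seeds[5])
  ld <- compute_ld_blocks(ref_panel, max_block_size = setting$block_size)

  annot <- annotation_map(gwas_panel$variants$variant_id,
                          lapply(truth$group, function(k) truth$groups[k]))
  if (setting$overlap != "none")
    annot <- make_overlap(annot, setting, seed = seeds[6])
  if (misclassify)
    annot <- misclassify_annotations(annot, seed = seeds[6])

  list(ss = ss, ld = ld, annot = annot, truth = truth,
       test_panel = test_panel, test_phenotype = y_test, setting = setting)
}
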