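test_that("setting presets encode the study grid at both scales", {
  st <- sim_setting(1)
  expect_equal(st$K, 4L)
  expect_equal(sum(st$M_k), st$M)
  expect_equal(st$q_k, c(0, 0, 0.1, 0.9))
  expect_equal(st$h2, 0.7)
  full <- sim_setting(5, scale = "full")
  expect_equal(full$M, 125000L)
  expect_equal(full$K, 10L)
  expect_equal(sum(full$M_k), 125000L)
  expect_equal(full$N_sumstat, 50000L)
  expect_equal(full$N_test, 24000L)
  expect_equal(sum(full$q_k), 1)
})

test_that("settings round-trip through the config file format", {
  for (s in c(1L, 5L, 6L)) {
    st <- sim_setting(s, iou_high = 0.4, iou_low = 0.05)
    f <- tempfile()
    write_sim_setting(st, f)
    back <- read_sim_setting(f)
    expect_equal(back[names(back) != "scale"], st[names(st) != "scale"],
                 tolerance = 1e-12)
  }
})

test_that("simulated genotypes respect MAF, HWE symmetry, and determinism", {
  p1 <- simulate_genotypes(10, 4000, block_size = 5, maf = rep(0.5, 10),
                           rho = 0, seed = 1, standardize = FALSE)
  expect_true(all(p1$X %in% 0:2))
  expect_equal(unname(colMeans(p1$X)), rep(1, 10), tolerance = 0.06)

  p2 <- simulate_genotypes(10, 500, block_size = 5, maf = c(0.1, 0.5),
                           rho = 0.5, seed = 2)
  p3 <- simulate_genotypes(10, 500, block_size = 5, maf = c(0.1, 0.5),
                           rho = 0.5, seed = 2)
  expect_identical(p2$X, p3$X)

  # rho = 0: empirical correlations bounded by 4/sqrt(N)
  p4 <- simulate_genotypes(12, 2000, block_size = 6, maf = c(0.2, 0.5),
                           rho = 0, seed = 3)
  C <- cor(p4$X)
  expect_lt(max(abs(C[upper.tri(C)])), 4 / sqrt(2000))

  # rho > 0: adjacent variants within a block are clearly correlated
  p5 <- simulate_genotypes(10, 2000, block_size = 5, maf = c(0.3, 0.5),
                           rho = 0.8, seed = 4)
  C5 <- cor(p5$X)
  expect_gt(mean(C5[cbind(1:4, 2:5)]), 0.3)
  # but block boundaries break correlation
  expect_lt(abs(C5[5, 6]), 4 / sqrt(2000))
})

test_that("point-Normal effects follow the stratified architecture", {
  st <- sim_setting(4)   # equal q, causal fractions 0.5..2%
  truth <- draw_effects(st, seed = 1)
  expect_equal(length(truth$beta), st$M)
  expect_equal(tabulate(truth$group, st$K), st$M_k)
  expect_equal(truth$per_snp_h2, truth$beta^2)

  # expected causal count = sum M_k p_k (~20 at this scale)
  counts <- vapply(1:30, function(r) sum(draw_effects(st, seed = r)$causal),
                   numeric(1))
  expected <- sum(st$M_k * st$p_k)
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 30))

  # q_k = 0 group has all-zero effects even with p_k > 0
  st1 <- sim_setting(1)
  t1 <- draw_effects(st1, seed = 2)
  expect_true(all(t1$beta[t1$group %in% 1:2] == 0))

  # p_k = 0 with q_k > 0 is a configuration error
  st_bad <- sim_setting(1, p_k = c(0.005, 0.01, 0, 0.02))
  expect_error(draw_effects(st_bad, seed = 1), "unassignable")
})

test_that("per-group effect variance matches its heritability share", {
  st <- sim_setting(1)
  reps <- 50
  shares <- matrix(0, reps, st$K)
  for (r in seq_len(reps)) {
    tr <- draw_effects(st, seed = 1000 + r)
    shares[r, ] <- tapply(tr$beta^2, factor(tr$group, levels = 1:st$K), sum)
  }
  means <- colMeans(shares)
  ses <- apply(shares, 2, sd) / sqrt(reps)
  for (k in seq_len(st$K)) {
    expect_lt(abs(means[k] - st$q_k[k] * st$h2), 3 * ses[k] + 1e-12)
  }
})

test_that("phenotypes fix the in-sample heritability exactly", {
  panel <- simulate_genotypes(50, 300, block_size = 25, maf = c(0.1, 0.5),
                              rho = 0.4, seed = 5)
  beta <- numeric(50); beta[1:5] <- 0.3
  y <- simulate_phenotype(panel, beta, h2 = 0.7, seed = 5)
  gv <- as.numeric(panel$X %*% beta)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_equal(sd(y), 1, tolerance = 1e-12)
  # in-sample genetic variance share is exactly h2: R2 of y on the genetic value
  expect_equal(summary(lm(y ~ gv))$r.squared, 0.7, tolerance = 1e-6)
  expect_identical(y, simulate_phenotype(panel, beta, h2 = 0.7, seed = 5))

  expect_error(simulate_phenotype(panel, numeric(50), seed = 1), "degenerate")

  yh <- simulate_phenotype(panel, beta, h2 = 1 - 1e-12, seed = 6)
  expect_equal(cor(yh, gv)^2, 1, tolerance = 1e-9)
})

test_that("marginal GWAS equals per-variant OLS on standardized data", {
  panel <- simulate_genotypes(30, 400, block_size = 10, maf = c(0.1, 0.5),
                              rho = 0.3, seed = 7)
  beta <- numeric(30); beta[1] <- 0.5
  y <- simulate_phenotype(panel, beta, h2 = 0.6, seed = 7)
  ss <- marginal_gwas(panel, y)
  ols <- apply(panel$X, 2, function(g) sum(g * y) / sum(g^2) * mean(g^2))
  expect_equal(ss$beta_hat, unname(ols), tolerance = 1e-12)
  expect_equal(ss$n_gwas[1], 400L)

  # y equal to one standardized variant: its marginal effect is 1
  g1 <- panel$X[, 1]
  ss1 <- marginal_gwas(panel, g1)
  expect_equal(ss1$beta_hat[1], mean(g1^2), tolerance = 1e-12)

  # null phenotype: nearly all effects inside the normal tail bound
  set.seed(8)
  ss0 <- marginal_gwas(panel, rnorm(400))
  expect_gt(mean(abs(ss0$beta_hat) < 4 / sqrt(400)), 0.99)
})

test_that("overlap construction hits requested IOUs and keeps the rest", {
  st <- sim_setting(6, iou_high = 0.3, iou_low = 0)
  truth <- draw_effects(st, seed = 9)
  annot <- annotation_map(paste0("v", seq_len(st$M)),
                          lapply(truth$group, function(k) paste0("g", k)))
  ov <- make_overlap(annot, st, seed = 9)
  expect_gt(ov$M_prime, ov$M)
  iou <- attr(ov, "achieved_iou")
  hi <- iou$target > 0
  expect_true(all(abs(iou$achieved[hi] - iou$target[hi]) < 0.02))
  expect_true(all(iou$achieved[!hi] == 0))
  # pattern I: the high pair is among the zero-heritability groups (1, 2)
  expect_true(all(iou$k1[hi] %in% 1:2 & iou$k2[hi] %in% 1:2))

  # pattern II targets the two heritability-carrying groups
  st7 <- sim_setting(7, iou_high = 0.3)
  ov7 <- make_overlap(annot, st7, seed = 9)
  iou7 <- attr(ov7, "achieved_iou")
  hi7 <- iou7$target > 0
  expect_true(all(iou7$k1[hi7] %in% 3:4 & iou7$k2[hi7] %in% 3:4))

  # iou_high = 0 reduces to the non-overlapping map
  st0 <- sim_setting(6, iou_high = 0, iou_low = 0)
  ov0 <- make_overlap(annot, st0, seed = 9)
  expect_equal(ov0$M_prime, annot$M)

  # infeasible request errors with the bound
  expect_error(make_overlap(annot, sim_setting(6, iou_high = 0.9), seed = 1),
               "infeasible")
})

test_that("misclassification is uniform and label-preserving", {
  am1 <- annotation_map(paste0("v", 1:10), rep(list("g1"), 10))
  expect_identical(misclassify_annotations(am1, seed = 1)$copy_group,
                   am1$copy_group)

  st <- sim_setting(4)
  truth <- draw_effects(st, seed = 3)
  annot <- annotation_map(paste0("v", seq_len(st$M)),
                          lapply(truth$group, function(k) paste0("g", k)))
  mis <- misclassify_annotations(annot, seed = 4)
  expect_equal(mis$M_prime, annot$M)
  # expected fraction keeping their true group = 1/K
  keep <- mean(mis$copy_group == annot$copy_group)
  expect_lt(abs(keep - 1 / 4), 3 * sqrt(0.25 * 0.75 / st$M))
  # groups roughly M/K each
  expect_lt(max(abs(mis$sizes - st$M / 4)), 3 * sqrt(st$M * 0.25 * 0.75))
})

test_that("the full study pipeline is deterministic and internally aligned", {
  st <- sim_setting(1)
  s1 <- simulate_study(st, seed = 4)
  s2 <- simulate_study(st, seed = 4)
  expect_identical(s1$ss$beta_hat, s2$ss$beta_hat)
  expect_identical(s1$truth$beta, s2$truth$beta)
  expect_identical(s1$test_phenotype, s2$test_phenotype)
  expect_equal(s1$ss$variant_id, s1$ld$variant_ids)
  expect_equal(s1$ss$variant_id, s1$annot$variant_ids)
  # disjoint panels: GWAS and test genotypes differ
  expect_false(identical(s1$test_panel$X[1, ], s2$test_panel$X[2, ]))
})
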