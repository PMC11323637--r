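# Small fixture builders shared across tests; everything is generated in code.

# tiny genotype panel with given dosage matrix
toy_panel <- function(X, chrom = "1", a1 = NULL, a2 = NULL) {
  m <- ncol(X)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  genotype_panel(X, data.frame(variant_id = paste0("rs", seq_len(m)),
                               chrom = chrom, pos = 1000L * seq_len(m),
                               a1 = a1, a2 = a2, stringsAsFactors = FALSE))
}

# sumstats data.frame built directly (already on the standardized scale)
toy_sumstats <- function(beta_hat, n_gwas = 1000L, a1 = NULL, a2 = NULL,
                         ids = NULL) {
  m <- length(beta_hat)
  if (is.null(ids)) ids <- paste0("rs", seq_len(m))
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  out <- data.frame(variant_id = ids, chrom = "1", pos = 1000L * seq_len(m),
                    a1 = a1, a2 = a2, beta_hat = beta_hat,
                    n_gwas = as.integer(n_gwas), stringsAsFactors = FALSE)
  class(out) <- c("prsbils_sumstats", "data.frame")
  out
}

# write a sumstats text file with the given columns
write_ss_file <- function(df) {
  f <- tempfile(fileext = ".txt")
  utils::write.table(df, f, sep = " ", quote = FALSE, row.names = FALSE)
  f
}

# identity-LD blocks for m variants
identity_ld <- function(ids, block_sizes = length(ids)) {
  idx <- split(seq_along(ids), rep(seq_along(block_sizes), block_sizes))
  ld_blocks_from_matrices(idx, lapply(block_sizes, diag), ids, n_ref = 1000L)
}

# single-group annotation for a set of variant ids
single_group_annot <- function(ids) {
  annotation_map(ids, rep(list("all"), length(ids)))
}

# a small aligned (ss, ld, annot) triple with simulated consistency
toy_gibbs_inputs <- function(M = 60, N = 800, K = 2, seed = 42,
                             block_size = 20) {
  set.seed(seed)
  maf <- runif(M, 0.1, 0.5)
  panel <- simulate_genotypes(M, N, block_size, maf, rho = 0.4, seed = seed)
  beta <- numeric(M)
  beta[seq_len(4)] <- rnorm(4, 0, 0.15)
  y <- simulate_phenotype(panel, beta, h2 = 0.5, seed = seed)
  ss <- marginal_gwas(panel, y)
  ld <- compute_ld_blocks(panel, max_block_size = block_size)
  annot <- annotation_map(ss$variant_id,
                          lapply(rep_len(seq_len(K), M), function(k) paste0("g", k)))
  list(ss = ss, ld = ld, annot = annot, panel = panel, y = y, beta = beta)
}
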