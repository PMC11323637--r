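#' Partition variants into contiguous LD windows
#'
#' Greedy fixed-size windows that never span chromosomes. This is the block
#' structure used by the Gibbs sampler's joint multivariate-normal updates;
#' variants in different blocks are treated as uncorrelated.
#'
#' @param variants `data.frame` with `chrom` and `pos` columns,
#'   position-sorted within chromosome.
#' @param max_block_size Maximum variants per block.
#' @return A list of integer index vectors (one per block, in order).
#' @export
partition_by_window <- function(variants, max_block_size = 500L) {
  stopifnot(max_block_size >= 1L)
  m <- nrow(variants)
  if (m == 0L) return(list())
  chrom <- as.character(variants$chrom)
  blocks <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    starts <- seq(1L, length(idx), by = max_block_size)
    for (s in starts)
      blocks[[length(blocks) + 1L]] <- idx[s:min(s + max_block_size - 1L, length(idx))]
  }
  blocks
}

#' Compute per-block LD correlation matrices from a reference panel
#'
#' Builds \eqn{D_b = G_b^T G_b / n_{ref}} on standardized genotypes for each
#' block of the partition, the block-diagonal LD approximation the sampler
#' works with. An optional ridge pulls each block towards the identity,
#' \eqn{D_b \leftarrow (1-\epsilon) D_b + \epsilon I}, useful for small
#' reference panels.
#'
#' @param panel A `genotype_panel` (standardized; standardized on the fly
#'   otherwise).
#' @param partition Block index list from [partition_by_window()], or `NULL`
#'   to partition here.
#' @param max_block_size Used when `partition` is `NULL`.
#' @param ridge Ridge weight \eqn{\epsilon \in [0, 1)}, default 0.
#' @return An object of class `ld_blocks`: list with `blocks` (each holding
#'   `idx` and correlation matrix `D`), `variant_ids`, `n_ref`.
#' @export
compute_ld_blocks <- function(panel, partition = NULL, max_block_size = 500L,
                              ridge = 0) {
  stopifnot(inherits(panel, "genotype_panel"), ridge >= 0, ridge < 1)
  panel <- standardize_panel(panel)
  if (is.null(partition)) partition <- partition_by_window(panel$variants, max_block_size)
  got <- sort(unlist(partition))
  if (!identical(got, seq_len(ncol(panel$X))))
    stop("partition must cover every variant exactly once")
  n_ref <- nrow(panel$X)
  blocks <- lapply(partition, function(idx) {
    D <- crossprod(panel$X[, idx, drop = FALSE]) / n_ref
    if (ridge > 0) {
      D <- (1 - ridge) * D
      diag(D) <- diag(D) + ridge
    }
    list(idx = idx, D = D)
  })
  structure(list(blocks = blocks, variant_ids = panel$variants$variant_id,
                 n_ref = n_ref),
            class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) length(b$idx), integer(1))
  cat("ld_blocks:", length(x$blocks), "blocks over", sum(sizes),
      "variants (max block", max(sizes), "), n_ref =", x$n_ref, "\n")
  invisible(x)
}

#' Assemble LD blocks directly from correlation matrices
#'
#' For precomputed references (or exact simulation LD): supply the block
#' index list and matching correlation matrices.
#'
#' @param partition List of integer index vectors.
#' @param D_list List of symmetric correlation matrices, same lengths.
#' @param variant_ids Character vector covering all indices.
#' @param n_ref Nominal reference sample count (for documentation only).
#' @return An `ld_blocks` object.
#' @export
ld_blocks_from_matrices <- function(partition, D_list, variant_ids, n_ref = NA_integer_) {
  stopifnot(length(partition) == length(D_list))
  blocks <- Map(function(idx, D) {
    stopifnot(nrow(D) == length(idx), ncol(D) == length(idx))
    list(idx = idx, D = (D + t(D)) / 2)
  }, partition, D_list)
  structure(list(blocks = blocks, variant_ids = variant_ids, n_ref = n_ref),
            class = "ld_blocks")
}
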