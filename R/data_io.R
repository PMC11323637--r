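#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics file with a header
#' and converts the reported marginal effects to the standardized scale
#' \eqn{\hat\beta = z/\sqrt{N}} assumed throughout the package (standardized
#' genotypes and phenotype, so that \eqn{\hat\beta = G^T y / N}).
#'
#' Recognized columns (case-insensitive): `SNP`/`ID` (variant id), `CHR`,
#' `POS`/`BP`, `A1` (effect allele), `A2`, `BETA`, `OR` (log-transformed on
#' read), `SE`, `Z`, `P`, `N`. Which effect columns are required depends on
#' `dialect`:
#' \describe{
#'   \item{`beta_se`}{`BETA` (or `OR`) and `SE`; \eqn{z = \beta/se}.}
#'   \item{`z`}{`Z` used directly.}
#'   \item{`pval_sign`}{`P` and `BETA`/`OR`/`Z` for the sign;
#'     \eqn{z = \mathrm{sign} \cdot |\Phi^{-1}(p/2)|}.}
#' }
#'
#' @param path Path to the summary-statistics file.
#' @param n_gwas GWAS sample size \eqn{N} (single positive integer for the
#'   whole study).
#' @param dialect One of `"beta_se"`, `"z"`, `"pval_sign"`.
#' @return A `data.frame` of class `prsbils_sumstats` with columns
#'   `variant_id`, `chrom`, `pos`, `a1`, `a2`, `beta_hat`, `n_gwas`. Rows with
#'   non-finite effects are dropped (count reported via `message()`);
#'   duplicate variant ids keep the first occurrence.
#' @examples
#' f <- tempfile()
#' writeLines(c("SNP CHR POS A1 A2 BETA SE",
#'              "rs1 1 100 A G 0.2 0.1"), f)
#' ss <- read_sumstats(f, n_gwas = 400)
#' ss$beta_hat  # (0.2/0.1)/sqrt(400) = 0.1
#' @export
read_sumstats <- function(path, n_gwas, dialect = c("beta_se", "z", "pval_sign")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(n_gwas) || length(n_gwas) != 1L || !is.finite(n_gwas) || n_gwas <= 0)
    stop("`n_gwas` must be a single positive number")
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  cols <- toupper(names(raw))
  pick <- function(...) {
    for (nm in c(...)) {
      i <- match(nm, cols)
      if (!is.na(i)) return(raw[[i]])
    }
    NULL
  }
  need <- function(x, what) {
    if (is.null(x)) stop("summary-statistics file is missing a required column: ", what)
    x
  }
  id <- as.character(need(pick("SNP", "ID", "VARIANT_ID", "RSID"), "SNP/ID"))
  a1 <- toupper(as.character(need(pick("A1", "ALT", "EFFECT_ALLELE"), "A1")))
  a2 <- toupper(as.character(need(pick("A2", "REF", "OTHER_ALLELE"), "A2")))
  chrom <- pick("CHR", "CHROM")
  pos <- pick("POS", "BP")
  chrom <- if (is.null(chrom)) rep(NA_character_, length(id)) else sub("^chr", "", as.character(chrom))
  pos <- if (is.null(pos)) rep(NA_integer_, length(id)) else as.integer(pos)

  beta <- pick("BETA")
  if (is.null(beta)) {
    or <- pick("OR")
    if (!is.null(or)) beta <- log(as.numeric(or))
  }
  z <- switch(dialect,
    beta_se = {
      se <- need(pick("SE"), "SE")
      as.numeric(need(beta, "BETA/OR")) / as.numeric(se)
    },
    z = as.numeric(need(pick("Z"), "Z")),
    pval_sign = {
      p <- as.numeric(need(pick("P", "PVAL", "P_VALUE"), "P"))
      sgn <- pick("Z")
      if (is.null(sgn)) sgn <- beta
      sgn <- sign(as.numeric(need(sgn, "BETA/OR/Z (for the sign)")))
      sgn * abs(stats::qnorm(p / 2))
    })
  beta_hat <- z / sqrt(n_gwas)

  out <- data.frame(variant_id = id, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
                    beta_hat = beta_hat, n_gwas = as.integer(n_gwas),
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$beta_hat)
  if (any(bad)) {
    message(sum(bad), " variant(s) dropped for non-finite effects")
    out <- out[!bad, , drop = FALSE]
  }
  dup <- duplicated(out$variant_id)
  if (any(dup)) {
    message(sum(dup), " duplicate variant id(s) dropped (first kept)")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("prsbils_sumstats", "data.frame")
  out
}

#' Write summary statistics
#'
#' Writes a `prsbils_sumstats` table as whitespace-delimited text with a
#' `Z` column (`z = beta_hat * sqrt(N)`), so that reading it back with
#' `read_sumstats(dialect = "z")` is a fixed point.
#'
#' @param ss A `prsbils_sumstats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$variant_id, CHR = ss$chrom, POS = ss$pos,
                    A1 = ss$a1, A2 = ss$a2,
                    Z = signif(ss$beta_hat * sqrt(ss$n_gwas), 10),
                    N = ss$n_gwas)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genotype panel
#'
#' A genotype panel bundles a dosage (or standardized) matrix with its
#' variant table and sample ids. Dosages are 0/1/2 counts of `a1`.
#'
#' @param X Numeric matrix, samples x variants.
#' @param variants `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `a1`, `a2` (one row per column of `X`).
#' @param sample_id Character vector of sample ids (defaults to `S1..Sn`).
#' @param standardized Logical; `TRUE` when columns are already mean 0,
#'   variance 1.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(X, variants, sample_id = NULL, standardized = FALSE) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == nrow(variants))
  req <- c("variant_id", "chrom", "pos", "a1", "a2")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(X)))
  variants$chrom <- sub("^chr", "", as.character(variants$chrom))
  colnames(X) <- variants$variant_id
  structure(list(X = X, variants = variants, sample_id = as.character(sample_id),
                 standardized = isTRUE(standardized)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$X), "samples x", ncol(x$X), "variants;",
      if (x$standardized) "standardized" else "dosage scale", "\n")
  invisible(x)
}

#' Standardize a genotype panel
#'
#' Mean-imputes missing dosages per variant, then centres and scales each
#' variant to mean 0, variance 1. Monomorphic variants (zero variance) are an
#' error and should be filtered upstream.
#'
#' @param panel A `genotype_panel`.
#' @return The panel with standardized genotype matrix.
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$standardized) return(panel)
  X <- panel$X
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- panel$variants$variant_id[which(sds == 0 | !is.finite(sds))]
    stop("monomorphic variant(s) with zero variance: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  # population-style scaling (divide by sd with denominator n) keeps
  # crossprod(X)/n an exact correlation matrix
  X <- scale(X)
  n <- nrow(X)
  X <- X * sqrt(n / (n - 1))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  panel$X <- X
  panel$standardized <- TRUE
  panel
}

#' Match summary statistics to a genotype panel by alleles
#'
#' Restricts summary statistics to the variants present in the panel,
#' reconciling alleles: direct matches are kept as is, swapped matches
#' (`a1`/`a2` exchanged) have the effect sign flipped, strand-ambiguous
#' palindromic pairs (A/T, C/G) are dropped, and anything else is dropped.
#' Output rows follow the panel's variant order.
#'
#' @param ss A `prsbils_sumstats` object.
#' @param panel A `genotype_panel`.
#' @return Filtered/reordered `prsbils_sumstats`; attributes `n_flipped` and
#'   `n_dropped` record what matching did.
#' @export
match_alleles <- function(ss, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  pv <- panel$variants
  i <- match(pv$variant_id, ss$variant_id)
  keep <- !is.na(i)
  out <- ss[i[keep], , drop = FALSE]
  pa1 <- toupper(pv$a1[keep]); pa2 <- toupper(pv$a2[keep])
  ambiguous <- function(x, y) (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "C" & y == "G") | (x == "G" & y == "C")
  direct <- out$a1 == pa1 & out$a2 == pa2
  swapped <- out$a1 == pa2 & out$a2 == pa1 & !direct
  ok <- (direct | swapped) & !ambiguous(out$a1, out$a2)
  out$beta_hat[swapped] <- -out$beta_hat[swapped]
  out$a1[swapped] <- pa1[swapped]
  out$a2[swapped] <- pa2[swapped]
  n_dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no variants shared between summary statistics and panel after allele ",
         "matching; check the genome build and variant id scheme")
  rownames(out) <- NULL
  class(out) <- c("prsbils_sumstats", "data.frame")
  attr(out, "n_flipped") <- sum(swapped & ok)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write / read posterior effect-size weight files
#'
#' Plain TSV with columns `variant_id`, `a1`, `effect` (plus optional `group`
#' when per-annotation-copy effects are written), usable as a scoring weight
#' file. Values round-trip at 6 significant digits.
#'
#' @param effects `data.frame` with columns `variant_id`, `a1`, `effect` and
#'   optionally `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(effects, path) {
  req <- c("variant_id", "a1", "effect")
  miss <- setdiff(req, names(effects))
  if (length(miss)) stop("effects table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(effects$effect))) stop("non-finite effect values")
  out <- effects[, intersect(c("variant_id", "a1", "group", "effect"), names(effects))]
  out$effect <- signif(out$effect, 8)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a genotype panel as plain text
#'
#' Two files: `<prefix>.vars.tsv` (variant table) and `<prefix>.geno.tsv`
#' (sample id + one dosage column per variant). Intended for small panels and
#' reproducible fixtures.
#'
#' @param panel A `genotype_panel`.
#' @param prefix Path prefix.
#' @return `prefix` invisibly (`write_panel`); a `genotype_panel`
#'   (`read_panel`).
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  utils::write.table(panel$variants, paste0(prefix, ".vars.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- data.frame(sample_id = panel$sample_id,
                  signif(panel$X, 8), check.names = FALSE)
  utils::write.table(g, paste0(prefix, ".geno.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  variants <- utils::read.table(paste0(prefix, ".vars.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE,
                                colClasses = c(chrom = "character"))
  g <- utils::read.table(paste0(prefix, ".geno.tsv"), header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  X <- as.matrix(g[, -1, drop = FALSE])
  genotype_panel(X, variants, sample_id = g[[1]])
}

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' Minimal reader for PLINK 1 binary genotype filesets (SNP-major .bed).
#' Dosages count the .bim A1 allele; missing calls become `NA` (mean-imputed
#' later by [standardize_panel()]).
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` files.
#' @return A `genotype_panel` on the dosage scale.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(108L, 27L, 1L)))
    stop("not a SNP-major PLINK .bed file: ", prefix, ".bed")
  bytes_per_var <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_var * m)
  if (length(raw) < bytes_per_var * m) stop("truncated .bed file")
  bits <- matrix(as.integer(rawToBits(raw)), nrow = 8 * bytes_per_var)
  b0 <- bits[seq(1, 2 * n, by = 2), , drop = FALSE]
  b1 <- bits[seq(2, 2 * n, by = 2), , drop = FALSE]
  # PLINK 2-bit codes: 00 hom A1, 10 het, 11 hom A2, 01 missing
  X <- matrix(NA_real_, n, m)
  X[b0 == 0 & b1 == 0] <- 2
  X[b0 == 0 & b1 == 1] <- 1
  X[b0 == 1 & b1 == 1] <- 0
  vars <- data.frame(variant_id = bim$variant_id, chrom = bim$chrom,
                     pos = bim$pos, a1 = bim$a1, a2 = bim$a2,
                     stringsAsFactors = FALSE)
  genotype_panel(X, vars, sample_id = paste(fam[[1]], fam[[2]], sep = "_"))
}
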