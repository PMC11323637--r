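#' Variant-to-annotation-group assignment map
#'
#' An annotation map assigns every variant to one or more annotation groups
#' (gene categories, pathways, ...). Variants without any annotation go to a
#' reserved catch-all group `"_unannotated"`. Because groups may overlap, the
#' map also carries the *copy expansion*: one (variant, group) copy per
#' membership, \eqn{M' = \sum_k \sum_j I(k \in A_j)} copies in total, in
#' variant-major order (all copies of variant 1, then variant 2, ...). The
#' Gibbs sampler assigns a separate local shrinkage scale, and draws a
#' separate effect, for each copy.
#'
#' @param variant_ids Character vector of M variant ids, in panel order.
#' @param membership List of length M; each element a character vector of
#'   group labels (empty elements get the catch-all).
#' @return An object of class `annotation_map` with elements `groups` (K
#'   labels, sorted, catch-all last), `membership` (list of group index
#'   vectors), `copy_variant`, `copy_group` (parallel integer vectors of
#'   length M'), `sizes` (M_k), `M`, `K`, `M_prime`.
#' @export
annotation_map <- function(variant_ids, membership) {
  stopifnot(length(variant_ids) == length(membership))
  membership <- lapply(membership, function(g) unique(as.character(g)))
  none <- lengths(membership) == 0L
  membership[none] <- list("_unannotated")
  labels <- sort(unique(setdiff(unlist(membership), "_unannotated")))
  if (any(vapply(membership, function(g) "_unannotated" %in% g, logical(1))))
    labels <- c(labels, "_unannotated")
  midx <- unname(lapply(membership, function(g) sort(match(g, labels))))
  copy_variant <- rep(seq_along(variant_ids), lengths(midx))
  copy_group <- unlist(midx, use.names = FALSE)
  sizes <- tabulate(copy_group, nbins = length(labels))
  structure(list(groups = labels, variant_ids = as.character(variant_ids),
                 membership = midx, copy_variant = copy_variant,
                 copy_group = copy_group, sizes = sizes,
                 M = length(variant_ids), K = length(labels),
                 M_prime = length(copy_variant)),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", x$M, "variants,", x$K, "groups, M' =", x$M_prime,
      if (x$M_prime > x$M) "(overlapping)" else "(non-overlapping)", "\n")
  invisible(x)
}

#' Load annotation assignments from a two-column TSV
#'
#' The file maps `variant_id` to `group_label`, one row per membership
#' (repeated variant ids express membership in several groups). Variants in
#' `variants` that the file does not cover are placed in the reserved
#' `"_unannotated"` group; file rows for variants outside `variants` are
#' ignored.
#'
#' @param path Path to the TSV (header optional; detected).
#' @param variants Ordered character vector of variant ids to annotate.
#' @return An [annotation_map()].
#' @export
load_annotations <- function(path, variants) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("variant|snp|id", strsplit(first, "\t| +")[[1]][1],
                      ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("variant_id", "group_label"))
  tab <- tab[tab$variant_id %in% variants, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("annotation file shares no variants with the supplied variant list")
  membership <- split(tab$group_label, factor(tab$variant_id, levels = variants))
  annotation_map(variants, membership)
}

#' Write an annotation map as a two-column TSV
#'
#' @param annot An `annotation_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path) {
  tab <- data.frame(variant_id = annot$variant_ids[annot$copy_variant],
                    group_label = annot$groups[annot$copy_group])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersection-over-union between two annotation groups
#'
#' \eqn{|members(k_1) \cap members(k_2)| / |members(k_1) \cup members(k_2)|},
#' computed on variant sets (not copies). An empty union returns 0 by
#' convention.
#'
#' @param annot An `annotation_map`.
#' @param k1,k2 Group labels or indices.
#' @return A fraction in \[0, 1\].
#' @export
group_iou <- function(annot, k1, k2) {
  ik <- function(k) {
    if (is.character(k)) k <- match(k, annot$groups)
    if (is.na(k) || k < 1 || k > annot$K) stop("no such annotation group")
    k
  }
  m1 <- annot$copy_variant[annot$copy_group == ik(k1)]
  m2 <- annot$copy_variant[annot$copy_group == ik(k2)]
  u <- length(union(m1, m2))
  if (u == 0L) {
    message("both groups empty; IOU 0 by convention")
    return(0)
  }
  length(intersect(m1, m2)) / u
}

#' Collapse an annotation map to a single group
#'
#' Used by the single-group (PRS-CS-auto style) sampler mode: every variant
#' gets exactly one copy in one group, so M' = M.
#'
#' @param annot An `annotation_map`.
#' @return An `annotation_map` with K = 1.
#' @export
collapse_annotations <- function(annot) {
  annotation_map(annot$variant_ids,
                 rep(list("all"), annot$M))
}
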