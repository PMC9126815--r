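#' Reads-per-million normalization
#'
#' `rpm[g, s] = counts[g, s] / sum(counts[, s]) * 1e6`; every column of the
#' result sums to one million.
#'
#' @param counts Non-negative integer matrix genes x samples.
#' @return Numeric RPM matrix with the same dimnames.
#' @export
rpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop_socphys("normalization_error",
                 "zero-total sample(s): cannot normalize")
  sweep(counts, 2, totals, "/") * 1e6
}

#' Expression filter on RPM
#'
#' Keeps genes whose RPM exceeds `min_rpm` (strictly greater: a gene at
#' exactly the threshold is removed) in all samples, any sample, or on the
#' per-gene mean, according to `rule`.
#'
#' @param rpm RPM matrix (genes x samples).
#' @param min_rpm Threshold.
#' @param rule `"all"` (default, strictest), `"any"`, or `"mean"`.
#' @return The filtered RPM matrix (possibly zero rows, with a warning).
#' @export
filter_expressed <- function(rpm, min_rpm = 10,
                             rule = c("all", "any", "mean")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
                 all  = apply(rpm > min_rpm, 1, all),
                 any  = apply(rpm > min_rpm, 1, any),
                 mean = rowMeans(rpm) > min_rpm)
  if (!any(keep)) warning("expression filter removed every gene")
  rpm[keep, , drop = FALSE]
}

#' Worst-case pairwise fold-change selection
#'
#' For each gene, computes the fold change of every cross-group replicate
#' pair `(i in A, j in B)`, `r_ij = (b_j + eps)/(a_i + eps)`. A gene is
#' direction-concordant when all pairwise ratios fall on the same side of
#' 1; its worst-case fold change is the minimum over pairs of
#' `max(r, 1/r)` — the fold change of the least favorable replicate pair.
#' A gene is selected when it is concordant and its worst-case fold change
#' reaches the threshold. This is a conservative selection rule: a single
#' discordant or weak replicate pair vetoes the gene.
#'
#' @param rpm RPM matrix (genes x samples), pre-filtered for expression.
#' @param group_a,group_b Column names or indices of the two groups (at
#'   least 2 samples each); fold changes are oriented B over A, so
#'   direction `"up"` means higher in `group_b`.
#' @param threshold Selection threshold on the fold-change scale (>= 1).
#' @param pseudocount Added to both members of every ratio; the default 0
#'   assumes the expression filter has made values safely positive.
#' @return An object of class `wcfc_result`: data frame `gene`, `wcfc`,
#'   `direction` (`up`/`down`/`discordant`), `selected`, `pair_a`,
#'   `pair_b` (the replicate pair attaining the worst case).
#' @export
worst_case_fc <- function(rpm, group_a, group_b, threshold = 1.5,
                          pseudocount = 0) {
  a <- rpm[, group_a, drop = FALSE]
  b <- rpm[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop_socphys("pairing_error",
                 "worst-case fold change needs >= 2 replicates per group")
  if (pseudocount == 0 && (any(a == 0) || any(b == 0)))
    stop_socphys("pairing_error",
                 "zero values with pseudocount 0; filter or set pseudocount")
  genes <- rownames(rpm) %||% as.character(seq_len(nrow(rpm)))
  n <- nrow(rpm)
  wcfc <- numeric(n); dir <- character(n)
  pa <- character(n); pb <- character(n)
  a_ids <- colnames(a) %||% paste0("a", seq_len(ncol(a)))
  b_ids <- colnames(b) %||% paste0("b", seq_len(ncol(b)))
  for (g in seq_len(n)) {
    r <- outer(a[g, ] + pseudocount, b[g, ] + pseudocount,
               function(x, y) y / x)  # rows: A replicate, cols: B replicate
    mag <- pmax(r, 1 / r)
    k <- which.min(mag)
    wcfc[g] <- mag[k]
    dir[g] <- if (all(r > 1)) "up" else if (all(r < 1)) "down" else
      "discordant"
    ij <- arrayInd(k, dim(r))
    pa[g] <- a_ids[ij[1]]; pb[g] <- b_ids[ij[2]]
  }
  res <- data.frame(gene = genes, wcfc = wcfc, direction = dir,
                    selected = dir != "discordant" & wcfc >= threshold,
                    pair_a = pa, pair_b = pb)
  rownames(res) <- NULL
  class(res) <- c("wcfc_result", "data.frame")
  attr(res, "threshold") <- threshold
  res
}

#' Intersect selections across populations
#'
#' Set operations over the `selected` gene sets of several
#' [worst_case_fc()] results computed on a common gene universe, with
#' direction agreement annotated on the shared set.
#'
#' @param results Named list of `wcfc_result` objects (>= 2).
#' @return A list with `shared` (data frame: gene, per-result direction,
#'   `direction_agrees`), `unique` (list of genes selected only in that
#'   result), and `selected` (the per-result selected gene sets).
#' @export
intersect_de <- function(results) {
  stopifnot(length(results) >= 2)
  universes <- lapply(results, function(r) sort(r$gene))
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]])))
    stop_socphys("universe_error",
                 "results must share a common gene universe")
  sel <- lapply(results, function(r) r$gene[r$selected])
  shared_genes <- Reduce(intersect, sel)
  dirs <- vapply(results, function(r) {
    r$direction[match(shared_genes, r$gene)]
  }, character(length(shared_genes)))
  if (length(shared_genes) == 1) dirs <- matrix(dirs, nrow = 1)
  shared <- data.frame(gene = shared_genes)
  for (nm in names(results)) {
    shared[[paste0("direction_", nm)]] <-
      if (length(shared_genes)) dirs[, which(names(results) == nm)] else
        character(0)
  }
  shared$direction_agrees <- if (length(shared_genes))
    apply(dirs, 1, function(d) length(unique(d)) == 1) else logical(0)
  uniq <- lapply(seq_along(sel), function(k) {
    setdiff(sel[[k]], Reduce(union, sel[-k]))
  })
  names(uniq) <- names(results)
  list(shared = shared, unique = uniq, selected = sel)
}

#' PCA on transformed expression values
#'
#' Transforms the (selected-gene) RPM submatrix (default `log2(x + 1)`),
#' centers genes, and computes principal components of the samples by
#' singular value decomposition. An approximation to variance-stabilized
#' PCA: the log transform plays the role of the regularized log of
#' model-based pipelines.
#'
#' @param rpm RPM matrix genes x samples.
#' @param genes Optional gene subset (e.g. the union of selected genes).
#' @param transform `"log2"` (log2(x+1), default) or `"none"`.
#' @return A list with `scores` (samples x PCs), `var_explained`
#'   (fractions summing to 1), `sdev`.
#' @export
pca_transform <- function(rpm, genes = NULL, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  x <- if (is.null(genes)) rpm else rpm[genes, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop_socphys("degenerate_pca_error", "need >= 2 genes and >= 2 samples")
  if (transform == "log2") x <- log2(x + 1)
  xs <- t(scale(t(x), center = TRUE, scale = FALSE))  # center each gene
  if (all(abs(xs) < 1e-12))
    stop_socphys("degenerate_pca_error", "constant expression matrix")
  pr <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  list(scores = pr$x,
       var_explained = pr$sdev^2 / sum(pr$sdev^2),
       sdev = pr$sdev)
}

#' Fisher exact enrichment of a gene set
#'
#' Hypergeometric (Fisher exact) test of the overlap between a selected
#' gene set and an annotation set within a common universe; one-sided
#' (enrichment) by default.
#'
#' @param selected,annotation Character vectors, subsets of `universe`.
#' @param universe Character vector of all tested genes.
#' @param alternative Test sidedness, default `"greater"`.
#' @return An object of class `enrichment_result`: list with `table`
#'   (2 x 2), `odds_ratio` (conditional MLE from the exact test),
#'   `p_value`, `alternative`, `overlap`.
#' @export
fisher_enrichment <- function(selected, annotation, universe,
                              alternative = "greater") {
  if (!length(universe))
    stop_socphys("parameter_error", "empty universe")
  selected <- intersect(unique(selected), universe)
  annotation <- intersect(unique(annotation), universe)
  a <- length(intersect(selected, annotation))
  b <- length(setdiff(selected, annotation))
  cc <- length(setdiff(annotation, selected))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("selected", "not_selected"),
                                c("in_set", "not_in_set")))
  ft <- fisher.test(tab, alternative = alternative)
  structure(
    list(table = tab, odds_ratio = unname(ft$estimate),
         p_value = ft$p.value, alternative = alternative, overlap = a),
    class = "enrichment_result"
  )
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt = dCt -
#' mean(dCt[control])`; relative expression `2^(-ddCt)`.
#'
#' @param ct_target,ct_reference Ct values per sample (finite).
#' @param group Group label per sample.
#' @param control_group The calibrator group (non-empty in `group`).
#' @return Data frame `group`, `delta_ct`, `delta_delta_ct`, `rel_expr`.
#' @export
delta_delta_ct <- function(ct_target, ct_reference, group, control_group) {
  if (length(ct_target) != length(ct_reference) ||
      length(ct_target) != length(group))
    stop_socphys("parameter_error", "inputs must have equal length")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop_socphys("parameter_error", "Ct values must be finite")
  if (!any(group == control_group))
    stop_socphys("parameter_error", "control group absent")
  dct <- ct_target - ct_reference
  ddct <- dct - mean(dct[group == control_group])
  data.frame(group = group, delta_ct = dct, delta_delta_ct = ddct,
             rel_expr = 2^(-ddct))
}
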