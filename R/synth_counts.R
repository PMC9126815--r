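#' Design for a synthetic FACS-sorted count table
#'
#' Describes a negative-binomial gene x sample simulation over a factorial
#' design of cell populations (e.g. D1-positive / D1-negative, each
#' infected or not) under two conditions (scrambled vs knockdown). A
#' fraction of genes is planted as differentially expressed in the `sh`
#' condition of the designated populations.
#'
#' @param n_genes Number of genes.
#' @param populations Population labels.
#' @param infections Infection-status labels.
#' @param conditions Condition labels; the second is the perturbed one.
#' @param replicates_per_cell Replicates per design cell (>= 2: the
#'   worst-case fold-change rule needs pairs).
#' @param de_fraction Fraction of genes planted DE.
#' @param log2fc_range Range of |log2 fold change| for planted genes.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   `0` makes counts deterministic (`round(mu)`).
#' @param baseline_mean_range Range of baseline expression (RPM scale);
#'   drawn log-uniformly.
#' @param libsize_range Library-size range (reads).
#' @param de_infections Infection level(s) whose populations carry the
#'   planted effect.
#' @param seed Seed used by [simulate_counts()].
#' @return An object of class `count_design`.
#' @export
count_design <- function(n_genes = 2000,
                         populations = c("D1pos", "D1neg"),
                         infections = c("infected", "noninfected"),
                         conditions = c("scr", "sh"),
                         replicates_per_cell = 3,
                         de_fraction = 0.05,
                         log2fc_range = c(1, 2),
                         dispersion = 0.05,
                         baseline_mean_range = c(20, 500),
                         libsize_range = c(0.8e6, 1.2e6),
                         de_infections = "infected",
                         seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1)
    stop_socphys("parameter_error", "de_fraction must be in [0, 1]")
  if (replicates_per_cell < 2)
    stop_socphys("parameter_error",
                 "replicates_per_cell must be >= 2 (pairwise rule needs pairs)")
  if (dispersion < 0)
    stop_socphys("parameter_error", "dispersion must be >= 0")
  structure(as.list(environment()), class = "count_design")
}

#' Simulate a negative-binomial count table with planted fold changes
#'
#' Draws per-gene baseline means (log-uniform, RPM scale), per-sample
#' library sizes, and NB counts with the design's dispersion. Planted genes
#' carry their log2 fold change in the perturbed condition of the
#' designated (by default infected) populations, with random sign.
#'
#' @param design A [count_design()].
#' @return A list with `counts` (integer matrix genes x samples), `samples`
#'   (data frame `sample_id`, `population`, `infection`, `condition`,
#'   `replicate`), and `truth` (data frame `gene`, `is_de`, `log2fc`).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "count_design"))
  set.seed(design$seed)
  samples <- expand.grid(
    replicate = seq_len(design$replicates_per_cell),
    condition = design$conditions,
    infection = design$infections,
    population = design$populations,
    stringsAsFactors = FALSE
  )[, c("population", "infection", "condition", "replicate")]
  samples$sample_id <- with(samples, paste(population, infection, condition,
                                           paste0("r", replicate), sep = "_"))
  n_s <- nrow(samples)
  genes <- sprintf("gene%05d", seq_len(design$n_genes))

  n_de <- round(design$de_fraction * design$n_genes)
  if (design$de_fraction > 0 && n_de < 1)
    warning("de_fraction * n_genes < 1: zero planted genes")
  is_de <- rep(FALSE, design$n_genes)
  if (n_de >= 1) is_de[sample.int(design$n_genes, n_de)] <- TRUE
  lfc <- numeric(design$n_genes)
  lfc[is_de] <- sample(c(-1, 1), n_de, replace = TRUE) *
    runif(n_de, design$log2fc_range[1], design$log2fc_range[2])

  base_rpm <- exp(runif(design$n_genes,
                        log(design$baseline_mean_range[1]),
                        log(design$baseline_mean_range[2])))
  libsize <- runif(n_s, design$libsize_range[1], design$libsize_range[2])

  perturbed <- samples$condition == design$conditions[2] &
    samples$infection %in% design$de_infections
  counts <- matrix(0L, design$n_genes, n_s,
                   dimnames = list(genes, samples$sample_id))
  for (j in seq_len(n_s)) {
    rpm_mean <- base_rpm
    if (perturbed[j]) rpm_mean <- base_rpm * 2^lfc
    mu <- rpm_mean * libsize[j] / 1e6
    counts[, j] <- if (design$dispersion == 0) {
      as.integer(round(mu))
    } else {
      as.integer(rnbinom(design$n_genes, mu = mu,
                         size = 1 / design$dispersion))
    }
  }
  list(
    counts = counts,
    samples = samples[, c("sample_id", "population", "infection",
                          "condition", "replicate")],
    truth = data.frame(gene = genes, is_de = is_de, log2fc = lfc)
  )
}
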