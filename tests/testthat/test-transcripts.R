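test_that("RPM normalization: units, conservation, oracle", {
  counts <- matrix(c(10, 999990, 5, 999995), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  rpm <- rpm_normalize(counts)
  expect_equal(rpm["g1", "s1"], 10)
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6))
  set.seed(3)
  big <- matrix(rpois(200, 50), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  rpm2 <- rpm_normalize(big)
  for (j in 1:10) for (i in c(1, 7, 20)) {
    expect_equal(rpm2[i, j], big[i, j] / sum(big[, j]) * 1e6)
  }
  zero <- big; zero[, 3] <- 0
  expect_error(rpm_normalize(zero), class = "normalization_error")
})

test_that("expression filter is strict and rule semantics differ", {
  rpm <- rbind(at10 = rep(10, 4), at11 = rep(11, 4),
               mixed = c(5, 15, 15, 15))
  expect_false("at10" %in% rownames(filter_expressed(rpm)))
  expect_true("at11" %in% rownames(filter_expressed(rpm)))
  expect_false("mixed" %in% rownames(filter_expressed(rpm, rule = "all")))
  expect_true("mixed" %in% rownames(filter_expressed(rpm, rule = "any")))
  expect_true("mixed" %in% rownames(filter_expressed(rpm, rule = "mean")))
  expect_warning(filter_expressed(rbind(low = rep(1, 3))),
                 "removed every gene")
})

test_that("worst-case fold change matches pairwise enumeration", {
  rpm <- rbind(sel = c(10, 12, 20, 30),
               rej = c(10, 12, 14, 30),
               flat = c(25, 25, 25, 25))
  colnames(rpm) <- c("a1", "a2", "b1", "b2")
  w <- worst_case_fc(rpm, c("a1", "a2"), c("b1", "b2"))
  # printed toy example: ratios {2, 3, 1.667, 2.5} -> wcfc 20/12
  expect_equal(w$wcfc[w$gene == "sel"], 20 / 12)
  expect_true(w$selected[w$gene == "sel"])
  expect_equal(w$direction[w$gene == "sel"], "up")
  expect_equal(w$pair_a[w$gene == "sel"], "a2")
  expect_equal(w$pair_b[w$gene == "sel"], "b1")
  # weakest pair 14/12 < 1.5 -> rejected
  expect_equal(w$wcfc[w$gene == "rej"], 14 / 12)
  expect_false(w$selected[w$gene == "rej"])
  # identical groups: wcfc 1, discordant (ratios sit on 1), unselected
  expect_equal(w$wcfc[w$gene == "flat"], 1)
  expect_false(w$selected[w$gene == "flat"])
  # random tables vs double-loop oracle
  set.seed(8)
  for (rep in 1:20) {
    a <- runif(3, 5, 50); b <- runif(4, 5, 50)
    m <- matrix(c(a, b), 1, dimnames = list("g", NULL))
    colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:4))
    w2 <- worst_case_fc(m, paste0("a", 1:3), paste0("b", 1:4))
    o <- oracle_wcfc(a, b)
    expect_equal(w2$wcfc, o$wcfc)
    expect_equal(w2$direction, o$direction)
  }
})

test_that("worst-case fold change properties", {
  set.seed(5)
  rpm <- matrix(runif(60, 11, 200), 10, 6,
                dimnames = list(paste0("g", 1:10),
                                c(paste0("a", 1:3), paste0("b", 1:3))))
  A <- paste0("a", 1:3); B <- paste0("b", 1:3)
  w_ab <- worst_case_fc(rpm, A, B)
  w_ba <- worst_case_fc(rpm, B, A)
  # symmetric under group swap, direction flipped
  expect_equal(w_ab$wcfc, w_ba$wcfc)
  flip <- c(up = "down", down = "up", discordant = "discordant")
  expect_equal(unname(flip[w_ab$direction]), w_ba$direction)
  # wcfc >= 1 always
  expect_true(all(w_ab$wcfc >= 1))
  # adding a replicate can only shrink wcfc (min over a superset)
  w_sub <- worst_case_fc(rpm[, c(A[1:2], B)], A[1:2], B)
  expect_true(all(w_ab$wcfc <= w_sub$wcfc + 1e-12))
  # selection monotone in threshold
  w_lo <- worst_case_fc(rpm, A, B, threshold = 1.2)
  expect_true(all(w_ab$selected <= w_lo$selected))
  # guards
  expect_error(worst_case_fc(rpm, A[1], B), class = "pairing_error")
  rpm0 <- rpm; rpm0[1, 1] <- 0
  expect_error(worst_case_fc(rpm0, A, B), class = "pairing_error")
})

test_that("intersection of selections across populations", {
  r1 <- data.frame(gene = paste0("g", 1:6),
                   wcfc = c(2, 2, 2, 1.1, 1.1, 3),
                   direction = c("up", "up", "down", "up", "up", "up"),
                   selected = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  r2 <- r1; r2$selected <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  r2$direction <- c("up", "up", "up", "up", "up", "up")
  out <- intersect_de(list(pop1 = r1, pop2 = r2))
  expect_setequal(out$shared$gene, c("g1", "g3"))
  expect_equal(out$shared$direction_agrees[out$shared$gene == "g1"], TRUE)
  expect_equal(out$shared$direction_agrees[out$shared$gene == "g3"], FALSE)
  expect_setequal(out$unique$pop1, c("g2", "g6"))
  expect_setequal(out$unique$pop2, "g4")
  # identical selections share everything; disjoint share nothing
  expect_equal(nrow(intersect_de(list(a = r1, b = r1))$shared), 4)
  r3 <- r1; r3$selected <- !r1$selected
  expect_equal(nrow(intersect_de(list(a = r1, b = r3))$shared), 0)
  r4 <- r1; r4$gene <- paste0("h", 1:6)
  expect_error(intersect_de(list(a = r1, b = r4)),
               class = "universe_error")
})

test_that("PCA separates duplicated groups and conserves variance", {
  base <- c(100, 20, 50, 5, 80, 10)
  rpm <- cbind(s1 = base, s2 = base,
               s3 = base * c(4, 0.25, 1, 1, 2, 0.5),
               s4 = base * c(4, 0.25, 1, 1, 2, 0.5))
  rownames(rpm) <- paste0("g", 1:6)
  p <- pca_transform(rpm)
  expect_equal(sum(p$var_explained), 1)
  expect_gt(p$var_explained[1], 0.999)  # noiseless two-profile design
  expect_lt(abs(p$scores["s1", 1] - p$scores["s2", 1]), 1e-9)
  expect_gt(abs(p$scores["s1", 1] - p$scores["s3", 1]), 1)
  expect_error(pca_transform(matrix(5, 3, 3)),
               class = "degenerate_pca_error")
})

test_that("planted condition effect separates samples along PC1", {
  d <- count_design(n_genes = 600, populations = "D1pos",
                    infections = "infected", replicates_per_cell = 3,
                    de_fraction = 0.2, log2fc_range = c(1.5, 2.5),
                    dispersion = 0.01, seed = 17)
  sim <- simulate_counts(d)
  rpm <- filter_expressed(rpm_normalize(sim$counts))
  w <- worst_case_fc(rpm, grep("_scr_", colnames(rpm), value = TRUE),
                     grep("_sh_", colnames(rpm), value = TRUE))
  p <- pca_transform(rpm, genes = w$gene[w$selected])
  pc1 <- p$scores[, 1]
  grp <- grepl("_sh_", rownames(p$scores))
  # the two conditions occupy disjoint PC1 ranges
  expect_true(max(pc1[grp]) < min(pc1[!grp]) ||
                min(pc1[grp]) > max(pc1[!grp]))
})

test_that("Fisher enrichment matches exhaustive hypergeometric tails", {
  universe <- paste0("g", 1:40)
  res <- fisher_enrichment(universe[1:20], universe[c(1:10, 21:30)],
                           universe)
  # table [[10,10],[10,10]]: OR 1, one-sided p = P(overlap >= 10)
  expect_equal(res$table, matrix(c(10, 10, 10, 10), 2, 2,
                                 dimnames = dimnames(res$table)))
  expect_equal(res$p_value, oracle_fisher_greater(10, 10, 10, 10))
  # selected subset of annotation = universe: p = 1
  res2 <- fisher_enrichment(universe[1:5], universe, universe)
  expect_equal(res2$p_value, 1)
  # random small tables against the enumeration oracle
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(10:30, 1)
    uni <- paste0("x", seq_len(n))
    sel <- sample(uni, sample(2:(n - 2), 1))
    ann <- sample(uni, sample(2:(n - 2), 1))
    r <- fisher_enrichment(sel, ann, uni)
    o <- oracle_fisher_greater(r$table[1, 1], r$table[1, 2],
                               r$table[2, 1], r$table[2, 2])
    expect_equal(r$p_value, o, tolerance = 1e-12)
  }
  expect_error(fisher_enrichment("a", "a", character()),
               class = "parameter_error")
})

test_that("delta-delta-Ct relative quantification", {
  # control sample at the control mean: expression 1
  r <- delta_delta_ct(c(20, 21, 18), c(15, 16, 14),
                      group = c("ctrl", "ctrl", "trt"), "ctrl")
  expect_equal(r$rel_expr[1:2], c(1, 1))
  expect_equal(r$delta_ct, c(5, 5, 4))
  expect_equal(r$rel_expr[3], 2)  # ddCt = -1 -> doubling
  # random tables vs spreadsheet-style oracle
  set.seed(4)
  ct_t <- runif(12, 18, 30); ct_r <- runif(12, 14, 18)
  grp <- rep(c("ctrl", "trt"), each = 6)
  r2 <- delta_delta_ct(ct_t, ct_r, grp, "ctrl")
  expect_equal(r2$rel_expr, oracle_ddct(ct_t, ct_r, grp, "ctrl"))
  expect_error(delta_delta_ct(c(20, NA), c(15, 15), c("a", "b"), "a"),
               class = "parameter_error")
  expect_error(delta_delta_ct(20, 15, "a", "zzz"),
               class = "parameter_error")
})
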