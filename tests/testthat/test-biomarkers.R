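test_that("extend_bem applies the deletion/amplification/mutation rule", {
  mut <- matrix(c(0, 1, 0, 0, 0, 1), 2, 3,
                dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  cn <- matrix(c(8, 2, 7, 0, 2, 2), 2, 3, dimnames = dimnames(mut))
  bem <- extend_bem(mut, cn)
  expect_equal(unname(bem["g1", ]), c(1L, 0L, 0L))  # 8 copies; 7 copies; 2
  expect_equal(unname(bem["g2", ]), c(1L, 1L, 1L))  # mutation; deletion; mut
  prov <- attr(bem, "provenance")
  expect_equal(unname(prov["g1", "c1"]), "amplification")
  expect_equal(unname(prov["g2", "c2"]), "deletion")
  expect_equal(unname(prov["g2", "c1"]), "mutation")
  expect_error(extend_bem(mut, cn - 1), "non-negative")
  expect_error(extend_bem(mut, cn + 0.5), "integers")
})

test_that("monotherapy_association reproduces the exact rank-sum p", {
  bem <- matrix(c(1, 1, 1, 0, 0, 0), 1, 6,
                dimnames = list("g1", sprintf("c%d", 1:6)))
  mono <- data.frame(drug_id = "D01", cell_id = sprintf("c%d", 1:6),
                     sensitivity = c(1, 2, 3, 7, 8, 9) / 10)
  res <- monotherapy_association(mono, bem, min_group = 3)
  expect_equal(res$p, 0.1)
  expect_equal(res$direction, "resistance")
  expect_equal(res$n_mut, 3)
  # swapping group labels flips direction, preserves p
  bem2 <- 1 - bem; dimnames(bem2) <- dimnames(bem)
  res2 <- monotherapy_association(mono, bem2, min_group = 3)
  expect_equal(res2$p, res$p)
  expect_equal(res2$direction, "sensitivity")
  # identical groups: p = 1, no direction
  mono3 <- mono; mono3$sensitivity <- rep(c(0.2, 0.5, 0.8), 2)
  res3 <- monotherapy_association(mono3, bem, min_group = 3)
  expect_equal(res3$p, 1)
  expect_true(is.na(res3$direction))
  # too-small groups are skipped
  bem4 <- bem; bem4[1, ] <- c(1, 1, 0, 0, 0, 0)
  expect_equal(nrow(monotherapy_association(mono, bem4, min_group = 3)), 0)
})

test_that("rank-sum p matches full enumeration for group sizes <= 5", {
  set.seed(71)
  for (sizes in list(c(3, 3), c(3, 5), c(4, 4), c(5, 5))) {
    x <- round(runif(sizes[1]), 3)
    y <- round(runif(sizes[2]), 3)
    cells <- sprintf("c%d", seq_len(sum(sizes)))
    bem <- matrix(rep(c(1L, 0L), sizes), 1, sum(sizes),
                  dimnames = list("g1", cells))
    mono <- data.frame(drug_id = "D", cell_id = cells,
                       sensitivity = c(x, y))
    res <- monotherapy_association(mono, bem, min_group = 3)
    expect_equal(res$p, exact_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("synergy_enrichment selects nested sets and hits boundaries", {
  # two drugs, one real resistance marker, constructed synergy table
  cells <- sprintf("c%d", 1:10)
  bem <- matrix(rep(c(1L, 0L), each = 5), 1, 10,
                dimnames = list("g1", cells))
  assocs <- data.frame(drug_id = "D1", gene = "g1", p = 1e-3,
                       direction = "resistance", n_mut = 5, n_wt = 5)
  synergy <- data.frame(combo_id = "C1", cell_id = cells,
                        drug_a = "D1", drug_b = "D2",
                        score = c(30, 25, 40, 21, 50, 0, -5, 3, 1, 2))
  enr <- synergy_enrichment(assocs, synergy, bem, seed = 1)
  cv <- enr$curve
  # nested: selected fraction non-increasing in threshold
  expect_true(all(diff(cv$selected_fraction) <= 0))
  # t = 0: all marker-carrying experiments selected, all synergistic here
  expect_equal(cv$selected_fraction[1], 0.5)
  expect_equal(cv$pct_synergistic[1], 100)
  # beyond the association strength nothing is linked
  expect_equal(cv$n_linked[cv$threshold > 3], integer(0))
  expect_true(all(cv$n_linked[cv$threshold <= 3] == 5))
  expect_length(enr$boot, 5)
  # bootstrap reproducibility
  enr2 <- synergy_enrichment(assocs, synergy, bem, seed = 1)
  expect_identical(enr$boot, enr2$boot)
  expect_error(synergy_enrichment(assocs[0, ], synergy, bem), "non-empty")
})

test_that("synergy_biomarker_anova computes effects, p and BH jointly", {
  cells <- sprintf("c%d", 1:4)
  bem <- matrix(c(1L, 1L, 0L, 0L), 1, 4, dimnames = list("g1", cells))
  tissues <- setNames(rep("breast", 4), cells)
  synergy <- data.frame(combo_id = "C1", cell_id = cells,
                        score = c(30, 40, 0, 10))
  cands <- data.frame(gene = "g1", combo_id = "C1")
  expect_warning(res <- synergy_biomarker_anova(synergy, bem, tissues, cands),
                 "one tissue")
  expect_equal(res$effect_size, 30)
  expect_equal(res$q, res$p)
  # multi-candidate BH equals the step-up oracle
  set.seed(72)
  panel <- make_panel(24, 6, seed = 73)
  syn <- data.frame(combo_id = "C1", cell_id = panel$cell_ids,
                    score = rnorm(24, 10, 15))
  cands2 <- data.frame(gene = rownames(panel$bem), combo_id = "C1")
  res2 <- synergy_biomarker_anova(syn, panel$bem, panel$tissue, cands2)
  expect_equal(res2$q, stats::p.adjust(res2$p, "BH"))
  expect_true(all(res2$q >= res2$p))
})

test_that("ANOVA event p is invariant to consistent relabeling", {
  set.seed(74)
  panel <- make_panel(30, 4, seed = 75)
  syn <- data.frame(combo_id = "C1", cell_id = panel$cell_ids,
                    score = rnorm(30, 10, 15))
  cands <- data.frame(gene = rownames(panel$bem)[1], combo_id = "C1")
  r1 <- synergy_biomarker_anova(syn, panel$bem, panel$tissue, cands)
  perm <- sample(seq_len(30))
  syn2 <- syn[perm, ]
  r2 <- synergy_biomarker_anova(syn2, panel$bem, panel$tissue, cands)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$effect_size, r2$effect_size, tolerance = 1e-12)
})

test_that("validate_directionality counts sign concordance", {
  cells <- sprintf("c%d", 1:6)
  bem <- matrix(rep(c(1L, 0L), 3), 2, 6, byrow = TRUE,
                dimnames = list(c("g1", "g2"), cells))
  bem[2, ] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  syn <- data.frame(combo_id = rep(c("C1", "C2"), each = 6),
                    cell_id = rep(cells, 2),
                    score = c(30, 0, 35, 5, 28, 2, 25, 22, 30, 0, 5, 2))
  cands <- data.frame(gene = c("g1", "g2"), combo_id = c("C1", "C2"))
  tissues <- setNames(rep(c("a", "b"), 3), cells)
  disc <- synergy_biomarker_anova(syn, bem, tissues, cands)
  same <- validate_directionality(disc, syn, bem)
  expect_equal(same$concordance, 1)
  flipped <- syn; flipped$score <- -flipped$score
  opp <- validate_directionality(disc, flipped, bem)
  expect_equal(opp$concordance, 0)
  # absent candidates leave the denominator
  part <- validate_directionality(disc, syn[syn$combo_id == "C1", ], bem)
  expect_equal(nrow(part$detail), 1)
})

test_that("monotherapy_sensitivity orders curves by potency", {
  d <- dose_series(10)
  potent <- hill_curve(100, 10, 0.5, 2)
  weak <- hill_curve(100, 80, 5, 2)
  expect_gt(monotherapy_sensitivity(potent, d),
            monotherapy_sensitivity(weak, d))
  none <- hill_curve(100, 100, 1, 1, no_effect = TRUE)
  expect_lt(monotherapy_sensitivity(none, d), 1e-9)
})
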