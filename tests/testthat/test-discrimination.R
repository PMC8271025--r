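test_that("mann-whitney AUC matches worked examples", {
  mw <- mann_whitney_auc(1:3, 4:6)
  expect_equal(mw$u, 9); expect_equal(mw$auc, 1)
  expect_equal(mann_whitney_auc(1:3, 1:3)$auc, 0.5)  # ties force 1/2
  mw2 <- mann_whitney_auc(c(1, 2, 3, 4, 5, 7), c(6, 8, 9, 10, 11, 12))
  expect_equal(mw2$u, 35); expect_equal(mw2$auc, 35 / 36)
  expect_error(mann_whitney_auc(numeric(0), 1:3))
})

test_that("midrank U equals brute-force pair counting on random inputs", {
  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    # discrete values force cross-group ties
    a <- sample(1:5, n1, replace = TRUE)
    b <- sample(1:5, n2, replace = TRUE)
    mw <- mann_whitney_auc(a, b)
    expect_equal(mw$u, u_oracle(a, b))
    expect_equal(mw$auc + mann_whitney_auc(b, a)$auc, 1)
  }
})

test_that("gini score is the exact rescaling of AUC", {
  expect_equal(gini_score(1), 1)
  expect_equal(gini_score(0.5), 0)
  expect_equal(gini_score(35 / 36), 34 / 36)
  expect_equal(gini_score(0), -1)
  expect_error(gini_score(1.2))
})

test_that("perfect-separation null matches enumeration of rank splits", {
  expect_equal(perfect_separation_pvalue(6, 6), 1 / 924)
  expect_equal(perfect_separation_pvalue(1, 1), 1 / 2)
  expect_equal(perfect_separation_pvalue(2, 2), 1 / 6)
  expect_equal(perfect_separation_pvalue(6, 6, two_sided = TRUE), 2 / 924)
  # exhaustive: of all C(12,6) = 924 assignments of ranks to group b,
  # exactly one has auc = 1 in the fixed orientation
  splits <- utils::combn(12, 6)
  aucs <- apply(splits, 2, function(b_ranks) {
    mann_whitney_auc(setdiff(1:12, b_ranks), b_ranks)$auc
  })
  expect_equal(ncol(splits), 924)
  expect_equal(sum(aucs == 1), 1L)
  expect_equal(mean(aucs == 1), perfect_separation_pvalue(6, 6))
  # same for the 2-vs-2 case
  s4 <- utils::combn(4, 2)
  a4 <- apply(s4, 2, function(b) mann_whitney_auc(setdiff(1:4, b), b)$auc)
  expect_equal(mean(a4 == 1), perfect_separation_pvalue(2, 2))
})

test_that("group FDR and the all-pairs bound follow exact arithmetic", {
  expect_equal(group_fdr(1 / 924, 106), 1 - (1 - 1 / 924)^106)
  expect_equal(group_fdr(0.3, 1), 0.3)
  expect_equal(all_pairs_bound(0.108, 120), 0.108^120)
  expect_lte(all_pairs_bound(group_fdr(1 / 924, 106), 120), 1e-58)
})

test_that("gini grid covers all unordered pairs and flags perfection", {
  objs <- c("apple1", "apple2", "kiwi1", "kiwi2")
  x <- make_feature_table(
    objects = objs, features = c("firstorder_Mean", "glcm_Imc1"),
    sequences = c("T2 map", "HASTE"),
    values = function(o, sc, se, f) {
      if (f == "firstorder_Mean") 10 * match(o, objs) + sc else 1
    }
  )
  g <- pairwise_gini_grid(x)
  expect_equal(nrow(g), choose(4, 2) * 2 * 2)
  expect_true(all(g$object_a < g$object_b))
  expect_true(all(g$n1 == 6 & g$n2 == 6))
  expect_equal(g$auc, g$u / (g$n1 * g$n2))
  expect_equal(g$gini, 2 * g$auc - 1)
  # the separating feature is perfect everywhere, the constant one nowhere
  expect_true(all(g$perfect[g$feature_name == "firstorder_Mean"]))
  expect_true(!any(g$perfect[g$feature_name == "glcm_Imc1"]))
  # two objects, one feature, one sequence -> a single result
  x1 <- make_feature_table(values = function(o, sc, se, f) match(o, c(
    "apple1", "kiwi1")))
  expect_equal(nrow(pairwise_gini_grid(x1)), 1L)
})

test_that("a tie straddling the two groups vetoes perfection", {
  objs <- c("apple1", "kiwi1")
  x <- make_feature_table(
    objects = objs,
    values = function(o, sc, se, f) {
      # kiwi1 all larger except one value tied with apple1's maximum
      if (o == "apple1") match(se, radstab::session_labels) + 3 * (sc - 1)
      else 6 + match(se, radstab::session_labels) + 3 * (sc - 1) -
        (sc == 1 && se == "R1S1") * 6
    }
  )
  g <- pairwise_gini_grid(x)
  expect_lt(g$auc, 1)
  expect_false(g$perfect)
})

test_that("success counts obey the at-least-one-perfect definition", {
  objs <- c("apple1", "apple2", "kiwi1")
  x <- make_feature_table(
    objects = objs,
    features = c("firstorder_Mean", "firstorder_Median", "glcm_Imc1"),
    values = function(o, sc, se, f) {
      # only firstorder_Mean separates, and only apple pairs vs kiwi1
      if (f == "firstorder_Mean" && o == "kiwi1") 100 else
        match(o, objs) / 10 + match(se, radstab::session_labels) + sc
    }
  )
  g <- pairwise_gini_grid(x)
  sc_seq <- success_counts(g, "sequence")
  expect_equal(sc_seq$n_successes, 2L)  # (apple1,kiwi1), (apple2,kiwi1)
  expect_equal(sc_seq$n_pairs, 3L)
  by_feat <- success_counts(g, "feature")
  expect_equal(
    by_feat$n_successes[by_feat$feature_name == "firstorder_Mean"], 2L)
  expect_true(all(
    by_feat$n_successes[by_feat$feature_name != "firstorder_Mean"] == 0L))
  # group monotonicity: the sequence group (all features) succeeds at
  # least as often as any single feature
  expect_true(all(sc_seq$n_successes >= by_feat$n_successes))
  # competition ranking: ties share a rank, next rank skips
  expect_equal(by_feat$rank, c(1L, 2L, 2L))

  # relabeling objects permutes the grid but not per-sequence counts
  xp <- x
  xp$object_id <- c(apple1 = "kiwi1", apple2 = "apple1",
                    kiwi1 = "apple2")[xp$object_id]
  xp$object_type <- sub("[0-9]+$", "", xp$object_id)
  gp <- pairwise_gini_grid(xp)
  expect_equal(success_counts(gp, "sequence")$n_successes,
               sc_seq$n_successes)
})
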