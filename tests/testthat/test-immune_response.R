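multiplex_panel <- function(stim, ctrl, pre_deltas, analyte = "IFNg") {
  pre_ctrl <- rep(1, length(stim))
  cytokine_panel(data.frame(
    sample_id = sprintf("s%d", seq_along(stim)), analyte = analyte,
    stimulated = stim, control = ctrl,
    pre_stimulated = pmax(pre_ctrl + pre_deltas, 0), pre_control = pre_ctrl
  ), assay = "multiplex-PBMC")
}

test_that("multiplex rule applies the three strict criteria", {
  # deltas (-4, 1, 3, 10) and ratios (0.5, 1.5, 2.5, 3);
  # analyte threshold = |-4|/2 = 2
  panel <- multiplex_panel(stim = c(4, 3, 5, 15), ctrl = c(8, 2, 2, 5),
                           pre_deltas = c(0, 0, 2, 1))
  calls <- call_positivity_multiplex(panel)
  # s3: delta 3 > 2, ratio 2.5 > 2, post-pre = 3-2 = 1 > 0 -> positive
  # s2: delta 1 fails the delta criterion
  expect_identical(unname(calls[, "IFNg"]), c(0L, 0L, 1L, 1L))

  # ratio exactly 2 is negative ("superior to" is strict):
  # deltas (-4, 3), ratios (0.5, 2)
  panel2 <- multiplex_panel(stim = c(4, 6), ctrl = c(8, 3),
                            pre_deltas = c(0, 0))
  expect_identical(unname(call_positivity_multiplex(panel2)[2, ]), 0L)

  # all-positive deltas (2, 6, 10): threshold = smallest positive delta / 2
  panel3 <- multiplex_panel(stim = c(3, 9, 15), ctrl = c(1, 3, 5),
                            pre_deltas = c(0, 0, 0))
  calls3 <- call_positivity_multiplex(panel3)
  expect_identical(unname(calls3[, 1]), c(1L, 1L, 1L))  # threshold 1
})

test_that("positivity is monotone in stimulated concentration", {
  set.seed(1)
  for (rep in 1:20) {
    panel <- multiplex_panel(stim = runif(6, 0, 20), ctrl = runif(6, 0.5, 5),
                             pre_deltas = rnorm(6))
    calls <- call_positivity_multiplex(panel)
    idx <- 3
    d3 <- panel$data
    d3$stimulated[idx] <- d3$stimulated[idx] + 5  # raise one sample only
    calls3 <- call_positivity_multiplex(
      cytokine_panel(d3, assay = "multiplex-PBMC"))
    # the raised sample's call never flips positive -> negative; the other
    # samples' thresholds can only rise through the cohort minimum, which a
    # raised stimulated value cannot lower
    if (calls[idx, 1] == 1L) expect_identical(calls3[idx, 1], 1L)
  }
})

test_that("whole-blood ratio rule is strict and handles zeros", {
  panel <- cytokine_panel(data.frame(
    sample_id = c("a", "b", "c", "d"), analyte = "IFNg",
    stimulated = c(10, 4, 0, 1), control = c(2, 2, 0, 0)
  ), assay = "whole-blood-multiplex")
  calls <- call_positivity_wholeblood_ratio(panel)
  # 10/2=5 positive; 4/2=2 negative (strict); 0/0 negative; 1/floor positive
  expect_identical(unname(calls[, 1]), c(1L, 0L, 0L, 1L))
})

test_that("VIDAS IFNg rule matches its two-branch definition", {
  expect_true(call_vidas_ifng(0.5, 0.02))
  expect_false(call_vidas_ifng(0.20, 0.15))  # nil high, diff 0.05 <= 0.08
  expect_true(call_vidas_ifng(1.0, 0.5))     # diff 0.5 > 0.08
  expect_false(call_vidas_ifng(0.08, 0.0))   # boundary is strict
  expect_error(call_vidas_ifng(-0.1, 0), "non-negative")
})

test_that("frequency filter boundary is exact", {
  calls <- matrix(0L, 75, 3, dimnames = list(NULL, c("a", "b", "c")))
  calls[1:7, "a"] <- 1L          # 9.33% -> excluded
  calls[1:8, "b"] <- 1L          # 10.67% -> retained
  calls[1:15, "c"] <- 1L         # 20% -> retained
  expect_setequal(filter_low_frequency(calls, 0.10), c("b", "c"))
  calls10 <- matrix(0L, 10, 1, dimnames = list(NULL, "x"))
  calls10[1, 1] <- 1L            # exactly 10% -> retained
  expect_identical(filter_low_frequency(calls10, 0.10), "x")
  expect_error(filter_low_frequency(calls[, 1, drop = FALSE], 0.10),
               "no analytes retained")
})

test_that("reactivity clustering recovers a clean two-block structure", {
  # 3 all-positive and 3 all-negative samples
  calls <- rbind(matrix(1L, 3, 4), matrix(0L, 3, 4))
  dimnames(calls) <- list(sprintf("s%d", 1:6), sprintf("a%d", 1:4))
  res <- cluster_reactivity(calls)
  expect_false(res$degenerate)
  expect_identical(unname(res$cluster), rep(c(1L, 0L), each = 3))

  pc <- planted_calls(n = 10, k = 6)
  res2 <- cluster_reactivity(pc$calls)
  expect_identical(unname(res2$cluster), pc$truth)
  # cluster 1 is the one with higher positivity frequency
  expect_gt(mean(pc$calls[res2$cluster == 1, ]),
            mean(pc$calls[res2$cluster == 0, ]))
})

test_that("clustering is invariant to sample and analyte order", {
  pc <- planted_calls(n = 24, k = 8, flip = 0.05, seed = 3)
  res <- cluster_reactivity(pc$calls)
  set.seed(9)
  perm <- sample(nrow(pc$calls))
  res_p <- cluster_reactivity(pc$calls[perm, ])
  expect_identical(res_p$cluster[rownames(pc$calls)], res$cluster)
  res_a <- cluster_reactivity(pc$calls[, sample(ncol(pc$calls))])
  expect_identical(res_a$cluster, res$cluster)
})

test_that("noisy planted clusters are recovered (ARI >= 0.8)", {
  aris <- vapply(1:10, function(s) {
    pc <- planted_calls(n = 75, k = 10, flip = 0.05, seed = s)
    res <- cluster_reactivity(pc$calls)
    adjusted_rand_index(res$cluster, pc$truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("identical rows give a degenerate flag, not an arbitrary split", {
  calls <- matrix(1L, 5, 3, dimnames = list(sprintf("s%d", 1:5), c("a", "b", "c")))
  res <- cluster_reactivity(calls)
  expect_true(res$degenerate)
  expect_identical(unname(res$cluster), rep(0L, 5))
})

test_that("median split follows the tie-to-group-0 convention", {
  expect_identical(unname(median_split(c(50, 90, 200, 400))),
                   c(0L, 0L, 1L, 1L))
  # external median 110: ties go to group 0
  expect_identical(unname(median_split(c(110, 110, 200, 50),
                                       median_value = 110)),
                   c(0L, 0L, 1L, 0L))
  # n = 26 distinct scores -> 13/13 split
  set.seed(4)
  scores <- sample(1000, 26)
  grp <- median_split(scores)
  expect_identical(as.vector(table(grp)), c(13L, 13L))
  expect_error(median_split(rep(5, 4)), "no split possible")
})

test_that("booster response needs both fold and absolute titer", {
  expect_true(call_booster_response(5, 25))
  expect_false(call_booster_response(15, 25))   # fold 1.67
  expect_false(call_booster_response(1, 15))    # post <= 20
  expect_true(call_booster_response(0, 25))     # zero pre -> fold infinite
  expect_false(call_booster_response(10, 20))   # both boundaries strict
})
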