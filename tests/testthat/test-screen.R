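# 2^-ddCt quantification, the down-and-restored screen, 2^-dCt relative
# levels, and the heat-map export.

make_ct <- function(ct, groups, ic = "U6") ct_table(ct, groups, ic)

test_that("delta_delta_ct reproduces the textbook worked example", {
  # Ct_target 24, Ct_U6 20 => dCt 4; control-averaged dCt 5 => ddCt -1, fold 2
  ct <- matrix(c(25, 25, 25, 24,
                 20, 20, 20, 20), 2, 4, byrow = TRUE,
               dimnames = list(c("t", "U6"), c("c1", "c2", "c3", "e1")))
  groups <- c(c1 = "control", c2 = "control", c3 = "control", e1 = "exp")
  ft <- delta_delta_ct(make_ct(ct, groups), c("c1", "c2", "c3"))
  expect_equal(unname(ft$control_avg_delta_ct["t"]), 5)
  expect_equal(unname(ft$delta_delta_ct["t", "e1"]), -1)
  expect_equal(unname(ft$fold["t", "e1"]), 2.0)
  # a sample whose dCt equals the control average sits at fold 1
  expect_equal(unname(ft$fold["t", "c1"]), 1.0)
})

test_that("noiseless simulated panels round-trip designed folds exactly", {
  tr <- design_screen_truth(40, 6, fold_down = 0.25, seed = 2)
  pan <- simulate_qpcr_panel(tr$expression, tr$groups, noise_sd = 0)
  ctrl <- names(tr$groups)[tr$groups == "control"]
  ft <- delta_delta_ct(pan, ctrl)
  expect_equal(ft$fold, tr$expression, tolerance = 1e-9)
  expect_equal(unname(ft$fold[tr$down_restored[1],
                              tr$groups == "disease"][1]), 0.25,
               tolerance = 1e-9)
  # normalization identity: geometric mean of control folds = 1 per target
  gm <- exp(rowMeans(log(ft$fold[, ctrl, drop = FALSE])))
  expect_equal(unname(gm), rep(1, nrow(ft$fold)), tolerance = 1e-9)
})

test_that("per-sample Ct offsets cancel (internal-control invariance)", {
  tr <- design_screen_truth(10, 2, seed = 4)
  pan <- simulate_qpcr_panel(tr$expression, tr$groups)
  ctrl <- names(tr$groups)[tr$groups == "control"]
  shifted <- pan$ct
  shifted[, 3] <- shifted[, 3] + 2.5   # e.g. twice the input RNA
  ft0 <- delta_delta_ct(pan, ctrl)
  ft1 <- delta_delta_ct(make_ct(shifted, tr$groups), ctrl)
  expect_equal(ft1$fold, ft0$fold, tolerance = 1e-12)
})

test_that("ct_table validates its invariants", {
  ct <- matrix(c(24, 23, 20, NA), 2, 2,
               dimnames = list(c("t", "U6"), c("s1", "s2")))
  g <- c(s1 = "a", s2 = "b")
  expect_error(ct_table(ct, g), "internal-control")
  expect_error(ct_table(ct[1, , drop = FALSE], g), "not in Ct table")
  ct[2, 2] <- -1
  expect_error(ct_table(ct, g), "positive")
  expect_error(delta_delta_ct(make_ct(matrix(c(24, 20), 2, 1,
                                             dimnames = list(c("t", "U6"),
                                                             "s1")),
                                      c(s1 = "a")), "s9"),
               "not in Ct table")
})

test_that("missing target Ct propagates to a missing fold", {
  ct <- matrix(c(24, NA, 25, 20, 20, 20), 2, 3, byrow = TRUE,
               dimnames = list(c("t", "U6"), c("c1", "c2", "e1")))
  g <- c(c1 = "ctl", c2 = "ctl", e1 = "exp")
  ft <- delta_delta_ct(make_ct(ct, g), "c1")
  expect_true(is.na(ft$fold["t", "c2"]))
  expect_false(anyNA(ft$fold["t", c("c1", "e1")]))
})

test_that("rel_quant_delta_ct normalizes to the control-averaged Ct", {
  ct <- c(ctl1 = 21, ctl2 = 22, ctl3 = 23, kd1 = 23.321928)
  rel <- rel_quant_delta_ct(ct, c("ctl1", "ctl2", "ctl3"))
  # geometric mean of control relative levels is 1 by construction
  expect_equal(exp(mean(log(rel[1:3]))), 1, tolerance = 1e-12)
  # one cycle above the control average halves the level
  expect_equal(unname(rel_quant_delta_ct(c(a = 20, b = 21), "a")[["b"]]),
               0.5)
  # 60% reduction round trip: level 0.4 => Ct + log2(1/0.4)
  ct2 <- c(c1 = 20, c2 = 20, t1 = 20 + log2(1 / 0.4))
  expect_equal(unname(rel_quant_delta_ct(ct2, c("c1", "c2"))[["t1"]]), 0.4,
               tolerance = 1e-12)
  expect_error(rel_quant_delta_ct(ct, character(0)), ">= 1 control")
})

test_that("screen_restored recovers the designed set exactly (noiseless)", {
  tr <- design_screen_truth(200, 20, n_decoy = 10, fold_down = 0.25,
                            seed = 5)
  pan <- simulate_qpcr_panel(tr$expression, tr$groups, noise_sd = 0)
  ctrl <- names(tr$groups)[tr$groups == "control"]
  scr <- screen_restored(delta_delta_ct(pan, ctrl),
                         c(control = "control", disease = "disease",
                           knockdown = "knockdown"))
  expect_setequal(scr$selected, tr$down_restored)
  # down-but-not-restored decoys are excluded by the restore rule
  expect_length(intersect(scr$selected, tr$decoys), 0)
  v <- scr$verdicts[scr$verdicts$mirna_id %in% tr$decoys, ]
  expect_true(all(v$down) && !any(v$restored))
})

test_that("screen on identical groups selects nothing; errors are explicit", {
  tr <- design_screen_truth(30, 0, seed = 6)
  pan <- simulate_qpcr_panel(tr$expression, tr$groups, noise_sd = 0)
  ctrl <- names(tr$groups)[tr$groups == "control"]
  ft <- delta_delta_ct(pan, ctrl)
  roles <- c(control = "control", disease = "disease",
             knockdown = "knockdown")
  expect_length(screen_restored(ft, roles)$selected, 0)
  expect_error(screen_restored(ft, c(control = "control",
                                     disease = "nope",
                                     knockdown = "knockdown")),
               "absent")
})

test_that("export_heatmap_matrix writes log2 folds of the selection", {
  tr <- design_screen_truth(20, 4, fold_down = 0.25, seed = 7)
  pan <- simulate_qpcr_panel(tr$expression, tr$groups, noise_sd = 0)
  ctrl <- names(tr$groups)[tr$groups == "control"]
  ft <- delta_delta_ct(pan, ctrl)
  one <- export_heatmap_matrix(ft, tr$down_restored[1])
  expect_equal(dim(one), c(1L, 9L))
  expect_equal(unname(one[1, tr$groups == "disease"]), rep(-2, 3),
               tolerance = 1e-9)
  # fold 1 everywhere => all-zero rows
  flat <- export_heatmap_matrix(ft, setdiff(rownames(ft$fold), c(
    tr$down_restored, tr$decoys)))
  expect_true(all(abs(flat) < 1e-9))
  # screen output rows are exactly the selected set
  scr <- screen_restored(ft, c(control = "control", disease = "disease",
                               knockdown = "knockdown"))
  d <- withr::local_tempdir()
  f <- file.path(d, "hm.csv")
  export_heatmap_matrix(ft, scr$selected, f)
  expect_setequal(utils::read.csv(f)$mirna_id, scr$selected)
  expect_error(export_heatmap_matrix(ft, character(0)), "non-empty")
})

test_that("screen verdicts carry a threshold provenance header", {
  tr <- design_screen_truth(15, 3, seed = 8)
  pan <- simulate_qpcr_panel(tr$expression, tr$groups)
  ctrl <- names(tr$groups)[tr$groups == "control"]
  scr <- screen_restored(delta_delta_ct(pan, ctrl),
                         c(control = "control", disease = "disease",
                           knockdown = "knockdown"),
                         down_threshold = 0.7, restore_range = c(0.9, 1.1))
  d <- withr::local_tempdir()
  f <- file.path(d, "screen.tsv")
  write_screen_verdicts(scr, f)
  hdr <- readLines(f, n = 4)
  expect_true(any(grepl("down_threshold=0.7", hdr)))
  expect_true(any(grepl("restore_range=\\[0.9,1.1\\]", hdr)))
})
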