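test_that("the fusion rule reproduces the worked per-patient examples", {
  expect_identical(fuse("RIGHT", "LEFT", "RIGHT"), "RIGHT")  # sum -1
  expect_identical(fuse("RIGHT", "NONE", "LEFT"), "RIGHT")   # sum 0 tie
  expect_identical(fuse("RIGHT", "LEFT", "LEFT"), "LEFT")    # sum +1
  expect_identical(fuse("NONE", "NONE", "NONE"), "RIGHT")    # all missing
  expect_identical(fuse(0, 1, 1), "LEFT")                    # encoded form
})

test_that("side encoding is the documented signed convention", {
  expect_identical(encode_side(c("LEFT", "RIGHT", "NONE")), c(1L, -1L, 0L))
  expect_identical(decode_side(c(1L, -1L, 0L)), c("LEFT", "RIGHT", "NONE"))
  expect_error(encode_side("UP"), "unknown")
  expect_error(decode_side(2L))
})

test_that("fusion antisymmetry holds over all 27 label combinations", {
  sides <- c("LEFT", "RIGHT", "NONE")
  flip <- function(s) ifelse(s == "LEFT", "RIGHT", ifelse(s == "RIGHT", "LEFT", "NONE"))
  for (a in sides) for (b in sides) for (c in sides) {
    total <- sum(encode_side(c(a, b, c)))
    f1 <- fuse(a, b, c)
    f2 <- fuse(flip(a), flip(b), flip(c))
    if (total == 0) {
      # the documented tie behavior: both orientations fall to RIGHT
      expect_identical(f1, "RIGHT")
      expect_identical(f2, "RIGHT")
    } else {
      expect_false(f1 == f2)
    }
  }
})

test_that("the packaged label table parses into the documented categories", {
  tab <- read_label_table()
  expect_identical(nrow(tab), 15L)
  expect_true(all(tab$expert_eeg %in% c("LEFT", "RIGHT")))
  expect_identical(tab$L1[1], "NONE")           # post-lobectomy patient
  expect_identical(sum(tab$expert_mri == "BILATERAL"), 2L)
  expect_identical(sum(tab$L2 == "NONE"), 3L)
})

test_that("row-wise fusion reproduces the printed final column for all 15 patients", {
  tab <- read_label_table()
  ft <- fuse_table(tab)
  expect_identical(ft$fused, ft$final)
  # permuting rows leaves per-patient results unchanged
  perm <- sample(nrow(tab))
  ft2 <- fuse_table(tab[perm, ])
  expect_identical(ft2$fused, ft$fused[perm])
})

test_that("overlap ratio counts bilateral findings as eligible non-matches", {
  ov <- overlap_ratio(c("LEFT", "BILATERAL", "RIGHT", "NONE"),
                      c("LEFT", "LEFT", "LEFT", "LEFT"))
  expect_identical(ov$matched, 1L)
  expect_identical(ov$eligible, 3L)

  ident <- overlap_ratio(c("LEFT", "RIGHT"), c("LEFT", "RIGHT"))
  expect_equal(ident$ratio, 100)
  expect_error(overlap_ratio(c("NONE", "NONE"), c("LEFT", "RIGHT")),
               "eligible")
  expect_error(overlap_ratio("LEFT", c("LEFT", "RIGHT")), "aligned")
})

test_that("overlap ratio is symmetric and order-invariant", {
  set.seed(37)
  a <- sample(c("LEFT", "RIGHT", "NONE", "BILATERAL"), 30, replace = TRUE)
  b <- sample(c("LEFT", "RIGHT", "NONE"), 30, replace = TRUE)
  if (!any(a %in% c("LEFT", "RIGHT", "BILATERAL") &
           b %in% c("LEFT", "RIGHT"))) skip("degenerate draw")
  o1 <- overlap_ratio(a, b)
  o2 <- overlap_ratio(b, a)
  expect_identical(o1, o2)
  perm <- sample(30)
  o3 <- overlap_ratio(a[perm], b[perm])
  expect_identical(o1, o3)
})

test_that("the overlap report reproduces every published comparison", {
  rep <- reproduce_overlap_table(read_label_table())
  get <- function(name, field) rep[rep$comparison == name, field]
  expect_equal(get("expert_mri_vs_expert_eeg", "ratio"), 50)
  expect_identical(get("expert_mri_vs_expert_eeg", "eligible"), 6L)
  expect_equal(get("analysis1_vs_expert_eeg", "ratio"), 78.6)
  expect_identical(get("analysis1_vs_expert_eeg", "matched"), 11L)
  expect_equal(get("analysis2_vs_expert_eeg", "ratio"), 91.7)
  expect_equal(get("analysis3_vs_expert_eeg", "ratio"), 86.7)
  expect_equal(get("decision_tree_vs_expert_eeg", "ratio"), 100)
  expect_equal(get("analysis1_vs_expert_mri", "ratio"), 60)
  expect_identical(get("analysis1_vs_expert_mri", "eligible"), 5L)
  expect_equal(get("analysis2_vs_analysis3", "ratio"), 91.7)
  expect_equal(get("analysis2_detection_rate", "ratio"), 80)
  expect_equal(get("expert_mri_detection_rate", "ratio"), 40)
})

test_that("percentages round half-up to one decimal", {
  expect_equal(overlap_ratio(rep("LEFT", 14), c(rep("LEFT", 11), rep("RIGHT", 3)))$ratio,
               78.6)   # 11/14 = 78.571...
  expect_equal(overlap_ratio(rep("LEFT", 12), c(rep("LEFT", 11), "RIGHT"))$ratio,
               91.7)   # 11/12 = 91.666...
})
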