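test_that("CSV round trip preserves a dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(51)
  ds <- figp_dataset(data.frame(logp = runif(3), rbc = c(1, 2, 3),
                                tpsa = c(20, 40, 60), mw = c(100, 150, 200)),
                     c(6.1, 7.2, 8.3))
  write_table(ds, path)
  ds2 <- read_table(path)
  expect_equal(ds2$X, ds$X, tolerance = 1e-12)
  expect_equal(ds2$y, ds$y, tolerance = 1e-12)

  # missing requested column is named in the error
  expect_error(read_table(path, feature_columns = c("logp", "don")), "don")
})

test_that("rows with missing values are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("logp,tpsa,pKi", "1.0,20,6.5", "2.0,,7.1", "3.0,50,8.0"), path)
  expect_message(ds <- read_table(path), "1 row")
  expect_equal(nrow(ds$X), 2L)
})

test_that("feature-set presets are exact", {
  expect_length(feature_set("FEAT10"), 10)
  expect_equal(feature_set("FEAT7"),
               c("arings", "acc", "don", "logp", "rbc", "tpsa", "mw"))
  expect_equal(feature_set("FEAT4"), c("logp", "rbc", "tpsa", "mw"))
  expect_true(all(feature_set("FEAT4") %in% feature_set("FEAT7")))
  expect_true(all(feature_set("FEAT7") %in% feature_set("FEAT10")))
})

test_that("train/test splitting partitions reproducibly at the stated sizes", {
  set.seed(52)
  ds <- figp_dataset(data.frame(logp = runif(40)), runif(40, 5, 9))
  set.seed(1); sp <- split_train_test(ds, 0.2)
  expect_equal(nrow(sp$train$X), 8L)   # round(40 * 0.2)
  expect_equal(nrow(sp$test$X), 32L)

  set.seed(7); a <- split_train_test(ds, 0.8)
  set.seed(7); b <- split_train_test(ds, 0.8)
  expect_identical(a$train_idx, b$train_idx)

  for (s in 1:100) {
    set.seed(s)
    sp <- split_train_test(ds, 0.5)
    got <- sort(c(which(seq_len(40) %in% sp$train_idx),
                  which(!seq_len(40) %in% sp$train_idx)))
    expect_identical(got, seq_len(40))
    expect_length(intersect(sp$train_idx,
                            setdiff(seq_len(40), sp$train_idx)), 0)
  }
  expect_error(split_train_test(ds, 0.02), "split too small")
})

test_that("subset-then-split equals split-then-subset under one seed", {
  set.seed(53)
  ds <- figp_dataset(data.frame(logp = runif(30), tpsa = runif(30, 0, 100),
                                mw = runif(30, 50, 400)),
                     runif(30, 5, 9))
  set.seed(11); a <- split_train_test(subset_features(ds, c("logp", "mw")), 0.5)
  set.seed(11); b <- split_train_test(ds, 0.5)
  expect_equal(a$train$X, subset_features(b$train, c("logp", "mw"))$X)
})

test_that("the synthetic generator honors its ground truth and noise", {
  gt <- synthetic_ground_truth("linear")
  set.seed(54)
  ds0 <- generate_synthetic(gt$tree, gt$variable_box, 50, 0)
  expect_equal(ds0$y, evaluate(gt$tree, ds0$X)$values)

  set.seed(55)
  ds <- generate_synthetic(gt$tree, gt$variable_box, 10000, 0.3)
  resid <- ds$y - evaluate(gt$tree, ds$X)$values
  expect_equal(sd(resid), 0.3, tolerance = 0.1 * 0.3)

  set.seed(56); a <- generate_synthetic(gt$tree, gt$variable_box, 20, 0.1)
  set.seed(56); b <- generate_synthetic(gt$tree, gt$variable_box, 20, 0.1)
  expect_identical(a$X, b$X); expect_identical(a$y, b$y)

  # ground truth invalid in the box is a generation error
  expect_error(
    generate_synthetic("ln(x)", list(x = c(-1, 1)), 50),
    "generation error")
})

test_that("structure-based descriptors match forced counts and the toolkit", {
  d <- compute_substituent_descriptors(c("C", "c1ccccc1", "CCO", "CCCC"))
  # methyl fragment
  expect_equal(d$a_heavy[1], 1)
  expect_equal(d$rings[1], 0); expect_equal(d$arings[1], 0)
  expect_equal(d$don[1], 0);   expect_equal(d$rbc[1], 0)
  # benzene
  expect_equal(d$arings[2], 1); expect_equal(d$rings[2], 1)
  expect_equal(d$a_heavy[2], 6)
  # ethanol: both bonds touch a terminal atom, so nothing rotates
  expect_equal(d$a_heavy[3], 3)
  expect_equal(d$don[3], 1)
  expect_equal(d$rbc[3], 0)
  # butane: only the central C-C bond is rotatable
  expect_equal(d$rbc[4], 1)
  expect_true(all(is.finite(as.matrix(d))))
  expect_gt(d$mw[2], 70); expect_lt(d$mw[1], 20)

  # toolkit self-consistency on logp/tpsa
  p <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", "CCO", identity))
  expect_equal(d$logp[3], as.numeric(p$logP[1]))
  expect_equal(d$tpsa[3], as.numeric(p$TPSA[1]))

  expect_error(compute_substituent_descriptors("not_a_smiles(("),
               "unparseable")
})
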