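test_that("generation is a pure function of the config", {
  cfg <- synth_config(n0 = 30, n1 = 10, seed = 42)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a, b)
  # and leaves the caller's RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_synthetic(cfg)); after <- rnorm(1)
  expect_identical(before, after)
  # different seeds give different data
  expect_false(identical(a$sequence,
                         generate_synthetic(synth_config(n0 = 30, n1 = 10,
                                                         seed = 43))$sequence))
})

test_that("lengths stay inside the configured band", {
  for (s in 1:3) {
    d <- generate_synthetic(synth_config(n0 = 60, n1 = 20, seed = s))
    lens <- nchar(d$sequence)
    expect_gte(min(lens), 33)
    expect_lte(max(lens), 38)
  }
  d2 <- generate_synthetic(synth_config(n0 = 25, n1 = 0,
                                        length_range = c(10, 12), seed = 1))
  expect_true(all(nchar(d2$sequence) %in% 10:12))
})

test_that("labels and ids follow the configured class sizes", {
  d <- generate_synthetic(synth_config(n0 = 7, n1 = 4, seed = 5))
  expect_equal(nrow(d), 11L)
  expect_equal(sum(d$label == 0L), 7L)
  expect_equal(sum(d$label == 1L), 4L)
  expect_false(anyDuplicated(d$id) > 0)
})

test_that("impossible or invalid configs are rejected", {
  expect_error(synth_config(n0 = 0, n1 = 0), "positive")
  expect_error(synth_config(class_signal = 1.2))
  expect_error(synth_config(length_range = c(1, 5)))
  expect_error(synth_config(indel_rate = -1))
})

test_that("class-0 residue composition converges to the uniform base", {
  d <- generate_synthetic(synth_config(n0 = 600, n1 = 0, seed = 8))
  counts <- table(factor(strsplit(paste(d$sequence, collapse = ""), "")[[1]],
                         levels = AA_CANONICAL))
  gof <- stats::chisq.test(counts, p = rep(1 / 20, 20))
  expect_gt(gof$p.value, 0.01)
})

test_that("class 1 is enriched in hydrophobic residues at positive signal", {
  d <- generate_synthetic(synth_config(n0 = 300, n1 = 300, class_signal = 0.6,
                                       seed = 9))
  frac_hydro <- function(seqs) {
    ch <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    mean(ch %in% c("I", "V", "L", "F", "C", "M", "A"))
  }
  f0 <- frac_hydro(d$sequence[d$label == 0L])
  f1 <- frac_hydro(d$sequence[d$label == 1L])
  expect_gt(f1, f0 + 0.1)
  expect_equal(f0, 0.35, tolerance = 0.05)
})

test_that("indel churn preserves length and the composition model", {
  d <- generate_synthetic(synth_config(n0 = 50, n1 = 0, indel_rate = 0.2,
                                       seed = 12))
  expect_true(all(nchar(d$sequence) %in% 33:38))
})

test_that("downstream AUC increases with the planted class signal", {
  mean_auc <- function(sig) {
    mean(vapply(1:5, function(s) {
      d <- generate_synthetic(synth_config(n0 = 150, n1 = 80,
                                           class_signal = sig, seed = s))
      demo_classification(build_feature_matrix(d, dims = 35), seed = s)$auc
    }, numeric(1)))
  }
  aucs <- vapply(c(0, 0.3, 0.6, 0.9), mean_auc, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_lt(aucs[1], 0.6)
  expect_gt(aucs[4], 0.9)
})
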