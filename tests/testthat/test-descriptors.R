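test_that("the bundled database has 532 scales: 531 AAindex + 1 empirical", {
  db <- descriptor_db()
  expect_s3_class(db, "aa_scale_db")
  expect_length(db, 532L)
  emp <- purrr::map_lgl(db$scales, "empirical")
  expect_equal(sum(emp), 1L)
  expect_true(emp[[532]])
  acc <- purrr::map_chr(db$scales, "accession")
  expect_false(anyDuplicated(acc) > 0)
  # AAindex-sourced accessions follow the 10-character alphanumeric style
  expect_true(all(grepl("^[A-Z0-9]{10}$", acc[!emp])))
})

test_that("index lookup is 1-based, bounded, and 151 is Kyte-Doolittle", {
  db <- descriptor_db()
  kd <- get_scale(db, 151)
  expect_equal(kd$accession, "KYTJ820101")
  expect_equal(kd$values, KD_FIXTURE)
  expect_equal(get_scale(db, 1)$accession,
               purrr::map_chr(db$scales, "accession")[1])
  expect_error(get_scale(db, 533), "1\\.\\.532")
  expect_error(get_scale(db, 0), "1\\.\\.532")
  expect_error(get_scale(db, 151.5), "integer")
})

test_that("interval normalization maps the scale extremes exactly", {
  db <- descriptor_db()
  kd <- get_scale(db, 151)   # spans [-4.5, 4.5]
  u <- rescale_scale(kd, "unit")
  expect_equal(unname(range(u$values)), c(0, 1))
  s <- rescale_scale(kd, "symmetric_unit")
  expect_equal(unname(range(s$values)), c(-1, 1))
  # affine midpoint: a value of 0.0 on a [-4.5, 4.5] scale lands on 0.5
  probe <- aa_scale("PROBE00001", "span probe",
                    setNames(c(-4.5, 4.5, 0, runif(17, -4.4, 4.4)),
                             AA_CANONICAL))
  expect_equal(rescale_scale(probe, "unit")$values[["N"]], 0.5)
  # mode none is the identity
  expect_identical(rescale_scale(kd, "none"), kd)
  expect_identical(rescale_scale(kd, 0), kd)
})

test_that("rescaling is idempotent and order-preserving on all scales", {
  db <- descriptor_db()
  set.seed(5)
  for (idx in c(1, 151, 300, 532, sample(532, 10))) {
    sc <- get_scale(db, idx)
    for (mode in c("unit", "symmetric_unit")) {
      r1 <- rescale_scale(sc, mode)
      iv <- if (mode == "unit") c(0, 1) else c(-1, 1)
      expect_equal(unname(range(r1$values)), iv, tolerance = 1e-12)
      expect_equal(order(r1$values), order(sc$values))
      r2 <- rescale_scale(r1, mode)
      expect_equal(r2$values, r1$values, tolerance = 1e-12)
    }
  }
})

test_that("degenerate constant scales refuse interval normalization", {
  flat <- aa_scale("FLAT000001", "constant", setNames(rep(2, 20), AA_CANONICAL))
  expect_error(rescale_scale(flat, "unit"), "identical")
  expect_identical(rescale_scale(flat, "none"), flat)
})

test_that("mode codes 0/1/2 map onto the named modes", {
  expect_equal(parse_normalization_mode(0), "none")
  expect_equal(parse_normalization_mode(1), "symmetric_unit")
  expect_equal(parse_normalization_mode(2), "unit")
  expect_error(parse_normalization_mode(3), "mode")
  expect_error(parse_normalization_mode("minmax"), "mode")
})

test_that("list_descriptors() exposes the database as a tibble", {
  tb <- list_descriptors()
  expect_s3_class(tb, "tbl_df")
  expect_equal(nrow(tb), 532L)
  expect_equal(tb$index, 1:532)
  expect_equal(tb$accession[151], "KYTJ820101")
  expect_identical(tidy(descriptor_db()), tb)
})
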