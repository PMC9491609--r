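test_that("default model satisfies the structural invariants", {
  m <- the_model()
  expect_s3_class(m, "gait_model")
  expect_identical(nrow(m$coordinates), 11L)
  expect_identical(rownames(m$coordinates), hemigait:::coordinate_names)
  expect_true(all(m$coordinates[, "lower"] < m$coordinates[, "upper"]))
  expect_length(m$muscles, 12L)
  expect_length(m$contact$spheres, 5L)
  expect_equal(m$body_mass, 75.01, tolerance = 1e-6)
  fl <- hemigait:::model_flat(m)
  expect_length(fl$fmax, 24L)
  expect_length(fl$sph_r, 10L)
  expect_true(all(fl$mass >= 0), all(fl$izz >= 0))
})

test_that("unilateral weakness reproduces all published strengths to 0.1 N", {
  m <- the_model()
  base <- muscle_strengths(m)
  expect_equal(base$right, strength_table$base, tolerance = 1e-12)
  expect_equal(base$left, strength_table$base, tolerance = 1e-12)
  for (cond in list(c(0.20, "w20"), c(0.40, "w40"), c(0.60, "w60"))) {
    wk <- apply_weakness(m, as.numeric(cond[1]))
    st <- muscle_strengths(wk)
    expect_lt(max(abs(st$left - strength_table[[cond[2]]])), 0.05)
    # right (non-paretic) limb untouched
    expect_identical(st$right, base$right)
  }
})

test_that("weakness scaling keeps muscle masses and all other parameters fixed", {
  m <- the_model()
  wk <- apply_weakness(m, 0.6)
  f0 <- hemigait:::model_flat(m)
  f1 <- hemigait:::model_flat(wk)
  expect_identical(f0$mmass, f1$mmass)
  expect_identical(f0$lopt, f1$lopt)
  expect_identical(f0$arms, f1$arms)
  expect_equal(f1$fmax[13:24], 0.4 * f0$fmax[13:24])
  expect_identical(f1$fmax[1:12], f0$fmax[1:12])
  # zero weakness is the identity
  expect_identical(hemigait:::model_flat(apply_weakness(m, 0)), f0)
})

test_that("weakness argument validation", {
  m <- the_model()
  expect_error(apply_weakness(m, 1.0))
  expect_error(apply_weakness(m, -0.1))
  expect_error(apply_weakness(m, NA_real_))
})

test_that("models survive serialization (external pointers rebuilt lazily)", {
  m <- apply_weakness(the_model(), 0.2)
  f <- tempfile(fileext = ".rds")
  saveRDS(m, f)
  m2 <- readRDS(f)
  expect_identical(hemigait:::model_flat(m), hemigait:::model_flat(m2))
  # the pointer cache is rebuilt on demand after deserialization
  expect_silent(contact_forces(m2, c(0, 0.95, rep(0, 9))))
  unlink(f)
})
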