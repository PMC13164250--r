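test_that("spec validation rejects impossible designs", {
  expect_error(cohort_spec(n_per_group = c(noDM = 0, PreDM = 5, T2DM = 5)), "positive")
  expect_error(cohort_spec(noise_sd = -1), "negative")
  expect_error(cohort_spec(n_clusters = 500), "exceeds sample count")
  expect_error(cohort_spec(missing_low_rate = 1.5), "\\[0, 1\\]")
})

test_that("zero-noise cohort equals its deterministic mean structure", {
  spec <- small_spec(noise_sd = 0, missing_low_rate = 0,
                     missing_high_proteins = character(0),
                     batch_offsets = 0, n_bridge = 0)
  co <- generate_cohort(spec)
  expect_false(anyNA(co$npx$values))
  # reconstruct the planted mean structure from truth + clinical
  tr <- co$truth
  cl <- co$clinical
  n <- nrow(cl)
  expected <- matrix(rep(tr$baseline, each = n), n, spec$n_proteins,
                     dimnames = list(cl$sample_id, spec$proteins))
  for (k in seq_along(tr$cluster_blocks)) {
    members <- names(tr$cluster_label)[tr$cluster_label == k]
    expected[members, tr$cluster_blocks[[k]]] <-
      expected[members, tr$cluster_blocks[[k]]] + tr$cluster_shift
  }
  grp <- as.character(cl$glycemic_class)
  for (r in seq_len(nrow(tr$group_shift_table))) {
    pr <- tr$group_shift_table$protein[r]
    for (g in c("PreDM", "T2DM")) {
      expected[grp == g, pr] <- expected[grp == g, pr] + tr$group_shift_table[[g]][r]
    }
  }
  for (r in seq_len(nrow(tr$effect_table))) {
    cov <- cl[[tr$effect_table$covariate[r]]]
    centred <- cov - ave(cov, grp, FUN = mean)
    expected[, tr$effect_table$protein[r]] <-
      expected[, tr$effect_table$protein[r]] + tr$effect_table$slope[r] * centred
  }
  got <- co$npx$values
  rownames(got) <- co$npx$sample_id
  expect_equal(got[cl$sample_id, ], expected, tolerance = 1e-12)
})

test_that("identical seed and spec give bit-identical cohorts", {
  a <- generate_cohort(small_spec(seed = 5))
  b <- generate_cohort(small_spec(seed = 5))
  expect_identical(a$npx$values, b$npx$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c_ <- generate_cohort(small_spec(seed = 6))
  expect_false(identical(a$npx$values, c_$npx$values))
})

test_that("generated cohorts respect their own invariants", {
  for (s in 1:3) {
    co <- generate_cohort(small_spec(seed = s))
    expect_length(co$truth$cluster_label, nrow(co$clinical))
    expect_setequal(names(co$truth$batch_offsets), co$spec$proteins)
    # bridge samples appear exactly once per plate
    bridge <- co$npx$sample_id[co$npx$is_bridge]
    tab <- table(co$npx$sample_id[co$npx$is_bridge], co$npx$plate[co$npx$is_bridge])
    expect_true(all(tab %in% 0:1))
    expect_equal(length(unique(bridge)), co$spec$n_bridge)
    # clinical levels restricted
    expect_true(all(co$clinical$glycemic_class %in% c("noDM", "PreDM", "T2DM")))
    expect_true(all(co$clinical$FPG[co$clinical$glycemic_class == "PreDM"] >= 110))
    expect_true(all(co$clinical$FPG[co$clinical$glycemic_class == "PreDM"] < 126))
  }
})

test_that("fixtures round-trip through the CSV dialects", {
  dir <- withr::local_tempdir()
  spec <- small_spec(seed = 3)
  paths <- write_fixture(spec, dir)
  expect_true(all(file.exists(paths)))
  m <- read_npx_wide(paths[["npx"]])
  co <- generate_cohort(spec)
  expect_equal(nrow(m$values), nrow(co$npx$values))
  # values and mask identical after round trip (row order may differ)
  key <- function(x) order(x$sample_id, x$plate)
  expect_equal(m$values[key(m), ], co$npx$values[key(co$npx), ], tolerance = 1e-12)
  expect_identical(is.na(m$values[key(m), ]), is.na(co$npx$values[key(co$npx), ]))
  cl <- read_clinical(paths[["clinical"]])
  expect_equal(nrow(cl), nrow(co$clinical))
  # a second write of the same spec is byte-stable
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture(spec, dir2)
  expect_identical(unname(tools::md5sum(paths[["npx"]])),
                   unname(tools::md5sum(paths2[["npx"]])))
  expect_error(write_fixture(cohort_spec(n_per_group = c(0, 0, 0)), dir), "positive")
})
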