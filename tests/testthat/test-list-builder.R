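test_that("catalog filtering applies the familiarity thresholds", {
  cat_df <- tibble::tibble(
    item_id = sprintf("w%d", 1:5),
    zipf_us = c(1.9, 2.0, 3.6, 4.0, 4.0),
    zipf_it = c(3, 3, 3, 3, 3),
    n_exemplars = c(150, 150, 150, 99, 100))
  out <- filter_catalog(cat_df, quiet = TRUE)
  # zipf_us exactly 2 is retained ("lower than 2" excludes), 99 exemplars is not
  expect_identical(out$item_id, c("w2", "w3", "w5"))
  expect_identical(nrow(filter_catalog(cat_df[0, ], quiet = TRUE)), 0L)
  expect_message(filter_catalog(cat_df), "retained")
})

test_that("partition_space assigns every item to k nonempty clusters", {
  run <- default_run()
  cl <- partition_space(run$spaces$vision, 12L, seed = 2L)
  expect_length(cl, 1687L)
  expect_setequal(unique(cl), 1:12)
  expect_identical(cl, partition_space(run$spaces$vision, 12L, seed = 2L))

  sp <- toy_space(n = 5L)
  expect_identical(unname(partition_space(sp, 1L, seed = 1L)), rep(1L, 5L))
  expect_error(partition_space(sp, 6L, seed = 1L), class = "drm_precondition_error")
})

test_that("partition_space matches the exhaustive best 2-partition on separated blobs", {
  withr::with_seed(14, {
    n <- 12L
    blob <- rbind(matrix(rnorm(n / 2 * 2, mean = c(4, 0), sd = 0.3), ncol = 2, byrow = TRUE),
                  matrix(rnorm(n / 2 * 2, mean = c(0, 4), sd = 0.3), ncol = 2, byrow = TRUE))
    sp <- embedding_space(blob, sprintf("b%02d", 1:n))
  })
  unit <- unclass(sp) / sqrt(rowSums(unclass(sp)^2))

  # oracle: enumerate all nonempty bipartitions, minimize within-cluster
  # squared distance to the cluster mean on the unit sphere
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(mask))[1:n]
    obj <- sum(vapply(0:1, function(g) {
      m <- unit[grp == g, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
    if (obj < best_obj) { best_obj <- obj; best <- grp }
  }
  got <- partition_space(sp, 2L, seed = 5L)
  agree <- max(mean((got - 1L) == best), mean((got - 1L) == (1L - best)))
  expect_equal(agree, 1)
})

test_that("build_lists satisfies every structural invariant across seeds", {
  run <- default_run()
  for (seed in c(11L, 57L, 203L)) {
    lists <- build_lists(run$spaces$vision, list_config(seed = seed))
    expect_length(lists, 12L)
    assigned <- character(0)
    for (l in lists) {
      expect_length(l$studied, 30L)
      expect_length(l$targets, 10L)
      expect_length(l$lures_close, 10L)
      expect_length(l$lures_far, 10L)
      expect_true(all(l$targets %in% l$studied))
      lures <- c(l$lures_close, l$lures_far)
      expect_length(intersect(l$studied, lures), 0L)
      expect_length(intersect(l$lures_close, l$lures_far), 0L)
      expect_length(unique(c(l$targets, lures)), 30L)  # recognition set
      assigned <- c(assigned, l$studied, lures)
    }
    expect_length(unique(assigned), 12L * 50L)  # cross-list disjointness
  }
})

test_that("close lures exceed far lures in vision similarity for every seed", {
  run <- default_run()
  for (seed in c(31L, 32L, 33L, 34L, 35L)) {
    lists <- build_lists(run$spaces$vision, list_config(seed = seed))
    tab <- similarity_table(lists, run$spaces$vision, run$spaces$language)
    for (id in unique(tab$list_id)) {
      i <- tab$list_id == id
      expect_gt(mean(tab$sim_vision[i & tab$origin == "close"]),
                mean(tab$sim_vision[i & tab$origin == "far"]))
    }
  }
})

test_that("build_lists is deterministic and serializes byte-identically", {
  run <- default_run()
  cfg <- list_config(seed = 99L)
  l1 <- build_lists(run$spaces$vision, cfg)
  l2 <- build_lists(run$spaces$vision, cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_lists(l1, f1); write_lists(l2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_lists(f1), l1)
})

test_that("build_lists reports insufficient capacity", {
  sp <- toy_space(n = 30L, d = 4L)
  expect_error(build_lists(sp, list_config(k_lists = 2L, close_size = 10L,
                                           far_size = 10L, n_studied = 6L,
                                           n_targets = 2L, n_lure_close = 2L,
                                           n_lure_far = 2L, seed = 1L)),
               class = "drm_capacity_error")
  expect_error(list_config(n_studied = 45L, n_lure_close = 10L, close_size = 50L),
               class = "drm_precondition_error")
})

test_that("similarity_table rows equal the centroid-similarity oracle", {
  run <- default_run()
  tab <- run$tab
  expect_identical(nrow(tab), 240L)
  by_list <- setNames(run$lists, vapply(run$lists, `[[`, integer(1), "list_id"))
  withr::with_seed(6, idx <- sample(nrow(tab), 25L))
  for (i in idx) {
    l <- by_list[[as.character(tab$list_id[i])]]
    expect_equal(tab$sim_vision[i],
                 centroid_similarity(tab$item_id[i], l$studied, run$spaces$vision),
                 tolerance = 1e-10)
    expect_equal(tab$sim_language[i],
                 centroid_similarity(tab$item_id[i], l$studied, run$spaces$language),
                 tolerance = 1e-10)
  }
  # target-inclusive variant covers the full recognition set
  tab360 <- similarity_table(run$lists, run$spaces$vision, run$spaces$language,
                             include_targets = TRUE)
  expect_identical(nrow(tab360), 360L)
  expect_identical(sum(tab360$origin == "target"), 120L)

  truncated <- embedding_space(unclass(run$spaces$vision)[1:100, ])
  expect_error(similarity_table(run$lists, truncated, run$spaces$language),
               class = "drm_lookup_error")
})

test_that("cross_modal_correlation is a Spearman correlation with guards", {
  run <- default_run()
  tab <- run$tab
  same <- tab
  same$sim_language <- same$sim_vision
  expect_equal(cross_modal_correlation(same)$rho, 1)

  got <- cross_modal_correlation(tab)
  oracle <- cor(tab$sim_vision, tab$sim_language, method = "spearman")
  expect_equal(got$rho, oracle)
  expect_identical(got$n, 240L)

  # Monte-Carlo null: independent columns stay near zero
  withr::with_seed(77, {
    null_ok <- vapply(1:100, function(i) {
      t2 <- tab
      t2$sim_vision <- rnorm(240)
      t2$sim_language <- rnorm(240)
      abs(cross_modal_correlation(t2)$rho) < 0.15
    }, logical(1))
  })
  expect_gte(mean(null_ok), 0.95)

  const <- tab
  const$sim_vision <- 0.5
  expect_error(cross_modal_correlation(const), class = "drm_degenerate_error")
  expect_error(cross_modal_correlation(tab[1:2, ]), class = "drm_precondition_error")
})

test_that("rescale_unit is an order-preserving idempotent affine map", {
  expect_equal(rescale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  withr::with_seed(5, x <- rnorm(50))
  y <- rescale_unit(x)
  expect_equal(rescale_unit(y), y)
  expect_identical(order(y), order(x))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(rescale_unit(rep(1, 5)), class = "drm_degenerate_error")
  expect_error(rescale_unit(3), class = "drm_precondition_error")
})
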