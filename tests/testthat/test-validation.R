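stage_tab <- data.frame(stage_id = c("old", "mid", "young"),
                        t_old = c(160, 149, 139),
                        t_young = c(149, 139, 129))

mask_for <- function() {
  b <- flat_bathymetry(1, 4000)
  b$values[80:120, 100:200] <- 50
  build_shallow_mask(b)
}

test_that("fossil age binning follows the strict majority-overlap rule", {
  mask <- mask_for()
  masks <- list(old = mask, mid = mask, young = mask)
  occ <- occurrence_set(
    lon = c(10, 20, 30, 40, 50),
    lat = c(5, 6, 7, 8, 9),
    age_min = c(140, 139, 135, 130, 140),
    age_max = c(150, 159, 135, 160, 150))
  # a malformed interval (min > max) can arrive via raw input tables
  occ$age_min[5] <- 150; occ$age_max[5] <- 140
  # record 1: 140-150 vs stage 149-139: overlap 9/10 = 90% -> assigned
  # record 2: 139-159 splits 50/50 between old and mid -> excluded
  # record 3: point age 135 inside "young" (139-129) -> assigned
  # record 4: 130-160 spans all three, no stage >50% -> excluded
  # record 5: malformed (min > max) -> rejected
  out <- bin_fossils(occ, stage_tab, masks)
  expect_equal(out$mid$n_records, 1)
  expect_equal(out$old$n_records, 0)
  expect_equal(out$young$n_records, 1)
  exc <- attr(out, "excluded")
  expect_setequal(exc$index, c(2, 4, 5))
  expect_true("malformed interval" %in% exc$reason)
})

test_that("fossil cells are deduplicated per stage with counts", {
  mask <- mask_for()
  occ <- occurrence_set(lon = c(10.2, 10.7, 11.4), lat = c(5.1, 5.6, 5.2),
                        age_min = 140, age_max = 150)
  out <- bin_fossils(occ, stage_tab, list(old = mask, mid = mask, young = mask))
  expect_equal(out$mid$n_records, 3)
  expect_equal(nrow(out$mid$cells), 2)
  expect_equal(sum(out$mid$cells$count), 3)
})

test_that("predictive success counts fossil cells on suitable cells", {
  mask <- mask_for()
  g <- lat_lon_grid(1)
  g$values[mask$values] <- 0
  g$values[100, 150] <- 1
  g$values[100, 160] <- 1
  bin <- binary_map(g, 0.5, stage_id = "s")
  fossils <- data.frame(row = c(100, 100, 100), col = c(150, 160, 170))
  expect_equal(predictive_success(fossils, bin), 100 * 2 / 3)
  expect_warning(
    expect_true(is.na(predictive_success(fossils[0, ], bin))), "no fossil")
})

test_that("the queen buffer counts diagonal and dateline neighbours", {
  g <- lat_lon_grid(1)
  g$values[] <- 0
  g$values[100, 150] <- 1
  bin <- binary_map(g, 0.5)
  diag_fossil <- data.frame(row = 101, col = 151)
  expect_equal(predictive_success(diag_fossil, bin, buffer = 0), 0)
  expect_equal(predictive_success(diag_fossil, bin, buffer = 1), 100)
  # suitable cell just west of the dateline, fossil just east of it
  g2 <- lat_lon_grid(1)
  g2$values[] <- 0
  g2$values[90, 360] <- 1
  bin2 <- binary_map(g2, 0.5)
  wrap_fossil <- data.frame(row = 90, col = 1)
  expect_equal(predictive_success(wrap_fossil, bin2, buffer = 0), 0)
  expect_equal(predictive_success(wrap_fossil, bin2, buffer = 1), 100)
  # buffered success never falls below unbuffered success
  m <- study_model()
  w <- study_world()
  bin3 <- binary_map(m$sm$median, m$ltp)
  expect_gte(predictive_success(w$presences, bin3, buffer = 1),
             predictive_success(w$presences, bin3, buffer = 0))
})

test_that("random-point nulls hit the degenerate extremes exactly", {
  mask <- mask_for()
  all_suit <- binary_map({g <- lat_lon_grid(1); g$values[] <- 1; g}, 0.5)
  none_suit <- binary_map({g <- lat_lon_grid(1); g$values[] <- 0; g}, 0.5)
  r1 <- random_null(mask, all_suit, n_points = 7, n_sets = 50, seed = 2)
  expect_true(all(r1$pct == 100))
  r0 <- random_null(mask, none_suit, n_points = 7, n_sets = 50, seed = 2)
  expect_true(all(r0$pct == 0))
})

test_that("the null mean converges to the suitable fraction of the mask", {
  mask <- mask_for()
  cells <- mask_cells(mask)
  set.seed(10)
  suit_idx <- sample(nrow(cells), round(0.3 * nrow(cells)))
  g <- lat_lon_grid(1)
  g$values[] <- 0
  g$values[cbind(cells$row[suit_idx], cells$col[suit_idx])] <- 1
  bin <- binary_map(g, 0.5)
  f <- length(suit_idx) / nrow(cells)
  n_points <- 15; n_sets <- 1000
  r <- random_null(mask, bin, n_points = n_points, n_sets = n_sets, seed = 4)
  se <- 100 * sqrt(f * (1 - f) / (n_points * n_sets))
  expect_lt(abs(r$mean - 100 * f), 3 * se)
  expect_true(r$lo <= r$mean && r$mean <= r$hi)
})

test_that("signed-rank p-values match exhaustive enumeration and stats::wilcox.test", {
  set.seed(6)
  for (rep in 1:10) {
    x <- round(rnorm(8, 50, 10), 3)
    mu <- 55
    for (alt in c("less", "greater")) {
      ours <- wilcoxon_one_sample(x, mu, alternative = alt)
      expect_true(ours$exact)
      expect_equal(ours$p_value, signed_rank_p_enum(x, mu, alt))
      ref <- stats::wilcox.test(x, mu = mu, alternative = alt)
      expect_equal(ours$p_value, unname(ref$p.value))
    }
  }
  # large tied sample: tie-corrected normal approximation tracks wilcox.test
  set.seed(7)
  big <- round(rnorm(300, 40, 5))
  ours <- wilcoxon_one_sample(big, 41, alternative = "less")
  ref <- stats::wilcox.test(big, mu = 41, alternative = "less",
                            exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-6)
  expect_error(wilcoxon_one_sample(c(1, 2, 3), 0), "at least 6")
  expect_error(wilcoxon_one_sample(rep(5, 10), 5), "zero")
})

test_that("null percentages far below the observed value give p < 0.001", {
  set.seed(9)
  null_pct <- runif(1000, 2, 10)
  p <- wilcoxon_one_sample(null_pct, 80, alternative = "less")$p_value
  expect_lt(p, 0.001)
  # symmetry around the observed value gives p near one half
  sym <- 50 + c(-(1:300), 1:300) * 0.05
  p2 <- wilcoxon_one_sample(sym, 50, alternative = "less")$p_value
  expect_gt(p2, 0.3); expect_lt(p2, 0.7)
})

test_that("Mann-Whitney U equals the brute-force pair count", {
  set.seed(12)
  for (rep in 1:10) {
    x <- round(runif(8), 2); y <- round(runif(8), 2)
    U_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(wilcoxon_two_sample(x, y)$statistic, U_brute)
  }
  # exact tail matches wilcox.test for untied small samples
  set.seed(13)
  x <- rnorm(9); y <- rnorm(12)
  ours <- wilcoxon_two_sample(x, y, alternative = "greater")
  ref <- stats::wilcox.test(x, y, alternative = "greater")
  expect_true(ours$exact)
  expect_equal(ours$p_value, unname(ref$p.value))
  # complete separation is overwhelming evidence
  expect_lt(wilcoxon_two_sample(rep(0.9, 30) + runif(30) / 100,
                                rep(0.1, 30) + runif(30) / 100)$p_value, 1e-6)
})

test_that("two-sample p-values are uniform under the null", {
  set.seed(15)
  ps <- replicate(500, {
    x <- rnorm(12); y <- rnorm(15)
    wilcoxon_two_sample(x, y, alternative = "greater")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stage validation detects truth-driven fossils against the null", {
  w <- study_world()
  m <- study_model()
  wc <- w$config
  st <- stage_table(wc)
  fstages <- lapply(2:wc$n_stages, function(i) c(w$stages[[i]], list(stage_index = i)))
  fossils <- make_fossils(wc, fstages)
  masks <- stats::setNames(lapply(w$stages, `[[`, "mask"), st$stage_id)
  binned <- bin_fossils(fossils, st, masks)
  rows <- list()
  for (i in 2:wc$n_stages) {
    sid <- st$stage_id[i]
    h <- hindcast(m$sm, w$stages[[i]]$climate, w$stages[[i]]$mask)
    bin <- binary_map(h$median, m$ltp, stage_id = sid)
    rows[[sid]] <- validate_stage(binned[[sid]]$cells, bin, h$median,
                                  w$stages[[i]]$mask, n_sets = 300,
                                  seed = 100 + i)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$n_fossils >= 10
  expect_true(any(ok))
  # fossils drawn from truth suitability are found far above the null
  expect_true(all(tab$pct[ok] > tab$null_mean[ok]))
  expect_true(all(tab$p1[ok] < 0.05))
  expect_true(all(tab$p2[ok] < 0.05))
  expect_true(all(tab$pct_buffer[ok] >= tab$pct[ok]))
})
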