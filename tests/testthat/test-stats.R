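test_that("Mann-Whitney exact branch reproduces enumeration on extreme samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 0.1)     # 2 extreme tables x 2 tails / C(6,3)
  expect_equal(res$method, "exact")
  expect_equal(res$p_raw, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("Mann-Whitney is symmetric and near 1 for identical samples", {
  x <- c(3, 9, 27); y <- c(1, 81, 243)
  expect_equal(mann_whitney_u(x, y)$p_raw, mann_whitney_u(y, x)$p_raw)
  same <- mann_whitney_u(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gte(same$p_raw, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact branch matches full enumeration across small sample sizes", {
  grid <- c(0.7, 1.9, 3.1, 4.6, 5.2, 8.8, 9.4, 12.5)
  set.seed(314)
  for (nx in 2:4) for (ny in 2:4) {
    for (rep in 1:3) {
      idx <- sample(length(grid), nx + ny)
      x <- grid[idx[1:nx]]; y <- grid[idx[(nx + 1):(nx + ny)]]
      for (alt in c("two_sided", "less", "greater")) {
        expect_equal(mann_whitney_u(x, y, alt)$p_raw, mw_enum_p(x, y, alt),
                     info = sprintf("nx=%d ny=%d alt=%s", nx, ny, alt))
      }
    }
  }
})

test_that("large or tied samples use the tie-corrected normal approximation", {
  set.seed(1)
  big <- mann_whitney_u(rnorm(15), rnorm(20))
  expect_equal(big$method, "normal_approx")
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 4, 5))
  expect_equal(tied$method, "normal_approx")
  expect_true(tied$p_raw > 0 && tied$p_raw <= 1)
})

test_that("sign test gives the exact binomial two-sided p with ties dropped", {
  expect_equal(sign_test(c(1.2, 1.1, 1.3), 1)$p_raw, 0.25)   # 2 * (1/2)^3
  expect_equal(sign_test(c(1.2, 0.9, 1.3), 1)$p_raw, 1)
  expect_equal(sign_test(rep(1.5, 5), 1)$p_raw, 0.0625)      # 2 * (1/2)^5
  tied <- sign_test(c(1, 1, 1.4), 1)
  expect_equal(tied$n_ties, 2)
  expect_equal(tied$n_used, 1)
  degen <- sign_test(c(1, 1, 1), 1)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_raw))
})

test_that("sign test is invariant under strictly monotone transforms", {
  v <- c(1.3, 0.8, 2.2, 1.7, 0.5)
  p0 <- sign_test(v, 1)$p_raw
  expect_equal(sign_test(log(v), 0)$p_raw, p0)
  expect_equal(sign_test(v^3, 1)$p_raw, p0)
})

test_that("Holm adjustment matches the step-down formula and printed family", {
  expect_equal(holm_adjust(c(0.25, 1, 1)), c(0.75, 1, 1))
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(numeric(0)), "empty")
})

test_that("Holm matches a hand oracle on random families and is permutation-stable", {
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(diff(adj[order(p)]) >= 0))   # monotone in sorted order
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])
    expect_true(all(adj >= p))
  }
})

test_that("fold changes normalize by loading and pair lanes within replicates", {
  tab <- data.frame(timepoint = rep(c("0", "15"), each = 2),
                    replicate = rep(1:2, 2),
                    band_density = c(100, 200, 200, 200),
                    loading_density = c(50, 100, 50, 100))
  fc <- densitometry_foldchange(tab, "0")
  expect_true(all(fc$fold_change[fc$timepoint == "0"] == 1))
  expect_equal(fc$fold_change[fc$timepoint == "15"], c(2, 1))
  # scaling band AND loading together leaves folds unchanged
  tab2 <- tab; tab2$band_density <- tab2$band_density * 7
  tab2$loading_density <- tab2$loading_density * 7
  expect_equal(densitometry_foldchange(tab2, "0")$fold_change, fc$fold_change)
  expect_error(densitometry_foldchange(tab[-1, ], "0"), "replicate 1")
  expect_error(densitometry_foldchange(tab, "99"), "control")
})

test_that("membrane-marker family reproduces uniform-sign vs mixed-sign pattern", {
  tab <- data.frame(
    timepoint = rep(c("0", "15", "30", "60"), each = 3),
    replicate = rep(1:3, 4),
    band_density = c(100, 100, 100,    # control
                     105, 95, 102,     # mixed
                     110, 104, 108,    # all above
                     99, 101, 95),     # mixed
    loading_density = 100)
  res <- membrane_marker_test(densitometry_foldchange(tab, "0"))
  expect_equal(res$p_adjusted[match(c("15", "30", "60"), res$timepoint)],
               c(1, 0.75, 1))
})

test_that("null densitometry with n=3 can never reach significance after Holm", {
  # minimum attainable sign-test p at n=3 is 0.25; with three timepoints the
  # Holm floor is 0.75, so alpha = 0.05 is unreachable by construction
  for (seed in 1:10) {
    dt <- generate_densitometry(c("0", "15", "30", "60"), 3, effect = 1,
                                noise_cv = 0.2, seed = seed)
    res <- membrane_marker_test(densitometry_foldchange(dt, "0"))
    expect_true(all(is.na(res$p_adjusted) | res$p_adjusted >= 0.75))
  }
})

test_that("timecourse tests compare each condition with control under Holm", {
  set.seed(5)
  vals <- list(ctrl = rnorm(15, 10), a = rnorm(15, 10), b = rnorm(15, 14))
  res <- timecourse_tests(vals, "ctrl")
  expect_equal(nrow(res), 2)
  expect_equal(res$method, rep("normal_approx", 2))
  expect_true(res$significant[res$condition == "b"])
  expect_false(res$significant[res$condition == "a"])
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_error(timecourse_tests(vals, "zzz"), "not among")
})
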