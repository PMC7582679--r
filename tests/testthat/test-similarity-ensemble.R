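# Similarity-ensemble scoring: Tanimoto, raw scores, background calibration,
# z-scores and extreme-value E-values.

test_that("tanimoto matches hand-counted set arithmetic", {
  expect_equal(tanimoto(bitvec(1:3), bitvec(1:3)), 1.0)
  expect_equal(tanimoto(bitvec(1:3), bitvec(4:6)), 0.0)
  # {1,2,3} vs {2,3,4}: intersection 2, union 4
  expect_equal(tanimoto(bitvec(1:3), bitvec(2:4)), 0.5)
  expect_equal(tanimoto(logical(16), logical(16)), 0.0)
  expect_error(tanimoto(bitvec(1, 8), bitvec(1, 16)), "length mismatch")
})

test_that("raw score truncates at the threshold on a hand-built 2x2 ensemble", {
  # pairwise Tanimotos by construction: (q1,r1)=0.8, (q1,r2)=0.3,
  # (q2,r1)=0.6, (q2,r2)=0.1; at threshold 0.57 only 0.8+0.6 survive.
  Q <- rbind(bitvec(1:10), bitvec(c(3:8, 21, 22)))
  R <- rbind(bitvec(1:8), bitvec(1:3))
  tc <- tanimoto_matrix(Q, R)
  expect_equal(as.numeric(tc), c(0.8, 0.6, 0.3, 0.1))
  rs <- raw_score(Q, R, 0.57)
  expect_equal(rs$raw, 1.4)
  expect_equal(rs$max_tc, 0.8)
  # threshold 0: the full pairwise sum
  expect_equal(raw_score(Q, R, 0)$raw, sum(tc))
  # threshold 1 with no identical pair
  expect_equal(raw_score(Q, R, 1)$raw, 0)
})

test_that("raw score equals the brute-force double loop on random small sets", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      Q <- random_fps(sample(1:5, 1))
      T <- random_fps(sample(1:5, 1))
      thr <- runif(1)
      rs <- raw_score(Q, T, thr)
      br <- brute_raw(Q, T, thr)
      expect_equal(rs$raw, br$raw)
      expect_equal(rs$max_tc, br$max_tc)
      # symmetry under equal thresholds
      expect_equal(raw_score(T, Q, thr)$raw, rs$raw)
    }
  })
})

test_that("background fitting is deterministic and self-consistent", {
  withr::with_seed(21, pool <- random_fps(80, bits = 128))
  sizes <- list(c(2, 2), c(2, 5), c(5, 5), c(5, 10))
  bg1 <- fit_background(pool, sizes, threshold = 0.3, n_samples = 60, seed = 9)
  bg2 <- fit_background(pool, sizes, threshold = 0.3, n_samples = 60, seed = 9)
  expect_identical(bg1$mean_coeffs, bg2$mean_coeffs)
  expect_identical(bg1$sd_coeffs, bg2$sd_coeffs)
  expect_true(all(tarfish:::bg_sd(bg1, seq(4, 50)) > 0))

  # Monte-Carlo oracle: fitted mean at nm = 25 close to a fresh empirical mean
  withr::with_seed(33, {
    fresh <- replicate(400, tarfish:::.sample_raw(pool, 5, 5, 0.3))
  })
  se <- sd(fresh) / sqrt(length(fresh))
  expect_lt(abs(tarfish:::bg_mean(bg1, 25) - mean(fresh)), 3 * se + 0.05 * mean(fresh))
})

test_that("degenerate-spread backgrounds fall back to a positive sd floor", {
  pool <- diag(32) > 0  # all pairwise Tanimotos are 0
  expect_warning(
    bg <- fit_background(pool, list(c(1, 1)), threshold = 1, n_samples = 50, seed = 2),
    "degenerate"
  )
  expect_equal(tarfish:::bg_mean(bg, 1), 0)
  expect_gt(tarfish:::bg_sd(bg, 1), 0)
})

test_that("z-scores of fresh random ensembles are standardized", {
  # a chemically structured decoy pool gives raw scores genuine spread at
  # the default operating threshold
  pool <- fingerprint_set(tarfish:::ob_canonical(generate_decoy_pool(100, seed = 7)))$circular
  sizes <- list(c(2, 4), c(4, 4), c(4, 8), c(8, 8))
  bg <- fit_background(pool, sizes, threshold = 0.57, n_samples = 120, seed = 17)
  zs <- withr::with_seed(99, {
    vapply(1:400, function(i) {
      sz <- sizes[[1 + (i - 1) %% length(sizes)]]
      raw <- tarfish:::.sample_raw(pool, sz[1], sz[2], 0.57)
      z_score(raw, sz[1], sz[2], bg)
    }, numeric(1))
  })
  expect_lt(abs(mean(zs)), 0.15)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("z-score is an exact standardization of the fitted background", {
  bg <- structure(list(tanimoto_threshold = 0.57, mean_coeffs = c(1, 0.5),
                       sd_coeffs = c(2, 0.5), nm_range = c(1, 100)),
                  class = "background_model")
  # raw equal to the mean -> 0; mean + sd -> 1
  mu <- tarfish:::bg_mean(bg, 20)
  s <- tarfish:::bg_sd(bg, 20)
  expect_equal(z_score(mu, 4, 5, bg), 0)
  expect_equal(z_score(mu + s, 4, 5, bg), 1)
  expect_message(z_score(mu, 20, 20, bg), "extrapolating")
})

test_that("E-values follow the Gumbel closed form and its limits", {
  gamma <- -digamma(1)
  expect_equal(e_value(0, 10), 10 * (1 - exp(-exp(-gamma))), tolerance = 1e-12)
  expect_equal(e_value(50, 10), 0, tolerance = 1e-10)
  expect_equal(e_value(-50, 10), 10)
  # monotone non-increasing in z; ordering is the reverse of the z ordering
  zgrid <- seq(-6, 6, by = 0.25)
  ev <- e_value(zgrid, 100)
  expect_true(all(diff(ev) <= 0))
  expect_error(e_value(0, 0), "n_comparisons")
})

test_that("background models survive a JSON round trip", {
  withr::with_seed(3, pool <- random_fps(60, bits = 128))
  bg <- fit_background(pool, list(c(2, 3), c(3, 4)), 0.3, n_samples = 50, seed = 4)
  path <- tempfile(fileext = ".json")
  write_background_model(bg, path)
  back <- read_background_model(path)
  expect_equal(back$mean_coeffs, bg$mean_coeffs)
  expect_equal(back$sd_coeffs, bg$sd_coeffs)
  expect_equal(back$tanimoto_threshold, bg$tanimoto_threshold)
  expect_equal(z_score(2, 2, 3, back), z_score(2, 2, 3, bg))
})

test_that("target prediction ranks self-similar references first", {
  pool <- fingerprint_set(tarfish:::ob_canonical(generate_decoy_pool(80, seed = 7)))$circular
  withr::with_seed(41, {
    query <- pool[sample.int(nrow(pool), 3), , drop = FALSE]
    refs <- c(
      list(target_ligand_set("SELF", query)),
      lapply(1:20, function(i) {
        target_ligand_set(sprintf("DEC%02d", i),
                          pool[sample.int(nrow(pool), 4), , drop = FALSE])
      })
    )
    bg <- fit_background(pool, list(c(3, 3), c(3, 4)), 0.57, n_samples = 60, seed = 6)
    preds <- predict_targets(query, refs, bg, e_cutoff = 1e-5)
  })
  expect_equal(preds$target_id[1], "SELF")
  expect_equal(nrow(preds), 21)
  expect_true(preds$predicted[preds$target_id == "SELF"])
  # e_cutoff = 0 flags nothing
  none <- predict_targets(pool[1:2, , drop = FALSE], refs, bg, e_cutoff = 0)
  expect_false(any(none$predicted))
  # kind/length mismatch is fatal
  expect_error(predict_targets(random_fps(1, bits = 64), refs, bg), "mismatch")
})
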