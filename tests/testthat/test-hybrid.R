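# Hybrid 2D/3D channel: conformer embedding, electroshape descriptors and
# the logistic fusion model.

test_that("conformer embedding is deterministic and charge-conserving", {
  c1 <- embed_conformer("CCCCC", seed = 1)
  c2 <- embed_conformer("CCCCC", seed = 1)
  expect_identical(c1$xyz, c2$xyz)
  expect_identical(c1$charge, c2$charge)
  # neutral alkane: Gasteiger charges sum to the total formal charge (0);
  # the mol2 text rounds per-atom charges to 4 decimals, so the bound is
  # n_atoms * 5e-5
  expect_lt(abs(sum(c1$charge)), length(c1$charge) * 5e-5)
  expect_null(embed_conformer("not_a_smiles$$"))
})

test_that("electroshape of a two-point geometry matches the closed form", {
  d <- 3
  conf <- list(xyz = rbind(c(0, 0, 0), c(d, 0, 0)), charge = c(0, 0))
  v <- as.numeric(electroshape(conf, charge_scale = 25))
  half <- d / 2
  expect_equal(v[1:3], c(half, 0, 0))              # centroid: both atoms at d/2
  expect_equal(v[4:6], c(half, half, 0))           # ref at atom 1: {0, d}
  expect_equal(v[7:9], c(half, half, 0))           # ref at atom 2: {d, 0}
  r45 <- sqrt(half^2 + 25^2)                       # charge-displaced centroids
  expect_equal(v[10:12], c(r45, 0, 0))
  expect_equal(v[13:15], c(r45, 0, 0))
})

test_that("electroshape is invariant under rigid rotation and translation", {
  conf <- embed_conformer("OCC(N)c1ccccc1")
  v1 <- electroshape(conf)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  conf2 <- conf
  conf2$xyz <- sweep(conf$xyz %*% t(R), 2, c(5, -3, 11), `+`)
  v2 <- electroshape(conf2)
  expect_lt(sum(abs(unclass(v1) - unclass(v2))), 1e-8)
  expect_equal(similarity_3d(v1, v2), 1.0, tolerance = 1e-9)
})

test_that("3D similarity is the bounded transform of the Manhattan distance", {
  a <- structure(rep(0, 15), class = "electroshape")
  b <- a
  b[1] <- 15  # mean absolute difference 1
  expect_equal(similarity_3d(a, a), 1.0)
  expect_equal(similarity_3d(a, b), 0.5)
  # strictly decreasing as the distance grows
  sims <- vapply(seq(0, 30, by = 5), function(delta) {
    bb <- a
    bb[1] <- delta
    similarity_3d(a, bb)
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("logistic training is deterministic and recovers planted signal", {
  withr::with_seed(8, {
    n <- 500
    null_df <- data.frame(s2d = runif(n), s3d = runif(n),
                          label = rbinom(n, 1, 0.5))
  })
  m0a <- train_hybrid(null_df, seed = 1)
  m0b <- train_hybrid(null_df, seed = 1)
  expect_identical(m0a$beta1, m0b$beta1)
  # labels independent of features: coefficients near zero
  expect_lt(abs(m0a$beta1), 0.5)
  expect_lt(abs(m0a$beta2), 0.5)

  withr::with_seed(9, {
    sig <- data.frame(s2d = runif(n), s3d = runif(n))
    # noisy threshold rule on s2d only
    sig$label <- as.integer(sig$s2d + rnorm(n, sd = 0.1) > 0.5)
  })
  m1 <- train_hybrid(sig, seed = 1)
  expect_gt(m1$beta1, 0)
  expect_gt(m1$beta1, abs(m1$beta2))
})

test_that("logistic fit matches a brute-force likelihood grid search", {
  withr::with_seed(14, {
    df <- data.frame(s2d = round(runif(20), 2), s3d = round(runif(20), 2))
    df$label <- as.integer(plogis(-1 + 3 * df$s2d + 1.5 * df$s3d) > runif(20))
  })
  if (length(unique(df$label)) < 2) df$label[1] <- 1 - df$label[1]
  m <- train_hybrid(df, seed = 0)
  loglik <- function(b) {
    eta <- b[1] + b[2] * df$s2d + b[3] * df$s3d
    sum(df$label * eta - log1p(exp(eta)))
  }
  # independent coarse-to-fine grid search over the coefficient cube
  center <- c(0, 0, 0)
  width <- 16
  for (round in 1:8) {
    grid <- expand.grid(b0 = center[1] + seq(-width, width, length.out = 9),
                        b1 = center[2] + seq(-width, width, length.out = 9),
                        b2 = center[3] + seq(-width, width, length.out = 9))
    ll <- apply(grid, 1, loglik)
    center <- as.numeric(grid[which.max(ll), ])
    width <- width / 4
  }
  expect_equal(m$beta0, center[1], tolerance = 0.01)
  expect_equal(m$beta1, center[2], tolerance = 0.01)
  expect_equal(m$beta2, center[3], tolerance = 0.01)
})

test_that("complete separation falls back to the ridge-penalized fit", {
  df <- data.frame(s2d = c(seq(0, 0.4, length.out = 10), seq(0.6, 1, length.out = 10)),
                   s3d = 0.5, label = rep(c(0, 1), each = 10))
  expect_message(m <- train_hybrid(df, seed = 0), "separation")
  expect_true(m$ridge)
  expect_true(is.finite(m$beta1))
  expect_gt(m$beta1, 0)
})

test_that("hybrid prediction behaves at the model's edge cases", {
  fps <- fingerprint_set(c(q = "Oc1ccc(CCC(=O)c2c(O)cc(O)cc2O)cc1",
                           r1 = "Oc1ccc(CCC(=O)c2c(O)cc(O)cc2O)cc1",
                           r2 = "CCCCCCCC"))
  es <- lapply(c("Oc1ccc(CCC(=O)c2c(O)cc(O)cc2O)cc1",
                 "Oc1ccc(CCC(=O)c2c(O)cc(O)cc2O)cc1", "CCCCCCCC"),
               function(s) electroshape(embed_conformer(s)))
  refs <- list(
    list(target_id = "MATCH", path_fps = fps$path[2, , drop = FALSE], es = es[2]),
    list(target_id = "OTHER", path_fps = fps$path[3, , drop = FALSE], es = es[3])
  )
  # all-zero coefficients: probability 1/2 everywhere
  m0 <- structure(list(beta0 = 0, beta1 = 0, beta2 = 0, fallback_beta = c(0, 0),
                       decision_threshold = 0.5, ridge = FALSE),
                  class = "hybrid_model")
  p0 <- predict_hybrid(fps$path[1, ], es[[1]], refs, m0)
  expect_equal(p0$probability, c(0.5, 0.5))

  # positive weights: the identical reference attains the maximum
  m1 <- structure(list(beta0 = -4, beta1 = 4, beta2 = 4, fallback_beta = c(-2, 4),
                       decision_threshold = 0.5, ridge = FALSE),
                  class = "hybrid_model")
  p1 <- predict_hybrid(fps$path[1, ], es[[1]], refs, m1)
  expect_equal(p1$target_id[1], "MATCH")
  expect_equal(p1$s2d[p1$target_id == "MATCH"], 1.0)

  # missing query 3D descriptor: 2D-only fallback with a message
  expect_message(p2 <- predict_hybrid(fps$path[1, ], NULL, refs, m1), "fallback")
  expect_true(all(is.na(p2$s3d)))
  expect_equal(p2$target_id[1], "MATCH")
})

test_that("hybrid classifier separates same-scaffold from random pairs", {
  # planted separable data: same-scaffold pairs score high s2d/s3d
  lib <- generate_library(fixture_spec(seed = 3, n_compounds = 14))
  dec <- generate_decoy_pool(14, seed = 4)
  all_smi <- tarfish:::ob_canonical(c(lib$smiles, dec))
  fps <- fingerprint_set(all_smi)
  n <- length(all_smi)
  same <- t(combn(1:14, 2))
  withr::with_seed(10, {
    diff_pairs <- cbind(sample(1:14, 60, replace = TRUE),
                        sample(15:n, 60, replace = TRUE))
  })
  pair_df <- function(pairs, label) {
    data.frame(
      s2d = vapply(seq_len(nrow(pairs)), function(i) {
        tanimoto(fps$path[pairs[i, 1], ], fps$path[pairs[i, 2], ])
      }, numeric(1)),
      s3d = 0.5, label = label)
  }
  df <- rbind(pair_df(same, 1), pair_df(diff_pairs, 0))
  withr::with_seed(20, idx <- sample.int(nrow(df)))
  train <- df[idx[1:100], ]
  test <- df[idx[101:nrow(df)], ]
  m <- suppressMessages(train_hybrid(train, seed = 1))
  pred <- plogis(m$beta0 + m$beta1 * test$s2d + m$beta2 * test$s3d) >= 0.5
  expect_gt(mean(pred == (test$label == 1)), 0.9)
})
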