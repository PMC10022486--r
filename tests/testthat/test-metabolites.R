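test_that("cascade k-means finds the planted cluster number with clean labels", {
  for (seed in 1:5) {
    sim <- simulate_metabolites(n_clusters = 3, per_cluster = 20,
                                noise_sd = 0.1, seed = seed)
    cp <- kmeans_cascade(sim$metab, k_range = c(2, 6), seed = seed + 100)
    expect_equal(cp$k, 3L)
    # one planted cluster per recovered label (perfect up to relabeling)
    tab <- table(sim$labels, cp$labels)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("cluster number selection is invariant to row duplication", {
  sim <- simulate_metabolites(n_clusters = 3, per_cluster = 15,
                              noise_sd = 0.1, seed = 61)
  dup <- rbind(sim$metab, sim$metab)
  rownames(dup) <- make.unique(rownames(dup))
  k1 <- kmeans_cascade(sim$metab, k_range = c(2, 6), seed = 7)$k
  k2 <- kmeans_cascade(dup, k_range = c(2, 6), seed = 7)$k
  expect_equal(k1, k2)
})

test_that("degenerate k ranges and oversized k are handled", {
  sim <- simulate_metabolites(seed = 62)
  cp <- kmeans_cascade(sim$metab, k_range = c(2, 2), seed = 3)
  expect_equal(cp$k, 2L)
  expect_error(kmeans_cascade(sim$metab[1:5, ], k_range = c(2, 10)),
               "must be <")
})

test_that("accumulation rate matches the finite-difference fixture", {
  v <- accumulation_rate(rbind(m = c(2, 5, 11, 23)), c(45, 60, 75, 90))
  expect_equal(as.numeric(v), c(0.2, 0.4, 0.8))
  expect_equal(colnames(v), c("45-60", "60-75", "75-90"))

  expect_equal(as.numeric(accumulation_rate(rbind(c(7, 7, 7)), c(1, 2, 4))),
               c(0, 0))
  expect_equal(dim(accumulation_rate(rbind(c(1, 3)), c(0, 10))), c(1L, 1L))
  expect_error(accumulation_rate(rbind(c(1, 2, 3)), c(45, 45, 90)),
               "strictly increasing")
  expect_error(accumulation_rate(rbind(c(1, 2, 3)), c(45, 60)), "one sampling")
})

test_that("accumulation rate is linear and time-unit equivariant", {
  set.seed(63)
  m1 <- matrix(rnorm(12), 3, 4)
  m2 <- matrix(rnorm(12), 3, 4)
  tt <- c(10, 20, 40, 80)
  lhs <- accumulation_rate(2 * m1 + 5 * m2, tt)
  rhs <- 2 * accumulation_rate(m1, tt) + 5 * accumulation_rate(m2, tt)
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  expect_equal(unname(accumulation_rate(m1, 3 * tt)),
               unname(accumulation_rate(m1, tt) / 3), tolerance = 1e-12)
})

test_that("integration grid averages member correlations as stated", {
  prof <- c(1, 3, 2, 5)
  eig <- cbind(M1 = as.numeric(scale(prof)))
  rownames(eig) <- paste0("T", 1:4)
  # every member equals the eigengene profile -> mean r = 1
  metab <- rbind(a = prof, b = 2 * prof + 1, c = prof)
  colnames(metab) <- paste0("T", 1:4)
  ic <- correlate_modules_metabolites(eig, metab, c(a = 1, b = 1, c = 1))
  expect_equal(unname(ic$mean_r["M1", "1"]), 1, tolerance = 1e-9)

  # a perfectly anti-correlated pair averages to zero
  metab2 <- rbind(up = prof, down = -prof)
  colnames(metab2) <- paste0("T", 1:4)
  ic2 <- correlate_modules_metabolites(eig, metab2, c(up = 1, down = 1))
  expect_equal(unname(ic2$mean_r["M1", "1"]), 0, tolerance = 1e-9)

  # Pearson invariance to affine transforms of either side
  ic3 <- correlate_modules_metabolites(eig * 3 - 1, metab, c(a = 1, b = 1, c = 1))
  expect_equal(ic3$mean_r, ic$mean_r, tolerance = 1e-9)

  expect_error(
    correlate_modules_metabolites(eig[1:2, , drop = FALSE], metab[, 1:2],
                                  c(a = 1, b = 1, c = 1)),
    "fewer than 3")
})

test_that("a metabolite cluster locked to a module latent tops the grid", {
  # treat the 8 samples as a fruit developmental series sampled at 8 times
  sim <- simulate_expression(n_samples = 8, seed = 64)
  res <- coexpression_pipeline(sim$expr, traits = sim$traits)
  eig <- res$eigengenes
  times <- seq(15, 85, by = 10)
  # lock metabolite cluster 1 to one planted module latent, then identify
  # which recovered module carries that latent
  ms <- simulate_metabolites(times = times,
                             link = sim$latents[, "M4"], seed = 65)
  ic <- correlate_modules_metabolites(eig, ms$metab, ms$labels)
  r_latent <- cor(res$eigengenes, sim$latents[, "M4"])
  linked_module <- rownames(r_latent)[which.max(abs(r_latent))]
  expect_equal(ic$top$module, linked_module)
  expect_equal(ic$top$cluster, "1")
  expect_gte(ic$top$mean_r, 0.8)

  # the same holds on accumulation rates
  mrate <- accumulation_rate(ms$metab, ms$times)
  erate <- t(accumulation_rate(t(eig), ms$times))
  icr <- correlate_modules_metabolites(erate, mrate, ms$labels)
  expect_equal(icr$top$cluster, "1")
})

test_that("anthocyanin quantification follows the absorbance formula", {
  expect_equal(anthocyanin_value(0.5, 0.2, 1), 0.45)
  expect_equal(anthocyanin_value(0.25 * 0.8, 0.8, 2), 0)
  expect_equal(anthocyanin_value(c(0.5, 0.3), c(0.2, 0.0), c(1, 2)),
               c(0.45, 0.15))
  expect_error(anthocyanin_value(0.5, 0.2, 0), "> 0")
  expect_error(anthocyanin_value(-0.1, 0.2, 1), ">= 0")
})
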