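# Brute-force TOM oracle: triple loop straight from the definition.
tom_oracle <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j)
      shared <- shared + adj[i, u] * adj[u, j]
    tom[i, j] <- (shared + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

test_that("TOM matches the brute-force oracle on small networks", {
  set.seed(51)
  for (n in 2:15) {
    a <- random_adjacency(n)
    expect_equal(tom_from_adjacency(a), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("TOM degenerate cases have closed forms", {
  # two genes, a_12 = 1: TOM_12 = (0 + 1)/(1 + 1 - 1) = 1
  a <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(tom_from_adjacency(a)[1, 2], 1)
  # empty network: off-diagonal 0
  z <- matrix(0, 4, 4)
  expect_equal(tom_from_adjacency(z), diag(4))
  # entries bounded in [0, 1], symmetric
  set.seed(52)
  a <- random_adjacency(10)
  tom <- tom_from_adjacency(a)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom), tolerance = 1e-12)
})

test_that("soft-threshold scan is deterministic and honors its invariant", {
  sim <- simulate_expression(seed = 53)
  s1 <- pick_soft_threshold(sim$expr)
  s2 <- pick_soft_threshold(sim$expr)
  expect_identical(s1, s2)
  # singleton power list
  expect_equal(pick_soft_threshold(sim$expr, powers = 8)$selected_power, 8)
  # selected is smallest power reaching the cut, else the argmax
  hit <- which(s1$r2 >= 0.8)
  if (length(hit)) {
    expect_equal(s1$selected_power, s1$powers[min(hit)])
  } else {
    expect_equal(s1$selected_power, s1$powers[which.max(s1$r2)])
  }
  expect_error(pick_soft_threshold(matrix(1, 25, 5)), "genes")
})

test_that("pure noise exercises the fallback selection path", {
  sim <- simulate_expression(n_modules = 0, n_background = 100, seed = 54)
  s <- pick_soft_threshold(sim$expr, powers = 1:10, r2_cut = 0.999)
  expect_equal(s$selected_power, s$powers[which.max(s$r2)])
})

test_that("planted modules are recovered with high ARI", {
  sim <- simulate_expression(seed = 55) # 4 modules x 50 genes + 100 noise
  tom <- tom_similarity(sim$expr, 8)
  part <- cut_modules(tom, sim$expr)
  expect_gte(ari(part$labels, sim$labels), 0.9)
  expect_equal(length(setdiff(unique(part$labels), "unassigned")), 4L)
})

test_that("pure noise leaves most genes unassigned", {
  sim <- simulate_expression(n_modules = 0, n_background = 300, seed = 56)
  tom <- tom_similarity(sim$expr, 8)
  part <- cut_modules(tom, sim$expr)
  expect_gte(mean(part$labels == "unassigned"), 0.5)
})

test_that("module size floor is enforced", {
  sim <- simulate_expression(seed = 57)
  tom <- tom_similarity(sim$expr, 8)
  part <- cut_modules(tom, sim$expr, min_module_size = nrow(sim$expr) + 1L)
  expect_true(all(part$labels == "unassigned"))
  expect_error(cut_modules(tom, sim$expr, min_module_size = 1L), ">= 2")
})

test_that("eigengenes summarize modules with aligned sign and unit variance", {
  # identical genes: eigengene equals the shared standardized profile
  profile <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expr <- rbind(g1 = profile, g2 = profile, g3 = profile)
  colnames(expr) <- paste0("s", 1:8)
  labels <- c(g1 = "M1", g2 = "M1", g3 = "M1")
  e <- module_eigengenes(expr, labels)
  expect_equal(as.numeric(e[, "M1"]), as.numeric(scale(profile)),
               tolerance = 1e-9)
  expect_equal(sd(e[, "M1"]), 1, tolerance = 1e-9)

  # half the genes negated: sign alignment keeps positive mean correlation
  expr2 <- rbind(g1 = profile, g2 = profile, g3 = -profile)
  colnames(expr2) <- paste0("s", 1:8)
  labels2 <- c(g1 = "M1", g2 = "M1", g3 = "M1")
  e2 <- module_eigengenes(expr2, labels2)
  expect_gte(cor(e2[, "M1"], colMeans(t(scale(t(expr2))))), 0)

  # planted fixture: eigengene tracks the planted latent profile
  sim <- simulate_expression(seed = 58)
  e3 <- module_eigengenes(sim$expr, sim$labels)
  for (m in colnames(sim$latents))
    expect_gte(abs(cor(e3[, m], sim$latents[, m])), 0.95)
})

test_that("module-trait correlation applies the |r| > 0.8, p < 0.001 rule", {
  set.seed(59)
  n <- 12
  trait <- c(rep(1, 4), rep(0, 8))
  eig <- cbind(M1 = as.numeric(scale(trait)),
               M2 = as.numeric(scale(rnorm(n))))
  traits <- cbind(t1 = trait, t2 = rep(1, n))
  mt <- module_trait_correlation(eig, traits)
  expect_equal(mt$r["M1", "t1"], 1, tolerance = 1e-9)
  expect_true(mt$significant["M1", "t1"])
  expect_false(mt$significant["M2", "t1"])
  # constant trait: undefined, flagged not significant
  expect_true(is.na(mt$r["M1", "t2"]))
  expect_false(mt$significant["M1", "t2"])
  expect_error(module_trait_correlation(eig[1:2, ], traits[1:2, ]), ">= 3")
})

test_that("the full network stage is deterministic", {
  sim <- simulate_expression(seed = 60)
  r1 <- coexpression_pipeline(sim$expr, traits = sim$traits)
  r2 <- coexpression_pipeline(sim$expr, traits = sim$traits)
  expect_identical(r1$partition$labels, r2$partition$labels)
  expect_identical(r1$trait_cor$r, r2$trait_cor$r)
})
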