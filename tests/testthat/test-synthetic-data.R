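test_that("study designs validate their invariants", {
  expect_error(study_design(days = c(1, 5, 5)), "strictly increasing")
  expect_error(study_design(mice_per_day = 1), ">= 2")
  expect_error(study_design(litters = 0), "litters")
  expect_error(study_design(library_size_range = c(100, 10)), "increasing pairs")
  d <- study_design(mice_per_day = c(3, 3, 4, 3, 4))
  expect_identical(d$mice_per_day, c(3L, 3L, 4L, 3L, 4L))
})

test_that("effect specs validate compositions, dispersions and edges", {
  tt <- matrix(0.6, 2, 5, dimnames = list(c("A", "B"), c(1, 5, 8, 14, 25)))
  expect_error(effect_spec(taxon_trajectories = tt), "sum to <= 1")
  expect_error(effect_spec(noise = list(taxon_concentration = -1)), "> 0")
  pe <- data.frame(feature_a = "x", feature_b = "y", rho = 1)
  expect_error(effect_spec(planted_edges = pe), "rho")
  # trajectory/design dimension mismatch is a validation error
  expect_error(simulate_study(study_design(days = c(1, 8)), effect_spec()),
               "day columns")
})

test_that("the same (design, effects, seed) triple is bit-reproducible", {
  d <- study_design(seed = 9, mice_per_day = 2)
  s1 <- simulate_study(d, effect_spec())
  s2 <- simulate_study(d, effect_spec())
  expect_identical(s1$taxa$counts, s2$taxa$counts)
  expect_identical(s1$otus$counts, s2$otus$counts)
  expect_identical(s1$functions$counts, s2$functions$counts)
  expect_identical(s1$host_markers, s2$host_markers)
  expect_identical(s1$flagellin, s2$flagellin)
  # written artifacts are byte-identical too
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  f1 <- write_simulation(s1, o1); f2 <- write_simulation(s2, o2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), label = k)
  }
  # a different seed gives different data
  s3 <- simulate_study(study_design(seed = 10, mice_per_day = 2), effect_spec())
  expect_false(identical(s1$taxa$counts, s3$taxa$counts))
})

test_that("count tables are integer, non-negative, with totals in range", {
  d <- study_design(seed = 4)
  sim <- simulate_study(d, effect_spec())
  for (nm in c("taxa", "otus", "functions")) {
    tab <- sim[[nm]]
    expect_true(all(tab$counts >= 0))
    expect_true(all(tab$counts == round(tab$counts)))
  }
  rng <- list(taxa = d$library_size_range, otus = d$otu_library_size_range,
              functions = d$function_library_size_range)
  for (nm in names(rng)) {
    tot <- colSums(sim[[nm]]$counts)
    expect_true(all(tot >= rng[[nm]][1] & tot <= rng[[nm]][2]))
  }
  expect_identical(ncol(sim$taxa$counts), nrow(sim$samples))
})

test_that("dominant orders carry ~95% of healthy rRNA reads", {
  sim <- simulate_study(study_design(seed = 42), effect_spec())
  rel <- relative_abundance(aggregate_by_rank(sim$taxa, "order"))
  day1 <- sim$samples$day == 1
  dom <- colSums(rel[c("Clostridiales", "Bacteroidales"), day1, drop = FALSE])
  expect_true(all(dom > 0.90 & dom < 0.99))
  expect_gt(mean(dom), 0.92)
  expect_lt(mean(dom), 0.97)
})

test_that("flat effects leave no recoverable day structure", {
  sim <- simulate_study(study_design(seed = 77), flat_effects())
  days <- sim$samples$day
  ct <- aggregate_categories(sim$functions, sim$hierarchy, level = 1)
  res <- category_group_test(ct, days, 1, 8)
  # no planted effect: Motility day contrast should not be overwhelming
  expect_gt(res$p[res$category == "Motility and Chemotaxis"], 0.001)
  pch <- percent_change_vs_baseline(ct, days, 1)
  expect_lt(max(abs(pch["Motility and Chemotaxis", ])), 15)
})

test_that("planted latent correlations match rho in oversampled validation", {
  eff <- effect_spec()
  sim <- simulate_study(study_design(seed = 55, mice_per_day = 50), eff)
  z <- sim$truth$latent
  expect_gte(ncol(z), 200)
  for (i in seq_len(nrow(eff$planted_edges))) {
    a <- eff$planted_edges$feature_a[i]
    b <- eff$planted_edges$feature_b[i]
    expect_equal(cor(z[a, ], z[b, ]), eff$planted_edges$rho[i],
                 tolerance = 0.05 / abs(eff$planted_edges$rho[i]),
                 label = paste(a, b))
  }
})

test_that("edges sharing a feature must share |rho|; modules need rho in (0,1)", {
  pe <- data.frame(feature_a = c("h", "h"), feature_b = c("x", "y"),
                   rho = c(0.8, 0.5))
  expect_error(simulate_study(study_design(mice_per_day = 2),
                              effect_spec(planted_edges = pe)),
               "share \\|rho\\|")
  expect_error(simulate_study(
    study_design(mice_per_day = 2),
    effect_spec(planted_modules = list(list(features = c("a", "b"), rho = -0.5)))),
    "module rho")
})

test_that("flagellin group means recover the planted day effects", {
  eff <- effect_spec()
  # average over replicate cohorts; tolerance is 3 standard errors
  reps <- 6
  ms <- sapply(seq_len(reps), function(i) {
    sim <- simulate_study(study_design(seed = 700 + i), eff)
    idx <- flagellin_index(
      data.frame(mouse = sim$flagellin$mouse,
                 copies_per_ul = sim$flagellin$transcript_copies_per_ul),
      data.frame(mouse = sim$flagellin$mouse,
                 copies_per_ul = sim$flagellin$gene_copies_per_ul))
    flagellin_group_means(idx, sim$flagellin$day)$mean
  })
  n_per_day <- 4 * reps
  for (d in seq_along(eff$flagellin_logratio_means)) {
    tol <- 3 * eff$flagellin_logratio_sds[d] / sqrt(n_per_day)
    expect_lt(abs(mean(ms[d, ]) - eff$flagellin_logratio_means[d]), tol)
  }
})

test_that("null datasets are independent with stable marginals across seeds", {
  fm <- simulate_null_dataset(n_features = 50, n_samples = 20, seed = 31)
  expect_identical(dim(fm$values), c(50L, 20L))
  expect_true(all(apply(fm$values, 1, sd) > 0))
  # empirical |r| > 0.6 rate over feature pairs matches the Monte-Carlo null
  R <- cor(t(fm$values))
  rate <- mean(abs(R[upper.tri(R)]) > 0.6)
  p0 <- mc_null_edge_prob(20, 0.6, reps = 1e5)
  npairs <- choose(50, 2)
  expect_lt(abs(rate - p0), 4 * sqrt(p0 * (1 - p0) / npairs) + 1e-3)
  # disjoint seeds: different values, same marginal distribution (KS)
  fm2 <- simulate_null_dataset(n_features = 50, n_samples = 20, seed = 32)
  expect_false(identical(fm$values, fm2$values))
  ks <- suppressWarnings(ks.test(as.vector(fm$values), as.vector(fm2$values)))
  expect_gt(ks$p.value, 0.001)
  expect_error(simulate_null_dataset(n_features = 1), ">= 2")
})

test_that("ground truth dimensions track the emitted tables", {
  sim <- simulate_study(study_design(seed = 21, mice_per_day = 2))
  expect_identical(colnames(sim$truth$taxon_composition),
                   colnames(sim$taxa$counts))
  expect_identical(dim(sim$truth$otu_composition), dim(sim$otus$counts))
  expect_true(all(abs(colSums(sim$truth$gene_composition) - 1) < 1e-9))
  expect_identical(colnames(sim$truth$category_fractions),
                   colnames(sim$functions$counts))
})
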