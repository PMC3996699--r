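host3 <- function(n = 6) {
  matrix(rnorm(3 * n), 3, n, dimnames = list(c("IFNg", "IL10", "TLR5"),
                                             paste0("s", 1:n)))
}

test_that("the 1% abundance filter is inclusive at the boundary", {
  set.seed(5)
  n <- 6
  otu <- rbind(keep_high = runif(n, 0.3, 0.5),
               keep_boundary = c(0.01, rep(0.002, n - 1)),
               drop_low = c(0.009, rep(0.002, n - 1)))
  colnames(otu) <- paste0("s", 1:n)
  categ <- matrix(runif(2 * n, 0.2, 0.8), 2,
                  dimnames = list(c("catA", "catB"), paste0("s", 1:n)))
  fm <- assemble_features(host3(n), otu, categ)
  expect_true(all(c("keep_high", "keep_boundary") %in% rownames(fm$values)))
  expect_false("drop_low" %in% rownames(fm$values))
  expect_identical(fm$dropped$otu_below_filter, "drop_low")
  # host markers are exempt from the abundance filter
  expect_true(all(c("IFNg", "IL10", "TLR5") %in% rownames(fm$values)))
})

test_that("blocks are joined on the shared sample set", {
  set.seed(6)
  h <- host3(20)
  otu <- matrix(runif(2 * 19, 0.05, 0.5), 2,
                dimnames = list(c("o1", "o2"), paste0("s", 1:19)))
  categ <- matrix(runif(2 * 20, 0.05, 0.5), 2,
                  dimnames = list(c("c1", "c2"), paste0("s", 1:20)))
  fm <- assemble_features(h, otu, categ)
  expect_length(fm$samples, 19)
  expect_identical(fm$dropped$samples, "s20")
  bad <- otu; colnames(bad) <- paste0("x", 1:19)
  expect_error(assemble_features(h, bad, categ), "empty sample intersection")
})

test_that("log normalization keeps correlations and rank order", {
  m <- matrix(c(rep(1, 5), 2, 4, 8, 16, 32), 2, byrow = TRUE,
              dimnames = list(c("ones", "geo"), paste0("s", 1:5)))
  ln <- log_normalize(m, pseudocount = 0)
  expect_equal(unname(ln["ones", ]), rep(0, 5))
  # rescaling a row by 10 shifts its log row by exactly 1
  m10 <- m; m10["geo", ] <- m["geo", ] * 10
  ln10 <- log_normalize(m10, pseudocount = 0)
  expect_equal(unname(ln10["geo", ] - ln["geo", ]), rep(1, 5))
  # zeros need a pseudocount; default keeps values finite, order preserved
  mz <- rbind(z = c(0, 1, 10, 100, 3), w = c(5, 4, 3, 2, 1))
  colnames(mz) <- paste0("s", 1:5)
  expect_error(log_normalize(mz, pseudocount = 0), "zero values")
  lz <- log_normalize(mz)
  expect_true(all(is.finite(lz)))
  expect_identical(order(lz["z", ]), order(mz["z", ]))
  expect_error(log_normalize(rbind(a = c(-1, 1)), 0.1), "negative")
})

test_that("edges appear exactly where |r| strictly exceeds the threshold", {
  set.seed(9)
  base <- rnorm(10)
  m <- rbind(a = base, b = base, c = -base + rnorm(10, 0, 1e-8),
             d = rnorm(10))
  colnames(m) <- paste0("s", 1:10)
  net <- build_network(m, threshold = 0.6)
  e <- network_edges(net)
  ab <- e[(e$from == "a" & e$to == "b") | (e$from == "b" & e$to == "a"), ]
  expect_equal(ab$r, 1)
  expect_identical(ab$sign, "positive")
  ac <- e[(e$from == "a" & e$to == "c") | (e$from == "c" & e$to == "a"), ]
  expect_equal(ac$r, -1, tolerance = 1e-6)
  expect_identical(ac$sign, "negative")
  # strictness: a pair whose |r| equals the threshold exactly gets no edge
  r_ad <- cor(m["a", ], m["d", ])
  net2 <- build_network(m, threshold = abs(r_ad))
  e2 <- network_edges(net2)
  expect_false(any((e2$from == "a" & e2$to == "d") |
                   (e2$from == "d" & e2$to == "a")))
  expect_error(build_network(m, threshold = 1.2), "threshold")
  expect_error(build_network(rbind(const = rep(1, 10), x = rnorm(10)), 0.6),
               "zero-variance")
})

test_that("edge sets are invariant to affine maps and sample permutation", {
  set.seed(10)
  m <- matrix(rnorm(8 * 15), 8, 15,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:15)))
  net <- build_network(m, 0.3)
  key <- function(n) {
    e <- network_edges(n)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), e$sign))
  }
  m2 <- m; m2[3, ] <- 5.5 * m2[3, ] - 2   # strictly increasing affine map
  expect_identical(key(build_network(m2, 0.3)), key(net))
  perm <- sample(15)
  expect_identical(key(build_network(m[, perm], 0.3)), key(net))
})

test_that("chance edges among independent features match the null oracle", {
  n <- 20; nf <- 30
  fm <- simulate_null_dataset(n_features = nf, n_samples = n, seed = 808)
  net <- build_network(fm, 0.6)
  npairs <- nf * (nf - 1) / 2
  p0 <- mc_null_edge_prob(n = n, threshold = 0.6, reps = 1e5)
  observed <- igraph::ecount(net$graph)
  # generous Poisson-style bound around the expected chance edge count
  expect_lte(observed, qpois(0.9999, npairs * p0 * 1.2) + 1)
})

test_that("planted correlation modules are recovered through neighborhoods", {
  module <- list(features = c("HostMarkerX", paste0("modOTU", 1:5)), rho = 0.85)
  eff <- flat_effects(planted_modules = list(module))
  # 40 samples: 8 mice on each of 5 days
  sim <- simulate_study(study_design(seed = 404, mice_per_day = 8), eff)
  z <- sim$truth$latent
  vals <- rbind(z, decoy = matrix(rnorm(3 * ncol(z)), 3,
                                  dimnames = list(paste0("decoy", 1:3), NULL)))
  colnames(vals) <- colnames(z)
  net <- build_network(vals, 0.6)
  nb <- neighborhood(net, "HostMarkerX", order = 1)
  found <- intersect(igraph::V(nb$graph)$name, paste0("modOTU", 1:5))
  expect_gte(length(found), 4)
  # an isolated node's neighbourhood is itself
  iso <- build_network(rbind(a = rnorm(10), b = 1:10 + rnorm(10, 0, 5),
                             c = rnorm(10))[, , drop = FALSE], 0.99)
  nb_iso <- neighborhood(iso, "a", 1)
  expect_identical(igraph::V(nb_iso$graph)$name, "a")
  expect_error(neighborhood(net, "nope", 1), "unknown node")
  expect_error(neighborhood(net, "HostMarkerX", 3), "order")
})

test_that("first and second order neighbourhoods follow graph distance", {
  # exact path a - b - c: construct sample-orthogonal z1, z2 so that
  # cor(a,b) = cor(b,c) = 1/sqrt(2) > 0.6 and cor(a,c) = 0
  set.seed(12)
  f1 <- rnorm(50); f2 <- rnorm(50)
  z1 <- scale(f1)[, 1]
  z2 <- scale(residuals(lm(f2 ~ f1)))[, 1]
  m <- rbind(a = z1, b = z1 + z2, c = z2)
  colnames(m) <- paste0("s", 1:50)
  net <- build_network(m, 0.6)
  expect_true(igraph::are_adjacent(net$graph, "a", "b"))
  expect_true(igraph::are_adjacent(net$graph, "b", "c"))
  expect_false(igraph::are_adjacent(net$graph, "a", "c"))
  nb1 <- neighborhood(net, "a", 1)
  expect_setequal(igraph::V(nb1$graph)$name, c("a", "b"))
  nb2 <- neighborhood(net, "a", 2)
  expect_setequal(igraph::V(nb2$graph)$name, c("a", "b", "c"))
})

test_that("GraphML round trip preserves nodes, edges and attributes", {
  set.seed(14)
  m <- matrix(rnorm(6 * 12), 6, 12,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:12)))
  fm <- structure(list(values = m,
                       block = setNames(rep(c("host_marker", "otu"), each = 3),
                                        rownames(m)),
                       samples = colnames(m), dropped = list(),
                       min_rel_abund = 0.01),
                  class = "feature_matrix")
  net <- build_network(fm, 0.25)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  back <- import_network(path)
  expect_setequal(igraph::V(back$graph)$name, igraph::V(net$graph)$name)
  expect_equal(igraph::ecount(back$graph), igraph::ecount(net$graph))
  eo <- network_edges(net); eb <- network_edges(back)
  ko <- order(eo$from, eo$to); kb <- order(eb$from, eb$to)
  expect_equal(eo$r[ko], eb$r[kb], tolerance = 1e-12)
  expect_identical(eo$sign[ko], eb$sign[kb])
  expect_identical(
    igraph::V(back$graph)$block[match(igraph::V(net$graph)$name,
                                      igraph::V(back$graph)$name)],
    igraph::V(net$graph)$block)
  expect_equal(back$threshold, net$threshold)
  # signs always match sign(r)
  expect_identical(eb$sign, ifelse(eb$r > 0, "positive", "negative"))
  # an empty network still exports valid GraphML
  net0 <- build_network(matrix(rnorm(30), 3, 10,
                               dimnames = list(letters[1:3], paste0("s", 1:10))),
                        0.999)
  path0 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net0, path0)
  expect_equal(igraph::ecount(import_network(path0)$graph), 0)
  # edge-list export
  pathe <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, pathe, "edgelist")
  el <- read.delim(pathe)
  expect_identical(nrow(el), nrow(eo))
})
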