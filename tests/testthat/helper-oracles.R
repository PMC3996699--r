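# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# naive per-pair Bray-Curtis formula
naive_bray <- function(x, y, binary = FALSE) {
  if (binary) { x <- as.numeric(x > 0); y <- as.numeric(y > 0) }
  sum(abs(x - y)) / sum(x + y)
}

# brute-force category fraction: loop over genes, sum counts per category,
# divide by the per-sample total
naive_category_fractions <- function(counts, gene2cat) {
  cats <- sort(unique(gene2cat))
  out <- matrix(0, length(cats), ncol(counts),
                dimnames = list(cats, colnames(counts)))
  for (s in seq_len(ncol(counts))) {
    tot <- 0
    for (g in rownames(counts)) tot <- tot + counts[g, s]
    for (g in rownames(counts)) {
      cc <- gene2cat[[g]]
      out[cc, s] <- out[cc, s] + counts[g, s] / tot
    }
  }
  out
}

# Monte-Carlo null probability P(|r| > threshold | rho = 0, n) for the
# sample Pearson correlation of two independent Gaussians
mc_null_edge_prob <- function(n, threshold, reps = 1e5, seed = 123) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  a <- matrix(rnorm(n * reps), n)
  b <- matrix(rnorm(n * reps), n)
  a <- scale(a); b <- scale(b)
  r <- colSums(a * b) / (n - 1)
  mean(abs(r) > threshold)
}

# tiny taxon table used by several io/profile tests
tiny_taxon_table <- function() {
  m <- matrix(c(96L, 50L, 3L, 30L, 1L, 20L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  count_table(m, kind = "taxon",
              annotation = data.frame(
                phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
                order = c("Clostridiales", "Clostridiales", "Bacteroidales"),
                family = c("Lachnospiraceae", "Ruminococcaceae", "Bacteroidaceae")))
}
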