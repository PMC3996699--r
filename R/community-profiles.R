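#' Rarefy a count table to fixed depth
#'
#' Randomly subsamples each sample's reads without replacement to a common
#' depth before diversity computation (the standard equal-effort
#' normalization for amplicon libraries, e.g. resampling at 3500 reads).
#' Samples whose library is smaller than `depth` are dropped with a warning
#' rather than scaled up.
#'
#' @param x a `count_table`
#' @param depth target reads per sample (>= 1)
#' @param seed integer RNG seed; recorded so the single draw is reproducible
#' @return rarefied `count_table`; every retained sample sums exactly to
#'   `depth`. Attribute `"rarefaction"` records depth, seed and dropped
#'   samples.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "count_table"), depth >= 1)
  depth <- as.integer(depth)
  totals <- colSums(x$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below rarefaction depth ", depth)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(x$counts)[!keep], collapse = ", "))
  }
  counts <- x$counts[, keep, drop = FALSE]
  out <- counts
  withr_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      if (totals[keep][j] == depth) next   # already at depth: identity
      reads <- rep.int(seq_len(nrow(counts)), counts[, j])
      drawn <- sample(reads, depth, replace = FALSE)
      out[, j] <- tabulate(drawn, nbins = nrow(counts))
    }
  })
  res <- count_table(out, kind = x$kind,
                     annotation = x$annotation[, , drop = FALSE])
  attr(res, "rarefaction") <- list(depth = depth, seed = seed,
                                   dropped = colnames(x$counts)[!keep])
  res
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Column-normalize counts to relative abundances
#'
#' @param x a `count_table` (or bare numeric matrix)
#' @return matrix of proportions with the same dimnames; every column sums
#'   to 1. Idempotent on already-normalized input.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    stop("zero-sum sample column(s): ", paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2, tot, "/")
}

#' Collapse a taxon table to a taxonomic rank
#'
#' Sums counts of all features sharing the annotation value at `rank`.
#' Features unclassified at that rank are pooled as
#' `"unclassified <parent>"`, where the parent is the next-higher annotated
#' rank (mirroring the "uc, unclassified" grouping convention of rRNA
#' profiles). Per-sample totals are conserved exactly.
#'
#' @param x a taxon- or otu-kind `count_table` with ranked lineage
#'   annotation columns (highest rank first, e.g. phylum, order, family)
#' @param rank annotation column name to collapse to
#' @return `count_table` with one row per rank value
#' @export
aggregate_by_rank <- function(x, rank) {
  stopifnot(inherits(x, "count_table"))
  if (!rank %in% names(x$annotation)) {
    stop("rank '", rank, "' not in lineage schema (",
         paste(names(x$annotation), collapse = ", "), ")")
  }
  ranks <- names(x$annotation)
  ri <- match(rank, ranks)
  lab <- x$annotation[[rank]]
  uc <- lab == "unclassified"
  if (any(uc)) {
    parent <- rep("root", sum(uc))
    if (ri > 1) {
      # nearest annotated ancestor above this rank
      for (k in seq_len(ri - 1)) {
        anc <- x$annotation[[ranks[ri - k]]][uc]
        fill <- parent == "root" & anc != "unclassified"
        parent[fill] <- anc[fill]
      }
    }
    lab[uc] <- paste("unclassified", parent)
  }
  agg <- rowsum(x$counts, group = lab, reorder = FALSE)
  anno <- NULL
  if (ri > 1) {
    # carry the higher ranks of the first member of each group
    first <- match(rownames(agg), lab)
    anno <- x$annotation[first, seq_len(ri - 1), drop = FALSE]
    anno[[rank]] <- rownames(agg)
  } else {
    anno <- data.frame(stats::setNames(list(rownames(agg)), rank),
                       stringsAsFactors = FALSE)
  }
  rownames(anno) <- rownames(agg)
  count_table(agg, kind = x$kind, annotation = anno)
}

#' Alpha diversity at fixed rarefaction depth
#'
#' Richness is the number of features observed after a single rarefaction
#' draw; evenness is Pielou's J = H / ln(S) with Shannon entropy H in
#' natural-log units. For a single-feature sample J is undefined and
#' returned as NA (flagged, never coerced to 0).
#'
#' @param x a `count_table`
#' @param depth rarefaction depth
#' @param seed RNG seed for the rarefaction draw
#' @param replicates number of independent rarefaction draws to average
#'   richness/evenness over (default 1, a single recorded draw)
#' @return data.frame with columns sample, richness, shannon, evenness,
#'   depth, seed
#' @export
alpha_diversity <- function(x, depth, seed = 1L, replicates = 1L) {
  stopifnot(inherits(x, "count_table"), replicates >= 1)
  acc <- NULL
  for (r in seq_len(replicates)) {
    rt <- rarefy(x, depth, seed = seed + r - 1L)
    m <- rt$counts
    rich <- colSums(m > 0)
    p <- sweep(m, 2, colSums(m), "/")
    H <- apply(p, 2, function(q) { q <- q[q > 0]; -sum(q * log(q)) })
    J <- ifelse(rich >= 2, H / log(rich), NA_real_)
    d <- data.frame(sample = colnames(m), richness = rich, shannon = H,
                    evenness = J, stringsAsFactors = FALSE, row.names = NULL)
    acc <- if (is.null(acc)) d else rbind(acc, d)
  }
  out <- stats::aggregate(cbind(richness, shannon, evenness) ~ sample,
                          data = acc, FUN = mean, na.action = stats::na.pass)
  out <- out[match(unique(acc$sample), out$sample), ]
  out$depth <- depth
  out$seed <- seed
  rownames(out) <- NULL
  out
}

#' Per-sample abundance ratio of two taxa
#'
#' Used e.g. for the Clostridiales:Bacteroidales rRNA ratio. A zero
#' denominator yields `Inf`, flagged via the `"flagged"` attribute and to be
#' excluded from group tests by the caller, not raised as an error.
#'
#' @param rel relative-abundance matrix (taxa x samples), e.g. from
#'   [relative_abundance()] after [aggregate_by_rank()]
#' @param numerator,denominator row names of the two taxa
#' @return named numeric vector of per-sample ratios with attribute
#'   `"flagged"` listing samples with zero denominator
#' @export
taxon_ratio <- function(rel, numerator, denominator) {
  rel <- as.matrix(rel)
  miss <- setdiff(c(numerator, denominator), rownames(rel))
  if (length(miss)) stop("taxon row(s) not found: ", paste(miss, collapse = ", "))
  ratio <- rel[numerator, ] / rel[denominator, ]
  flagged <- colnames(rel)[rel[denominator, ] == 0]
  if (length(flagged)) {
    warning("zero denominator for sample(s): ", paste(flagged, collapse = ", "),
            " (flagged infinite; exclude from group tests)")
  }
  attr(ratio, "flagged") <- flagged
  ratio
}
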