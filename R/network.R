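#' Assemble the multi-block feature matrix for network inference
#'
#' Stacks host-marker values, OTU relative abundances and function-category
#' fractions into one feature-by-sample matrix over the samples shared by
#' all blocks (inner join; exclusions are recorded). Abundance blocks (OTUs
#' and categories) are filtered to features that reach at least
#' `min_rel_abund` (default 1\%) relative abundance in at least one sample
#' — the threshold is inclusive, so a feature peaking exactly at 1\% is
#' retained. Host markers are not abundances and are exempt from the
#' filter. Zero-variance rows are removed with a log entry: a constant
#' feature has no defined Pearson correlation.
#'
#' @param host matrix of host-marker values (markers x samples), typically
#'   log-scale expression ratios
#' @param otu_rel OTU relative-abundance matrix (otus x samples)
#' @param categ function-category fraction matrix (categories x samples),
#'   e.g. `aggregate_categories(...)$fractions`
#' @param min_rel_abund abundance-filter threshold on the relative scale
#' @return object of class `feature_matrix`: `values` (features x shared
#'   samples), `block` (host_marker | otu | function_category per row),
#'   `dropped` (filter/variance log), `samples`
#' @export
assemble_features <- function(host, otu_rel, categ, min_rel_abund = 0.01) {
  blocks <- list(host_marker = as.matrix(host), otu = as.matrix(otu_rel),
                 function_category = as.matrix(categ))
  shared <- Reduce(intersect, lapply(blocks, colnames))
  if (length(shared) == 0) stop("empty sample intersection across blocks")
  dropped <- list()
  excluded_samples <- setdiff(unique(unlist(lapply(blocks, colnames))), shared)
  if (length(excluded_samples)) {
    dropped$samples <- excluded_samples
  }
  rows <- list(); lab <- character(0)
  for (bn in names(blocks)) {
    b <- blocks[[bn]][, shared, drop = FALSE]
    if (bn != "host_marker") {
      keep <- apply(b, 1, max) >= min_rel_abund
      if (any(!keep)) {
        dropped[[paste0(bn, "_below_filter")]] <- rownames(b)[!keep]
      }
      b <- b[keep, , drop = FALSE]
    }
    rows[[bn]] <- b
    lab <- c(lab, rep(bn, nrow(b)))
  }
  values <- do.call(rbind, rows)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids across blocks: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  vr <- apply(values, 1, stats::sd)
  if (any(vr == 0)) {
    dropped$zero_variance <- rownames(values)[vr == 0]
    lab <- lab[vr > 0]
    values <- values[vr > 0, , drop = FALSE]
  }
  structure(list(values = values, block = stats::setNames(lab, rownames(values)),
                 samples = shared, dropped = dropped,
                 min_rel_abund = min_rel_abund),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tb <- table(x$block)
  cat(sprintf("feature_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), length(x$samples),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", ")))
  if (length(x$dropped)) {
    cat("  dropped:", paste(sprintf("%s (%d)", names(x$dropped),
                                    lengths(x$dropped)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Log-normalize abundance blocks of a feature matrix
#'
#' Applies x -> log10(x + pseudocount) to the OTU and function-category
#' blocks (host markers arrive already log-scale and are passed through
#' unless `include_host = TRUE`). The default pseudocount is half the
#' smallest nonzero value of each abundance block, which keeps zeros finite
#' while preserving rank order; a fixed constant (e.g. 1e-6) may be given
#' instead.
#'
#' @param x a `feature_matrix` (or bare non-negative matrix)
#' @param pseudocount `"half_min_nonzero"` or a non-negative number
#' @param include_host also log-transform the host block (default FALSE)
#' @return the input with transformed values; pseudocounts used are
#'   recorded in attribute/field `pseudocount_used`
#' @export
log_normalize <- function(x, pseudocount = "half_min_nonzero",
                          include_host = FALSE) {
  bare <- !inherits(x, "feature_matrix")
  values <- if (bare) as.matrix(x) else x$values
  block <- if (bare) rep("otu", nrow(values)) else x$block
  used <- c()
  for (bn in unique(block)) {
    if (bn == "host_marker" && !include_host) next
    idx <- block == bn
    v <- values[idx, , drop = FALSE]
    if (any(v < 0)) stop("negative values in block '", bn, "'; cannot log-normalize")
    pc <- if (identical(pseudocount, "half_min_nonzero")) {
      nz <- v[v > 0]
      if (length(nz)) min(nz) / 2 else 0
    } else {
      stopifnot(is.numeric(pseudocount), pseudocount >= 0)
      pseudocount
    }
    if (pc == 0 && any(v == 0)) {
      stop("zero values with zero pseudocount in block '", bn, "'")
    }
    values[idx, ] <- log10(v + pc)
    used[bn] <- pc
  }
  if (bare) {
    attr(values, "pseudocount_used") <- used
    return(values)
  }
  x$values <- values
  x$pseudocount_used <- used
  x
}

#' Build a thresholded Pearson correlation network
#'
#' Computes all pairwise Pearson correlations between feature rows and
#' keeps an undirected edge wherever r > threshold or r < -threshold
#' (strict inequalities). Edge sign is sign(r); r itself is stored on the
#' edge. Because Pearson r is invariant under strictly increasing affine
#' transforms of any row, so is the edge set.
#'
#' @param x a `feature_matrix` (log-normalized) or bare numeric matrix
#'   (features x samples)
#' @param threshold |r| cut-off in (0, 1); 0.6 is the conventional default
#' @return object of class `correlation_network`: an igraph `graph` with
#'   vertex attribute `block` and edge attributes `r` and `sign`, plus
#'   `threshold`, `n` (samples) and the full correlation `matrix`
#' @export
build_network <- function(x, threshold = 0.6) {
  bare <- !inherits(x, "feature_matrix")
  values <- if (bare) as.matrix(x) else x$values
  block <- if (bare) rep("feature", nrow(values)) else x$block
  if (ncol(values) < 3) stop("need at least 3 samples")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  vr <- apply(values, 1, stats::sd)
  if (any(vr == 0)) {
    stop("zero-variance feature row(s): ",
         paste(rownames(values)[vr == 0], collapse = ", "),
         " (filter before building the network)")
  }
  R <- stats::cor(t(values))
  adj <- abs(R) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$block <- unname(block[match(igraph::V(g)$name, rownames(values))])
  el <- igraph::as_edgelist(g)
  r <- R[cbind(el[, 1], el[, 2])]
  igraph::E(g)$r <- unname(r)
  igraph::E(g)$sign <- ifelse(r > 0, "positive", "negative")
  structure(list(graph = g, threshold = threshold, n = ncol(values),
                 matrix = R),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("correlation_network: %d nodes, %d edges (|r| > %g, n = %d samples)\n",
              igraph::vcount(g), igraph::ecount(g), x$threshold, x$n))
  if (igraph::ecount(g) > 0) {
    cat(sprintf("  %d positive, %d negative edges\n",
                sum(igraph::E(g)$sign == "positive"),
                sum(igraph::E(g)$sign == "negative")))
  }
  invisible(x)
}

#' @export
summary.correlation_network <- function(object, ...) {
  g <- object$graph
  data.frame(nodes = igraph::vcount(g), edges = igraph::ecount(g),
             positive = sum(igraph::E(g)$sign == "positive"),
             negative = sum(igraph::E(g)$sign == "negative"),
             threshold = object$threshold, n_samples = object$n)
}

#' @export
plot.correlation_network <- function(x, ...) {
  g <- x$graph
  blocks <- factor(igraph::V(g)$block)
  igraph::plot.igraph(
    g, vertex.color = as.integer(blocks) + 1,
    edge.color = ifelse(igraph::E(g)$sign == "positive", "black", "red"),
    vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Edge list of a correlation network
#' @param x a `correlation_network`
#' @return data.frame from, to, r, sign
#' @export
network_edges <- function(x) {
  stopifnot(inherits(x, "correlation_network"))
  g <- x$graph
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      r = numeric(0), sign = character(0)))
  }
  data.frame(from = el[, 1], to = el[, 2], r = igraph::E(g)$r,
             sign = igraph::E(g)$sign, stringsAsFactors = FALSE)
}

#' First/second-neighbour sub-network of seed nodes
#'
#' Induced sub-network on the seed nodes plus every node within graph
#' distance `order` (1 = first neighbours, 2 = first and second) — the
#' neighbourhood query used to nominate candidate phylotype biomarkers
#' around host markers.
#'
#' @param x a `correlation_network`
#' @param seeds character vector of node ids
#' @param order 1 or 2
#' @return `correlation_network` restricted to the induced node set
#' @export
neighborhood <- function(x, seeds, order = 1) {
  stopifnot(inherits(x, "correlation_network"))
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  g <- x$graph
  known <- igraph::V(g)$name
  miss <- setdiff(seeds, known)
  if (length(miss)) {
    stop("unknown node(s): ", paste(miss, collapse = ", "),
         "; known ids: ", paste(utils::head(known, 20), collapse = ", "),
         if (length(known) > 20) ", ..." else "")
  }
  keep <- unique(unlist(lapply(
    igraph::ego(g, order = order, nodes = seeds), names)))
  sub <- igraph::induced_subgraph(g, vids = keep)
  out <- x
  out$graph <- sub
  out$matrix <- x$matrix[keep, keep, drop = FALSE]
  out$seeds <- seeds
  out$order <- order
  out
}

#' Export a correlation network to GraphML or a TSV edge list
#'
#' GraphML carries the node `block` attribute and edge attributes `r` and
#' `sign`; [import_network()] round-trips it losslessly. The edge-list
#' alternative is a plain TSV `from / to / r / sign`.
#'
#' @param x a `correlation_network`
#' @param path output file
#' @param format `"graphml"` or `"edgelist"`
#' @return `path`, invisibly
#' @export
export_network <- function(x, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(x, "correlation_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- x$graph
    g <- igraph::set_graph_attr(g, "threshold", x$threshold)
    g <- igraph::set_graph_attr(g, "n_samples", x$n)
    tryCatch(igraph::write_graph(g, path, format = "graphml"),
             error = function(e) stop("GraphML export failed for '", path,
                                      "': ", conditionMessage(e)))
  } else {
    write_tsv_canonical(network_edges(x), path)
  }
  invisible(path)
}

#' Import a GraphML correlation network
#' @param path GraphML file written by [export_network()]
#' @return a `correlation_network` (without the full correlation matrix)
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  structure(list(graph = g,
                 threshold = igraph::graph_attr(g, "threshold"),
                 n = igraph::graph_attr(g, "n_samples"),
                 matrix = NULL),
            class = "correlation_network")
}
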