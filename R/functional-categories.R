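#' Aggregate function-gene counts into SEED-style categories
#'
#' Sums mRNA counts up the 3-level function hierarchy and expresses each
#' category as a fraction of a per-sample denominator: either all
#' functionally annotated reads (`denominator = "all"`), or the reads
#' attributed to one taxon (`denominator = "taxon_subset"` with `taxon`),
#' which reproduces within-taxon transcript profiles such as the motility
#' fraction of the Firmicutes metatranscriptome. Genes without a hierarchy
#' entry are pooled as `"unclassified"`.
#'
#' @param x a function-gene `count_table`
#' @param hierarchy a `function_hierarchy` mapping gene -> level1/2/3
#' @param level hierarchy level to aggregate at (1, 2 or 3)
#' @param denominator `"all"` or `"taxon_subset"`
#' @param taxon taxon name matched against the table's `taxon` annotation
#'   column when `denominator = "taxon_subset"`; both the summed counts and
#'   the denominator are then restricted to that taxon's genes
#' @return object of class `category_table`: `fractions` (category x
#'   sample), `counts`, `denominator` (per-sample totals used), and the
#'   settings
#' @export
aggregate_categories <- function(x, hierarchy, level = 1,
                                 denominator = c("all", "taxon_subset"),
                                 taxon = NULL) {
  stopifnot(inherits(x, "count_table"), x$kind == "function_gene")
  denominator <- match.arg(denominator)
  if (!level %in% 1:3) stop("level must be 1, 2 or 3")
  m <- x$counts
  if (denominator == "taxon_subset") {
    if (is.null(taxon)) stop("taxon required for denominator = 'taxon_subset'")
    if (!"taxon" %in% names(x$annotation)) {
      stop("table has no 'taxon' annotation column")
    }
    keep <- x$annotation$taxon == taxon
    if (!any(keep)) stop("no genes attributed to taxon '", taxon, "'")
    m <- m[keep, , drop = FALSE]
  }
  lev_col <- paste0("level", level)
  idx <- match(rownames(m), hierarchy$function_gene)
  cat_lab <- ifelse(is.na(idx), "unclassified", hierarchy[[lev_col]][idx])
  agg <- rowsum(m, group = cat_lab, reorder = TRUE)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("zero annotated reads in sample(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  }
  structure(list(fractions = sweep(agg, 2, totals, "/"), counts = agg,
                 denominator = totals, level = level,
                 denominator_kind = denominator, taxon = taxon),
            class = "category_table")
}

#' @export
print.category_table <- function(x, ...) {
  cat(sprintf("category_table: level %d, %d categories x %d samples (denominator: %s%s)\n",
              x$level, nrow(x$fractions), ncol(x$fractions),
              x$denominator_kind,
              if (!is.null(x$taxon)) paste0(" = ", x$taxon) else ""))
  invisible(x)
}

#' Curated gene-panel fraction per sample
#'
#' Sums the counts of a named gene panel (e.g. the mucin-degradation
#' enzymes: beta-hexosaminidase, alpha/beta-mannosidase,
#' neuraminidase/sialidase, beta-galactosidase, sulfatase; or the butyrate
#' pathway) and divides by the per-sample denominator — all annotated reads
#' or a taxon-restricted subset. Panel members absent from the table are
#' logged via a warning, not an error, as long as at least one resolves.
#'
#' @param x a function-gene `count_table`
#' @param panel character vector of function_gene ids, or a list with
#'   elements `name` and `genes` (the YAML panel layout)
#' @inheritParams aggregate_categories
#' @return named numeric vector of per-sample panel fractions
#' @export
panel_fraction <- function(x, panel, denominator = c("all", "taxon_subset"),
                           taxon = NULL) {
  stopifnot(inherits(x, "count_table"), x$kind == "function_gene")
  denominator <- match.arg(denominator)
  genes <- if (is.list(panel)) panel$genes else panel
  if (!length(genes)) stop("empty gene panel")
  m <- x$counts
  if (denominator == "taxon_subset") {
    if (is.null(taxon)) stop("taxon required for denominator = 'taxon_subset'")
    keep <- x$annotation$taxon == taxon
    if (!any(keep)) stop("no genes attributed to taxon '", taxon, "'")
    m <- m[keep, , drop = FALSE]
  }
  hit <- intersect(genes, rownames(m))
  miss <- setdiff(genes, rownames(m))
  if (!length(hit)) stop("no panel gene resolves against the table")
  if (length(miss)) {
    warning("panel gene(s) not in table: ", paste(miss, collapse = ", "))
  }
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero denominator in sample(s): ",
                          paste(colnames(m)[tot == 0], collapse = ", "))
  colSums(m[hit, , drop = FALSE]) / tot
}

#' Read a gene panel from YAML
#'
#' Panels are editable YAML files (`name:`, `genes:` list); the package
#' ships seed panels for mucin degradation and the butyrate pathway under
#' `inst/extdata/panels/`.
#'
#' @param path YAML file
#' @return list with `name` and `genes`
#' @export
read_panel <- function(path) {
  p <- yaml::read_yaml(path)
  if (is.null(p$genes) || !length(p$genes)) stop("panel has no genes: ", path)
  p$genes <- as.character(p$genes)
  p
}

#' Percent change of per-day group means vs a baseline day
#'
#' 100 * (mean_day - mean_baseline) / mean_baseline per category; a planted
#' decline of "21% fewer transcripts" at a day reads as -21 here. A zero
#' baseline mean yields NA (flagged undefined).
#'
#' @param categ a `category_table` (or bare fraction matrix)
#' @param days day label per sample column
#' @param baseline_day the reference day (must be present)
#' @return matrix category x day of percent changes; the baseline column is
#'   identically 0
#' @export
percent_change_vs_baseline <- function(categ, days, baseline_day) {
  fr <- if (inherits(categ, "category_table")) categ$fractions else as.matrix(categ)
  stopifnot(length(days) == ncol(fr))
  days <- as.character(days)
  baseline_day <- as.character(baseline_day)
  if (!baseline_day %in% days) stop("baseline day ", baseline_day, " has no samples")
  ud <- unique(days)
  means <- vapply(ud, function(d) rowMeans(fr[, days == d, drop = FALSE]),
                  numeric(nrow(fr)))
  if (nrow(fr) == 1) means <- matrix(means, nrow = 1, dimnames = list(rownames(fr), ud))
  base <- means[, baseline_day]
  pc <- 100 * sweep(sweep(means, 1, base, "-"), 1, base, "/")
  pc[base == 0, ] <- NA_real_
  dimnames(pc) <- list(rownames(fr), ud)
  pc
}

#' Per-category unpaired t-test between two days
#'
#' Mirrors the per-category day-1-vs-day-8 comparisons of longitudinal
#' category profiles: Welch-free, classical unpaired two-sided t-test per
#' category, no multiple-testing correction by default (each category is
#' reported at its nominal p); Benjamini-Hochberg adjusted values are
#' available via `adjust = "BH"`.
#'
#' @param categ a `category_table` or fraction matrix
#' @param days day label per sample column
#' @param day_a,day_b the two days to compare (>= 2 samples each)
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method
#' @return data.frame category, mean_a, mean_b, t, p, p_adj, significant
#'   (p < 0.05 on the adjusted value), flagged (zero variance in both
#'   groups)
#' @export
category_group_test <- function(categ, days, day_a, day_b, adjust = "none") {
  fr <- if (inherits(categ, "category_table")) categ$fractions else as.matrix(categ)
  days <- as.character(days)
  ia <- which(days == as.character(day_a))
  ib <- which(days == as.character(day_b))
  if (length(ia) < 2 || length(ib) < 2) stop("need >= 2 samples per day")
  out <- lapply(rownames(fr), function(cc) {
    a <- fr[cc, ia]; b <- fr[cc, ib]
    flagged <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (flagged) {
      data.frame(category = cc, mean_a = mean(a), mean_b = mean(b),
                 t = NA_real_, p = NA_real_, flagged = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(category = cc, mean_a = mean(a), mean_b = mean(b),
                 t = unname(tt$statistic), p = tt$p.value, flagged = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}
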