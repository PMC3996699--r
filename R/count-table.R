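#' Feature-by-sample count tables
#'
#' A `count_table` holds a non-negative integer matrix of features (rows)
#' by samples (columns) together with the feature kind and per-feature
#' annotation. Three kinds are supported:
#' \describe{
#'   \item{`"taxon"`}{rRNA-derived taxa; annotation columns are a ranked
#'     lineage (e.g. `phylum`, `order`, `family`).}
#'   \item{`"otu"`}{97\%-identity amplicon OTUs; annotation as for taxa.}
#'   \item{`"function_gene"`}{functionally annotated mRNA genes; annotation
#'     columns are the 3-level category path `level1`, `level2`, `level3`
#'     and optionally a `taxon` attribution.}
#' }
#'
#' @param counts integer matrix, features x samples; must have rownames
#'   (feature ids) and colnames (sample ids).
#' @param kind one of `"taxon"`, `"otu"`, `"function_gene"`.
#' @param annotation data.frame of per-feature annotation, one row per
#'   feature in the same order as `counts`. Missing entries are replaced by
#'   `"unclassified"` rather than dropped.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, kind = c("taxon", "otu", "function_gene"),
                        annotation = NULL) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: feature '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "double"   # exact for counts < 2^53; avoids int overflow on sums
  if (is.null(annotation)) {
    annotation <- data.frame(row.names = rownames(counts))
  } else {
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
    if (nrow(annotation) != nrow(counts)) {
      stop("annotation must have one row per feature")
    }
    rownames(annotation) <- rownames(counts)
    for (j in seq_along(annotation)) {
      x <- as.character(annotation[[j]])
      x[is.na(x) | x == ""] <- "unclassified"
      annotation[[j]] <- x
    }
  }
  structure(list(counts = counts, kind = kind, annotation = annotation),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d features x %d samples\n",
              x$kind, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total counts: %s; annotation columns: %s\n",
              format(sum(x$counts), big.mark = ","),
              if (ncol(x$annotation)) paste(names(x$annotation), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Sample totals of a count table
#' @param x a `count_table`
#' @return named numeric vector of per-sample totals
#' @export
sample_sums <- function(x) {
  stopifnot(inherits(x, "count_table"))
  colSums(x$counts)
}

# annotation columns carry this prefix in the TSV dialect so a single header
# row distinguishes them from sample columns
ANNO_PREFIX <- "anno_"

#' Read a count table from TSV
#'
#' The canonical dialect is tab-delimited UTF-8 with '.' decimals: first
#' column `feature_id`, annotation columns prefixed `anno_` (e.g.
#' `anno_family`, `anno_level1`), all remaining columns samples holding
#' non-negative integer counts. Row and column order are preserved.
#'
#' @param path TSV file path
#' @param kind feature kind, see [count_table()]
#' @return a validated `count_table`
#' @export
read_count_table <- function(path, kind = c("taxon", "otu", "function_gene")) {
  kind <- match.arg(kind)
  df <- read_tsv_checked(path)
  if (names(df)[1] != "feature_id") {
    stop("first column must be 'feature_id', got '", names(df)[1], "' in ", path)
  }
  is_anno <- startsWith(names(df), ANNO_PREFIX)
  sample_cols <- which(!is_anno)[-1]
  if (length(sample_cols) == 0) stop("no sample columns in ", path)
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "double")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s: invalid count at feature '%s', sample '%s'",
                 path, df$feature_id[bad[1, 1]], names(df)[sample_cols][bad[1, 2]]))
  }
  rownames(counts) <- df$feature_id
  anno <- df[, is_anno, drop = FALSE]
  names(anno) <- sub(paste0("^", ANNO_PREFIX), "", names(anno))
  count_table(counts, kind = kind, annotation = if (ncol(anno)) anno else NULL)
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x))`
#' reproduces `x` exactly.
#'
#' @param x a `count_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(feature_id = rownames(x$counts), stringsAsFactors = FALSE)
  if (ncol(x$annotation) > 0) {
    anno <- x$annotation
    names(anno) <- paste0(ANNO_PREFIX, names(anno))
    df <- cbind(df, anno)
  }
  cnt <- as.data.frame(x$counts)
  df <- cbind(df, cnt)
  write_tsv_canonical(df, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects columns `sample`, `mouse`, `litter`, `day`, `group`. In strict
#' mode a day outside `expected_days` is an error; in permissive mode it is
#' a warning.
#'
#' @param path TSV file path
#' @param expected_days integer days the study design allows, or NULL to
#'   skip the check
#' @param strict error (TRUE) or warn (FALSE) on unexpected days
#' @return data.frame of class `sample_info`
#' @export
read_sample_info <- function(path, expected_days = NULL, strict = TRUE) {
  df <- read_tsv_checked(path)
  sample_info(df, expected_days = expected_days, strict = strict)
}

#' Construct/validate a sample-information table
#' @param df data.frame with columns sample, mouse, litter, day, group
#' @inheritParams read_sample_info
#' @return data.frame of class `sample_info`
#' @export
sample_info <- function(df, expected_days = NULL, strict = TRUE) {
  need <- c("sample", "mouse", "litter", "day", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample ids in sample sheet: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  df$day <- as.integer(df$day)
  if (!is.null(expected_days)) {
    odd <- setdiff(df$day, expected_days)
    if (length(odd)) {
      msg <- paste0("sample sheet contains days outside the design: ",
                    paste(odd, collapse = ", "))
      if (strict) stop(msg) else warning(msg)
    }
  }
  class(df) <- c("sample_info", "data.frame")
  df
}

#' Write a sample sheet as TSV
#' @param x `sample_info` data.frame
#' @param path output path
#' @export
write_sample_info <- function(x, path) {
  write_tsv_canonical(as.data.frame(x), path)
  invisible(path)
}

#' Read a 3-level function hierarchy
#'
#' Maps each function gene to a `(level1, level2, level3)` SEED-style
#' category path. Paths must form a tree: a level-2 name maps to exactly one
#' level-1 parent, and a level-3 name to one level-2 parent.
#'
#' @param path TSV with columns `function_gene`, `level1`, `level2`, `level3`
#' @return data.frame of class `function_hierarchy`
#' @export
read_hierarchy <- function(path) {
  df <- read_tsv_checked(path)
  function_hierarchy(df)
}

#' Construct/validate a function hierarchy
#' @param df data.frame with columns function_gene, level1, level2, level3
#' @return data.frame of class `function_hierarchy`
#' @export
function_hierarchy <- function(df) {
  need <- c("function_gene", "level1", "level2", "level3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hierarchy missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$function_gene)) {
    stop("duplicate function_gene entries in hierarchy")
  }
  p2 <- unique(df[, c("level1", "level2")])
  dup2 <- p2$level2[duplicated(p2$level2)]
  if (length(dup2)) {
    stop("hierarchy is not a tree: level2 name(s) under multiple level1 parents: ",
         paste(unique(dup2), collapse = ", "))
  }
  p3 <- unique(df[, c("level2", "level3")])
  dup3 <- p3$level3[duplicated(p3$level3)]
  if (length(dup3)) {
    stop("hierarchy is not a tree: level3 name(s) under multiple level2 parents: ",
         paste(unique(dup3), collapse = ", "))
  }
  class(df) <- c("function_hierarchy", "data.frame")
  df
}

#' Write a function hierarchy as TSV
#' @param x `function_hierarchy`
#' @param path output path
#' @export
write_hierarchy <- function(x, path) {
  write_tsv_canonical(as.data.frame(x), path)
  invisible(path)
}

# -- internal TSV helpers ----------------------------------------------------

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("no records in ", path)
  df
}

write_tsv_canonical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8", eol = "\n")
}
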