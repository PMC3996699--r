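#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template copies. The amplification
#' efficiency is expressed as fold-amplification per cycle,
#' E = 10^(-1/slope); E = 2 corresponds to perfect doubling (100%
#' efficiency), and percent efficiency E - 1 is reported alongside.
#'
#' @param log10_copies numeric vector of log10 template copies of the
#'   dilution series
#' @param ct corresponding Ct values
#' @return object of class `standard_curve` with slope, intercept (Ct at
#'   1 copy), efficiency, percent_efficiency, r_squared and the calibrated
#'   log10-copy range
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  stopifnot(length(log10_copies) == length(ct))
  if (length(unique(log10_copies)) < 3 && length(log10_copies) < 3) {
    stop("need at least 3 standard points")
  }
  if (length(log10_copies) < 3) stop("need at least 3 standard points")
  if (diff(range(log10_copies)) < 2) {
    stop("standard points must span at least 2 log10 units")
  }
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("non-amplifying curve: slope must be negative")
  intercept <- unname(stats::coef(fit)[1])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope),
                 percent_efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 log10_range = range(log10_copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Ct = %.3f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency E = %.3f (%.1f%%), R^2 = %.4f, calibrated %g-%g log10 copies\n",
              x$efficiency, 100 * x$percent_efficiency, x$r_squared,
              x$log10_range[1], x$log10_range[2]))
  invisible(x)
}

#' Absolute quantification from Ct values
#'
#' Inverts the standard curve, copies = 10^((ct - intercept)/slope), and
#' normalizes the raw per-reaction copy estimate both per microgram of
#' template nucleic acid and per microliter of preparation. Ct values
#' outside the calibrated range (plus an extrapolation margin in log10
#' units) are flagged, not rejected.
#'
#' @param ct Ct value(s)
#' @param curve a `standard_curve`
#' @param template_mass_ug micrograms of DNA/RNA in the reaction template
#' @param volume_ul microliters of preparation in the reaction template
#' @param extrapolation_margin allowed excursion beyond the calibrated
#'   log10-copy range before flagging (default 1 log10 unit)
#' @return data.frame with copies, copies_per_ug, copies_per_ul and an
#'   `extrapolated` flag
#' @export
quantify <- function(ct, curve, template_mass_ug = 1, volume_ul = 1,
                     extrapolation_margin = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  lc <- (ct - curve$intercept) / curve$slope
  extrap <- lc < curve$log10_range[1] - extrapolation_margin |
            lc > curve$log10_range[2] + extrapolation_margin
  if (any(extrap)) {
    warning(sum(extrap), " Ct value(s) outside the calibrated range; ",
            "copy estimates are extrapolations")
  }
  copies <- 10^lc
  data.frame(ct = ct, copies = copies,
             copies_per_ug = copies / template_mass_ug,
             copies_per_ul = copies / volume_ul,
             extrapolated = extrap)
}

#' Flagellin transcript:gene expression index
#'
#' The per-mouse log10 ratio of flagellin transcript copies to flagellin
#' gene copies in the same nucleic-acid preparation (per-microliter
#' normalization by default). Because transcripts and genes come from one
#' extraction, the index separates transcriptional downregulation from a
#' mere decline of the flagellated population, and it is invariant under
#' joint rescaling of both copy estimates. Mice present in only one of the
#' two tables are excluded with a warning.
#'
#' @param transcripts,genes data.frames with columns `mouse` and a copy
#'   column (`copies_per_ul` by default), one row per mouse
#' @param value column holding the copy estimate
#' @return data.frame of class `flagellin_index` with mouse and log_ratio
#' @export
flagellin_index <- function(transcripts, genes, value = "copies_per_ul") {
  stopifnot(value %in% names(transcripts), value %in% names(genes))
  common <- intersect(transcripts$mouse, genes$mouse)
  lost <- setdiff(union(transcripts$mouse, genes$mouse), common)
  if (length(lost)) {
    warning("excluding unpaired mouse/mice: ", paste(lost, collapse = ", "))
  }
  if (!length(common)) stop("no paired mice")
  tr <- transcripts[match(common, transcripts$mouse), value]
  ge <- genes[match(common, genes$mouse), value]
  if (any(ge <= 0)) stop("gene copies must be > 0 for the index")
  out <- data.frame(mouse = common, log_ratio = log10(tr / ge),
                    stringsAsFactors = FALSE)
  class(out) <- c("flagellin_index", "data.frame")
  out
}

#' Per-group means of a flagellin index
#' @param index a `flagellin_index`
#' @param groups group label per row (e.g. day)
#' @return data.frame group, n, mean, sd
#' @export
flagellin_group_means <- function(index, groups) {
  stopifnot(length(groups) == nrow(index))
  g <- as.character(groups)
  out <- lapply(unique(g), function(gg) {
    v <- index$log_ratio[g == gg]
    data.frame(group = gg, n = length(v), mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# mean Ct per group with basic validation; x: data.frame(sample, ct)
ct_vector <- function(x, ids, label) {
  if (!all(c("sample", "ct") %in% names(x))) {
    stop("Ct table needs columns 'sample' and 'ct'")
  }
  miss <- setdiff(ids, x$sample)
  if (length(miss)) stop("missing ", label, " measurements for sample(s): ",
                         paste(miss, collapse = ", "))
  stats::setNames(x$ct[match(ids, x$sample)], ids)
}

#' Efficiency-corrected, housekeeping-normalized expression ratio
#'
#' The REST-style ratio
#' \deqn{R = E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}}
#' with \eqn{\Delta Ct = \bar{Ct}(control) - \bar{Ct}(treatment)} for the
#' target (t) and reference/housekeeping (r) genes. A plate-wide constant
#' added to every Ct cancels exactly.
#'
#' @param target,housekeeping data.frames with columns `sample`, `ct`
#' @param control_ids,treatment_ids sample ids of the two groups (>= 2 each)
#' @param E_target,E_ref amplification efficiencies (fold per cycle);
#'   default 2 = perfect doubling. Pass `curve$efficiency` for per-assay
#'   values.
#' @return list of class `expression_ratio` with ratio, log2_ratio, the two
#'   delta-Ct values and group sizes
#' @export
expression_ratio <- function(target, housekeeping, control_ids, treatment_ids,
                             E_target = 2, E_ref = 2) {
  if (length(control_ids) < 2 || length(treatment_ids) < 2) {
    stop("need at least 2 samples per group")
  }
  tc <- ct_vector(target, c(control_ids, treatment_ids), "target")
  rc <- ct_vector(housekeeping, c(control_ids, treatment_ids), "housekeeping")
  d_t <- mean(tc[control_ids]) - mean(tc[treatment_ids])
  d_r <- mean(rc[control_ids]) - mean(rc[treatment_ids])
  ratio <- E_target^d_t / E_ref^d_r
  structure(list(ratio = ratio, log2_ratio = log2(ratio),
                 delta_ct_target = d_t, delta_ct_ref = d_r,
                 E_target = E_target, E_ref = E_ref,
                 n_control = length(control_ids),
                 n_treatment = length(treatment_ids)),
            class = "expression_ratio")
}

#' @export
print.expression_ratio <- function(x, ...) {
  cat(sprintf("expression_ratio: R = %.4g (log2 %.3f)\n", x$ratio, x$log2_ratio))
  cat(sprintf("  dCt target %.3f (E=%.3f), dCt reference %.3f (E=%.3f), n=%d vs %d\n",
              x$delta_ct_target, x$E_target, x$delta_ct_ref, x$E_ref,
              x$n_control, x$n_treatment))
  if (!is.null(x$p_value)) {
    cat(sprintf("  fixed-reallocation p = %.4g (%d reallocations, seed %d)\n",
                x$p_value, x$n_reallocations, x$seed))
  }
  invisible(x)
}

#' Pairwise fixed reallocation randomization test
#'
#' Significance test for an efficiency-corrected, housekeeping-normalized
#' expression ratio. Group labels are randomly reallocated across samples;
#' each sample's target and reference Ct values travel together (fixed
#' pairing), so the reference normalization is preserved under every
#' reallocation. The two-sided statistic is |log ratio|, and the p-value
#' uses the add-one correction
#' p = (1 + #\{|log R*| >= |log R|\}) / (1 + n_reallocations).
#' Reallocations are drawn uniformly with replacement (at small n the
#' requested number may exceed the distinct label permutations).
#'
#' @inheritParams expression_ratio
#' @param n_reallocations number of random label reallocations (>= 100);
#'   2000 is the conventional default
#' @param seed integer RNG seed
#' @return `expression_ratio` object augmented with p_value,
#'   n_reallocations and seed
#' @export
fixed_reallocation_test <- function(target, housekeeping, control_ids,
                                    treatment_ids, E_target = 2, E_ref = 2,
                                    n_reallocations = 2000, seed = 1L) {
  if (n_reallocations < 100) stop("n_reallocations must be >= 100")
  obs <- expression_ratio(target, housekeeping, control_ids, treatment_ids,
                          E_target, E_ref)
  ids <- c(control_ids, treatment_ids)
  n <- length(ids)
  nc <- length(control_ids)
  tc <- ct_vector(target, ids, "target")
  rc <- ct_vector(housekeeping, ids, "housekeeping")
  # per-sample efficiency-weighted log contribution; the log ratio for a
  # control mask m is mean-difference of this composite between groups
  comp <- log(E_target) * tc - log(E_ref) * rc
  if (stats::sd(comp) == 0) {
    warning("all observations identical after normalization; p = 1")
    obs$p_value <- 1
    obs$n_reallocations <- as.integer(n_reallocations)
    obs$seed <- as.integer(seed)
    return(obs)
  }
  obs_stat <- abs(log(obs$ratio))
  withr_seed(seed, {
    idx <- vapply(seq_len(n_reallocations),
                  function(i) sample.int(n, nc), integer(nc))
  })
  mask <- matrix(0, n_reallocations, n)
  mask[cbind(rep(seq_len(n_reallocations), each = nc), as.vector(idx))] <- 1
  mean_ctl <- as.vector(mask %*% comp) / nc
  mean_trt <- as.vector((1 - mask) %*% comp) / (n - nc)
  perm_stat <- abs(mean_ctl - mean_trt)
  obs$p_value <- (1 + sum(perm_stat >= obs_stat - 1e-12)) / (1 + n_reallocations)
  obs$n_reallocations <- as.integer(n_reallocations)
  obs$seed <- as.integer(seed)
  obs
}

#' Group comparison: t-test / one-way ANOVA with SNK letters
#'
#' Two groups: unpaired two-sided t-test (pooled variance, so that the
#' one-way ANOVA F equals t^2) alongside the ANOVA. More groups: one-way
#' ANOVA followed by the Student-Newman-Keuls all-pairwise stepwise
#' procedure at `alpha`, summarized as a compact letter display (groups
#' sharing a letter are not significantly different).
#'
#' @param values numeric response
#' @param groups group labels (>= 2 groups with >= 2 values each)
#' @param alpha significance level for the SNK procedure
#' @return object of class `group_tests` with the ANOVA table, F, p,
#'   per-group summaries, SNK comparisons and letters (and t-test p for 2
#'   groups)
#' @export
group_tests <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("need at least 2 values per group")
  if (all(tapply(values, g, stats::sd) == 0)) {
    stop("zero within-group variance in every group; ANOVA undefined")
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  Fst <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  res <- list(F = Fst, p = p, anova = tab,
              groups = data.frame(group = levels(g),
                                  n = as.vector(table(g)),
                                  mean = as.vector(tapply(values, g, mean)),
                                  sd = as.vector(tapply(values, g, stats::sd))))
  if (nlevels(g) == 2) {
    res$t_test <- stats::t.test(values ~ g, var.equal = TRUE)
  }
  snk <- snk_letters(values, g, alpha = alpha)
  res$snk <- snk$comparisons
  res$letters <- snk$letters
  res$alpha <- alpha
  class(res) <- "group_tests"
  res
}

#' @export
print.group_tests <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g\n", x$F, x$p))
  gs <- x$groups
  gs$letters <- x$letters[gs$group]
  print(gs, row.names = FALSE)
  if (!is.null(x$t_test)) {
    cat(sprintf("Unpaired t-test (pooled): t = %.4g, p = %.4g\n",
                x$t_test$statistic, x$t_test$p.value))
  }
  invisible(x)
}

# Student-Newman-Keuls stepwise procedure with compact letter display.
# Means sorted descending; a span of p means is tested against the
# studentized range quantile q(1-alpha, p, df_error); once a range is
# non-significant all its sub-ranges are declared homogeneous untested.
# Ties in means are broken by group (factor level) order.
snk_letters <- function(values, g, alpha = 0.05) {
  k <- nlevels(g)
  ns <- as.vector(table(g))
  means <- as.vector(tapply(values, g, mean))
  df_err <- length(values) - k
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / df_err
  ord <- order(-means, seq_len(k))           # descending, ties by level order
  m <- means[ord]; nn <- ns[ord]; labs <- levels(g)[ord]
  nonsig <- matrix(FALSE, k, k)              # [i,j] homogeneous range i..j (sorted idx)
  comparisons <- NULL
  if (df_err > 0 && mse > 0) {
    for (span in k:2) {
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        # contained in an already-homogeneous range -> not tested
        contained <- FALSE
        if (span < k) {
          for (a in seq_len(k)) for (b in seq_len(k)) {
            if (nonsig[a, b] && a <= i && j <= b) { contained <- TRUE }
          }
        }
        if (contained) { nonsig[i, j] <- TRUE; next }
        se <- sqrt(mse / 2 * (1 / nn[i] + 1 / nn[j]))
        q <- (m[i] - m[j]) / se
        qcrit <- stats::qtukey(1 - alpha, span, df_err)
        sig <- q > qcrit
        comparisons <- rbind(comparisons, data.frame(
          group_a = labs[i], group_b = labs[j], span = span,
          diff = m[i] - m[j], q = q, q_crit = qcrit, significant = sig,
          stringsAsFactors = FALSE))
        if (!sig) nonsig[i, j] <- TRUE
      }
    }
  } else {
    # no error degrees of freedom / zero MSE: all groups declared one class
    nonsig[1, k] <- TRUE
  }
  # maximal homogeneous ranges (SNK ranges are contiguous in sorted order)
  ranges <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j || nonsig[i, j]) {
      covered <- any(vapply(ranges, function(r) r[1] <= i && j <= r[2], logical(1)))
      if (!covered) {
        ranges <- Filter(function(r) !(i <= r[1] && r[2] <= j), ranges)
        ranges <- c(ranges, list(c(i, j)))
      }
    }
  }
  ranges <- ranges[order(vapply(ranges, `[`, numeric(1), 1))]
  letters_sorted <- rep("", k)
  for (ri in seq_along(ranges)) {
    r <- ranges[[ri]]
    for (idx in r[1]:r[2]) {
      letters_sorted[idx] <- paste0(letters_sorted[idx], letters[ri])
    }
  }
  out <- stats::setNames(letters_sorted[match(seq_len(k), ord)], levels(g))
  list(letters = out, comparisons = comparisons)
}
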