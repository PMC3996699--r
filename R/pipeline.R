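#' Composite histology inflammation score
#'
#' Sum of three integer subscores — inflammation severity, inflammation
#' extent and crypt damage — each graded 0-4 on blinded H&E sections, so
#' the composite ranges from 0 to a maximum possible score of 12.
#'
#' @param severity,extent,crypt_damage integer subscores in 0-4 (vectorized)
#' @return data.frame with the three subscores and `composite`
#' @export
composite_score <- function(severity, extent, crypt_damage) {
  sub <- cbind(severity = severity, extent = extent,
               crypt_damage = crypt_damage)
  if (any(!is.finite(sub)) || any(sub != round(sub)) ||
      any(sub < 0) || any(sub > 4)) {
    stop("each subscore must be an integer in 0-4")
  }
  data.frame(severity = severity, extent = extent,
             crypt_damage = crypt_damage,
             composite = as.integer(severity + extent + crypt_damage))
}

#' Default run configuration
#'
#' Every stochastic stage carries an explicit seed; unspecified fields are
#' filled with these defaults and the fully resolved configuration is
#' echoed verbatim into the run report so that under-specified conventions
#' (pseudocounts, evenness metric, efficiency handling) stay auditable.
#'
#' @param seed master seed; stage seeds default to offsets of it
#' @param outdir output directory
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 42L, outdir = "dysbiosr_run") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(seed = as.integer(seed)),
    rarefaction = list(depth = 3500L, seed = as.integer(seed) + 1L),
    pca = list(rank = "family"),
    functions = list(level = 1L),
    qpcr = list(n_reallocations = 2000L, alpha = 0.05,
                seed = as.integer(seed) + 2L),
    network = list(threshold = 0.6, min_rel_abund = 0.01,
                   pseudocount = "half_min_nonzero")),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of [run_config()]; the
#' master `seed` is mandatory (no silent default when running from file).
#'
#' @param path YAML config file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set an explicit master seed")
  base <- run_config(seed = cfg$seed,
                     outdir = if (is.null(cfg$outdir)) "dysbiosr_run" else cfg$outdir)
  merged <- utils::modifyList(unclass(base), cfg)
  # YAML numerics arrive as doubles; pin the integer-valued fields
  merged$seed <- as.integer(merged$seed)
  merged$simulate$seed <- as.integer(merged$simulate$seed)
  merged$rarefaction$depth <- as.integer(merged$rarefaction$depth)
  merged$rarefaction$seed <- as.integer(merged$rarefaction$seed)
  merged$qpcr$n_reallocations <- as.integer(merged$qpcr$n_reallocations)
  merged$qpcr$seed <- as.integer(merged$qpcr$seed)
  merged$functions$level <- as.integer(merged$functions$level)
  class(merged) <- "run_config"
  merged
}

#' Run the full simulate-then-analyze pipeline
#'
#' Executes the seven stages — simulate, profile, diversity, ordinate,
#' functions, qpcr, network — writing every stage's outputs as TSV (plus
#' GraphML for the network) under `config$outdir`, together with a
#' machine-readable YAML report listing each stage's parameters, seed and
#' output file MD5 hashes. Re-running with the same config reproduces all
#' outputs bit for bit.
#'
#' @param config a `run_config`
#' @param effects an `effect_spec` for the simulation stage
#' @return list of class `pipeline_run` with per-stage results and the
#'   report (invisibly returns file hashes in `report$stages`)
#' @export
run_pipeline <- function(config = run_config(), effects = effect_spec()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) stop("config must set an explicit master seed")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = unclass(config), stages = list())
  results <- list()
  stage_files <- character(0)
  stage <- function(name, code) {
    out <- tryCatch(code(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    new_files <- setdiff(list.files(outdir, full.names = TRUE, recursive = TRUE),
                         stage_files)
    stage_files <<- union(stage_files, new_files)
    md5 <- tools::md5sum(sort(new_files))
    names(md5) <- substring(names(md5), nchar(outdir) + 2)  # outdir-relative
    report$stages[[name]] <<- list(outputs = as.list(md5))
    out
  }

  results$simulate <- stage("simulate", function() {
    design <- study_design(seed = config$simulate$seed)
    sim <- simulate_study(design, effects)
    write_simulation(sim, file.path(outdir, "simulated"))
    sim
  })
  sim <- results$simulate
  days <- sim$samples$day[match(colnames(sim$taxa$counts), sim$samples$sample)]

  results$profile <- stage("profile", function() {
    fam <- aggregate_by_rank(sim$taxa, "family")
    rel <- relative_abundance(fam)
    write_tsv_canonical(data.frame(family = rownames(rel), signif(rel, 8)),
                        file.path(outdir, "family_relative_abundance.tsv"))
    ord <- relative_abundance(aggregate_by_rank(sim$taxa, "order"))
    ratio <- taxon_ratio(ord, "Clostridiales", "Bacteroidales")
    write_tsv_canonical(data.frame(sample = names(ratio), day = days,
                                   clostridiales_bacteroidales = signif(ratio, 8)),
                        file.path(outdir, "taxon_ratio.tsv"))
    list(family_rel = rel, order_rel = ord, ratio = ratio)
  })

  results$diversity <- stage("diversity", function() {
    ad <- alpha_diversity(sim$otus, depth = config$rarefaction$depth,
                          seed = config$rarefaction$seed)
    ad$richness <- signif(ad$richness, 8)
    ad$shannon <- signif(ad$shannon, 8)
    ad$evenness <- signif(ad$evenness, 8)
    write_tsv_canonical(ad, file.path(outdir, "alpha_diversity.tsv"))
    ad
  })

  results$ordinate <- stage("ordinate", function() {
    rel <- results$profile$family_rel
    bc <- dissimilarity_matrix(rel, mode = "abundance")
    bcb <- dissimilarity_matrix(rel, mode = "binary")
    write_tsv_canonical(data.frame(sample = rownames(bc$matrix),
                                   signif(bc$matrix, 8)),
                        file.path(outdir, "bray_curtis_abundance.tsv"))
    write_tsv_canonical(data.frame(sample = rownames(bcb$matrix),
                                   signif(bcb$matrix, 8)),
                        file.path(outdir, "bray_curtis_binary.tsv"))
    pc <- pca(t(rel))
    write_tsv_canonical(data.frame(sample = rownames(pc$scores),
                                   day = days, signif(pc$scores, 8)),
                        file.path(outdir, "pca_scores.tsv"))
    write_tsv_canonical(data.frame(variable = rownames(pc$loadings),
                                   signif(pc$loadings, 8)),
                        file.path(outdir, "pca_loadings.tsv"))
    write_tsv_canonical(data.frame(component = seq_along(pc$eigenvalues),
                                   eigenvalue = signif(pc$eigenvalues, 8),
                                   prop_variance = signif(pc$prop_variance, 8)),
                        file.path(outdir, "pca_eigenvalues.tsv"))
    list(bc = bc, bc_binary = bcb, pca = pc)
  })

  results$functions <- stage("functions", function() {
    ct <- aggregate_categories(sim$functions, sim$hierarchy,
                               level = config$functions$level)
    write_tsv_canonical(data.frame(category = rownames(ct$fractions),
                                   signif(ct$fractions, 8)),
                        file.path(outdir, "category_fractions.tsv"))
    pch <- percent_change_vs_baseline(ct, days, baseline_day = min(days))
    write_tsv_canonical(data.frame(category = rownames(pch), signif(pch, 8)),
                        file.path(outdir, "category_percent_change.tsv"))
    mucin <- panel_fraction(sim$functions, mucin_panel_genes(),
                            denominator = "taxon_subset", taxon = "Bacteroidetes")
    write_tsv_canonical(data.frame(sample = names(mucin), day = days,
                                   mucin_fraction = signif(mucin, 8)),
                        file.path(outdir, "mucin_panel_fraction.tsv"))
    list(categories = ct, percent_change = pch, mucin = mucin)
  })

  results$qpcr <- stage("qpcr", function() {
    curve <- fit_standard_curve(sim$qpcr_curve$log10_copies, sim$qpcr_curve$ct)
    idx <- flagellin_index(
      transcripts = data.frame(mouse = sim$flagellin$mouse,
                               copies_per_ul = sim$flagellin$transcript_copies_per_ul),
      genes = data.frame(mouse = sim$flagellin$mouse,
                         copies_per_ul = sim$flagellin$gene_copies_per_ul))
    gm <- flagellin_group_means(idx, sim$flagellin$day)
    write_tsv_canonical(transform(gm, mean = signif(mean, 8), sd = signif(sd, 8)),
                        file.path(outdir, "flagellin_group_means.tsv"))
    day1 <- sim$samples$sample[sim$samples$day == min(days)]
    rest <- lapply(setdiff(unique(days), min(days)), function(d) {
      ids <- sim$samples$sample[sim$samples$day == d]
      res <- lapply(setdiff(unique(sim$host_qpcr$gene), "GAPDH"), function(g) {
        tg <- sim$host_qpcr[sim$host_qpcr$gene == g, c("sample", "ct")]
        hk <- sim$host_qpcr[sim$host_qpcr$gene == "GAPDH", c("sample", "ct")]
        r <- fixed_reallocation_test(tg, hk, day1, ids,
                                     n_reallocations = config$qpcr$n_reallocations,
                                     seed = config$qpcr$seed)
        data.frame(day = d, gene = g, ratio = signif(r$ratio, 8),
                   p = signif(r$p_value, 8), stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    })
    rest <- do.call(rbind, rest)
    write_tsv_canonical(rest, file.path(outdir, "expression_ratios.tsv"))
    list(curve = curve, index = idx, group_means = gm, ratios = rest)
  })

  results$network <- stage("network", function() {
    fm <- assemble_features(host = sim$host_markers,
                            otu_rel = relative_abundance(sim$otus),
                            categ = results$functions$categories$fractions,
                            min_rel_abund = config$network$min_rel_abund)
    fm <- log_normalize(fm, pseudocount = config$network$pseudocount)
    net <- build_network(fm, threshold = config$network$threshold)
    export_network(net, file.path(outdir, "network.graphml"), "graphml")
    export_network(net, file.path(outdir, "network_edges.tsv"), "edgelist")
    net
  })

  report$n_stages <- length(report$stages)
  yaml::write_yaml(report, file.path(outdir, "report.yaml"))
  structure(list(results = results, report = report, outdir = outdir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: %d stages completed -> %s\n",
              x$report$n_stages, x$outdir))
  for (s in names(x$report$stages)) {
    cat(sprintf("  %-10s %d output file(s)\n", s,
                length(x$report$stages[[s]]$outputs)))
  }
  invisible(x)
}
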