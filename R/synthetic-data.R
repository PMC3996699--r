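#' Study design for the synthetic DSS-colitis time course
#'
#' Captures the sampling frame of a longitudinal colitis experiment:
#' cross-sectional sacrifice of a few mice per day over a
#' treatment-and-recovery time course, with per-kind sequencing depths.
#'
#' @param days strictly increasing sampling days (default the classic
#'   1/5/8/14/25 course: before treatment, end of treatment, peak
#'   inflammation, early and late recovery)
#' @param mice_per_day mice sacrificed per day; a single integer (>= 2, so
#'   group statistics exist) or one integer per day
#' @param litters number of litters mice are drawn from (assigned
#'   round-robin)
#' @param seed integer RNG seed; the whole simulation is a deterministic
#'   function of (design, effects, seed)
#' @param library_size_range reads per sample for the rRNA-derived taxon
#'   table (emulating ~1e5 classified rRNA reads)
#' @param otu_library_size_range reads per sample for the amplicon OTU
#'   table; must not fall below the rarefaction depth used downstream
#' @param function_library_size_range functionally annotated mRNA reads per
#'   sample
#' @return list of class `study_design`
#' @export
study_design <- function(days = c(1L, 5L, 8L, 14L, 25L),
                         mice_per_day = 4L,
                         litters = 3L,
                         seed = 42L,
                         library_size_range = c(80000L, 120000L),
                         otu_library_size_range = c(5000L, 26000L),
                         function_library_size_range = c(100000L, 200000L)) {
  days <- as.integer(days)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  mice_per_day <- as.integer(rep(mice_per_day, length.out = length(days)))
  if (any(mice_per_day < 2)) stop("mice_per_day must be >= 2")
  if (litters < 1) stop("litters must be >= 1")
  for (r in list(library_size_range, otu_library_size_range,
                 function_library_size_range)) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      stop("library size ranges must be increasing pairs of positive integers")
    }
  }
  structure(list(days = days, mice_per_day = mice_per_day, litters = litters,
                 seed = as.integer(seed),
                 library_size_range = as.integer(library_size_range),
                 otu_library_size_range = as.integer(otu_library_size_range),
                 function_library_size_range = as.integer(function_library_size_range)),
            class = "study_design")
}

#' Default family-level mean relative-abundance trajectories
#'
#' Two dominant orders (Clostridiales + Bacteroidales ~95% of rRNA reads at
#' day 1), a Clostridiales dip and Bacteroidales expansion at peak
#' inflammation, and low-abundance bloomers during the acute phase.
#' @return family x day matrix of mean relative abundances
#' @export
default_taxon_trajectories <- function() {
  tr <- rbind(
    Lachnospiraceae      = c(0.450, 0.380, 0.220, 0.380, 0.420),
    Ruminococcaceae      = c(0.180, 0.150, 0.100, 0.150, 0.170),
    uc_Clostridiales     = c(0.020, 0.018, 0.015, 0.018, 0.020),
    Bacteroidaceae       = c(0.080, 0.100, 0.200, 0.100, 0.090),
    Porphyromonadaceae   = c(0.060, 0.070, 0.110, 0.070, 0.060),
    Prevotellaceae       = c(0.050, 0.060, 0.100, 0.060, 0.050),
    Rikenellaceae        = c(0.050, 0.050, 0.060, 0.050, 0.050),
    uc_Bacteroidales     = c(0.060, 0.120, 0.080, 0.070, 0.060),
    Enterobacteriaceae   = c(0.002, 0.010, 0.030, 0.004, 0.002),
    Verrucomicrobiaceae  = c(0.002, 0.008, 0.022, 0.003, 0.002),
    Erysipelotrichaceae  = c(0.003, 0.008, 0.015, 0.010, 0.005),
    Turicibacteraceae    = c(0.008, 0.012, 0.025, 0.012, 0.008),
    Deferribacteraceae   = c(0.002, 0.006, 0.014, 0.003, 0.002))
  colnames(tr) <- c(1, 5, 8, 14, 25)
  tr
}

#' Lineages (family/order/phylum) for the default taxon trajectories
#' @return data.frame with columns family, order, phylum
#' @export
default_taxon_lineages <- function() {
  data.frame(
    family = rownames(default_taxon_trajectories()),
    order = c("Clostridiales", "Clostridiales", "Clostridiales",
              "Bacteroidales", "Bacteroidales", "Bacteroidales",
              "Bacteroidales", "Bacteroidales", "Enterobacteriales",
              "Verrucomicrobiales", "Erysipelotrichales",
              "Erysipelotrichales", "Deferribacterales"),
    phylum = c("Firmicutes", "Firmicutes", "Firmicutes",
               "Bacteroidetes", "Bacteroidetes", "Bacteroidetes",
               "Bacteroidetes", "Bacteroidetes", "Proteobacteria",
               "Verrucomicrobia", "Firmicutes", "Firmicutes",
               "Deferribacteres"),
    stringsAsFactors = FALSE)
}

#' Default level-1 category mean fractions of annotated mRNA reads
#'
#' 'Motility and Chemotaxis' carries the planted 21%/49% declines at days
#' 5/8; the remainder of each day's simplex is emitted as a Miscellaneous
#' pool at simulation time.
#' @return category x day matrix of mean fractions
#' @export
default_category_trajectories <- function() {
  tr <- rbind(
    "Protein Metabolism"          = c(0.200, 0.200, 0.200, 0.200, 0.200),
    "Carbohydrate Metabolism"     = c(0.220, 0.220, 0.200, 0.220, 0.220),
    "Motility and Chemotaxis"     = c(0.080, 0.080 * 0.79, 0.080 * 0.51,
                                      0.070, 0.075),
    "Virulence"                   = c(0.050, 0.060, 0.080, 0.060, 0.050),
    "RNA Metabolism"              = c(0.040, 0.050, 0.060, 0.045, 0.040),
    "Stress Response"             = c(0.030, 0.040, 0.050, 0.035, 0.030),
    "Sulfur Metabolism"           = c(0.010, 0.012, 0.020, 0.012, 0.010),
    "Regulation and Cell Signalling" = c(0.030, 0.028, 0.020, 0.028, 0.030),
    "Clustering-based subsystems" = c(0.050, 0.055, 0.065, 0.050, 0.050),
    "DNA Metabolism"              = c(0.030, 0.033, 0.040, 0.033, 0.030),
    "Cofactors, Vitamins, Prosthetic Groups, Pigments" =
                                    c(0.040, 0.044, 0.050, 0.044, 0.040),
    "Fatty Acids"                 = c(0.010, 0.012, 0.015, 0.012, 0.010))
  colnames(tr) <- c(1, 5, 8, 14, 25)
  tr
}

#' Mucin-degradation gene panel
#' @return character vector of the curated panel gene ids
#' @export
mucin_panel_genes <- function() {
  c("beta_hexosaminidase", "alpha_mannosidase", "beta_mannosidase",
    "neuraminidase_sialidase", "beta_galactosidase", "sulfatase")
}

#' Butyrate-pathway gene panel
#' @return character vector of the curated panel gene ids
#' @export
butyrate_panel_genes <- function() {
  c("acetyl_CoA_acetyltransferase", "hydroxybutyryl_CoA_dehydratase",
    "butyryl_CoA_dehydrogenase", "butyrate_kinase",
    "phosphate_butyryltransferase", "butyryl_CoA_acetate_CoA_transferase")
}

# gene catalog: function_gene -> category path, taxon attribution, and a
# fixed within-category weight used to split category mass across genes
default_gene_catalog <- function(categories) {
  special <- list(
    "Motility and Chemotaxis" = data.frame(
      function_gene = c("flagellin_fliC", "flagellar_hook_flgE",
                        "flagellar_motor_motA", "chemotaxis_cheA",
                        "chemotaxis_cheY", "methyl_accepting_mcp"),
      level2 = c(rep("Flagellar Motility", 3), rep("Bacterial Chemotaxis", 3)),
      level3 = c("Flagellum biosynthesis", "Flagellum biosynthesis",
                 "Flagellar motor", "Chemotaxis signal transduction",
                 "Chemotaxis signal transduction", "Chemoreceptors"),
      taxon = rep("Firmicutes", 6),
      weight = c(0.45, 0.20, 0.15, 0.08, 0.07, 0.05),
      stringsAsFactors = FALSE),
    "Carbohydrate Metabolism" = rbind(
      data.frame(function_gene = mucin_panel_genes(),
                 level2 = c(rep("Aminosugars", 2), "Aminosugars",
                            "Aminosugars", "Aminosugars", "Sulfatases"),
                 level3 = c("N-acetylglucosamine utilization",
                            "Mannose degradation", "Mannose degradation",
                            "Sialic acid metabolism", "Lactose degradation",
                            "Mucin sulfate removal"),
                 taxon = rep("Bacteroidetes", 6),
                 weight = rep(0, 6),      # mass assigned by mucin trajectory
                 stringsAsFactors = FALSE),
      data.frame(function_gene = butyrate_panel_genes(),
                 level2 = rep("Fermentation", 6),
                 level3 = rep("Acetyl-CoA fermentation to butyrate", 6),
                 taxon = rep("Firmicutes", 6),
                 weight = c(0.08, 0.06, 0.06, 0.04, 0.04, 0.02),
                 stringsAsFactors = FALSE),
      data.frame(function_gene = c("glycogen_phosphorylase", "pyruvate_kinase",
                                   "mglA_galactose_ABC", "pfl_pyruvate_formate_lyase"),
                 level2 = c("Polysaccharides", "Glycolysis", "Monosaccharides",
                            "Fermentation"),
                 level3 = c("Glycogen metabolism", "Glycolysis core",
                            "Galactose uptake MglABC", "Butanol Biosynthesis"),
                 taxon = c("Bacteroidetes", "Firmicutes", "Firmicutes",
                           "Firmicutes"),
                 weight = c(0.25, 0.25, 0.10, 0.10),
                 stringsAsFactors = FALSE)))
  out <- NULL
  taxa_cycle <- c("Firmicutes", "Bacteroidetes", "Firmicutes", "other")
  for (cc in categories) {
    if (cc %in% names(special)) {
      d <- special[[cc]]
    } else {
      k <- 4
      d <- data.frame(
        function_gene = paste0(gsub("[^A-Za-z]+", "_", cc), "_gene", seq_len(k)),
        level2 = paste(cc, "subsystems", rep(c("A", "B"), each = 2)),
        level3 = paste(cc, "pathway", seq_len(k)),
        taxon = taxa_cycle[seq_len(k)],
        weight = c(0.4, 0.3, 0.2, 0.1),
        stringsAsFactors = FALSE)
    }
    d$level1 <- cc
    out <- rbind(out, d)
  }
  out[, c("function_gene", "level1", "level2", "level3", "taxon", "weight")]
}

#' Default host-marker trajectories
#'
#' Mean log2 expression ratios vs day 1 for cytokines, iNOS and TLR5, plus
#' the composite pathology score on its own 0-12 scale.
#' @return marker x day matrix
#' @export
default_host_marker_trajectories <- function() {
  tr <- rbind(
    IL1b  = c(0, 0.5, 3.0, 2.0, 1.5),
    IL6   = c(0, 0.5, 3.5, 2.0, 1.5),
    IFNg  = c(0, 0.3, 2.5, 1.5, 0.0),
    CXCL1 = c(0, 0.5, 3.0, 2.0, 1.5),
    IL10  = c(0, -1.5, 0.0, 0.0, 0.0),
    iNOS  = c(0, 0.3, 2.8, 2.0, 0.0),
    TLR5  = c(0, -0.3, -1.0, -0.5, -0.2),
    pathology_score = c(0.5, 3.0, 9.0, 6.0, 3.0))
  colnames(tr) <- c(1, 5, 8, 14, 25)
  tr
}

#' Default planted host-marker/phylotype correlations
#' @return data.frame feature_a, feature_b, rho
#' @export
default_planted_edges <- function() {
  data.frame(
    feature_a = c("IFNg", "IFNg", "iNOS", "IL10", "IL10", "TLR5"),
    feature_b = c("Turicibacteraceae_OTU_2651", "Bacteroidales_OTU_102",
                  "Lachnospiraceae_OTU_2896", "Ruminococcaceae_OTU_1695",
                  "Akkermansia_OTU_711", "Motility and Chemotaxis"),
    rho = c(0.8, -0.8, -0.7, 0.7, 0.7, 0.7),
    stringsAsFactors = FALSE)
}

#' Effect specification for the synthetic time course
#'
#' All planted biology of the simulation, with defaults calibrated to the
#' summary statistics of a moderate-to-severe DSS course: two dominant
#' orders jointly ~95\% of rRNA reads in health, a 21\%/49\% decline of
#' 'Motility and Chemotaxis' transcripts at days 5/8, a
#' Bacteroidetes-restricted mucin-degradation panel rising from 1.36\% to
#' 2.03\% of Bacteroidetes reads at day 8, flagellin transcript:gene log10
#' ratios near 0.09 in health vs -0.34 at peak colitis, and a set of
#' planted host-marker/OTU/category correlations.
#'
#' @param taxon_trajectories family x day matrix of mean relative
#'   abundances; per-day columns must each sum to <= 1 (the remainder goes
#'   to an `other` bin that is never emitted as a biological taxon)
#' @param taxon_lineages data.frame family/order/phylum for the rows above
#' @param category_trajectories level-1 category x day matrix of mean mRNA
#'   fractions (per-day sums <= 1, remainder to `other`)
#' @param gene_catalog data.frame function_gene/level1/level2/level3/
#'   taxon/weight used to split category mass into genes
#' @param mucin_trajectory per-day mucin-panel fraction of
#'   Bacteroidetes-attributed reads
#' @param host_marker_trajectories marker x day matrix of mean log2
#'   expression ratios vs day 1
#' @param host_marker_sd Gaussian sd of marker values on the log2 scale
#' @param flagellin_logratio_means,flagellin_logratio_sds per-day mean and
#'   sd of log10(transcript copies / gene copies)
#' @param flagellin_gene_log10_means per-day mean log10 flagellin gene
#'   copies per microliter
#' @param planted_edges data.frame feature_a/feature_b/rho of pairwise
#'   correlations to plant (|rho| < 1); implemented through shared latent
#'   Gaussian factors on the log scale. Edges sharing a feature form one
#'   factor and must share |rho|.
#' @param planted_modules optional list of `list(features =, rho =)` blocks
#'   of mutually correlated features (rho > 0)
#' @param noise list of dispersion parameters: `taxon_concentration` and
#'   `otu_concentration` (Dirichlet precision of per-sample compositions),
#'   `function_dispersion` (gamma shape of per-gene rate noise; the
#'   negative-binomial size once counts are drawn), `otu_factor_sd` and
#'   `category_factor_sd` (log10-scale sd through which latent factors act
#'   on abundances), `host_ct_sd` (technical Ct noise)
#' @param otus_per_family OTUs each family is split into
#' @return list of class `effect_spec`
#' @export
effect_spec <- function(taxon_trajectories = default_taxon_trajectories(),
                        taxon_lineages = default_taxon_lineages(),
                        category_trajectories = default_category_trajectories(),
                        gene_catalog = NULL,
                        mucin_trajectory = c(1.36, 1.39, 2.03, 1.31, 1.33) / 100,
                        host_marker_trajectories = default_host_marker_trajectories(),
                        host_marker_sd = 0.5,
                        flagellin_logratio_means = c(0.09, 0.05, -0.34, -0.10, -0.25),
                        flagellin_logratio_sds = c(0.18, 0.20, 0.31, 0.35, 0.25),
                        flagellin_gene_log10_means = c(5.0, 4.9, 4.4, 4.8, 4.9),
                        planted_edges = default_planted_edges(),
                        planted_modules = list(),
                        noise = list(),
                        otus_per_family = 3L) {
  noise_def <- list(taxon_concentration = 200, otu_concentration = 100,
                    function_dispersion = 200, otu_factor_sd = 0.3,
                    category_factor_sd = 0.02, host_ct_sd = 0.15)
  noise <- utils::modifyList(noise_def, noise)
  if (any(unlist(noise) <= 0)) stop("all dispersion/noise parameters must be > 0")
  if (any(taxon_trajectories < 0) || any(taxon_trajectories > 1)) {
    stop("taxon relative abundances must lie in [0, 1]")
  }
  if (any(colSums(taxon_trajectories) > 1 + 1e-9)) {
    stop("per-day taxon abundances must sum to <= 1")
  }
  if (any(colSums(category_trajectories) > 1 + 1e-9) ||
      any(category_trajectories < 0)) {
    stop("per-day category fractions must lie in [0, 1] and sum to <= 1")
  }
  if (nrow(planted_edges) > 0 && any(abs(planted_edges$rho) >= 1)) {
    stop("|rho| must be < 1 for all planted edges")
  }
  if (is.null(gene_catalog)) {
    gene_catalog <- default_gene_catalog(rownames(category_trajectories))
  }
  structure(list(taxon_trajectories = taxon_trajectories,
                 taxon_lineages = taxon_lineages,
                 category_trajectories = category_trajectories,
                 gene_catalog = gene_catalog,
                 mucin_trajectory = mucin_trajectory,
                 host_marker_trajectories = host_marker_trajectories,
                 host_marker_sd = host_marker_sd,
                 flagellin_logratio_means = flagellin_logratio_means,
                 flagellin_logratio_sds = flagellin_logratio_sds,
                 flagellin_gene_log10_means = flagellin_gene_log10_means,
                 planted_edges = planted_edges,
                 planted_modules = planted_modules,
                 noise = noise,
                 otus_per_family = as.integer(otus_per_family)),
            class = "effect_spec")
}

#' A flat (null) effect specification
#'
#' All trajectories constant at their day-1 value and no planted edges
#' (unless supplied): no day effect is recoverable and downstream analyses
#' should report no structure beyond chance.
#'
#' @param planted_edges optional planted correlations to keep
#' @param planted_modules optional planted modules to keep
#' @param ... passed through to [effect_spec()]
#' @return an `effect_spec`
#' @export
flat_effects <- function(planted_edges = default_planted_edges()[0, ],
                         planted_modules = list(), ...) {
  tt <- default_taxon_trajectories(); tt[] <- tt[, 1]
  ct <- default_category_trajectories(); ct[] <- ct[, 1]
  hm <- default_host_marker_trajectories(); hm[] <- hm[, 1]
  effect_spec(taxon_trajectories = tt, category_trajectories = ct,
              host_marker_trajectories = hm,
              mucin_trajectory = rep(0.0136, 5),
              flagellin_logratio_means = rep(0.09, 5),
              flagellin_logratio_sds = rep(0.18, 5),
              flagellin_gene_log10_means = rep(5, 5),
              planted_edges = planted_edges,
              planted_modules = planted_modules, ...)
}

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))   # pathological tiny alpha
  stats::setNames(g / sum(g), names(alpha))
}

# latent factor matrix for planted edges/modules; returns features x samples
# z-values with the requested pairwise correlations on the latent scale
planted_latents <- function(edges, modules, n) {
  feats <- unique(c(edges$feature_a, edges$feature_b,
                    unlist(lapply(modules, `[[`, "features"))))
  z <- matrix(0, length(feats), n, dimnames = list(feats, NULL))
  if (!length(feats)) return(z)
  assigned <- character(0)
  # connected components of the edge list
  if (nrow(edges) > 0) {
    comp <- seq_len(nrow(edges))
    nodes <- unique(c(edges$feature_a, edges$feature_b))
    cid <- stats::setNames(seq_along(nodes), nodes)
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(edges))) {
        a <- cid[edges$feature_a[i]]; b <- cid[edges$feature_b[i]]
        if (a != b) { cid[cid == max(a, b)] <- min(a, b); changed <- TRUE }
      }
      if (!changed) break
    }
    for (cc in unique(cid)) {
      members <- names(cid)[cid == cc]
      sub <- edges[edges$feature_a %in% members | edges$feature_b %in% members, ]
      rho <- abs(sub$rho)
      if (max(rho) - min(rho) > 1e-9) {
        stop("planted edges sharing a feature must share |rho| (features: ",
             paste(members, collapse = ", "), ")")
      }
      rho <- rho[1]
      # sign assignment by BFS so that sign_a * sign_b = sign(rho_ab)
      sgn <- stats::setNames(rep(NA_real_, length(members)), members)
      sgn[members[1]] <- 1
      repeat {
        progressed <- FALSE
        for (i in seq_len(nrow(sub))) {
          a <- sub$feature_a[i]; b <- sub$feature_b[i]; s <- sign(sub$rho[i])
          if (!is.na(sgn[a]) && is.na(sgn[b])) { sgn[b] <- sgn[a] * s; progressed <- TRUE }
          if (!is.na(sgn[b]) && is.na(sgn[a])) { sgn[a] <- sgn[b] * s; progressed <- TRUE }
          if (!is.na(sgn[a]) && !is.na(sgn[b]) && sgn[a] * sgn[b] != s) {
            stop("inconsistent edge signs in planted component: ",
                 paste(members, collapse = ", "))
          }
        }
        if (!progressed) break
      }
      f <- stats::rnorm(n)
      for (m in members) {
        z[m, ] <- sgn[m] * sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
      }
      assigned <- c(assigned, members)
    }
  }
  for (mod in modules) {
    if (mod$rho <= 0 || mod$rho >= 1) stop("module rho must be in (0, 1)")
    overlap <- intersect(mod$features, assigned)
    if (length(overlap)) stop("feature(s) in both edges and modules: ",
                              paste(overlap, collapse = ", "))
    f <- stats::rnorm(n)
    for (m in mod$features) {
      z[m, ] <- sqrt(mod$rho) * f + sqrt(1 - mod$rho) * stats::rnorm(n)
    }
    assigned <- c(assigned, mod$features)
  }
  z
}

# split families into OTUs with fixed geometric within-family weights;
# canonical OTU names for phylotypes referenced by default planted edges
otu_catalog <- function(lineages, otus_per_family) {
  named_first <- c(Bacteroidaceae = "Bacteroides_acidifaciens_OTU_1812",
                   Lachnospiraceae = "Lachnospiraceae_OTU_2896",
                   Ruminococcaceae = "Ruminococcaceae_OTU_1695",
                   Verrucomicrobiaceae = "Akkermansia_OTU_711",
                   Turicibacteraceae = "Turicibacteraceae_OTU_2651",
                   uc_Bacteroidales = "Bacteroidales_OTU_102")
  named_second <- c(uc_Bacteroidales = "Bacteroidales_OTU_183")
  named_third <- c(uc_Bacteroidales = "Bacteroidales_OTU_1366")
  out <- NULL
  for (i in seq_len(nrow(lineages))) {
    fam <- lineages$family[i]
    k <- otus_per_family
    w <- 0.55^(seq_len(k) - 1); w <- w / sum(w)
    ids <- paste0(fam, "_OTU_", 1000 + i * 10 + seq_len(k))
    if (fam %in% names(named_first)) ids[1] <- named_first[[fam]]
    if (fam %in% names(named_second) && k >= 2) ids[2] <- named_second[[fam]]
    if (fam %in% names(named_third) && k >= 3) ids[3] <- named_third[[fam]]
    out <- rbind(out, data.frame(otu = ids, family = fam,
                                 order = lineages$order[i],
                                 phylum = lineages$phylum[i],
                                 weight = w, stringsAsFactors = FALSE))
  }
  out
}

#' Simulate a complete synthetic DSS-colitis study
#'
#' Generates, from a [study_design()] and an [effect_spec()], the derived
#' tables a longitudinal colitis study produces: an rRNA taxon count table,
#' an amplicon OTU count table, a function-gene mRNA count table with its
#' 3-level hierarchy, host-marker expression values (log2 ratios vs day 1)
#' with matching qPCR Ct measurements, a flagellin transcript/gene qPCR
#' panel, the sample sheet, and the full ground truth. Taxon and OTU counts
#' are multinomial draws from Dirichlet-perturbed per-sample compositions;
#' function-gene counts follow gamma-overdispersed gene rates conditioned
#' on the drawn library size (negative-binomial-type overdispersion at a
#' controlled total). Planted correlations act through shared latent
#' Gaussian factors on the log scale. The same (design, effects, seed)
#' triple reproduces the output bit for bit.
#'
#' @param design a `study_design`
#' @param effects an `effect_spec`
#' @return list of class `dysbiosis_simulation`: `taxa`, `otus`,
#'   `functions` (count_tables), `hierarchy`, `samples` (sample_info),
#'   `host_markers` (marker x sample matrix), `host_qpcr` (long Ct table
#'   incl. GAPDH), `flagellin` (per-mouse copy numbers), `qpcr_curve`
#'   (standard-curve points), and `truth`
#' @export
simulate_study <- function(design = study_design(), effects = effect_spec()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  nd <- length(design$days)
  for (m in list(effects$taxon_trajectories, effects$category_trajectories,
                 effects$host_marker_trajectories)) {
    if (ncol(m) != nd) {
      stop("trajectory has ", ncol(m), " day columns but the design has ", nd)
    }
  }
  for (v in list(effects$mucin_trajectory, effects$flagellin_logratio_means,
                 effects$flagellin_logratio_sds,
                 effects$flagellin_gene_log10_means)) {
    if (length(v) != nd) stop("per-day effect vector length != number of days")
  }
  withr_seed(design$seed, simulate_study_impl(design, effects))
}

simulate_study_impl <- function(design, effects) {
  days <- design$days
  day_of <- rep(days, design$mice_per_day)
  n <- length(day_of)
  mouse <- paste0("M", sprintf("%02d", seq_len(n)))
  sample_id <- sprintf("d%02d_%s", day_of, mouse)
  litter <- paste0("L", (seq_len(n) - 1) %% design$litters + 1)
  samples <- sample_info(data.frame(
    sample = sample_id, mouse = mouse, litter = litter, day = day_of,
    group = ifelse(day_of == days[1], "control", "treated"),
    stringsAsFactors = FALSE), expected_days = days)
  di <- match(day_of, days)
  noise <- effects$noise

  z <- planted_latents(effects$planted_edges, effects$planted_modules, n)
  colnames(z) <- sample_id

  ## taxon table -------------------------------------------------------------
  tt <- effects$taxon_trajectories
  taxa_names <- c(rownames(tt), "other")
  taxa_p_true <- matrix(0, length(taxa_names), n,
                        dimnames = list(taxa_names, sample_id))
  taxa_counts <- taxa_p_true
  for (s in seq_len(n)) {
    comp <- c(tt[, di[s]], other = max(0, 1 - sum(tt[, di[s]])))
    p <- rdirichlet1(noise$taxon_concentration * comp)
    lib <- sample(design$library_size_range[1]:design$library_size_range[2], 1)
    taxa_p_true[, s] <- p
    taxa_counts[, s] <- stats::rmultinom(1, lib, p)
  }
  lin <- effects$taxon_lineages
  anno_t <- data.frame(
    phylum = c(lin$phylum, "unclassified"),
    order = c(lin$order, "unclassified"),
    family = c(sub("^uc_", "unclassified ", lin$family), "unclassified"),
    stringsAsFactors = FALSE)
  taxa <- count_table(taxa_counts, kind = "taxon", annotation = anno_t)

  ## OTU table ---------------------------------------------------------------
  oc <- otu_catalog(effects$taxon_lineages, effects$otus_per_family)
  base <- tt[oc$family, , drop = FALSE] * oc$weight    # otu x day means
  rownames(base) <- oc$otu
  # residual composition mass is emitted as an explicit unclassified
  # phylotype pool, so per-sample totals stay at the drawn library size
  otu_ids <- c(oc$otu, "unclassified_OTU_0")
  otu_p_true <- matrix(0, length(otu_ids), n, dimnames = list(otu_ids, sample_id))
  otu_counts <- otu_p_true
  planted_otus <- intersect(rownames(base), rownames(z))
  for (s in seq_len(n)) {
    comp <- stats::setNames(c(base[, di[s]], max(0, 1 - sum(base[, di[s]]))),
                            otu_ids)
    p <- rdirichlet1(noise$otu_concentration * comp / sum(comp))
    if (length(planted_otus)) {
      # for planted phylotypes the latent factor IS the per-sample
      # perturbation (it replaces the Dirichlet draw): the log-scale
      # correlation then survives count sampling without attenuation by
      # compositional noise
      pp <- base[planted_otus, di[s]] *
        10^(noise$otu_factor_sd * z[planted_otus, s])
      free <- setdiff(names(p), planted_otus)
      p[free] <- p[free] / sum(p[free]) * max(1e-12, 1 - sum(pp))
      p[planted_otus] <- pp
    }
    lib <- sample(design$otu_library_size_range[1]:design$otu_library_size_range[2], 1)
    otu_p_true[, s] <- p
    otu_counts[, s] <- stats::rmultinom(1, lib, p)
  }
  anno_o <- data.frame(phylum = c(oc$phylum, "unclassified"),
                       order = c(oc$order, "unclassified"),
                       family = c(sub("^uc_", "unclassified ", oc$family),
                                  "unclassified"),
                       stringsAsFactors = FALSE)
  otus <- count_table(otu_counts, kind = "otu", annotation = anno_o)

  ## function table ----------------------------------------------------------
  cat_tr <- effects$category_trajectories
  gc <- effects$gene_catalog
  # residual mRNA mass goes to an explicit Miscellaneous pool so the level-1
  # categories partition every annotated read (fractions sum to 1)
  if (!"miscellaneous_pool" %in% gc$function_gene) {
    gc <- rbind(gc, data.frame(function_gene = "miscellaneous_pool",
                               level1 = "Miscellaneous",
                               level2 = "Miscellaneous subsystems",
                               level3 = "Miscellaneous pool",
                               taxon = "other", weight = 1,
                               stringsAsFactors = FALSE))
  }
  mucin <- mucin_panel_genes()
  genes <- gc$function_gene
  gene_p_true <- matrix(0, length(genes), n, dimnames = list(genes, sample_id))
  fun_counts <- gene_p_true
  cat_frac_true <- matrix(0, nrow(cat_tr), n,
                          dimnames = list(rownames(cat_tr), sample_id))
  planted_cats <- intersect(rownames(cat_tr), rownames(z))
  for (s in seq_len(n)) {
    cf <- cat_tr[, di[s]]
    if (length(planted_cats)) {
      cf[planted_cats] <- cf[planted_cats] *
        10^(noise$category_factor_sd * z[planted_cats, s])
    }
    # split category mass into gene means via catalog weights
    gm <- stats::setNames(numeric(length(genes)), genes)
    for (cc in rownames(cat_tr)) {
      rows <- which(gc$level1 == cc & !(gc$function_gene %in% mucin))
      w <- gc$weight[rows]
      gm[gc$function_gene[rows]] <- cf[cc] * w / sum(w)
    }
    # mucin panel: fixed fraction of Bacteroidetes-attributed reads, carved
    # out of the carbohydrate share so totals stay put
    f_muc <- effects$mucin_trajectory[di[s]]
    b0 <- sum(gm[gc$function_gene[gc$taxon == "Bacteroidetes" &
                                  !(gc$function_gene %in% mucin)]])
    m_mass <- f_muc / (1 - f_muc) * b0
    w_m <- c(0.30, 0.18, 0.12, 0.15, 0.15, 0.10)
    gm[mucin] <- m_mass * w_m
    carb_rows <- gc$function_gene[gc$level1 == "Carbohydrate Metabolism" &
                                  !(gc$function_gene %in% mucin)]
    gm[carb_rows] <- gm[carb_rows] * max(0, 1 - m_mass / sum(gm[carb_rows]))
    gm["miscellaneous_pool"] <- max(0, 1 - sum(gm))
    rate <- gm * stats::rgamma(length(gm), shape = noise$function_dispersion,
                               rate = noise$function_dispersion)
    p <- rate / sum(rate)
    lib <- sample(design$function_library_size_range[1]:
                  design$function_library_size_range[2], 1)
    cnt <- stats::rmultinom(1, lib, p)
    gene_p_true[, s] <- p
    fun_counts[, s] <- cnt
    cat_frac_true[, s] <- vapply(rownames(cat_tr), function(cc) {
      sum(p[gc$function_gene[gc$level1 == cc]])
    }, numeric(1))
  }
  anno_f <- gc[, c("level1", "level2", "level3", "taxon")]
  funs <- count_table(fun_counts, kind = "function_gene", annotation = anno_f)
  hierarchy <- function_hierarchy(gc[, c("function_gene", "level1", "level2",
                                         "level3")])

  ## host markers ------------------------------------------------------------
  hm_tr <- effects$host_marker_trajectories
  markers <- rownames(hm_tr)
  host <- matrix(0, length(markers), n, dimnames = list(markers, sample_id))
  for (m in markers) {
    zz <- if (m %in% rownames(z)) z[m, ] else stats::rnorm(n)
    host[m, ] <- hm_tr[m, di] + effects$host_marker_sd * zz
  }
  # matched Ct-level measurements (E = 2 chemistry): one target Ct per
  # marker per sample plus the GAPDH housekeeping gene
  base_ct <- 25
  hq <- expand.grid(sample = sample_id,
                    gene = c(markers[markers != "pathology_score"], "GAPDH"),
                    stringsAsFactors = FALSE)
  hq$ct <- vapply(seq_len(nrow(hq)), function(i) {
    g <- hq$gene[i]; s <- hq$sample[i]
    mu <- if (g == "GAPDH") 20 else base_ct - host[g, s]
    mu + stats::rnorm(1, 0, noise$host_ct_sd)
  }, numeric(1))

  ## flagellin qPCR panel ----------------------------------------------------
  gene_log10 <- effects$flagellin_gene_log10_means[di] + stats::rnorm(n, 0, 0.2)
  ratio <- effects$flagellin_logratio_means[di] +
    stats::rnorm(n, 0, effects$flagellin_logratio_sds[di])
  flag <- data.frame(mouse = mouse, sample = sample_id, day = day_of,
                     gene_copies_per_ul = 10^gene_log10,
                     transcript_copies_per_ul = 10^(gene_log10 + ratio),
                     stringsAsFactors = FALSE)
  # a perfect-doubling dilution series for standard-curve fitting
  curve_pts <- data.frame(log10_copies = 1:7,
                          ct = 40 - log2(10) * (1:7))

  truth <- list(
    taxon_composition = taxa_p_true,
    otu_composition = otu_p_true,
    gene_composition = gene_p_true,
    category_fractions = cat_frac_true,
    planted_edges = effects$planted_edges,
    planted_modules = effects$planted_modules,
    latent = z,
    flagellin_by_day = data.frame(day = days,
                                  mean = effects$flagellin_logratio_means,
                                  sd = effects$flagellin_logratio_sds),
    marker_trajectories = hm_tr,
    seed = design$seed)

  structure(list(taxa = taxa, otus = otus, functions = funs,
                 hierarchy = hierarchy, samples = samples,
                 host_markers = host, host_qpcr = hq, flagellin = flag,
                 qpcr_curve = curve_pts, truth = truth,
                 design = design, effects = effects),
            class = "dysbiosis_simulation")
}

#' @export
print.dysbiosis_simulation <- function(x, ...) {
  cat(sprintf("dysbiosis_simulation: %d samples over days %s (seed %d)\n",
              nrow(x$samples), paste(x$design$days, collapse = "/"),
              x$design$seed))
  cat(sprintf("  taxa %d, OTUs %d, function genes %d, host markers %d\n",
              nrow(x$taxa$counts), nrow(x$otus$counts),
              nrow(x$functions$counts), nrow(x$host_markers)))
  invisible(x)
}

#' Write all simulated tables to a directory
#'
#' Emits the TSV dialects the pipeline reads plus the ground truth as YAML.
#' Identical simulations produce byte-identical files.
#'
#' @param sim a `dysbiosis_simulation`
#' @param outdir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "dysbiosis_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_count_table(sim$taxa, p("taxa.tsv"))
  write_count_table(sim$otus, p("otus.tsv"))
  write_count_table(sim$functions, p("function_genes.tsv"))
  write_hierarchy(sim$hierarchy, p("hierarchy.tsv"))
  write_sample_info(sim$samples, p("samples.tsv"))
  write_tsv_canonical(data.frame(marker = rownames(sim$host_markers),
                                 signif(sim$host_markers, 10)),
                      p("host_markers.tsv"))
  write_tsv_canonical(transform(sim$host_qpcr, ct = signif(ct, 10)),
                      p("host_qpcr.tsv"))
  fl <- sim$flagellin
  fl$gene_copies_per_ul <- signif(fl$gene_copies_per_ul, 10)
  fl$transcript_copies_per_ul <- signif(fl$transcript_copies_per_ul, 10)
  write_tsv_canonical(fl, p("flagellin_qpcr.tsv"))
  write_tsv_canonical(sim$qpcr_curve, p("standard_curve.tsv"))
  tr <- sim$truth
  tr$taxon_composition <- NULL; tr$otu_composition <- NULL
  tr$gene_composition <- NULL; tr$category_fractions <- NULL
  tr$latent <- NULL
  tr$marker_trajectories <- as.data.frame(tr$marker_trajectories)
  yaml::write_yaml(tr, p("ground_truth.yaml"))
  files <- c("taxa.tsv", "otus.tsv", "function_genes.tsv", "hierarchy.tsv",
             "samples.tsv", "host_markers.tsv", "host_qpcr.tsv",
             "flagellin_qpcr.tsv", "standard_curve.tsv", "ground_truth.yaml")
  invisible(stats::setNames(file.path(outdir, files), files))
}

#' Simulate a null dataset of mutually independent features
#'
#' All features are independent standard Gaussians given the day — no
#' planted structure whatsoever. Used to calibrate the type-I error of the
#' randomization test and the chance edge rate of thresholded correlation
#' networks. Zero-variance rows cannot occur (continuous draws; a guard
#' adds jitter should a degenerate row ever appear).
#'
#' @param design a `study_design` (defines sample count and seed) — or pass
#'   `n_samples` directly
#' @param n_features number of independent features (>= 2)
#' @param n_samples override the design's sample count
#' @param seed override the design's seed
#' @return a `feature_matrix` ready for [build_network()]
#' @export
simulate_null_dataset <- function(design = study_design(), n_features,
                                  n_samples = NULL, seed = NULL) {
  if (n_features < 2) stop("n_features must be >= 2")
  n <- if (is.null(n_samples)) sum(design$mice_per_day) else as.integer(n_samples)
  sd_seed <- if (is.null(seed)) design$seed else as.integer(seed)
  v <- withr_seed(sd_seed, {
    m <- matrix(stats::rnorm(n_features * n), n_features, n)
    degen <- apply(m, 1, stats::sd) == 0
    if (any(degen)) m[degen, ] <- m[degen, ] + stats::rnorm(sum(degen) * n, 0, 1e-6)
    m
  })
  dimnames(v) <- list(paste0("feat_", seq_len(n_features)),
                      paste0("s", seq_len(n)))
  structure(list(values = v,
                 block = stats::setNames(rep("feature", n_features), rownames(v)),
                 samples = colnames(v), dropped = list(),
                 min_rel_abund = NA_real_),
            class = "feature_matrix")
}

#' Simulate a two-group qPCR dataset (target + housekeeping Ct values)
#'
#' For calibration and power analysis of the fixed reallocation test: under
#' the null (`log2_fold_change = 0`) target and housekeeping Cts differ
#' between groups only by Gaussian technical noise; a planted fold change
#' lowers the treatment group's target Ct by log2(fold) cycles (E = 2
#' chemistry).
#'
#' @param n_control,n_treatment group sizes
#' @param log2_fold_change planted target expression change (log2 scale)
#' @param ct_sd Gaussian sd of Ct noise
#' @param seed RNG seed
#' @return list with `target`, `housekeeping` (data.frames sample/ct),
#'   `control_ids`, `treatment_ids`
#' @export
simulate_qpcr_dataset <- function(n_control = 4, n_treatment = 4,
                                  log2_fold_change = 0, ct_sd = 0.25,
                                  seed = 1L) {
  ids <- c(paste0("ctl", seq_len(n_control)), paste0("trt", seq_len(n_treatment)))
  grp <- rep(c("ctl", "trt"), c(n_control, n_treatment))
  withr_seed(seed, {
    tgt <- 28 - ifelse(grp == "trt", log2_fold_change, 0) +
      stats::rnorm(length(ids), 0, ct_sd)
    ref <- 20 + stats::rnorm(length(ids), 0, ct_sd)
  })
  list(target = data.frame(sample = ids, ct = tgt, stringsAsFactors = FALSE),
       housekeeping = data.frame(sample = ids, ct = ref, stringsAsFactors = FALSE),
       control_ids = ids[grp == "ctl"], treatment_ids = ids[grp == "trt"])
}
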