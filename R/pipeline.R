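#' Subset an OTU table by samples
#'
#' @param x an [otu_table()].
#' @param samples logical/integer/character index of samples to keep.
#' @return An [otu_table()] with the selected samples (OTU set unchanged).
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "otu_table"))
  otu_table(x$counts[samples, , drop = FALSE],
            group = x$group[samples], domain = x$domain[samples],
            taxonomy = x$taxonomy)
}

# Generate the paired cultivated/control tables (and tree) for a scenario.
synth_scenario <- function(scenario, seed, S = 300, m = 0.1, N = 10000,
                           n_samples = 25, sigma_sel = 0.3) {
  src <- simulate_source_community(S, seed = substream_seed(seed, 21))
  tree <- simulate_birth_death_tree(S, seed = substream_seed(seed, 22),
                                    tip_labels = src$taxon_ids)
  make <- function(group, sub) {
    if (scenario == "neutral") {
      simulate_neutral_metacommunity(src, m = m, N = N,
                                     n_samples = n_samples,
                                     seed = substream_seed(seed, sub),
                                     group = group)
    } else if (scenario == "selected") {
      env <- with_seed(substream_seed(seed, sub + 50),
                       stats::rnorm(n_samples, sd = 1))
      simulate_selected_metacommunity(src, tree, sigma_sel = sigma_sel,
                                      env = env, N = N,
                                      seed = substream_seed(seed, sub),
                                      group = group)
    } else {
      stop("unknown scenario: ", scenario)
    }
  }
  cultivated <- make("cultivated", 23)
  control <- make("control", 24)
  counts <- rbind(cultivated$counts, control$counts)
  rownames(counts) <- c(paste0("cul_", rownames(cultivated$counts)),
                        paste0("ctl_", rownames(control$counts)))
  table <- otu_table(counts,
                     group = c(cultivated$group, control$group),
                     domain = c(cultivated$domain, control$domain),
                     taxonomy = cultivated$taxonomy)
  list(table = table, tree = tree, source = src)
}

pipeline_defaults <- function() {
  list(rare_cut = 1e-4, abundant_cut = 1e-2, ct_max = 31,
       n_null = 999, n_boot = 1000, seed = 1)
}

#' Run the full periphyton analysis pipeline
#'
#' Executes the analysis chain — abundance classification, alpha diversity
#' and cultivated/control contribution ratios, neutral-model fit, betaNTI
#' assembly inference, and optionally gene-chip scoring and response-surface
#' optimization — from a single configuration, writing per-stage TSV/JSON
#' outputs, a summary report and a content-hash manifest to `out_dir`.
#'
#' The configuration (a list, or a path to a YAML file) must provide either
#' file inputs (`otu_table`, `metadata`, `tree`) or a synthetic scenario
#' (`synth: list(scenario = "neutral"|"selected", ...)`). Optional blocks:
#' `chip` (paths `ct`, `abs16s`, or `synth = TRUE`), `bbd` (list with
#' `responses` or `synth = TRUE`), and the thresholds `rare_cut`,
#' `abundant_cut`, `ct_max`, `n_null`, `n_boot`, `seed`.
#'
#' @param config list or path to a YAML config file.
#' @param out_dir output directory (created if missing); overrides any
#'   `out_dir` in the config.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("config error: out_dir required")
  has_files <- !is.null(cfg$otu_table)
  has_synth <- !is.null(cfg$synth$scenario)
  if (!has_files && !has_synth) {
    stop("config error: provide either otu_table/metadata paths or a ",
         "synth scenario")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(cfg$out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  results <- list()

  inputs <- stage("input", {
    if (has_synth) {
      args <- cfg$synth
      args$scenario <- NULL
      do.call(synth_scenario, c(list(scenario = cfg$synth$scenario,
                                     seed = cfg$seed), args))
    } else {
      tab <- read_otu_table(cfg$otu_table, cfg$metadata)
      tree <- if (!is.null(cfg$tree)) read_newick_tree(cfg$tree)
      list(table = tab, tree = tree)
    }
  })
  tab <- inputs$table

  results$classification <- stage("classify", {
    cls <- classify_abundance(tab, cfg$rare_cut, cfg$abundant_cut)
    utils::write.table(
      data.frame(otu_id = names(cls$label), label = unname(cls$label)),
      outfile("classification.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    cls
  })

  results$diversity <- stage("diversity", {
    div <- do.call(rbind, lapply(c("richness", "shannon", "chao1", "ace"),
                                 function(m) alpha_diversity(tab, m)))
    utils::write.table(div, outfile("alpha_diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    contrib <- lapply(split(div, div$metric), function(dd) {
      means <- tapply(dd$value, dd$group, mean)
      if (all(c("cultivated", "control") %in% names(means))) {
        contribution_ratio(means[["cultivated"]], means[["control"]])
      }
    })
    contrib <- contrib[!vapply(contrib, is.null, logical(1))]
    jsonlite::write_json(contrib, outfile("contribution.json"),
                         auto_unbox = TRUE, digits = NA)
    list(table = div, contribution = contrib)
  })

  results$ncm <- stage("ncm", {
    fit <- fit_ncm(subset_samples(tab, tab$group == "cultivated"),
                   n_boot = cfg$n_boot, seed = cfg$seed)
    utils::write.table(fit$otu, outfile("ncm_otus.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(Nm = fit$Nm, m = fit$m, N = fit$N, d = fit$d,
           r_squared = fit$r_squared, Nm_ci = fit$Nm_ci),
      outfile("ncm_summary.json"), auto_unbox = TRUE, digits = NA)
    fit
  })

  if (!is.null(inputs$tree)) {
    results$assembly <- stage("bnti", {
      res <- beta_nti(tab, inputs$tree, n_null = cfg$n_null, seed = cfg$seed)
      utils::write.table(bnti_pairs(res), outfile("bnti_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- summarize_assembly(res)
      jsonlite::write_json(
        list(fractions = summ$fractions, t = summ$t, p = summ$p),
        outfile("assembly_summary.json"), auto_unbox = TRUE, digits = NA)
      list(result = res, summary = summ)
    })
  }

  if (!is.null(cfg$chip)) {
    results$funcgene <- stage("funcgene", {
      chip <- if (isTRUE(cfg$chip$synth)) {
        simulate_genechip(
          genes = c("korA", "nifH", "phoD", "dsrA"),
          cycle_labels = c("C", "N", "P", "S"),
          control_ct_means = c(22, 24, 23, 25),
          fold = c(1.0, 0.75, 0.5, 0.9),
          seed = substream_seed(cfg$seed, 30))
      } else {
        read_genechip_table(cfg$chip$ct, cfg$chip$abs16s)
      }
      fp <- functional_proportion(chip, ct_max = cfg$ct_max)
      utils::write.table(fp$genes, outfile("functional_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(fp$cycles, outfile("functional_cycles.json"),
                           auto_unbox = TRUE, digits = NA)
      fp
    })
  }

  if (!is.null(cfg$bbd)) {
    results$bbd <- stage("bbd", {
      design <- build_bbd_design(cultivation_factors(), n_center = 5)
      y <- if (isTRUE(cfg$bbd$synth)) {
        simulate_bbd_responses(design, eq2_coefficients(), noise_sd = 10,
                               seed = substream_seed(cfg$seed, 31))
      } else {
        as.numeric(cfg$bbd$responses)
      }
      fit <- fit_quadratic(design, y)
      av <- anova_type3(fit)
      utils::write.table(av, outfile("bbd_anova.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      opt <- optimize_response(fit, cultivation_factors())
      jsonlite::write_json(
        list(coded = as.list(opt$coded), natural = as.list(opt$natural),
             predicted = opt$value),
        outfile("bbd_optimum.json"), auto_unbox = TRUE, digits = NA)
      list(fit = fit, anova = av, optimum = opt)
    })
  }

  report <- list(
    seed = cfg$seed,
    n_samples = nrow(tab$counts),
    n_otus = ncol(tab$counts),
    classification = as.list(table(results$classification$label)),
    ncm = list(Nm = results$ncm$Nm, m = results$ncm$m,
               r_squared = results$ncm$r_squared),
    assembly = if (!is.null(results$assembly)) {
      list(p = results$assembly$summary$p,
           deterministic = results$assembly$summary$fractions$deterministic)
    },
    contribution = results$diversity$contribution)
  jsonlite::write_json(report, outfile("report.json"), auto_unbox = TRUE,
                       digits = NA)

  files <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                   outfile("manifest.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, outfile("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(results, list(manifest = manifest, report = report)))
}
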