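#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`,
#' the usual "leveling" step before diversity comparisons. A single
#' rarefaction with a fixed seed (not repeated averaging).
#'
#' @param x an [otu_table()].
#' @param depth target reads per sample; default the minimum sample total.
#' @param seed integer seed.
#' @return A rarefied [otu_table()] with every sample total equal to `depth`.
#' @export
rarefy <- function(x, depth = NULL, seed = 1) {
  stopifnot(inherits(x, "otu_table"))
  tot <- rowSums(x$counts)
  if (is.null(depth)) depth <- min(tot)
  if (depth < 1) stop("depth must be >= 1")
  short <- tot < depth
  if (any(short)) {
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(rownames(x$counts)[short], collapse = ", "))
  }
  counts <- with_seed(substream_seed(seed, 8),
                      vegan::rrarefy(x$counts, depth))
  otu_table(counts, group = x$group, domain = x$domain,
            taxonomy = x$taxonomy)
}

#' Classify OTUs as abundant, rare or intermediate
#'
#' Rare OTUs have relative abundance below `rare_cut` in every sample;
#' abundant OTUs exceed `abundant_cut` (by default as a mean across samples;
#' `rule = "any"` requires a single sample above the cut instead). Everything
#' else is intermediate. Defaults are the conventional 0.01% / 1% thresholds.
#'
#' @param x an [otu_table()].
#' @param rare_cut relative-abundance fraction below which an OTU is rare
#'   (default 1e-4, i.e. 0.01%).
#' @param abundant_cut relative-abundance fraction above which an OTU is
#'   abundant (default 1e-2, i.e. 1%).
#' @param rule `"mean"` (mean relative abundance above the cut) or `"any"`
#'   (above the cut in at least one sample).
#' @return Object of class `abundance_classification`: list with per-OTU
#'   `label`, the thresholds and the rule.
#' @export
classify_abundance <- function(x, rare_cut = 1e-4, abundant_cut = 1e-2,
                               rule = c("mean", "any")) {
  stopifnot(inherits(x, "otu_table"))
  rule <- match.arg(rule)
  if (rare_cut >= abundant_cut) stop("rare_cut must be below abundant_cut")
  rel <- relative_abundance(x)
  rare <- apply(rel, 2, max) < rare_cut
  abundant <- if (rule == "mean") {
    colMeans(rel) > abundant_cut
  } else {
    apply(rel, 2, max) > abundant_cut
  }
  label <- rep("intermediate", ncol(rel))
  label[rare] <- "rare"
  label[abundant] <- "abundant"
  structure(list(label = stats::setNames(label, colnames(rel)),
                 rare_cut = rare_cut, abundant_cut = abundant_cut,
                 rule = rule),
            class = "abundance_classification")
}

#' @export
print.abundance_classification <- function(x, ...) {
  tb <- table(factor(x$label, levels = c("abundant", "intermediate", "rare")))
  cat(sprintf(
    "Abundance classification (%s rule, rare < %g, abundant > %g):\n",
    x$rule, x$rare_cut, x$abundant_cut))
  cat(" ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

chao1_index <- function(n) {
  n <- n[n > 0]
  s <- length(n)
  f1 <- sum(n == 1)
  f2 <- sum(n == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

ace_index <- function(n, k = 10) {
  n <- n[n > 0]
  s_abund <- sum(n > k)
  rare <- n[n <= k]
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (n_rare == f1) {
    # no coverage information; fall back to Chao1 as vegan does not define ACE
    return(chao1_index(n))
  }
  c_ace <- 1 - f1 / n_rare
  fi <- vapply(seq_len(k), function(i) sum(rare == i), numeric(1))
  gamma2 <- max(
    s_rare / c_ace * sum(seq_len(k) * (seq_len(k) - 1) * fi) /
      (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Per-sample alpha diversity
#'
#' Richness (observed OTUs), Shannon entropy (natural log), Chao1 (classic
#' form S + F1^2 / (2 F2), bias-corrected F1 (F1 - 1) / 2 when F2 = 0) and
#' ACE (abundance-based coverage estimator with rare cutoff `k = 10`).
#' Chao1 and ACE require integer counts.
#'
#' @param x an [otu_table()].
#' @param metric one of `"richness"`, `"shannon"`, `"chao1"`, `"ace"`.
#' @return data.frame with columns `sample_id`, `group`, `domain`, `metric`,
#'   `value`.
#' @examples
#' m <- matrix(c(5L, 3L, 2L, 1L, 1L), 1, dimnames = list("s1", paste0("o", 1:5)))
#' ot <- otu_table(m, group = "control", domain = "prokaryote")
#' alpha_diversity(ot, "chao1")$value  # 7
#' @export
alpha_diversity <- function(x, metric = c("richness", "shannon", "chao1",
                                          "ace")) {
  stopifnot(inherits(x, "otu_table"))
  metric <- match.arg(metric)
  if (any(rowSums(x$counts) == 0)) {
    stop("empty sample(s): ",
         paste(rownames(x$counts)[rowSums(x$counts) == 0], collapse = ", "))
  }
  value <- switch(metric,
    richness = rowSums(x$counts > 0),
    shannon = vegan::diversity(x$counts, index = "shannon"),
    chao1 = apply(x$counts, 1, chao1_index),
    ace = apply(x$counts, 1, ace_index))
  data.frame(sample_id = rownames(x$counts), group = unname(x$group),
             domain = unname(x$domain), metric = metric,
             value = unname(value), stringsAsFactors = FALSE)
}

#' Diversity contribution of one community relative to another
#'
#' The percent ratio of a diversity index in the cultivated community to the
#' same index in the control (in situ) community — the "how much of the
#' original diversity did the abundant-taxa system retain" summary.
#'
#' @param index_cultivated,index_control positive diversity index values
#'   (typically group means of an [alpha_diversity()] metric).
#' @return Percentage, 100 * cultivated / control.
#' @export
contribution_ratio <- function(index_cultivated, index_control) {
  if (any(index_control == 0)) stop("control index must be nonzero")
  100 * index_cultivated / index_control
}

extract_phylum <- function(taxonomy) {
  vapply(strsplit(taxonomy, ";", fixed = TRUE), function(parts) {
    parts <- trimws(parts)
    hit <- grep("^p__", parts, value = TRUE)
    if (length(hit)) sub("^p__", "", hit[1])
    else if (length(parts) >= 2) parts[2]
    else parts[1]
  }, character(1))
}

#' STAMP-style comparison of taxon proportions between groups
#'
#' Aggregates counts to a taxonomic level (phylum by default), converts to
#' per-sample proportions and runs a two-sided Welch t-test per taxon, with
#' the Welch-Satterthwaite 95% confidence interval of the difference in mean
#' proportions. Taxa are ranked by pooled mean proportion; no multiplicity
#' correction by default (Benjamini-Hochberg via `p_adjust = "BH"`).
#'
#' @param x an [otu_table()] with taxonomy.
#' @param group_a,group_b the two sample groups to compare (>= 2 samples
#'   each).
#' @param level taxonomic level; only `"phylum"` aggregation is implemented.
#' @param top_n optionally keep only the top-N taxa by pooled mean.
#' @param p_adjust multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return data.frame with per-taxon mean proportions, difference, 95% CI,
#'   t statistic and p-value, ordered by pooled mean.
#' @export
compare_proportions <- function(x, group_a = "cultivated",
                                group_b = "control", level = "phylum",
                                top_n = NULL, p_adjust = "none") {
  stopifnot(inherits(x, "otu_table"))
  if (level != "phylum") stop("only phylum-level aggregation is implemented")
  if (is.null(x$taxonomy)) stop("taxonomy required for aggregation")
  na <- sum(x$group == group_a)
  nb <- sum(x$group == group_b)
  if (na < 2 || nb < 2) {
    stop("need >= 2 samples per group; got ", na, " (", group_a, "), ",
         nb, " (", group_b, ")")
  }
  phylum <- extract_phylum(x$taxonomy)
  rel <- relative_abundance(x)
  agg <- t(rowsum(t(rel), phylum))  # samples x phyla
  in_a <- x$group == group_a
  in_b <- x$group == group_b
  res <- do.call(rbind, lapply(colnames(agg), function(ph) {
    va <- agg[in_a, ph]
    vb <- agg[in_b, ph]
    if (stats::var(va) + stats::var(vb) == 0) {
      d <- mean(va) - mean(vb)
      data.frame(taxon = ph, mean_a = mean(va), mean_b = mean(vb),
                 diff = d, ci_lo = d, ci_hi = d,
                 t = 0, p = if (d == 0) 1 else NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(va, vb, var.equal = FALSE, conf.level = 0.95)
      data.frame(taxon = ph, mean_a = mean(va), mean_b = mean(vb),
                 diff = mean(va) - mean(vb),
                 ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  }))
  res$pooled_mean <- (res$mean_a * na + res$mean_b * nb) / (na + nb)
  res <- res[order(-res$pooled_mean), ]
  if (!is.null(top_n)) res <- utils::head(res, top_n)
  res$p_adj <- stats::p.adjust(res$p, method = p_adjust)
  rownames(res) <- NULL
  res
}
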