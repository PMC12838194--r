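#' Quality-control filtering of a gene-chip Ct table
#'
#' Masks wells with Ct above `ct_max` (treated as non-detections) and
#' discards a gene's measurements within a group when it was detected in
#' fewer than `min_positive_fraction` of that group's replicates. The
#' defaults (Ct 31, two-thirds detection) follow common SmartChip practice.
#' The 16S reference row must survive QC in every sample.
#'
#' @param chip a [genechip_table()].
#' @param ct_max detection threshold in cycles.
#' @param min_positive_fraction minimum detected fraction of a group's
#'   replicates for a gene x group to be retained.
#' @return A filtered [genechip_table()]; genes undetectable in both groups
#'   are dropped.
#' @export
qc_filter <- function(chip, ct_max = 31, min_positive_fraction = 2 / 3) {
  stopifnot(inherits(chip, "genechip_table"))
  ct <- chip$ct
  ct[!is.na(ct) & ct > ct_max] <- NA_real_
  i16 <- which(chip$cycle == "16S")
  if (anyNA(ct[i16, ])) {
    stop("16S reference undetected after QC in sample(s): ",
         paste(colnames(ct)[is.na(ct[i16, ])], collapse = ", "))
  }
  for (g in unique(chip$group)) {
    cols <- chip$group == g
    frac <- rowMeans(!is.na(ct[, cols, drop = FALSE]))
    fail <- frac < min_positive_fraction
    fail[i16] <- FALSE
    ct[fail, cols] <- NA_real_
  }
  keep <- rowSums(!is.na(ct)) > 0
  if (sum(keep & chip$cycle != "16S") == 0) {
    stop("all functional genes removed by QC")
  }
  genechip_table(ct[keep, , drop = FALSE], cycle = chip$cycle[keep],
                 group = chip$group, abs_16s = chip$abs_16s)
}

#' Convert Ct values to relative copy numbers
#'
#' copies = 10^((ct_max - ct) / (10/3)): ten-thirds cycles per decade of
#' template, the perfect-efficiency qPCR convention (one cycle is a
#' 10^0.3 ~ 2-fold change), anchored so that Ct = ct_max maps to 1.
#'
#' @param ct numeric Ct value(s); values above `ct_max` return `NA`
#'   (non-detection, masked upstream by [qc_filter()]).
#' @param ct_max detection threshold in cycles.
#' @return Relative copy number(s).
#' @examples
#' ct_to_relative_copies(c(31, 21))  # 1, 1000
#' @export
ct_to_relative_copies <- function(ct, ct_max = 31) {
  out <- 10^((ct_max - ct) / (10 / 3))
  out[!is.na(ct) & ct > ct_max] <- NA_real_
  out
}

#' Absolute gene abundances from a gene chip
#'
#' Per sample, a gene's relative copies (from Ct) are rescaled by the
#' sample's absolute 16S quantification: abs_gene = rel_gene *
#' (abs_16S / rel_16S). Samples whose 16S Ct is missing are masked.
#'
#' @param chip a [genechip_table()].
#' @param ct_max detection threshold passed to [ct_to_relative_copies()].
#' @return genes x samples matrix of absolute copies per gram (the 16S row
#'   equals the sidecar quantification by construction).
#' @export
absolute_abundance <- function(chip, ct_max = 31) {
  stopifnot(inherits(chip, "genechip_table"))
  rel <- ct_to_relative_copies(chip$ct, ct_max)
  i16 <- which(chip$cycle == "16S")
  scale <- chip$abs_16s / rel[i16, ]
  out <- sweep(rel, 2, scale, "*")
  out[, is.na(rel[i16, ])] <- NA_real_
  out
}

#' Functional-gene proportions of cultivated relative to control periphyton
#'
#' For each functional gene, the percent ratio of its mean absolute
#' abundance in the cultivated group to the baseline (control, naturally
#' collected) group: ratio of replicate means, not mean of ratios. The
#' standard deviation is delta-method propagated from replicate variation.
#' Per-cycle summaries are arithmetic means of the gene proportions within
#' each nutrient cycle. Proportions are not capped at 100%.
#'
#' @param chip a [genechip_table()].
#' @param baseline_group the reference group (default `"control"`).
#' @param ct_max,min_positive_fraction QC settings, see [qc_filter()].
#' @param qc apply [qc_filter()] first (default TRUE).
#' @return Object of class `functional_proportion`: data.frame `genes`
#'   (gene, cycle, proportion, sd, replicate counts; `NA` proportion =
#'   not evaluable) and data.frame `cycles` (per-cycle mean of evaluable
#'   gene proportions).
#' @export
functional_proportion <- function(chip, baseline_group = "control",
                                  ct_max = 31, min_positive_fraction = 2 / 3,
                                  qc = TRUE) {
  stopifnot(inherits(chip, "genechip_table"))
  groups <- unique(chip$group)
  if (!baseline_group %in% groups) {
    stop("baseline group '", baseline_group, "' not present")
  }
  if (length(groups) < 2) stop("both groups required")
  target_group <- setdiff(groups, baseline_group)[1]
  if (qc) chip <- qc_filter(chip, ct_max, min_positive_fraction)
  abs_mat <- absolute_abundance(chip, ct_max)
  fun <- chip$cycle != "16S"
  in_t <- chip$group == target_group
  in_b <- chip$group == baseline_group
  genes <- do.call(rbind, lapply(which(fun), function(i) {
    a <- abs_mat[i, in_t]
    b <- abs_mat[i, in_b]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(b) == 0 || length(a) == 0) {
      return(data.frame(gene = rownames(chip$ct)[i], cycle = chip$cycle[i],
                        proportion = NA_real_, sd = NA_real_,
                        n_target = length(a), n_baseline = length(b),
                        stringsAsFactors = FALSE))
    }
    prop <- 100 * mean(a) / mean(b)
    va <- if (length(a) > 1) stats::var(a) else 0
    vb <- if (length(b) > 1) stats::var(b) else 0
    sdp <- prop * sqrt(va / (length(a) * mean(a)^2) +
                       vb / (length(b) * mean(b)^2))
    data.frame(gene = rownames(chip$ct)[i], cycle = chip$cycle[i],
               proportion = prop, sd = sdp,
               n_target = length(a), n_baseline = length(b),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  evaluable <- genes[!is.na(genes$proportion), ]
  cycles <- if (nrow(evaluable)) {
    stats::aggregate(proportion ~ cycle, evaluable, mean)
  } else {
    data.frame(cycle = character(), proportion = numeric())
  }
  names(cycles) <- c("cycle", "mean_proportion")
  structure(list(genes = genes, cycles = cycles,
                 baseline_group = baseline_group,
                 target_group = target_group),
            class = "functional_proportion")
}

#' @export
print.functional_proportion <- function(x, ...) {
  cat(sprintf("Functional-gene proportions: %s relative to %s (100%% = equal)\n",
              x$target_group, x$baseline_group))
  print.data.frame(x$cycles, row.names = FALSE, digits = 4)
  ne <- sum(is.na(x$genes$proportion))
  if (ne) cat(sprintf("  %d gene(s) not evaluable after QC\n", ne))
  invisible(x)
}
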