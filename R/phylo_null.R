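#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' For samples k and l, the abundance-weighted average of each taxon's
#' patristic distance to its nearest relative in the other sample:
#' 0.5 * (sum over i in k of f_ik * min over j in l of d_ij + the mirror
#' term). Shared taxa contribute zero (a taxon is its own nearest relative).
#' With `weighted = FALSE` every present taxon gets equal weight.
#'
#' @param x an [otu_table()].
#' @param distances patristic distance matrix covering the table's taxa
#'   (see [patristic_distances()]).
#' @param weighted use relative abundances as weights (default) or equal
#'   weights on present taxa.
#' @return Symmetric samples x samples matrix of betaMNTD values.
#' @export
beta_mntd <- function(x, distances, weighted = TRUE) {
  stopifnot(inherits(x, "otu_table"))
  taxa <- colnames(x$counts)
  missing_taxa <- setdiff(taxa, rownames(distances))
  if (length(missing_taxa)) {
    stop("taxa missing from the distance matrix: ",
         paste(utils::head(missing_taxa, 5), collapse = ", "),
         if (length(missing_taxa) > 5) sprintf(" (+%d more)",
                                               length(missing_taxa) - 5))
  }
  fw <- bmntd_weights(x, weighted)
  D <- distances[taxa, taxa]
  out <- bmntd_matrix(D, fw, seq_along(taxa) - 1L)
  dimnames(out) <- list(rownames(x$counts), rownames(x$counts))
  out
}

bmntd_weights <- function(x, weighted) {
  if (weighted) {
    relative_abundance(x)
  } else {
    pres <- x$counts > 0
    tot <- rowSums(pres)
    if (any(tot == 0)) {
      stop("sample(s) with zero total: ",
           paste(rownames(x$counts)[tot == 0], collapse = ", "))
    }
    sweep(pres * 1, 1, tot, "/")
  }
}

#' Beta nearest taxon index (betaNTI) by tip-shuffle null model
#'
#' Standardizes each pair's observed betaMNTD against a null distribution
#' obtained by shuffling taxon labels across all tree tips (abundances stay
#' with their sample; only phylogenetic identity is randomized):
#' betaNTI = (observed - null mean) / null sd. |betaNTI| > 2 indicates
#' deterministic (selection-driven) assembly, |betaNTI| <= 2 stochastic.
#' All pairs share one shuffle sequence per run, so results are reproducible
#' from the seed.
#'
#' @param x an [otu_table()] with >= 2 samples.
#' @param tree phylogeny covering the table's taxa.
#' @param n_null number of label shuffles (>= 99; default 999).
#' @param seed integer seed.
#' @param weighted abundance-weighted betaMNTD (default) or presence-only.
#' @return Object of class `beta_nti`: matrices `bnti`, `bmntd_obs`,
#'   `null_mean`, `null_sd`, plus `n_null`, `seed` and the sample `group`
#'   labels. Pairs with a degenerate null (sd = 0) are `NA` in `bnti`.
#' @export
beta_nti <- function(x, tree, n_null = 999, seed = 1, weighted = TRUE) {
  stopifnot(inherits(x, "otu_table"))
  if (nrow(x$counts) < 2) stop("need >= 2 samples")
  if (n_null < 99) stop("n_null must be >= 99")
  distances <- patristic_distances(tree)
  taxa <- colnames(x$counts)
  missing_taxa <- setdiff(taxa, rownames(distances))
  if (length(missing_taxa)) {
    stop("taxa missing from the tree: ",
         paste(utils::head(missing_taxa, 5), collapse = ", "),
         if (length(missing_taxa) > 5) sprintf(" (+%d more)",
                                               length(missing_taxa) - 5))
  }
  D <- distances[taxa, taxa]
  fw <- bmntd_weights(x, weighted)
  S <- length(taxa)
  ident <- seq_len(S) - 1L
  obs <- bmntd_matrix(D, fw, ident)

  n <- nrow(fw)
  sum1 <- matrix(0, n, n)
  sum2 <- matrix(0, n, n)
  nul_min <- matrix(Inf, n, n)
  nul_max <- matrix(-Inf, n, n)
  with_seed(substream_seed(seed, 10), {
    for (r in seq_len(n_null)) {
      perm <- sample.int(S) - 1L
      nul <- bmntd_matrix(D, fw, perm)
      sum1 <- sum1 + nul
      sum2 <- sum2 + nul^2
      nul_min <- pmin(nul_min, nul)
      nul_max <- pmax(nul_max, nul)
    }
  })
  null_mean <- sum1 / n_null
  null_sd <- sqrt(pmax(sum2 / n_null - null_mean^2, 0) *
                    n_null / (n_null - 1))
  bnti <- (obs - null_mean) / null_sd
  # a null that never moves (up to roundoff) cannot standardize anything
  degenerate <- (nul_max - nul_min) <= 1e-9 * (abs(null_mean) + 1)
  bnti[degenerate] <- NA_real_
  diag(bnti) <- NA_real_
  sample_ids <- rownames(x$counts)
  dimnames(obs) <- dimnames(null_mean) <- dimnames(null_sd) <-
    dimnames(bnti) <- list(sample_ids, sample_ids)
  structure(list(bnti = bnti, bmntd_obs = obs, null_mean = null_mean,
                 null_sd = null_sd, n_null = n_null, seed = seed,
                 weighted = weighted, group = x$group),
            class = "beta_nti")
}

#' @export
print.beta_nti <- function(x, ...) {
  v <- x$bnti[upper.tri(x$bnti)]
  v <- v[!is.na(v)]
  cat(sprintf("betaNTI over %d sample pairs (%d tip shuffles, %s betaMNTD)\n",
              length(v), x$n_null,
              if (x$weighted) "weighted" else "unweighted"))
  cat(sprintf("  mean %.3f, sd %.3f, |betaNTI| > 2 in %.1f%% of pairs\n",
              mean(v), stats::sd(v), 100 * mean(abs(v) > 2)))
  invisible(x)
}

#' Pairwise betaNTI values as a tidy data.frame
#'
#' One row per unordered sample pair, with the pair's group assignment:
#' a pair belongs to a group when both its samples do; mixed pairs are
#' labelled `"between"`.
#'
#' @param result a [beta_nti()] object.
#' @return data.frame with columns `sample_a`, `sample_b`, `group`,
#'   `bmntd`, `null_mean`, `null_sd`, `bnti`.
#' @export
bnti_pairs <- function(result) {
  stopifnot(inherits(result, "beta_nti"))
  ids <- rownames(result$bnti)
  idx <- which(upper.tri(result$bnti), arr.ind = TRUE)
  ga <- result$group[ids[idx[, 1]]]
  gb <- result$group[ids[idx[, 2]]]
  data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
             group = ifelse(ga == gb, ga, "between"),
             bmntd = result$bmntd_obs[idx],
             null_mean = result$null_mean[idx],
             null_sd = result$null_sd[idx],
             bnti = result$bnti[idx],
             stringsAsFactors = FALSE)
}

#' Summarize assembly processes from betaNTI values
#'
#' Per group of within-group sample pairs: the fraction of pairs with
#' |betaNTI| > 2 (deterministic assembly) and <= 2 (stochastic), plus a
#' two-sided t-test comparing the two groups' betaNTI values when exactly
#' two groups are present. Pairs with undefined betaNTI (degenerate null)
#' are excluded.
#'
#' @param result a [beta_nti()] object.
#' @param groups optional character vector of group names to summarize;
#'   default all within-group pair sets.
#' @return Object of class `assembly_summary`: per-group data.frame
#'   `fractions` and, with two groups, `t` and `p` of the comparison.
#' @export
summarize_assembly <- function(result, groups = NULL) {
  pairs <- bnti_pairs(result)
  pairs <- pairs[!is.na(pairs$bnti) & pairs$group != "between", ]
  if (is.null(groups)) groups <- sort(unique(unname(result$group)))
  vals <- lapply(groups, function(g) pairs$bnti[pairs$group == g])
  names(vals) <- groups
  small <- groups[vapply(vals, length, integer(1)) < 2]
  if (length(small)) {
    stop("group(s) with < 2 betaNTI values: ", paste(small, collapse = ", "))
  }
  fractions <- data.frame(
    group = groups,
    n_pairs = vapply(vals, length, integer(1)),
    deterministic = vapply(vals, function(v) mean(abs(v) > 2), numeric(1)),
    stochastic = vapply(vals, function(v) mean(abs(v) <= 2), numeric(1)),
    mean_bnti = vapply(vals, mean, numeric(1)),
    stringsAsFactors = FALSE)
  tstat <- p <- NA_real_
  if (length(groups) == 2) {
    a <- vals[[1]]
    b <- vals[[2]]
    if (stats::var(a) + stats::var(b) == 0) {
      tstat <- 0
      p <- if (mean(a) == mean(b)) 1 else NA_real_
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
  }
  structure(list(fractions = fractions, t = tstat, p = p),
            class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Assembly-process summary (|betaNTI| > 2 = deterministic)\n")
  print.data.frame(x$fractions, row.names = FALSE, digits = 4)
  if (!is.na(x$t)) {
    cat(sprintf("  two-group t-test: t = %.3f, p = %.4f\n", x$t, x$p))
  }
  invisible(x)
}
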