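#' @useDynLib periphyton, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic substream seed for stage k of a master seed (stays < 2^31).
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

#' Simulate a source (meta)community abundance distribution
#'
#' Draws the relative abundances of the regional species pool that the
#' neutral model's migrants are sampled from. Lognormal is the default
#' rank-abundance shape for soil and periphyton communities; a log-series
#' option gives a longer rare tail.
#'
#' @param S number of taxa (>= 2).
#' @param distribution `"lognormal"` or `"logseries"`.
#' @param params list of shape parameters: `sd` (lognormal sigma, default 1.5)
#'   or `x` (log-series parameter in (0,1), default 0.999).
#' @param seed integer seed.
#' @return Object of class `source_community`: list with `taxon_ids` and
#'   relative abundances `p` (sorted descending, summing to 1).
#' @export
simulate_source_community <- function(S, distribution = c("lognormal",
                                                          "logseries"),
                                      params = list(), seed = 1) {
  if (S < 2) stop("S must be >= 2")
  distribution <- match.arg(distribution)
  p <- with_seed(seed, {
    if (distribution == "lognormal") {
      sdlog <- if (is.null(params$sd)) 1.5 else params$sd
      x <- stats::rlnorm(S, meanlog = 0, sdlog = sdlog)
    } else {
      xs <- if (is.null(params$x)) 0.999 else params$x
      if (xs <= 0 || xs >= 1) stop("log-series parameter x must be in (0,1)")
      # inverse-CDF draw of abundance classes k with P(k) = -x^k / (k log(1-x))
      kmax <- 100000L
      k <- seq_len(kmax)
      pk <- xs^k / k
      cdf <- cumsum(pk) / sum(pk)
      u <- stats::runif(S)
      x <- as.numeric(findInterval(u, cdf) + 1L)
    }
    sort(x / sum(x), decreasing = TRUE)
  })
  structure(list(taxon_ids = sprintf("OTU_%04d", seq_len(S)), p = p),
            class = "source_community")
}

#' @export
print.source_community <- function(x, ...) {
  cat(sprintf("Source community: %d taxa, top abundance %.3g, evenness %.3f\n",
              length(x$p), x$p[1],
              -sum(x$p * log(x$p)) / log(length(x$p))))
  invisible(x)
}

default_taxonomy <- function(otu_ids, n_phyla, seed) {
  phyla <- sprintf("Phylum%02d", seq_len(n_phyla))
  assign <- with_seed(seed, sample(phyla, length(otu_ids), replace = TRUE))
  paste0("k__Microbes;p__", assign)
}

#' Simulate a neutral metacommunity OTU table
#'
#' Each sample's composition is drawn from Dirichlet(N m p) and its counts
#' from Multinomial(N, composition). The Dirichlet-multinomial has exactly
#' the beta-distributed per-taxon marginals the Sloan neutral model assumes
#' at stationarity, so this generator tests the estimator without simulating
#' birth-death-immigration dynamics.
#'
#' @param source a [simulate_source_community()] object.
#' @param m migration probability in (0, 1].
#' @param N local community size (reads per sample, >= 10).
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param group,domain sample labels (recycled).
#' @param n_phyla number of pseudo-phyla for the generated taxonomy strings.
#' @return An [otu_table()], samples x taxa, every row summing to `N`.
#' @export
simulate_neutral_metacommunity <- function(source, m, N, n_samples, seed = 1,
                                           group = "cultivated",
                                           domain = "prokaryote",
                                           n_phyla = 9) {
  stopifnot(inherits(source, "source_community"))
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (N < 10) stop("N must be >= 10")
  S <- length(source$p)
  alpha <- N * m * source$p
  counts <- with_seed(substream_seed(seed, 1), {
    t(vapply(seq_len(n_samples), function(i) {
      comp <- stats::rgamma(S, shape = alpha)
      comp <- comp / sum(comp)
      drop(stats::rmultinom(1, size = N, prob = comp))
    }, numeric(S)))
  })
  dimnames(counts) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                           source$taxon_ids)
  otu_table(counts,
            group = rep_len(group, n_samples),
            domain = rep_len(domain, n_samples),
            taxonomy = default_taxonomy(source$taxon_ids, n_phyla,
                                        substream_seed(seed, 2)))
}

#' Simulate a selection-structured metacommunity OTU table
#'
#' Deterministic (niche-based) assembly: a one-dimensional trait evolves by
#' Brownian motion on the phylogeny, each sample has an environmental optimum
#' `env`, and taxon i's sampling weight is p_i * exp(-(trait_i - env)^2 /
#' (2 sigma_sel^2)), renormalized; counts are multinomial. Small `sigma_sel`
#' means strong phylogenetically conserved selection; as `sigma_sel` grows
#' the model collapses to neutral multinomial sampling from the source pool.
#'
#' @param source a [simulate_source_community()] object.
#' @param tree phylogeny whose tip labels equal the source taxon ids.
#' @param sigma_sel selection bandwidth (> 0), trait units.
#' @param env numeric vector of per-sample environmental optima.
#' @param N reads per sample.
#' @param seed integer seed.
#' @param group,domain sample labels (recycled).
#' @return An [otu_table()]; the pre-multinomial expected compositions are
#'   attached as `attr(, "expected")` (samples x taxa).
#' @export
simulate_selected_metacommunity <- function(source, tree, sigma_sel, env,
                                            N = 10000, seed = 1,
                                            group = "cultivated",
                                            domain = "prokaryote") {
  stopifnot(inherits(source, "source_community"))
  validate_phylogeny(tree)
  if (sigma_sel <= 0) stop("sigma_sel must be > 0")
  if (!setequal(tree$tip.label, source$taxon_ids)) {
    stop("tree tips must match source taxon ids")
  }
  n_samples <- length(env)
  traits <- with_seed(substream_seed(seed, 3),
                      ape::rTraitCont(tree, model = "BM", sigma = 1))
  traits <- traits[source$taxon_ids]
  W <- t(vapply(env, function(e) {
    w <- source$p * exp(-(traits - e)^2 / (2 * sigma_sel^2))
    w / sum(w)
  }, numeric(length(source$p))))
  counts <- with_seed(substream_seed(seed, 4), {
    t(vapply(seq_len(n_samples), function(i) {
      drop(stats::rmultinom(1, size = N, prob = W[i, ]))
    }, numeric(length(source$p))))
  })
  dimnames(counts) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                           source$taxon_ids)
  dimnames(W) <- dimnames(counts)
  out <- otu_table(counts,
                   group = rep_len(group, n_samples),
                   domain = rep_len(domain, n_samples),
                   taxonomy = default_taxonomy(source$taxon_ids, 9,
                                               substream_seed(seed, 2)))
  attr(out, "expected") <- W
  attr(out, "traits") <- traits
  out
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree with total depth rescaled to 1, tips labelled to
#' match [simulate_source_community()] taxon ids.
#'
#' @param S number of tips (>= 2).
#' @param seed integer seed.
#' @param tip_labels optional character vector of tip labels (length `S`).
#' @return An ultrametric [ape::phylo] object.
#' @export
simulate_birth_death_tree <- function(S, seed = 1, tip_labels = NULL) {
  if (S < 2) stop("S must be >= 2")
  tree <- with_seed(substream_seed(seed, 5),
                    ape::rphylo(S, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- if (is.null(tip_labels)) {
    sprintf("OTU_%04d", seq_len(S))
  } else {
    stopifnot(length(tip_labels) == S)
    tip_labels
  }
  tree
}

#' Simulate responses from a quadratic surface on a Box-Behnken design
#'
#' y = quadratic(true_coeffs, coded runs) + Normal(0, noise_sd).
#'
#' @param design a [build_bbd_design()] object or coded run matrix.
#' @param true_coeffs the 10 generating coefficients (intercept, 3 linear,
#'   3 interaction, 3 quadratic).
#' @param noise_sd response noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return Numeric response vector, one per run.
#' @export
simulate_bbd_responses <- function(design, true_coeffs, noise_sd = 10,
                                   seed = 1) {
  if (length(true_coeffs) != 10) stop("exactly 10 coefficients required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  coded <- if (inherits(design, "bbd_design")) design$coded else
    as.matrix(design)
  mu <- predict_response(as.numeric(true_coeffs), coded)
  with_seed(substream_seed(seed, 6),
            mu + stats::rnorm(length(mu), sd = noise_sd))
}

#' Simulate a qPCR gene-chip Ct table with group-wise fold changes
#'
#' Control-group Ct values are Normal(control_ct_means, ct_sd); cultivated
#' Ct = control mean - (10/3) log10(fold) + Normal(0, ct_sd), i.e. a
#' `fold`-times change in template under the 10/3-cycles-per-decade
#' convention. A 16S reference row (fold 1) and constant per-sample absolute
#' 16S copies are included.
#'
#' @param genes character vector of functional gene names.
#' @param cycle_labels per-gene nutrient cycle, in `{"C","N","P","S"}`.
#' @param control_ct_means per-gene mean control Ct.
#' @param fold per-gene cultivated/control fold change (> 0).
#' @param replicates samples per group (default 15, three technical
#'   replicates of five subsamples as in the chip design emulated).
#' @param ct_sd Ct noise, cycles (default 0.3).
#' @param ct_16s mean Ct of the 16S reference row.
#' @param abs_16s absolute 16S copies per gram (constant across samples).
#' @param seed integer seed.
#' @return A [genechip_table()].
#' @export
simulate_genechip <- function(genes, cycle_labels, control_ct_means, fold,
                              replicates = 15, ct_sd = 0.3, ct_16s = 15,
                              abs_16s = 1e9, seed = 1) {
  stopifnot(length(genes) == length(cycle_labels),
            length(genes) == length(control_ct_means),
            length(genes) == length(fold))
  if (any(fold <= 0)) stop("fold must be > 0 for every gene")
  n <- as.integer(replicates)
  sample_ids <- c(sprintf("ctl_%02d", seq_len(n)),
                  sprintf("cul_%02d", seq_len(n)))
  group <- rep(c("control", "cultivated"), each = n)
  mu <- rbind(cbind(matrix(control_ct_means, length(genes), n),
                    matrix(control_ct_means - (10 / 3) * log10(fold),
                           length(genes), n)),
              rep(ct_16s, 2 * n))
  ct <- with_seed(substream_seed(seed, 7),
                  mu + matrix(stats::rnorm(length(mu), sd = ct_sd),
                              nrow(mu), ncol(mu)))
  ct <- pmin(pmax(ct, 1e-6), 44.999)
  dimnames(ct) <- list(c(genes, "16S_rRNA"), sample_ids)
  genechip_table(ct, cycle = c(cycle_labels, "16S"), group = group,
                 abs_16s = rep(abs_16s, 2 * n))
}
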