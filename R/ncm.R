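#' Occupancy predicted by the Sloan neutral community model
#'
#' Under neutral assembly with migration, a taxon's local relative abundance
#' is beta-distributed with parameters (Nm p, Nm (1 - p)), where p is its
#' mean relative abundance in the source pool and Nm the product of
#' community size and migration rate. The probability of detecting the taxon
#' (local abundance above the detection limit d) is therefore
#' 1 - I_d(Nm p, Nm (1 - p)), with I the regularized incomplete beta
#' function.
#'
#' @param p mean relative abundance(s) in (0, 1).
#' @param Nm migration parameter (> 0).
#' @param d detection limit as a fraction in (0, 1); typically 1/N, one read.
#' @return Predicted occupancy frequency in `[0, 1]`, vectorized over `p`.
#' @export
ncm_predicted_frequency <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (Nm <= 0) stop("Nm must be > 0")
  if (d <= 0 || d >= 1) stop("d must lie in (0, 1)")
  stats::pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

ncm_sse <- function(log10_nm, p, occ, d) {
  pred <- ncm_predicted_frequency(p, 10^log10_nm, d)
  sum((occ - pred)^2)
}

fit_nm_scalar <- function(p, occ, d, lower = 0, upper = 7) {
  # coarse log-spaced bracket, then golden-section refinement
  grid <- seq(lower, upper, length.out = 60)
  sse <- vapply(grid, ncm_sse, numeric(1), p = p, occ = occ, d = d)
  i <- which.min(sse)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ncm_sse, interval = c(lo, hi), p = p, occ = occ,
                         d = d, tol = 1e-10)
  if (opt$minimum <= lower + 1e-6 || opt$minimum >= upper - 1e-6) {
    stop("Nm estimate at bracket boundary [10^", lower, ", 10^", upper,
         "]; minimum at 10^", signif(opt$minimum, 4))
  }
  10^opt$minimum
}

#' Fit the Sloan neutral community model to an OTU table
#'
#' Estimates Nm by least squares of observed occupancy frequencies on the
#' neutral prediction across OTUs, on the untransformed frequency scale with
#' Nm bracketed in [1, 10^7] (log-spaced scan plus refinement). N is the mean
#' sample depth and m = Nm / N. The detection limit defaults to the
#' sampling-consistent threshold d = 1 - 2^(-1/N) (approximately ln(2)/N),
#' the relative abundance at which a taxon has a 50% chance of yielding at
#' least one read among N: occupancy is observed through finite sequencing
#' depth, and the hard threshold that best mimics binomial detection sits at
#' the median of the detection ramp, not at one full read. The conventional
#' d = 1/N is available via the `d` argument (it inflates Nm by roughly 25%
#' on data whose occupancy truly arises from read sampling).
#' R^2 = 1 - SSE/SST about the mean observed occupancy. The 95%
#' confidence interval of Nm comes from a percentile bootstrap that resamples
#' OTUs — the regression's unit of observation. Per-OTU 95% prediction bands
#' are Wilson binomial limits around the predicted frequency at the observed
#' number of samples; OTUs are partitioned as above / within / below band.
#' OTUs observed in zero samples are excluded.
#'
#' @param x an [otu_table()] (>= 5 samples, >= 10 nonzero OTUs).
#' @param d detection limit; default `1 - 2^(-1/N)`.
#' @param n_boot bootstrap replicates for the Nm confidence interval
#'   (default 1000; 0 skips the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `ncm_fit`: `Nm`, `m`, `N`, `d`, `r_squared`,
#'   `Nm_ci`, and per-OTU data.frame `otu` (mean relative abundance,
#'   occupancy, prediction, band, partition).
#' @seealso [partition_otus()], [abundant_variance_share()]
#' @export
fit_ncm <- function(x, d = NULL, n_boot = 1000, seed = 1) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (nrow(counts) < 5) stop("need >= 5 samples, got ", nrow(counts))
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 10) {
    stop("need >= 10 OTUs with nonzero totals, got ", ncol(counts))
  }
  n_samples <- nrow(counts)
  N <- mean(rowSums(counts))
  if (is.null(d)) d <- 1 - 2^(-1 / N)
  rel <- sweep(counts, 1, rowSums(counts), "/")
  p <- colMeans(rel)
  occ <- colMeans(counts > 0)
  if (all(occ == occ[1])) {
    stop("degenerate occupancy: all OTUs detected in the same fraction ",
         "of samples (SST = 0)")
  }
  keep <- p > 0 & p < 1
  p <- p[keep]
  occ <- occ[keep]
  Nm <- fit_nm_scalar(p, occ, d)
  pred <- ncm_predicted_frequency(p, Nm, d)
  sse <- sum((occ - pred)^2)
  sst <- sum((occ - mean(occ))^2)
  r2 <- 1 - sse / sst

  Nm_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(substream_seed(seed, 9), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(p), replace = TRUE)
        tryCatch(fit_nm_scalar(p[idx], occ[idx], d),
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    Nm_ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }

  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / n_samples
  # Wilson limits from the integer detection count nearest the prediction:
  # occupancy lives on the 1/n grid, and rounding keeps the band achievable
  # (a prediction of ~1 over n samples must admit detection in all n)
  phat <- round(pred * n_samples) / n_samples
  center <- (phat + z^2 / (2 * n_samples)) / denom
  half <- z * sqrt(phat * (1 - phat) / n_samples +
                   z^2 / (4 * n_samples^2)) / denom
  lower <- pmax(0, center - half)
  upper <- pmin(1, center + half)
  eps <- 1e-9  # guard the closed boundary against roundoff
  partition <- ifelse(occ > upper + eps, "above",
                      ifelse(occ < lower - eps, "below", "within"))
  otu <- data.frame(otu_id = names(p), p = unname(p), occupancy = unname(occ),
                    predicted = unname(pred), lower = unname(lower),
                    upper = unname(upper), partition = unname(partition),
                    stringsAsFactors = FALSE)
  structure(list(Nm = Nm, m = Nm / N, N = N, d = d, r_squared = r2,
                 Nm_ci = Nm_ci, n_boot = n_boot, n_samples = n_samples,
                 otu = otu),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.4g (m = %.4g, N = %.4g, d = %.3g)\n",
              x$Nm, x$m, x$N, x$d))
  if (!anyNA(x$Nm_ci)) {
    cat(sprintf("  95%% bootstrap CI for Nm: [%.4g, %.4g] (%d replicates)\n",
                x$Nm_ci[1], x$Nm_ci[2], x$n_boot))
  }
  cat(sprintf("  R^2 = %.4f over %d OTUs, %d samples\n",
              x$r_squared, nrow(x$otu), x$n_samples))
  tb <- table(factor(x$otu$partition, c("above", "within", "below")))
  cat("  partition:", paste(sprintf("%s=%d", names(tb), tb),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ncm_fit <- function(object, ...) {
  c(Nm = object$Nm, m = object$m, N = object$N, d = object$d,
    r_squared = object$r_squared)
}

#' @export
predict.ncm_fit <- function(object, p = NULL, ...) {
  if (is.null(p)) return(object$otu$predicted)
  ncm_predicted_frequency(p, object$Nm, object$d)
}

#' Occupancy-abundance plot of a neutral-model fit
#'
#' @param x an [fit_ncm()] object.
#' @param ... passed to [plot()].
#' @export
plot.ncm_fit <- function(x, ...) {
  ord <- order(x$otu$p)
  o <- x$otu[ord, ]
  cols <- c(above = "#1b9e77", within = "grey40", below = "#d95f02")
  plot(log10(o$p), o$occupancy, pch = 16, cex = 0.6,
       col = cols[o$partition],
       xlab = "log10 mean relative abundance",
       ylab = "occupancy frequency",
       main = sprintf("NCM fit: Nm = %.3g, R2 = %.3f", x$Nm, x$r_squared),
       ...)
  graphics::lines(log10(o$p), o$predicted, col = "blue", lwd = 2)
  graphics::lines(log10(o$p), o$lower, col = "blue", lty = 2)
  graphics::lines(log10(o$p), o$upper, col = "blue", lty = 2)
  invisible(x)
}

#' Partition of OTUs against the neutral prediction bands
#'
#' @param fit an [fit_ncm()] object.
#' @return data.frame with one row per partition (`above`, `within`,
#'   `below`): OTU counts and fractions (fractions sum to 1).
#' @export
partition_otus <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  lev <- c("above", "within", "below")
  n <- as.numeric(table(factor(fit$otu$partition, lev)))
  data.frame(partition = lev, n = n, fraction = n / sum(n),
             stringsAsFactors = FALSE)
}

#' Share of the neutral model's explained variance from abundant OTUs
#'
#' Attributes the regression sum of squares of the occupancy-abundance fit
#' to OTU classes: 100 * sum over abundant OTUs of (predicted - mean
#' occupancy)^2 divided by the same sum over all fitted OTUs.
#'
#' @param fit an [fit_ncm()] object.
#' @param classification an [classify_abundance()] result covering the
#'   fitted OTUs.
#' @return Percentage of explained variance attributable to abundant OTUs.
#' @export
abundant_variance_share <- function(fit, classification) {
  stopifnot(inherits(fit, "ncm_fit"),
            inherits(classification, "abundance_classification"))
  ids <- fit$otu$otu_id
  missing_ids <- setdiff(ids, names(classification$label))
  if (length(missing_ids)) {
    stop("classification missing fitted OTU(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  lab <- classification$label[ids]
  dev2 <- (fit$otu$predicted - mean(fit$otu$occupancy))^2
  if (!any(lab == "abundant")) {
    warning("no abundant OTUs among fitted OTUs; share is 0")
    return(0)
  }
  100 * sum(dev2[lab == "abundant"]) / sum(dev2)
}
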