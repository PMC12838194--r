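#' Define the three cultivation factors
#'
#' Factor levels for the three-level Box-Behnken design used to optimize the
#' periphyton cultivation system: soil extract (% v/v), mineral solution (%)
#' and culture temperature (degrees C). Levels must be equally spaced so the
#' coded scale is (natural - center) / step.
#'
#' @param name character vector of factor names.
#' @param low,center,high numeric vectors of the natural-unit levels coded
#'   -1, 0, +1.
#' @return A data.frame of class `bbd_factors` with columns `name`, `low`,
#'   `center`, `high`, `step`.
#' @examples
#' cultivation_factors()
#' @export
bbd_factors <- function(name, low, center, high) {
  stopifnot(length(name) == length(low), length(low) == length(center),
            length(center) == length(high))
  if (any(!(low < center & center < high))) {
    stop("factor levels must satisfy low < center < high")
  }
  if (any(abs(center - (low + high) / 2) > 1e-9 * pmax(1, abs(high)))) {
    stop("levels must be equally spaced: center = (low + high)/2")
  }
  structure(data.frame(name = name, low = low, center = center, high = high,
                       step = (high - low) / 2, stringsAsFactors = FALSE),
            class = c("bbd_factors", "data.frame"))
}

#' Factor levels of the periphyton cultivation study
#'
#' Soil extract 0/10/20 % (v/v), mineral solution 0.5/1.0/1.5 %, culture
#' temperature 26/30.5/35 degrees C.
#'
#' @return A [bbd_factors()] object with the three cultivation factors.
#' @export
cultivation_factors <- function() {
  bbd_factors(name = c("soil_extract", "mineral_solution", "temperature"),
              low = c(0, 0.5, 26), center = c(10, 1.0, 30.5),
              high = c(20, 1.5, 35))
}

#' Build a three-factor Box-Behnken design
#'
#' The 12 edge runs are every permutation of (+/-1, +/-1, 0) over the three
#' factor pairs; center runs are replicated `n_center` times for a pure-error
#' estimate. With `n_center = 5` this is the classic 17-run design.
#'
#' @param factors a [bbd_factors()] object with exactly 3 factors.
#' @param n_center number of replicated center points (>= 1; >= 2 needed for
#'   pure error).
#' @return An object of class `bbd_design`: list with `coded` and `natural`
#'   run matrices, `n_center`, and the `factors`.
#' @examples
#' d <- build_bbd_design(cultivation_factors(), n_center = 5)
#' nrow(d$coded)  # 17
#' @export
build_bbd_design <- function(factors, n_center = 5) {
  stopifnot(inherits(factors, "bbd_factors"))
  if (nrow(factors) != 3) {
    stop("unsupported design: exactly 3 factors required, got ", nrow(factors))
  }
  if (n_center < 1) stop("n_center must be >= 1")
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  edge <- do.call(rbind, lapply(pairs, function(p) {
    m <- matrix(0, nrow = 4, ncol = 3)
    m[, p] <- signs
    m
  }))
  coded <- rbind(edge, matrix(0, nrow = n_center, ncol = 3))
  colnames(coded) <- factors$name
  rownames(coded) <- sprintf("run%02d", seq_len(nrow(coded)))
  natural <- sweep(sweep(coded, 2, factors$step, "*"), 2, factors$center, "+")
  structure(list(coded = coded, natural = natural, n_center = n_center,
                 factors = factors),
            class = "bbd_design")
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d runs (12 edge + %d center), factors: %s\n",
              nrow(x$coded), x$n_center, paste(x$factors$name, collapse = ", ")))
  invisible(x)
}

#' Code a natural-unit point onto the design scale (and back)
#'
#' `code_point` maps natural units to the coded -1..+1 scale; `decode_point`
#' inverts it. Points outside the factor range are allowed (extrapolation),
#' carried through with a `extrapolated` attribute.
#'
#' @param factors a [bbd_factors()] object.
#' @param natural,coded numeric vector, one value per factor.
#' @return Numeric vector on the other scale, named by factor.
#' @examples
#' f <- cultivation_factors()
#' code_point(f, c(10, 0.5, 30.5))   # 0, -1, 0
#' decode_point(f, c(0, -1, -1))     # 10, 0.5, 26
#' @export
code_point <- function(factors, natural) {
  stopifnot(inherits(factors, "bbd_factors"), length(natural) == nrow(factors))
  coded <- (as.numeric(natural) - factors$center) / factors$step
  names(coded) <- factors$name
  attr(coded, "extrapolated") <- abs(coded) > 1 + 1e-12
  coded
}

#' @rdname code_point
#' @export
decode_point <- function(factors, coded) {
  stopifnot(inherits(factors, "bbd_factors"), length(coded) == nrow(factors))
  natural <- as.numeric(coded) * factors$step + factors$center
  names(natural) <- factors$name
  natural
}

quad_term_names <- function(fnames = c("X1", "X2", "X3")) {
  c("(Intercept)", fnames,
    paste0(fnames[c(1, 1, 2)], ":", fnames[c(2, 3, 3)]),
    paste0(fnames, "^2"))
}

#' Model matrix of the full second-order polynomial on coded factors
#'
#' Columns: intercept, 3 linear, 3 pairwise interactions, 3 quadratic.
#'
#' @param coded numeric matrix of coded runs (rows) by factors (columns).
#' @return n x 10 model matrix.
#' @export
quadratic_model_matrix <- function(coded) {
  coded <- as.matrix(coded)
  stopifnot(ncol(coded) == 3)
  fn <- colnames(coded)
  if (is.null(fn)) fn <- c("X1", "X2", "X3")
  X <- cbind(1, coded,
             coded[, 1] * coded[, 2], coded[, 1] * coded[, 3],
             coded[, 2] * coded[, 3], coded^2)
  colnames(X) <- quad_term_names(fn)
  X
}

#' Fit the second-order response-surface model
#'
#' Ordinary least squares of the response on the 10-term coded quadratic
#' polynomial Y = b0 + sum(bi Xi) + sum(bii Xi^2) + sum(bij Xi Xj). Fitting is
#' on the coded scale only; natural-scale effects are obtained by decoding
#' points, never by refitting.
#'
#' @param design a [build_bbd_design()] object, or a coded run matrix.
#' @param responses numeric response vector, one value per run.
#' @return An object of class `bbd_fit` with coefficients, fitted values,
#'   residual and total sums of squares, and the inverse information matrix
#'   of the coded model (used for Type III sums of squares).
#' @seealso [anova.bbd_fit()], [predict.bbd_fit()], [optimize_response()]
#' @export
fit_quadratic <- function(design, responses) {
  coded <- if (inherits(design, "bbd_design")) design$coded else as.matrix(design)
  y <- as.numeric(responses)
  if (length(y) != nrow(coded)) {
    stop("responses length (", length(y), ") must equal design rows (",
         nrow(coded), ")")
  }
  X <- quadratic_model_matrix(coded)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank-deficient for the 10-term model; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 fitted.values = fitted, residuals = y - fitted,
                 rss = rss, df.residual = length(y) - ncol(X), tss = tss,
                 xtx_inv = xtx_inv, responses = y, coded = coded,
                 design = if (inherits(design, "bbd_design")) design else NULL),
            class = "bbd_fit")
}

#' @export
print.bbd_fit <- function(x, digits = 4, ...) {
  cat("Second-order response-surface fit (coded scale)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Residual SS %.4g on %d df; corrected total SS %.4g\n",
              x$rss, x$df.residual, x$tss))
  invisible(x)
}

#' @export
coef.bbd_fit <- function(object, ...) object$coefficients

#' @export
residuals.bbd_fit <- function(object, ...) object$residuals

#' Predict the response at coded points
#'
#' @param object a [fit_quadratic()] fit.
#' @param newdata coded point (length-3 vector) or matrix of coded points;
#'   defaults to the design runs.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.bbd_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  predict_response(object$coefficients, newdata)
}

#' @export
summary.bbd_fit <- function(object, ...) {
  r2 <- 1 - object$rss / object$tss
  n <- length(object$responses)
  adj <- 1 - (1 - r2) * (n - 1) / object$df.residual
  out <- list(fit = object, r.squared = r2, adj.r.squared = adj,
              anova = anova_type3(object))
  class(out) <- "summary.bbd_fit"
  out
}

#' @export
print.summary.bbd_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("R-squared %.4f (adjusted %.4f)\n", x$r.squared, x$adj.r.squared))
  print(x$anova)
  invisible(x)
}

#' Type III ANOVA for a response-surface fit
#'
#' Partial (Type III) sum of squares per model term, computed as beta_j^2 /
#' c_jj with c_jj the corresponding diagonal of the inverse information
#' matrix (X'X)^-1 of the coded model — the decomposition response-surface
#' software prints. The residual is split into lack-of-fit and pure error
#' using the replicated center runs; the lack-of-fit F ratio is MS_LOF /
#' MS_PE, every other F is MS_term / MS_residual.
#'
#' @param fit a [fit_quadratic()] object.
#' @param ... unused.
#' @return A data.frame of class `bbd_anova` with columns `term`, `ss`, `df`,
#'   `ms`, `f`, `p`, rows ordered Model, the nine effects, Residual,
#'   Lack of fit, Pure error, Cor total.
#' @export
anova_type3 <- function(fit, ...) {
  stopifnot(inherits(fit, "bbd_fit"))
  beta <- fit$coefficients
  cjj <- diag(fit$xtx_inv)
  terms <- names(beta)[-1]
  ss_term <- beta[terms]^2 / cjj[terms]
  ms_resid <- fit$rss / fit$df.residual

  center <- rowSums(fit$coded != 0) == 0
  n_center <- sum(center)
  has_pe <- n_center >= 2
  if (!has_pe) {
    warning("no replicated center points: pure-error rows omitted")
    ss_pe <- df_pe <- NA_real_
  } else {
    yc <- fit$responses[center]
    ss_pe <- sum((yc - mean(yc))^2)
    df_pe <- n_center - 1
  }
  ss_model <- fit$tss - fit$rss
  df_model <- length(beta) - 1
  rows <- data.frame(
    term = c("Model", terms, "Residual", "Lack of fit", "Pure error",
             "Cor total"),
    ss = c(ss_model, ss_term, fit$rss,
           if (has_pe) fit$rss - ss_pe else NA_real_, ss_pe, fit$tss),
    df = c(df_model, rep(1, length(terms)), fit$df.residual,
           if (has_pe) fit$df.residual - df_pe else NA_real_, df_pe,
           length(fit$responses) - 1),
    stringsAsFactors = FALSE)
  rows$ms <- rows$ss / rows$df
  rows$ms[rows$term == "Cor total"] <- NA_real_
  f <- rep(NA_real_, nrow(rows))
  p <- rep(NA_real_, nrow(rows))
  testable <- !(rows$term %in% c("Residual", "Pure error", "Cor total"))
  for (i in which(testable)) {
    if (rows$term[i] == "Lack of fit") {
      if (has_pe && df_pe > 0 && ss_pe > 0) {
        f[i] <- rows$ms[i] / (ss_pe / df_pe)
        p[i] <- stats::pf(f[i], rows$df[i], df_pe, lower.tail = FALSE)
      }
    } else {
      f[i] <- rows$ms[i] / ms_resid
      p[i] <- stats::pf(f[i], rows$df[i], fit$df.residual, lower.tail = FALSE)
    }
  }
  rows$f <- f
  rows$p <- p
  structure(rows, class = c("bbd_anova", "data.frame"))
}

#' @export
anova.bbd_fit <- function(object, ...) anova_type3(object)

#' @export
print.bbd_anova <- function(x, ...) {
  out <- x
  out$ss <- round(out$ss, 2)
  out$ms <- round(out$ms, 2)
  out$f <- round(out$f, 2)
  out$p <- formatC(out$p, format = "f", digits = 4)
  out$p[out$p == "NA"] <- ""
  print.data.frame(out, row.names = FALSE)
  invisible(x)
}

#' Re-derive per-term sums of squares from published coefficients
#'
#' Given the 10 coefficients of a reported coded-scale quadratic model (e.g. a
#' published fitted polynomial), reconstructs each term's partial SS as
#' beta_j^2 / c_jj on a given design, and F ratios against a supplied residual
#' mean square. On the 17-run Box-Behnken design this reduces to 8 beta^2 for
#' linear terms, 4 beta^2 for interactions and (80/19) beta^2 for quadratics.
#'
#' @param coeffs numeric vector of 10 coefficients ordered intercept, linear
#'   (3), interaction (X1X2, X1X3, X2X3), quadratic (3).
#' @param design a [build_bbd_design()] object or coded run matrix.
#' @param residual_ms residual mean square to scale F ratios (optional).
#' @param df_residual residual degrees of freedom for p-values (default
#'   `nrow - 10`).
#' @return data.frame with columns `term`, `ss`, and when `residual_ms` is
#'   given `f` and `p`.
#' @export
anova_from_coefficients <- function(coeffs, design, residual_ms = NULL,
                                    df_residual = NULL) {
  coded <- if (inherits(design, "bbd_design")) design$coded else as.matrix(design)
  if (length(coeffs) != 10) stop("exactly 10 coefficients required")
  X <- quadratic_model_matrix(coded)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(X))),
                      error = function(e) stop("design mismatch: singular ",
                                               "information matrix"))
  cjj <- diag(xtx_inv)[-1]
  terms <- colnames(X)[-1]
  beta <- as.numeric(coeffs)[-1]
  out <- data.frame(term = terms, ss = beta^2 / cjj, stringsAsFactors = FALSE)
  if (!is.null(residual_ms)) {
    if (is.null(df_residual)) df_residual <- nrow(X) - 10
    out$f <- out$ss / residual_ms
    out$p <- stats::pf(out$f, 1, df_residual, lower.tail = FALSE)
  }
  out
}

#' Evaluate a second-order polynomial at coded points
#'
#' @param fit_or_coeffs a [fit_quadratic()] object or the 10 coefficients
#'   (intercept, 3 linear, 3 interaction, 3 quadratic).
#' @param point coded point (length-3 vector) or matrix of coded points.
#' @return Predicted response(s).
#' @examples
#' predict_response(eq2_coefficients(), c(0, 0, 0))  # 102.80
#' @export
predict_response <- function(fit_or_coeffs, point) {
  beta <- if (inherits(fit_or_coeffs, "bbd_fit")) {
    fit_or_coeffs$coefficients
  } else {
    as.numeric(fit_or_coeffs)
  }
  if (length(beta) != 10) stop("exactly 10 coefficients required")
  pt <- if (is.null(dim(point))) matrix(point, nrow = 1) else as.matrix(point)
  colnames(pt) <- NULL
  drop(quadratic_model_matrix(pt) %*% beta)
}

#' Published coefficients of the cultivation response surface
#'
#' The coded-scale quadratic model for abundant-species richness fitted to
#' the 17-run cultivation experiment: Y = 102.80 - 1.00 X1 - 14.62 X2 -
#' 7.12 X3 - 3.00 X1X2 - 2.00 X1X3 + 3.75 X2X3 - 4.28 X1^2 + 10.47 X2^2 +
#' 25.48 X3^2, with X1 soil extract, X2 mineral solution, X3 temperature.
#'
#' @return Named numeric vector of 10 coefficients.
#' @export
eq2_coefficients <- function() {
  stats::setNames(
    c(102.80, -1.00, -14.62, -7.12, -3.00, -2.00, 3.75, -4.28, 10.47, 25.48),
    quad_term_names())
}

#' Constrained optimum of a response surface over the coded cube
#'
#' Maximizes (or minimizes) the quadratic over [-1, 1]^3 by exhaustive face
#' decomposition: every one of the 27 combinations of each coordinate being
#' free, at -1 or at +1 is solved in closed form (stationary point of the
#' restricted quadratic), candidates inside the box are kept, and a dense
#' grid pass confirms the winner. No iterative optimizer, no convergence
#' knobs.
#'
#' @param fit_or_coeffs a [fit_quadratic()] object or the 10 coefficients.
#' @param factors optional [bbd_factors()] to report the optimum in natural
#'   units.
#' @param sense `"maximize"` or `"minimize"`.
#' @param grid_n grid points per axis for the confirmation pass.
#' @return An object of class `bbd_optimum`: list with `coded`, `natural`
#'   (if `factors` given), `value`, and per-factor `at_boundary` flags.
#' @examples
#' opt <- optimize_response(eq2_coefficients(), cultivation_factors())
#' opt$natural  # mineral solution 0.5, temperature 26
#' @export
optimize_response <- function(fit_or_coeffs, factors = NULL,
                              sense = c("maximize", "minimize"),
                              grid_n = 41) {
  sense <- match.arg(sense)
  beta <- if (inherits(fit_or_coeffs, "bbd_fit")) {
    unname(fit_or_coeffs$coefficients)
  } else {
    as.numeric(fit_or_coeffs)
  }
  if (length(beta) != 10) stop("exactly 10 coefficients required")
  sgn <- if (sense == "maximize") 1 else -1
  g <- beta[2:4]
  H <- diag(beta[8:10])
  H[1, 2] <- H[2, 1] <- beta[5] / 2
  H[1, 3] <- H[3, 1] <- beta[6] / 2
  H[2, 3] <- H[3, 2] <- beta[7] / 2
  evalq3 <- function(x) beta[1] + sum(g * x) + drop(t(x) %*% H %*% x)

  best_x <- NULL
  best_v <- -Inf
  states <- expand.grid(s1 = c(0, -1, 1), s2 = c(0, -1, 1), s3 = c(0, -1, 1))
  for (r in seq_len(nrow(states))) {
    s <- as.numeric(states[r, ])
    free <- which(s == 0)
    x <- s
    if (length(free)) {
      fixed <- which(s != 0)
      Hee <- H[free, free, drop = FALSE]
      rhs <- g[free]
      if (length(fixed)) {
        rhs <- rhs + 2 * drop(H[free, fixed, drop = FALSE] %*% s[fixed])
      }
      xe <- tryCatch(-0.5 * solve(Hee, rhs), error = function(e) NULL)
      if (is.null(xe) || any(abs(xe) > 1 + 1e-12)) next
      x[free] <- xe
    }
    v <- sgn * evalq3(x)
    if (v > best_v) {
      best_v <- v
      best_x <- x
    }
  }
  # vertices are covered by the all-fixed states; grid pass confirms
  gr <- seq(-1, 1, length.out = grid_n)
  G <- as.matrix(expand.grid(gr, gr, gr))
  vals <- sgn * predict_response(beta, G)
  i <- which.max(vals)
  if (vals[i] > best_v + 1e-8) {
    best_v <- vals[i]
    best_x <- as.numeric(G[i, ])
  }
  coded <- best_x
  names(coded) <- if (!is.null(factors)) factors$name else c("X1", "X2", "X3")
  out <- list(coded = coded,
              natural = if (!is.null(factors)) decode_point(factors, coded),
              value = sgn * best_v, sense = sense,
              at_boundary = abs(abs(coded) - 1) < 1e-6)
  class(out) <- "bbd_optimum"
  out
}

#' @export
print.bbd_optimum <- function(x, ...) {
  cat(sprintf("Constrained %s of the response surface\n", x$sense))
  cat("  coded optimum:  ",
      paste(sprintf("%s=%.4f", names(x$coded), x$coded), collapse = ", "), "\n")
  if (!is.null(x$natural)) {
    cat("  natural units:  ",
        paste(sprintf("%s=%.4g", names(x$natural), x$natural),
              collapse = ", "), "\n")
  }
  cat(sprintf("  predicted response: %.4f\n", x$value))
  bnd <- names(x$coded)[x$at_boundary]
  if (length(bnd)) cat("  at boundary:    ", paste(bnd, collapse = ", "), "\n")
  invisible(x)
}
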