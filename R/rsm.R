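#' Response-surface polynomial fit on coded CCD factors
#'
#' Fits an ordinary least-squares polynomial in the coded factors of a
#' three-factor central composite design. Three model orders are
#' supported: `"linear"` (main effects), `"2FI"` (main effects plus all
#' two-factor interactions) and `"quadratic"` (2FI plus pure squared
#' terms). All fitting is on the coded scale, where coefficient
#' magnitudes are directly comparable across factors; this is the
#' convention used by the common DOE software packages.
#'
#' Alongside the coefficients the fit carries the usual response-surface
#' diagnostics: R-squared, adjusted R-squared, PRESS (prediction error
#' sum of squares from leave-one-out residuals e/(1 - h)), predicted
#' R-squared = 1 - PRESS/SS_total, the model F test, per-term partial
#' t tests (equivalent to Type III partial F tests for single-df terms),
#' and a lack-of-fit F test whose pure-error component comes from
#' replicated design points (typically the centre runs).
#'
#' @param design A `ccd_design` (see [ccd_design()], [gp_design()]).
#' @param response Either a numeric vector aligned with the design rows,
#'   or a data frame with columns `run_id` and `value` (matched to the
#'   design by `run_id`).
#' @param order Model order: `"2FI"`, `"quadratic"` or `"linear"`.
#' @param response_name Optional label used in printing.
#' @return An object of class `rsm_fit` with components `lm` (the
#'   underlying fit), `coefficients` (coded scale, display-labelled),
#'   `r2`, `adj_r2`, `press`, `pred_r2`, `model_f`, `model_p`,
#'   `lack_of_fit` (list with `f`, `p`, `df` or a reason it is
#'   unavailable), `term_p`, `significant_terms`, `sigma`, plus the
#'   design, order and term bookkeeping.
#' @examples
#' fit <- rsm_fit(gp_design(), gp_response("yield"), order = "2FI")
#' coef(fit)["A"]   # pressure main effect on the coded scale
#' summary(fit)
#' @seealso [predict.rsm_fit()], [rsm_optimize()], [synth_response()]
#' @export
rsm_fit <- function(design, response, order = c("2FI", "quadratic", "linear"),
                    response_name = NULL) {
  stopifnot(inherits(design, "ccd_design"))
  order <- match.arg(order)
  if (is.null(response_name))
    response_name <- if (is.numeric(response)) "response"
                     else deparse(substitute(response))[1]

  pts <- design$points
  y <- align_response(response, pts$run_id)
  dat <- coded_frame(design)
  dat$value <- y

  fml <- rsm_formula(order)
  labels <- rsm_term_labels(order)
  n_terms <- length(labels) + 1L
  if (nrow(dat) <= n_terms)
    stop(sprintf("need more runs (%d) than model terms (%d)",
                 nrow(dat), n_terms), call. = FALSE)

  mm <- stats::model.matrix(fml, dat)
  qd <- qr(mm)
  if (qd$rank < ncol(mm)) {
    bad <- colnames(mm)[qd$pivot[(qd$rank + 1L):ncol(mm)]]
    stop("rank-deficient design matrix; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  n <- nrow(dat)
  ss_tot <- sum((y - mean(y))^2)
  constant_response <- ss_tot < 1e-12 * max(1, mean(y)^2)

  map <- rsm_label_map(order)
  cf <- stats::coef(fit)
  names(cf) <- unname(map[names(cf)])
  cf <- cf[c("(Intercept)", labels)]

  h <- stats::hatvalues(fit)
  press <- sum((stats::resid(fit) / (1 - h))^2)

  if (constant_response) {
    warning("constant response: total sum of squares is zero; ",
            "R-squared statistics are undefined", call. = FALSE)
    r2 <- adj_r2 <- pred_r2 <- model_f <- model_p <- NA_real_
    term_p <- stats::setNames(rep(NA_real_, length(labels)), labels)
  } else {
    r2 <- sm$r.squared
    adj_r2 <- sm$adj.r.squared
    pred_r2 <- 1 - press / ss_tot
    fstat <- sm$fstatistic
    model_f <- unname(fstat[1L])
    model_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
    term_p <- sm$coefficients[, "Pr(>|t|)"]
    names(term_p) <- unname(map[rownames(sm$coefficients)])
    term_p <- term_p[labels]
  }

  lof <- lack_of_fit_test(fit, dat, pts, n_terms)

  structure(list(
    lm = fit, design = design, order = order, terms = labels,
    response_name = response_name, response = y,
    coefficients = cf, r2 = r2, adj_r2 = adj_r2,
    press = press, pred_r2 = pred_r2,
    model_f = model_f, model_p = model_p,
    lack_of_fit = lof, term_p = term_p,
    significant_terms = names(term_p)[!is.na(term_p) & term_p < 0.05],
    sigma = sm$sigma, constant_response = constant_response
  ), class = "rsm_fit")
}

# coded data frame with syntactic names A, B, C in factor order
coded_frame <- function(design, actual = NULL) {
  nm <- factor_names(design$factors)
  if (is.null(actual)) actual <- design$points[nm]
  cl <- code_levels(actual, design$factors)
  out <- as.data.frame(cl)
  names(out) <- c("A", "B", "C")
  out
}

rsm_term_labels <- function(order) {
  lab <- c("A", "B", "C")
  if (order %in% c("2FI", "quadratic")) lab <- c(lab, "AB", "AC", "BC")
  if (order == "quadratic") lab <- c(lab, "A2", "B2", "C2")
  lab
}

# map from lm's term names to the display labels above
rsm_label_map <- function(order) {
  map <- c("(Intercept)" = "(Intercept)", A = "A", B = "B", C = "C",
           "A:B" = "AB", "A:C" = "AC", "B:C" = "BC",
           "I(A^2)" = "A2", "I(B^2)" = "B2", "I(C^2)" = "C2")
  map[map %in% c("(Intercept)", rsm_term_labels(order))]
}

rsm_formula <- function(order) {
  rhs <- "A + B + C"
  if (order %in% c("2FI", "quadratic"))
    rhs <- paste(rhs, "+ A:B + A:C + B:C")
  if (order == "quadratic")
    rhs <- paste(rhs, "+ I(A^2) + I(B^2) + I(C^2)")
  stats::as.formula(paste("value ~", rhs))
}

align_response <- function(response, run_ids) {
  if (is.data.frame(response)) {
    if (!all(c("run_id", "value") %in% names(response)))
      stop("response data frame needs columns run_id and value", call. = FALSE)
    idx <- match(run_ids, response$run_id)
    if (anyNA(idx))
      stop("response is missing run_id(s): ",
           paste(run_ids[is.na(idx)], collapse = ", "), call. = FALSE)
    return(as.numeric(response$value[idx]))
  }
  response <- as.numeric(response)
  if (length(response) != length(run_ids))
    stop("response length must match the number of design runs", call. = FALSE)
  response
}

# Residual SS split into lack-of-fit and pure error from replicated points.
lack_of_fit_test <- function(fit, dat, pts, n_terms) {
  key <- interaction(dat$A, dat$B, dat$C, drop = TRUE)
  y <- dat$value
  group_means <- stats::ave(y, key)
  ss_pe <- sum((y - group_means)^2)
  df_pe <- length(y) - nlevels(key)
  if (df_pe == 0L)
    return(list(available = FALSE, reason = "no replicate runs: pure error has zero degrees of freedom"))
  rss <- sum(stats::resid(fit)^2)
  ss_lof <- max(rss - ss_pe, 0)
  df_lof <- nlevels(key) - n_terms
  if (df_lof <= 0L)
    return(list(available = FALSE, reason = "model saturates the distinct design points: no lack-of-fit degrees of freedom"))
  if (ss_pe <= 0)
    return(list(available = FALSE, reason = "replicates are identical: pure error is zero"))
  f <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(available = TRUE, f = f,
       p = stats::pf(f, df_lof, df_pe, lower.tail = FALSE),
       ss_lof = ss_lof, df_lof = df_lof, ss_pe = ss_pe, df_pe = df_pe)
}

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Response-surface fit (%s) for %s on coded factors\n",
              x$order, x$response_name))
  print(round(x$coefficients, digits))
  if (!x$constant_response)
    cat(sprintf("R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f\n",
                x$r2, x$adj_r2, x$pred_r2))
  else
    cat("R-squared undefined (constant response)\n")
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
fitted.rsm_fit <- function(object, ...) unname(stats::fitted(object$lm))

#' @export
residuals.rsm_fit <- function(object, ...) unname(stats::resid(object$lm))

#' Summarize a response-surface fit
#'
#' @param object An `rsm_fit`.
#' @param ... Unused.
#' @return The object, invisibly, after printing the coefficient table
#'   with partial-test p-values, the model F test, the lack-of-fit test
#'   and the R-squared family.
#' @export
summary.rsm_fit <- function(object, ...) {
  x <- object
  cat(sprintf("Response-surface model (%s) for %s, n = %d runs\n\n",
              x$order, x$response_name, length(x$response)))
  tab <- data.frame(
    coefficient = round(x$coefficients, 4),
    p_value = c(NA, round(x$term_p, 4)),
    significant = c("", ifelse(names(x$coefficients)[-1] %in%
                                 x$significant_terms, "*", ""))
  )
  print(tab)
  if (!x$constant_response) {
    cat(sprintf("\nModel F = %.3f, Prob > F = %.4g\n", x$model_f, x$model_p))
    cat(sprintf("R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f, PRESS = %.4g\n",
                x$r2, x$adj_r2, x$pred_r2, x$press))
  } else {
    cat("\nConstant response: fit statistics undefined\n")
  }
  if (isTRUE(x$lack_of_fit$available))
    cat(sprintf("Lack of fit: F = %.3f on (%d, %d) df, p = %.4f\n",
                x$lack_of_fit$f, x$lack_of_fit$df_lof,
                x$lack_of_fit$df_pe, x$lack_of_fit$p))
  else
    cat("Lack of fit unavailable:", x$lack_of_fit$reason, "\n")
  invisible(x)
}

#' Predict from a response-surface fit
#'
#' Codes the supplied point(s) and evaluates the fitted polynomial. A
#' warning (not an error) is raised for points outside the coded design
#' box spanned by the axial levels, where the polynomial extrapolates.
#'
#' @param object An `rsm_fit`.
#' @param newdata A numeric vector of length 3 (one point, factor order
#'   of the design), or a matrix/data frame with one column per factor
#'   (matched by factor name when named). Omit for fitted values.
#' @param coded Set `TRUE` when `newdata` is already on the coded scale.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @examples
#' fit <- rsm_fit(gp_design(), gp_response("solubility"), "quadratic")
#' predict(fit, c(21, 65, 33))
#' @export
predict.rsm_fit <- function(object, newdata, coded = FALSE, ...) {
  if (missing(newdata) || is.null(newdata)) return(fitted(object))
  design <- object$design
  if (is.null(dim(newdata)))
    newdata <- matrix(as.numeric(newdata), nrow = 1L,
                      dimnames = list(NULL, factor_names(design$factors)))
  if (coded) {
    cd <- as.data.frame(as.matrix(newdata))
    names(cd) <- c("A", "B", "C")
  } else {
    cd <- coded_frame(design, newdata)
  }
  box <- coded_box(design)
  out_of_box <- vapply(seq_len(nrow(cd)), function(i)
    any(cd[i, ] < box[1, ] - 1e-8) || any(cd[i, ] > box[2, ] + 1e-8),
    logical(1))
  if (any(out_of_box))
    warning(sum(out_of_box),
            " point(s) outside the design region: prediction extrapolates",
            call. = FALSE)
  unname(stats::predict(object$lm, newdata = cd))
}

# coded bounds spanned by the axial levels: 2 x 3 matrix (lower, upper)
coded_box <- function(design) {
  lows <- vapply(design$factors, `[[`, numeric(1), "axial_low")
  highs <- vapply(design$factors, `[[`, numeric(1), "axial_high")
  rbind(lower = code_levels(lows, design$factors),
        upper = code_levels(highs, design$factors))
}

#' Optimize a fitted response surface over the design region
#'
#' Maximizes (or minimizes) the fitted polynomial over a coded box,
#' defaulting to the box spanned by the axial levels. Uses multi-start
#' local search (`optim` L-BFGS-B) from a deterministic grid of starting
#' points; for quadratic fits the analytic stationary point is also
#' checked when it lies inside the box. For models without curvature
#' (linear, 2FI) the optimum necessarily sits on the boundary.
#'
#' @param object An `rsm_fit`.
#' @param maximize Maximize (`TRUE`, default) or minimize.
#' @param bounds Optional 2 x 3 matrix of coded lower/upper bounds.
#' @param n_starts Grid points per factor for the multi-start (default 4,
#'   i.e. 64 starts).
#' @return An object of class `rsm_optimum`: list with `coded`, `actual`
#'   (named numeric), `value`, and `maximize`. Ties within 1e-8 are
#'   broken by the first-found start.
#' @examples
#' fit <- rsm_fit(gp_design(), gp_response("solubility"), "quadratic")
#' rsm_optimize(fit)
#' @export
rsm_optimize <- function(object, maximize = TRUE, bounds = NULL,
                         n_starts = 4L) {
  stopifnot(inherits(object, "rsm_fit"))
  if (is.null(bounds)) bounds <- coded_box(object$design)
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2L, ncol(bounds) == 3L,
            all(bounds[1, ] < bounds[2, ]))
  sgn <- if (maximize) -1 else 1
  obj <- function(x) sgn * predict(object, x, coded = TRUE)

  grids <- lapply(1:3, function(j)
    seq(bounds[1, j], bounds[2, j], length.out = n_starts))
  starts <- as.matrix(expand.grid(grids))
  sp <- quadratic_stationary_point(object)
  if (!is.null(sp) && all(sp >= bounds[1, ]) && all(sp <= bounds[2, ]))
    starts <- rbind(sp, starts)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                        lower = bounds[1, ], upper = bounds[2, ],
                        control = list(factr = 10))
    if (is.null(best) || res$value < best$value - 1e-8) best <- res
  }
  coded <- stats::setNames(best$par, c("A", "B", "C"))
  actual <- decode_levels(unname(coded), object$design$factors)
  structure(list(coded = coded, actual = actual,
                 value = sgn * best$value, maximize = maximize),
            class = "rsm_optimum")
}

# Stationary point of a quadratic fit: solve H x = -g for the full
# quadratic form; NULL for models without squared terms or singular H.
quadratic_stationary_point <- function(object) {
  if (object$order != "quadratic") return(NULL)
  cf <- object$coefficients
  g <- cf[c("A", "B", "C")]
  H <- diag(2 * cf[c("A2", "B2", "C2")])
  H[1, 2] <- H[2, 1] <- cf["AB"]
  H[1, 3] <- H[3, 1] <- cf["AC"]
  H[2, 3] <- H[3, 2] <- cf["BC"]
  sp <- tryCatch(solve(H, -g), error = function(e) NULL)
  if (is.null(sp) || anyNA(sp)) return(NULL)
  unname(sp)
}

#' @export
print.rsm_optimum <- function(x, digits = 4, ...) {
  cat(sprintf("%s of fitted surface: value %.*f\n",
              if (x$maximize) "Maximum" else "Minimum", digits, x$value))
  cat("  at actual levels:",
      paste(sprintf("%s = %.4g", names(x$actual), x$actual), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate responses from a fitted surface
#'
#' Draws new response vectors at the design points from the fitted
#' polynomial plus Gaussian noise at the residual standard error.
#'
#' @param object An `rsm_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed (scoped locally).
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.rsm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- lapply(seq_len(nsim), function(i) synth_response(
    object$design, object$coefficients, order = object$order,
    noise_sd = object$sigma,
    seed = if (is.null(seed)) NULL else seed + i - 1L)$value)
  stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
}

#' Contour plot of a fitted response surface
#'
#' Plots the fitted response over two factors with the remaining factor
#' held at a fixed coded level (default: the centre).
#'
#' @param x An `rsm_fit`.
#' @param which Indices of the two factors to vary (default 1:2).
#' @param fixed Coded level of the remaining factor (default 0).
#' @param n Grid resolution per axis.
#' @param ... Passed to [graphics::contour()].
#' @return The grid of predicted values, invisibly.
#' @export
plot.rsm_fit <- function(x, which = c(1L, 2L), fixed = 0, n = 40L, ...) {
  stopifnot(length(which) == 2L, all(which %in% 1:3))
  other <- setdiff(1:3, which)
  box <- coded_box(x$design)
  g1 <- seq(box[1, which[1]], box[2, which[1]], length.out = n)
  g2 <- seq(box[1, which[2]], box[2, which[2]], length.out = n)
  grid <- expand.grid(g1, g2)
  pts <- matrix(0, nrow(grid), 3)
  pts[, which[1]] <- grid[[1]]
  pts[, which[2]] <- grid[[2]]
  pts[, other] <- fixed
  z <- matrix(predict(x, pts, coded = TRUE), n, n)
  nm <- factor_names(x$design$factors)
  graphics::contour(g1, g2, z, xlab = paste0(nm[which[1]], " (coded)"),
                    ylab = paste0(nm[which[2]], " (coded)"),
                    main = paste("Fitted", x$response_name), ...)
  invisible(z)
}
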