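#' Define a design factor
#'
#' A factor in a three-factor central composite design (CCD) is described
#' by its centre, the half-range of its factorial levels (the coding step),
#' and its two axial (star) levels. Axial levels are stored verbatim rather
#' than derived from an alpha parameter, so designs transcribed from a
#' printed table are reproduced exactly even when the printed axial
#' distances are not consistent across factors.
#'
#' @param name Syntactic column name for the factor, e.g. `"pressure_mpa"`.
#' @param units Unit label, e.g. `"MPa"`.
#' @param center Centre level in actual units.
#' @param step Coding step: half the factorial range, must be positive.
#'   Coded level = (actual - center) / step.
#' @param axial_low,axial_high Actual levels of the two axial points on
#'   this factor's axis. Must bracket `center`.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("pressure_mpa", "MPa", center = 21, step = 3,
#'             axial_low = 17, axial_high = 25)
#' @export
factor_spec <- function(name, units, center, step, axial_low, axial_high) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("degenerate factor '", name, "': step must be a positive number",
         call. = FALSE)
  if (!(axial_low < center && center < axial_high))
    stop("factor '", name, "': need axial_low < center < axial_high",
         call. = FALSE)
  structure(
    list(name = name, units = units, center = as.numeric(center),
         step = as.numeric(step), axial_low = as.numeric(axial_low),
         axial_high = as.numeric(axial_high)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s (%s): center %g, step %g, axial %g / %g\n",
              x$name, x$units, x$center, x$step, x$axial_low, x$axial_high))
  invisible(x)
}

check_factors <- function(factors) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("unsupported design: exactly 3 factor_spec objects are required",
         call. = FALSE)
  invisible(factors)
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")

#' Convert actual factor levels to coded units
#'
#' Coded level = (actual - center) / step per factor, the standard CCD
#' coding in which factorial points sit at plus/minus 1.
#'
#' @param actual Numeric vector (one point, ordered as `factors`), or a
#'   matrix/data frame with one column per factor.
#' @param factors List of three [factor_spec()] objects.
#' @return Coded levels with the same shape as `actual`.
#' @seealso [decode_levels()] for the exact inverse.
#' @examples
#' f <- gp_factors()
#' code_levels(c(24, 70, 30), f)  # a factorial corner: (1, 1, 1)
#' @export
code_levels <- function(actual, factors) {
  check_factors(factors)
  centers <- vapply(factors, `[[`, numeric(1), "center")
  steps <- vapply(factors, `[[`, numeric(1), "step")
  transform_levels(actual, factors, function(m)
    sweep(sweep(m, 2L, centers, "-"), 2L, steps, "/"))
}

#' Convert coded factor levels back to actual units
#'
#' Exact inverse of [code_levels()]: actual = center + step * coded.
#'
#' @inheritParams code_levels
#' @param coded Coded levels, same shapes accepted as in [code_levels()].
#' @return Actual levels with the same shape as `coded`.
#' @export
decode_levels <- function(coded, factors) {
  check_factors(factors)
  centers <- vapply(factors, `[[`, numeric(1), "center")
  steps <- vapply(factors, `[[`, numeric(1), "step")
  transform_levels(coded, factors, function(m)
    sweep(sweep(m, 2L, steps, "*"), 2L, centers, "+"))
}

transform_levels <- function(x, factors, f) {
  nm <- factor_names(factors)
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    m <- matrix(as.numeric(x), nrow = 1L)
    out <- f(m)[1L, ]
    names(out) <- nm
    return(out)
  }
  m <- as.matrix(x)
  if (!is.null(colnames(m)) && all(nm %in% colnames(m))) m <- m[, nm, drop = FALSE]
  stopifnot(ncol(m) == 3L)
  out <- f(m)
  colnames(out) <- nm
  out
}

#' Build a three-factor central composite design
#'
#' Generates the 2^3 = 8 factorial points (all plus/minus 1 combinations
#' in coded units), 6 axial points at each factor's stored axial levels,
#' and `n_center` replicated centre points, in that order. Axial levels
#' come verbatim from the [factor_spec()]s, never from an alpha value; a
#' warning is raised when the implied coded axial distances differ across
#' factors (a transcribed design that is not rotatable).
#'
#' Run ordering is factorial (standard order, first factor fastest), then
#' axial (low/high per factor), then centre replicates.
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param n_center Number of centre-point replicates (>= 1).
#' @return An object of class `ccd_design`: list with `factors` and
#'   `points` (data frame: `run_id`, one column per factor in actual
#'   units, `ccd_role` in `{"factorial", "axial", "center"}`).
#' @examples
#' des <- suppressWarnings(ccd_design(gp_factors(), n_center = 6))
#' table(des$points$ccd_role)
#' @export
ccd_design <- function(factors, n_center = 6L) {
  check_factors(factors)
  n_center <- as.integer(n_center)
  stopifnot(n_center >= 1L)
  nm <- factor_names(factors)
  centers <- vapply(factors, `[[`, numeric(1), "center")
  steps <- vapply(factors, `[[`, numeric(1), "step")

  fact_coded <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1)))
  fact <- decode_levels(fact_coded, factors)

  axial <- matrix(rep(centers, each = 6L), nrow = 6L)
  for (j in 1:3) {
    axial[2L * j - 1L, j] <- factors[[j]]$axial_low
    axial[2L * j, j] <- factors[[j]]$axial_high
  }
  colnames(axial) <- nm

  alpha <- abs(code_levels(axial, factors))
  alpha <- apply(alpha, 2L, max)
  if (diff(range(alpha)) > 1e-8)
    warning(sprintf(
      "axial coded distances differ across factors (%s): design is not rotatable",
      paste(sprintf("%s=%.3g", nm, alpha), collapse = ", ")), call. = FALSE)

  ctr <- matrix(rep(centers, each = n_center), nrow = n_center,
                dimnames = list(NULL, nm))
  pts <- rbind(fact, axial, ctr)
  points <- data.frame(run_id = seq_len(nrow(pts)), pts,
                       ccd_role = rep(c("factorial", "axial", "center"),
                                      c(8L, 6L, n_center)))
  new_ccd_design(factors, points)
}

new_ccd_design <- function(factors, points) {
  structure(list(factors = factors, points = points), class = "ccd_design")
}

#' @export
print.ccd_design <- function(x, ...) {
  tab <- table(x$points$ccd_role)
  cat(sprintf("Central composite design: %d runs (%s)\n", nrow(x$points),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  for (f in x$factors) print(f)
  invisible(x)
}

#' Tabulate a design with coded columns
#'
#' @param x A `ccd_design`.
#' @param row.names,optional Ignored; standard S3 arguments.
#' @param coded Include `coded_*` columns? Default `TRUE`.
#' @param ... Unused.
#' @return Data frame with `run_id`, actual levels, `ccd_role`, and
#'   (optionally) coded levels.
#' @export
as.data.frame.ccd_design <- function(x, row.names = NULL, optional = FALSE,
                                     coded = TRUE, ...) {
  out <- x$points
  if (coded) {
    cl <- code_levels(out[factor_names(x$factors)], x$factors)
    colnames(cl) <- paste0("coded_", colnames(cl))
    out <- cbind(out, cl)
  }
  rownames(out) <- NULL
  out
}

#' Write a design to CSV / read it back
#'
#' The CSV carries `run_id`, one actual-level column per factor,
#' `ccd_role`, and coded columns; `read_design()` needs the same
#' `factor_spec`s to rebuild the object and ignores any coded columns.
#'
#' @param design A `ccd_design`.
#' @param path File path.
#' @param factors List of three [factor_spec()]s matching the CSV columns.
#' @return `read_design()` returns a `ccd_design`; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, factors) {
  check_factors(factors)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", factor_names(factors), "ccd_role")
  if (!all(need %in% names(df)))
    stop("design CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  new_ccd_design(factors, df[need])
}
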