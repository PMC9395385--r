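# Rank-based multi-criteria selection of the best operating condition:
# per-condition solubility, operational cost and CSTS are each converted
# to a rank index (n = best ... 1 = worst) and summed,
#   I_performance = I_solubility + I_cost + I_safety,
# aiming for the highest solubility at the lowest cost in the safest
# co-solvent environment.

#' Rank index of a criterion column
#'
#' The best value receives index n (the number of conditions), the worst
#' receives 1; ties share the mean of their rank positions. For
#' `"lower_better"` criteria (cost, hazard score) the orientation is
#' reversed before ranking.
#'
#' @param values Finite numeric vector, one per condition.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return Numeric vector of rank indices in [1, n].
#' @examples
#' rank_index(c(3, 1, 2), "higher_better")  # 3 1 2
#' rank_index(c(2, 2, 1), "higher_better")  # 2.5 2.5 1
#' @export
rank_index <- function(values, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) stop("empty criterion column", call. = FALSE)
  if (!all(is.finite(values)))
    stop("criterion values must be finite", call. = FALSE)
  if (direction == "lower_better") values <- -values
  rank(values, ties.method = "average")
}

#' Assemble per-condition records for the performance index
#'
#' Builds one record per operating condition from a design and its
#' measured solubilities: the solubility (measured, or model-predicted
#' when a fit is supplied), the annual operational cost at the
#' condition's water content, and the co-solvent CSTS. Replicated centre
#' points are collapsed to a single condition with their mean solubility
#' by default.
#'
#' @param design A `ccd_design`.
#' @param solubility Response as in [rsm_fit()] (vector or
#'   `run_id`/`value` data frame).
#' @param cost_cfg A [cost_config()].
#' @param db A [solvent_db()].
#' @param fit Optional `rsm_fit`; when given, solubility is the model
#'   prediction at each condition instead of the measured value.
#' @param group_centers Collapse duplicated conditions (default `TRUE`)?
#' @param activity_model Passed to [csts()].
#' @return Data frame with the factor columns, `solubility`, `oc`,
#'   `csts`, one row per condition.
#' @export
assess_conditions <- function(design, solubility, cost_cfg = cost_config(),
                              db = solvent_db(), fit = NULL,
                              group_centers = TRUE,
                              activity_model = "van_laar") {
  stopifnot(inherits(design, "ccd_design"))
  nm <- factor_names(design$factors)
  pts <- design$points
  df <- pts[nm]
  df$solubility <- align_response(solubility, pts$run_id)

  if (group_centers) {
    key <- do.call(paste, c(df[nm], sep = "\r"))
    agg <- stats::aggregate(df["solubility"], by = list(key = key), FUN = mean)
    first <- !duplicated(key)
    out <- df[first, nm, drop = FALSE]
    out$solubility <- agg$solubility[match(key[first], agg$key)]
  } else {
    out <- df
  }
  rownames(out) <- NULL

  if (!is.null(fit)) {
    stopifnot(inherits(fit, "rsm_fit"))
    out$solubility <- predict(fit, as.matrix(out[nm]))
  }

  water_col <- grep("water", nm, value = TRUE)[1]
  if (is.na(water_col))
    stop("design has no water-content factor; cannot vary cost/safety",
         call. = FALSE)
  w_levels <- unique(out[[water_col]])
  oc_by_w <- vapply(w_levels, function(w)
    operational_cost(cost_cfg, water_pct = w)$oc, numeric(1))
  csts_by_w <- vapply(w_levels, function(w)
    csts(w, db, activity_model = activity_model)$csts, numeric(1))
  out$oc <- oc_by_w[match(out[[water_col]], w_levels)]
  out$csts <- csts_by_w[match(out[[water_col]], w_levels)]
  out
}

#' Overall performance index and best condition
#'
#' Converts the three criterion columns into indices and sums them:
#' solubility is ranked higher-is-better, operational cost and CSTS
#' lower-is-better. The default index is the shared-ties rank of
#' [rank_index()]; `scale = "normalized"` instead rescales each oriented
#' criterion to [0, 1] (min-max), an alternative weighting exposed for
#' sensitivity checks. The best condition is the `i_performance` argmax;
#' exact ties are broken by higher `i_solubility`, then lower cost.
#'
#' @param records Data frame from [assess_conditions()] (or any frame
#'   with columns `solubility`, `oc`, `csts` plus condition identifiers).
#' @param scale `"rank"` (default) or `"normalized"`.
#' @return Object of class `performance_table`: `table` (records plus
#'   `i_solubility`, `i_cost`, `i_safety`, `i_performance`) and `best`
#'   (the winning row).
#' @examples
#' rec <- assess_conditions(gp_design(), gp_response("solubility"))
#' overall_performance(rec)
#' @export
overall_performance <- function(records, scale = c("rank", "normalized")) {
  scale <- match.arg(scale)
  need <- c("solubility", "oc", "csts")
  for (col in need) {
    if (!col %in% names(records))
      stop("records are missing the '", col, "' column", call. = FALSE)
    bad <- !is.finite(records[[col]])
    if (any(bad))
      stop("missing ", col, " for condition(s): ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  }
  idx <- if (scale == "rank") {
    data.frame(
      i_solubility = rank_index(records$solubility, "higher_better"),
      i_cost = rank_index(records$oc, "lower_better"),
      i_safety = rank_index(records$csts, "lower_better")
    )
  } else {
    minmax <- function(v) if (diff(range(v)) == 0) rep(0.5, length(v))
                          else (v - min(v)) / diff(range(v))
    data.frame(
      i_solubility = minmax(records$solubility),
      i_cost = minmax(-records$oc),
      i_safety = minmax(-records$csts)
    )
  }
  tab <- cbind(records, idx)
  tab$i_performance <- idx$i_solubility + idx$i_cost + idx$i_safety

  ord <- order(-tab$i_performance, -tab$i_solubility, tab$oc)
  best <- tab[ord[1L], , drop = FALSE]
  structure(list(table = tab, best = best, scale = scale),
            class = "performance_table")
}

#' @export
print.performance_table <- function(x, digits = 3, ...) {
  cat(sprintf("Overall performance (%s scale) over %d conditions\n",
              x$scale, nrow(x$table)))
  tab <- x$table[order(-x$table$i_performance), , drop = FALSE]
  print(format(utils::head(tab, 10), digits = digits), row.names = FALSE)
  if (nrow(tab) > 10) cat("  ...\n")
  cond <- x$best[setdiff(names(x$best),
                         c("solubility", "oc", "csts", "i_solubility",
                           "i_cost", "i_safety", "i_performance"))]
  cat("Best condition:",
      paste(sprintf("%s = %.4g", names(cond), unlist(cond)), collapse = ", "),
      sprintf("(I_performance = %.4g)\n", x$best$i_performance))
  invisible(x)
}

#' Compare the index-selected condition with the RSM optimum
#'
#' Puts the best condition of a [overall_performance()] table side by
#' side with a fitted-surface optimum, both evaluated through the same
#' solubility model, and reports the solubility ratio (index / RSM).
#'
#' @param perf A `performance_table`.
#' @param fit The fitted solubility model (`rsm_fit`).
#' @param rsm_opt An `rsm_optimum` from [rsm_optimize()], or a numeric
#'   vector of actual factor levels to treat as the RSM condition.
#' @return Data frame with two rows (`index`, `rsm`): condition levels
#'   and predicted solubility, with the ratio in attribute
#'   `solubility_ratio` and printed.
#' @export
compare_with_rsm <- function(perf, fit, rsm_opt) {
  stopifnot(inherits(perf, "performance_table"), inherits(fit, "rsm_fit"))
  nm <- factor_names(fit$design$factors)
  idx_cond <- unlist(perf$best[nm])
  rsm_cond <- if (inherits(rsm_opt, "rsm_optimum")) rsm_opt$actual
              else stats::setNames(as.numeric(rsm_opt), nm)
  pred <- predict(fit, rbind(idx_cond, rsm_cond))
  out <- data.frame(method = c("index", "rsm"),
                    rbind(idx_cond, rsm_cond),
                    predicted_solubility = pred)
  rownames(out) <- NULL
  attr(out, "solubility_ratio") <- pred[1] / pred[2]
  out
}

#' One-call multifactor assessment
#'
#' Convenience pipeline: fits the solubility surface, assembles the
#' per-condition records, ranks them, and compares the index winner with
#' the response-surface optimum.
#'
#' @param design A `ccd_design`; default the packaged case study.
#' @param solubility Solubility response; default the packaged data.
#' @param cost_cfg,db Configurations for the cost and safety modules.
#' @param order Model order for the solubility surface.
#' @param ... Passed to [assess_conditions()].
#' @return List with `fit` (`rsm_fit`), `performance`
#'   (`performance_table`), `optimum` (`rsm_optimum`) and `comparison`
#'   (data frame from [compare_with_rsm()]).
#' @examples
#' res <- sfe_performance()
#' res$performance$best
#' @export
sfe_performance <- function(design = gp_design(),
                            solubility = gp_response("solubility"),
                            cost_cfg = cost_config(), db = solvent_db(),
                            order = "quadratic", ...) {
  fit <- rsm_fit(design, solubility, order = order,
                 response_name = "solubility")
  rec <- assess_conditions(design, solubility, cost_cfg, db, ...)
  perf <- overall_performance(rec)
  opt <- rsm_optimize(fit)
  list(fit = fit, performance = perf, optimum = opt,
       comparison = compare_with_rsm(perf, fit, opt))
}
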