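# Pairwise association statistics on a common correlation-like scale.
# Every endpoint association is ultimately a Spearman correlation between
# the molecular variable and a per-sample "evidence score" derived from the
# endpoint, so values of -1, 0, +1 mean deterministic negative association,
# no association, and deterministic positive association throughout.

assoc_stat <- function(value, n_used, endpoint_name = NA_character_) {
  structure(list(value = value, n_used = as.integer(n_used),
                 endpoint_name = endpoint_name),
            class = "AssociationStat")
}

#' @export
print.AssociationStat <- function(x, ...) {
  cat(sprintf("AssociationStat: %.4f (n = %d%s)\n", x$value, x$n_used,
              if (is.na(x$endpoint_name)) ""
              else paste0(", endpoint ", x$endpoint_name)))
  invisible(x)
}

# average ranks; returns NULL if degenerate (constant after NA removal)
rank_avg <- function(v) rank(v, ties.method = "average", na.last = "keep")

pairwise_complete <- function(...) {
  args <- list(...)
  ok <- Reduce(`&`, lapply(args, function(v) !is.na(v)))
  lapply(args, function(v) v[ok])
}

#' Spearman rank correlation on a correlation-like scale
#'
#' Average ranks are used for ties; missing values are removed pairwise.
#' At least 3 complete pairs and 2 distinct values per vector are required.
#'
#' @param x,y Numeric vectors of equal length.
#' @return An `AssociationStat` with elements `value` (in \[-1, 1\]) and
#'   `n_used`.
#' @examples
#' spearman_assoc(c(1, 2, 3), c(10, 20, 30))$value # +1
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  v <- pairwise_complete(x, y)
  n <- length(v[[1L]])
  if (n < 3L) stop("insufficient data: fewer than 3 complete pairs")
  rx <- rank_avg(v[[1L]]); ry <- rank_avg(v[[2L]])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined statistic: constant vector")
  assoc_stat(stats::cor(rx, ry), n)
}

#' Association of a numeric variable with a binary group
#'
#' The Spearman correlation of `x` with the 0/1 indicator, a rank-biserial
#' form bounded in \[-1, 1\]; positive values mean larger `x` in group 1.
#'
#' @param x Numeric vector.
#' @param group 0/1 vector of equal length.
#' @return An `AssociationStat`.
#' @export
binary_assoc <- function(x, group) {
  if (!all(group %in% c(0, 1, NA)))
    stop("group must be coded 0/1")
  v <- pairwise_complete(x, group)
  if (length(unique(v[[2L]])) < 2L)
    stop("undefined statistic: only one group present")
  spearman_assoc(v[[1L]], v[[2L]])
}

# Null-model (no covariate) martingale residuals: event indicator minus the
# Nelson-Aalen cumulative hazard at the observed time.
null_martingale <- function(time, event) {
  fit <- survival::coxph(survival::Surv(time, event) ~ 1)
  as.numeric(stats::residuals(fit, type = "martingale"))
}

#' Association of a numeric variable with a censored time-to-event endpoint
#'
#' The Spearman correlation of `x` with the null-model martingale residuals
#' (event indicator minus Nelson-Aalen cumulative hazard at the observed
#' time), negated so that positive values mean higher `x` goes with longer
#' survival. Bounded in \[-1, 1\]. With zero events there is no
#' information: the value is 0 with a warning.
#'
#' @param x Numeric vector.
#' @param time Non-negative event/censoring times.
#' @param event 0/1 event indicators.
#' @return An `AssociationStat`.
#' @export
survival_assoc <- function(x, time, event) {
  if (!all(event %in% c(0, 1, NA))) stop("event must be coded 0/1")
  v <- pairwise_complete(x, time, event)
  n <- length(v[[1L]])
  if (n < 3L) stop("insufficient data: fewer than 3 complete cases")
  if (sum(v[[3L]]) == 0) {
    warning("no events: survival association carries no information")
    return(assoc_stat(0, n))
  }
  if (stats::sd(v[[1L]]) == 0) stop("undefined statistic: constant x")
  res <- null_martingale(v[[2L]], v[[3L]])
  st <- spearman_assoc(v[[1L]], res)
  assoc_stat(-st$value, st$n_used)
}

#' Pearson correlation with a t-distribution p-value
#'
#' Used for the within-gene methylation-expression marker correlations
#' r_gfl; linear (Pearson) for consistency with canonical correlation.
#'
#' @param x,m Numeric vectors of equal length (>= 3 complete pairs, both
#'   non-constant).
#' @return An object of class `PairCorrelation`: list with `r`, `p`
#'   (two-sided, from t with n-2 df), `n_used`.
#' @export
pair_correlation <- function(x, m) {
  if (length(x) != length(m)) stop("x and m must have equal length")
  v <- pairwise_complete(x, m)
  n <- length(v[[1L]])
  if (n < 3L) stop("insufficient data: fewer than 3 complete pairs")
  if (stats::sd(v[[1L]]) == 0 || stats::sd(v[[2L]]) == 0)
    stop("undefined statistic: constant input")
  r <- stats::cor(v[[1L]], v[[2L]])
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  structure(list(r = r, p = p, n_used = n), class = "PairCorrelation")
}

# Per-sample evidence score for one endpoint: a vector z such that the
# endpoint association statistic of feature x is spearman(x, z) times the
# endpoint's direction sign. For survival the score is the negated
# martingale residual (computed from the full observed endpoint, which is
# invariant under sample permutation as a set).
endpoint_score <- function(spec, value) {
  if (spec$kind == "survival") {
    z <- rep(NA_real_, length(value$time))
    ok <- !is.na(value$time) & !is.na(value$event)
    if (sum(value$event[ok], na.rm = TRUE) == 0) {
      warning("endpoint '", spec$name, "': no events, no information")
      z[ok] <- 0
    } else {
      z[ok] <- -null_martingale(value$time[ok], value$event[ok])
    }
    z
  } else {
    as.numeric(value)
  }
}

#' Association of one molecular feature with every endpoint
#'
#' Dispatches per endpoint kind (Spearman for quantitative/ordinal, its
#' 0/1 form for binary, the martingale-residual correlation for survival)
#' and multiplies each statistic by the endpoint's `direction_sign`, so
#' that biologically "interesting" associations are positive for every
#' endpoint. Per-endpoint failures (constant input, too few complete
#' pairs) become `NA` entries with a warning rather than errors.
#'
#' @param feature Numeric vector, aligned to `endpoints$sample_ids`.
#' @param endpoints An [endpoint_table()].
#' @return Data frame with one row per endpoint: `endpoint`, `value`,
#'   `n_used`.
#' @export
endpoint_assoc_vector <- function(feature, endpoints) {
  stopifnot(inherits(endpoints, "EndpointTable"))
  if (length(feature) != length(endpoints$sample_ids))
    stop("feature length does not match endpoint table samples")
  K <- n_endpoints(endpoints)
  out <- data.frame(endpoint = character(K), value = NA_real_,
                    n_used = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    sp <- endpoints$endpoints[[k]]
    out$endpoint[k] <- sp$name
    st <- tryCatch({
      if (sp$kind == "survival") {
        v <- endpoints$values[[k]]
        survival_assoc(feature, v$time, v$event)
      } else if (sp$kind == "binary") {
        binary_assoc(feature, endpoints$values[[k]])
      } else {
        spearman_assoc(feature, endpoints$values[[k]])
      }
    }, error = function(e) {
      warning("endpoint '", sp$name, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(st)) {
      out$value[k] <- st$value * sp$direction_sign
      out$n_used[k] <- st$n_used
    }
  }
  if (all(is.na(out$value)))
    warning("all endpoint associations undefined for this feature")
  out
}
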