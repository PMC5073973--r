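#' Construct a molecular data matrix
#'
#' An `OmicsMatrix` holds one molecular data type (e.g. methylation
#' beta-values or expression intensities) as a features x samples numeric
#' matrix with unique feature and sample identifiers. Non-finite values are
#' converted to `NA` (missing) with a warning.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @return An object of class `OmicsMatrix` with elements `values`,
#'   `feature_ids`, `sample_ids`.
#' @examples
#' om <- omics_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2", "s3"))))
#' dim(om$values)
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature_ids and sample_ids are required (or set dimnames)")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("number of feature_ids (", length(feature_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("number of sample_ids (", length(sample_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ",
         feature_ids[duplicated(feature_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad)) {
    warning(sum(bad), " non-finite value(s) set to NA")
    values[bad] <- NA_real_
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids),
            class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat("OmicsMatrix:", length(x$feature_ids), "features x",
      length(x$sample_ids), "samples;",
      sum(is.na(x$values)), "missing values\n")
  invisible(x)
}

#' Declare one clinical endpoint
#'
#' Each endpoint carries a kind and a direction sign. The direction sign is
#' the multiplier that makes a biologically "interesting" association
#' positive on the correlation-like scale (e.g. -1 for an endpoint where
#' smaller values mean better response). Unordered categorical endpoints
#' with more than two levels are not supported: a composite statistic on a
#' correlation-like scale needs a direction, which such endpoints lack.
#'
#' @param name Endpoint name.
#' @param kind One of `"quantitative"`, `"ordinal"`, `"binary"`,
#'   `"survival"`.
#' @param direction_sign Either `+1` or `-1`.
#' @return An object of class `EndpointSpec`.
#' @export
endpoint_spec <- function(name, kind = c("quantitative", "ordinal",
                                         "binary", "survival"),
                          direction_sign = 1) {
  kind <- match.arg(kind)
  if (!direction_sign %in% c(-1, 1))
    stop("direction_sign must be -1 or +1")
  structure(list(name = as.character(name), kind = kind,
                 direction_sign = as.numeric(direction_sign)),
            class = "EndpointSpec")
}

#' Construct an endpoint table
#'
#' Holds per-sample values for K >= 1 endpoints of possibly mixed kinds.
#' Quantitative, ordinal and binary endpoints are numeric vectors; a
#' survival endpoint is a list with components `time` (non-negative) and
#' `event` (0/1). Missing values are allowed and are excluded pairwise from
#' each endpoint's association statistic.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param endpoints List of [endpoint_spec()] objects.
#' @param values Named list, one element per endpoint (names must match the
#'   specs): numeric vector, or for survival a `list(time =, event =)`.
#' @return An object of class `EndpointTable`.
#' @export
endpoint_table <- function(sample_ids, endpoints, values) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (length(endpoints) < 1L) stop("at least one endpoint is required")
  if (!all(vapply(endpoints, inherits, logical(1), "EndpointSpec")))
    stop("endpoints must be a list of EndpointSpec objects")
  nm <- vapply(endpoints, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate endpoint name")
  if (!setequal(names(values), nm))
    stop("names of values must match endpoint names")
  values <- values[nm]
  n <- length(sample_ids)
  for (k in seq_along(endpoints)) {
    v <- values[[k]]
    if (endpoints[[k]]$kind == "survival") {
      if (!is.list(v) || !all(c("time", "event") %in% names(v)))
        stop("survival endpoint '", nm[k],
             "' needs list(time =, event =)")
      if (length(v$time) != n || length(v$event) != n)
        stop("survival endpoint '", nm[k], "' has wrong length")
      if (any(v$time < 0, na.rm = TRUE))
        stop("negative time in survival endpoint '", nm[k], "'")
      if (!all(v$event %in% c(0, 1, NA)))
        stop("event indicator of '", nm[k], "' must be 0/1")
    } else {
      if (length(v) != n)
        stop("endpoint '", nm[k], "' has wrong length")
      if (endpoints[[k]]$kind == "binary" &&
          !all(v %in% c(0, 1, NA)))
        stop("binary endpoint '", nm[k], "' must be coded 0/1")
    }
  }
  structure(list(sample_ids = sample_ids, endpoints = endpoints,
                 values = values),
            class = "EndpointTable")
}

#' @export
print.EndpointTable <- function(x, ...) {
  cat("EndpointTable:", length(x$sample_ids), "samples,",
      length(x$endpoints), "endpoint(s):",
      paste(vapply(x$endpoints, function(e)
        paste0(e$name, " [", e$kind, ", sign ",
               ifelse(e$direction_sign > 0, "+1", "-1"), "]"),
        character(1)), collapse = ", "), "\n")
  invisible(x)
}

n_endpoints <- function(endpoints) length(endpoints$endpoints)

# subset an EndpointTable to sample indices idx (internal)
subset_endpoints <- function(et, idx) {
  vals <- lapply(seq_along(et$endpoints), function(k) {
    v <- et$values[[k]]
    if (et$endpoints[[k]]$kind == "survival")
      list(time = v$time[idx], event = v$event[idx])
    else v[idx]
  })
  names(vals) <- vapply(et$endpoints, `[[`, character(1), "name")
  endpoint_table(et$sample_ids[idx], et$endpoints, vals)
}

#' Map a gene to its features in each molecular data type
#'
#' @param gene_id Gene identifier.
#' @param meth_feature_ids Non-empty, duplicate-free character vector of
#'   methylation marker ids for the gene.
#' @param expr_feature_ids Non-empty, duplicate-free character vector of
#'   expression feature ids for the gene.
#' @return An object of class `GeneFeatureMap`.
#' @export
gene_feature_map <- function(gene_id, meth_feature_ids, expr_feature_ids) {
  meth_feature_ids <- as.character(meth_feature_ids)
  expr_feature_ids <- as.character(expr_feature_ids)
  if (length(meth_feature_ids) < 1L || length(expr_feature_ids) < 1L)
    stop("gene '", gene_id, "': feature lists must be non-empty")
  if (anyDuplicated(meth_feature_ids) || anyDuplicated(expr_feature_ids))
    stop("gene '", gene_id, "': duplicate feature id in map")
  structure(list(gene_id = as.character(gene_id),
                 meth_feature_ids = meth_feature_ids,
                 expr_feature_ids = expr_feature_ids),
            class = "GeneFeatureMap")
}

#' Align two molecular matrices and an endpoint table on common samples
#'
#' Restricts all three inputs to the intersection of their sample ids, in a
#' common order (the order of first appearance in the methylation matrix).
#' Matching is by id string, never positional. Aligning an already aligned
#' dataset is a no-op.
#'
#' @param meth,expr [omics_matrix()] objects.
#' @param endpoints An [endpoint_table()].
#' @return An object of class `AlignedDataset`: list with elements `meth`,
#'   `expr`, `endpoints` and `dropped` (named counts of samples dropped
#'   from each input).
#' @export
align_dataset <- function(meth, expr, endpoints) {
  stopifnot(inherits(meth, "OmicsMatrix"), inherits(expr, "OmicsMatrix"),
            inherits(endpoints, "EndpointTable"))
  common <- intersect(intersect(meth$sample_ids, expr$sample_ids),
                      endpoints$sample_ids)
  if (length(common) == 0L)
    stop("no samples shared by the three inputs; first unmatched ids: ",
         "meth '", meth$sample_ids[1L], "', expr '", expr$sample_ids[1L],
         "', endpoints '", endpoints$sample_ids[1L], "'")
  common <- meth$sample_ids[meth$sample_ids %in% common]
  dropped <- c(meth = length(meth$sample_ids) - length(common),
               expr = length(expr$sample_ids) - length(common),
               endpoints = length(endpoints$sample_ids) - length(common))
  m <- omics_matrix(meth$values[, common, drop = FALSE],
                    meth$feature_ids, common)
  x <- omics_matrix(expr$values[, common, drop = FALSE],
                    expr$feature_ids, common)
  e <- subset_endpoints(endpoints, match(common, endpoints$sample_ids))
  structure(list(meth = m, expr = x, endpoints = e, dropped = dropped),
            class = "AlignedDataset")
}

#' Validate a set of gene-feature maps against the data matrices
#'
#' Feature ids absent from the corresponding matrix are removed. Genes left
#' without any methylation marker or any expression feature are flagged as
#' skipped (with a reason), never silently dropped. No ids are invented:
#' the output id sets are subsets of the input id sets.
#'
#' @param maps A single [gene_feature_map()] or a list of them.
#' @param meth,expr [omics_matrix()] objects.
#' @return List with `maps` (the pruned usable maps, named by gene) and
#'   `skipped` (data frame with columns `gene_id`, `reason`).
#' @export
validate_gene_map <- function(maps, meth, expr) {
  if (inherits(maps, "GeneFeatureMap")) maps <- list(maps)
  kept <- list()
  skipped <- list()
  for (gm in maps) {
    ml <- gm$meth_feature_ids[gm$meth_feature_ids %in% meth$feature_ids]
    xl <- gm$expr_feature_ids[gm$expr_feature_ids %in% expr$feature_ids]
    n_rm <- (length(gm$meth_feature_ids) - length(ml)) +
      (length(gm$expr_feature_ids) - length(xl))
    if (length(ml) == 0L || length(xl) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        gene_id = gm$gene_id,
        reason = if (length(ml) == 0L) "no methylation markers in data"
                 else "no expression features in data",
        stringsAsFactors = FALSE)
      next
    }
    if (n_rm > 0L)
      warning("gene '", gm$gene_id, "': ", n_rm,
              " feature id(s) absent from the data were removed")
    kept[[gm$gene_id]] <- gene_feature_map(gm$gene_id, ml, xl)
  }
  list(maps = kept,
       skipped = if (length(skipped))
         do.call(rbind, skipped)
       else data.frame(gene_id = character(), reason = character(),
                       stringsAsFactors = FALSE))
}
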