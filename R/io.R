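# Delimited-text readers/writers. Canonical dialect is TSV: molecular
# matrices have the feature id in the first column and a header row of
# sample ids; the endpoint table has the sample id first and one column
# per endpoint (survival endpoints as <name>_time, <name>_event); the
# gene map has columns gene_id, data_type (meth|expr), feature_id.

check_ragged <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "")
  if (length(unique(nf)) > 1L)
    stop("ragged rows in '", path, "': line ",
         which(nf != nf[1L])[1L], " has ", nf[nf != nf[1L]][1L],
         " fields, expected ", nf[1L])
}

#' Read a molecular data matrix from delimited text
#'
#' First column: feature id; header row: sample ids. Non-numeric cells
#' become missing, with a warning giving the tally.
#'
#' @param path File path.
#' @param sep Field separator (default tab; use `","` for CSV).
#' @return An [omics_matrix()].
#' @export
read_omics_tsv <- function(path, sep = "\t") {
  check_ragged(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id in '", path, "': ",
         ids[duplicated(ids)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals),
                                 ncol(vals)))
  n_bad <- sum(is.na(num) & !is.na(vals) &
                 !toupper(trimws(vals)) %in% c("NA", ""))
  if (n_bad > 0L)
    warning(n_bad, " non-numeric cell(s) in '", path,
            "' treated as missing")
  omics_matrix(num, ids, colnames(vals))
}

#' Write a molecular data matrix to delimited text
#'
#' Inverse of [read_omics_tsv()]; values are written with 17 significant
#' digits so a write/read round trip reproduces them exactly.
#'
#' @param om An [omics_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_omics_tsv <- function(om, path, sep = "\t") {
  stopifnot(inherits(om, "OmicsMatrix"))
  df <- data.frame(feature_id = om$feature_ids,
                   format(om$values, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", om$sample_ids)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an endpoint table from delimited text
#'
#' First column: sample id. Each declared endpoint must have its column
#' present; a survival endpoint needs both `<name>_time` and
#' `<name>_event` columns with events coded 0/1.
#'
#' @param path File path.
#' @param spec List of [endpoint_spec()]s declaring the endpoints.
#' @param sep Field separator.
#' @return An [endpoint_table()].
#' @export
read_endpoints_tsv <- function(path, spec, sep = "\t") {
  check_ragged(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, comment.char = "",
                          quote = "\"")
  sid <- as.character(df[[1L]])
  vals <- list()
  for (sp in spec) {
    if (sp$kind == "survival") {
      tc <- paste0(sp$name, "_time"); ec <- paste0(sp$name, "_event")
      for (col in c(tc, ec))
        if (!col %in% colnames(df))
          stop("declared endpoint column '", col, "' missing from '",
               path, "'")
      ev <- df[[ec]]
      if (!all(ev %in% c(0, 1, NA)))
        stop("event values of endpoint '", sp$name,
             "' must be 0/1; found ",
             ev[!ev %in% c(0, 1, NA)][1L])
      vals[[sp$name]] <- list(time = as.numeric(df[[tc]]),
                              event = as.numeric(ev))
    } else {
      if (!sp$name %in% colnames(df))
        stop("declared endpoint column '", sp$name,
             "' missing from '", path, "'")
      vals[[sp$name]] <- as.numeric(df[[sp$name]])
    }
  }
  endpoint_table(sid, spec, vals)
}

#' Read a gene-to-feature map from delimited text
#'
#' Columns `gene_id`, `data_type` (one of `meth`, `expr`), `feature_id`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Named list of [gene_feature_map()]s.
#' @export
read_gene_map_tsv <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "data_type", "feature_id")
  if (!all(need %in% colnames(df)))
    stop("gene map must have columns ", paste(need, collapse = ", "))
  if (!all(df$data_type %in% c("meth", "expr")))
    stop("data_type must be 'meth' or 'expr'")
  out <- lapply(split(df, df$gene_id), function(d)
    gene_feature_map(d$gene_id[1L],
                     d$feature_id[d$data_type == "meth"],
                     d$feature_id[d$data_type == "expr"]))
  out[unique(df$gene_id)]
}

#' Write per-gene results with a reproducibility sidecar
#'
#' Writes the result table as TSV (stable column order, one gene per row)
#' plus a JSON sidecar `<path>.json` holding the configuration, seed,
#' package version and skip counts needed to reproduce the run.
#'
#' @param results A [run_study()] result table.
#' @param path Output TSV path.
#' @param config Optional named list recorded in the sidecar.
#' @param seed Seed recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, config = list(), seed = NULL) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  skipped <- attr(results, "skipped")
  sidecar <- list(
    config = config, seed = seed,
    version = as.character(utils::packageVersion("ccpromise")),
    n_genes = nrow(results),
    n_skipped = if (is.null(skipped)) 0L else nrow(skipped),
    skip_reasons = if (is.null(skipped) || !nrow(skipped)) list()
      else as.list(table(skipped$reason)))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Expected number of false discoveries at a raw p-value threshold
#'
#' With `n_genes` true nulls tested at threshold `p`, about
#' `p * n_genes` false discoveries are expected; reported in run
#' summaries so a raw permutation threshold can be reasoned about without
#' imposing an FDR procedure.
#'
#' @param threshold Raw p-value threshold in (0, 1).
#' @param n_genes Number of genes tested.
#' @return `threshold * n_genes`.
#' @examples
#' expected_false_discoveries(0.001, 11620) # 11.6
#' @export
expected_false_discoveries <- function(threshold, n_genes) {
  stopifnot(threshold > 0, threshold < 1, n_genes >= 0)
  threshold * n_genes
}
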