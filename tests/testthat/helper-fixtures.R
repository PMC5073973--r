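# Small in-code fixtures shared across tests.

make_omics <- function(values, features, samples) {
  omics_matrix(matrix(values, length(features), length(samples),
                      dimnames = list(features, samples)),
               features, samples)
}

# a toy aligned two-omics dataset: n samples, 3 meth markers, 2 expr
# features, 2 quantitative endpoints loosely linked to expr_1
toy_dataset <- function(n = 20, seed = 42) {
  set.seed(seed)
  sid <- paste0("s", seq_len(n))
  M <- matrix(rnorm(3 * n), 3, n, dimnames = list(paste0("m", 1:3), sid))
  X <- rbind(m_linked = 0.8 * M[1, ] + rnorm(n, sd = 0.5),
             noise = rnorm(n))
  rownames(X) <- c("x1", "x2"); colnames(X) <- sid
  y1 <- 0.7 * X[1, ] + rnorm(n, sd = 0.5)
  y2 <- 0.5 * X[1, ] + rnorm(n, sd = 0.5)
  eps <- list(endpoint_spec("y1", "quantitative", 1),
              endpoint_spec("y2", "quantitative", 1))
  et <- endpoint_table(sid, eps, list(y1 = y1, y2 = y2))
  align_dataset(omics_matrix(M), omics_matrix(X), et)
}

toy_lambda <- function(normalized = TRUE) {
  build_evidence_vector(list(endpoint_spec("y1", "quantitative", 1),
                             endpoint_spec("y2", "quantitative", 1)),
                        normalized = normalized)
}
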