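# Independent oracles and tiny fixture builders shared across tests.

# naive double-loop Hopfield energy: E = -1/2 sum_{i != j} w_ij s_i s_j
naive_energy <- function(state, weights) {
  m <- length(state)
  e <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) e <- e + weights[i, j] * state[i] * state[j]
    }
  }
  -0.5 * e
}

# closed-form self-attractor energy in the zero-one convention
closed_form_energy <- function(k) -k * (k - 1) / 2

random_binary <- function(m, p_active = 0.5) {
  as.numeric(stats::runif(m) < p_active)
}

# small dense TSV fixture on disk; returns the path
write_tsv_fixture <- function(values, gene_ids, cell_ids,
                              path = tempfile(fileext = ".tsv")) {
  lines <- c(
    paste(c("gene_id", cell_ids), collapse = "\t"),
    vapply(seq_along(gene_ids), function(i) {
      paste(c(gene_ids[i], format(values[i, ], scientific = FALSE)),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}

small_expression <- function() {
  expression_matrix(
    matrix(c(2, 4, 6, 5, 5, 5, 1, 0, 3, 2, 8, 9), nrow = 4, byrow = TRUE),
    gene_ids = c("gA", "gB", "gC", "gD"),
    cell_ids = c("c1", "c2", "c3")
  )
}
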