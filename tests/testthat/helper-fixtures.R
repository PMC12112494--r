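# Shared fixtures: all built in code, no stored data.

toy_schema <- function(with_md = TRUE) {
  rels <- list(c("M", "X"), c("X", "D"))
  if (with_md) rels <- c(rels, list(c("M", "D")))
  graph_schema(c("M", "D", "X"), rels)
}

# A fixed tiny graph on the toy schema.
toy_graph <- function() {
  hetero_graph(
    toy_schema(),
    nodes = list(M = c("m1", "m2", "m3"), D = c("d1", "d2"),
                 X = c("x1", "x2")),
    edges = list(
      "M-X" = rbind(c(1, 1), c(2, 1), c(3, 2), c(1, 2), c(2, 2)),
      "X-D" = rbind(c(1, 1), c(2, 1), c(2, 2)),
      "M-D" = rbind(c(1, 1), c(2, 2), c(3, 1))
    ))
}

# Random heterogeneous graph on a 3-type miRNA/disease/mRNA schema
# (about 30 nodes), used by the straight-line pipeline oracle.
pipe_schema <- function() {
  graph_schema(c("miRNA", "disease", "mRNA"),
               list(c("miRNA", "disease"), c("miRNA", "mRNA"),
                    c("disease", "mRNA")))
}

pipe_graph <- function(seed = 7, nm = 10, nd = 10, nx = 10, p = 0.25) {
  sch <- pipe_schema()
  withr::with_seed(seed, {
    draw <- function(na, nb) {
      m <- which(matrix(runif(na * nb) < p, na, nb), arr.ind = TRUE)
      cbind(m[, 1], m[, 2])
    }
    hetero_graph(sch,
      nodes = list(miRNA = paste0("m", seq_len(nm)),
                   disease = paste0("d", seq_len(nd)),
                   mRNA = paste0("r", seq_len(nx))),
      edges = list("miRNA-disease" = draw(nm, nd),
                   "miRNA-mRNA" = draw(nm, nx),
                   "disease-mRNA" = draw(nd, nx)))
  })
}

# Small synthetic biological network for integration-style tests.
mini_bio <- function(seed = 0, mode = "mixed") {
  synth_generate(synth_config(
    counts = c(miRNA = 12, disease = 12, mRNA = 15, lncRNA = 8,
               circRNA = 6, protein = 10, drug = 8, microbe = 4),
    C = 2, mode = mode, seed = seed))
}

# Random schema for enumeration property tests: up to `n_types` types with
# random relations; "M" and "D" always present.
random_schema <- function(seed, n_types = 6) {
  withr::with_seed(seed, {
    tys <- c("M", "D", paste0("T", seq_len(max(0, n_types - 2))))
    pairs <- t(combn(tys, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
    graph_schema(tys, lapply(which(keep), function(i) pairs[i, ]))
  })
}

# Writes rows to a temp edge TSV; rows is a character vector of lines.
write_edge_file <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(rows, f)
  f
}
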