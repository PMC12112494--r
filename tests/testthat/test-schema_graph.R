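test_that("edge TSV loading registers nodes, collapses duplicates, rejects bad rows", {
  sch <- toy_schema()
  f <- write_edge_file(c(
    "M\tm1\tM-X\tX\tx1",
    "X\tx1\tM-X\tM\tm2",       # reversed orientation, still valid
    "M\tm1\tM-D\tD\td1",
    "M\tm1\tM-X\tX\tx1"))      # duplicate of row 1
  expect_warning(g <- load_edges(f, sch), "1 duplicate")
  expect_equal(n_edges(g), 3)
  expect_setequal(g$nodes$M, c("m1", "m2"))
  expect_setequal(g$nodes$X, c("x1"))

  empty <- write_edge_file(character(0))
  g0 <- load_edges(empty, sch)
  expect_equal(n_edges(g0), 0)
  expect_true(all(lengths(g0$nodes) == 0))

  bad <- write_edge_file("M\tm1\tmiRNA-planet\tX\tx1")
  expect_error(load_edges(bad, sch), "schema violation")

  wrongtype <- write_edge_file("M\tm1\tX-D\tX\tx1")
  expect_error(load_edges(wrongtype, sch), "schema violation")
})

test_that("write_edges/load_edges round-trips the canonical edge multiset", {
  g <- toy_graph()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(g, path)
  g2 <- load_edges(path, g$schema)
  key <- function(gr) {
    sort(unlist(lapply(names(gr$edges), function(lab) {
      e <- gr$edges[[lab]]
      tys <- gr$schema$relations[match(lab, gr$schema$relations$label), ]
      if (nrow(e) == 0) return(character(0))
      paste(lab, gr$nodes[[tys$type_a]][e[, 1]],
            gr$nodes[[tys$type_b]][e[, 2]])
    })))
  }
  expect_identical(key(g2), key(g))
})

test_that("hetero_graph enforces its invariants", {
  sch <- toy_schema()
  expect_error(hetero_graph(sch, nodes = list(M = "m1", X = "x1"),
                            edges = list("M-X" = rbind(c(1, 2)))),
               "out of range")
  expect_error(hetero_graph(sch, nodes = list(M = c("m1", "m1"))),
               "duplicate node ids")
  expect_error(hetero_graph(sch, nodes = list(M = "m1", X = "x1"),
                            edges = list("M-X" = rbind(c(1, 1), c(1, 1)))),
               "duplicate undirected edge")
})

make_bipartite_graph <- function(n_pos = 100, nm = 20, nd = 30, seed = 3) {
  sch <- toy_schema()
  withr::with_seed(seed, {
    lin <- sample.int(nm * nd, n_pos)
    hetero_graph(sch,
      nodes = list(M = paste0("m", 1:nm), D = paste0("d", 1:nd),
                   X = "x1"),
      edges = list("M-D" = cbind((lin - 1) %% nm + 1,
                                 (lin - 1) %/% nm + 1)))
  })
}

test_that("make_splits produces exact floor-partitioned counts with 1:1 negatives", {
  g <- make_bipartite_graph(100)
  sp <- make_splits(g, c(0.75, 0.10, 0.15), seed = 1, target = "M-D")
  expect_equal(vapply(sp$pos, nrow, 1L), c(train = 75, valid = 10, test = 15))
  expect_equal(vapply(sp$neg, nrow, 1L), c(train = 75, valid = 10, test = 15))

  sp2 <- make_splits(g, c(0.75, 0.10, 0.15), seed = 1, target = "M-D")
  expect_identical(sp, sp2)

  # remainder goes to train: 101 positives -> 76/10/15
  g2 <- make_bipartite_graph(101)
  sp3 <- make_splits(g2, c(0.75, 0.10, 0.15), seed = 2, target = "M-D")
  expect_equal(nrow(sp3$pos$train), 76)
})

test_that("split invariants hold across seeds and ratios", {
  g <- make_bipartite_graph(83, nm = 15, nd = 20)
  key <- function(m) paste(m[, 1], m[, 2])
  all_pos <- key(g$edges[["M-D"]])
  for (seed in c(1, 9, 42)) {
    sp <- make_splits(g, c(0.6, 0.2, 0.2), seed = seed, target = "M-D")
    pk <- lapply(sp$pos, key); nk <- lapply(sp$neg, key)
    expect_setequal(unlist(pk), all_pos)
    expect_length(intersect(pk$train, pk$valid), 0)
    expect_length(intersect(pk$train, pk$test), 0)
    expect_length(intersect(pk$valid, pk$test), 0)
    expect_length(intersect(unlist(nk), all_pos), 0)
    expect_equal(anyDuplicated(unlist(nk)), 0)
    expect_equal(lengths(nk), lengths(pk))
  }
})

test_that("a complete bipartite target relation raises a capacity error", {
  sch <- toy_schema()
  g <- hetero_graph(sch,
    nodes = list(M = c("m1", "m2"), D = c("d1", "d2"), X = "x1"),
    edges = list("M-D" = cbind(rep(1:2, 2), rep(1:2, each = 2))))
  expect_error(make_splits(g, seed = 1, target = "M-D"), "capacity")
})

test_that("build_training_graph removes exactly the held-out target edges", {
  g <- make_bipartite_graph(100)
  sp <- make_splits(g, c(0.75, 0.10, 0.15), seed = 5, target = "M-D")
  tg <- build_training_graph(g, sp)
  expect_equal(n_edges(tg, "M-D"), 75)
  expect_identical(tg$edges[["M-D"]], sp$pos$train)
  expect_identical(tg$nodes, g$nodes)

  key <- function(m) paste(m[, 1], m[, 2])
  held <- c(key(sp$pos$valid), key(sp$pos$test))
  expect_length(intersect(held, key(tg$edges[["M-D"]])), 0)

  # no held-out edges at all: training graph equals the input (as sets)
  sp0 <- make_splits(g, c(1, 0, 0), seed = 1, target = "M-D")
  tg0 <- build_training_graph(g, sp0)
  expect_setequal(key(tg0$edges[["M-D"]]), key(g$edges[["M-D"]]))
  expect_identical(tg0$edges[names(tg0$edges) != "M-D"],
                   g$edges[names(g$edges) != "M-D"])
})

test_that("fixed_test resplitting keeps the test set fixed and pools disjoint", {
  g <- make_bipartite_graph(100)
  base <- make_splits(g, seed = 11, target = "M-D")
  key <- function(m) paste(m[, 1], m[, 2])
  for (s in 1:3) {
    sp <- make_splits(g, seed = s, target = "M-D", fixed_test = base)
    expect_identical(sp$pos$test, base$pos$test)
    expect_identical(sp$neg$test, base$neg$test)
    expect_setequal(c(key(sp$pos$train), key(sp$pos$valid), key(sp$pos$test)),
                    key(g$edges[["M-D"]]))
    expect_length(intersect(key(rbind(sp$neg$train, sp$neg$valid)),
                            key(base$neg$test)), 0)
  }
})

test_that("split TSV export has the documented shape", {
  g <- make_bipartite_graph(40)
  sp <- make_splits(g, seed = 2, target = "M-D")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, g, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("split", "label", "miRNA_id", "disease_id"))
  expect_setequal(unique(tab$split), c("train", "valid", "test"))
  expect_equal(nrow(tab), 2 * 40)
})
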