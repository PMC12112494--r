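table6_node_specific <- c(
  "miRNA-mRNA-miRNA", "miRNA-drug-miRNA", "miRNA-circRNA-miRNA",
  "miRNA-lncRNA-miRNA", "miRNA-protein-miRNA", "miRNA-disease-miRNA",
  "disease-mRNA-disease", "disease-drug-disease", "disease-circRNA-disease",
  "disease-lncRNA-disease", "disease-microbe-disease",
  "disease-miRNA-disease")

table6_common <- c(
  "miRNA-drug-disease", "miRNA-mRNA-disease", "miRNA-lncRNA-disease",
  "miRNA-circRNA-disease", "miRNA-disease-miRNA-disease",
  "miRNA-drug-mRNA-disease", "miRNA-drug-microbe-disease",
  "miRNA-mRNA-drug-disease", "miRNA-mRNA-lncRNA-disease",
  "miRNA-protein-drug-disease", "miRNA-protein-mRNA-disease",
  "miRNA-protein-lncRNA-disease", "miRNA-lncRNA-mRNA-disease")

test_that("the biological schema yields exactly the published 12 + 13 catalogue", {
  sch <- mda_schema()
  ns <- enumerate_node_specific_types(sch)
  cm <- enumerate_common_types(sch)
  expect_length(ns, 12)
  expect_length(cm, 13)
  expect_setequal(names(ns), table6_node_specific)
  expect_setequal(names(cm), table6_common)
})

test_that("toy-schema enumerations match the brute-force DFS oracle", {
  sch <- toy_schema()
  expect_setequal(names(enumerate_node_specific_types(sch, c("M", "D"))),
                  c("M-X-M", "M-D-M", "D-X-D", "D-M-D"))
  expect_setequal(names(enumerate_common_types(sch, source = "M",
                                               target = "D")),
                  c("M-X-D", "M-D-M-D"))
  sch2 <- toy_schema(with_md = FALSE)
  expect_setequal(names(enumerate_common_types(sch2, source = "M",
                                               target = "D")),
                  "M-X-D")
})

test_that("enumeration errors on bad input", {
  sch <- toy_schema()
  expect_error(enumerate_node_specific_types(sch, c("M", "Q")), "missing")
  expect_error(enumerate_common_types(sch, max_len = 1, source = "M",
                                      target = "D"), "max_len")
  lonely <- graph_schema(c("M", "D", "X", "Y"), list(c("X", "Y")))
  expect_length(enumerate_node_specific_types(lonely, c("M", "D")), 0)
})

test_that("enumeration agrees with the DFS oracle on random schemas", {
  nm <- function(x) sort(as.character(names(x)))
  for (seed in 1:20) {
    sch <- random_schema(seed, n_types = sample(4:10, 1))
    expect_identical(
      nm(enumerate_node_specific_types(sch, c("M", "D"))),
      oracle_node_specific(sch, c("M", "D")),
      info = paste("schema seed", seed))
    expect_identical(
      nm(enumerate_common_types(sch, source = "M", target = "D")),
      oracle_common(sch, "M", "D"),
      info = paste("schema seed", seed))
  }
})

test_that("materialize_instances traverses exhaustively and deterministically", {
  sch <- toy_schema()
  g <- hetero_graph(sch,
    nodes = list(M = c("m1", "m2"), X = "x1", D = character(0)),
    edges = list("M-X" = rbind(c(1, 1), c(2, 1))))
  mp <- metapath_type(c("M", "X", "M"), c("M-X", "M-X"), "node_specific")
  st <- materialize_instances(g, mp, c("m1"), cap = 10, seed = 1)
  off_x <- 2  # M nodes come first
  expect_equal(st[["m1"]], matrix(c(1, 2 + 1, 2), 1))

  # anchor with no incident first-relation edge
  g2 <- hetero_graph(sch, nodes = list(M = c("m1", "m2"), X = "x1"),
                     edges = list("M-X" = rbind(c(2, 1))))
  expect_null(materialize_instances(g2, mp, "m1", cap = 10, seed = 1)[["m1"]])

  # cap subsampling is deterministic
  g3 <- toy_graph()
  mpx <- metapath_type(c("M", "X", "M"), c("M-X", "M-X"), "node_specific")
  full <- materialize_instances(g3, mpx, "m1", cap = Inf, seed = 1)[["m1"]]
  expect_gt(nrow(full), 2)
  s1 <- materialize_instances(g3, mpx, "m1", cap = 2, seed = 7)[["m1"]]
  s2 <- materialize_instances(g3, mpx, "m1", cap = 2, seed = 7)[["m1"]]
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2)
  expect_true(all(apply(s1, 1, function(r)
    any(apply(full, 1, function(f) all(f == r))))))
})

test_that("materialized instances validate against type and training graph", {
  sg <- mini_bio(seed = 2)
  g <- sg$graph
  split <- make_splits(g, seed = 1)
  tg <- build_training_graph(g, split)
  adjacency_has <- function(graph, ta, tb, la, lb_) {
    lab <- NULL
    r <- graph$schema$relations
    i <- which((r$type_a == ta & r$type_b == tb) |
               (r$type_a == tb & r$type_b == ta))
    e <- graph$edges[[r$label[i]]]
    if (r$type_a[i] == ta) any(e[, 1] == la & e[, 2] == lb_)
    else any(e[, 2] == la & e[, 1] == lb_)
  }
  off <- c(0, cumsum(lengths(tg$nodes)))
  names(off) <- c(names(tg$nodes), "end")
  type_of <- function(gidx) {
    names(which(off[seq_along(tg$nodes)] < gidx &
                gidx <= off[-1]))[1]
  }
  cls <- enumerate_common_types(tg$schema)
  for (nm in c("miRNA-mRNA-disease", "miRNA-disease-miRNA-disease",
               "miRNA-protein-drug-disease")) {
    mp <- cls[[nm]]
    pairs <- split_pairs(split, "train")[1:12, 1:2]
    st <- materialize_instances(tg, mp, pairs, cap = Inf, seed = 1)
    for (key in names(st)) {
      m <- st[[key]]
      for (r in seq_len(nrow(m))) {
        p <- m[r, ]
        expect_equal(anyDuplicated(p), 0)
        for (k in seq_len(length(p) - 1)) {
          ta <- mp$types[k]; tb <- mp$types[k + 1]
          expect_identical(type_of(p[k]), ta)
          expect_true(adjacency_has(tg, ta, tb, p[k] - off[[ta]],
                                    p[k + 1] - off[[tb]]),
                      info = paste(nm, key, r))
        }
      }
    }
  }
})

test_that("pair_instances excludes the target edge and falls back to (u, v)", {
  sch <- toy_schema()
  # two X-mediated paths between m1 and d1
  g <- hetero_graph(sch,
    nodes = list(M = c("m1", "m2"), D = c("d1"), X = c("x1", "x2")),
    edges = list("M-X" = rbind(c(1, 1), c(1, 2)),
                 "X-D" = rbind(c(1, 1), c(2, 1)),
                 "M-D" = rbind(c(1, 1))))
  store <- build_instance_store(g, pairs = cbind(1, 1), cap = 32, seed = 1,
                                target = "M-D")
  mp <- store$pair_classes[["M-X-D"]]
  got <- pair_instances(store, "m1", "d1", mp)
  expect_equal(nrow(got), 2)

  # only alternating instance would be (u, v, u, v): excluded, fallback
  mp_alt <- store$pair_classes[["M-D-M-D"]]
  got_alt <- pair_instances(store, "m1", "d1", mp_alt)
  off_m <- 0; off_d <- 2
  expect_equal(got_alt, matrix(c(off_m + 1, off_d + 1), 1))

  # totally disconnected pair -> fallback
  got_disc <- pair_instances(store, "m2", "d1", mp)
  expect_equal(got_disc, matrix(c(off_m + 2, off_d + 1), 1))

  expect_error(pair_instances(store, "zzz", "d1", mp), "unknown")
  expect_error(pair_instances(store, "m1", "d1",
                              store$node_classes[[1]]), "common")
})

test_that("no served pair instance traverses the pair's own edge", {
  sg <- mini_bio(seed = 4)
  split <- make_splits(sg$graph, seed = 2)
  tg <- build_training_graph(sg$graph, split)
  pairs <- split_pairs(split, "train")[, 1:2]
  store <- build_instance_store(tg, pairs = pairs, cap = 32, seed = 1)
  off <- c(miRNA = 0, disease = 12)
  for (nm in names(store$pair_classes)) {
    mp <- store$pair_classes[[nm]]
    for (i in seq_len(min(nrow(pairs), 25))) {
      m <- pair_instances(store, pairs[i, 1], pairs[i, 2], mp)
      gu <- off[["miRNA"]] + pairs[i, 1]
      gv <- off[["disease"]] + pairs[i, 2]
      if (ncol(m) < 3) next   # degenerate (u, v) fallback, not an edge step
      for (r in seq_len(nrow(m))) {
        p <- m[r, ]
        steps <- cbind(p[-length(p)], p[-1])
        expect_false(any((steps[, 1] == gu & steps[, 2] == gv) |
                         (steps[, 1] == gv & steps[, 2] == gu)))
      }
    }
  }
})

test_that("adding an edge never decreases uncapped instance counts", {
  g <- toy_graph()
  mp <- metapath_type(c("M", "X", "M"), c("M-X", "M-X"), "node_specific")
  count_all <- function(graph) {
    st <- materialize_instances(graph, mp, c("m1", "m2", "m3"),
                                cap = Inf, seed = 1)
    sum(vapply(st, nrow, integer(1)))
  }
  n0 <- count_all(g)
  g2 <- g
  g2$edges[["M-X"]] <- rbind(g2$edges[["M-X"]], c(2, 2))
  expect_gte(count_all(g2), n0)
})

test_that("instance store persists as TSV and catalogue as JSON", {
  g <- toy_graph()
  store <- build_instance_store(g, pairs = cbind(c(1, 2), c(1, 2)),
                                cap = 8, seed = 1, target = "M-D")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_instance_store(store, tsv)
  lines <- readLines(tsv)
  expect_gt(length(lines), 0)
  expect_true(all(lengths(strsplit(lines, "\t")) >= 3))

  js <- withr::local_tempfile(fileext = ".json")
  write_metapath_catalogue(c(store$node_classes, store$pair_classes), js)
  cat_back <- jsonlite::read_json(js)
  expect_length(cat_back, length(store$node_classes) +
                  length(store$pair_classes))
  expect_setequal(vapply(cat_back, function(x) x$category, ""),
                  c("node_specific", "common"))
})
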