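#' Leakage-safe train/valid/test split of the target relation
#'
#' Partitions the positive miRNA-disease edges into train/valid/test by
#' floor-partitioned counts (remainder to train, so the test fraction never
#' exceeds its nominal share) and samples 1:1 negatives uniformly without
#' replacement from the non-edge miRNA x disease pairs, disjoint across
#' splits.  All randomness is governed by `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param graph a [hetero_graph()] containing the target relation.
#' @param ratios length-3 numeric summing to 1 (train, valid, test).
#' @param seed integer seed.
#' @param target relation label of the edge set being predicted.
#' @param fixed_test optionally, a previous `edge_split` whose test
#'   positives and negatives are reused verbatim while train/valid are
#'   re-drawn from the remainder (the multi-seed protocol keeps the test
#'   set fixed across seeds).
#' @return An object of class `edge_split`: lists `pos` and `neg` each with
#'   two-column integer matrices `train`/`valid`/`test` (miRNA index,
#'   disease index), plus `seed`, `ratios`, `target`.
#' @export
make_splits <- function(graph, ratios = c(0.75, 0.10, 0.15), seed = 1L,
                        target = "miRNA-disease", fixed_test = NULL) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  tys <- relation_types(graph$schema, target)
  pos <- graph$edges[[target]]
  n <- nrow(pos)
  if (n == 0) stop("target relation ", target, " is empty")
  nm <- n_nodes(graph, tys[1]); nd <- n_nodes(graph, tys[2])
  pos_lin <- (pos[, 2] - 1) * nm + pos[, 1]

  pair_key <- function(m) paste(m[, 1], m[, 2])
  if (is.null(fixed_test)) {
    n_valid <- floor(n * ratios[2])
    n_test <- floor(n * ratios[3])
    n_train <- n - n_valid - n_test
  } else {
    stopifnot(inherits(fixed_test, "edge_split"))
    n_test <- nrow(fixed_test$pos$test)
    n_valid <- floor(n * ratios[2])
    n_train <- n - n_valid - n_test
  }
  if (n_train <= 0) stop("training split is empty")

  non_edges <- setdiff(seq_len(nm * nd), pos_lin)

  res <- with_seed(seed, {
    if (is.null(fixed_test)) {
      perm <- sample.int(n)
      idx_train <- perm[seq_len(n_train)]
      idx_valid <- perm[n_train + seq_len(n_valid)]
      idx_test <- perm[n_train + n_valid + seq_len(n_test)]
      pos_test <- pos[idx_test, , drop = FALSE]
      neg_pool <- non_edges
      need <- n_train + n_valid + n_test
      if (length(neg_pool) < need)
        stop("capacity error: only ", length(neg_pool),
             " non-edges for ", need, " negatives")
      draw <- sample(neg_pool, need)
      neg_test <- draw[n_train + n_valid + seq_len(n_test)]
    } else {
      pos_test <- fixed_test$pos$test
      rest <- setdiff(seq_len(n), match(pair_key(pos_test), pair_key(pos)))
      if (length(rest) != n_train + n_valid)
        stop("fixed_test positives do not match this graph")
      perm <- sample(rest)
      idx_train <- perm[seq_len(n_train)]
      idx_valid <- perm[n_train + seq_len(n_valid)]
      fixed_neg <- (fixed_test$neg$test[, 2] - 1) * nm +
        fixed_test$neg$test[, 1]
      neg_pool <- setdiff(non_edges, fixed_neg)
      need <- n_train + n_valid
      if (length(neg_pool) < need)
        stop("capacity error: only ", length(neg_pool),
             " non-edges for ", need, " negatives")
      draw <- c(sample(neg_pool, need), fixed_neg)
      neg_test <- fixed_neg
    }
    list(idx_train = idx_train, idx_valid = idx_valid,
         pos_test = pos_test, draw = draw, neg_test = neg_test,
         n_train = n_train, n_valid = n_valid)
  })

  lin2mat <- function(lin) cbind(as.integer((lin - 1) %% nm + 1),
                                 as.integer((lin - 1) %/% nm + 1))
  neg_train <- lin2mat(res$draw[seq_len(res$n_train)])
  neg_valid <- lin2mat(res$draw[res$n_train + seq_len(res$n_valid)])
  neg_test <- lin2mat(res$neg_test)

  structure(list(
    pos = list(train = pos[res$idx_train, , drop = FALSE],
               valid = pos[res$idx_valid, , drop = FALSE],
               test = res$pos_test),
    neg = list(train = neg_train, valid = neg_valid, test = neg_test),
    seed = as.integer(seed), ratios = ratios, target = target
  ), class = "edge_split")
}

#' Remove held-out target edges from the graph
#'
#' Returns the graph used for message passing and metapath materialization:
#' identical to the input except that the target relation retains exactly
#' the training positives.  This is the anti-leakage step -- validation and
#' test edges never enter the training graph.
#'
#' @param graph a [hetero_graph()].
#' @param split an `edge_split` built from `graph`.
#' @return A [hetero_graph()] with the target relation restricted to
#'   `split$pos$train`.
#' @export
build_training_graph <- function(graph, split) {
  stopifnot(inherits(split, "edge_split"))
  graph$edges[[split$target]] <- split$pos$train
  validate_graph(graph)
  graph
}

#' Write a split as TSV
#'
#' Columns `split  label  miRNA_id  disease_id`, with split in
#' train/valid/test and label 1 for positives, 0 for sampled negatives.
#'
#' @param split an `edge_split`.
#' @param graph the [hetero_graph()] it was built from (for id lookup).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, graph, path) {
  tys <- relation_types(graph$schema, split$target)
  rows <- list()
  for (s in c("train", "valid", "test")) {
    for (lb in c(1L, 0L)) {
      m <- if (lb == 1L) split$pos[[s]] else split$neg[[s]]
      if (nrow(m) == 0) next
      rows[[paste(s, lb)]] <- data.frame(
        split = s, label = lb,
        miRNA_id = graph$nodes[[tys[1]]][m[, 1]],
        disease_id = graph$nodes[[tys[2]]][m[, 2]],
        stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Labelled pairs of one split part
#'
#' Stacks the positives and sampled negatives of one split part into a
#' three-column matrix (miRNA index, disease index, label).
#'
#' @param split an `edge_split`.
#' @param part `"train"`, `"valid"` or `"test"`.
#' @return Integer matrix with columns (miRNA, disease, label).
#' @export
split_pairs <- function(split, part) {
  rbind(
    cbind(split$pos[[part]], 1L),
    cbind(split$neg[[part]], 0L)
  )
}
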