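#' Metapath types
#'
#' A metapath type is an ordered sequence of node types joined by schema
#' relations.  Two categories are used: *node-specific* metapaths start and
#' end at the same anchor type (miRNA or disease) and capture
#' homogeneous-neighbor semantics; *common* metapaths bridge a miRNA to a
#' disease through intermediate entities and provide the structural
#' evidence for a candidate link.
#'
#' @param types character vector of node types (length 3 or 4).
#' @param relations character vector of relation labels (length
#'   `length(types) - 1`).
#' @param category `"node_specific"` or `"common"`.
#' @return An object of class `metapath_type` with a canonical `name`
#'   (types joined by `-`).
#' @export
metapath_type <- function(types, relations, category) {
  stopifnot(length(relations) == length(types) - 1,
            category %in% c("node_specific", "common"))
  structure(list(types = types, relations = relations,
                 category = category,
                 name = paste(types, collapse = "-")),
            class = "metapath_type")
}

#' @export
print.metapath_type <- function(x, ...) {
  cat(sprintf("metapath_type [%s] %s\n", x$category, x$name))
  invisible(x)
}

# Check a metapath type against a schema (consecutive pairs must be
# relations, labels must match).
validate_metapath_type <- function(mptype, schema) {
  for (k in seq_along(mptype$relations)) {
    lab <- schema_relation(schema, mptype$types[k], mptype$types[k + 1])
    if (is.na(lab) || lab != mptype$relations[k])
      stop("metapath ", mptype$name, " is not valid for this schema")
  }
  invisible(mptype)
}

#' Enumerate node-specific metapath types
#'
#' All length-2 type paths `A-X-A` with anchor `A` in `anchors` and `A-X` a
#' schema relation.  On the biological schema this yields the 12 classes
#' (six per anchor type) used by the node-specific encoding pipeline.
#'
#' @param schema a [graph_schema()].
#' @param anchors anchor node types; default miRNA and disease.
#' @return Named list of [metapath_type()] objects, sorted by name.
#' @export
enumerate_node_specific_types <- function(schema,
                                          anchors = c("miRNA", "disease")) {
  if (!all(anchors %in% schema$node_types))
    stop("anchor type missing from schema: ",
         paste(setdiff(anchors, schema$node_types), collapse = ", "))
  out <- list()
  for (a in anchors) {
    nb <- schema_neighbors(schema, a)
    for (i in seq_len(nrow(nb))) {
      mp <- metapath_type(c(a, nb$type[i], a),
                          c(nb$label[i], nb$label[i]),
                          "node_specific")
      out[[mp$name]] <- mp
    }
  }
  if (length(out) == 0) return(out)
  out[order(names(out))]
}

#' Enumerate common metapath types
#'
#' All `source -> ... -> target` type paths of length 2 or 3 whose
#' intermediate types exclude the source and target types, plus -- when the
#' direct source-target relation exists -- the alternating pattern
#' `source-target-source-target`, which encodes shared-association
#' structure akin to common neighbors on the bipartite target graph.
#' Generic paths with miRNA or disease as intermediates are deliberately
#' not emitted; the alternating pattern is the only class that revisits the
#' anchor types.
#'
#' @param schema a [graph_schema()].
#' @param max_len maximum path length in edges (>= 2; default 3).
#' @param source,target endpoint node types (miRNA, disease).
#' @return Named list of [metapath_type()] objects, sorted by length then
#'   name.
#' @export
enumerate_common_types <- function(schema, max_len = 3L,
                                   source = "miRNA", target = "disease") {
  if (max_len < 2) stop("max_len must be >= 2")
  if (!all(c(source, target) %in% schema$node_types))
    stop("source/target type missing from schema")
  mids <- setdiff(schema$node_types, c(source, target))
  out <- list()
  add <- function(types) {
    rels <- character(length(types) - 1)
    for (k in seq_along(rels)) {
      lab <- schema_relation(schema, types[k], types[k + 1])
      if (is.na(lab)) return(invisible(NULL))
      rels[k] <- lab
    }
    mp <- metapath_type(types, rels, "common")
    out[[mp$name]] <<- mp
  }
  for (x in mids) add(c(source, x, target))
  if (max_len >= 3) {
    for (x in mids) for (y in mids) if (x != y)
      add(c(source, x, y, target))
    if (!is.na(schema_relation(schema, source, target)))
      add(c(source, target, source, target))
  }
  if (length(out) == 0) return(out)
  lens <- vapply(out, function(m) length(m$types), integer(1))
  out[order(lens, names(out))]
}

# ---- instance materialization -------------------------------------------

# Neighbor lists for one directed metapath step, indexed by *global* source
# node index offset to local position: nbrs[[local_src]] -> global targets.
step_neighbors <- function(adj, schema, from_type, to_type, label) {
  a <- adj[[label]]
  if (a$type_a == from_type && a$type_b == to_type) a$fwd
  else if (a$type_b == from_type && a$type_a == to_type) a$rev
  else stop("relation ", label, " does not join ", from_type, " -> ", to_type)
}

#' Materialize metapath instances on the training graph
#'
#' Depth-first expansion over typed adjacency from the given anchors,
#' producing node-simple instances (no repeated node) of the given metapath
#' type.  For common types, instances are grouped per (miRNA, disease) pair
#' and any instance traversing the target pair's own edge is removed
#' (target-edge exclusion).  When more than `cap` instances survive for a
#' key, a uniform subsample without replacement is drawn under a seed
#' derived deterministically from `seed` and the key.
#'
#' Instances are integer matrices of global node indices, one row per
#' instance; keys are anchor node ids (node-specific) or `"u|v"` id pairs
#' (common).  Keys with zero surviving instances are absent here; the
#' degenerate fallbacks are supplied by [pair_instances()] /
#' [node_instances()].
#'
#' @param graph the *training* [hetero_graph()] (leakage guard upstream).
#' @param mptype a [metapath_type()].
#' @param anchors for node-specific types, character ids (or integer local
#'   indices) of anchor nodes; for common types, a two-column matrix of
#'   (miRNA, disease) ids or local indices.
#' @param cap maximum instances kept per key (default 32).
#' @param seed base seed for subsampling.
#' @return Named list of instance matrices.
#' @export
materialize_instances <- function(graph, mptype, anchors, cap = 32L,
                                  seed = 1L) {
  validate_metapath_type(mptype, graph$schema)
  off <- type_offsets(graph)
  adj <- build_adjacency(graph)
  t1 <- mptype$types[1]
  if (mptype$category == "common") {
    pairs <- anchors
    if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2)
    u_loc <- resolve_ids(graph, t1, pairs[, 1])
    tl <- mptype$types[length(mptype$types)]
    v_loc <- resolve_ids(graph, tl, pairs[, 2])
    starts <- unique(u_loc)
  } else {
    starts <- resolve_ids(graph, t1, anchors)
  }
  paths <- matrix(off[[t1]] + starts, ncol = 1)
  for (k in seq_along(mptype$relations)) {
    nbrs <- step_neighbors(adj, graph$schema, mptype$types[k],
                           mptype$types[k + 1], mptype$relations[k])
    last_local <- paths[, k] - off[[mptype$types[k]]]
    nb <- nbrs[last_local]
    cnt <- lengths(nb)
    rep_idx <- rep.int(seq_len(nrow(paths)), cnt)
    paths <- cbind(paths[rep_idx, , drop = FALSE], unlist(nb, use.names = FALSE))
    if (nrow(paths)) {
      keep <- rowSums(paths[, seq_len(k), drop = FALSE] ==
                        paths[, k + 1]) == 0
      paths <- paths[keep, , drop = FALSE]
    }
  }
  if (mptype$category == "common") {
    gu <- off[[t1]] + u_loc
    gv <- off[[mptype$types[length(mptype$types)]]] + v_loc
    want <- paste(gu, gv)
    grp <- paste(paths[, 1], paths[, ncol(paths)])
    by_pair <- split(seq_len(nrow(paths)), grp)
    out <- list()
    ids_u <- graph$nodes[[t1]]; ids_v <- graph$nodes[[mptype$types[length(mptype$types)]]]
    for (i in seq_along(want)) {
      m <- paths[by_pair[[want[i]]], , drop = FALSE]
      if (is.null(by_pair[[want[i]]])) m <- paths[0, , drop = FALSE]
      m <- drop_target_edge(m, gu[i], gv[i])
      key <- paste(ids_u[u_loc[i]], ids_v[v_loc[i]], sep = "|")
      if (nrow(m) == 0) next
      out[[key]] <- cap_instances(m, cap, seed, paste(mptype$name, key))
    }
    out
  } else {
    by_anchor <- split(seq_len(nrow(paths)), paths[, 1])
    out <- list()
    ids <- graph$nodes[[t1]]
    for (s in starts) {
      g <- off[[t1]] + s
      m <- paths[by_anchor[[as.character(g)]], , drop = FALSE]
      if (nrow(m) == 0) next
      key <- ids[s]
      out[[key]] <- cap_instances(m, cap, seed, paste(mptype$name, key))
    }
    out
  }
}

resolve_ids <- function(graph, type, x) {
  if (is.numeric(x)) return(as.integer(x))
  j <- match(as.character(x), graph$nodes[[type]])
  if (anyNA(j)) stop("unknown ", type, " id: ",
                     paste(x[is.na(j)], collapse = ", "))
  j
}

# Remove instances containing the consecutive step (u,v) or (v,u).
# Node-simple expansion already forbids these, but the guard is kept
# explicit: evidence for a pair must never include the pair's own edge.
drop_target_edge <- function(m, gu, gv) {
  if (nrow(m) == 0 || ncol(m) < 2) return(m)
  bad <- rep(FALSE, nrow(m))
  for (j in seq_len(ncol(m) - 1)) {
    bad <- bad | (m[, j] == gu & m[, j + 1] == gv) |
      (m[, j] == gv & m[, j + 1] == gu)
  }
  m[!bad, , drop = FALSE]
}

cap_instances <- function(m, cap, seed, key) {
  if (is.infinite(cap) || nrow(m) <= cap) return(m)
  pick <- with_seed(derive_seed(seed, key),
                    sort(sample.int(nrow(m), cap)))
  m[pick, , drop = FALSE]
}

# ---- instance stores -----------------------------------------------------

#' Build the instance store for the secondary encoder
#'
#' Materializes, on the training graph, (a) node-specific instances for all
#' miRNA and disease anchors over every node-specific class and (b) common
#' instances for the supplied candidate pairs over every common class.
#' Deterministic given `(graph, cap, seed)`.
#'
#' @param graph the training [hetero_graph()].
#' @param pairs two-column matrix of (miRNA, disease) local indices (e.g.
#'   rows of [split_pairs()]); may be `NULL` to skip the pair store.
#' @param cap per-key instance cap (default 32).
#' @param seed base seed for instance subsampling.
#' @param target label of the relation being predicted; its two endpoint
#'   types are the metapath anchor types.
#' @return An object of class `instance_store` with elements
#'   `node_classes`, `pair_classes` (metapath type lists), `node`, `pair`
#'   (per-class keyed instance lists), `cap`, `seed`.
#' @export
build_instance_store <- function(graph, pairs = NULL, cap = 32L, seed = 1L,
                                 target = "miRNA-disease") {
  tys <- relation_types(graph$schema, target)
  node_classes <- enumerate_node_specific_types(graph$schema, tys)
  pair_classes <- enumerate_common_types(graph$schema,
                                         source = tys[1], target = tys[2])
  node <- list()
  for (nm in names(node_classes)) {
    mp <- node_classes[[nm]]
    anchors <- seq_len(n_nodes(graph, mp$types[1]))
    node[[nm]] <- materialize_instances(graph, mp, anchors, cap, seed)
  }
  pair <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- unique(pairs[, 1:2, drop = FALSE])
    for (nm in names(pair_classes)) {
      pair[[nm]] <- materialize_instances(graph, pair_classes[[nm]],
                                          pairs, cap, seed)
    }
  }
  structure(list(node_classes = node_classes, pair_classes = pair_classes,
                 node = node, pair = pair, cap = cap, seed = as.integer(seed),
                 offsets = type_offsets(graph),
                 ids = graph$nodes, target = target, anchor_types = tys),
            class = "instance_store")
}

#' Materialize common instances for pairs not yet in a store
#'
#' Extends the pair store of `store` (built on the training graph) with
#' the given pairs, materializing only those not already covered.  Used to
#' score held-out pairs: the instances still come exclusively from the
#' training graph.
#'
#' @param store an [build_instance_store()] result.
#' @param graph the training [hetero_graph()] the store was built on.
#' @param pairs two-column matrix of (miRNA, disease) local indices.
#' @return The extended `instance_store`.
#' @export
extend_pair_store <- function(store, graph, pairs) {
  pairs <- unique(as.matrix(pairs[, 1:2, drop = FALSE]))
  tys <- store$anchor_types
  keys <- paste(store$ids[[tys[1]]][pairs[, 1]],
                store$ids[[tys[2]]][pairs[, 2]], sep = "|")
  first_cls <- names(store$pair_classes)[1]
  seen <- if (length(store$pair)) {
    Reduce(union, lapply(store$pair, names), character(0))
  } else character(0)
  todo <- !(keys %in% seen)
  if (!any(todo)) return(store)
  new_pairs <- pairs[todo, , drop = FALSE]
  for (nm in names(store$pair_classes)) {
    add <- materialize_instances(graph, store$pair_classes[[nm]],
                                 new_pairs, store$cap, store$seed)
    store$pair[[nm]] <- c(store$pair[[nm]] %||% list(), add)
  }
  store
}

#' Serve common-metapath instances for a candidate pair
#'
#' Returns the stored, target-edge-excluded instances of `mptype` starting
#' at miRNA `u` and ending at disease `v`.  If none survive (or the pair
#' has no connectivity at all under this class), the single degenerate
#' fallback instance `(u, v)` is returned, so every class always
#' contributes a vector and the inter-class attention operates over a
#' constant number of classes.
#'
#' @param store an [build_instance_store()] result whose pair store covers
#'   `(u, v)`.
#' @param u miRNA node id (character) or local index.
#' @param v disease node id (character) or local index.
#' @param mptype a common [metapath_type()].
#' @return Integer matrix of global node indices, one instance per row.
#' @export
pair_instances <- function(store, u, v, mptype) {
  if (mptype$category != "common") stop("mptype must be a common metapath")
  tu <- mptype$types[1]; tv <- mptype$types[length(mptype$types)]
  u_loc <- if (is.numeric(u)) as.integer(u) else match(as.character(u), store$ids[[tu]])
  v_loc <- if (is.numeric(v)) as.integer(v) else match(as.character(v), store$ids[[tv]])
  if (is.na(u_loc) || u_loc < 1 || u_loc > length(store$ids[[tu]]))
    stop("unknown or wrongly typed node u")
  if (is.na(v_loc) || v_loc < 1 || v_loc > length(store$ids[[tv]]))
    stop("unknown or wrongly typed node v")
  key <- paste(store$ids[[tu]][u_loc], store$ids[[tv]][v_loc], sep = "|")
  m <- store$pair[[mptype$name]][[key]]
  if (is.null(m) || nrow(m) == 0) {
    m <- matrix(c(store$offsets[[tu]] + u_loc, store$offsets[[tv]] + v_loc),
                nrow = 1)
  }
  m
}

#' Serve node-specific instances for an anchor node
#'
#' Like [pair_instances()] but for node-specific classes; the fallback for
#' an anchor with no instances is the degenerate single-node instance
#' `(v)`.
#'
#' @param store an [build_instance_store()] result.
#' @param v anchor node id (character) or local index.
#' @param mptype a node-specific [metapath_type()].
#' @return Integer matrix of global node indices, one instance per row.
#' @export
node_instances <- function(store, v, mptype) {
  if (mptype$category != "node_specific")
    stop("mptype must be a node-specific metapath")
  t1 <- mptype$types[1]
  v_loc <- if (is.numeric(v)) as.integer(v) else match(as.character(v), store$ids[[t1]])
  if (is.na(v_loc)) stop("unknown or wrongly typed anchor node")
  key <- store$ids[[t1]][v_loc]
  m <- store$node[[mptype$name]][[key]]
  if (is.null(m) || nrow(m) == 0)
    m <- matrix(store$offsets[[t1]] + v_loc, nrow = 1)
  m
}

#' Write the metapath catalogue as JSON
#'
#' @param types named list of [metapath_type()] (e.g. the concatenation of
#'   both enumerations).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metapath_catalogue <- function(types, path) {
  cat_list <- lapply(types, function(m)
    list(name = m$name, types = m$types, relations = m$relations,
         category = m$category))
  jsonlite::write_json(unname(cat_list), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write an instance store as TSV
#'
#' One row per instance: `anchor  metapath_name  node_id_1 ... node_id_k`
#' (pair anchors as `u|v`).  Node ids are resolved from global indices.
#'
#' @param store an [build_instance_store()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instance_store <- function(store, path) {
  all_ids <- unlist(store$ids, use.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  dump <- function(classes, inst) {
    for (nm in names(inst)) {
      for (key in names(inst[[nm]])) {
        m <- inst[[nm]][[key]]
        for (r in seq_len(nrow(m))) {
          writeLines(paste(c(key, nm, all_ids[m[r, ]]), collapse = "\t"),
                     con)
        }
      }
    }
  }
  dump(store$node_classes, store$node)
  dump(store$pair_classes, store$pair)
  invisible(path)
}
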