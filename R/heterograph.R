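#' Construct a typed heterogeneous graph
#'
#' Container for a heterogeneous network: per-type node-id vectors, optional
#' per-type feature matrices, and per-relation undirected edge lists stored
#' as local (per-type) integer index pairs.  Node ids are opaque strings;
#' contiguous per-type indices are assigned in registration order.
#'
#' @param schema a [graph_schema()].
#' @param nodes named list (one entry per node type present) of character
#'   id vectors.  Types absent from the list get zero nodes.
#' @param edges named list (by relation label) of two-column integer
#'   matrices; column 1 indexes `nodes[[type_a]]`, column 2
#'   `nodes[[type_b]]`.  Relations absent from the list get zero edges.
#' @param features optional named list of numeric matrices, one row per
#'   node of that type.
#' @return An object of class `hetero_graph`.
#' @export
hetero_graph <- function(schema, nodes = list(), edges = list(),
                         features = NULL) {
  stopifnot(inherits(schema, "graph_schema"))
  full_nodes <- setNames(vector("list", length(schema$node_types)),
                         schema$node_types)
  for (t in schema$node_types) {
    ids <- as.character(nodes[[t]] %||% character(0))
    if (anyDuplicated(ids)) stop("duplicate node ids for type ", t)
    full_nodes[[t]] <- ids
  }
  full_edges <- setNames(vector("list", nrow(schema$relations)),
                         schema$relations$label)
  for (lab in schema$relations$label) {
    e <- edges[[lab]]
    if (is.null(e)) e <- matrix(integer(0), ncol = 2)
    e <- matrix(as.integer(e), ncol = 2)
    full_edges[[lab]] <- e
  }
  g <- structure(list(schema = schema, nodes = full_nodes,
                      edges = full_edges, features = features),
                 class = "hetero_graph")
  validate_graph(g)
  g
}

# Enforce the container invariants: endpoints exist and match the
# relation's types, no self-loops, no duplicate undirected edges.
validate_graph <- function(graph) {
  sch <- graph$schema
  for (i in seq_len(nrow(sch$relations))) {
    lab <- sch$relations$label[i]
    ta <- sch$relations$type_a[i]; tb <- sch$relations$type_b[i]
    e <- graph$edges[[lab]]
    if (nrow(e) == 0) next
    na <- length(graph$nodes[[ta]]); nb <- length(graph$nodes[[tb]])
    if (any(e[, 1] < 1 | e[, 1] > na) || any(e[, 2] < 1 | e[, 2] > nb))
      stop("edge endpoint out of range for relation ", lab)
    if (ta == tb && any(e[, 1] == e[, 2]))
      stop("self-loop in relation ", lab)
    key <- if (ta == tb) {
      paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    } else paste(e[, 1], e[, 2])
    if (anyDuplicated(key)) stop("duplicate undirected edge in ", lab)
  }
  if (!is.null(graph$features)) {
    for (t in names(graph$features)) {
      if (nrow(graph$features[[t]]) != length(graph$nodes[[t]]))
        stop("feature matrix rows do not match node count for type ", t)
    }
  }
  invisible(graph)
}

#' Node and edge counts
#'
#' @param graph a [hetero_graph()].
#' @param type optional node type; `NULL` counts all nodes.
#' @param relation optional relation label; `NULL` counts all edges.
#' @return Integer count.
#' @export
n_nodes <- function(graph, type = NULL) {
  if (is.null(type)) sum(lengths(graph$nodes))
  else length(graph$nodes[[type]])
}

#' @rdname n_nodes
#' @export
n_edges <- function(graph, relation = NULL) {
  if (is.null(relation)) sum(vapply(graph$edges, nrow, integer(1)))
  else nrow(graph$edges[[relation]])
}

# Per-type offsets mapping (type, local index) -> global node index.
type_offsets <- function(graph) {
  sizes <- lengths(graph$nodes)
  setNames(cumsum(c(0, sizes[-length(sizes)])), names(sizes))
}

global_index <- function(graph, type, local_idx) {
  type_offsets(graph)[[type]] + local_idx
}

relation_types <- function(schema, label) {
  i <- match(label, schema$relations$label)
  if (is.na(i)) stop("unknown relation ", label)
  c(schema$relations$type_a[i], schema$relations$type_b[i])
}

# Directed adjacency lists over *global* node indices: for every relation
# label, `fwd` maps type_a nodes to type_b neighbors and `rev` the reverse.
build_adjacency <- function(graph) {
  off <- type_offsets(graph)
  out <- list()
  for (i in seq_len(nrow(graph$schema$relations))) {
    lab <- graph$schema$relations$label[i]
    ta <- graph$schema$relations$type_a[i]
    tb <- graph$schema$relations$type_b[i]
    e <- graph$edges[[lab]]
    ga <- off[[ta]] + e[, 1]
    gb <- off[[tb]] + e[, 2]
    fwd <- split(gb, factor(ga, levels = off[[ta]] + seq_len(n_nodes(graph, ta))))
    rev <- split(ga, factor(gb, levels = off[[tb]] + seq_len(n_nodes(graph, tb))))
    out[[lab]] <- list(fwd = fwd, rev = rev, type_a = ta, type_b = tb)
  }
  out
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("hetero_graph:", n_nodes(x), "nodes,", n_edges(x),
      "undirected edges\n")
  for (t in x$schema$node_types)
    cat(sprintf("  %-8s %5d nodes\n", t, n_nodes(x, t)))
  invisible(x)
}

#' Load typed edge lists into a heterogeneous graph
#'
#' Reads one or more tab-separated edge files with columns
#' `src_type  src_id  relation  dst_type  dst_id` (UTF-8, no header; lines
#' starting `#` are comments).  Node ids are registered on first sight;
#' duplicate rows (after undirected canonicalization) are collapsed with a
#' warning stating the count.
#'
#' @param edge_files character vector of TSV paths.
#' @param schema a [graph_schema()]; every row's types and relation must
#'   appear in it.
#' @return A [hetero_graph()].
#' @export
load_edges <- function(edge_files, schema) {
  rows <- list()
  for (f in edge_files) {
    tab <- tryCatch(
      read.table(f, sep = "\t", header = FALSE, comment.char = "#",
                 colClasses = "character", quote = "",
                 col.names = c("src_type", "src_id", "relation",
                               "dst_type", "dst_id")),
      error = function(e) {
        if (grepl("no lines available", conditionMessage(e))) return(NULL)
        stop("parse error in ", f, ": ", conditionMessage(e))
      })
    if (!is.null(tab)) {
      bad <- which(is.na(tab$dst_id) | tab$dst_id == "")
      if (length(bad))
        stop("malformed row at line ", bad[1], " of ", f)
      rows[[f]] <- tab
    }
  }
  nodes <- setNames(lapply(schema$node_types, function(t) character(0)),
                    schema$node_types)
  edges <- list()
  n_dup <- 0L
  register <- function(type, id) {
    j <- match(id, nodes[[type]])
    if (is.na(j)) {
      nodes[[type]] <<- c(nodes[[type]], id)
      j <- length(nodes[[type]])
    }
    j
  }
  for (f in names(rows)) {
    tab <- rows[[f]]
    for (k in seq_len(nrow(tab))) {
      rel <- tab$relation[k]
      i <- match(rel, schema$relations$label)
      if (is.na(i))
        stop("schema violation: unknown relation '", rel, "' at line ",
             k, " of ", f)
      ta <- schema$relations$type_a[i]; tb <- schema$relations$type_b[i]
      st <- tab$src_type[k]; dt <- tab$dst_type[k]
      if (st == ta && dt == tb) {
        a_id <- tab$src_id[k]; b_id <- tab$dst_id[k]
      } else if (st == tb && dt == ta) {
        a_id <- tab$dst_id[k]; b_id <- tab$src_id[k]
      } else {
        stop("schema violation: relation '", rel, "' does not join types ",
             st, " and ", dt, " at line ", k, " of ", f)
      }
      ia <- register(ta, a_id); ib <- register(tb, b_id)
      if (ta == tb && ia == ib)
        stop("self-loop at line ", k, " of ", f)
      if (ta == tb && ia > ib) { tmp <- ia; ia <- ib; ib <- tmp }
      key <- paste(ia, ib)
      if (is.null(edges[[rel]])) edges[[rel]] <- list(a = integer(0),
                                                      b = integer(0),
                                                      keys = character(0))
      if (key %in% edges[[rel]]$keys) {
        n_dup <- n_dup + 1L
      } else {
        edges[[rel]]$a <- c(edges[[rel]]$a, ia)
        edges[[rel]]$b <- c(edges[[rel]]$b, ib)
        edges[[rel]]$keys <- c(edges[[rel]]$keys, key)
      }
    }
  }
  if (n_dup > 0)
    warning(n_dup, " duplicate edge row(s) collapsed", call. = FALSE)
  edge_mats <- lapply(edges, function(e) cbind(e$a, e$b))
  hetero_graph(schema, nodes = nodes, edges = edge_mats)
}

#' Write a heterogeneous graph as a typed edge TSV
#'
#' Inverse of [load_edges()]: emits `src_type  src_id  relation  dst_type
#' dst_id` rows, one per undirected edge, in canonical relation order.
#'
#' @param graph a [hetero_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(graph, path) {
  sch <- graph$schema
  out <- list()
  for (i in seq_len(nrow(sch$relations))) {
    lab <- sch$relations$label[i]
    ta <- sch$relations$type_a[i]; tb <- sch$relations$type_b[i]
    e <- graph$edges[[lab]]
    if (nrow(e) == 0) next
    out[[lab]] <- data.frame(
      src_type = ta, src_id = graph$nodes[[ta]][e[, 1]],
      relation = lab,
      dst_type = tb, dst_id = graph$nodes[[tb]][e[, 2]],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  if (is.null(tab)) tab <- data.frame()
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
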