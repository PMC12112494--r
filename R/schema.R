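#' Construct a typed-graph schema
#'
#' A schema is the type-level description of a heterogeneous network: a set
#' of node types plus a set of undirected relation types, each relation an
#' unordered pair of node types with a unique label.  Metapath types are
#' enumerated on this object, and every [hetero_graph()] validates its edges
#' against it.
#'
#' @param node_types character vector of distinct node-type names.
#' @param relations list of length-2 character vectors (the two endpoint
#'   types of each undirected relation), or a two-column character matrix /
#'   data.frame.
#' @param labels optional character vector of relation labels; defaults to
#'   `"<type_a>-<type_b>"` in the order given.
#' @return An object of class `graph_schema` with elements `node_types` and
#'   `relations` (data.frame with columns `label`, `type_a`, `type_b`).
#' @examples
#' sch <- graph_schema(c("M", "D", "X"),
#'                     list(c("M", "X"), c("X", "D"), c("M", "D")))
#' @export
graph_schema <- function(node_types, relations, labels = NULL) {
  node_types <- as.character(node_types)
  if (anyDuplicated(node_types)) stop("duplicate node types")
  if (is.matrix(relations) || is.data.frame(relations)) {
    relations <- lapply(seq_len(nrow(relations)),
                       function(i) as.character(unlist(relations[i, 1:2])))
  }
  ta <- vapply(relations, `[`, character(1), 1)
  tb <- vapply(relations, `[`, character(1), 2)
  if (!all(c(ta, tb) %in% node_types))
    stop("relation endpoint type not in node_types")
  if (is.null(labels)) labels <- paste(ta, tb, sep = "-")
  if (anyDuplicated(labels)) stop("relation labels must be unique")
  key <- paste(pmin(ta, tb), pmax(ta, tb))
  if (anyDuplicated(key)) stop("duplicate relation (unordered type pair)")
  structure(list(
    node_types = node_types,
    relations = data.frame(label = labels, type_a = ta, type_b = tb,
                           stringsAsFactors = FALSE)
  ), class = "graph_schema")
}

#' The biological miRNA-disease network schema
#'
#' The 8-node-type, 17-relation schema of the biological heterogeneous
#' network used for miRNA-disease association prediction: miRNA, disease,
#' mRNA, lncRNA, circRNA, protein, drug and microbe nodes, with the standard
#' database-derived association types (miRNA-mRNA, lncRNA-protein,
#' drug-microbe, ...) plus the target miRNA-disease relation.
#'
#' @return A [graph_schema()] with 8 node types and 17 undirected relations.
#' @export
mda_schema <- function() {
  graph_schema(
    node_types = c("miRNA", "disease", "mRNA", "lncRNA", "circRNA",
                   "protein", "drug", "microbe"),
    relations = list(
      c("miRNA", "disease"),
      c("miRNA", "mRNA"),
      c("miRNA", "drug"),
      c("miRNA", "circRNA"),
      c("miRNA", "lncRNA"),
      c("miRNA", "protein"),
      c("disease", "mRNA"),
      c("disease", "drug"),
      c("disease", "circRNA"),
      c("disease", "lncRNA"),
      c("disease", "microbe"),
      c("drug", "microbe"),
      c("drug", "mRNA"),
      c("drug", "protein"),
      c("lncRNA", "mRNA"),
      c("lncRNA", "protein"),
      c("mRNA", "protein")
    )
  )
}

# Look up the relation label joining two types (order-free); NA if absent.
schema_relation <- function(schema, type_a, type_b) {
  r <- schema$relations
  hit <- (r$type_a == type_a & r$type_b == type_b) |
         (r$type_a == type_b & r$type_b == type_a)
  if (!any(hit)) return(NA_character_)
  r$label[which(hit)[1]]
}

# All types adjacent to `type` in the schema, with the joining relation.
schema_neighbors <- function(schema, type) {
  r <- schema$relations
  out <- character(0); lab <- character(0)
  sel_a <- r$type_a == type
  sel_b <- r$type_b == type
  out <- c(r$type_b[sel_a], r$type_a[sel_b])
  lab <- c(r$label[sel_a], r$label[sel_b])
  data.frame(type = out, label = lab, stringsAsFactors = FALSE)
}

#' @export
print.graph_schema <- function(x, ...) {
  cat("graph_schema:", length(x$node_types), "node types,",
      nrow(x$relations), "undirected relations\n")
  cat("  types:", paste(x$node_types, collapse = ", "), "\n")
  invisible(x)
}
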