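#' Construct a GO DAG from terms and is_a edges
#'
#' The ontology container used by the consistency module: a rooted, acyclic
#' is_a hierarchy. Obsolete terms are kept (so annotation files referring to
#' them can be diagnosed) but excluded from all transitive closures.
#'
#' @param terms `data.frame` with columns `id`, `name`, `obsolete` (logical).
#' @param edges `data.frame` with columns `child`, `parent` (is_a links,
#'   child and parent both non-obsolete term ids).
#'
#' @return A `go_dag` object: list with `terms`, `edges`, `root_id` and an
#'   internal igraph (edges point child -> parent).
#' @export
#' @examples
#' dag <- go_dag(
#'   data.frame(id = c("GO:R", "GO:A"), name = c("root", "a"), obsolete = FALSE),
#'   data.frame(child = "GO:A", parent = "GO:R")
#' )
#' dag$root_id
go_dag <- function(terms, edges) {
  terms$obsolete <- as.logical(terms$obsolete)
  if (anyDuplicated(terms$id)) {
    rc_validation_error("duplicate term ids in ontology")
  }
  live <- terms$id[!terms$obsolete]
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
    if (length(missing)) {
      rc_validation_error(paste0(
        "edge endpoint(s) not among terms: ", paste(missing, collapse = ", ")
      ))
    }
    if (any(edges$child == edges$parent)) {
      rc_validation_error("a term cannot be its own is_a parent")
    }
    obs <- setdiff(unique(c(edges$child, edges$parent)), live)
    if (length(obs)) {
      rc_validation_error(paste0(
        "is_a edge(s) touch obsolete term(s): ", paste(obs, collapse = ", ")
      ))
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = live)
  )
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    rc_validation_error(paste0(
      "ontology contains a cycle (e.g. through edge ",
      paste(attr(cyc, "vnames") %||% "?", collapse = ", "), ")"
    ))
  }
  outdeg <- igraph::degree(g, mode = "out")
  roots <- names(outdeg)[outdeg == 0]
  if (length(roots) != 1L) {
    rc_validation_error(paste0(
      "ontology must have exactly one root, found ", length(roots),
      if (length(roots)) paste0(": ", paste(roots, collapse = ", ")) else ""
    ))
  }
  structure(
    list(terms = terms, edges = edges, root_id = roots, graph = g),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat(
    "go_dag:", nrow(x$terms), "terms (", sum(x$terms$obsolete), "obsolete ),",
    nrow(x$edges), "is_a edges, root", x$root_id, "\n"
  )
  invisible(x)
}

#' Read a Gene Ontology DAG from an OBO 1.2 file
#'
#' Only `[Term]` stanzas in the requested namespace are kept; only `is_a`
#' lines become edges (part_of and other relationships are ignored, as the
#' specificity metric is defined on a single hierarchy). Edges to or from
#' terms outside the namespace, and edges touching obsolete terms, are
#' dropped. Obsolete terms stay in the term table, flagged, and never enter
#' closures. The root is detected as the single term without parents.
#'
#' @param path Path to an OBO file.
#' @param namespace_filter Namespace to retain (default
#'   `"molecular_function"`).
#' @return A [go_dag].
#' @export
read_obo <- function(path, namespace_filter = "molecular_function") {
  if (!file.exists(path)) rc_format_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_rows <- list()
  edge_rows <- list()
  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k]
    to <- if (k < length(stanza_starts)) stanza_starts[k + 1] - 1L else length(lines)
    if (!identical(lines[from], "[Term]")) next
    body <- lines[(from + 1L):to]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), body, value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) rc_format_error(paste0("[Term] stanza without id at line ", from))
    ns <- get1("namespace")
    if (!is.na(ns) && !identical(ns, namespace_filter)) next
    obsolete <- identical(get1("is_obsolete"), "true")
    isa <- grep("^is_a: ", body, value = TRUE)
    parents <- sub("\\s*!.*$", "", sub("^is_a: ", "", isa))
    term_rows[[length(term_rows) + 1L]] <- data.frame(
      id = id, name = get1("name") %||% "", obsolete = obsolete,
      stringsAsFactors = FALSE
    )
    if (!obsolete && length(parents)) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        child = id, parent = parents, stringsAsFactors = FALSE
      )
    }
  }
  terms <- if (length(term_rows)) do.call(rbind, term_rows) else {
    data.frame(id = character(), name = character(), obsolete = logical())
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else {
    data.frame(child = character(), parent = character())
  }
  # cross-namespace and obsolete-target parents fall outside the term table
  live <- terms$id[!terms$obsolete]
  edges <- edges[edges$parent %in% live & edges$child %in% live, , drop = FALSE]
  go_dag(terms, edges)
}

#' Write a GO DAG as OBO 1.2 text
#'
#' Emits the minimal stanza set ([read_obo()] round-trips it): id, name,
#' namespace, is_a lines and an is_obsolete flag where set.
#'
#' @param dag A [go_dag].
#' @param path Output path.
#' @param namespace Namespace written on every stanza.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path, namespace = "molecular_function") {
  out <- c("format-version: 1.2", "")
  ord <- order(dag$terms$id)
  for (i in ord) {
    id <- dag$terms$id[i]
    stanza <- c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", dag$terms$name[i]),
      paste0("namespace: ", namespace)
    )
    parents <- sort(dag$edges$parent[dag$edges$child == id])
    stanza <- c(stanza, if (length(parents)) paste0("is_a: ", parents))
    if (dag$terms$obsolete[i]) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' Read protein-to-GO annotations
#'
#' Accepts any tab-separated file whose first two columns are a protein id
#' and a GO term id; extra columns (evidence codes, qualifiers, GAF-like
#' payload) are ignored — evidence codes never filter rows. Terms missing
#' from the ontology or obsolete are dropped, with a single count reported
#' via the `dropped` attribute and a message.
#'
#' @param path Tab-separated annotation file.
#' @param dag The companion [go_dag].
#' @return An `annotation_set`: named list protein id -> character vector of
#'   direct term ids (set semantics), with attribute `dropped` (rows removed
#'   because their term was unknown or obsolete).
#' @export
read_annotations <- function(path, dag) {
  if (!file.exists(path)) rc_format_error(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) {
    return(structure(list(), class = "annotation_set", dropped = 0L, skipped = 0L))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L || !nzchar(p[1]) || !nzchar(p[2]), logical(1))
  if (any(bad)) {
    warning(sum(bad), " unreadable annotation row(s) skipped in ", path,
      call. = FALSE
    )
  }
  parts <- parts[!bad]
  pid <- vapply(parts, `[[`, character(1), 1L)
  go <- vapply(parts, `[[`, character(1), 2L)
  live <- dag$terms$id[!dag$terms$obsolete]
  keep <- go %in% live
  dropped <- sum(!keep)
  if (dropped) {
    message(dropped, " annotation row(s) dropped (unknown or obsolete term) in ", path)
  }
  ann <- lapply(split(go[keep], pid[keep]), function(x) sort(unique(x)))
  structure(ann, class = "annotation_set", dropped = dropped, skipped = sum(bad))
}
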