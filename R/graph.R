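# The accession graph: every typed reference link between SRA metadata
# objects becomes a directed edge, and any accession is resolved to its
# study/-ies by walking the link topology (run -> experiment -> study,
# sample <- experiment -> study, analysis -> study, submission -> owned).

#' Build the accession graph from parsed metadata objects
#'
#' Assembles the ID-mapping structure: one node per metadata object, one
#' directed typed edge per reference link. Links whose target object is
#' absent from the input are kept and additionally listed in `dangling` —
#' they are data (incomplete submissions are common), not errors. Duplicate
#' accessions are resolved last-wins with a warning, so incremental dumps
#' merge deterministically.
#'
#' @param objects A tibble of metadata objects from [parse_sra_xml()],
#'   [read_sra_dir()] or [sra_object()], all kinds combined.
#' @return An `accession_graph` object: a list with `nodes` (the object
#'   tibble), `edges` (`from`, `to`, `kind` of the target), and `dangling`
#'   (`from`, `to` pairs whose target is absent).
#' @export
build_accession_graph <- function(objects) {
  objects <- if (is.null(objects) || nrow(objects) == 0) .empty_objects()
             else as_tibble(objects)
  dup <- duplicated(objects$accession, fromLast = TRUE)
  if (any(dup)) {
    warn(paste0(
      "duplicate accessions, keeping last occurrence: ",
      paste(unique(objects$accession[dup]), collapse = ", ")
    ))
    objects <- objects[!dup, ]
  }
  per_row <- map2(objects$accession, objects$references, function(a, r) {
    if (is.null(r) || nrow(r) == 0) NULL
    else tibble(from = a, to = r$accession, kind = r$kind)
  })
  edges <- bind_rows(compact(per_row))
  if (nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(), kind = character())
  }
  edges <- edges |>
    filter(.data$from != .data$to) |>
    distinct()
  dangling <- edges |>
    filter(!.data$to %in% objects$accession) |>
    select("from", "to")
  g <- structure(
    list(nodes = objects, edges = edges, dangling = dangling),
    class = "accession_graph"
  )
  g$resolution <- .resolution_igraph(g)
  g
}

# Directed igraph over existing nodes whose edges are the legal resolution
# steps; reachable study nodes from x are exactly resolve_to_study(x).
.resolution_igraph <- function(graph) {
  nodes <- graph$nodes
  kind_of <- stats::setNames(nodes$kind, nodes$accession)
  e <- graph$edges |>
    filter(.data$to %in% nodes$accession)
  from_kind <- unname(kind_of[e$from])
  step <- tibble(from = e$from, to = e$to, from_kind = from_kind, to_kind = e$kind)
  forward <- step |>
    filter(
      (.data$from_kind == "run" & .data$to_kind == "experiment") |
      (.data$from_kind == "experiment" & .data$to_kind == "study") |
      (.data$from_kind == "analysis" & .data$to_kind == "study") |
      (.data$from_kind == "submission")
    ) |>
    select("from", "to")
  exp_sample <- step |>
    filter(.data$from_kind == "experiment" & .data$to_kind == "sample")
  backward <- tibble(from = exp_sample$to, to = exp_sample$from)
  edges <- bind_rows(forward, backward)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = tibble(name = nodes$accession))
}

#' Resolve an accession to its study accession(s)
#'
#' Follows the reference-link topology to the study ("project") level: a run
#' resolves through its experiment, a sample through the experiments that
#' sequenced it, an analysis or experiment directly, a submission through
#' everything it owns. A study accession resolves to itself. Because
#' relationships are one-to-many, the result is a set and may hold several
#' studies.
#'
#' @param graph An `accession_graph`.
#' @param accession A single accession string of any SRA kind.
#' @return Character vector of study accessions, sorted; empty when the
#'   accession is syntactically valid but unknown to the graph (the
#'   situation the publication-list false-positive filter exploits).
#'   A syntactically invalid accession is an error, deliberately distinct
#'   from the empty result.
#' @export
resolve_to_study <- function(graph, accession) {
  stopifnot(inherits(graph, "accession_graph"),
            is.character(accession), length(accession) == 1)
  acc <- normalize_accession(accession)
  if (!is_sra_accession(acc)) {
    abort(paste0("not a syntactically valid SRA accession: ", accession))
  }
  nodes <- graph$nodes
  if (!acc %in% nodes$accession) return(character())
  reach <- igraph::subcomponent(graph$resolution, acc, mode = "out")
  reach <- names(reach)
  kind_of <- stats::setNames(nodes$kind, nodes$accession)
  sort(reach[kind_of[reach] == "study"])
}

#' Resolve many accessions at once
#'
#' @param graph An `accession_graph`.
#' @param accessions Character vector of SRA accessions (syntactically
#'   valid).
#' @return A tibble `accession`, `study_accession` with one row per resolved
#'   (input, study) pair; unresolvable inputs contribute no rows.
#' @export
resolve_studies <- function(graph, accessions) {
  accessions <- unique(normalize_accession(accessions))
  hits <- map(accessions, function(a) {
    s <- resolve_to_study(graph, a)
    if (length(s) == 0) NULL else tibble(accession = a, study_accession = s)
  })
  out <- bind_rows(compact(hits))
  if (nrow(out) == 0)
    tibble(accession = character(), study_accession = character())
  else out
}

#' @export
print.accession_graph <- function(x, ...) {
  k <- table(factor(x$nodes$kind, levels = .sra_kinds))
  cat("<accession_graph> ", nrow(x$nodes), " objects, ", nrow(x$edges),
      " links (", nrow(x$dangling), " dangling)\n", sep = "")
  cat("  ", paste(names(k), unname(k), sep = ": ", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy an accession graph into its edge list
#'
#' @param x An `accession_graph`.
#' @param ... Unused.
#' @return Tibble of edges: `from`, `to`, `kind` of the link target, and
#'   `dangling` flag.
#' @method tidy accession_graph
#' @export
tidy.accession_graph <- function(x, ...) {
  x$edges |>
    mutate(dangling = !.data$to %in% x$nodes$accession)
}

#' One-row summary of an accession graph
#'
#' @param x An `accession_graph`.
#' @param ... Unused.
#' @return Tibble with node/edge counts per object kind.
#' @method glance accession_graph
#' @export
glance.accession_graph <- function(x, ...) {
  tibble(
    n_objects = nrow(x$nodes),
    n_submissions = sum(x$nodes$kind == "submission"),
    n_studies = sum(x$nodes$kind == "study"),
    n_experiments = sum(x$nodes$kind == "experiment"),
    n_runs = sum(x$nodes$kind == "run"),
    n_samples = sum(x$nodes$kind == "sample"),
    n_analyses = sum(x$nodes$kind == "analysis"),
    n_edges = nrow(x$edges),
    n_dangling = nrow(x$dangling)
  )
}

# membership table: one row per (node, study it resolves to)
.study_closure <- function(graph) {
  nodes <- graph$nodes
  studies <- nodes$accession[nodes$kind == "study"]
  kind_of <- stats::setNames(nodes$kind, nodes$accession)
  rows <- map(studies, function(s) {
    members <- names(igraph::subcomponent(graph$resolution, s, mode = "in"))
    tibble(accession = members, kind = unname(kind_of[members]),
           study_accession = s)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    tibble(accession = character(), kind = character(),
           study_accession = character())
  else out
}
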