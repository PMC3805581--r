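# Characterizing studies by disease: MeSH branch filtering, study-disease
# annotation, frequency list, hierarchical tree view, and the Disease
# Ontology route from MeSH headings to OMIM entries (used to hyperlink the
# Gendoo disease feature profiles).

.is_disease_trees <- function(tree_numbers) {
  any(grepl("^C[0-9.]", tree_numbers)) || any(grepl("^F03(\\.|$)", tree_numbers))
}

#' Is a MeSH descriptor a disease term?
#'
#' A descriptor qualifies when *any* of its tree numbers lies in the
#' Diseases branch (`C...`) or the Mental Disorders sub-branch (`F03`,
#' boundary-checked so `F02...` codes do not leak in). Any-match semantics:
#' a descriptor with one disease position among others qualifies.
#'
#' @param descriptors MeSH descriptor tibble (from [parse_mesh_ascii()]),
#'   or a list of character vectors of tree numbers.
#' @return Logical vector, one element per descriptor.
#' @export
is_disease_descriptor <- function(descriptors) {
  trees <- if (is.data.frame(descriptors)) descriptors$tree_numbers
           else descriptors
  map_lgl(trees, .is_disease_trees)
}

#' Annotate studies with disease MeSH terms
#'
#' Crosses the publication list with the MeSH headings of the linked
#' articles: for every (study, PMID) link, each heading of that article
#' that names a disease descriptor yields one study-disease annotation.
#' Headings are matched to the vocabulary by exact preferred name or UI —
#' lexical variants are deliberately not resolved (the tree view is the
#' answer to term multiplicity). Unknown headings are skipped with one
#' summary warning.
#'
#' @param links Publication link tibble (see [merge_publication_list()]).
#' @param articles Article tibble with `pmid` and `mesh_headings`.
#' @param vocab MeSH descriptor tibble from [parse_mesh_ascii()].
#' @return Tibble with one row per (study, descriptor): `study_accession`,
#'   `ui`, `name`, `supporting_pmids` (list of integer, merged over
#'   articles).
#' @export
annotate_diseases <- function(links, articles, vocab) {
  empty <- tibble(study_accession = character(), ui = character(),
                  name = character(), supporting_pmids = list())
  if (nrow(links) == 0 || nrow(articles) == 0 || nrow(vocab) == 0) return(empty)
  headings <- articles |>
    select("pmid", "mesh_headings") |>
    tidyr::unnest_longer("mesh_headings", values_to = "heading") |>
    filter(!is.na(.data$heading))
  by_name <- stats::setNames(seq_len(nrow(vocab)), vocab$name)
  by_ui <- stats::setNames(seq_len(nrow(vocab)), vocab$ui)
  idx <- dplyr::coalesce(unname(by_name[headings$heading]),
                         unname(by_ui[headings$heading]))
  unknown <- unique(headings$heading[is.na(idx)])
  if (length(unknown) > 0) {
    warn(paste0("MeSH headings not in vocabulary, skipped: ",
                paste(unknown, collapse = ", ")))
  }
  headings <- headings[!is.na(idx), ]
  idx <- idx[!is.na(idx)]
  if (nrow(headings) == 0) return(empty)
  headings$ui <- vocab$ui[idx]
  headings$name <- vocab$name[idx]
  disease <- is_disease_descriptor(vocab)[idx]
  headings <- headings[disease, ]
  if (nrow(headings) == 0) return(empty)
  links |>
    select("study_accession", "pmid") |>
    distinct() |>
    dplyr::inner_join(headings, by = "pmid", relationship = "many-to-many") |>
    group_by(.data$study_accession, .data$ui, .data$name) |>
    summarise(supporting_pmids = list(sort(unique(.data$pmid))),
              .groups = "drop") |>
    arrange(.data$study_accession, .data$ui)
}

#' Disease frequency list
#'
#' Counts, for each disease descriptor, the number of distinct studies
#' annotated with it, and attaches the OMIM identifiers reachable through
#' the Disease Ontology when a mapping is supplied.
#'
#' @param annotations Output of [annotate_diseases()].
#' @param mesh_omim Optional mapping from [mesh_to_omim()]; diseases
#'   without an entry get an empty OMIM set (some diseases simply have no
#'   link in the ontology).
#' @return Tibble `name`, `ui`, `n_projects`, `omim_ids` (list of
#'   integer), sorted by `n_projects` descending, ties by name.
#' @export
disease_frequency <- function(annotations, mesh_omim = NULL) {
  empty <- tibble(name = character(), ui = character(),
                  n_projects = integer(), omim_ids = list())
  if (nrow(annotations) == 0) return(empty)
  rows <- annotations |>
    group_by(.data$ui, .data$name) |>
    summarise(n_projects = dplyr::n_distinct(.data$study_accession),
              .groups = "drop") |>
    mutate(n_projects = as.integer(.data$n_projects))
  omim_of <- function(ui) integer()
  if (!is.null(mesh_omim) && nrow(mesh_omim) > 0) {
    lut <- stats::setNames(mesh_omim$omim_ids, mesh_omim$ui)
    omim_of <- function(ui) {
      hit <- lut[[ui]]
      if (is.null(hit)) integer() else sort(unique(hit))
    }
  }
  rows |>
    mutate(omim_ids = map(.data$ui, omim_of)) |>
    select("name", "ui", "n_projects", "omim_ids") |>
    arrange(desc(.data$n_projects), .data$name)
}

.tree_prefixes <- function(tree_number) {
  parts <- strsplit(tree_number, ".", fixed = TRUE)[[1]]
  map_chr(seq_along(parts), function(i) paste(parts[1:i], collapse = "."))
}

#' Hierarchical tree view of annotated disease terms
#'
#' Places every annotated descriptor at each of its tree positions and
#' materializes all ancestor nodes, so the annotation counts can be browsed
#' down the MeSH hierarchy. `own_count` is the number of distinct studies
#' annotated exactly at a node; `rolled_count` the distinct studies
#' annotated at the node or anywhere beneath it (a study annotated at two
#' descendants counts once).
#'
#' @param annotations Output of [annotate_diseases()].
#' @param vocab MeSH descriptor tibble (names/UIs for the nodes; ancestor
#'   positions not named in the vocabulary get `NA`).
#' @return A `mesh_tree`: tibble of nodes `tree_number`, `parent` (`NA` at
#'   roots), `depth`, `ui`, `name`, `own_count`, `rolled_count`, sorted by
#'   `tree_number`. Convert to the nested form with [tree_as_list()].
#' @export
build_disease_tree <- function(annotations, vocab) {
  empty <- structure(
    tibble(tree_number = character(), parent = character(), depth = integer(),
           ui = character(), name = character(), own_count = integer(),
           rolled_count = integer()),
    class = c("mesh_tree", "tbl_df", "tbl", "data.frame")
  )
  if (nrow(annotations) == 0) return(empty)
  vocab_trees <- vocab |>
    select("ui", "name", "tree_numbers") |>
    tidyr::unnest_longer("tree_numbers", values_to = "tree_number")
  placed <- annotations |>
    select("study_accession", "ui") |>
    dplyr::inner_join(vocab_trees, by = "ui",
                      relationship = "many-to-many")
  if (nrow(placed) == 0) return(empty)
  node_ids <- sort(unique(unlist(map(unique(placed$tree_number), .tree_prefixes))))
  own <- placed |>
    group_by(.data$tree_number) |>
    summarise(own_count = dplyr::n_distinct(.data$study_accession),
              .groups = "drop")
  rolled <- map_int(node_ids, function(tn) {
    under <- placed$tree_number == tn |
      str_starts(placed$tree_number, paste0(tn, "."))
    dplyr::n_distinct(placed$study_accession[under])
  })
  label <- vocab_trees |>
    distinct(.data$tree_number, .keep_all = TRUE)
  out <- tibble(tree_number = node_ids) |>
    mutate(
      parent = map_chr(.data$tree_number, function(tn) {
        p <- .tree_prefixes(tn)
        if (length(p) > 1) p[length(p) - 1] else NA_character_
      }),
      depth = lengths(strsplit(.data$tree_number, ".", fixed = TRUE))
    ) |>
    left_join(label, by = "tree_number") |>
    left_join(own, by = "tree_number") |>
    mutate(
      own_count = as.integer(dplyr::coalesce(.data$own_count, 0L)),
      rolled_count = as.integer(rolled)
    ) |>
    select("tree_number", "parent", "depth", "ui", "name",
           "own_count", "rolled_count") |>
    arrange(.data$tree_number)
  structure(out, class = c("mesh_tree", class(tibble())))
}

#' Nest a disease tree for JSON serialization
#'
#' @param tree A `mesh_tree` from [build_disease_tree()].
#' @return A list of root nodes; each node is a named list
#'   (`tree_number`, `ui`, `name`, `own_count`, `rolled_count`,
#'   `children`) with children sorted by tree number.
#' @export
tree_as_list <- function(tree) {
  if (nrow(tree) == 0) return(list())
  as_node <- function(i) {
    kids <- which(!is.na(tree$parent) & tree$parent == tree$tree_number[i])
    list(
      tree_number = tree$tree_number[i],
      ui = tree$ui[i],
      name = tree$name[i],
      own_count = tree$own_count[i],
      rolled_count = tree$rolled_count[i],
      children = map(kids, as_node)
    )
  }
  roots <- which(is.na(tree$parent))
  map(roots, as_node)
}

#' Map MeSH identifiers to OMIM entries through the Disease Ontology
#'
#' Disease Ontology terms cross-reference several vocabularies; every
#' non-obsolete term carrying both an `MSH` xref and one or more `OMIM`
#' xrefs contributes its OMIM ids to that MeSH descriptor (union over
#' terms). MeSH descriptors that never co-occur with an OMIM xref map to
#' the empty set — some diseases simply have no link in the ontology.
#'
#' @param terms Disease Ontology term tibble from [parse_do_obo()].
#' @return Tibble `ui`, `omim_ids` (list of sorted integer, possibly
#'   empty), one row per MeSH descriptor seen in the ontology.
#' @export
mesh_to_omim <- function(terms) {
  empty <- tibble(ui = character(), omim_ids = list())
  if (nrow(terms) == 0) return(empty)
  live <- terms |> filter(!.data$obsolete)
  if (nrow(live) == 0) return(empty)
  per_term <- map(live$xrefs, function(x) {
    msh <- x$id[x$namespace == "MSH"]
    omim <- suppressWarnings(as.integer(x$id[x$namespace == "OMIM"]))
    omim <- omim[!is.na(omim)]
    if (length(msh) == 0) return(NULL)
    tidyr::expand_grid(ui = msh, omim_id = if (length(omim)) omim else NA_integer_)
  })
  pairs <- bind_rows(compact(per_term))
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    group_by(.data$ui) |>
    summarise(omim_ids = list(sort(unique(.data$omim_id[!is.na(.data$omim_id)]))),
              .groups = "drop") |>
    arrange(.data$ui)
}

#' Hyperlink to a Gendoo disease feature profile
#'
#' Gendoo keys its disease feature profiles by OMIM entry; the link is a
#' deterministic interpolation of the OMIM id into a URL template.
#'
#' @param omim_id Positive integer vector of OMIM identifiers.
#' @param template `sprintf`-style template with one `%s` placeholder.
#' @return Character vector of URLs.
#' @export
gendoo_url <- function(omim_id,
                       template = "https://gendoo.dbcls.jp/omim/%s.html") {
  omim_id <- as.integer(omim_id)
  if (length(omim_id) == 0) return(character())
  if (any(is.na(omim_id) | omim_id <= 0)) {
    abort("omim_id must be a positive integer")
  }
  sprintf(template, format(omim_id, scientific = FALSE, trim = TRUE))
}
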