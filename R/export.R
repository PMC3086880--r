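#' Export a known + predicted signaling network
#'
#' Writes the combined network of known annotations/interactions and
#' predictions to SIF or GraphML for downstream viewers. Nodes carry
#' the species, the known pathways, the predicted pathways, and a
#' status (`known` for proteins with any known annotation or
#' interaction, `predicted` for proteins introduced only by
#' predictions). Edges carry evidence, effect and a status: known
#' interactions are `known`, interologs are `predicted`. The SIF format
#' is one line per edge, `node <TAB> relation <TAB> node`, with
#' relation `known` or `interolog`; GraphML is written through igraph
#' and can be re-read by any GraphML-aware tool.
#'
#' @param dataset A `signalog_dataset` contributing known annotations
#'   and interactions.
#' @param predictions Optional `signalog_predictions` tibble.
#' @param interologs Optional `interolog_set` tibble.
#' @param fmt `"SIF"` or `"GraphML"` (case-insensitive).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(dataset, predictions = NULL, interologs = NULL,
                           fmt = c("SIF", "GraphML"), path) {
  fmt <- match.arg(toupper(fmt[1]), c("SIF", "GRAPHML"))
  g <- build_network(dataset, predictions, interologs)
  if (fmt == "SIF") {
    el <- igraph::as_data_frame(g, what = "edges")
    lines <- if (nrow(el) > 0) {
      paste(el$from,
            ifelse(el$status == "predicted", "interolog", "known"),
            el$to, sep = "\t")
    } else character()
    con <- file(path, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Assemble the igraph object behind [export_network()]
#'
#' @inheritParams export_network
#' @return An undirected-for-interologs / directed-for-known mixed
#'   igraph is not representable, so the graph is directed and
#'   interolog edges appear once in canonical orientation.
#' @export
build_network <- function(dataset, predictions = NULL, interologs = NULL) {
  ia <- dataset$interactions
  edges_known <- if (nrow(ia) > 0) {
    tibble::tibble(from = ia$source_id, to = ia$target_id,
                   evidence = ia$evidence, effect = ia$effect,
                   status = "known")
  } else NULL
  edges_pred <- if (!is.null(interologs) && nrow(interologs) > 0) {
    tibble::tibble(from = interologs$protein_a, to = interologs$protein_b,
                   evidence = "indirect", effect = "unknown",
                   status = "predicted")
  } else NULL
  edges <- dplyr::bind_rows(edges_known, edges_pred)

  ann <- dataset$annotations
  known_nodes <- tibble::tibble(
    name = c(ann$protein_id, ia$source_id, ia$target_id),
    species = c(ann$species, ia$species, ia$species)
  )
  pred_nodes <- if (!is.null(predictions) && nrow(predictions) > 0) {
    tibble::tibble(name = predictions$protein_id,
                   species = predictions$species)
  } else NULL
  nodes <- dplyr::bind_rows(known_nodes, pred_nodes)
  if (!is.null(edges) && nrow(edges) > 0) {
    # endpoints referenced only by edges
    extra <- setdiff(norm_id(c(edges$from, edges$to)), norm_id(nodes$name))
    if (length(extra) > 0) {
      all_ids <- c(edges$from, edges$to)
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        name = all_ids[match(extra, norm_id(all_ids))],
        species = NA_character_
      ))
    }
  }
  nodes <- nodes[!duplicated(norm_id(nodes$name)), , drop = FALSE]

  known_by_prot <- split(ann$pathway, norm_id(ann$protein_id))
  pred_by_prot <- if (!is.null(predictions)) {
    split(predictions$pathway, norm_id(predictions$protein_id))
  } else list()
  key <- norm_id(nodes$name)
  nodes$pathways <- vapply(key, function(k) {
    paste(sort(unique(known_by_prot[[k]])), collapse = ";")
  }, character(1))
  nodes$predicted_pathways <- vapply(key, function(k) {
    paste(sort(unique(pred_by_prot[[k]])), collapse = ";")
  }, character(1))
  nodes$status <- ifelse(nzchar(nodes$pathways) |
                           key %in% norm_id(c(ia$source_id, ia$target_id)),
                         "known", "predicted")
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            evidence = character(), effect = character(),
                            status = character())
  }
  # edge endpoints must match node names exactly (case may differ)
  edges$from <- nodes$name[match(norm_id(edges$from), key)]
  edges$to <- nodes$name[match(norm_id(edges$to), key)]
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = as.data.frame(nodes))
}
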