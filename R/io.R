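# TSV dialects. All files are UTF-8, tab-separated with a header row;
# lines starting with '#' are comments; list-valued cells use ';'.

CLUSTER_COLS     <- c("cluster_id", "species_pair", "species", "protein_id",
                      "inparalog_score")
ANNOTATION_COLS  <- c("species", "protein_id", "pathway", "role", "pmids")
INTERACTION_COLS <- c("species", "source_id", "target_id", "evidence",
                      "effect", "pmids")
ATTRIBUTE_COLS   <- c("species", "protein_id", "is_membrane", "is_enzyme",
                      "has_kinase_domain", "is_disease_related",
                      "known_drugs", "orthologs_known", "function_known",
                      "disease_names")
REFERENCE_COLS   <- c("resource", "species", "protein_id", "pathway_name")

ROLES    <- c("ligand", "receptor", "mediator", "co-factor",
              "transcription factor", "other")
EVIDENCE <- c("direct", "indirect")
EFFECTS  <- c("stimulation", "inhibition", "unknown")

read_dialect <- function(path, cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, na = character())
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[cols])
}

write_dialect <- function(df, path, header = NULL) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read an ortholog cluster table
#'
#' Parses an InParanoid-style cluster table: one row per cluster member,
#' with the cluster id, the species pair (e.g. `"CEL-HSA"`), the member's
#' species, its protein id and its inparalog score in (0, 1]. Each
#' cluster is anchored by one seed ortholog per species (score exactly
#' 1.0); inparalogs that arose by duplication after speciation carry
#' lower scores.
#'
#' @param path Path to a tab-separated cluster file.
#' @return A tibble with columns `cluster_id`, `species_pair`, `species`,
#'   `protein_id`, `inparalog_score`; row order within clusters preserved.
#' @seealso [write_clusters()], [build_ortholog_map()]
#' @export
read_clusters <- function(path) {
  df <- read_dialect(path, CLUSTER_COLS)
  score <- suppressWarnings(as.numeric(df$inparalog_score))
  bad <- which(is.na(score) | score <= 0 | score > 1)
  if (length(bad) > 0) {
    stop("malformed inparalog_score at data row(s) ",
         paste(bad, collapse = ", "), " of ", basename(path),
         ": scores must be real numbers in (0,1]", call. = FALSE)
  }
  df$inparalog_score <- score
  validate_clusters(df)
  df
}

#' Validate a cluster tibble
#'
#' Checks the structural invariants of ortholog clusters: the species
#' pair is two distinct codes; every member belongs to the pair; each
#' species of the pair contributes at least one member and exactly one
#' seed ortholog (score 1.0); scores lie in (0, 1].
#'
#' @param clusters A cluster tibble (see [read_clusters()]).
#' @return The input, invisibly, on success; otherwise an error naming
#'   the offending cluster.
#' @export
validate_clusters <- function(clusters) {
  if (nrow(clusters) == 0) return(invisible(clusters))
  if (any(clusters$inparalog_score <= 0 | clusters$inparalog_score > 1)) {
    stop("inparalog scores must lie in (0,1]", call. = FALSE)
  }
  for (cid in unique(clusters$cluster_id)) {
    cl <- clusters[clusters$cluster_id == cid, ]
    pair <- sort(unique(unlist(strsplit(cl$species_pair[1], "-", fixed = TRUE))))
    if (length(pair) != 2) {
      stop("cluster ", cid, ": species_pair must name two distinct species",
           call. = FALSE)
    }
    if (!all(cl$species %in% pair)) {
      stop("cluster ", cid, ": member species outside the species pair",
           call. = FALSE)
    }
    for (sp in pair) {
      n_seed <- sum(cl$species == sp & cl$inparalog_score == 1)
      if (sum(cl$species == sp) < 1 || n_seed != 1) {
        stop("cluster ", cid, ": species ", sp,
             " must have >=1 member and exactly one seed ortholog ",
             "(score 1.0); found ", n_seed, " seed(s)", call. = FALSE)
      }
    }
  }
  invisible(clusters)
}

#' @rdname read_clusters
#' @param clusters Cluster tibble to write.
#' @export
write_clusters <- function(clusters, path) {
  df <- clusters[CLUSTER_COLS]
  df$inparalog_score <- format(df$inparalog_score, trim = TRUE, digits = 15)
  write_dialect(df, path)
}

#' Read pathway membership annotations
#'
#' One row per (protein, pathway) membership with a curation role
#' (ligand, receptor, mediator, co-factor, transcription factor, other)
#' and supporting PubMed ids. Duplicate (protein, pathway) rows are
#' collapsed and their pmids unioned. Pathway names are resolved against
#' the vocabulary through the synonym map; an unknown name is an error.
#'
#' @param path Path to a tab-separated annotation file.
#' @param vocabulary Canonical pathway vocabulary.
#' @param synonyms Pathway synonym map.
#' @return A tibble with columns `species`, `protein_id`, `pathway`,
#'   `role`, `pmids` (list column of integer vectors).
#' @export
read_annotations <- function(path,
                             vocabulary = default_pathways(),
                             synonyms = default_pathway_synonyms()) {
  df <- read_dialect(path, ANNOTATION_COLS)
  tidy_annotations(df, vocabulary = vocabulary, synonyms = synonyms)
}

tidy_annotations <- function(df, vocabulary = default_pathways(),
                             synonyms = default_pathway_synonyms()) {
  df$pathway <- resolve_pathways(df$pathway, vocabulary, synonyms,
                                 strict = TRUE)
  df$role <- ifelse(df$role %in% ROLES, df$role, "other")
  df$pmids <- split_pmids(df$pmids)
  df |>
    dplyr::mutate(.key = paste(norm_id(.data$species),
                               norm_id(.data$protein_id),
                               .data$pathway, sep = "\r")) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      species = dplyr::first(.data$species),
      protein_id = dplyr::first(.data$protein_id),
      pathway = dplyr::first(.data$pathway),
      role = dplyr::first(.data$role),
      pmids = list(sort(unique(unlist(.data$pmids)))),
      .groups = "drop"
    ) |>
    dplyr::select(-".key") |>
    dplyr::arrange(.data$species, norm_id(.data$protein_id), .data$pathway)
}

#' @rdname read_annotations
#' @param annotations Annotation tibble to write.
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations[ANNOTATION_COLS]
  df$pmids <- join_list_field(df$pmids)
  write_dialect(df, path)
}

#' Read directed signaling interactions
#'
#' One row per curated directed interaction within one species, with an
#' evidence type (`direct` biochemical evidence vs `indirect`) and an
#' effect sign (`stimulation`, `inhibition`, `unknown`).
#'
#' @param path Path to a tab-separated interaction file.
#' @return A tibble with columns `species`, `source_id`, `target_id`,
#'   `evidence`, `effect`, `pmids` (list column).
#' @export
read_interactions <- function(path) {
  df <- read_dialect(path, INTERACTION_COLS)
  bad <- which(!df$evidence %in% EVIDENCE)
  if (length(bad) > 0) {
    stop("unknown evidence value at data row(s) ",
         paste(bad, collapse = ", "), "; expected direct|indirect",
         call. = FALSE)
  }
  bad <- which(!df$effect %in% EFFECTS)
  if (length(bad) > 0) {
    stop("unknown effect value at data row(s) ",
         paste(bad, collapse = ", "),
         "; expected stimulation|inhibition|unknown", call. = FALSE)
  }
  df$pmids <- split_pmids(df$pmids)
  df
}

#' @rdname read_interactions
#' @param interactions Interaction tibble to write.
#' @export
write_interactions <- function(interactions, path) {
  df <- interactions[INTERACTION_COLS]
  df$pmids <- join_list_field(df$pmids)
  write_dialect(df, path)
}

#' Read per-protein attribute flags
#'
#' Flags driving novelty classification and drug-target relevance
#' scoring: membrane localization, enzymatic activity, kinase domain,
#' disease relatedness (the four key drug-target properties), plus
#' literature flags (`orthologs_known`, `function_known`), known drugs
#' and associated disease names. Booleans are encoded 0/1 in the file.
#'
#' @param path Path to a tab-separated attribute file.
#' @return A tibble with one row per protein; logical flag columns,
#'   `known_drugs` and `disease_names` as list columns.
#' @export
read_attributes <- function(path) {
  df <- read_dialect(path, ATTRIBUTE_COLS)
  flags <- c("is_membrane", "is_enzyme", "has_kinase_domain",
             "is_disease_related", "orthologs_known", "function_known")
  for (f in flags) {
    v <- df[[f]]
    ok <- v %in% c("0", "1", "TRUE", "FALSE")
    if (!all(ok)) {
      stop("attribute flag ", f, " must be 0/1 (data row(s) ",
           paste(which(!ok), collapse = ", "), ")", call. = FALSE)
    }
    df[[f]] <- v %in% c("1", "TRUE")
  }
  df$known_drugs <- split_list_field(df$known_drugs)
  df$disease_names <- split_list_field(df$disease_names)
  df
}

#' @rdname read_attributes
#' @param attributes Attribute tibble to write.
#' @export
write_attributes <- function(attributes, path) {
  df <- attributes[ATTRIBUTE_COLS]
  flags <- c("is_membrane", "is_enzyme", "has_kinase_domain",
             "is_disease_related", "orthologs_known", "function_known")
  for (f in flags) df[[f]] <- as.integer(df[[f]])
  df$known_drugs <- join_list_field(df$known_drugs)
  df$disease_names <- join_list_field(df$disease_names)
  write_dialect(df, path)
}

#' Read reference pathway annotations
#'
#' Pathway membership tables exported from reference resources
#' (KEGG/Reactome-like): resource name, species, protein id and the
#' resource's own pathway name, which is mapped onto the canonical
#' vocabulary only at comparison time (see [compare_to_reference()]).
#'
#' @param path Path to a tab-separated reference annotation file.
#' @return A tibble with columns `resource`, `species`, `protein_id`,
#'   `pathway_name`.
#' @export
read_reference_annotations <- function(path) {
  read_dialect(path, REFERENCE_COLS)
}

#' Assemble a multi-species signaling dataset
#'
#' Bundles the four input tables into one validated object: ortholog
#' clusters, pathway annotations, directed interactions and per-protein
#' attributes. Proteins referenced by annotations or interactions that
#' lack an attribute record are tolerated; [attributes_for()] synthesizes
#' all-false placeholder rows for them, since attribute sources (GO,
#' DrugBank, OMIM-like resources) are incomplete in practice.
#'
#' @param clusters Cluster tibble ([read_clusters()]); may be empty.
#' @param annotations Annotation tibble ([read_annotations()]).
#' @param interactions Interaction tibble ([read_interactions()]).
#' @param attributes Attribute tibble ([read_attributes()]).
#' @param species Configured species codes (>= 2).
#' @param pathways Pathway vocabulary.
#' @return An object of class `signalog_dataset` (a named list of
#'   tibbles plus the configured vocabularies).
#' @export
signalog_dataset <- function(clusters = empty_clusters(),
                             annotations = empty_annotations(),
                             interactions = empty_interactions(),
                             attributes = empty_attributes(),
                             species = default_species(),
                             pathways = default_pathways()) {
  stopifnot(length(species) >= 2)
  validate_clusters(clusters)
  used <- unique(c(clusters$species, annotations$species,
                   interactions$species, attributes$species))
  unknown <- setdiff(used, species)
  if (length(unknown) > 0) {
    stop("species code(s) outside the configured set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(annotations$pathway %in% pathways)) {
    stop("annotation pathway outside the configured vocabulary",
         call. = FALSE)
  }
  structure(
    list(clusters = clusters, annotations = annotations,
         interactions = interactions, attributes = attributes,
         species = species, pathways = pathways),
    class = "signalog_dataset"
  )
}

#' @export
print.signalog_dataset <- function(x, ...) {
  cat("<signalog_dataset>\n")
  cat("  species:      ", paste(x$species, collapse = ", "), "\n")
  cat("  clusters:     ", length(unique(x$clusters$cluster_id)),
      " (", nrow(x$clusters), " member rows)\n", sep = "")
  cat("  annotations:  ", nrow(x$annotations), "\n", sep = "")
  cat("  interactions: ", nrow(x$interactions), "\n", sep = "")
  cat("  attributes:   ", nrow(x$attributes), "\n", sep = "")
  invisible(x)
}

empty_clusters <- function() {
  tibble::tibble(cluster_id = character(), species_pair = character(),
                 species = character(), protein_id = character(),
                 inparalog_score = numeric())
}

empty_annotations <- function() {
  tibble::tibble(species = character(), protein_id = character(),
                 pathway = character(), role = character(),
                 pmids = list())
}

empty_interactions <- function() {
  tibble::tibble(species = character(), source_id = character(),
                 target_id = character(), evidence = character(),
                 effect = character(), pmids = list())
}

empty_attributes <- function() {
  tibble::tibble(species = character(), protein_id = character(),
                 is_membrane = logical(), is_enzyme = logical(),
                 has_kinase_domain = logical(),
                 is_disease_related = logical(), known_drugs = list(),
                 orthologs_known = logical(), function_known = logical(),
                 disease_names = list())
}

#' Look up attributes, synthesizing placeholders for missing proteins
#'
#' Returns one attribute row per requested protein. Proteins without a
#' record receive all-false flags and empty drug/disease lists, with a
#' warning, so downstream scoring never fails on incomplete attribute
#' sources.
#'
#' @param attributes Attribute tibble.
#' @param species Species code (scalar).
#' @param protein_ids Character vector of protein ids.
#' @return Attribute tibble with `length(protein_ids)` rows, in input
#'   order.
#' @export
attributes_for <- function(attributes, species, protein_ids) {
  key <- paste(norm_id(attributes$species), norm_id(attributes$protein_id))
  want <- paste(norm_id(species), norm_id(protein_ids))
  idx <- match(want, key)
  out <- attributes[ifelse(is.na(idx), 1L, idx), ]
  miss <- is.na(idx)
  if (any(miss)) {
    warning(sum(miss), " protein(s) without attribute records; ",
            "using all-false placeholders", call. = FALSE)
    blank <- empty_attributes()[rep(1L, 0), ]
    for (i in which(miss)) {
      out[i, ] <- tibble::tibble(
        species = species, protein_id = protein_ids[i],
        is_membrane = FALSE, is_enzyme = FALSE,
        has_kinase_domain = FALSE, is_disease_related = FALSE,
        known_drugs = list(character()), orthologs_known = FALSE,
        function_known = FALSE, disease_names = list(character())
      )
    }
  }
  out$species <- rep(species, length(protein_ids))
  out$protein_id <- protein_ids
  out
}

#' Read or write a dataset directory
#'
#' A dataset directory holds the standard TSV set: `clusters.tsv`,
#' `annotations.tsv`, `interactions.tsv`, `attributes.tsv`. Missing
#' files load as empty tables.
#'
#' @param dir Directory path.
#' @param species,pathways Configured vocabularies.
#' @return `read_dataset()` a `signalog_dataset`; `write_dataset()` the
#'   directory path, invisibly.
#' @export
read_dataset <- function(dir, species = default_species(),
                         pathways = default_pathways()) {
  p <- function(f) file.path(dir, f)
  signalog_dataset(
    clusters = if (file.exists(p("clusters.tsv")))
      read_clusters(p("clusters.tsv")) else empty_clusters(),
    annotations = if (file.exists(p("annotations.tsv")))
      read_annotations(p("annotations.tsv"), pathways) else empty_annotations(),
    interactions = if (file.exists(p("interactions.tsv")))
      read_interactions(p("interactions.tsv")) else empty_interactions(),
    attributes = if (file.exists(p("attributes.tsv")))
      read_attributes(p("attributes.tsv")) else empty_attributes(),
    species = species, pathways = pathways
  )
}

#' @rdname read_dataset
#' @param dataset A `signalog_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_clusters(dataset$clusters, file.path(dir, "clusters.tsv"))
  write_annotations(dataset$annotations, file.path(dir, "annotations.tsv"))
  write_interactions(dataset$interactions, file.path(dir, "interactions.tsv"))
  write_attributes(dataset$attributes, file.path(dir, "attributes.tsv"))
  invisible(dir)
}
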