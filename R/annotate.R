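#' Classify the novelty of a signalog prediction
#'
#' Predictions are graded into five classes by how much the literature
#' already knew about the protein, from most to least novel:
#' \describe{
#'   \item{1}{neither orthology nor biochemical function documented}
#'   \item{2}{orthologs documented, biochemical function unknown}
#'   \item{3}{orthology undocumented, biochemical function known}
#'   \item{4}{orthologs and function known, no prior pathway annotation}
#'   \item{5}{orthologs, function and some pathway annotation all known
#'     (the prediction still adds at least one novel membership)}
#' }
#' "Known orthologs" means literature-documented orthology (the
#' `orthologs_known` attribute flag), which is distinct from the
#' cluster-derived orthology used for prediction: the method routinely
#' predicts roles for proteins whose orthology was never discussed in
#' the literature. The classes are evaluated most-specific-first and
#' partition all eight flag combinations, so exactly one class applies.
#'
#' @param orthologs_known,function_known,pathway_known Logical vectors
#'   (recycled to common length).
#' @return Integer vector of classes in 1..5.
#' @export
#' @examples
#' classify_novelty(TRUE, TRUE, FALSE)   # class 4
#' classify_novelty(FALSE, TRUE, FALSE)  # class 3
classify_novelty <- function(orthologs_known, function_known,
                             pathway_known = FALSE) {
  n <- max(length(orthologs_known), length(function_known),
           length(pathway_known))
  o <- rep_len(as.logical(orthologs_known), n)
  f <- rep_len(as.logical(function_known), n)
  p <- rep_len(as.logical(pathway_known), n)
  if (anyNA(o) || anyNA(f) || anyNA(p)) {
    stop("novelty flags must be resolved TRUE/FALSE", call. = FALSE)
  }
  dplyr::case_when(
    o & f & p   ~ 5L,
    o & f & !p  ~ 4L,
    !o & f      ~ 3L,
    o & !f      ~ 2L,
    .default = 1L
  )
}

#' Drug-target relevance score
#'
#' The number of key drug-target properties a protein has, out of four:
#' membrane localization (M), enzymatic activity (E), kinase domain (K)
#' and disease relatedness (D). Established drug targets tend to score
#' high; a score of 4 corresponds to proteins with all four properties.
#'
#' @param attributes Attribute tibble (rows are proteins) or a single
#'   logical flag per argument via the `...`-free columns.
#' @return Integer vector of scores in 0..4, one per row.
#' @export
#' @examples
#' relevance_score(tibble::tibble(
#'   is_membrane = TRUE, is_enzyme = TRUE,
#'   has_kinase_domain = TRUE, is_disease_related = TRUE
#' ))
relevance_score <- function(attributes) {
  flags <- c("is_membrane", "is_enzyme", "has_kinase_domain",
             "is_disease_related")
  missing <- setdiff(flags, names(attributes))
  if (length(missing) > 0) {
    stop("attribute column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- vapply(flags, function(f) as.logical(attributes[[f]]),
              logical(nrow(attributes)))
  m <- matrix(m, nrow = nrow(attributes))
  if (anyNA(m)) stop("relevance flags must be resolved TRUE/FALSE",
                     call. = FALSE)
  as.integer(rowSums(m))
}

#' Which of the four key properties a protein has
#'
#' @param attributes Attribute tibble.
#' @return Character vector, one per row, of ';'-joined component names
#'   from {membrane, enzyme, kinase_domain, disease}.
#' @export
relevance_components <- function(attributes) {
  labels <- c(is_membrane = "membrane", is_enzyme = "enzyme",
              has_kinase_domain = "kinase_domain",
              is_disease_related = "disease")
  vapply(seq_len(nrow(attributes)), function(i) {
    on <- names(labels)[vapply(names(labels),
                               function(f) isTRUE(attributes[[f]][i]),
                               logical(1))]
    paste(labels[on], collapse = ";")
  }, character(1))
}

#' Rank signalogs as drug-target candidates
#'
#' One row per signalog protein, with its predicted pathways, its known
#' drugs, the relevance score, and whether it is already an established
#' drug target. Rows are sorted by score (descending) then protein id;
#' *novel candidates* are the rows not currently targeted by any drug.
#'
#' @param predictions A `signalog_predictions` tibble for one species.
#' @param attributes Attribute tibble; proteins missing from it get
#'   all-false placeholder flags.
#' @param drug_target_ids Character vector of protein ids currently
#'   listed as drug targets (e.g. a DrugBank export); defaults to the
#'   proteins whose attribute record lists at least one known drug.
#' @param min_score Optional score threshold for the candidate flag.
#' @return A `candidate_table` tibble: `protein_id`,
#'   `predicted_pathways`, `known_drugs`, `score`, `components`,
#'   `is_current_target`, `is_novel_candidate`.
#' @export
candidate_table <- function(predictions, attributes,
                            drug_target_ids = NULL, min_score = 0L) {
  sp <- unique(predictions$species)
  if (length(sp) > 1) {
    stop("candidate_table expects predictions for a single species",
         call. = FALSE)
  }
  if (nrow(predictions) == 0) {
    return(tibble::tibble(protein_id = character(),
                          predicted_pathways = character(),
                          known_drugs = character(), score = integer(),
                          components = character(),
                          is_current_target = logical(),
                          is_novel_candidate = logical()))
  }
  per_prot <- tibble::as_tibble(predictions) |>
    dplyr::mutate(.key = norm_id(.data$protein_id)) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      protein_id = dplyr::first(.data$protein_id),
      predicted_pathways = paste(sort(unique(.data$pathway)),
                                 collapse = ";"),
      .groups = "drop"
    )
  attrs <- suppressWarnings(
    attributes_for(attributes, sp, per_prot$protein_id))
  per_prot$score <- relevance_score(attrs)
  per_prot$components <- relevance_components(attrs)
  per_prot$known_drugs <- join_list_field(attrs$known_drugs)
  if (is.null(drug_target_ids)) {
    per_prot$is_current_target <- nzchar(per_prot$known_drugs)
  } else {
    per_prot$is_current_target <-
      per_prot$.key %in% norm_id(drug_target_ids)
  }
  per_prot$is_novel_candidate <- !per_prot$is_current_target &
    per_prot$score >= min_score
  per_prot |>
    dplyr::select("protein_id", "predicted_pathways", "known_drugs",
                  "score", "components", "is_current_target",
                  "is_novel_candidate") |>
    dplyr::arrange(dplyr::desc(.data$score), norm_id(.data$protein_id))
}

#' Orthodisease report: signalogs with disease-linked orthologs
#'
#' An *orthodisease* protein is a model-organism protein whose ortholog
#' in the disease species (typically human) is linked to a disease.
#' This report lists the signalog proteins having at least one ortholog
#' in `disease_species` whose `is_disease_related` flag is set, together
#' with the aggregated disease names of those orthologs.
#'
#' @param predictions A `signalog_predictions` tibble (model organism).
#' @param maps Ortholog maps covering (prediction species,
#'   `disease_species`).
#' @param attributes Attribute tibble providing `is_disease_related` and
#'   `disease_names` for the disease species.
#' @param disease_species Species whose disease links are consulted;
#'   must differ from the predictions' species.
#' @return Tibble with one row per orthodisease signalog: `protein_id`,
#'   `predicted_pathways`, `disease_orthologs`, `diseases`.
#' @export
orthodisease_report <- function(predictions, maps, attributes,
                                disease_species) {
  sp <- unique(predictions$species)
  if (length(sp) > 1) stop("predictions must refer to one species",
                           call. = FALSE)
  if (length(sp) == 1 && sp == disease_species) {
    stop("disease_species must differ from the predictions' species",
         call. = FALSE)
  }
  empty <- tibble::tibble(protein_id = character(),
                          predicted_pathways = character(),
                          disease_orthologs = character(),
                          diseases = character())
  if (nrow(predictions) == 0) return(empty)
  links <- directed_links(maps)
  links <- links[links$species == sp &
                   links$ortholog_species == disease_species, ]
  if (nrow(links) == 0) return(empty)
  akey <- paste(norm_id(attributes$species), norm_id(attributes$protein_id))
  links$.aidx <- match(paste(norm_id(disease_species),
                             norm_id(links$ortholog_id)), akey)
  links$.disease <- !is.na(links$.aidx) &
    attributes$is_disease_related[ifelse(is.na(links$.aidx), 1L,
                                         links$.aidx)]
  links <- links[links$.disease, , drop = FALSE]
  if (nrow(links) == 0) return(empty)

  per_prot <- tibble::as_tibble(predictions) |>
    dplyr::mutate(.key = norm_id(.data$protein_id)) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      protein_id = dplyr::first(.data$protein_id),
      predicted_pathways = paste(sort(unique(.data$pathway)),
                                 collapse = ";"),
      .groups = "drop"
    )
  links$.key <- norm_id(links$protein_id)
  hit <- links[links$.key %in% per_prot$.key, ]
  if (nrow(hit) == 0) return(empty)
  agg <- hit |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      disease_orthologs = paste(sort(unique(.data$ortholog_id)),
                                collapse = ";"),
      diseases = paste(sort(unique(unlist(
        attributes$disease_names[.data$.aidx]))), collapse = ";"),
      .groups = "drop"
    )
  dplyr::inner_join(per_prot, agg, by = ".key") |>
    dplyr::select("protein_id", "predicted_pathways",
                  "disease_orthologs", "diseases") |>
    dplyr::arrange(norm_id(.data$protein_id))
}
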