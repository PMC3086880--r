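#' Overlap of predictions with a reference pathway resource
#'
#' Quantifies how novel a prediction set is relative to a reference
#' pathway-annotation resource (a KEGG/Reactome-like export). A
#' signalog protein counts as *present* when it appears in the
#' reference under any pathway — even one outside the canonical
#' vocabulary — and as *same-pathway* when, after mapping the
#' reference's pathway names through the synonym map, at least one of
#' its predicted pathways matches. Reference pathway names that resolve
#' to nothing are counted as "other" with a warning.
#'
#' @param predictions A `signalog_predictions` tibble for one species.
#' @param reference Reference annotation tibble
#'   ([read_reference_annotations()]) or any tibble with `species`,
#'   `protein_id`, `pathway_name`.
#' @param synonyms Pathway synonym map.
#' @param vocabulary Canonical pathway vocabulary.
#' @return One-row tibble: `n_signalogs`, `n_present_in_ref`,
#'   `n_same_pathway`, `pct_present`, `pct_same_pathway`,
#'   `pct_novel_annotations` (share of predicted annotations, for
#'   proteins present in the reference, that the reference does not
#'   list).
#' @export
compare_to_reference <- function(predictions, reference,
                                 synonyms = default_pathway_synonyms(),
                                 vocabulary = default_pathways()) {
  sp <- unique(predictions$species)
  rsp <- unique(reference$species)
  if (length(sp) == 1 && length(rsp) >= 1 &&
      !all(norm_id(rsp) == norm_id(sp))) {
    stop("predictions and reference refer to different species",
         call. = FALSE)
  }
  sig <- unique(norm_id(predictions$protein_id))
  ref_prot <- unique(norm_id(reference$protein_id))
  ref_path <- suppressWarnings(
    resolve_pathways(reference$pathway_name, vocabulary, synonyms))
  n_unres <- sum(is.na(ref_path) & !is.na(reference$pathway_name))
  if (n_unres > 0) {
    warning(n_unres, " reference annotation(s) under unmapped pathway ",
            "names; counted as \"other\"", call. = FALSE)
  }
  ref_key <- paste(norm_id(reference$protein_id), ref_path)
  present <- sig[sig %in% ref_prot]
  pred_key <- paste(norm_id(predictions$protein_id), predictions$pathway)
  same <- unique(norm_id(
    predictions$protein_id[pred_key %in% ref_key]))
  # annotations predicted for proteins the reference already lists
  on_present <- pred_key[norm_id(predictions$protein_id) %in% present]
  n_on_present <- length(unique(on_present))
  n_confirmed <- length(unique(on_present[on_present %in% ref_key]))
  n_sig <- length(sig)
  tibble::tibble(
    n_signalogs = n_sig,
    n_present_in_ref = length(present),
    n_same_pathway = length(same),
    pct_present =
      if (n_sig > 0) percent1(100 * length(present) / n_sig) else NA_real_,
    pct_same_pathway =
      if (n_sig > 0) percent1(100 * length(same) / n_sig) else NA_real_,
    pct_novel_annotations = if (n_on_present > 0)
      percent1(100 * (n_on_present - n_confirmed) / n_on_present)
    else NA_real_
  )
}

#' Overlap of two prediction sets
#'
#' Compares two independent prediction sets for the same species (e.g.
#' orthology-transferred memberships against a machine-learning
#' predictor's output), after mapping both through the pathway synonym
#' map. Counts are over shared proteins and their synonym-mapped
#' (protein, pathway) pairs.
#'
#' @param predictions_a,predictions_b Prediction tibbles with
#'   `protein_id` and `pathway` columns, one species.
#' @param synonyms Pathway synonym map.
#' @param vocabulary Canonical pathway vocabulary.
#' @return One-row tibble: `n_shared_proteins`, `n_annotations_a`,
#'   `n_annotations_b` (annotations on the shared proteins),
#'   `n_identical_annotations`.
#' @export
compare_to_prediction_set <- function(predictions_a, predictions_b,
                                      synonyms = default_pathway_synonyms(),
                                      vocabulary = default_pathways()) {
  canon <- function(df) {
    tibble::tibble(
      key = norm_id(df$protein_id),
      pathway = suppressWarnings(
        resolve_pathways(df$pathway, vocabulary, synonyms))
    )
  }
  a <- canon(predictions_a)
  b <- canon(predictions_b)
  shared <- intersect(unique(a$key), unique(b$key))
  a_sh <- unique(paste(a$key, a$pathway)[a$key %in% shared])
  b_sh <- unique(paste(b$key, b$pathway)[b$key %in% shared])
  tibble::tibble(
    n_shared_proteins = length(shared),
    n_annotations_a = length(a_sh),
    n_annotations_b = length(b_sh),
    n_identical_annotations = length(intersect(a_sh, b_sh))
  )
}
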