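#' Predict signalogs: orthology-based pathway membership transfer
#'
#' The core of the method. A protein of the target species is predicted
#' to be a member of every signaling pathway to which one of its
#' orthologs (in any other species, under the thresholded ortholog map)
#' is annotated, unless that (protein, pathway) membership is already
#' known in the target species. Such predicted novel pathway members are
#' called *signalogs*. A signalog can be annotated to more than one
#' pathway when its orthologs are. Predictions supported by several
#' orthologs or source species are merged into one record whose
#' provenance lists every supporting ortholog.
#'
#' The candidate universe is the set of target-species proteins that
#' appear in some ortholog cluster: transfer happens only through
#' orthology, so un-clustered proteins can never be signalogs. A protein
#' already annotated to some pathway may still receive a *different*
#' pathway; such proteins have `is_new_protein = FALSE`.
#'
#' @param dataset A `signalog_dataset`.
#' @param target_species Species receiving the transferred annotations.
#' @param maps Ortholog maps; built from `dataset$clusters` at
#'   `threshold` when `NULL`.
#' @param threshold Inparalog score threshold for map construction.
#' @param require_no_interactions Additionally exclude proteins already
#'   participating in any known interaction of the target species
#'   (stricter reading of "no known signaling interactions").
#' @return A `signalog_predictions` tibble, sorted by (protein id,
#'   pathway), with columns `species`, `protein_id`, `pathway`,
#'   `is_new_protein` and `provenance` (';'-joined
#'   `"SRC:ortholog:score"` entries).
#' @export
#' @examples
#' ds <- load_fixture("table1_notch")
#' predict_signalogs(ds, "CEL")
predict_signalogs <- function(dataset, target_species, maps = NULL,
                              threshold = 0.3,
                              require_no_interactions = FALSE) {
  if (!target_species %in% dataset$species) {
    stop("target_species ", target_species,
         " is outside the configured species set", call. = FALSE)
  }
  if (is.null(maps)) maps <- build_ortholog_maps(dataset, threshold)
  links <- directed_links(maps)
  links <- links[links$species == target_species, , drop = FALSE]
  out <- empty_predictions(target_species, threshold)
  if (nrow(links) == 0) return(out)

  ann <- dataset$annotations
  # pathways known for each ortholog in its own species
  ortho_ann <- dplyr::inner_join(
    dplyr::mutate(links, .okey = paste(norm_id(.data$ortholog_species),
                                       norm_id(.data$ortholog_id))),
    dplyr::mutate(ann, .okey = paste(norm_id(.data$species),
                                     norm_id(.data$protein_id))) |>
      dplyr::select(".okey", "pathway"),
    by = ".okey", relationship = "many-to-many"
  )
  if (nrow(ortho_ann) == 0) return(out)

  # drop memberships already known in the target species
  known_key <- paste(norm_id(ann$species[ann$species == target_species]),
                     norm_id(ann$protein_id[ann$species == target_species]),
                     ann$pathway[ann$species == target_species])
  ortho_ann$.pkey <- paste(norm_id(target_species),
                           norm_id(ortho_ann$protein_id),
                           ortho_ann$pathway)
  novel <- ortho_ann[!ortho_ann$.pkey %in% known_key, , drop = FALSE]

  if (require_no_interactions) {
    ia <- dataset$interactions
    ia <- ia[ia$species == target_species, ]
    busy <- unique(norm_id(c(ia$source_id, ia$target_id)))
    novel <- novel[!norm_id(novel$protein_id) %in% busy, , drop = FALSE]
  }
  if (nrow(novel) == 0) return(out)

  annotated_target <- unique(norm_id(
    ann$protein_id[ann$species == target_species]))
  novel$.prov <- paste(novel$ortholog_species, novel$ortholog_id,
                       format(novel$ortholog_score, trim = TRUE, digits = 4),
                       sep = ":")
  res <- novel |>
    dplyr::mutate(.gkey = paste(norm_id(.data$protein_id), .data$pathway,
                                sep = "\r")) |>
    dplyr::group_by(.data$.gkey) |>
    dplyr::summarise(
      protein_id = dplyr::first(.data$protein_id),
      pathway = dplyr::first(.data$pathway),
      provenance = paste(sort(unique(.data$.prov)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      species = target_species,
      is_new_protein = !norm_id(.data$protein_id) %in% annotated_target
    ) |>
    dplyr::select("species", "protein_id", "pathway", "is_new_protein",
                  "provenance") |>
    dplyr::arrange(norm_id(.data$protein_id), .data$pathway)
  structure(res, class = c("signalog_predictions", class(res)),
            target_species = target_species, threshold = threshold)
}

empty_predictions <- function(target_species, threshold = 0.3) {
  res <- tibble::tibble(species = character(), protein_id = character(),
                        pathway = character(), is_new_protein = logical(),
                        provenance = character())
  structure(res, class = c("signalog_predictions", class(res)),
            target_species = target_species, threshold = threshold)
}

#' Turn a plain tibble into a `signalog_predictions` object
#'
#' For prediction tables assembled by hand or read back from disk.
#'
#' @param x Tibble with columns `species`, `protein_id`, `pathway`, and
#'   optionally `is_new_protein` and `provenance`.
#' @param threshold Threshold recorded on the object.
#' @return A `signalog_predictions` tibble.
#' @export
as_signalog_predictions <- function(x, threshold = 0.3) {
  if (!"is_new_protein" %in% names(x)) x$is_new_protein <- TRUE
  if (!"provenance" %in% names(x)) x$provenance <- ""
  sp <- unique(x$species)
  if (length(sp) > 1) {
    stop("a prediction set must refer to a single species", call. = FALSE)
  }
  x <- tibble::as_tibble(x)[, c("species", "protein_id", "pathway",
                                "is_new_protein", "provenance")]
  structure(x, class = c("signalog_predictions", class(x)),
            target_species = if (length(sp)) sp else NA_character_,
            threshold = threshold)
}

#' Read/write a prediction table
#'
#' @param path File path.
#' @return `read_predictions()` a `signalog_predictions` tibble.
#' @export
read_predictions <- function(path) {
  df <- read_dialect(path, c("species", "protein_id", "pathway",
                             "is_new_protein", "provenance"))
  df$is_new_protein <- df$is_new_protein %in% c("1", "TRUE")
  as_signalog_predictions(df)
}

#' @rdname read_predictions
#' @param predictions Prediction tibble.
#' @param header Optional '#' header line(s).
#' @export
write_predictions <- function(predictions, path, header = NULL) {
  df <- tibble::as_tibble(predictions)
  df$is_new_protein <- as.integer(df$is_new_protein)
  write_dialect(df, path, header = header)
}

#' Summarize a prediction set
#'
#' Counts signalog proteins, predicted pathway annotations, and the
#' multi-pathway subset, plus a per-pathway breakdown. The arithmetic
#' identity `n_annotations == (n_signalog_proteins -
#' n_multi_pathway_proteins) + n_annotations_of_multi` holds by
#' construction. Per-pathway percentages are reported against both
#' plausible denominators — annotations and proteins — since either
#' convention occurs in practice; percentages use one-decimal
#' round-half-even.
#'
#' @param predictions A `signalog_predictions` tibble (or any tibble
#'   with `protein_id` and `pathway` columns).
#' @return A `signalog_summary` list with counts and a `per_pathway`
#'   tibble.
#' @export
summarize_predictions <- function(predictions) {
  df <- tibble::as_tibble(predictions)
  per_protein <- df |>
    dplyr::count(key = norm_id(.data$protein_id), name = "n_pathways")
  n_prot <- nrow(per_protein)
  n_ann <- nrow(df)
  multi <- per_protein[per_protein$n_pathways > 1, , drop = FALSE]
  per_pathway <- df |>
    dplyr::count(.data$pathway, name = "n") |>
    dplyr::mutate(
      pct_of_annotations = percent1(100 * .data$n / max(n_ann, 1)),
      pct_of_proteins = percent1(100 * .data$n / max(n_prot, 1))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$pathway)
  structure(
    list(n_signalog_proteins = n_prot,
         n_annotations = n_ann,
         n_multi_pathway_proteins = nrow(multi),
         n_annotations_of_multi = sum(multi$n_pathways),
         per_pathway = per_pathway),
    class = "signalog_summary"
  )
}

#' @export
print.signalog_summary <- function(x, ...) {
  cat("<signalog_summary>\n")
  cat("  signalog proteins:      ", x$n_signalog_proteins, "\n")
  cat("  pathway annotations:    ", x$n_annotations, "\n")
  cat("  multi-pathway proteins: ", x$n_multi_pathway_proteins,
      " (carrying ", x$n_annotations_of_multi, " annotations)\n", sep = "")
  print(x$per_pathway)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.signalog_predictions <- function(x, ...) {
  df <- tibble::as_tibble(x)
  df |>
    dplyr::mutate(provenance = split_list_field(.data$provenance)) |>
    tidyr::unnest_longer("provenance", values_to = "provenance") |>
    tidyr::separate_wider_delim("provenance", ":",
                                names = c("source_species", "ortholog_id",
                                          "inparalog_score")) |>
    dplyr::mutate(inparalog_score = as.numeric(.data$inparalog_score))
}

#' @export
glance.signalog_predictions <- function(x, ...) {
  s <- summarize_predictions(x)
  tibble::tibble(
    species = attr(x, "target_species"),
    n_signalog_proteins = s$n_signalog_proteins,
    n_annotations = s$n_annotations,
    n_multi_pathway_proteins = s$n_multi_pathway_proteins,
    n_annotations_of_multi = s$n_annotations_of_multi,
    n_new_proteins = sum(tibble::as_tibble(x) |>
                           dplyr::distinct(norm_id(.data$protein_id),
                                           .data$is_new_protein) |>
                           dplyr::pull(.data$is_new_protein))
  )
}

#' @export
tidy.signalog_summary <- function(x, ...) x$per_pathway

#' @export
glance.signalog_summary <- function(x, ...) {
  tibble::tibble(
    n_signalog_proteins = x$n_signalog_proteins,
    n_annotations = x$n_annotations,
    n_multi_pathway_proteins = x$n_multi_pathway_proteins,
    n_annotations_of_multi = x$n_annotations_of_multi
  )
}

#' Orthology-coverage statistics for known signaling proteins
#'
#' Sanity check underpinning annotation transfer: for each species,
#' what fraction of its known (annotated) signaling proteins has at
#' least one ortholog in the other species; of those, what fraction has
#' an ortholog that is itself a known signaling protein; and what
#' fraction has an ortholog annotated to an *identical* pathway. High
#' values justify transferring membership through orthology.
#'
#' @param dataset A `signalog_dataset`.
#' @param maps Ortholog maps; built at `threshold` when `NULL`.
#' @param threshold Inparalog score threshold.
#' @return A `coverage_stats` tibble with one row per species:
#'   `n_annotated`, `frac_with_ortholog`, `frac_ortholog_signaling`,
#'   `frac_identical_pathway` (percentages, one decimal). Species with
#'   no annotated proteins get `NA` fractions with a warning. The
#'   unweighted mean of `frac_ortholog_signaling` is available through
#'   [glance()].
#' @export
coverage_stats <- function(dataset, maps = NULL, threshold = 0.3) {
  if (is.null(maps)) maps <- build_ortholog_maps(dataset, threshold)
  links <- directed_links(maps)
  ann <- dataset$annotations
  ann_key <- paste(norm_id(ann$species), norm_id(ann$protein_id))

  rows <- lapply(sort(dataset$species), function(sp) {
    prot <- unique(norm_id(ann$protein_id[ann$species == sp]))
    if (length(prot) == 0) {
      warning("species ", sp, " has no annotated proteins; ",
              "coverage fractions undefined", call. = FALSE)
      return(tibble::tibble(species = sp, n_annotated = 0L,
                            frac_with_ortholog = NA_real_,
                            frac_ortholog_signaling = NA_real_,
                            frac_identical_pathway = NA_real_))
    }
    lk <- links[links$species == sp, ]
    lk$.p <- norm_id(lk$protein_id)
    lk$.okey <- paste(norm_id(lk$ortholog_species), norm_id(lk$ortholog_id))
    has_orth <- prot %in% lk$.p
    orth_sig <- vapply(prot, function(p) {
      any(lk$.okey[lk$.p == p] %in% ann_key)
    }, logical(1))
    ident <- vapply(prot, function(p) {
      own <- ann$pathway[ann$species == sp & norm_id(ann$protein_id) == p]
      ok <- lk$.okey[lk$.p == p]
      if (length(ok) == 0) return(FALSE)
      any(ann$pathway[paste(norm_id(ann$species),
                            norm_id(ann$protein_id)) %in% ok] %in% own)
    }, logical(1))
    n_with <- sum(has_orth)
    tibble::tibble(
      species = sp, n_annotated = length(prot),
      frac_with_ortholog = percent1(100 * n_with / length(prot)),
      frac_ortholog_signaling =
        if (n_with > 0) percent1(100 * sum(orth_sig) / n_with) else NA_real_,
      frac_identical_pathway =
        if (n_with > 0) percent1(100 * sum(ident) / n_with) else NA_real_
    )
  })
  res <- dplyr::bind_rows(rows)
  structure(res, class = c("coverage_stats", class(res)))
}

#' @export
glance.coverage_stats <- function(x, ...) {
  tibble::tibble(
    mean_with_ortholog = coverage_mean(x$frac_with_ortholog),
    mean_ortholog_signaling = coverage_mean(x$frac_ortholog_signaling),
    mean_identical_pathway = coverage_mean(x$frac_identical_pathway)
  )
}
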