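#' Derive interologs from known interactions via orthology
#'
#' An *interolog* links two proteins of the target species whenever
#' their orthologs interact in at least one other species. Direction
#' and effect sign of the source interaction are dropped — external
#' interolog resources are undirected — but each supporting source
#' interaction is kept as provenance. Self-pairs (a protein linked to
#' itself) are suppressed; a source self-interaction whose endpoints
#' map to two distinct target proteins is allowed.
#'
#' @param dataset A `signalog_dataset` whose `interactions` table
#'   provides the source interactions.
#' @param target_species Species in which interologs are predicted.
#' @param maps Ortholog maps; built at `threshold` when `NULL`.
#' @param threshold Inparalog score threshold.
#' @return An `interolog_set` tibble with columns `species`,
#'   `protein_a`, `protein_b` (canonical order: `norm_id(protein_a) <=
#'   norm_id(protein_b)`) and `provenance` (';'-joined
#'   `"SRC:source->target"` entries), sorted.
#' @export
derive_interologs <- function(dataset, target_species, maps = NULL,
                              threshold = 0.3) {
  if (!target_species %in% dataset$species) {
    stop("target_species ", target_species,
         " is outside the configured species set", call. = FALSE)
  }
  if (is.null(maps)) maps <- build_ortholog_maps(dataset, threshold)
  links <- directed_links(maps)
  links <- links[links$species == target_species, , drop = FALSE]
  ia <- dataset$interactions
  ia <- ia[ia$species != target_species, , drop = FALSE]
  out <- empty_interologs(target_species)
  if (nrow(links) == 0 || nrow(ia) == 0) return(out)

  links$.okey <- paste(norm_id(links$ortholog_species),
                       norm_id(links$ortholog_id))
  ia$.skey <- paste(norm_id(ia$species), norm_id(ia$source_id))
  ia$.tkey <- paste(norm_id(ia$species), norm_id(ia$target_id))
  ia$.id <- seq_len(nrow(ia))

  back <- links[, c(".okey", "protein_id")]
  src <- dplyr::inner_join(ia, back, by = c(".skey" = ".okey"),
                           relationship = "many-to-many") |>
    dplyr::rename(a = "protein_id")
  both <- dplyr::inner_join(src, back, by = c(".tkey" = ".okey"),
                            relationship = "many-to-many") |>
    dplyr::rename(b = "protein_id")
  if (nrow(both) == 0) return(out)
  both <- both[norm_id(both$a) != norm_id(both$b), , drop = FALSE]
  if (nrow(both) == 0) return(out)

  swap <- norm_id(both$a) > norm_id(both$b)
  pa <- ifelse(swap, both$b, both$a)
  pb <- ifelse(swap, both$a, both$b)
  prov <- paste0(both$species, ":", both$source_id, "->", both$target_id)
  res <- tibble::tibble(protein_a = pa, protein_b = pb, .prov = prov) |>
    dplyr::mutate(.gkey = paste(norm_id(.data$protein_a),
                                norm_id(.data$protein_b), sep = "\r")) |>
    dplyr::group_by(.data$.gkey) |>
    dplyr::summarise(
      protein_a = dplyr::first(.data$protein_a),
      protein_b = dplyr::first(.data$protein_b),
      provenance = paste(sort(unique(.data$.prov)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(species = target_species) |>
    dplyr::select("species", "protein_a", "protein_b", "provenance") |>
    dplyr::arrange(norm_id(.data$protein_a), norm_id(.data$protein_b))
  structure(res, class = c("interolog_set", class(res)),
            target_species = target_species)
}

empty_interologs <- function(target_species) {
  res <- tibble::tibble(species = character(), protein_a = character(),
                        protein_b = character(), provenance = character())
  structure(res, class = c("interolog_set", class(res)),
            target_species = target_species)
}

#' Keep only interologs touching a signalog
#'
#' Restricts an interolog set to predicted interactions in which at
#' least one endpoint is a signalog protein, i.e. carries at least one
#' predicted pathway membership.
#'
#' @param interologs An `interolog_set` tibble.
#' @param predictions A `signalog_predictions` tibble for the same
#'   species.
#' @return The filtered `interolog_set`, a subset of the input.
#' @export
filter_signalog_touching <- function(interologs, predictions) {
  sig <- unique(norm_id(predictions$protein_id))
  keep <- norm_id(interologs$protein_a) %in% sig |
    norm_id(interologs$protein_b) %in% sig
  out <- interologs[keep, , drop = FALSE]
  structure(out, class = unique(c("interolog_set", class(out))),
            target_species = attr(interologs, "target_species"))
}

#' Compare two interolog sets
#'
#' Pairs are compared as unordered, case-normalized id pairs; counts are
#' over distinct pairs. The shared-percentage is reported against the
#' union and against either set, since overlap conventions differ
#' between resources.
#'
#' @param set_a,set_b Interolog tibbles (columns `species`, `protein_a`,
#'   `protein_b`) referring to the same species.
#' @return One-row tibble: `n_a`, `n_b`, `n_shared`, `n_only_a`,
#'   `n_only_b`, `pct_shared_of_union`, `pct_shared_of_a`,
#'   `pct_shared_of_b`.
#' @export
compare_interolog_sets <- function(set_a, set_b) {
  sp <- unique(c(set_a$species, set_b$species))
  if (length(sp) > 1) {
    stop("interolog sets refer to different species: ",
         paste(sp, collapse = ", "), call. = FALSE)
  }
  pair_keys <- function(s) {
    if (nrow(s) == 0) return(character())
    a <- norm_id(s$protein_a); b <- norm_id(s$protein_b)
    unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
  }
  ka <- pair_keys(set_a); kb <- pair_keys(set_b)
  n_shared <- length(intersect(ka, kb))
  n_union <- length(union(ka, kb))
  tibble::tibble(
    n_a = length(ka), n_b = length(kb), n_shared = n_shared,
    n_only_a = length(ka) - n_shared, n_only_b = length(kb) - n_shared,
    pct_shared_of_union =
      if (n_union > 0) percent1(100 * n_shared / n_union) else NA_real_,
    pct_shared_of_a =
      if (length(ka) > 0) percent1(100 * n_shared / length(ka)) else NA_real_,
    pct_shared_of_b =
      if (length(kb) > 0) percent1(100 * n_shared / length(kb)) else NA_real_
  )
}

#' Read/write an interolog table
#'
#' @param path File path.
#' @return `read_interologs()` an `interolog_set` tibble.
#' @export
read_interologs <- function(path) {
  df <- read_dialect(path, c("species", "protein_a", "protein_b",
                             "provenance"))
  sp <- unique(df$species)
  structure(df, class = c("interolog_set", class(df)),
            target_species = if (length(sp) == 1) sp else NA_character_)
}

#' @rdname read_interologs
#' @param interologs Interolog tibble.
#' @param header Optional '#' header line(s).
#' @export
write_interologs <- function(interologs, path, header = NULL) {
  write_dialect(tibble::as_tibble(interologs), path, header = header)
}
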