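#' Build a thresholded pairwise ortholog map from clusters
#'
#' Within each cluster covering the species pair, every cross-species
#' member pair is a candidate link. From the perspective of a protein
#' `p`, a counterpart `c` is retained iff `p` has exactly one counterpart
#' in the cluster, or `c`'s inparalog score exceeds the threshold
#' (strict `>`); seed orthologs (score 1.0) always pass. A link is kept
#' only when retained from both perspectives, so the resulting map is
#' symmetric by construction. The default threshold of 0.3 keeps, for
#' multi-ortholog proteins, only counterparts with inparalog score above
#' 0.3.
#'
#' @param clusters Cluster tibble ([read_clusters()]).
#' @param pair Character vector of two species codes (order irrelevant).
#' @param threshold Inparalog score threshold in \[0, 1\]; default 0.3.
#' @return An `ortholog_map`: a tibble with columns `species_a`,
#'   `protein_a`, `score_a`, `species_b`, `protein_b`, `score_b`,
#'   `cluster_id`, where side *a* is the lexicographically smaller
#'   species code. A pair covered by no cluster yields an empty map.
#' @export
#' @examples
#' cl <- tibble::tibble(
#'   cluster_id = "c1", species_pair = "CEL-HSA",
#'   species = c("CEL", "HSA"), protein_id = c("num-1", "NUMB"),
#'   inparalog_score = c(1, 1)
#' )
#' build_ortholog_map(cl, c("CEL", "HSA"))
build_ortholog_map <- function(clusters, pair, threshold = 0.3) {
  stopifnot(length(pair) == 2, pair[1] != pair[2],
            threshold >= 0, threshold <= 1)
  pair <- sort(pair)
  out <- empty_ortholog_map(pair, threshold)
  if (nrow(clusters) == 0) return(out)

  pair_key <- paste(pair, collapse = "-")
  norm_pair <- vapply(strsplit(clusters$species_pair, "-", fixed = TRUE),
                      function(s) paste(sort(s), collapse = "-"),
                      character(1))
  cl <- clusters[norm_pair == pair_key, , drop = FALSE]
  if (nrow(cl) == 0) return(out)

  links <- lapply(split(cl, cl$cluster_id), function(one) {
    a <- one[one$species == pair[1], ]
    b <- one[one$species == pair[2], ]
    if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
    grid <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    keep_b <- nrow(b) == 1 | b$inparalog_score[grid$j] > threshold |
      b$inparalog_score[grid$j] == 1
    keep_a <- nrow(a) == 1 | a$inparalog_score[grid$i] > threshold |
      a$inparalog_score[grid$i] == 1
    grid <- grid[keep_a & keep_b, , drop = FALSE]
    if (nrow(grid) == 0) return(NULL)
    tibble::tibble(
      species_a = pair[1], protein_a = a$protein_id[grid$i],
      score_a = a$inparalog_score[grid$i],
      species_b = pair[2], protein_b = b$protein_id[grid$j],
      score_b = b$inparalog_score[grid$j],
      cluster_id = one$cluster_id[1]
    )
  })
  links <- dplyr::bind_rows(links)
  if (nrow(links) > 0) {
    links <- dplyr::distinct(links) |>
      dplyr::arrange(norm_id(.data$protein_a), norm_id(.data$protein_b),
                     .data$cluster_id)
    out <- links
  }
  structure(out, class = c("ortholog_map", class(tibble::tibble())),
            pair = pair, threshold = threshold)
}

empty_ortholog_map <- function(pair, threshold) {
  structure(
    tibble::tibble(species_a = character(), protein_a = character(),
                   score_a = numeric(), species_b = character(),
                   protein_b = character(), score_b = numeric(),
                   cluster_id = character()),
    class = c("ortholog_map", class(tibble::tibble())),
    pair = pair, threshold = threshold
  )
}

#' Build all pairwise ortholog maps for a dataset
#'
#' @param dataset A `signalog_dataset`.
#' @param threshold Inparalog score threshold; default 0.3.
#' @return List of `ortholog_map` objects, one per species pair.
#' @export
build_ortholog_maps <- function(dataset, threshold = 0.3) {
  pairs <- utils::combn(sort(dataset$species), 2, simplify = FALSE)
  lapply(pairs, function(p) build_ortholog_map(dataset$clusters, p, threshold))
}

#' Query the orthologs of one protein
#'
#' Unions ortholog links for `protein_id` over all maps covering the
#' (protein species, target species) pair. Unknown proteins yield an
#' empty result with a warning.
#'
#' @param maps A single `ortholog_map` or a list of them.
#' @param species Species code of the query protein.
#' @param protein_id Query protein id (matched case-insensitively).
#' @param target_species Species in which orthologs are sought; must
#'   differ from `species`.
#' @param warn_unknown Warn when the protein appears in no cluster?
#' @return Tibble with columns `protein_id`, `inparalog_score` (the
#'   counterpart's score), `cluster_id`.
#' @export
orthologs_of <- function(maps, species, protein_id, target_species,
                         warn_unknown = TRUE) {
  stopifnot(species != target_species)
  if (inherits(maps, "ortholog_map")) maps <- list(maps)
  want <- sort(c(species, target_species))
  hits <- lapply(maps, function(m) {
    if (!identical(attr(m, "pair"), want)) return(NULL)
    if (species == want[1]) {
      sel <- m[norm_id(m$protein_a) == norm_id(protein_id), ]
      tibble::tibble(protein_id = sel$protein_b,
                     inparalog_score = sel$score_b,
                     cluster_id = sel$cluster_id)
    } else {
      sel <- m[norm_id(m$protein_b) == norm_id(protein_id), ]
      tibble::tibble(protein_id = sel$protein_a,
                     inparalog_score = sel$score_a,
                     cluster_id = sel$cluster_id)
    }
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    if (warn_unknown) {
      warning("protein ", protein_id, " (", species,
              ") has no orthologs in any supplied map", call. = FALSE)
    }
    return(tibble::tibble(protein_id = character(),
                          inparalog_score = numeric(),
                          cluster_id = character()))
  }
  dplyr::distinct(out) |>
    dplyr::arrange(norm_id(.data$protein_id), .data$cluster_id)
}

#' Flatten ortholog maps to one directed link table
#'
#' Internal convenience: each undirected link appears twice, once per
#' direction, so per-protein queries are simple joins.
#' @noRd
directed_links <- function(maps) {
  if (inherits(maps, "ortholog_map")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    m <- tibble::as_tibble(m)
    if (nrow(m) == 0) return(NULL)
    dplyr::bind_rows(
      tibble::tibble(species = m$species_a, protein_id = m$protein_a,
                     ortholog_species = m$species_b,
                     ortholog_id = m$protein_b,
                     ortholog_score = m$score_b,
                     cluster_id = m$cluster_id),
      tibble::tibble(species = m$species_b, protein_id = m$protein_b,
                     ortholog_species = m$species_a,
                     ortholog_id = m$protein_a,
                     ortholog_score = m$score_a,
                     cluster_id = m$cluster_id)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(species = character(), protein_id = character(),
                          ortholog_species = character(),
                          ortholog_id = character(),
                          ortholog_score = numeric(),
                          cluster_id = character()))
  }
  dplyr::distinct(out)
}

#' @rdname read_clusters
#' @param map An `ortholog_map`.
#' @export
write_ortholog_map <- function(map, path) {
  df <- tibble::as_tibble(map)
  df$score_a <- format(df$score_a, trim = TRUE, digits = 15)
  df$score_b <- format(df$score_b, trim = TRUE, digits = 15)
  write_dialect(df, path)
}
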