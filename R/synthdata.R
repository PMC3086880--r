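#' Configuration for the synthetic dataset generator
#'
#' Describes the statistical shape of a multi-species signaling dataset:
#' ortholog clusters anchored by seed orthologs (score 1.0) with a
#' Poisson number of extra inparalogs per side scoring uniform (0, 1];
#' sparse pathway annotations, a fraction of which carry a second
#' pathway; and directed interactions among annotated proteins.
#' Defaults emulate curated signaling data at desk scale: roughly
#' 60 proteins per species, 80% of proteins clustered, 40% of clustered
#' proteins annotated, 15% of annotated proteins in two pathways
#' (matching the observed multi-pathway share of curated signaling
#' maps), and 1.5 interactions per annotated protein.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param species Species codes (>= 2).
#' @param n_proteins_per_species Proteins per species (>= 1).
#' @param cluster_coverage Fraction of proteins placed in clusters.
#' @param inparalog_extra_rate Poisson mean of extra inparalogs per
#'   cluster side.
#' @param pathway_vocab Pathway vocabulary.
#' @param annotation_rate Fraction of clustered proteins annotated.
#' @param multi_pathway_rate Fraction of annotated proteins given a
#'   second pathway.
#' @param interaction_density Expected interactions per annotated
#'   protein.
#' @param attribute_flag_rates Named per-flag probabilities for
#'   `is_membrane`, `is_enzyme`, `has_kinase_domain`,
#'   `is_disease_related`, `orthologs_known`, `function_known`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             species = default_species(),
                             n_proteins_per_species = 60L,
                             cluster_coverage = 0.8,
                             inparalog_extra_rate = 0.4,
                             pathway_vocab = default_pathways(),
                             annotation_rate = 0.4,
                             multi_pathway_rate = 0.15,
                             interaction_density = 1.5,
                             attribute_flag_rates = c(
                               is_membrane = 0.3, is_enzyme = 0.4,
                               has_kinase_domain = 0.15,
                               is_disease_related = 0.25,
                               orthologs_known = 0.5,
                               function_known = 0.5)) {
  rates <- c(cluster_coverage = cluster_coverage,
             annotation_rate = annotation_rate,
             multi_pathway_rate = multi_pathway_rate,
             attribute_flag_rates)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0,1]", call. = FALSE)
  }
  if (n_proteins_per_species < 1) {
    stop("n_proteins_per_species must be >= 1", call. = FALSE)
  }
  if (length(species) < 2) stop("need at least two species", call. = FALSE)
  if (inparalog_extra_rate < 0 || interaction_density < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), species = species,
    n_proteins_per_species = as.integer(n_proteins_per_species),
    cluster_coverage = cluster_coverage,
    inparalog_extra_rate = inparalog_extra_rate,
    pathway_vocab = pathway_vocab, annotation_rate = annotation_rate,
    multi_pathway_rate = multi_pathway_rate,
    interaction_density = interaction_density,
    attribute_flag_rates = attribute_flag_rates
  ), class = "generator_config")
}

#' Generate a synthetic multi-species signaling dataset
#'
#' Draws a dataset satisfying every loader invariant: clusters carry
#' exactly one seed ortholog per species, annotations are unique per
#' (protein, pathway), and interactions run within one species among
#' annotated proteins. A single `set.seed()` call at entry plus a fixed
#' stage order (proteins, clusters per species pair, annotations,
#' interactions, attributes) makes output a deterministic function of
#' the config.
#'
#' @param config A [generator_config()].
#' @return A `signalog_dataset`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(seed = 42))
#' ds
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  species <- sort(config$species)
  n <- config$n_proteins_per_species
  proteins <- stats::setNames(
    lapply(species, function(sp) sprintf("%s_p%03d", tolower(sp), seq_len(n))),
    species)

  # clusters, per species pair
  cl_rows <- list()
  for (pr in utils::combn(species, 2, simplify = FALSE)) {
    n_cl <- round(n * config$cluster_coverage)
    if (n_cl == 0) next
    seeds_a <- sample(proteins[[pr[1]]], n_cl)
    seeds_b <- sample(proteins[[pr[2]]], n_cl)
    for (k in seq_len(n_cl)) {
      cid <- sprintf("%s_%s_c%03d", tolower(pr[1]), tolower(pr[2]), k)
      members <- tibble::tibble(
        cluster_id = cid,
        species_pair = paste(pr, collapse = "-"),
        species = c(pr[1], pr[2]),
        protein_id = c(seeds_a[k], seeds_b[k]),
        inparalog_score = c(1, 1)
      )
      for (side in 1:2) {
        n_extra <- stats::rpois(1, config$inparalog_extra_rate)
        pool <- setdiff(proteins[[pr[side]]], members$protein_id)
        n_extra <- min(n_extra, length(pool))
        if (n_extra > 0) {
          extra <- sample(pool, n_extra)
          # uniform on (0,1), kept strictly below the seed score of 1.0
          sc <- pmin(pmax(round(1 - stats::runif(n_extra), 3), 0.001), 0.999)
          members <- dplyr::bind_rows(members, tibble::tibble(
            cluster_id = cid, species_pair = paste(pr, collapse = "-"),
            species = pr[side], protein_id = extra,
            inparalog_score = sc
          ))
        }
      }
      cl_rows[[length(cl_rows) + 1]] <- members
    }
  }
  clusters <- if (length(cl_rows)) dplyr::bind_rows(cl_rows) else
    empty_clusters()

  # annotations among clustered proteins
  ann_rows <- list()
  for (sp in species) {
    clustered <- sort(unique(clusters$protein_id[clusters$species == sp]))
    if (length(clustered) == 0) next
    chosen <- clustered[stats::runif(length(clustered)) <
                          config$annotation_rate]
    for (p in chosen) {
      pws <- sample(config$pathway_vocab, 1)
      if (stats::runif(1) < config$multi_pathway_rate &&
          length(config$pathway_vocab) > 1) {
        pws <- c(pws, sample(setdiff(config$pathway_vocab, pws), 1))
      }
      ann_rows[[length(ann_rows) + 1]] <- tibble::tibble(
        species = sp, protein_id = p, pathway = pws,
        role = sample(ROLES, length(pws), replace = TRUE),
        pmids = lapply(seq_along(pws),
                       function(i) sample.int(99999L, sample(0:2, 1)))
      )
    }
  }
  annotations <- if (length(ann_rows)) dplyr::bind_rows(ann_rows) else
    empty_annotations()

  # directed interactions among annotated proteins
  ia_rows <- list()
  for (sp in species) {
    annotated <- sort(unique(
      annotations$protein_id[annotations$species == sp]))
    if (length(annotated) < 2) next
    n_ia <- round(length(annotated) * config$interaction_density)
    if (n_ia == 0) next
    src <- sample(annotated, n_ia, replace = TRUE)
    tgt <- sample(annotated, n_ia, replace = TRUE)
    keep <- src != tgt
    if (!any(keep)) next
    ia_rows[[length(ia_rows) + 1]] <- tibble::tibble(
      species = sp, source_id = src[keep], target_id = tgt[keep],
      evidence = sample(EVIDENCE, sum(keep), replace = TRUE,
                        prob = c(0.7, 0.3)),
      effect = sample(EFFECTS, sum(keep), replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)),
      pmids = lapply(seq_len(sum(keep)),
                     function(i) sample.int(99999L, sample(0:1, 1)))
    )
  }
  interactions <- if (length(ia_rows)) {
    dplyr::distinct(dplyr::bind_rows(ia_rows),
                    .data$species, .data$source_id, .data$target_id,
                    .keep_all = TRUE)
  } else empty_interactions()

  # per-protein attributes for every protein
  at_rows <- list()
  r <- config$attribute_flag_rates
  for (sp in species) {
    ids <- proteins[[sp]]
    m <- length(ids)
    dis <- stats::runif(m) < r[["is_disease_related"]]
    at_rows[[length(at_rows) + 1]] <- tibble::tibble(
      species = sp, protein_id = ids,
      is_membrane = stats::runif(m) < r[["is_membrane"]],
      is_enzyme = stats::runif(m) < r[["is_enzyme"]],
      has_kinase_domain = stats::runif(m) < r[["has_kinase_domain"]],
      is_disease_related = dis,
      known_drugs = rep(list(character()), m),
      orthologs_known = stats::runif(m) < r[["orthologs_known"]],
      function_known = stats::runif(m) < r[["function_known"]],
      disease_names = lapply(seq_len(m), function(i) {
        if (dis[i]) paste0("disease_", ids[i]) else character()
      })
    )
  }
  attributes <- dplyr::bind_rows(at_rows)

  signalog_dataset(clusters = clusters, annotations = annotations,
                   interactions = interactions, attributes = attributes,
                   species = species, pathways = config$pathway_vocab)
}
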