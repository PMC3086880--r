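# Brute-force oracles and fast random-instance builders, written
# independently of the package internals (plain loops over base data
# frames) so they can serve as references for the vectorized code.

# per-cluster filter: from each perspective, keep a counterpart iff it is
# the only one or its score beats the threshold (seeds always pass)
oracle_ortholog_map <- function(clusters, pair, threshold = 0.3) {
  pair <- sort(pair)
  rows <- data.frame(protein_a = character(), protein_b = character(),
                     cluster_id = character())
  if (nrow(clusters) == 0) return(rows)
  for (cid in unique(clusters$cluster_id)) {
    cl <- clusters[clusters$cluster_id == cid, ]
    sp_pair <- sort(strsplit(cl$species_pair[1], "-", fixed = TRUE)[[1]])
    if (!identical(sp_pair, pair)) next
    a <- cl[cl$species == pair[1], ]
    b <- cl[cl$species == pair[2], ]
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        keep_b <- nrow(b) == 1 || b$inparalog_score[j] > threshold ||
          b$inparalog_score[j] == 1
        keep_a <- nrow(a) == 1 || a$inparalog_score[i] > threshold ||
          a$inparalog_score[i] == 1
        if (keep_a && keep_b) {
          rows <- rbind(rows, data.frame(protein_a = a$protein_id[i],
                                         protein_b = b$protein_id[j],
                                         cluster_id = cid))
        }
      }
    }
  }
  unique(rows)
}

map_keys <- function(m) {
  sort(unique(paste(tolower(m$protein_a), tolower(m$protein_b),
                    m$cluster_id)))
}

# triple loop over (target protein, ortholog, ortholog annotation)
oracle_predict <- function(dataset, target, threshold = 0.3) {
  ann <- dataset$annotations
  known <- paste(tolower(ann$species[ann$species == target]),
                 tolower(ann$protein_id[ann$species == target]),
                 ann$pathway[ann$species == target])
  out <- character()
  others <- setdiff(dataset$species, target)
  for (y in others) {
    m <- oracle_ortholog_map(dataset$clusters, c(target, y), threshold)
    first <- sort(c(target, y))[1]
    for (r in seq_len(nrow(m))) {
      p <- if (first == target) m$protein_a[r] else m$protein_b[r]
      o <- if (first == target) m$protein_b[r] else m$protein_a[r]
      o_ann <- ann[ann$species == y &
                     tolower(ann$protein_id) == tolower(o), ]
      for (pw in o_ann$pathway) {
        k <- paste(tolower(target), tolower(p), pw)
        if (!k %in% known) out <- c(out, paste(tolower(p), pw))
      }
    }
  }
  sort(unique(out))
}

# quadruple loop over (interaction, ortholog of source, ortholog of target)
oracle_interologs <- function(dataset, target, threshold = 0.3) {
  out <- character()
  others <- setdiff(dataset$species, target)
  for (y in others) {
    m <- oracle_ortholog_map(dataset$clusters, c(target, y), threshold)
    first <- sort(c(target, y))[1]
    tgt_col <- if (first == target) "protein_a" else "protein_b"
    oth_col <- if (first == target) "protein_b" else "protein_a"
    ia <- dataset$interactions[dataset$interactions$species == y, ]
    for (r in seq_len(nrow(ia))) {
      as_ <- m[[tgt_col]][tolower(m[[oth_col]]) == tolower(ia$source_id[r])]
      bs_ <- m[[tgt_col]][tolower(m[[oth_col]]) == tolower(ia$target_id[r])]
      for (a in as_) for (b in bs_) {
        if (tolower(a) == tolower(b)) next
        k <- sort(c(tolower(a), tolower(b)))
        out <- c(out, paste(k[1], k[2]))
      }
    }
  }
  sort(unique(out))
}

# fast random instances (vector-built, no per-row tibble work)
rand_clusters <- function(n_clusters = 6, species = c("AAA", "BBB"),
                          max_extra = 3) {
  rows <- list()
  pair <- sort(species)
  for (k in seq_len(n_clusters)) {
    n_a <- 1 + sample(0:max_extra, 1)
    n_b <- 1 + sample(0:max_extra, 1)
    sc_a <- c(1, round(runif(n_a - 1, 0.01, 0.99), 3))
    sc_b <- c(1, round(runif(n_b - 1, 0.01, 0.99), 3))
    rows[[k]] <- data.frame(
      cluster_id = sprintf("c%02d", k),
      species_pair = paste(pair, collapse = "-"),
      species = c(rep(pair[1], n_a), rep(pair[2], n_b)),
      protein_id = c(sprintf("%s_%02d_%d", tolower(pair[1]), k, seq_len(n_a)),
                     sprintf("%s_%02d_%d", tolower(pair[2]), k, seq_len(n_b))),
      inparalog_score = c(sc_a, sc_b)
    )
  }
  tibble::as_tibble(do.call(rbind, rows))
}

rand_dataset <- function(n_per = 8, species = c("AAA", "BBB", "CCC"),
                         n_clusters = 5, p_annot = 0.5, n_int = 6,
                         pathways = default_pathways()[1:4]) {
  prot <- lapply(species, function(sp)
    sprintf("%s_p%02d", tolower(sp), seq_len(n_per)))
  names(prot) <- species
  cl <- list()
  k <- 0
  for (pr in utils::combn(sort(species), 2, simplify = FALSE)) {
    for (i in seq_len(n_clusters)) {
      k <- k + 1
      n_a <- 1 + sample(0:2, 1); n_b <- 1 + sample(0:2, 1)
      mem_a <- sample(prot[[pr[1]]], n_a)
      mem_b <- sample(prot[[pr[2]]], n_b)
      cl[[k]] <- data.frame(
        cluster_id = sprintf("c%03d", k),
        species_pair = paste(pr, collapse = "-"),
        species = c(rep(pr[1], n_a), rep(pr[2], n_b)),
        protein_id = c(mem_a, mem_b),
        inparalog_score = c(1, round(runif(n_a - 1, 0.01, 0.99), 3),
                            1, round(runif(n_b - 1, 0.01, 0.99), 3))
      )
    }
  }
  clusters <- tibble::as_tibble(do.call(rbind, cl))
  ann <- list()
  for (sp in species) {
    chosen <- prot[[sp]][runif(n_per) < p_annot]
    if (length(chosen) == 0) next
    ann[[sp]] <- data.frame(species = sp, protein_id = chosen,
                            pathway = sample(pathways, length(chosen),
                                             replace = TRUE),
                            role = "other")
  }
  annotations <- if (length(ann)) {
    a <- tibble::as_tibble(do.call(rbind, ann))
    a <- a[!duplicated(paste(a$species, tolower(a$protein_id), a$pathway)), ]
    a$pmids <- rep(list(integer()), nrow(a))
    a
  } else {
    signalogr:::empty_annotations()
  }
  ia <- list()
  for (sp in species) {
    src <- sample(prot[[sp]], n_int, replace = TRUE)
    tgt <- sample(prot[[sp]], n_int, replace = TRUE)
    keep <- src != tgt
    if (!any(keep)) next
    ia[[sp]] <- data.frame(species = sp, source_id = src[keep],
                           target_id = tgt[keep], evidence = "direct",
                           effect = "unknown")
  }
  interactions <- if (length(ia)) {
    x <- tibble::as_tibble(do.call(rbind, ia))
    x$pmids <- rep(list(integer()), nrow(x))
    x
  } else {
    signalogr:::empty_interactions()
  }
  signalog_dataset(clusters = clusters, annotations = annotations,
                   interactions = interactions,
                   species = species, pathways = pathways)
}

prediction_keys <- function(p) {
  sort(paste(tolower(p$protein_id), p$pathway))
}

interolog_keys <- function(il) {
  sort(paste(tolower(il$protein_a), tolower(il$protein_b)))
}
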