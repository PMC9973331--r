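#' Configuration for the gene-neighborhood simulator
#'
#' Emulates genome-neighborhood tables of the kind produced by genome
#' neighborhood tools: an anchor gene with up to `n_genes_per_side` neighbors
#' on each side, each neighbor annotated with a protein-family identifier.
#'
#' @param n_neighborhoods number of neighborhoods to generate.
#' @param n_genes_per_side neighbors on each side of the anchor (default 10,
#'   giving a 20-gene window).
#' @param defense_rate probability that a background neighbor carries a
#'   defense-associated family.
#' @param conserved_families list of `list(family_id =, rel_pos =,
#'   occupancy =)` describing families that recur at a fixed position
#'   (e.g. a helicase at +1, a nuclease at +2) with the given occupancy
#'   probability. `rel_pos` must be in `[-n, +n]` excluding 0.
#' @param defense_pool character vector of family ids treated as
#'   defense-associated for background draws.
#' @param background_pool character vector of non-defense family ids.
#' @param seed integer seed.
#' @return object of class `neighborhood_sim_config`.
#' @export
neighborhood_sim_config <- function(n_neighborhoods = 100L,
                                    n_genes_per_side = 10L,
                                    defense_rate = 0.03,
                                    conserved_families = list(),
                                    defense_pool = sprintf("PFdef%03d", 1:8),
                                    background_pool = sprintf("PFbg%03d", 1:40),
                                    seed = 1L) {
  stopifnot(n_neighborhoods >= 1, n_genes_per_side >= 1,
            defense_rate >= 0, defense_rate <= 1)
  for (cf in conserved_families) {
    stopifnot(is.character(cf$family_id),
              cf$rel_pos != 0,
              abs(cf$rel_pos) <= n_genes_per_side,
              cf$occupancy >= 0, cf$occupancy <= 1)
  }
  structure(
    list(n_neighborhoods = as.integer(n_neighborhoods),
         n_genes_per_side = as.integer(n_genes_per_side),
         defense_rate = defense_rate,
         conserved_families = conserved_families,
         defense_pool = defense_pool,
         background_pool = background_pool,
         seed = as.integer(seed)),
    class = "neighborhood_sim_config"
  )
}

#' Simulate gene-neighborhood tables
#'
#' One row per neighbor gene. Conserved families occupy their configured
#' relative position with their occupancy probability; every other slot
#' carries a defense family with probability `defense_rate` and a background
#' family otherwise.
#'
#' @param config a [neighborhood_sim_config()].
#' @return list with
#'   * `neighborhoods`: tibble `neighborhood_id, anchor_id, rel_pos,
#'     family_id`
#'   * `defense_families`: character vector of family ids that count as
#'     defense-associated (the pool plus conserved defense ids).
#' @export
simulate_neighborhoods <- function(config) {
  stopifnot(inherits(config, "neighborhood_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  npos <- config$n_genes_per_side
  rel_pos_all <- setdiff(seq(-npos, npos), 0L)
  conserved_pos <- vapply(config$conserved_families, function(cf) cf$rel_pos,
                          numeric(1))
  rows <- vector("list", config$n_neighborhoods)
  for (i in seq_len(config$n_neighborhoods)) {
    fam <- character(length(rel_pos_all))
    for (j in seq_along(rel_pos_all)) {
      pos <- rel_pos_all[j]
      ci <- match(pos, conserved_pos)
      if (!is.na(ci) &&
          stats::runif(1) < config$conserved_families[[ci]]$occupancy) {
        fam[j] <- config$conserved_families[[ci]]$family_id
      } else if (stats::runif(1) < config$defense_rate) {
        fam[j] <- sample(config$defense_pool, 1)
      } else {
        fam[j] <- sample(config$background_pool, 1)
      }
    }
    rows[[i]] <- tibble::tibble(
      neighborhood_id = sprintf("nbh%04d", i),
      anchor_id = sprintf("anchor%04d", i),
      rel_pos = as.integer(rel_pos_all),
      family_id = fam
    )
  }
  nbh <- dplyr::bind_rows(rows)
  conserved_ids <- vapply(config$conserved_families,
                          function(cf) cf$family_id, character(1))
  list(neighborhoods = nbh,
       defense_families = unique(c(config$defense_pool, conserved_ids)))
}

#' Simulate whole-genome gene tables for the random-neighborhood null
#'
#' Produces per-genome ordered gene lists in which each gene independently
#' carries a defense-associated family with probability `defense_rate`; used
#' as the sampling frame for [random_neighborhood_null()].
#'
#' @param n_genomes number of genomes.
#' @param genes_per_genome genes per genome.
#' @param defense_rate per-gene probability of a defense family.
#' @param defense_pool,background_pool family-id pools as in
#'   [neighborhood_sim_config()].
#' @param seed integer seed.
#' @return list with `genes` (tibble `genome_id, gene_index, family_id`) and
#'   `defense_families`.
#' @export
simulate_gene_tables <- function(n_genomes = 50L, genes_per_genome = 2000L,
                                 defense_rate = 0.03,
                                 defense_pool = sprintf("PFdef%03d", 1:8),
                                 background_pool = sprintf("PFbg%03d", 1:40),
                                 seed = 1L) {
  stopifnot(n_genomes >= 1, genes_per_genome >= 1,
            defense_rate >= 0, defense_rate <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- n_genomes * genes_per_genome
  is_def <- stats::runif(n) < defense_rate
  fam <- character(n)
  fam[is_def] <- sample(defense_pool, sum(is_def), replace = TRUE)
  fam[!is_def] <- sample(background_pool, sum(!is_def), replace = TRUE)
  genes <- tibble::tibble(
    genome_id = rep(sprintf("genome%03d", seq_len(n_genomes)),
                    each = genes_per_genome),
    gene_index = rep(seq_len(genes_per_genome), times = n_genomes),
    family_id = fam
  )
  list(genes = genes, defense_families = defense_pool)
}
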