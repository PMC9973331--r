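#' Read a gene-neighborhood table
#'
#' Accepts the package's TSV layout (`neighborhood_id, anchor_id, rel_pos,
#' family_id`) or any delimited export via a column mapping. A gene with
#' several family annotations carries them in one `family_id` field
#' separated by `;` — all are kept.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param col_map named character vector mapping the canonical column names
#'   to the file's column names, e.g. `c(neighborhood_id = "query",
#'   rel_pos = "position", family_id = "pfam")`.
#' @return tibble `neighborhood_id, anchor_id, rel_pos, family_ids`
#'   (list-column of character vectors).
#' @export
parse_neighborhood_table <- function(path, sep = "\t", col_map = NULL) {
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  canonical <- c("neighborhood_id", "anchor_id", "rel_pos", "family_id")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(canonical, names(raw))
  if ("anchor_id" %in% missing) {
    raw$anchor_id <- raw$neighborhood_id
    missing <- setdiff(missing, "anchor_id")
  }
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  as_neighborhoods(raw)
}

#' Validate and nest a flat neighborhood data frame
#'
#' @param df data frame with `neighborhood_id, anchor_id, rel_pos,
#'   family_id` (the last `;`-separated for multi-family genes).
#' @return tibble with list-column `family_ids`, one row per neighbor gene.
#' @export
as_neighborhoods <- function(df) {
  stopifnot(all(c("neighborhood_id", "anchor_id", "rel_pos", "family_id")
                %in% names(df)))
  df$rel_pos <- as.integer(df$rel_pos)
  if (any(df$rel_pos == 0L)) {
    stop("rel_pos 0 is reserved for the anchor gene")
  }
  dup <- duplicated(df[, c("neighborhood_id", "rel_pos")])
  if (any(dup)) {
    bad <- unique(df$neighborhood_id[dup])
    stop("duplicate rel_pos within neighborhood(s): ",
         paste(bad, collapse = ", "))
  }
  out <- tibble::as_tibble(df[, c("neighborhood_id", "anchor_id",
                                  "rel_pos")])
  out$family_ids <- strsplit(as.character(df$family_id), ";", fixed = TRUE)
  out
}

#' Write neighborhoods in the flat TSV layout
#'
#' @param nbh tibble from [as_neighborhoods()] or
#'   [simulate_neighborhoods()] (`family_id` column or `family_ids`
#'   list-column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood_table <- function(nbh, path) {
  fam <- if ("family_ids" %in% names(nbh)) {
    vapply(nbh$family_ids, paste, character(1), collapse = ";")
  } else {
    nbh$family_id
  }
  flat <- data.frame(neighborhood_id = nbh$neighborhood_id,
                     anchor_id = nbh$anchor_id,
                     rel_pos = nbh$rel_pos, family_id = fam)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.family_list_col <- function(nbh) {
  if ("family_ids" %in% names(nbh)) nbh$family_ids
  else strsplit(as.character(nbh$family_id), ";", fixed = TRUE)
}

#' Count defense-associated genes per neighborhood
#'
#' A neighbor gene counts once if at least one of its protein families is in
#' the defense list, regardless of how many listed families it carries.
#'
#' @param nbh neighborhood tibble (one row per neighbor gene).
#' @param defense_families character vector of defense-associated family
#'   ids.
#' @return tibble `neighborhood_id, defense_count`.
#' @export
count_defense_families <- function(nbh, defense_families) {
  if (length(defense_families) == 0L) {
    stop("defense family list must be nonempty")
  }
  fams <- .family_list_col(nbh)
  is_def <- vapply(fams, function(f) any(f %in% defense_families),
                   logical(1))
  tibble::tibble(neighborhood_id = nbh$neighborhood_id,
                 is_defense = is_def) |>
    dplyr::group_by(.data$neighborhood_id) |>
    dplyr::summarise(defense_count = sum(.data$is_defense),
                     .groups = "drop")
}

#' Random-gene-neighborhood null distribution of defense counts
#'
#' Samples `n_genomes` genomes from the supplied gene tables and, within
#' each, `n_per_genome` uniformly random contiguous windows of `window`
#' genes; returns the defense-gene count of every window. This is the
#' expected (null) distribution against which anchored neighborhoods are
#' compared.
#'
#' @param genes tibble `genome_id, gene_index, family_id` (or `family_ids`
#'   list-column), gene_index ordered along the genome.
#' @param defense_families defense family ids.
#' @param n_genomes genomes to sample (default 50; all if fewer).
#' @param n_per_genome windows per genome (default 20).
#' @param window window width in genes (default 20).
#' @param seed integer seed.
#' @return integer vector of defense counts (length
#'   `n_genomes * n_per_genome`).
#' @export
random_neighborhood_null <- function(genes, defense_families,
                                     n_genomes = 50L, n_per_genome = 20L,
                                     window = 20L, seed = 1L) {
  if (length(defense_families) == 0L) {
    stop("defense family list must be nonempty")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fams <- .family_list_col(genes)
  genes$is_defense <- vapply(fams, function(f) any(f %in% defense_families),
                             logical(1))
  ids <- unique(genes$genome_id)
  take <- if (length(ids) > n_genomes) sample(ids, n_genomes) else ids
  counts <- integer(0)
  for (g in take) {
    def <- genes$is_defense[genes$genome_id == g][
      order(genes$gene_index[genes$genome_id == g])]
    ng <- length(def)
    if (ng < window) {
      warning("genome ", g, " has fewer than ", window, " genes; skipped")
      next
    }
    starts <- sample.int(ng - window + 1L, n_per_genome, replace = TRUE)
    cs <- cumsum(c(0L, def))
    counts <- c(counts, cs[starts + window] - cs[starts])
  }
  counts
}

#' Compare observed neighborhood defense counts with a null
#'
#' @param observed integer vector of defense counts of anchored
#'   neighborhoods (e.g. `defense_count` from
#'   [count_defense_families()]).
#' @param null integer vector from [random_neighborhood_null()].
#' @return list with `observed_mean`, `observed_sd`, `null_mean`,
#'   `null_sd` (sample SDs, n-1 denominator), `difference` of means, and
#'   `proportions`: tibble `defense_count, prop_observed, prop_null`.
#' @export
enrichment_summary <- function(observed, null) {
  stopifnot(length(observed) > 0, length(null) > 0)
  rng <- 0:max(observed, null)
  prop <- tibble::tibble(
    defense_count = rng,
    prop_observed = as.numeric(table(factor(observed, levels = rng))) /
      length(observed),
    prop_null = as.numeric(table(factor(null, levels = rng))) /
      length(null)
  )
  list(observed_mean = mean(observed), observed_sd = stats::sd(observed),
       null_mean = mean(null), null_sd = stats::sd(null),
       difference = mean(observed) - mean(null),
       proportions = prop)
}

#' Positional frequency of the most common neighbor families
#'
#' Ranks families by total occurrence across neighborhoods and tabulates,
#' for the top `top_n` (ties at the boundary are all included, in
#' lexicographic order), how often each occurs at every relative position.
#'
#' @param nbh neighborhood tibble (one row per neighbor gene).
#' @param top_n number of top families (default 5).
#' @return tibble `family_id, rel_pos, count` restricted to the top
#'   families; `family_id` is a factor ordered by rank.
#' @export
positional_frequency <- function(nbh, top_n = 5L) {
  fams <- .family_list_col(nbh)
  flat <- tibble::tibble(
    rel_pos = rep(nbh$rel_pos, lengths(fams)),
    family_id = unlist(fams)
  )
  totals <- flat |>
    dplyr::count(.data$family_id, name = "total") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$family_id)
  if (nrow(totals) > top_n) {
    cutoff <- totals$total[top_n]
    totals <- totals[totals$total >= cutoff, ]
  }
  keep <- totals$family_id
  out <- flat |>
    dplyr::filter(.data$family_id %in% keep) |>
    dplyr::count(.data$family_id, .data$rel_pos, name = "count")
  out$family_id <- factor(out$family_id, levels = keep)
  dplyr::arrange(out, .data$family_id, .data$rel_pos)
}
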