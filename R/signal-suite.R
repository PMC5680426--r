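#' Default taxonomic group definitions
#'
#' Builds the standard seven analysis levels from the taxonomy columns of an
#' aggregated species table: all species; macroinvertebrates (from `group`);
#' each phylum among Chordata, Arthropoda, Mollusca; and the chordate classes
#' fish and amphibians (from `class`).  Groups whose defining column is
#' absent, or that match no species, are dropped.
#'
#' @param species_values Tibble from [aggregate_species()] including whatever
#'   of `phylum`, `class`, `group` are available.
#' @return Named list of character vectors of species.
#' @export
default_species_groups <- function(species_values) {
  sv <- species_values
  groups <- list(all = sv$species)
  pick <- function(col, value) {
    if (!col %in% names(sv)) return(character(0))
    sv$species[!is.na(sv[[col]]) & sv[[col]] == value]
  }
  groups$macroinvertebrates <- pick("group", "macroinvertebrate")
  groups$Chordata <- pick("phylum", "Chordata")
  groups$Arthropoda <- pick("phylum", "Arthropoda")
  groups$Mollusca <- pick("phylum", "Mollusca")
  groups$fish <- pick("class", "fish")
  groups$amphibians <- pick("class", "amphibian")
  groups[lengths(groups) > 0]
}

#' Run the full phylogenetic-signal suite over taxonomic groups
#'
#' For each group: prunes the tree to the group's species, aligns the
#' aggregated trait values, and computes maximum-likelihood Pagel's lambda
#' with its likelihood-ratio test, Blomberg's K with its permutation test,
#' and a Mantel test of patristic versus trait distances.  Groups with fewer
#' than 4 species present in the tree are skipped with a warning and recorded
#' in the `skipped` attribute; species present in the trait table but absent
#' from the tree are recorded in the `dropped_species` attribute.
#'
#' @param species_values Tibble with columns `species` and `lc50` (see
#'   [aggregate_species()]).
#' @param tree `phylo` tree; Grafen branch lengths are assigned when the tree
#'   carries none.
#' @param groups Named list of species subsets; default
#'   [default_species_groups()].
#' @param n_perm Permutations for the K and Mantel tests (default 999).
#' @param seed Integer seed governing every permutation stream.
#' @param trait_scale `"raw"` (mg/L) or `"log10"`; applied to the aggregated
#'   species values before all statistics.
#' @param regrafen_after_prune If TRUE, recompute Grafen lengths on each
#'   pruned subtree instead of keeping the merged full-tree lengths
#'   (default FALSE, the standard drop-tip behaviour).
#' @param rho Grafen power used whenever Grafen lengths are (re)computed.
#' @return Tibble with one row per analysed group: `group`, `n_species`,
#'   `lambda`, `p_lambda`, `K`, `p_K`, `mantel_r`, `p_mantel`, `n_perm`,
#'   `seed`, `trait_scale`; attributes `skipped` and `dropped_species`.
#' @export
run_signal_suite <- function(species_values, tree, groups = NULL,
                             n_perm = 999, seed = 1,
                             trait_scale = c("raw", "log10"),
                             regrafen_after_prune = FALSE, rho = 1) {
  trait_scale <- match.arg(trait_scale)
  stopifnot(is.data.frame(species_values), all(c("species", "lc50") %in% names(species_values)))
  validate_tree(tree)
  if (is.null(tree$edge.length)) tree <- grafen_branch_lengths(tree, rho = rho)
  if (is.null(groups)) groups <- default_species_groups(species_values)
  if (!length(groups)) abort("Empty group list.")
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    abort("Groups must be a uniquely named list.")
  }

  values <- setNames(species_values$lc50, species_values$species)
  if (trait_scale == "log10") values <- log10(values)
  dropped <- setdiff(names(values), tree$tip.label)
  if (length(dropped)) {
    inform(sprintf(
      "%d species in the trait table are absent from the tree and were dropped: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }

  skipped <- character(0)
  rows <- purrr::imap(groups, function(spp, gname) {
    spp <- intersect(intersect(spp, names(values)), tree$tip.label)
    if (length(spp) < 4) {
      warn(sprintf("Group '%s' has %d species in the tree (< 4); skipped.", gname, length(spp)))
      skipped <<- c(skipped, gname)
      return(NULL)
    }
    sub <- prune_to_taxa(tree, spp)
    if (regrafen_after_prune) sub <- grafen_branch_lengths(sub, rho = rho)
    x <- values[sub$tip.label]
    lam <- estimate_lambda(x, sub)
    kt <- permutation_test_K(x, sub, n_perm = n_perm, seed = split_seed(seed, 10L))
    mt <- mantel_test(
      patristic_distances(sub), trait_distance_matrix(x),
      n_perm = n_perm, seed = split_seed(seed, 11L)
    )
    tibble::tibble(
      group = gname, n_species = length(x),
      lambda = lam$lambda, p_lambda = lam$p_value,
      K = kt$K, p_K = kt$p_value,
      mantel_r = mt$r, p_mantel = mt$p_value,
      n_perm = as.integer(n_perm), seed = as.integer(seed),
      trait_scale = trait_scale
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  attr(out, "dropped_species") <- dropped
  out
}
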