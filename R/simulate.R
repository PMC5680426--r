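# Seeded generators emulating the statistical structure both analysis arms
# assume.  Each generator derives its own RNG stream from the user seed via
# split_seed(), so adding a call to one generator never shifts another's
# stream.

#' Simulate a Yule (pure-birth) tree
#'
#' Starts from two lineages at the root, waits exponential times with total
#' rate `k * birth_rate` while `k` lineages are extant, splits a uniformly
#' chosen lineage at each event, and after reaching `n_tips` extends all
#' lineages by one final waiting time so every pendant branch is positive.
#' The result is an ultrametric binary tree — the substrate the
#' Grafen-scaled comparative analyses run on.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Integer seed; identical seeds give identical Newick output.
#' @return An ultrametric `phylo` tree with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  withr::with_seed(split_seed(seed, 3L), {
    next_id <- 0L
    new_id <- function() {
      next_id <<- next_id + 1L
      next_id
    }
    root <- new_id()
    act_parent <- c(root, root)
    act_start <- c(0, 0)
    t <- 0
    k <- 2L
    ep <- integer(0)
    ec <- integer(0)
    el <- numeric(0)
    while (k < n_tips) {
      t <- t + rexp(1, k * birth_rate)
      i <- sample.int(k, 1)
      node <- new_id()
      ep <- c(ep, act_parent[i])
      ec <- c(ec, node)
      el <- c(el, t - act_start[i])
      act_parent[i] <- node
      act_start[i] <- t
      act_parent <- c(act_parent, node)
      act_start <- c(act_start, t)
      k <- k + 1L
    }
    t_final <- t + rexp(1, k * birth_rate)
    tip_ids <- integer(k)
    for (i in seq_len(k)) {
      tip <- new_id()
      ep <- c(ep, act_parent[i])
      ec <- c(ec, tip)
      el <- c(el, t_final - act_start[i])
      tip_ids[i] <- tip
    }
    internal_ids <- setdiff(sort(unique(ep)), tip_ids)
    internal_ids <- c(root, setdiff(internal_ids, root))
    remap <- integer(next_id)
    remap[tip_ids] <- seq_len(k)
    remap[internal_ids] <- k + seq_along(internal_ids)
    tree <- structure(
      list(
        edge = cbind(remap[ep], remap[ec]),
        edge.length = el,
        tip.label = paste0("t", seq_len(k)),
        Nnode = length(internal_ids)
      ),
      class = "phylo"
    )
    tree <- ape::reorder.phylo(tree, "cladewise")
    validate_tree(tree)
    tree
  })
}

#' Simulate trait values under (lambda-scaled) Brownian motion
#'
#' Draws one tip-trait vector from a multivariate normal with mean
#' `root_state` and covariance `sigma2 * lambda_transform(phylo_vcv(tree),
#' lambda_true)`, via a symmetric eigen factorization.  `lambda_true = 1` is
#' pure Brownian motion; `lambda_true = 0` makes tips independent.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param sigma2 Brownian rate (>= 0); 0 returns `root_state` at every tip.
#' @param root_state Trait value at the root.
#' @param lambda_true Pagel's lambda used for the simulation, in
#'   `[0, lambda_max]` of the tree's covariance.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, root_state = 0,
                               lambda_true = 1, seed = 1) {
  validate_tree(tree)
  stopifnot(sigma2 >= 0)
  labs <- tree$tip.label
  if (sigma2 == 0) {
    return(setNames(rep(root_state, length(labs)), labs))
  }
  C <- phylo_vcv(tree)
  Cl <- lambda_transform(C, lambda_true)
  e <- eigen(Cl, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)) * sqrt(sigma2), nrow(Cl))
  withr::with_seed(split_seed(seed, 4L), {
    z <- rnorm(nrow(Cl))
    setNames(root_state + drop(A %*% z), labs)
  })
}

#' Simulate acute-exposure mortality data
#'
#' Emulates the ten-pond acute-exposure design: for each of two population
#' types (`roadside`, `woodland`), `ponds_per_type` ponds receive every
#' concentration in `concentrations` replicated `replicates` times with
#' `n_per_unit` larvae per container.  Unit mortality follows a logit-linear
#' dose response `logit p = beta0[type] + beta1[type] * conc + b_pond +
#' b_unit` with `b_pond ~ N(0, sigma_pond^2)` and an observation-level
#' `b_unit ~ N(0, sigma_unit^2)` producing overdispersion; deaths are
#' binomial.  Defaults mirror the study design: concentrations
#' `{0, 3800, 5100, 6500, 7300}` mg/L Cl, 4 replicates of 10 larvae, 5 ponds
#' per type (200 units), per-type true LC50s of 3412 (roadside) and 4395
#' (woodland) mg/L with slope 1.5e-3 per mg/L, and moderate logit-scale
#' heterogeneity of 0.3 at both levels.
#'
#' @param ponds_per_type Ponds per population type.
#' @param concentrations Distinct chloride doses, mg/L.
#' @param replicates Containers per pond x concentration.
#' @param n_per_unit Larvae per container.
#' @param lc50 Named per-type true LC50s (mg/L); with `slope` they set
#'   `beta0 = -slope * lc50` unless `beta0`/`beta1` are given directly.
#' @param slope Named per-type logit slopes per mg/L (> 0 for mortality
#'   rising with dose).
#' @param beta0,beta1 Optional named per-type logit intercept/slope,
#'   overriding `lc50`/`slope`.
#' @param sigma_pond,sigma_unit Logit-scale SDs of the pond and unit random
#'   intercepts (>= 0).
#' @param seed Integer seed.
#' @return Mortality tibble (`pond_id, type, conc_mg_l, replicate,
#'   n_exposed, n_dead`) with `ponds_per_type * 2 * length(concentrations) *
#'   replicates` rows.
#' @examples
#' sim <- simulate_mortality(seed = 7)
#' nrow(sim) # 200 experimental units
#' @export
simulate_mortality <- function(ponds_per_type = 5,
                               concentrations = c(0, 3800, 5100, 6500, 7300),
                               replicates = 4, n_per_unit = 10,
                               lc50 = c(roadside = 3412, woodland = 4395),
                               slope = c(roadside = 1.5e-3, woodland = 1.5e-3),
                               beta0 = NULL, beta1 = NULL,
                               sigma_pond = 0.3, sigma_unit = 0.3, seed = 1) {
  stopifnot(
    ponds_per_type >= 1, replicates >= 1, n_per_unit >= 1,
    sigma_pond >= 0, sigma_unit >= 0,
    !anyDuplicated(concentrations)
  )
  types <- c("roadside", "woodland")
  if (is.null(beta1)) beta1 <- slope[types]
  if (is.null(beta0)) beta0 <- -beta1 * lc50[types]
  beta0 <- setNames(rep_len(unname(beta0), 2), types)
  beta1 <- setNames(rep_len(unname(beta1), 2), types)

  grid <- tidyr::expand_grid(
    type = types,
    pond = seq_len(ponds_per_type),
    conc_mg_l = as.numeric(concentrations),
    replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(pond_id = paste0(.data$type, "_", .data$pond))

  withr::with_seed(split_seed(seed, 5L), {
    ponds <- unique(grid$pond_id)
    b_pond <- setNames(rnorm(length(ponds), 0, sigma_pond), ponds)
    b_unit <- rnorm(nrow(grid), 0, sigma_unit)
    eta <- beta0[grid$type] + beta1[grid$type] * grid$conc_mg_l +
      b_pond[grid$pond_id] + b_unit
    p <- plogis(unname(eta))
    grid |>
      dplyr::transmute(
        pond_id = .data$pond_id,
        type = .data$type,
        conc_mg_l = .data$conc_mg_l,
        replicate = .data$replicate,
        n_exposed = as.integer(n_per_unit),
        n_dead = rbinom(dplyr::n(), n_per_unit, p)
      )
  })
}

#' Simulate a species-trait compilation on a tree
#'
#' Convenience generator for pipeline tests and examples: evolves
#' log10(LC50) by lambda-scaled Brownian motion on `tree`, back-transforms to
#' mg/L, and emits one single-study record per species with a two-clade
#' taxonomy derived from the root split (labels `PhylumA` / `PhylumB`, the
#' latter tagged `macroinvertebrate`).  Clearly synthetic: no real taxa.
#'
#' @inheritParams simulate_bm_traits
#' @param root_log10_lc50 Root state on the log10 mg/L scale (default 3.5,
#'   i.e. ~3160 mg/L).
#' @param duration_h Exposure duration recorded on every record.
#' @return Trait-record tibble accepted by [aggregate_species()].
#' @export
simulate_trait_dataset <- function(tree, sigma2 = 0.25, root_log10_lc50 = 3.5,
                                   lambda_true = 1, duration_h = 96, seed = 1) {
  x <- simulate_bm_traits(tree,
    sigma2 = sigma2, root_state = root_log10_lc50,
    lambda_true = lambda_true, seed = seed
  )
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  first_clade <- if (kids[1] <= ape::Ntip(tree)) {
    tree$tip.label[kids[1]]
  } else {
    ape::extract.clade(tree, kids[1])$tip.label
  }
  phylum <- ifelse(names(x) %in% first_clade, "PhylumA", "PhylumB")
  tibble::tibble(
    species = names(x),
    study = "synthetic",
    lc50_mg_l = 10^unname(x),
    duration_h = duration_h,
    phylum = phylum,
    class = NA_character_,
    group = ifelse(phylum == "PhylumB", "macroinvertebrate", NA_character_)
  )
}
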