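#' Specification of a simulated comparative dataset
#'
#' Defines the generative model for a tree-plus-traits dataset: a pure-birth
#' ultrametric phylogeny, tip size proxies `vl` drawn log-uniformly, and for
#' each trait `log(tp) = intercept + a * log(vl) + lifestyle offset +
#' phylogenetically correlated residual` (Brownian motion with Pagel-lambda
#' rescaling). Traits are exported on the raw (exponentiated) scale so the
#' analysis stage's log transform is exercised.
#'
#' The defaults emulate the composition of a sciuromorph femoral-head
#' comparative study: 69 species in 33 genera, 27 arboreal / 19 fossorial /
#' 15 semifossorial / 8 aerial (clade-clustered), slopes equal to observed
#' femoral-head scaling exponents, and realistic rodent trait baselines at
#' vl = 1 mm.
#'
#' @param n_species number of tips (>= 8).
#' @param birth_rate pure-birth speciation rate.
#' @param slopes named vector of log-log slopes against `vl` per trait.
#' @param intercepts named vector of log trait values at vl = 1 mm.
#' @param lifestyle_offsets matrix (lifestyle x trait) of additive log-scale
#'   shifts, or `NULL` for none.
#' @param bm_sigma Brownian residual standard deviation at unit tree height
#'   (log scale), >= 0.
#' @param lambda_true phylogenetic signal of the residuals in \[0, 1\].
#' @param vl_range interval (mm) for the log-uniform `vl` draw.
#' @param lifestyle_counts named integer vector of tips per lifestyle
#'   (must sum to `n_species`, each >= 2).
#' @param lifestyle_assignment `"clade"` (paint contiguous clades, mimicking
#'   phylogenetically clustered lifestyles) or `"random"`.
#' @param n_genera number of genus labels (monophyletic groups).
#' @param mass_coef mass (g) at vl = 1 mm for the optional body-mass column.
#' @param mass_sigma lognormal noise sd of body mass around isometry
#'   (exponent 3).
#' @param seed integer seed; all randomness flows from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_species = 69L,
                            birth_rate = 1,
                            slopes = c(DA = -0.193, ConnD = -2.138,
                                       TbTh = 0.835, TbSp = 0.593,
                                       BVTV = 0.166, BSBV = -0.829),
                            intercepts = log(c(DA = 0.65, ConnD = 50,
                                               TbTh = 0.10, TbSp = 0.25,
                                               BVTV = 0.40, BSBV = 20)),
                            lifestyle_offsets = NULL,
                            bm_sigma = 0.2,
                            lambda_true = 0.8,
                            vl_range = c(0.5, 5),
                            lifestyle_counts = NULL,
                            lifestyle_assignment = c("clade", "random"),
                            n_genera = NULL,
                            mass_coef = 60,
                            mass_sigma = 0.59,
                            seed = 1L) {
  lifestyle_assignment <- match.arg(lifestyle_assignment)
  n_species <- as.integer(n_species)
  if (n_species < 8L) stop("n_species must be >= 8")
  if (bm_sigma < 0) stop("bm_sigma must be >= 0")
  if (lambda_true < 0 || lambda_true > 1)
    stop("lambda_true must be in [0, 1]")
  if (vl_range[1] <= 0 || vl_range[2] <= vl_range[1])
    stop("vl_range must be an increasing positive interval")
  lifestyles <- c("arboreal", "fossorial", "semifossorial", "aerial")
  if (is.null(lifestyle_counts)) {
    if (n_species == 69L) {
      lifestyle_counts <- c(arboreal = 27L, fossorial = 19L,
                            semifossorial = 15L, aerial = 8L)
    } else {
      base <- pmax(2L, floor(n_species * c(27, 19, 15, 8) / 69))
      while (sum(base) > n_species) base[which.max(base)] <-
          base[which.max(base)] - 1L
      base[1] <- base[1] + (n_species - sum(base))
      lifestyle_counts <- setNames(base, lifestyles)
    }
  }
  if (sum(lifestyle_counts) != n_species)
    stop("lifestyle_counts must sum to n_species")
  if (any(lifestyle_counts < 2L))
    stop("each lifestyle needs >= 2 species")
  if (is.null(n_genera))
    n_genera <- if (n_species == 69L) 33L else max(1L, n_species %/% 2L)
  if (n_genera > n_species) stop("n_genera cannot exceed n_species")
  stopifnot(setequal(names(slopes), names(intercepts)))
  if (!is.null(lifestyle_offsets)) {
    lifestyle_offsets <- as.matrix(lifestyle_offsets)
    if (!setequal(rownames(lifestyle_offsets), lifestyles) ||
        !all(colnames(lifestyle_offsets) %in% names(slopes)))
      stop("lifestyle_offsets must be a lifestyle x trait matrix")
  }
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 slopes = slopes, intercepts = intercepts,
                 lifestyle_offsets = lifestyle_offsets,
                 bm_sigma = bm_sigma, lambda_true = lambda_true,
                 vl_range = vl_range, lifestyle_counts = lifestyle_counts,
                 lifestyle_assignment = lifestyle_assignment,
                 n_genera = as.integer(n_genera),
                 mass_coef = mass_coef, mass_sigma = mass_sigma,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a comparative dataset (tree + trait table)
#'
#' @param spec a [simulation_spec()].
#' @return A list of class `trab_simulation` with `tree` (an
#'   `ape::phylo`, ultrametric, unit height), `traits` (data frame with
#'   columns species, genus, lifestyle, vl, mass and one column per trait on
#'   the raw scale), and `spec`.
#' @export
simulate_comparative_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_species
    tree <- ape::rphylo(n, birth = spec$birth_rate, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(n))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth

    genus <- genus_partition(tree, spec$n_genera)
    lifestyle <- assign_lifestyles(tree, spec$lifestyle_counts,
                                   spec$lifestyle_assignment)

    log_vl <- runif(n, log(spec$vl_range[1]), log(spec$vl_range[2]))

    V <- ape::vcv.phylo(tree)
    Vl <- V * spec$lambda_true
    diag(Vl) <- diag(V)
    Ul <- chol(Vl)

    traits <- data.frame(species = tree$tip.label,
                         genus = genus,
                         lifestyle = lifestyle,
                         vl = exp(log_vl),
                         stringsAsFactors = FALSE)
    log_mass <- log(spec$mass_coef) + 3 * log_vl +
      rnorm(n, sd = spec$mass_sigma)
    traits$mass <- exp(log_mass)
    for (tp in names(spec$slopes)) {
      resid <- if (spec$bm_sigma > 0)
        spec$bm_sigma * drop(crossprod(Ul, rnorm(n))) else numeric(n)
      off <- if (is.null(spec$lifestyle_offsets)) 0 else
        spec$lifestyle_offsets[lifestyle, tp]
      traits[[tp]] <- exp(spec$intercepts[tp] + spec$slopes[tp] * log_vl +
                            off + resid)
    }
    structure(list(tree = tree, traits = traits, spec = spec),
              class = "trab_simulation")
  })
}

#' @export
print.trab_simulation <- function(x, ...) {
  cat(sprintf("Simulated comparative dataset: %d species, %d genera\n",
              nrow(x$traits), length(unique(x$traits$genus))))
  print(table(x$traits$lifestyle))
  invisible(x)
}

# children of each node, from the edge matrix
node_children <- function(tree) {
  split(tree$edge[, 2], tree$edge[, 1])
}

clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- node_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= n) out <- c(out, nd)
    else stack <- c(stack, kids[[as.character(nd)]])
  }
  out
}

# split the tree into k monophyletic groups by repeatedly splitting the
# largest current group at its root
genus_partition <- function(tree, k) {
  n <- length(tree$tip.label)
  kids <- node_children(tree)
  nodes <- ape::Ntip(tree) + 1L  # start from the root
  sizes <- n
  while (length(nodes) < k) {
    splittable <- which(sizes > 1L & nodes > n)
    if (!length(splittable)) break
    i <- splittable[which.max(sizes[splittable])]
    ch <- kids[[as.character(nodes[i])]]
    nodes <- c(nodes[-i], ch)
    sizes <- c(sizes[-i], vapply(ch, function(nd)
      length(clade_tips(tree, nd)), 1L))
  }
  genus <- character(n)
  ord <- order(vapply(nodes, function(nd) min(clade_tips(tree, nd)), 1L))
  for (gi in seq_along(ord)) {
    genus[clade_tips(tree, nodes[ord[gi]])] <- sprintf("genus%02d", gi)
  }
  genus
}

# paint lifestyles over the tree: either clade-clustered (greedily assign
# the largest whole clades that fit each quota, smallest lifestyle first)
# or uniformly at random
assign_lifestyles <- function(tree, counts, mode) {
  n <- length(tree$tip.label)
  lifestyle <- rep(NA_character_, n)
  if (mode == "random") {
    lifestyle <- sample(rep(names(counts), counts))
    return(lifestyle)
  }
  # all clades (including singletons) as tip index sets
  all_nodes <- c(seq_len(n), (n + 2L):(n + tree$Nnode))
  clades <- lapply(all_nodes, function(nd) clade_tips(tree, nd))
  ord_ls <- names(sort(counts))
  for (ls in ord_ls[-length(ord_ls)]) {
    quota <- counts[[ls]]
    while (quota > 0L) {
      fits <- which(vapply(clades, function(tp)
        length(tp) <= quota && all(is.na(lifestyle[tp])), TRUE))
      sz <- vapply(clades[fits], length, 1L)
      best <- fits[sz == max(sz)]
      pick <- if (length(best) > 1L) sample(best, 1L) else best
      lifestyle[clades[[pick]]] <- ls
      quota <- quota - length(clades[[pick]])
    }
  }
  lifestyle[is.na(lifestyle)] <- ord_ls[length(ord_ls)]
  lifestyle
}
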