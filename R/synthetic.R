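#' Simulate a host phylogeny
#'
#' Birth-death tree conditioned on the number of extant tips, via
#' [ape::rphylo()]. With the default speciation rate of 0.2 per Myr
#' (extinction 0), a few-hundred-tip tree has a crown age of tens of
#' millions of years, on the scale of a mammalian order. Deterministic
#' per seed.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param model `"yule"` (pure birth) or `"birth_death"`.
#' @param lambda speciation rate (per Myr; must exceed `mu_bd`).
#' @param mu_bd extinction rate (per Myr; >= 0; forced to 0 for
#'   `"yule"`).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a `phylo` with tip labels `t1..tn` and branch lengths in Myr.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "birth_death"),
                          lambda = 0.2, mu_bd = 0, seed = NULL) {
  model <- match.arg(model)
  if (n_tips < 2) stop("'n_tips' must be >= 2")
  if (model == "yule") mu_bd <- 0
  if (!(lambda > mu_bd && mu_bd >= 0))
    stop("rates must satisfy lambda > mu_bd >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = lambda, death = mu_bd)
  validate_tree(tr)
  tr
}

#' Simulate a phylogenetically structured host-parasite network
#'
#' Each parasite picks a uniformly random focal host and then infects
#' every other host independently with probability `exp(-d / phi)`, where
#' `d` is the patristic distance to the focal host and `phi` is the
#' phylogenetic decay length of host sharing (Myr). Small `phi` yields
#' specialists; large `phi` yields generalists spread across the tree.
#' The focal host is always infected, so richness is at least 1.
#'
#' @param tree host phylogeny.
#' @param n_parasites number of parasites to draw.
#' @param phi decay length of infection probability (Myr, > 0).
#' @param attributes host attribute table (e.g. from [assign_status()]);
#'   defaults to all-LC, non-domesticated, extant hosts.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a [host_parasite_network()] with parasites `sp1..spn`.
#' @export
simulate_network <- function(tree, n_parasites, phi, attributes = NULL,
                             seed = NULL) {
  validate_tree(tree)
  if (phi <= 0) stop("'phi' must be > 0")
  if (n_parasites < 1) stop("'n_parasites' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tips <- tree$tip.label
  dm <- ape::cophenetic.phylo(tree)
  edges <- vector("list", n_parasites)
  for (i in seq_len(n_parasites)) {
    focal <- sample(tips, 1L)
    p_inf <- exp(-dm[focal, ] / phi)
    hit <- tips[stats::runif(length(tips)) < p_inf]
    hit <- union(focal, hit)
    edges[[i]] <- data.frame(parasite = paste0("sp", i), host = hit)
  }
  edges <- do.call(rbind, edges)
  if (is.null(attributes))
    attributes <- data.frame(host = tips, iucn_status = "LC",
                             domesticated = FALSE, extinct = FALSE)
  host_parasite_network(edges, attributes)
}

#' Simulate trait-biased IUCN threat statuses
#'
#' Emulates non-random, trait-biased extinction risk: log body mass
#' evolves as Brownian motion on the tree (so mass is geometric Brownian
#' motion), and the probability of being threatened follows a logistic
#' model on the standardised predictor,
#' `P(threatened) = plogis(alpha + beta * z)`, where `z` is standardised
#' log mass (`bias = "mass"`) or standardised equal-splits ED
#' (`bias = "ed"`). Threatened hosts are assigned CR, EN, VU, NT by
#' descending risk quartile; all others are LC. Optionally the `n_extinct`
#' highest-risk hosts are flagged extinct. Deterministic per seed.
#'
#' @param tree host phylogeny.
#' @param alpha logistic intercept (default -1.1, i.e. roughly a quarter
#'   of hosts threatened at average mass, matching the global mammal
#'   assessment's order of magnitude).
#' @param beta logistic slope on the standardised predictor (default 0.8:
#'   markedly higher risk for the largest-bodied hosts).
#' @param bias `"mass"` or `"ed"` — which trait drives risk.
#' @param root_log_mass Brownian root state for log mass (default
#'   `log(1000)`, a 1 kg mammal).
#' @param sigma Brownian standard deviation of log mass per sqrt(Myr).
#' @param n_extinct flag the `n_extinct` highest-risk hosts as extinct.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return host attribute data frame (`host`, `iucn_status`,
#'   `domesticated`, `extinct`, `body_mass_g`).
#' @export
assign_status <- function(tree, alpha = -1.1, beta = 0.8,
                          bias = c("mass", "ed"),
                          root_log_mass = log(1000), sigma = 0.4,
                          n_extinct = 0, seed = NULL) {
  validate_tree(tree)
  bias <- match.arg(bias)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lm_ <- ape::rTraitCont(tree, model = "BM", sigma = sigma,
                         root.value = root_log_mass)
  lm_ <- lm_[tree$tip.label]
  z <- if (bias == "mass") as.numeric(scale(lm_))
  else as.numeric(scale(ed_equal_splits(tree)[tree$tip.label]))
  if (any(!is.finite(z))) z[] <- 0  # degenerate: no trait variance
  risk <- stats::plogis(alpha + beta * z)
  threatened <- stats::runif(length(risk)) < risk
  status <- rep("LC", length(risk))
  if (any(threatened)) {
    # among threatened hosts: most at risk -> CR, then EN, VU, NT
    q <- stats::quantile(risk[threatened], probs = c(0.25, 0.5, 0.75))
    cat_idx <- findInterval(risk[threatened], q, left.open = TRUE)
    status[threatened] <- c("NT", "VU", "EN", "CR")[cat_idx + 1L]
  }
  extinct <- rep(FALSE, length(risk))
  if (n_extinct > 0)
    extinct[order(risk, decreasing = TRUE)[seq_len(min(n_extinct,
                                                       length(risk)))]] <- TRUE
  data.frame(host = tree$tip.label, iucn_status = status,
             domesticated = FALSE, extinct = extinct,
             body_mass_g = unname(exp(lm_)), row.names = NULL)
}

#' Toy single-host-loss fixtures
#'
#' The canonical 3-tip tree `((A:1,B:1):2,C:3)` with four parasite
#' configurations that, under the loss of one host each, realise the four
#' qualitative outcomes of a single extinction: coextinction of a
#' specialist; a two-host parasite reduced to a single host; an apparent
#' specialist (MPD decreases, 14/3 -> 2); and an apparent generalist
#' (MPD increases, 14/3 -> 6).
#'
#' @return list with `tree`, `net` and `cases` (data frame `panel`,
#'   `parasite`, `lost_host`, `expected_outcome`).
#' @export
fixture_fig1 <- function() {
  tree <- read_newick("((A:1,B:1):2,C:3);")
  edges <- data.frame(
    parasite = c("Pa", "Pb", "Pb", "Pc", "Pc", "Pc", "Pd", "Pd", "Pd"),
    host = c("C", "A", "B", "A", "B", "C", "A", "B", "C"))
  attrs <- data.frame(host = c("A", "B", "C"), iucn_status = "LC",
                      domesticated = FALSE, extinct = FALSE)
  net <- host_parasite_network(edges, attrs)
  cases <- data.frame(
    panel = c("a", "b", "c", "d"),
    parasite = c("Pa", "Pb", "Pc", "Pd"),
    lost_host = c("C", "B", "C", "B"),
    expected_outcome = c("coextinction", "reduced_to_single_host",
                         "mpd_decrease", "mpd_increase"))
  list(tree = tree, net = net, cases = cases)
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact plain-text formats the pipeline consumes: a Newick
#' tree, a CSV association edge list and a CSV host attribute table.
#'
#' @param dir output directory (created if needed).
#' @param n_tips,n_parasites,phi,seed simulation parameters; see
#'   [simulate_tree()], [simulate_network()], [assign_status()].
#' @param ... further arguments passed to [assign_status()].
#' @return invisibly, the named paths written.
#' @export
write_synth_fixtures <- function(dir, n_tips = 100, n_parasites = 50,
                                 phi = 10, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(n_tips, seed = seed)
  attrs <- assign_status(tree, seed = seed + 1L, ...)
  net <- simulate_network(tree, n_parasites, phi, attributes = attrs,
                          seed = seed + 2L)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             edges = file.path(dir, "edges.csv"),
             attributes = file.path(dir, "attributes.csv"))
  write_newick(tree, paths[["tree"]])
  el <- do.call(rbind, lapply(network_parasites(net), function(p)
    data.frame(parasite = p, host = net$assoc[[p]])))
  utils::write.csv(el, paths[["edges"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(attrs, paths[["attributes"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
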