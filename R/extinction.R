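#' Coextinction rule
#'
#' Decides when a parasite counts as coextinct during a scenario run.
#' `"all_hosts_lost"` declares a parasite coextinct only when none of its
#' documented hosts survives. `"min_hosts_k"` models obligate multi-host
#' parasites that need at least `k` host species to persist: coextinct as
#' soon as surviving richness drops below `k`.
#'
#' @param mode `"all_hosts_lost"` or `"min_hosts_k"`.
#' @param k minimum number of surviving hosts (>= 1); only for
#'   `"min_hosts_k"`.
#' @return an object of class `coextinction_rule`.
#' @export
coextinction_rule <- function(mode = c("all_hosts_lost", "min_hosts_k"),
                              k = NULL) {
  mode <- match.arg(mode)
  if (mode == "min_hosts_k") {
    if (is.null(k) || !is.numeric(k) || k < 1 || k != round(k))
      stop("'k' must be an integer >= 1 for mode 'min_hosts_k'")
    k <- as.integer(k)
  } else {
    k <- 1L
  }
  structure(list(mode = mode, k = k), class = "coextinction_rule")
}

is_coextinct <- function(rule, richness) {
  if (rule$mode == "all_hosts_lost") richness == 0L else richness < rule$k
}

#' Extinction scenario
#'
#' An ordered list of removal events, each a non-empty set of host labels.
#' Events must be pairwise disjoint.
#'
#' @param events list of character vectors (hosts removed at each step).
#'   Empty events are allowed (a threat category can be empty).
#' @param provenance one of `"iucn_ordered"`, `"random_order"`, `"custom"`.
#' @param seed integer seed recorded for randomised scenarios.
#' @return an object of class `extinction_scenario`.
#' @export
extinction_scenario <- function(events, provenance = "custom", seed = NULL) {
  provenance <- match.arg(provenance,
                          c("iucn_ordered", "random_order", "custom"))
  events <- lapply(events, as.character)
  all_h <- unlist(events)
  if (anyDuplicated(all_h))
    stop("scenario events must be pairwise disjoint; repeated: ",
         paste(unique(all_h[duplicated(all_h)]), collapse = ", "))
  structure(list(events = events, provenance = provenance, seed = seed),
            class = "extinction_scenario")
}

#' @export
print.extinction_scenario <- function(x, ...) {
  cat("Extinction scenario (", x$provenance, "): ", length(x$events),
      " event(s), ", length(unlist(x$events)), " host(s) removed",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  for (i in seq_along(x$events)) {
    ev <- x$events[[i]]
    lab <- if (!is.null(names(x$events))) names(x$events)[i] else i
    cat("  ", lab, ": ",
        if (length(ev)) paste(ev, collapse = ", ") else "(empty)",
        "\n", sep = "")
  }
  invisible(x)
}

# effective IUCN status: domesticated and DD hosts are treated as LC
# (they are not assessed as threatened, so they are retained in every
# threat-ordered scenario)
effective_status <- function(hosts) {
  st <- hosts$iucn_status
  st[hosts$domesticated | st == "DD"] <- "LC"
  st
}

#' Threat-ordered extinction scenario
#'
#' Four batch events removing hosts by IUCN status in the order CR, EN,
#' VU, NT. Domesticated and Data Deficient hosts are treated as LC and are
#' never removed. Empty categories produce empty (kept) events.
#'
#' @param net a [host_parasite_network()].
#' @return an [extinction_scenario()] with provenance `"iucn_ordered"`.
#' @export
iucn_scenario <- function(net) {
  st <- effective_status(net$hosts)
  ev <- lapply(c(CR = "CR", EN = "EN", VU = "VU", NT = "NT"),
               function(s) sort(net$hosts$host[st == s]))
  empty <- names(ev)[lengths(ev) == 0L]
  if (length(empty))
    message("empty threat categories kept as empty events: ",
            paste(empty, collapse = ", "))
  extinction_scenario(ev, provenance = "iucn_ordered")
}

#' Randomised single-host extinction order for one parasite
#'
#' A uniformly random permutation of the parasite's documented hosts
#' (minus `exclusions`, e.g. humans and domesticated species), one host
#' removed per event. The same seed reproduces the same order.
#'
#' @param net a [host_parasite_network()].
#' @param parasite parasite label.
#' @param exclusions host labels never removed.
#' @param seed integer seed.
#' @return an [extinction_scenario()] with provenance `"random_order"`.
#' @export
random_order_scenario <- function(net, parasite, exclusions = character(),
                                  seed) {
  check_parasite(net, parasite)
  eligible <- setdiff(net$assoc[[parasite]], exclusions)
  if (length(eligible) == 0L)
    stop("no eligible hosts for ", parasite, " after exclusions")
  set.seed(as.integer(seed))
  ord <- sample(eligible)
  extinction_scenario(as.list(ord), provenance = "random_order",
                      seed = as.integer(seed))
}

#' Run an extinction scenario
#'
#' Steps through the scenario's removal events against a network and host
#' phylogeny. Step 0 is the pre-extinction baseline; at each subsequent
#' step the event's hosts are removed, parasites violating the
#' coextinction rule become (and stay) coextinct, and per-parasite
#' richness and MPD are recomputed on the surviving host set. Change in
#' MPD is reported relative to the step-0 baseline.
#'
#' @param scenario an [extinction_scenario()].
#' @param net a [host_parasite_network()]; its hosts must all be tips of
#'   `tree` (see [drop_missing_hosts()] for name-mismatch handling).
#' @param tree host phylogeny (`phylo`).
#' @param rule a [coextinction_rule()].
#' @return an object of class `extinction_trajectory`: a list with
#'   `steps` (long data frame: `step`, `parasite`, `host_richness`,
#'   `mpd`, `state`, `delta_mpd`), `surviving_n`, `newly_coextinct`,
#'   plus the scenario and rule.
#' @examples
#' fx <- fixture_fig1()
#' sc <- extinction_scenario(list("C", "B"))
#' run_scenario(sc, fx$net, fx$tree)
#' @export
run_scenario <- function(scenario, net, tree,
                         rule = coextinction_rule("all_hosts_lost")) {
  stopifnot(inherits(scenario, "extinction_scenario"),
            inherits(net, "host_parasite_network"),
            inherits(rule, "coextinction_rule"))
  validate_tree(tree)
  hosts <- network_hosts(net)
  unknown <- setdiff(unlist(scenario$events), hosts)
  if (length(unknown))
    stop("scenario removes hosts absent from network: ",
         paste(unknown, collapse = ", "))
  miss <- setdiff(unique(unlist(net$assoc)), tree$tip.label)
  if (length(miss))
    stop("host(s) missing from tree: ", paste(miss, collapse = ", "))

  surviving <- hosts
  coex <- character(0)
  steps <- vector("list", length(scenario$events) + 1L)
  newly <- vector("list", length(scenario$events) + 1L)
  surv_n <- integer(length(scenario$events) + 1L)
  baseline <- NULL
  for (s in seq_along(steps)) {
    if (s > 1L) surviving <- setdiff(surviving, scenario$events[[s - 1L]])
    tab <- specificity_table(net, tree, surviving)
    now_coex <- tab$parasite[is_coextinct(rule, tab$host_richness)]
    newly[[s]] <- setdiff(now_coex, coex)
    coex <- union(coex, now_coex)
    tab$state <- ifelse(tab$parasite %in% coex, "coextinct", "extant")
    if (s == 1L) baseline <- stats::setNames(tab$mpd, tab$parasite)
    tab$delta_mpd <- tab$mpd - baseline[tab$parasite]
    tab$step <- s - 1L
    steps[[s]] <- tab
    surv_n[s] <- length(surviving)
  }
  steps <- do.call(rbind, steps)
  steps <- steps[, c("step", "parasite", "host_richness", "mpd", "state",
                     "delta_mpd")]
  rownames(steps) <- NULL
  structure(list(steps = steps, surviving_n = surv_n,
                 newly_coextinct = newly, scenario = scenario, rule = rule),
            class = "extinction_trajectory")
}

#' @export
print.extinction_trajectory <- function(x, ...) {
  ns <- length(x$surviving_n)
  final <- x$steps[x$steps$step == ns - 1L, ]
  cat("Extinction trajectory:", ns - 1L, "step(s),",
      x$surviving_n[1L], "->", x$surviving_n[ns], "hosts\n")
  cat("Coextinct parasites:", sum(final$state == "coextinct"), "of",
      nrow(final), "\n")
  invisible(x)
}

#' @export
summary.extinction_trajectory <- function(object, ...) {
  st <- object$steps
  out <- do.call(rbind, lapply(split(st, st$step), function(d) {
    data.frame(step = d$step[1L],
               surviving_hosts = object$surviving_n[d$step[1L] + 1L],
               extant_parasites = sum(d$state == "extant"),
               coextinct = sum(d$state == "coextinct"),
               mean_mpd = mean(d$mpd[d$state == "extant"]),
               mean_delta_mpd = mean(d$delta_mpd[d$state == "extant"]))
  }))
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.extinction_trajectory <- function(x, ...) x$steps

#' Plot MPD trajectories per parasite
#'
#' One line per parasite, MPD against extinction step; lines stop where a
#' parasite goes coextinct.
#'
#' @param x an `extinction_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.extinction_trajectory <- function(x, ...) {
  st <- x$steps
  wide <- stats::reshape(st[, c("step", "parasite", "mpd")],
                         idvar = "step", timevar = "parasite",
                         direction = "wide")
  wide <- wide[order(wide$step), ]
  graphics::matplot(wide$step, as.matrix(wide[, -1L, drop = FALSE]),
                    type = "l", lty = 1,
                    xlab = "extinction step", ylab = "MPD (Myr)", ...)
  invisible(x)
}

#' Classify per-parasite outcomes of a single host loss
#'
#' For the loss of one host, each parasite in the network receives exactly
#' one label: `unaffected` (host not documented for it), `coextinction`
#' (it was a single-host parasite of the lost host),
#' `reduced_to_single_host` (a two-host parasite becomes a specialist), or
#' for parasites with three or more hosts, `mpd_decrease` /
#' `mpd_increase` / `unchanged` by comparing MPD before and after the loss
#' (tolerance 1e-9).
#'
#' @param net a [host_parasite_network()].
#' @param tree host phylogeny.
#' @param lost_host the host that goes extinct.
#' @return named character vector, one outcome per parasite.
#' @examples
#' fx <- fixture_fig1()
#' classify_outcome(fx$net, fx$tree, "C")
#' @export
classify_outcome <- function(net, tree, lost_host) {
  if (!lost_host %in% network_hosts(net))
    stop("unknown host: ", lost_host)
  hosts <- network_hosts(net)
  surv <- setdiff(hosts, lost_host)
  out <- vapply(network_parasites(net), function(p) {
    doc <- net$assoc[[p]]
    if (!lost_host %in% doc) return("unaffected")
    r <- length(doc)
    if (r == 1L) return("coextinction")
    if (r == 2L) return("reduced_to_single_host")
    before <- mpd(net, p, tree)
    after <- mpd(net, p, tree, surviving = surv)
    if (abs(after - before) <= 1e-9) "unchanged"
    else if (after < before) "mpd_decrease"
    else "mpd_increase"
  }, character(1))
  out
}

#' ED gains from pruning extinct taxa
#'
#' Computes per-tip equal-splits evolutionary distinctiveness on the full
#' tree (`ed_full`, i.e. including taxa now extinct) and on the tree
#' pruned to the survivors (`ed_extant`), and the gain
#' `ed_extant - ed_full`. As close relatives are lost, a surviving tip
#' inherits a larger share of the tree, so gains are non-negative for
#' every survivor. Extinct tips get NA `ed_extant` and `gain`.
#'
#' @param full_tree phylogeny including extinct taxa.
#' @param extinct_tips labels of the extinct tips (may be empty; must
#'   leave at least one survivor).
#' @return data frame with columns `tip`, `ed_full`, `ed_extant`, `gain`.
#' @examples
#' ed_shift(read_newick("((A:1,B:1):2,C:3);"), "B")
#' @export
ed_shift <- function(full_tree, extinct_tips = character(0)) {
  validate_tree(full_tree)
  extinct_tips <- as.character(extinct_tips)
  unknown <- setdiff(extinct_tips, full_tree$tip.label)
  if (length(unknown))
    stop("extinct tips not in tree: ", paste(unknown, collapse = ", "))
  survivors <- setdiff(full_tree$tip.label, extinct_tips)
  if (length(survivors) == 0L) stop("all tips extinct: no survivors")
  ed_full <- ed_equal_splits(full_tree)
  ed_ext <- if (length(extinct_tips) == 0L) ed_full else
    ed_equal_splits(prune_to(full_tree, survivors))
  tips <- full_tree$tip.label
  data.frame(tip = tips,
             ed_full = unname(ed_full[tips]),
             ed_extant = unname(ed_ext[tips]),
             gain = unname(ed_ext[tips] - ed_full[tips]),
             row.names = NULL)
}

#' Projected MPD under a keep-statuses extinction scenario
#'
#' For each parasite, current MPD and the MPD after the extinction of all
#' hosts except those whose (effective) IUCN status is in
#' `keep_statuses` — by default LC and DD, i.e. the loss of every
#' currently threatened host. Domesticated hosts are treated as LC.
#' Parasites with no surviving host are tagged coextinct with NA
#' `mpd_after`.
#'
#' @param net a [host_parasite_network()].
#' @param tree host phylogeny.
#' @param keep_statuses statuses whose hosts survive.
#' @return data frame `parasite`, `mpd_now`, `mpd_after`, `state`.
#' @export
delta_mpd_projection <- function(net, tree, keep_statuses = c("LC", "DD")) {
  bad <- setdiff(keep_statuses, IUCN_CODES)
  if (length(bad)) stop("unknown IUCN code(s): ", paste(bad, collapse = ", "))
  st <- effective_status(net$hosts)
  keep <- net$hosts$host[st %in% keep_statuses |
                           net$hosts$iucn_status %in% keep_statuses]
  now <- specificity_table(net, tree)
  after <- specificity_table(net, tree, surviving = keep)
  data.frame(parasite = now$parasite,
             mpd_now = now$mpd,
             mpd_after = after$mpd[match(now$parasite, after$parasite)],
             state = after$state[match(now$parasite, after$parasite)],
             row.names = NULL)
}

#' Drop network hosts absent from a tree
#'
#' Taxon-name mismatch between an association database and a phylogeny is
#' the dominant real-world failure mode, so the pipeline errors on it by
#' default. This helper implements the explicit opt-in alternative:
#' remove the offending hosts from the network (and any parasite left
#' hostless), with a message listing what was dropped.
#'
#' @param net a [host_parasite_network()].
#' @param tree host phylogeny.
#' @return the reduced network.
#' @export
drop_missing_hosts <- function(net, tree) {
  miss <- setdiff(network_hosts(net), tree$tip.label)
  if (length(miss) == 0L) return(net)
  message("dropping ", length(miss), " host(s) absent from tree: ",
          paste(miss, collapse = ", "))
  assoc <- lapply(net$assoc, setdiff, y = miss)
  lost <- names(assoc)[lengths(assoc) == 0L]
  if (length(lost))
    message("dropping ", length(lost),
            " parasite(s) left with no host: ", paste(lost, collapse = ", "))
  assoc <- assoc[lengths(assoc) > 0L]
  hosts <- net$hosts[!net$hosts$host %in% miss, , drop = FALSE]
  rownames(hosts) <- NULL
  structure(list(assoc = assoc, hosts = hosts),
            class = "host_parasite_network")
}
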