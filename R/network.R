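IUCN_CODES <- c("CR", "EN", "VU", "NT", "LC", "DD")

#' Construct a host-parasite association network
#'
#' Bipartite mapping from parasites to their documented host species, with
#' a host attribute table carrying IUCN threat status, domestication and
#' extinct flags and (optionally) body mass. Duplicate association rows
#' are deduplicated with a message; hosts named in the edge list but
#' absent from the attribute table are an error.
#'
#' @param associations data frame with character columns `parasite` and
#'   `host`, one row per documented association.
#' @param host_attributes data frame with columns `host`, `iucn_status`
#'   (one of CR, EN, VU, NT, LC, DD), `domesticated`, `extinct` (logical
#'   or 0/1) and optionally `body_mass_g` (positive).
#' @return an object of class `host_parasite_network`: a list with
#'   elements `assoc` (named list, parasite -> character vector of hosts)
#'   and `hosts` (the attribute data frame, keyed by `host`).
#' @examples
#' net <- host_parasite_network(
#'   data.frame(parasite = c("P1", "P1", "P2"), host = c("A", "B", "C")),
#'   data.frame(host = c("A", "B", "C"), iucn_status = c("LC", "EN", "LC"),
#'              domesticated = FALSE, extinct = FALSE))
#' net
#' @export
host_parasite_network <- function(associations, host_attributes) {
  need <- c("parasite", "host")
  if (!all(need %in% names(associations)))
    stop("association table must have columns 'parasite' and 'host'")
  associations <- associations[, need]
  associations[] <- lapply(associations, as.character)
  if (nrow(associations) == 0L) stop("association table is empty")
  if (anyNA(associations) || any(!nzchar(unlist(associations))))
    stop("empty parasite or host label in association table")
  ndup <- sum(duplicated(associations))
  if (ndup > 0) {
    message("deduplicated ", ndup, " repeated association row(s)")
    associations <- unique(associations)
  }
  hosts <- validate_host_attributes(host_attributes)
  missing <- setdiff(unique(associations$host), hosts$host)
  if (length(missing))
    stop("hosts in edge list missing from attribute table: ",
         paste(sort(missing), collapse = ", "))
  assoc <- lapply(split(associations$host, associations$parasite),
                  function(h) sort(unique(h)))
  structure(list(assoc = assoc, hosts = hosts),
            class = "host_parasite_network")
}

validate_host_attributes <- function(hosts) {
  need <- c("host", "iucn_status", "domesticated", "extinct")
  if (!all(need %in% names(hosts)))
    stop("attribute table must have columns: ", paste(need, collapse = ", "))
  hosts$host <- as.character(hosts$host)
  if (anyNA(hosts$host) || any(!nzchar(hosts$host)))
    stop("empty host label in attribute table")
  if (anyDuplicated(hosts$host))
    stop("duplicate hosts in attribute table: ",
         paste(unique(hosts$host[duplicated(hosts$host)]), collapse = ", "))
  hosts$iucn_status <- toupper(as.character(hosts$iucn_status))
  bad <- setdiff(unique(hosts$iucn_status), IUCN_CODES)
  if (length(bad))
    stop("unknown IUCN status code(s): ", paste(bad, collapse = ", "))
  for (fl in c("domesticated", "extinct")) {
    v <- hosts[[fl]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
    v <- as.logical(v)
    if (anyNA(v)) stop("column '", fl, "' must be logical (TRUE/FALSE)")
    hosts[[fl]] <- v
  }
  if ("body_mass_g" %in% names(hosts)) {
    m <- as.numeric(hosts$body_mass_g)
    if (any(!is.na(m) & m <= 0)) stop("body_mass_g must be positive")
    hosts$body_mass_g <- m
  }
  rownames(hosts) <- NULL
  hosts
}

#' Read a network from CSV files
#'
#' @param edge_file CSV with header `parasite,host`.
#' @param attr_file CSV with header
#'   `host,iucn_status,domesticated,extinct[,body_mass_g]`.
#' @return a [host_parasite_network()].
#' @export
read_associations <- function(edge_file, attr_file) {
  for (f in c(edge_file, attr_file))
    if (!file.exists(f)) stop("file not found: ", f)
  edges <- utils::read.csv(edge_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  attrs <- utils::read.csv(attr_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  host_parasite_network(edges, attrs)
}

#' @export
print.host_parasite_network <- function(x, ...) {
  rich <- lengths(x$assoc)
  cat("Host-parasite network:", length(x$assoc), "parasites,",
      nrow(x$hosts), "hosts,", sum(rich), "associations\n")
  cat("Host richness per parasite: median", stats::median(rich),
      "range", min(rich), "-", max(rich), "\n")
  st <- table(factor(x$hosts$iucn_status, levels = IUCN_CODES))
  cat("IUCN:", paste(names(st), st, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Hosts of a network
#' @param net a `host_parasite_network`.
#' @return character vector of all host labels.
#' @export
network_hosts <- function(net) net$hosts$host

#' Parasites of a network
#' @param net a `host_parasite_network`.
#' @return character vector of all parasite labels.
#' @export
network_parasites <- function(net) names(net$assoc)

check_parasite <- function(net, parasite) {
  if (!parasite %in% names(net$assoc)) stop("unknown parasite: ", parasite)
  invisible(parasite)
}

#' Surviving host richness of a parasite
#'
#' Number of a parasite's documented hosts present in the surviving host
#' set.
#'
#' @param net a `host_parasite_network`.
#' @param parasite parasite label.
#' @param surviving character vector of surviving host labels (defaults to
#'   all hosts).
#' @return integer count (0 when all documented hosts are lost).
#' @export
host_richness <- function(net, parasite, surviving = network_hosts(net)) {
  check_parasite(net, parasite)
  length(intersect(net$assoc[[parasite]], surviving))
}

#' Mean pairwise phylogenetic distance among a parasite's hosts
#'
#' The phylogenetic host-specificity metric: the unweighted mean of
#' patristic distances over all unordered pairs of the parasite's
#' surviving documented hosts. A parasite with exactly one surviving host
#' has MPD 0 by convention; a parasite with no surviving host is
#' coextinct and MPD is an error here (use [specificity_table()] to keep
#' coextinct parasites tagged in bulk output).
#'
#' @inheritParams host_richness
#' @param tree host phylogeny (`phylo`); all surviving documented hosts
#'   must be tips.
#' @return MPD in Myr.
#' @examples
#' tr <- read_newick("((A:1,B:1):2,C:3);")
#' net <- host_parasite_network(
#'   data.frame(parasite = "P1", host = c("A", "B", "C")),
#'   data.frame(host = c("A", "B", "C"), iucn_status = "LC",
#'              domesticated = FALSE, extinct = FALSE))
#' mpd(net, "P1", tr) # 14/3
#' @export
mpd <- function(net, parasite, tree, surviving = network_hosts(net)) {
  check_parasite(net, parasite)
  hs <- intersect(net$assoc[[parasite]], surviving)
  if (length(hs) == 0L)
    stop("parasite coextinct: no surviving documented host for ", parasite)
  miss <- setdiff(hs, tree$tip.label)
  if (length(miss))
    stop("host(s) missing from tree: ", paste(miss, collapse = ", "))
  if (length(hs) == 1L) return(0)
  dm <- ape::cophenetic.phylo(ape::keep.tip(tree, hs))
  mean(dm[lower.tri(dm)])
}

#' Per-parasite specificity table at a community state
#'
#' One record per parasite in the network: surviving host richness, MPD
#' (NA once no documented host survives) and a state tag. Coextinct
#' parasites are tagged, never dropped, so downstream trajectories can
#' count coextinctions.
#'
#' @inheritParams mpd
#' @return data frame with columns `parasite`, `host_richness`, `mpd`,
#'   `state` (`"extant"` or `"coextinct"`).
#' @export
specificity_table <- function(net, tree, surviving = network_hosts(net)) {
  ps <- network_parasites(net)
  if (length(ps) == 0L)
    return(data.frame(parasite = character(), host_richness = integer(),
                      mpd = numeric(), state = character()))
  alive <- lapply(net$assoc, intersect, y = surviving)
  union_hosts <- sort(unique(unlist(alive)))
  miss <- setdiff(union_hosts, tree$tip.label)
  if (length(miss))
    stop("host(s) missing from tree: ", paste(miss, collapse = ", "))
  dm <- if (length(union_hosts) >= 2L)
    ape::cophenetic.phylo(ape::keep.tip(tree, union_hosts)) else NULL
  rich <- lengths(alive)
  mpd_v <- vapply(ps, function(p) {
    h <- alive[[p]]
    if (length(h) == 0L) return(NA_real_)
    if (length(h) == 1L) return(0)
    sub <- dm[h, h]
    mean(sub[lower.tri(sub)])
  }, numeric(1))
  data.frame(parasite = ps,
             host_richness = as.integer(rich[ps]),
             mpd = unname(mpd_v),
             state = ifelse(rich[ps] == 0L, "coextinct", "extant"),
             row.names = NULL)
}
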