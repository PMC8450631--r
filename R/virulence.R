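#' Host class for the multi-host virulence model
#'
#' One host species (or clade) in a multi-host parasite system, described
#' by its relative contribution to the total force of infection and the
#' parameters of the transmission-virulence trade-off
#' `w(v) = b * v^s / (mu + v)`: exploitation raises transmission with
#' diminishing returns (exponent `s`), while higher virulence shortens
#' infections (loss rate `mu` plus disease-induced mortality `v`).
#'
#' @param id host label.
#' @param rho relative contribution to the total force of infection
#'   (>= 0; normalised across a system).
#' @param mu background loss rate of infections (per Myr-free time unit,
#'   > 0).
#' @param b transmission scale (> 0).
#' @param s trade-off exponent, 0 < s < 1 (guarantees a unimodal fitness
#'   curve with an interior optimum).
#' @return an object of class `host_class`.
#' @export
host_class <- function(id, rho, mu, b = 1, s = 0.5) {
  if (!is.character(id) || !nzchar(id)) stop("'id' must be a non-empty label")
  if (!is.numeric(rho) || rho < 0) stop("'rho' must be >= 0")
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be > 0")
  if (!is.numeric(b) || b <= 0) stop("'b' must be > 0")
  if (!is.numeric(s) || s <= 0 || s >= 1) stop("'s' must be in (0, 1)")
  structure(list(id = id, rho = rho, mu = mu, b = b, s = s),
            class = "host_class")
}

#' Multi-host parasite system
#'
#' A set of host classes sharing a single parasite with one virulence
#' strategy across all hosts (no host-specific plasticity). Force-of-
#' infection weights `rho` are normalised to sum to 1.
#'
#' @param hosts list of [host_class()] objects (>= 1), or a data frame
#'   with columns `id`, `rho`, `mu`, `b`, `s`.
#' @return an object of class `multi_host_system`.
#' @examples
#' sys <- multi_host_system(list(
#'   host_class("H1", rho = 0.7, mu = 1, s = 0.5),
#'   host_class("H2", rho = 0.3, mu = 4, s = 0.5)))
#' joint_optimum(sys)
#' @export
multi_host_system <- function(hosts) {
  if (is.data.frame(hosts)) {
    need <- c("id", "rho", "mu", "b", "s")
    if (!all(need %in% names(hosts)))
      stop("host table must have columns: ", paste(need, collapse = ", "))
    hosts <- lapply(seq_len(nrow(hosts)), function(i)
      host_class(as.character(hosts$id[i]), hosts$rho[i], hosts$mu[i],
                 hosts$b[i], hosts$s[i]))
  }
  if (length(hosts) < 1L) stop("need at least one host class")
  if (!all(vapply(hosts, inherits, logical(1), "host_class")))
    stop("'hosts' must be a list of host_class objects")
  ids <- vapply(hosts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate host ids")
  rho <- vapply(hosts, `[[`, numeric(1), "rho")
  if (sum(rho) <= 0) stop("at least one rho must be positive")
  rho <- rho / sum(rho)
  for (i in seq_along(hosts)) hosts[[i]]$rho <- rho[i]
  names(hosts) <- ids
  structure(list(hosts = hosts), class = "multi_host_system")
}

#' @export
print.multi_host_system <- function(x, ...) {
  cat("Multi-host system with", length(x$hosts), "host class(es):\n")
  for (h in x$hosts)
    cat(sprintf("  %s: rho=%.3f mu=%.3g b=%.3g s=%.3g (v* = %.4g)\n",
                h$id, h$rho, h$mu, h$b, h$s, single_host_optimum(h)))
  cat(sprintf("joint optimal virulence: %.6g\n", joint_optimum(x)))
  invisible(x)
}

#' Parasite fitness on one host at virulence v
#'
#' The transmission-virulence trade-off `w(v) = b * v^s / (mu + v)`:
#' zero at `v = 0`, unimodal with an interior maximum, and decaying to 0
#' as `v` grows (since `s < 1`).
#'
#' @param host a [host_class()].
#' @param v virulence (>= 0); vectorised.
#' @return fitness value(s).
#' @export
host_fitness <- function(host, v) {
  if (any(v < 0)) stop("virulence must be >= 0")
  host$b * v^host$s / (host$mu + v)
}

#' Single-host optimal virulence
#'
#' The virulence maximising [host_fitness()] when this host is the sole
#' host: the closed form `v* = s * mu / (1 - s)`.
#'
#' @param host a [host_class()].
#' @return optimal virulence.
#' @export
single_host_optimum <- function(host) {
  host$s * host$mu / (1 - host$s)
}

system_fitness <- function(system, v) {
  Reduce(`+`, lapply(system$hosts,
                     function(h) h$rho * host_fitness(h, v)))
}

#' Joint optimal virulence across hosts
#'
#' The single shared virulence maximising force-of-infection-weighted
#' fitness `sum_i rho_i w_i(v)`, found by bounded scalar optimisation on
#' `[0, 2 * max_i v*_i]`. The optimum always lies between the smallest
#' and largest single-host optima: a shared strategy is an intermediate
#' compromise that is optimal on no host unless all optima coincide.
#'
#' @param system a [multi_host_system()].
#' @param tol convergence tolerance for the optimiser.
#' @return the joint optimal virulence (numeric scalar).
#' @export
joint_optimum <- function(system, tol = 1e-8) {
  stopifnot(inherits(system, "multi_host_system"))
  active <- Filter(function(h) h$rho > 0, system$hosts)
  vstar <- vapply(active, single_host_optimum, numeric(1))
  if (length(active) == 1L) return(unname(vstar))
  lo <- min(vstar); hi <- max(vstar)
  if (hi - lo < tol) return(unname(vstar[1L]))
  opt <- stats::optimize(function(v) system_fitness(system, v),
                         interval = c(0, 2 * hi), maximum = TRUE, tol = tol)
  v <- opt$maximum
  # the optimum is bracketed by the single-host optima (the weighted
  # derivative is positive below min v*, negative above max v*); clamp
  # away optimiser jitter at the boundary
  if (v < lo - 1e-6 || v > hi + 1e-6)
    stop(sprintf("optimizer left the bracket [%.6g, %.6g]: v = %.6g",
                 lo, hi, v))
  min(max(v, lo), hi)
}

#' Virulence response to host extinction
#'
#' Removes a set of host classes, renormalises the force-of-infection
#' weights over the survivors, and recomputes the joint optimum. In
#' general virulence evolves towards the optima of the remaining hosts:
#' removing the host with the highest single-host optimum lowers (or
#' leaves unchanged) the joint optimum, and vice versa.
#'
#' @param system a [multi_host_system()].
#' @param removed host ids going extinct (proper subset of the system).
#' @return list with `v_before`, `v_after` and
#'   `direction` (`"increase"`, `"decrease"` or `"unchanged"`, tolerance
#'   1e-9).
#' @export
extinction_response <- function(system, removed) {
  stopifnot(inherits(system, "multi_host_system"))
  removed <- as.character(removed)
  unknown <- setdiff(removed, names(system$hosts))
  if (length(unknown))
    stop("unknown host id(s): ", paste(unknown, collapse = ", "))
  survivors <- system$hosts[setdiff(names(system$hosts), removed)]
  if (length(survivors) == 0L) stop("all hosts removed: no survivors")
  v_before <- joint_optimum(system)
  v_after <- joint_optimum(multi_host_system(survivors))
  d <- v_after - v_before
  direction <- if (abs(d) <= 1e-9) "unchanged" else
    if (d > 0) "increase" else "decrease"
  list(v_before = v_before, v_after = v_after, direction = direction)
}
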