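fmt6 <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

# comment header recorded at the top of every CSV output: package version,
# seed, and md5 of each input file, so identical configs give byte-identical
# files and outputs are traceable to their inputs
output_header <- function(seed = NULL, inputs = character(0)) {
  h <- paste0("# coextinct ",
              as.character(utils::packageVersion("coextinct")))
  if (!is.null(seed)) h <- c(h, paste0("# seed=", seed))
  for (f in inputs)
    h <- c(h, paste0("# input ", basename(f), " md5=",
                     unname(tools::md5sum(f))))
  h
}

# atomic CSV write: header comment lines + data, assembled in memory and
# written in one call so failures leave no partial file
write_csv_with_header <- function(lines_df, file, seed = NULL,
                                  inputs = character(0)) {
  txt <- c(output_header(seed, inputs),
           paste(names(lines_df), collapse = ","),
           do.call(paste, c(unname(lines_df), sep = ",")))
  writeLines(txt, file)
  invisible(file)
}

#' Write an ED table as CSV
#'
#' Columns `tip,ed`, 6 decimal places, preceded by a comment header
#' recording package version, seed and input hashes.
#'
#' @param ed named numeric vector from [ed_equal_splits()] or
#'   [ed_fair_proportion()].
#' @param file output path.
#' @param seed,inputs recorded in the header.
#' @export
write_ed_table <- function(ed, file, seed = NULL, inputs = character(0)) {
  write_csv_with_header(
    data.frame(tip = names(ed), ed = fmt6(unname(ed))),
    file, seed, inputs)
}

#' Write a specificity table as CSV
#'
#' Columns `parasite,host_richness,mpd,state`.
#'
#' @param tab data frame from [specificity_table()].
#' @param file output path.
#' @param seed,inputs recorded in the header.
#' @export
write_specificity_csv <- function(tab, file, seed = NULL,
                                  inputs = character(0)) {
  write_csv_with_header(
    data.frame(parasite = tab$parasite,
               host_richness = tab$host_richness,
               mpd = fmt6(tab$mpd), state = tab$state),
    file, seed, inputs)
}

#' Write a trajectory as long-format CSV
#'
#' Columns `step,parasite,host_richness,mpd,state,delta_mpd`.
#'
#' @param traj an `extinction_trajectory` from [run_scenario()].
#' @param file output path.
#' @param seed,inputs recorded in the header.
#' @export
write_trajectory_csv <- function(traj, file, seed = NULL,
                                 inputs = character(0)) {
  st <- traj$steps
  write_csv_with_header(
    data.frame(step = st$step, parasite = st$parasite,
               host_richness = st$host_richness, mpd = fmt6(st$mpd),
               state = st$state, delta_mpd = fmt6(st$delta_mpd)),
    file, seed, inputs)
}

#' Serialise / read an extinction scenario as JSON
#'
#' @param scenario an [extinction_scenario()].
#' @param file path.
#' @return `read_scenario_json()` returns an `extinction_scenario`.
#' @export
write_scenario_json <- function(scenario, file) {
  stopifnot(inherits(scenario, "extinction_scenario"))
  obj <- list(provenance = scenario$provenance,
              seed = scenario$seed,
              events = lapply(scenario$events, as.list))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(file) {
  if (!file.exists(file)) stop("scenario file not found: ", file)
  obj <- jsonlite::read_json(file)
  extinction_scenario(lapply(obj$events, function(e) unlist(e, use.names = FALSE)),
                      provenance = obj$provenance,
                      seed = if (is.null(obj$seed)) NULL else
                        as.integer(obj$seed))
}

#' Read / write a multi-host virulence system as JSON
#'
#' Format: `{"hosts": [{"id", "rho", "mu", "b", "s"}, ...]}`.
#'
#' @param file path.
#' @param system a [multi_host_system()].
#' @return `read_virulence_system()` returns a `multi_host_system`.
#' @export
read_virulence_system <- function(file) {
  if (!file.exists(file)) stop("system file not found: ", file)
  obj <- jsonlite::read_json(file)
  if (is.null(obj$hosts) || length(obj$hosts) == 0L)
    stop("system JSON must contain a non-empty 'hosts' array")
  multi_host_system(lapply(obj$hosts, function(h)
    host_class(h$id, h$rho, h$mu,
               b = if (is.null(h$b)) 1 else h$b,
               s = if (is.null(h$s)) 0.5 else h$s)))
}

#' @rdname read_virulence_system
#' @export
write_virulence_system <- function(system, file) {
  stopifnot(inherits(system, "multi_host_system"))
  obj <- list(hosts = lapply(unname(system$hosts), function(h)
    h[c("id", "rho", "mu", "b", "s")]))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
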